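test_that("identical groups give null results exactly", {
  counts <- matrix(rep(c(5L, 9L, 14L, 20L), each = 8L), nrow = 4L,
                   byrow = TRUE,
                   dimnames = list(paste0("f", 1:4), paste0("s", 1:8)))
  lib <- rep(1000, 8L)
  grp <- rep(c("CTCT", "CTPR"), each = 4L)
  de <- de_trf(counts, lib, grp)
  expect_equal(de$CTPR$log2fc, rep(0, 4L), tolerance = 1e-8)
  expect_equal(de$CTPR$p, rep(1, 4L), tolerance = 1e-8)
})

test_that("offsets make the test invariant to library size scaling", {
  set.seed(1)
  counts <- matrix(rnbinom(40 * 8, mu = 50, size = 5), nrow = 40,
                   dimnames = list(paste0("f", 1:40), paste0("s", 1:8)))
  lib <- rep(10000, 8L)
  grp <- rep(c("CTCT", "CTPR"), each = 4L)
  base <- de_trf(counts, lib, grp)
  # double the non-reference group's counts and library sizes together
  counts2 <- counts
  counts2[, grp == "CTPR"] <- counts2[, grp == "CTPR"] * 2L
  lib2 <- lib
  lib2[grp == "CTPR"] <- lib2[grp == "CTPR"] * 2L
  scaled <- de_trf(counts2, lib2, grp)
  expect_equal(scaled$CTPR$log2fc, base$CTPR$log2fc, tolerance = 1e-6)
  # a pure doubling of one group's counts shifts every log2FC by +1
  # (with equal library sizes within groups the group rate is the mean,
  # independent of the dispersion, so the shift is exact)
  counts3 <- counts
  counts3[, grp == "CTPR"] <- counts3[, grp == "CTPR"] * 2L
  fc <- de_trf(counts3, lib, grp)
  expect_equal(fc$CTPR$log2fc - base$CTPR$log2fc, rep(1, 40L),
               tolerance = 1e-6)
})

test_that("null simulation keeps raw p approximately uniform", {
  sim <- simulate_smallrna(null_srna_config(seed = 19L, de_fraction = 0,
                                            n_fragments = 400L))
  keep <- sim$profiles$group %in% c("CTCT", "CTPR")
  de <- de_trf(sim$trf_counts[, keep], sim$trf_lib_sizes[keep],
               sim$profiles$group[keep])
  frac <- mean(de$CTPR$p < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
  # BH adjustment is monotone in raw p
  o <- order(de$CTPR$p)
  expect_true(all(diff(de$CTPR$p_adj[o]) >= -1e-12))
})

test_that("perturbed fragments dominate the small p-values", {
  hits <- vapply(1:6, function(s) {
    sim <- simulate_smallrna(null_srna_config(
      seed = 300L + s, de_fraction = 0.1, de_log2fc = 2,
      n_fragments = 100L, reads_per_sample = 20000L))
    keep <- sim$profiles$group %in% c("CTCT", "CTPR")
    de <- de_trf(sim$trf_counts[, keep], sim$trf_lib_sizes[keep],
                 sim$profiles$group[keep])$CTPR
    pert <- sim$trf_perturbed[de$fragment]
    median(de$p[pert]) < median(de$p[!pert])
  }, logical(1))
  # sign test over seeds: all 6 of 6 gives binomial p = 2^-6 < 0.02
  expect_true(all(hits))
})

test_that("dispersion estimator recovers the simulated NB dispersion", {
  sim <- simulate_smallrna(null_srna_config(seed = 23L, de_fraction = 0,
                                            nb_dispersion = 0.2))
  phi <- estimate_common_dispersion(sim$trf_counts, sim$trf_lib_sizes,
                                    sim$profiles$group)
  expect_gt(phi, 0.1)
  expect_lt(phi, 0.35)
  # Poisson data push the estimate towards the floor
  simp <- simulate_smallrna(null_srna_config(seed = 24L, de_fraction = 0,
                                             nb_dispersion = 0))
  phip <- estimate_common_dispersion(simp$trf_counts, simp$trf_lib_sizes,
                                     simp$profiles$group)
  expect_lt(phip, 0.02)
})

test_that("group effect ranking agrees with an edgeR quasi-likelihood fit", {
  skip_if_not_installed("edgeR")
  sim <- simulate_smallrna(null_srna_config(seed = 29L, de_fraction = 0.15,
                                            de_log2fc = 2,
                                            n_fragments = 80L))
  keep <- sim$profiles$group %in% c("CTCT", "CTPR")
  grp <- factor(sim$profiles$group[keep], levels = c("CTCT", "CTPR"))
  de <- de_trf(sim$trf_counts[, keep], sim$trf_lib_sizes[keep], grp)$CTPR
  dge <- edgeR::DGEList(counts = sim$trf_counts[, keep],
                        lib.size = sim$trf_lib_sizes[keep],
                        group = grp)
  design <- model.matrix(~grp)
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmQLFit(dge, design)
  qlf <- edgeR::glmQLFTest(fit, coef = 2)
  tt <- qlf$table[de$fragment, ]
  expect_gt(cor(de$log2fc, tt$logFC), 0.98)
  expect_gt(cor(rank(de$p), rank(tt$PValue)), 0.9)
})
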