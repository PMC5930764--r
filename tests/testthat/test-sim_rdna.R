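test_that("degenerate mixture and forced-methylation configurations", {
  ref <- synthetic_rdna_ref()
  sim <- simulate_rdna_reads(ref, rdna_sim_config(
    n_reads = 50L, pct_a = 100, seq_error_rate = 0, seed = 1L))
  expect_true(all(substr(sim$reads, ref$variant_pos, ref$variant_pos) == "A"))
  expect_equal(sim$truth$pct_a, 100)

  sim2 <- simulate_rdna_reads(ref, rdna_sim_config(
    n_reads = 50L, meth_rate_a = 1, meth_rate_c = 1, conversion_rate = 1,
    seq_error_rate = 0, seed = 2L))
  p133 <- ref$cpg_pos[match(-133L, ref$cpg_offsets)]
  expect_true(all(substr(sim2$reads, p133, p133) == "C"))

  sim0 <- simulate_rdna_reads(ref, rdna_sim_config(n_reads = 0L, seed = 1L))
  expect_length(sim0$reads, 0L)
  expect_equal(sim0$truth$a_meth, 0L)
})

test_that("simulation is deterministic given the seed", {
  ref <- synthetic_rdna_ref()
  cfg <- rdna_sim_config(n_reads = 200L, seed = 42L)
  expect_identical(simulate_rdna_reads(ref, cfg)$reads,
                   simulate_rdna_reads(ref, cfg)$reads)
  cfg2 <- rdna_sim_config(n_reads = 200L, seed = 43L)
  expect_false(identical(simulate_rdna_reads(ref, cfg)$reads,
                         simulate_rdna_reads(ref, cfg2)$reads))
})

test_that("caller is an exact inverse of the noise-free generator", {
  ref <- synthetic_rdna_ref()
  sim <- simulate_rdna_reads(ref, rdna_sim_config(
    n_reads = 5000L, pct_a = 60, meth_rate_a = 0.5, meth_rate_c = 0.1,
    conversion_rate = 1, seq_error_rate = 0, seed = 7L))
  tab <- tabulate_reads(sim$reads, ref)
  expect_equal(tab$a_meth, sim$truth$a_meth)
  expect_equal(tab$a_unmeth, sim$truth$a_unmeth)
  expect_equal(tab$c_meth, sim$truth$c_meth)
  expect_equal(tab$c_unmeth, sim$truth$c_unmeth)
  expect_equal(sum(tab$discarded), 0L)
  s <- summarize_rdna(tab)
  expect_equal(s$pct_a, sim$truth$pct_a)
  expect_equal(s$a_meth_pct, 100 * sim$truth$meth_rate_a)
})

test_that("invalid probabilities are rejected at configuration time", {
  expect_error(rdna_sim_config(pct_a = 130), "pct_a")
  expect_error(rdna_sim_config(meth_rate_a = -0.1), "meth_rate_a")
  expect_error(rdna_sim_config(conversion_rate = 1.2), "conversion_rate")
  expect_error(rdna_sim_config(n_reads = -5), "n_reads")
})

test_that("expected A methylation is monotone in the simulated rate", {
  ref <- synthetic_rdna_ref()
  grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  means <- vapply(grid, function(rate) {
    est <- vapply(1:3, function(s) {
      sim <- simulate_rdna_reads(ref, rdna_sim_config(
        n_reads = 2000L, meth_rate_a = rate, conversion_rate = 1,
        seq_error_rate = 0, seed = 100L + s))
      summarize_rdna(tabulate_reads(sim$reads, ref))$a_meth_pct
    }, numeric(1))
    mean(est)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("allele mixture is symmetric under label exchange", {
  ref <- synthetic_rdna_ref()
  s1 <- summarize_rdna(tabulate_reads(simulate_rdna_reads(ref,
    rdna_sim_config(n_reads = 20000L, pct_a = 70, meth_rate_a = 0.6,
                    meth_rate_c = 0.2, conversion_rate = 1,
                    seq_error_rate = 0, seed = 11L))$reads, ref))
  s2 <- summarize_rdna(tabulate_reads(simulate_rdna_reads(ref,
    rdna_sim_config(n_reads = 20000L, pct_a = 30, meth_rate_a = 0.2,
                    meth_rate_c = 0.6, conversion_rate = 1,
                    seq_error_rate = 0, seed = 12L))$reads, ref))
  # mirrored mixture: %A swaps to 100 - %A and the per-allele methylation
  # summaries exchange, up to binomial noise at n = 20000
  expect_lt(abs(s1$pct_a - (100 - s2$pct_a)), 1.5)
  expect_lt(abs(s1$a_meth_pct - s2$c_meth_pct), 2.5)
  expect_lt(abs(s1$c_meth_pct - s2$a_meth_pct), 2.5)
})

test_that("FASTQ round trip preserves reads", {
  ref <- synthetic_rdna_ref()
  sim <- simulate_rdna_reads(ref, rdna_sim_config(n_reads = 25L, seed = 3L))
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq))
  write_fastq(sim$reads, fq)
  back <- read_fastq(fq)
  expect_equal(unname(back), sim$reads)
  lines <- readLines(fq)
  expect_equal(substr(lines[1], 1, 1), "@")
  expect_true(all(strsplit(lines[4], "")[[1]] == "I"))
})
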