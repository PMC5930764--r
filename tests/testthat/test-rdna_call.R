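test_that("single reads receive the correct joint call", {
  cases <- list(
    list(read = "GATCGA", variant = "A", meth = "methylated"),
    list(read = "GATTGA", variant = "A", meth = "unmethylated"),
    list(read = "GTTTGA", variant = "C", meth = "unmethylated"),
    list(read = "GCTCGA", variant = "C", meth = "methylated"))
  for (cs in cases) {
    cl <- toy_call(cs$read)
    expect_equal(cl$status, "accepted", info = cs$read)
    expect_equal(cl$variant, cs$variant, info = cs$read)
    expect_equal(cl$meth, cs$meth, info = cs$read)
  }
  # disallowed base inside the anchor is a consensus mismatch, not a
  # wrong start (the read is still clearly anchored)
  bad <- toy_call("GGTCGA")
  expect_equal(bad$status, "discarded")
  expect_equal(bad$reason, "consensus_mismatch")
  # a read that does not cover the variant/CpG span is too short
  expect_equal(toy_call("GAT")$reason, "too_short")
  # a read from elsewhere fails the start anchor wholesale
  expect_equal(toy_call("TCGGAT")$reason, "wrong_start")
})

test_that("T at a CpG-context variant is ambiguous and discarded", {
  ref <- toy_ref(variant_is_cpg_context = TRUE)
  cl <- call_read("GTTTGA", ref, meth_offset = -102L)
  expect_equal(cl$reason, "ambiguous_variant")
  # A and C calls unaffected
  expect_equal(call_read("GATCGA", ref, meth_offset = -102L)$variant, "A")
  expect_equal(call_read("GCTCGA", ref, meth_offset = -102L)$variant, "C")
})

test_that("tabulation counts classes and conserves reads", {
  reads <- c(rep("GATCGA", 3), rep("GATTGA", 2))
  tab <- toy_tab(reads)
  expect_equal(tab$a_meth, 3L)
  expect_equal(tab$a_unmeth, 2L)
  expect_equal(tab$c_meth + tab$c_unmeth, 0L)
  expect_equal(tab$accepted + sum(tab$discarded), tab$total)

  tab2 <- toy_tab("GGTCGA")
  expect_equal(tab2$accepted, 0L)
  expect_equal(unname(tab2$discarded["consensus_mismatch"]), 1L)

  tab0 <- toy_tab(character(0))
  expect_equal(tab0$total, 0L)
  expect_equal(tab0$accepted, 0L)
})

test_that("tabulation agrees with per-read calls on mixed input", {
  ref <- synthetic_rdna_ref()
  sim <- simulate_rdna_reads(ref, rdna_sim_config(n_reads = 300L, seed = 5L))
  tab <- tabulate_reads(sim$reads, ref)
  tpl <- converted_templates(ref)
  acc <- vapply(sim$reads, function(r)
    call_read(r, ref, templates = tpl)$status == "accepted", logical(1))
  expect_equal(tab$accepted, sum(acc))
  expect_equal(tab$accepted + sum(tab$discarded), 300L)
})

test_that("summary arithmetic and division guards", {
  mk <- function(am, au, cm, cu) {
    reads <- c(rep("GATCGA", am), rep("GATTGA", au),
               rep("GCTCGA", cm), rep("GTTTGA", cu))
    toy_tab(reads)
  }
  s <- summarize_rdna(mk(30, 30, 20, 20), min_reads = 10L)
  expect_equal(s$pct_a, 60)
  expect_equal(s$a_meth_pct, 50)
  expect_equal(s$c_meth_pct, 50)
  expect_equal(s$ratio_a_to_c, 1.5)

  s2 <- summarize_rdna(mk(0, 0, 5, 5), min_reads = 5L)
  expect_true(is.na(s2$a_meth_pct))
  expect_equal(s2$pct_a, 0)

  s3 <- summarize_rdna(mk(1, 0, 0, 0), min_reads = 1L)
  expect_equal(s3$pct_a, 100)
  expect_true(is.na(s3$ratio_a_to_c))

  expect_error(summarize_rdna(mk(3, 3, 3, 3), min_reads = 100L,
                              sample = "m1"), "m1")
})

test_that("purity score is the complement of mean absolute deviation", {
  expect_equal(purity_score(c(0, 1, 0, 1), c(0, 1, 0, 1))$score, 1)
  expect_equal(purity_score(rep(0.5, 4), c(0, 1, 0, 1))$score, 0.5)
  expect_equal(purity_score(c(0.1, 0.9), c(0, 1))$score, 0.9)
  expect_error(purity_score(numeric(0), numeric(0)), "at least one")
})
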