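# Tiny amplicon used throughout: "GATCGA" with the variant at string
# position 2 (offset -104 with the TSS placed at 106) and a single CpG at
# position 4 (offset -102). Mirrors the geometry of the rDNA assay at toy
# scale.
toy_ref <- function(...) {
  amplicon_ref(name = "toy", sequence = "GATCGA", tss_pos = 106L,
               variant_offset = -104L, cpg_offsets = -102L, ...)
}

toy_call <- function(read, ref = toy_ref(), ...) {
  call_read(read, ref, meth_offset = -102L, ...)
}

toy_tab <- function(reads, ref = toy_ref(), ...) {
  tabulate_reads(reads, ref, meth_offset = -102L, ...)
}

# Independent Fisher oracle: brute-force table probability via explicit
# factorial products (no shared code with fisher_exact_rxc).
oracle_table_prob <- function(cells, rm, cm) {
  n <- sum(rm)
  exp(sum(lfactorial(rm)) + sum(lfactorial(cm)) - lfactorial(n) -
        sum(lfactorial(cells)))
}

oracle_fisher_2x2 <- function(tab) {
  rm <- rowSums(tab); cm <- colSums(tab)
  p_obs <- oracle_table_prob(as.vector(tab), rm, cm)
  p <- 0
  for (a in 0:min(rm[1], cm[1])) {
    cells <- c(a, cm[1] - a, rm[1] - a, rm[2] - cm[1] + a)
    if (any(cells < 0)) next
    pr <- oracle_table_prob(cells, rm, cm)
    if (pr <= p_obs * (1 + 1e-7)) p <- p + pr
  }
  min(1, p)
}

oracle_fisher_2x3 <- function(tab) {
  rm <- rowSums(tab); cm <- colSums(tab)
  p_obs <- oracle_table_prob(as.vector(tab), rm, cm)
  p <- 0
  for (a in 0:min(rm[1], cm[1])) {
    for (b in 0:min(rm[1] - a, cm[2])) {
      cc <- rm[1] - a - b
      cells <- c(a, b, cc, cm[1] - a, cm[2] - b, cm[3] - cc)
      if (any(cells < 0) || cc > cm[3]) next
      pr <- oracle_table_prob(cells, rm, cm)
      if (pr <= p_obs * (1 + 1e-7)) p <- p + pr
    }
  }
  min(1, p)
}

# equal-composition small RNA config: a genuine global null for DE
null_srna_config <- function(...) {
  pr <- default_ribostress_proportions()
  srna_sim_config(class_proportions = list(CTCT = pr, CTPR = pr,
                                           PRCT = pr, PRPR = pr), ...)
}

default_ribostress_proportions <- function() {
  sim <- srna_sim_config(seed = 1L)
  sim$class_proportions$CTCT
}
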