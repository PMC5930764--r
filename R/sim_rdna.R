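#' Configuration for the bisulfite amplicon read simulator
#'
#' Parameters of the generative model inverted by the calling machinery:
#' each read draws an allele (A with probability `pct_a/100`), then a
#' methylation state at every assayed CpG (the -133 CpG rate depends on
#' the allele), then bisulfite chemistry (unmethylated C reads T with
#' probability `conversion_rate`; methylated C reads T with probability
#' `inappropriate_conversion`), and finally uniform substitution
#' sequencing errors.
#'
#' @param n_reads Number of reads (default 20000).
#' @param pct_a Percentage of rDNA copies carrying A at the variant
#'   (0-100; default 70).
#' @param meth_rate_a,meth_rate_c Per-read probability that an A- (resp.
#'   C-) allele read is methylated at the assayed CpG (-133).
#' @param other_cpg_meth_rates Named numeric vector, TSS-relative offset ->
#'   methylation probability, for the remaining assayed CpGs. Unlisted
#'   CpGs default to 0.2.
#' @param conversion_rate Bisulfite conversion efficiency (default 0.995).
#' @param inappropriate_conversion Probability a methylated C reads T
#'   (default 0).
#' @param seq_error_rate Per-base substitution probability (default 0.001).
#' @param read_length Read length in bp (default 150, MiSeq-like); capped
#'   at the amplicon length.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `rdna_sim_config`.
#' @export
rdna_sim_config <- function(n_reads = 20000L, pct_a = 70,
                            meth_rate_a = 0.3, meth_rate_c = 0.1,
                            other_cpg_meth_rates = NULL,
                            conversion_rate = 0.995,
                            inappropriate_conversion = 0,
                            seq_error_rate = 0.001,
                            read_length = 150L, seed = NULL) {
  check_count(n_reads, "n_reads")
  check_prob(pct_a, "pct_a", 0, 100)
  check_prob(meth_rate_a, "meth_rate_a")
  check_prob(meth_rate_c, "meth_rate_c")
  check_prob(conversion_rate, "conversion_rate")
  check_prob(inappropriate_conversion, "inappropriate_conversion")
  check_prob(seq_error_rate, "seq_error_rate")
  if (!is.null(other_cpg_meth_rates)) {
    check_prob(other_cpg_meth_rates, "other_cpg_meth_rates")
  }
  check_count(read_length, "read_length", min = 1L)
  structure(list(n_reads = as.integer(n_reads), pct_a = pct_a,
                 meth_rate_a = meth_rate_a, meth_rate_c = meth_rate_c,
                 other_cpg_meth_rates = other_cpg_meth_rates,
                 conversion_rate = conversion_rate,
                 inappropriate_conversion = inappropriate_conversion,
                 seq_error_rate = seq_error_rate,
                 read_length = as.integer(read_length), seed = seed),
            class = "rdna_sim_config")
}

#' Simulate bisulfite amplicon reads
#'
#' Generates single-end top-strand bisulfite reads that start exactly at
#' the amplicon start, following the model described in
#' [rdna_sim_config()]. The realised per-read truth (allele and -133
#' methylation state before chemistry and errors) is tallied so callers
#' can be validated as exact inverses in the noise-free regime.
#'
#' @param ref An [amplicon_ref()].
#' @param cfg An [rdna_sim_config()].
#' @return A list of class `rdna_sim`: `reads` (character vector),
#'   `truth` (list with realised `a_meth`, `a_unmeth`, `c_meth`,
#'   `c_unmeth` tallies and realised `pct_a`, `meth_rate_a`,
#'   `meth_rate_c`), and the `config` used.
#' @export
simulate_rdna_reads <- function(ref, cfg = rdna_sim_config()) {
  stopifnot(inherits(ref, "amplicon_ref"), inherits(cfg, "rdna_sim_config"))
  n <- cfg$n_reads
  L <- min(cfg$read_length, nchar(ref$sequence))
  if (L < max(ref$variant_pos, max(ref$cpg_pos))) {
    warning("read_length does not cover all assayed positions")
  }
  bases <- ref$bases[seq_len(L)]
  if (n == 0L) {
    return(structure(list(
      reads = character(0),
      truth = list(a_meth = 0L, a_unmeth = 0L, c_meth = 0L, c_unmeth = 0L,
                   pct_a = NA_real_, meth_rate_a = NA_real_,
                   meth_rate_c = NA_real_),
      config = cfg), class = "rdna_sim"))
  }
  with_seed(cfg$seed, {
    m <- matrix(rep(bases, each = n), nrow = n)
    is_a <- runif(n) < cfg$pct_a / 100
    a1 <- ref$variant_alleles[1]; a2 <- ref$variant_alleles[2]
    if (ref$variant_pos <= L) m[, ref$variant_pos] <- ifelse(is_a, a1, a2)
    # methylation state per assayed CpG; -133 is allele-dependent
    meth133 <- logical(n)
    cpg_rate <- function(off) {
      r <- cfg$other_cpg_meth_rates
      if (!is.null(r) && as.character(off) %in% names(r)) {
        r[[as.character(off)]]
      } else 0.2
    }
    meth_mat <- matrix(FALSE, n, length(ref$cpg_pos))
    for (j in seq_along(ref$cpg_pos)) {
      off <- ref$cpg_offsets[j]
      if (off == -133L) {
        rate <- ifelse(is_a, cfg$meth_rate_a, cfg$meth_rate_c)
        meth_mat[, j] <- runif(n) < rate
        meth133 <- meth_mat[, j]
      } else {
        meth_mat[, j] <- runif(n) < cpg_rate(off)
      }
    }
    # bisulfite chemistry at every cytosine of the template
    for (p in which(bases == "C")) {
      if (p == ref$variant_pos) next
      j <- match(p, ref$cpg_pos)
      if (!is.na(j)) {
        meth <- meth_mat[, j]
        to_t <- ifelse(meth, runif(n) < cfg$inappropriate_conversion,
                       runif(n) < cfg$conversion_rate)
      } else {
        to_t <- runif(n) < cfg$conversion_rate   # non-CpG C: unmethylated
      }
      m[to_t, p] <- "T"
    }
    # C alleles at a non-CpG-context variant are unmethylated cytosines
    if (ref$variant_pos <= L) {
      cv <- !is_a & m[, ref$variant_pos] == "C"
      if (!ref$variant_is_cpg_context && any(cv)) {
        to_t <- cv & runif(n) < cfg$conversion_rate
        m[to_t, ref$variant_pos] <- "T"
      }
    }
    if (cfg$seq_error_rate > 0) {
      err <- matrix(runif(n * L) < cfg$seq_error_rate, n, L)
      if (any(err)) {
        idx <- which(err)
        cur <- m[idx]
        alts <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                       nrow = 3,
                       dimnames = list(NULL, c("A", "C", "G", "T")))
        pick <- sample.int(3L, length(idx), replace = TRUE)
        m[idx] <- alts[cbind(pick, match(cur, colnames(alts)))]
      }
    }
    reads <- do.call(paste0, lapply(seq_len(L), function(j) m[, j]))
    n_a <- sum(is_a)
    truth <- list(
      a_meth = sum(is_a & meth133), a_unmeth = sum(is_a & !meth133),
      c_meth = sum(!is_a & meth133), c_unmeth = sum(!is_a & !meth133),
      pct_a = 100 * n_a / n,
      meth_rate_a = if (n_a > 0) mean(meth133[is_a]) else NA_real_,
      meth_rate_c = if (n_a < n) mean(meth133[!is_a]) else NA_real_)
    structure(list(reads = reads, truth = truth, config = cfg),
              class = "rdna_sim")
  })
}

#' Write reads to a FASTQ file
#'
#' Writes a character vector of reads as Phred+33 FASTQ with constant
#' quality 'I' (Q40), via Biostrings.
#'
#' @param reads Character vector of read sequences.
#' @param path Output file path.
#' @param ids Read identifiers (default `read_1`, `read_2`, ...).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  ids <- ids %||% paste0("read_", seq_along(reads))
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- ids
  qual <- Biostrings::PhredQuality(vapply(nchar(reads), function(n)
    strrep("I", n), character(1)))
  qs <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read sequences from a FASTQ file
#'
#' @param path FASTQ file path.
#' @return Character vector of read sequences, named by read id.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dna), names(dna))
}
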