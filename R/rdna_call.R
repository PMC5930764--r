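#' Call allele and CpG methylation state for one bisulfite read
#'
#' Classifies a single-end, top-strand bisulfite read that is expected to
#' start at the first base of the amplicon. A read is accepted only when
#' every base agrees with the bisulfite-converted consensus (see
#' [converted_templates()]); it then receives a joint call: allele at the
#' variant position (A or C for the default rDNA assay) and methylation
#' state at the assayed CpG of interest (default the -133 CpG).
#'
#' Discard reasons, in order of precedence:
#' \describe{
#'   \item{too_short}{the read does not cover both the variant and the
#'     assayed CpG;}
#'   \item{wrong_start}{more than a third of the first `anchor_len` bases
#'     disagree with the consensus, i.e. the read is not anchored at the
#'     amplicon start (isolated disallowed bases are treated as consensus
#'     mismatches instead);}
#'   \item{consensus_mismatch}{any disallowed base anywhere in the read;}
#'   \item{ambiguous_variant}{a T at the variant site when the C allele
#'     lies in CpG context (`variant_is_cpg_context = TRUE`), where the
#'     converted state cannot be attributed to one allele;}
#'   \item{ambiguous_meth}{an unexpected base at the assayed CpG.}
#' }
#' A T at the variant site is called as the C allele when the variant is
#' not in CpG context: a non-CpG cytosine is unmethylated and reads T
#' after conversion.
#'
#' @param read Read sequence (character scalar).
#' @param ref An [amplicon_ref()].
#' @param strict_mismatch If `TRUE` (default), non-CpG cytosines must read
#'   T; if `FALSE`, residual unconverted C is tolerated.
#' @param anchor_len Number of leading bases used for the start check
#'   (default 12).
#' @param meth_offset TSS-relative position of the assayed CpG used for
#'   the joint call (default -133); must be one of `ref$cpg_offsets`.
#' @param templates Optional precomputed [converted_templates()] result
#'   (avoids recomputation in tight loops).
#'
#' @return A list of class `read_call`: `status` ("accepted"/"discarded"),
#'   `reason` (NA or a discard reason), `variant` ("A"/"C"/NA),
#'   `meth` ("methylated"/"unmethylated"/NA).
#' @export
call_read <- function(read, ref, strict_mismatch = TRUE, anchor_len = 12L,
                      meth_offset = -133L, templates = NULL) {
  stopifnot(inherits(ref, "amplicon_ref"), is.character(read),
            length(read) == 1L, nzchar(read))
  if (!meth_offset %in% ref$cpg_offsets) {
    stop("meth_offset ", meth_offset, " is not an assayed CpG of this amplicon")
  }
  if (is.null(templates)) templates <- converted_templates(ref, strict_mismatch)
  meth_pos <- ref$cpg_pos[match(meth_offset, ref$cpg_offsets)]
  rb <- strsplit(toupper(read), "", fixed = TRUE)[[1]]
  call_read_impl(rb, ref, templates$allowed, anchor_len, meth_pos)
}

call_read_impl <- function(rb, ref, allowed, anchor_len, meth_pos) {
  out <- function(status, reason = NA_character_, variant = NA_character_,
                  meth = NA_character_) {
    structure(list(status = status, reason = reason, variant = variant,
                   meth = meth), class = "read_call")
  }
  len <- length(rb)
  if (len < max(ref$variant_pos, meth_pos)) return(out("discarded", "too_short"))
  span <- seq_len(min(len, length(allowed)))
  ok <- vapply(span, function(i) rb[i] %in% allowed[[i]], logical(1))
  k <- min(anchor_len, len)
  if (sum(!ok[seq_len(k)]) > k / 3) return(out("discarded", "wrong_start"))
  if (!all(ok)) return(out("discarded", "consensus_mismatch"))
  vb <- rb[ref$variant_pos]
  al <- ref$variant_alleles
  variant <- if (vb == al[1]) {
    al[1]
  } else if (vb == al[2]) {
    al[2]
  } else if (vb == "T" && al[2] == "C" && !ref$variant_is_cpg_context) {
    "C"
  } else {
    NA_character_
  }
  if (is.na(variant)) return(out("discarded", "ambiguous_variant"))
  mb <- rb[meth_pos]
  meth <- switch(mb, C = "methylated", T = "unmethylated", NA_character_)
  if (is.na(meth)) return(out("discarded", "ambiguous_meth"))
  out("accepted", variant = variant, meth = meth)
}

#' Tabulate joint allele/methylation read classes
#'
#' Applies [call_read()] to every read and sums the four accepted classes
#' (A-methylated, A-unmethylated, C-methylated, C-unmethylated) plus the
#' discard reasons. Counts always conserve the input:
#' `accepted + sum(discarded) == length(reads)`.
#'
#' @param reads Character vector of read sequences (possibly empty).
#' @inheritParams call_read
#' @return A list of class `read_class_counts`: `a_meth`, `a_unmeth`,
#'   `c_meth`, `c_unmeth`, `accepted`, `discarded` (named integer vector),
#'   `total`.
#' @export
tabulate_reads <- function(reads, ref, strict_mismatch = TRUE,
                           anchor_len = 12L, meth_offset = -133L) {
  stopifnot(inherits(ref, "amplicon_ref"))
  templates <- converted_templates(ref, strict_mismatch)
  meth_pos <- ref$cpg_pos[match(meth_offset, ref$cpg_offsets)]
  if (is.na(meth_pos)) stop("meth_offset is not an assayed CpG")
  reasons <- c("wrong_start", "consensus_mismatch", "ambiguous_variant",
               "ambiguous_meth", "too_short")
  counts <- c(a_meth = 0L, a_unmeth = 0L, c_meth = 0L, c_unmeth = 0L)
  discarded <- setNames(integer(length(reasons)), reasons)
  if (length(reads)) {
    split_reads <- strsplit(toupper(reads), "", fixed = TRUE)
    al <- ref$variant_alleles
    for (rb in split_reads) {
      cl <- call_read_impl(rb, ref, templates$allowed, anchor_len, meth_pos)
      if (cl$status == "accepted") {
        key <- paste0(if (cl$variant == al[1]) "a" else "c",
                      if (cl$meth == "methylated") "_meth" else "_unmeth")
        counts[key] <- counts[key] + 1L
      } else {
        discarded[cl$reason] <- discarded[cl$reason] + 1L
      }
    }
  }
  structure(list(a_meth = counts[["a_meth"]], a_unmeth = counts[["a_unmeth"]],
                 c_meth = counts[["c_meth"]], c_unmeth = counts[["c_unmeth"]],
                 accepted = sum(counts), discarded = discarded,
                 total = length(reads)),
            class = "read_class_counts")
}

#' @export
print.read_class_counts <- function(x, ...) {
  cat(sprintf("read classes: A-meth %d, A-unmeth %d, C-meth %d, C-unmeth %d\n",
              x$a_meth, x$a_unmeth, x$c_meth, x$c_unmeth))
  cat(sprintf("  accepted %d / %d; discarded: %s\n", x$accepted, x$total,
              paste(names(x$discarded), x$discarded, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Per-sample rDNA promoter summary
#'
#' Reduces the four-way read class counts to the per-sample quantities of
#' the assay: `pct_a`, the percentage of accepted reads carrying the A
#' allele; `a_meth_pct`, the percentage of A reads methylated at the
#' assayed CpG (`100 * a_meth / (a_meth + a_unmeth)`); `c_meth_pct`, the
#' analogue for C reads; and `ratio_a_to_c`, the raw abundance ratio
#' `(a_meth + a_unmeth) / (c_meth + c_unmeth)`. Undefined quantities
#' (empty denominator) are reported as `NA`.
#'
#' @param counts A `read_class_counts` object from [tabulate_reads()].
#' @param min_reads Minimum accepted reads required (default 100); fewer
#'   raises a coverage error naming the sample.
#' @param sample Sample label used in messages (default "sample").
#' @return A list of class `rdna_summary` with fields `pct_a`,
#'   `a_meth_pct`, `c_meth_pct`, `ratio_a_to_c`, `n_accepted`.
#' @export
summarize_rdna <- function(counts, min_reads = 100L, sample = "sample") {
  stopifnot(inherits(counts, "read_class_counts"))
  acc <- counts$accepted
  if (acc < min_reads) {
    stop(sprintf("sample '%s': %d accepted reads, below min_reads = %d",
                 sample, acc, as.integer(min_reads)), call. = FALSE)
  }
  a <- counts$a_meth + counts$a_unmeth
  cc <- counts$c_meth + counts$c_unmeth
  structure(list(
    pct_a = 100 * a / acc,
    a_meth_pct = if (a > 0) 100 * counts$a_meth / a else NA_real_,
    c_meth_pct = if (cc > 0) 100 * counts$c_meth / cc else NA_real_,
    ratio_a_to_c = if (cc > 0) a / cc else NA_real_,
    n_accepted = acc), class = "rdna_summary")
}

#' Sperm purity score from imprinting control region methylation
#'
#' Imprinting control regions are fully unmethylated in sperm when
#' maternally methylated (expected fraction 0) and fully methylated when
#' paternally methylated (expected 1), so the mean absolute deviation of
#' the observed methylation fractions from expectation measures somatic
#' contamination. The score is `1 - mean(|observed - expected|)`, i.e. 1
#' for perfectly pure sperm.
#'
#' @param observed Numeric vector of observed methylation fractions in
#'   \[0, 1\], one per imprinted amplicon.
#' @param expected Numeric vector of expected sperm fractions (0 or 1
#'   typically), same length.
#' @param amplicons Optional amplicon names (e.g. MEST, MCTS2, NESP,
#'   IGF2/H19).
#' @return A list: `score` in \[0, 1\] and a `deviations` data frame.
#' @export
purity_score <- function(observed, expected,
                         amplicons = names(observed) %||%
                           paste0("amplicon", seq_along(observed))) {
  if (!length(observed)) stop("purity_score needs at least one amplicon")
  if (length(observed) != length(expected)) {
    stop("observed and expected must have the same length")
  }
  check_prob(observed, "observed")
  check_prob(expected, "expected")
  dev <- abs(observed - expected)
  list(score = 1 - mean(dev),
       deviations = data.frame(amplicon = amplicons, observed = observed,
                               expected = expected, deviation = dev,
                               row.names = NULL))
}
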