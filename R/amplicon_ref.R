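#' Amplicon reference for targeted bisulfite methylation calling
#'
#' Describes one bisulfite PCR amplicon on the genomic top strand, together
#' with the coordinates (relative to the transcription start site) of the
#' assayed CpG cytosines and of a single-base variant. The rDNA promoter
#' assay uses the A/C variant at position -104 and the functional CpG at
#' -133; positions are TSS-relative with +1 at the TSS, negative upstream,
#' and no position 0, so string position = `tss_pos + offset` for negative
#' offsets.
#'
#' @param name Identifier for the amplicon.
#' @param sequence Genomic top-strand bases (character scalar, A/C/G/T).
#' @param tss_pos 1-based position within `sequence` of the TSS (+1) base.
#'   May lie beyond the sequence end when the amplicon is entirely
#'   upstream of the TSS; only the mapped variant and CpG positions must
#'   fall inside the sequence.
#' @param variant_offset TSS-relative position of the variant base
#'   (default -104).
#' @param variant_alleles Ordered pair of alleles (default `c("A", "C")`).
#' @param cpg_offsets Integer vector of TSS-relative positions of assayed
#'   CpG cytosines (the rDNA assay includes -133).
#' @param variant_is_cpg_context Does the C allele at the variant create a
#'   CpG? Controls how a T at the variant site is interpreted (see
#'   [call_read()]). Default `FALSE`.
#'
#' @return An object of class `amplicon_ref`.
#' @seealso [synthetic_rdna_ref()], [converted_templates()], [call_read()]
#' @export
amplicon_ref <- function(name, sequence, tss_pos,
                         variant_offset = -104L,
                         variant_alleles = c("A", "C"),
                         cpg_offsets,
                         variant_is_cpg_context = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("amplicon sequence must contain only A/C/G/T")
  }
  n <- length(bases)
  check_count(tss_pos, "tss_pos", min = 1L)
  cpg_offsets <- as.integer(sort(cpg_offsets))
  variant_offset <- as.integer(variant_offset)
  if (any(c(cpg_offsets, variant_offset) == 0L)) {
    stop("TSS-relative coordinates have no position 0")
  }
  pos_of <- function(off) ifelse(off < 0L, tss_pos + off, tss_pos + off - 1L)
  vpos <- pos_of(variant_offset)
  cpos <- pos_of(cpg_offsets)
  if (vpos < 1L || vpos > n) stop("variant_offset falls outside the amplicon")
  if (any(cpos < 1L) || any(cpos > n)) {
    stop("a cpg_offset falls outside the amplicon")
  }
  bad <- cpos[bases[cpos] != "C" | c(bases, "")[cpos + 1L] != "G"]
  if (length(bad)) {
    stop("reference is not CpG (C followed by G) at offset(s): ",
         paste(cpg_offsets[match(bad, cpos)], collapse = ", "))
  }
  variant_alleles <- toupper(variant_alleles)
  if (length(variant_alleles) != 2L ||
      !all(variant_alleles %in% c("A", "C", "G", "T"))) {
    stop("variant_alleles must be two bases")
  }
  if (!bases[vpos] %in% variant_alleles) {
    stop("reference base at the variant position (", bases[vpos],
         ") is not one of the stated alleles")
  }
  if (vpos %in% cpos) stop("the variant position cannot also be an assayed CpG")
  structure(
    list(name = as.character(name), sequence = sequence, bases = bases,
         tss_pos = as.integer(tss_pos), variant_offset = variant_offset,
         variant_pos = vpos, variant_alleles = variant_alleles,
         cpg_offsets = cpg_offsets, cpg_pos = cpos,
         variant_is_cpg_context = isTRUE(variant_is_cpg_context)),
    class = "amplicon_ref")
}

#' @export
print.amplicon_ref <- function(x, ...) {
  cat(sprintf("amplicon_ref '%s': %d bp, TSS at %d\n", x$name,
              nchar(x$sequence), x$tss_pos))
  cat(sprintf("  variant %s/%s at %+d (pos %d); assayed CpGs at %s\n",
              x$variant_alleles[1], x$variant_alleles[2], x$variant_offset,
              x$variant_pos, paste(x$cpg_offsets, collapse = ", ")))
  invisible(x)
}

#' Synthetic rDNA promoter amplicon
#'
#' A deterministic, fully synthetic 180-bp stand-in for the rDNA promoter
#' amplicon: it reproduces the coordinate geometry of the real assay (an
#' A/C variant at -104 and an assayed CpG at -133, among four further CpGs
#' and several non-CpG cytosines that exercise bisulfite conversion) but
#' shares no sequence with any genome. Use it to drive the read simulator
#' and to test the calling machinery without distributing reference data.
#'
#' @param assay_cpgs TSS-relative CpG positions to assay (subset of the
#'   CpGs present; default all five).
#' @return An [amplicon_ref()] spanning positions -160..+20 (TSS at 161).
#' @export
synthetic_rdna_ref <- function(assay_cpgs = c(-145L, -133L, -120L, -89L, -50L)) {
  motif <- strsplit("TAGGATTAGTTAGGTAATGA", "")[[1]]
  bases <- rep(motif, length.out = 180L)
  tss <- 161L
  cpg_all <- c(-145L, -133L, -120L, -89L, -50L)
  for (off in cpg_all) {
    p <- tss + off
    bases[p] <- "C"
    bases[p + 1L] <- "G"
  }
  # isolated non-CpG cytosines (followed by A in the motif frame)
  for (off in c(-150L, -70L, -30L, 11L)) {
    p <- if (off < 0L) tss + off else tss + off - 1L
    bases[p] <- "C"
  }
  bases[tss - 104L] <- "A"
  seq <- paste(bases, collapse = "")
  stopifnot(!any(assay_cpgs %in% setdiff(assay_cpgs, cpg_all)))
  amplicon_ref(name = "synthetic_rdna_promoter", sequence = seq,
               tss_pos = tss, variant_offset = -104L,
               variant_alleles = c("A", "C"),
               cpg_offsets = assay_cpgs,
               variant_is_cpg_context = FALSE)
}

#' Bisulfite-converted consensus templates
#'
#' Expands an amplicon reference into per-position allowed-base sets for
#' reads from fully converted top-strand bisulfite libraries. Assayed CpG
#' cytosines may read C (methylated) or T (unmethylated); the variant
#' position admits either allele plus T (a converted C allele); every other
#' cytosine must read T in strict mode, or C/T when tolerating incomplete
#' conversion; all remaining positions admit only the reference base.
#'
#' @param ref An [amplicon_ref()].
#' @param strict If `TRUE` (default) non-CpG cytosines admit only T; if
#'   `FALSE` they admit C or T (non-conversion tolerance).
#' @return A list with `allowed` (list of character vectors, one per
#'   reference position), and the methylated/unmethylated consensus strings
#'   `meth_template` / `unmeth_template`.
#' @export
converted_templates <- function(ref, strict = TRUE) {
  stopifnot(inherits(ref, "amplicon_ref"))
  bases <- ref$bases
  n <- length(bases)
  allowed <- as.list(bases)
  meth <- unmeth <- bases
  for (i in seq_len(n)) {
    if (i == ref$variant_pos) {
      allowed[[i]] <- unique(c(ref$variant_alleles, "T"))
      next
    }
    if (bases[i] != "C") next
    if (i %in% ref$cpg_pos) {
      allowed[[i]] <- c("C", "T")
      unmeth[i] <- "T"
    } else {
      allowed[[i]] <- if (strict) "T" else c("C", "T")
      meth[i] <- unmeth[i] <- "T"
    }
  }
  list(allowed = allowed,
       meth_template = paste(meth, collapse = ""),
       unmeth_template = paste(unmeth, collapse = ""))
}
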