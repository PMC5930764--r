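DEFAULT_CLASS_PRIORITY <- c("miRNA", "tRNA", "rRNA", "Mt_tRNA", "Mt_rRNA",
                            "piRNA", "snRNA", "snoRNA", "lincRNA", "other")

#' Build a small-RNA annotation index
#'
#' Holds per-class reference sequence sets and the class priority order
#' used for sequential annotation: a read is assigned to the first class
#' (in priority order) containing a reference in which the read occurs as
#' an exact substring. tRNA references are additionally indexed with a
#' CCA-appended copy, since mature tRNAs carry a post-transcriptional
#' 3' CCA absent from the genomic sequence.
#'
#' @param class_seqs Named list; each element a named character vector of
#'   reference sequences for that class.
#' @param priority Class priority order (default miRNA, tRNA, rRNA,
#'   Mt_tRNA, Mt_rRNA, piRNA, snRNA, snoRNA, lincRNA, other); classes
#'   absent from `class_seqs` are ignored.
#' @param min_read_len,max_read_len Length window of considered reads
#'   (defaults 15 and 45); reads outside it are counted as filtered.
#' @return A list of class `annotation_index`.
#' @export
annotation_index <- function(class_seqs,
                             priority = DEFAULT_CLASS_PRIORITY,
                             min_read_len = 15L, max_read_len = 45L) {
  if (!length(class_seqs)) stop("annotation_index needs at least one class")
  if (is.null(names(class_seqs)) || anyDuplicated(names(class_seqs))) {
    stop("class_seqs must be uniquely named by class")
  }
  priority <- unique(c(priority[priority %in% names(class_seqs)],
                       setdiff(names(class_seqs), priority)))
  class_seqs <- lapply(class_seqs, function(s) {
    nm <- names(s)
    s <- toupper(as.character(s))
    names(s) <- nm %||% paste0("ref", seq_along(s))
    s
  })
  empty <- names(class_seqs)[!vapply(class_seqs, length, 0L) > 0]
  if (length(empty)) stop("empty reference set for class: ",
                          paste(empty, collapse = ", "))
  search_seqs <- class_seqs
  if ("tRNA" %in% names(search_seqs)) {
    search_seqs$tRNA <- c(search_seqs$tRNA,
                          setNames(paste0(class_seqs$tRNA, "CCA"),
                                   names(class_seqs$tRNA)))
  }
  structure(list(class_seqs = class_seqs, search_seqs = search_seqs,
                 priority = priority,
                 min_read_len = as.integer(min_read_len),
                 max_read_len = as.integer(max_read_len)),
            class = "annotation_index")
}

#' Annotate small-RNA reads by priority substring matching
#'
#' Assigns each read within the length window to the first class in
#' priority order holding a reference in which the read occurs as an
#' exact substring (no mismatches). tRNA-assigned reads are recorded as
#' fragments keyed by `(tRNA id, start, length)` with a 1-based start in
#' the (CCA-extended) reference of the first match. Unmatched reads are
#' counted as unannotated; in this simplified annotator all length-passing
#' reads count towards the genome-mapped total.
#'
#' @param reads Character vector of read sequences.
#' @param index An [annotation_index()].
#' @param sample,group Optional labels stored in the profile row.
#' @return A list of class `srna_annotation`: `profile` (one-row
#'   data.frame with per-class counts, `unannotated`,
#'   `genome_mapped_total` and `filtered`), `trf` (data.frame
#'   fragment_id/tRNA/start/length/count), `length_hist` (list per class
#'   of read-length count tables).
#' @export
annotate_reads <- function(reads, index, sample = "sample1", group = NA) {
  stopifnot(inherits(index, "annotation_index"))
  lens <- nchar(reads)
  keep <- lens >= index$min_read_len & lens <= index$max_read_len
  filtered <- sum(!keep)
  reads <- toupper(reads[keep])
  classes <- index$priority
  cls_counts <- setNames(integer(length(classes)), classes)
  unann <- 0L
  trf_keys <- character(0)
  trf_counts <- integer(0)
  len_hist <- lapply(setNames(classes, classes), function(x) integer(0))
  if (length(reads)) {
    tab <- table(reads)
    uniq <- names(tab)
    mult <- as.integer(tab)
    assigned <- rep(NA_character_, length(uniq))
    trf_key_of <- rep(NA_character_, length(uniq))
    for (i in seq_along(uniq)) {
      rd <- uniq[i]
      for (cl in classes) {
        hit <- regexpr(rd, index$search_seqs[[cl]], fixed = TRUE)
        j <- which(hit > 0L)[1]
        if (!is.na(j)) {
          assigned[i] <- cl
          if (cl == "tRNA") {
            trf_key_of[i] <- paste(names(index$search_seqs$tRNA)[j],
                                   hit[j], nchar(rd), sep = "|")
          }
          break
        }
      }
    }
    for (cl in classes) {
      sel <- !is.na(assigned) & assigned == cl
      cls_counts[cl] <- sum(mult[sel])
      if (any(sel)) {
        lh <- tapply(mult[sel], nchar(uniq[sel]), sum)
        len_hist[[cl]] <- setNames(as.integer(lh), names(lh))
      }
    }
    unann <- sum(mult[is.na(assigned)])
    sel <- !is.na(trf_key_of)
    if (any(sel)) {
      agg <- tapply(mult[sel], trf_key_of[sel], sum)
      trf_keys <- names(agg)
      trf_counts <- as.integer(agg)
    }
  }
  profile <- data.frame(sample = sample, group = group,
                        as.list(cls_counts), unannotated = unann,
                        genome_mapped_total = sum(cls_counts) + unann,
                        filtered = filtered,
                        stringsAsFactors = FALSE, check.names = FALSE)
  trf <- if (length(trf_keys)) {
    parts <- do.call(rbind, strsplit(trf_keys, "|", fixed = TRUE))
    data.frame(fragment_id = trf_keys, tRNA = parts[, 1],
               start = as.integer(parts[, 2]),
               length = as.integer(parts[, 3]),
               count = trf_counts, stringsAsFactors = FALSE)
  } else {
    data.frame(fragment_id = character(0), tRNA = character(0),
               start = integer(0), length = integer(0), count = integer(0))
  }
  structure(list(profile = profile, trf = trf, length_hist = len_hist),
            class = "srna_annotation")
}

#' Summarise the tRNA fragment length band
#'
#' Reports the fraction of tRNA-class reads with length in the 28-34 nt
#' band characteristic of tRNA-derived fragments, and whether that band
#' holds a strict majority (> 0.5) of tRNA-class reads.
#'
#' @param length_hist Named integer vector: read length -> count for the
#'   tRNA class (e.g. `annotate_reads()$length_hist$tRNA`, or a column of
#'   a simulated `trf_length_hist`).
#' @param band Inclusive length band (default `c(28, 34)`).
#' @return A list: `fraction_in_band`, `majority` (strict > 0.5),
#'   `modal_length`, `n_reads`.
#' @export
trf_lengths <- function(length_hist, band = c(28L, 34L)) {
  if (!length(length_hist) || sum(length_hist) == 0) {
    stop("trf_lengths needs a non-empty length histogram")
  }
  lens <- as.integer(names(length_hist))
  if (anyNA(lens)) stop("length_hist must be named by integer read length")
  total <- sum(length_hist)
  inband <- sum(length_hist[lens >= band[1] & lens <= band[2]])
  frac <- inband / total
  list(fraction_in_band = frac, majority = frac > 0.5,
       modal_length = lens[which.max(length_hist)], n_reads = total)
}

#' Simulate per-class small-RNA reference sequences
#'
#' Generates fully synthetic reference sets (random sequences of
#' class-typical lengths) for exercising the annotator without any
#' database download: e.g. ~22 nt miRNAs, 73 nt tRNAs (CCA added at
#' match time by [annotation_index()]), longer rRNA/lincRNA entries.
#'
#' @param seed Integer seed.
#' @param n_per_class Optional named integer vector overriding the number
#'   of reference sequences per class.
#' @return A named list of named character vectors, ready for
#'   [annotation_index()].
#' @export
simulate_class_references <- function(seed = 1L, n_per_class = NULL) {
  spec <- list(miRNA = c(50L, 22L), tRNA = c(30L, 73L), rRNA = c(5L, 150L),
               Mt_tRNA = c(10L, 70L), Mt_rRNA = c(2L, 120L),
               piRNA = c(80L, 28L), snRNA = c(10L, 100L),
               snoRNA = c(10L, 90L), lincRNA = c(5L, 200L),
               other = c(5L, 200L))
  with_seed(seed, {
    out <- lapply(names(spec), function(cl) {
      n <- n_per_class[[cl]] %||% spec[[cl]][1]
      len <- spec[[cl]][2]
      seqs <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1))
      setNames(seqs, sprintf("%s_%03d", cl, seq_len(n)))
    })
    setNames(out, names(spec))
  })
}

#' Simulate small-RNA reads from class references
#'
#' Draws reads as exact substrings of the provided reference sequences,
#' with per-class read counts given by `class_counts` (reads for the
#' `unannotated` class, if present, are random sequences matching no
#' reference with overwhelming probability). tRNA-class read lengths
#' follow `trf_length_dist`; other classes use class-typical lengths.
#'
#' @param refs Reference list as from [simulate_class_references()].
#' @param class_counts Named integer vector of reads per class.
#' @param trf_length_dist Length distribution for tRNA reads (default
#'   [srna_sim_config()]'s default band).
#' @param seed Integer seed.
#' @return Character vector of reads (shuffled).
#' @export
simulate_smallrna_reads <- function(refs, class_counts,
                                    trf_length_dist = default_trf_length_dist(),
                                    seed = 1L) {
  with_seed(seed, {
    reads <- character(0)
    for (cl in names(class_counts)) {
      n <- class_counts[[cl]]
      if (n == 0L) next
      if (cl == "unannotated" || !cl %in% names(refs)) {
        rl <- sample(18:40, n, replace = TRUE)
        reads <- c(reads, vapply(rl, function(l)
          paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
                collapse = ""), character(1)))
        next
      }
      pool <- refs[[cl]]
      if (cl == "tRNA") pool <- paste0(pool, "CCA")
      src <- sample(seq_along(pool), n, replace = TRUE)
      lens <- if (cl == "tRNA") {
        as.integer(sample(as.integer(names(trf_length_dist)), n,
                          replace = TRUE, prob = trf_length_dist))
      } else {
        pmin(nchar(pool)[src], sample(18:34, n, replace = TRUE))
      }
      lens <- pmin(lens, nchar(pool)[src])
      starts <- vapply(seq_len(n), function(i)
        sample.int(nchar(pool)[src[i]] - lens[i] + 1L, 1L), integer(1))
      reads <- c(reads, substr(pool[src], starts, starts + lens - 1L))
    }
    sample(reads)
  })
}
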