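#' Small-RNA class composition as percentages of genome-mapped reads
#'
#' Converts per-sample class counts into percentages of the sample's
#' genome-mapped total (classes plus unannotated sum to 100 per sample)
#' and averages them, unweighted, within diet group. Samples with a zero
#' genome-mapped total are excluded with a warning.
#'
#' @param profiles A data.frame with columns `sample`, `group`,
#'   `genome_mapped_total` and one count column per class (e.g. the
#'   `profiles` element of [simulate_smallrna()], or rows of
#'   [annotate_reads()] profiles bound together).
#' @return A list of class `srna_composition`: `per_sample` (data.frame
#'   of percentages), `group_means` (groups x classes matrix of mean
#'   percentages), `classes`.
#' @export
composition <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("sample", "group", "genome_mapped_total") %in%
                  names(profiles)))
  classes <- setdiff(names(profiles),
                     c("sample", "group", "genome_mapped_total", "filtered"))
  if (!length(classes)) stop("no class count columns found")
  zero <- profiles$genome_mapped_total == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " sample(s) with zero genome-mapped reads")
    profiles <- profiles[!zero, , drop = FALSE]
  }
  if (!nrow(profiles)) stop("no samples with genome-mapped reads")
  pct <- sweep(as.matrix(profiles[classes]), 1,
               profiles$genome_mapped_total, "/") * 100
  per_sample <- data.frame(sample = profiles$sample, group = profiles$group,
                           pct, stringsAsFactors = FALSE, check.names = FALSE)
  gm <- do.call(rbind, lapply(split(as.data.frame(pct), profiles$group),
                              colMeans))
  structure(list(per_sample = per_sample, group_means = gm,
                 classes = classes), class = "srna_composition")
}

#' Fisher exact test of a small-RNA composition shift
#'
#' Builds a 2 x K contingency table of rounded-to-integer percentages for
#' two groups and applies [fisher_exact_rxc()], with a Bonferroni
#' multiplication for the number of group comparisons. The default
#' (`method = "group_mean"`) uses the two groups' mean percentages (rows
#' totalling ~100); `method = "pooled"` sums the rounded per-sample
#' percentages within each group (rows totalling ~100 per sample), which
#' weights the same shifts by the number of samples.
#'
#' @param comp An [composition()] result.
#' @param group_a,group_b The two groups to compare (by default the
#'   second is "CTCT", the reference).
#' @param n_tests Bonferroni family size (default 3: the three non-control
#'   groups each compared with the control).
#' @param method "group_mean" (default) or "pooled".
#' @return A list: `table` (the 2 x K integer table), `p` (raw),
#'   `p_adj` (Bonferroni, capped at 1), `method`, `n_tests`.
#' @export
composition_test <- function(comp, group_a, group_b = "CTCT", n_tests = 3L,
                             method = c("group_mean", "pooled")) {
  stopifnot(inherits(comp, "srna_composition"))
  method <- match.arg(method)
  rows <- lapply(c(group_a, group_b), function(g) {
    if (method == "group_mean") {
      if (!g %in% rownames(comp$group_means)) stop("no samples in group ", g)
      round(comp$group_means[g, ])
    } else {
      sel <- comp$per_sample$group == g
      if (!any(sel)) stop("no samples in group ", g)
      colSums(round(as.matrix(comp$per_sample[sel, comp$classes,
                                              drop = FALSE])))
    }
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- c(group_a, group_b)
  if (any(tab < 0)) stop("negative rounded cell in composition table")
  if (any(rowSums(tab) == 0)) stop("all-zero row in composition table")
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  p <- fisher_exact_rxc(tab)$p
  list(table = tab, p = p, p_adj = bonferroni(p, n_tests),
       method = method, n_tests = as.integer(n_tests))
}
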