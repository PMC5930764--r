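default_class_proportions <- function() {
  ctct <- c(tRNA = 0.30, piRNA = 0.25, rRNA = 0.08, Mt_tRNA = 0.03,
            Mt_rRNA = 0.01, miRNA = 0.04, snRNA = 0.02, snoRNA = 0.015,
            lincRNA = 0.01, other = 0.095, unannotated = 0.15)
  ctpr <- c(tRNA = 0.42, piRNA = 0.13, rRNA = 0.08, Mt_tRNA = 0.06,
            Mt_rRNA = 0.01, miRNA = 0.04, snRNA = 0.02, snoRNA = 0.004,
            lincRNA = 0.01, other = 0.076, unannotated = 0.15)
  prct <- c(tRNA = 0.33, piRNA = 0.22, rRNA = 0.08, Mt_tRNA = 0.03,
            Mt_rRNA = 0.01, miRNA = 0.04, snRNA = 0.02, snoRNA = 0.015,
            lincRNA = 0.01, other = 0.095, unannotated = 0.15)
  list(CTCT = ctct, CTPR = ctpr, PRCT = prct, PRPR = ctct)
}

default_trf_length_dist <- function() {
  # 28-34 nt fragment band carries most of the mass, with short/long tails
  core <- c(`28` = 0.08, `29` = 0.13, `30` = 0.20, `31` = 0.22,
            `32` = 0.15, `33` = 0.09, `34` = 0.05)
  tail_lo <- setNames(rep(0.06 / 8, 8), 20:27)
  tail_hi <- setNames(rep(0.02 / 6, 6), 35:40)
  d <- c(tail_lo, core, tail_hi)
  d / sum(d)
}

#' Configuration for the sperm small-RNA simulator
#'
#' Emulates per-sample small-RNA class composition (Dirichlet-multinomial
#' around group-specific proportions) and a matrix of tRNA-derived
#' fragment (tRF) counts (negative binomial with group log2 fold changes
#' on a perturbed subset). Default group proportions give the CTPR group
#' a composition shift (more tRF and mitochondrial tRNA, less piRNA and
#' snoRNA), the PRCT group a small shift, and PRPR identical to CTCT,
#' mirroring the diet-response pattern the design emulates.
#'
#' @param n_samples_per_group Samples (mice) per diet group (default 8).
#' @param reads_per_sample Genome-mapped reads per sample (default 50000).
#' @param class_proportions Named list (per diet group) of named class
#'   proportion vectors, each summing to 1 within 1e-9.
#' @param overdispersion Dirichlet concentration scalar; larger is less
#'   overdispersed (default 500).
#' @param n_fragments Number of distinct tRF species (default 200).
#' @param de_fraction Fraction of tRF species perturbed in `de_group`
#'   (default 0.1).
#' @param de_log2fc Log2 fold change applied to perturbed species
#'   (default 2).
#' @param de_group Group carrying the perturbation (default "CTPR").
#' @param nb_dispersion NB dispersion of fragment counts (default 0.2;
#'   0 gives Poisson counts).
#' @param trf_length_dist Named probability vector over read lengths for
#'   tRNA-class reads (default concentrated on 28-34 nt).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `srna_sim_config`.
#' @export
srna_sim_config <- function(n_samples_per_group = 8L,
                            reads_per_sample = 50000L,
                            class_proportions = default_class_proportions(),
                            overdispersion = 500,
                            n_fragments = 200L,
                            de_fraction = 0.1, de_log2fc = 2,
                            de_group = "CTPR",
                            nb_dispersion = 0.2,
                            trf_length_dist = default_trf_length_dist(),
                            seed = NULL) {
  check_count(n_samples_per_group, "n_samples_per_group")
  check_count(reads_per_sample, "reads_per_sample")
  check_count(n_fragments, "n_fragments")
  check_prob(de_fraction, "de_fraction")
  stopifnot(is.numeric(overdispersion), overdispersion > 0,
            is.numeric(nb_dispersion), nb_dispersion >= 0,
            de_group %in% DIET_GROUPS)
  stopifnot(all(DIET_GROUPS %in% names(class_proportions)))
  cls <- names(class_proportions[[1]])
  for (g in DIET_GROUPS) {
    p <- class_proportions[[g]]
    if (!identical(names(p), cls)) {
      stop("class_proportions must use the same class names in every group")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("class proportions for ", g, " must be non-negative and sum to 1")
    }
  }
  if (any(trf_length_dist < 0) || abs(sum(trf_length_dist) - 1) > 1e-9) {
    stop("trf_length_dist must be a probability vector")
  }
  structure(list(n_samples_per_group = as.integer(n_samples_per_group),
                 reads_per_sample = as.integer(reads_per_sample),
                 class_proportions = class_proportions,
                 overdispersion = overdispersion,
                 n_fragments = as.integer(n_fragments),
                 de_fraction = de_fraction, de_log2fc = de_log2fc,
                 de_group = de_group, nb_dispersion = nb_dispersion,
                 trf_length_dist = trf_length_dist, seed = seed),
            class = "srna_sim_config")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate small-RNA class profiles and a tRF count matrix
#'
#' Per sample, class counts are multinomial draws of `reads_per_sample`
#' reads with Dirichlet-distributed proportions centred on the group's
#' class proportions (concentration `overdispersion`); every
#' length-passing read is treated as genome-mapped, so
#' `genome_mapped_total` equals the read total and per-sample class
#' percentages sum to 100. tRF species counts are negative binomial with
#' means proportional to library size, with `de_log2fc` applied to a
#' `de_fraction` subset of species in `de_group`. tRNA-class read lengths
#' are drawn from `trf_length_dist`.
#'
#' @param cfg An [srna_sim_config()].
#' @return A list of class `srna_sim`: `profiles` (data.frame: sample,
#'   group, one count column per class plus `genome_mapped_total`),
#'   `trf_counts` (species x samples integer matrix), `trf_lib_sizes`
#'   (genome-mapped totals, named by sample), `trf_perturbed` (logical
#'   per species), `trf_length_hist` (lengths x samples count matrix for
#'   tRNA-class reads), and `config`.
#' @export
simulate_smallrna <- function(cfg = srna_sim_config()) {
  stopifnot(inherits(cfg, "srna_sim_config"))
  with_seed(cfg$seed, {
    cls <- names(cfg$class_proportions[[1]])
    groups <- rep(DIET_GROUPS, each = cfg$n_samples_per_group)
    samples <- paste0(groups, "_s", rep(seq_len(cfg$n_samples_per_group), 4L))
    ns <- length(samples)

    counts <- matrix(0L, ns, length(cls), dimnames = list(samples, cls))
    for (i in seq_len(ns)) {
      p <- rdirichlet1(cfg$overdispersion * cfg$class_proportions[[groups[i]]])
      counts[i, ] <- as.integer(rmultinom(1L, cfg$reads_per_sample, p))
    }
    profiles <- data.frame(sample = samples, group = factor(groups, DIET_GROUPS),
                           counts, genome_mapped_total = rowSums(counts),
                           stringsAsFactors = FALSE, check.names = FALSE)

    # tRF species: log-normal baseline abundances scaled so the expected
    # fragment total matches the group's tRNA class share of the library
    w <- rlnorm(cfg$n_fragments, meanlog = 0, sdlog = 1)
    w <- w / sum(w)
    frag_ids <- sprintf("tRNA%02d_%d_%d",
                        rep_len(seq_len(max(1L, cfg$n_fragments %/% 7L + 1L)),
                                cfg$n_fragments),
                        sample(1:40, cfg$n_fragments, replace = TRUE),
                        sample(28:34, cfg$n_fragments, replace = TRUE))
    frag_ids <- make.unique(frag_ids, sep = "x")
    perturbed <- logical(cfg$n_fragments)
    if (cfg$de_fraction > 0 && cfg$n_fragments > 0) {
      k <- round(cfg$de_fraction * cfg$n_fragments)
      perturbed[sample.int(cfg$n_fragments, k)] <- TRUE
    }
    lib <- profiles$genome_mapped_total
    trf <- matrix(0L, cfg$n_fragments, ns,
                  dimnames = list(frag_ids, samples))
    for (i in seq_len(ns)) {
      share <- cfg$class_proportions[[groups[i]]][["tRNA"]]
      mu <- lib[i] * share * w
      if (groups[i] == cfg$de_group) {
        mu[perturbed] <- mu[perturbed] * 2^cfg$de_log2fc
      }
      trf[, i] <- if (cfg$nb_dispersion > 0) {
        rnbinom(cfg$n_fragments, mu = mu, size = 1 / cfg$nb_dispersion)
      } else {
        rpois(cfg$n_fragments, mu)
      }
    }

    lens <- as.integer(names(cfg$trf_length_dist))
    lh <- matrix(0L, length(lens), ns,
                 dimnames = list(names(cfg$trf_length_dist), samples))
    for (i in seq_len(ns)) {
      nt <- counts[i, "tRNA"]
      if (nt > 0) lh[, i] <- as.integer(rmultinom(1L, nt, cfg$trf_length_dist))
    }

    structure(list(profiles = profiles, trf_counts = trf,
                   trf_lib_sizes = setNames(lib, samples),
                   trf_perturbed = setNames(perturbed, frag_ids),
                   trf_length_hist = lh, config = cfg),
              class = "srna_sim")
  })
}
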