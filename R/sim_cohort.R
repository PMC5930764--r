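#' Configuration for the litter-structured cohort simulator
#'
#' Emulates a four-group pre-/post-weaning protein-restriction design
#' (CTCT, CTPR, PRCT, PRPR): independent litters per group, additive
#' Gaussian litter (dam) random intercepts on body weights, on the rDNA
#' %A genotype (siblings share the dam's rDNA pool) and on the CpG -133
#' A-methylation level, a pre-weaning PR weaning-weight deficit, and a
#' linear %A -> A-meth% relationship present in the PRCT group only.
#'
#' Group-level death-weight and fasting-loss means default to the values
#' observed in the four-group mouse protein-restriction study the design
#' emulates (28.53/26.05/24.06/21.76 g and 10.6/8.87/11.99/9.37 %).
#'
#' @param n_litters_per_group Litters per diet group (default 10; at
#'   least 2 so clustered models are estimable).
#' @param litter_size_range Inclusive range of male pups per litter
#'   (default 5-10; must lie within 1-20).
#' @param weaning_weight_mean_ct Mean weaning (21 d) weight in grams of
#'   pre-weaning control litters (default 9.5 g).
#' @param pr_weaning_deficit Fractional weaning-weight deficit of
#'   pre-weaning PR litters (default 0.34).
#' @param litter_sd SD (g) of the additive litter intercept on adult
#'   weights (default 0.8).
#' @param individual_sd SD (g) of the individual deviation on adult
#'   weights (default 1.2).
#' @param pct_a_mean,pct_a_sd Mean and within-litter SD of %A (defaults
#'   70 and 6).
#' @param pct_a_litter_sd Between-litter SD of %A (default 2.5).
#' @param baseline_meth Baseline CpG -133 A-meth % (default 25).
#' @param slope_prct Slope of A-meth% on centred %A applied in PRCT only
#'   (default 0.5 %/%).
#' @param meth_noise_sd Individual SD of A-meth% (default 2).
#' @param meth_litter_sd Between-litter SD of A-meth% (default 3).
#' @param death_weight_means,fasting_loss_means Named numeric vectors
#'   (CTCT/CTPR/PRCT/PRPR) of group means for weight at death (g) and
#'   fasting weight loss (% of pre-fast weight).
#' @param fasting_loss_sd Individual SD of fasting loss % (default 1.5).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_litters_per_group = 10L,
                              litter_size_range = c(5L, 10L),
                              weaning_weight_mean_ct = 9.5,
                              pr_weaning_deficit = 0.34,
                              litter_sd = 0.8, individual_sd = 1.2,
                              pct_a_mean = 70, pct_a_sd = 6,
                              pct_a_litter_sd = 2.5,
                              baseline_meth = 25, slope_prct = 0.5,
                              meth_noise_sd = 2, meth_litter_sd = 3,
                              death_weight_means = c(CTCT = 28.53,
                                                     CTPR = 26.05,
                                                     PRCT = 24.06,
                                                     PRPR = 21.76),
                              fasting_loss_means = c(CTCT = 10.6,
                                                     CTPR = 8.87,
                                                     PRCT = 11.99,
                                                     PRPR = 9.37),
                              fasting_loss_sd = 1.5, seed = NULL) {
  check_count(n_litters_per_group, "n_litters_per_group")
  if (n_litters_per_group < 2L) {
    stop("n_litters_per_group must be >= 2 (clustered models need >= 2 litters)")
  }
  stopifnot(length(litter_size_range) == 2L)
  litter_size_range <- as.integer(litter_size_range)
  if (litter_size_range[1] < 1L || litter_size_range[2] > 20L ||
      litter_size_range[1] > litter_size_range[2]) {
    stop("litter_size_range must be an increasing interval within [1, 20]")
  }
  check_prob(pr_weaning_deficit, "pr_weaning_deficit")
  for (nm in c("litter_sd", "individual_sd", "pct_a_sd", "pct_a_litter_sd",
               "meth_noise_sd", "meth_litter_sd", "fasting_loss_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("'", nm, "' must be a single non-negative number")
    }
  }
  check_prob(pct_a_mean, "pct_a_mean", 0, 100)
  stopifnot(all(DIET_GROUPS %in% names(death_weight_means)),
            all(DIET_GROUPS %in% names(fasting_loss_means)))
  structure(as.list(environment()), class = "cohort_sim_config")
}

#' Simulate a litter-structured four-diet-group cohort
#'
#' Draws the cohort table consumed by the statistics layer: one row per
#' male mouse with litter id, diet group, weekly body weights (7-84 d),
#' weaning weight, pre-fast and death weights, relative organ weights,
#' %A and CpG -133 A-meth %. See [cohort_sim_config()] for the model.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A `data.frame` with one row per mouse. Weekly weights are in
#'   columns `weight_d7` ... `weight_d84`.
#' @export
simulate_cohort <- function(cfg = cohort_sim_config()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_seed(cfg$seed, {
    G <- cfg$n_litters_per_group
    groups <- rep(DIET_GROUPS, each = G)
    litter_ids <- paste0(groups, "_L", rep(seq_len(G), times = 4L))
    sizes <- sample(seq(cfg$litter_size_range[1], cfg$litter_size_range[2]),
                    length(litter_ids), replace = TRUE)
    litter_w <- rnorm(length(litter_ids), 0, cfg$litter_sd)
    litter_x <- rnorm(length(litter_ids), 0, cfg$pct_a_litter_sd)
    litter_m <- rnorm(length(litter_ids), 0, cfg$meth_litter_sd)

    li <- rep(seq_along(litter_ids), times = sizes)
    n <- length(li)
    group <- groups[li]
    litter <- litter_ids[li]
    pre_pr <- group %in% c("PRCT", "PRPR")

    weaning_mean <- ifelse(pre_pr,
                           cfg$weaning_weight_mean_ct * (1 - cfg$pr_weaning_deficit),
                           cfg$weaning_weight_mean_ct)
    weaning <- weaning_mean + 0.5 * litter_w[li] +
      rnorm(n, 0, 0.5 * cfg$individual_sd)
    weaning <- pmax(weaning, 0.5)

    death <- cfg$death_weight_means[group] + litter_w[li] +
      rnorm(n, 0, cfg$individual_sd)
    loss <- rnorm(n, cfg$fasting_loss_means[group], cfg$fasting_loss_sd)
    pre_fast <- death / (1 - loss / 100)

    days <- seq(7L, 84L, by = 7L)
    wk <- matrix(NA_real_, n, length(days),
                 dimnames = list(NULL, paste0("weight_d", days)))
    wk[, "weight_d7"] <- 0.55 * weaning + rnorm(n, 0, 0.2)
    wk[, "weight_d14"] <- 0.85 * weaning + rnorm(n, 0, 0.2)
    wk[, "weight_d21"] <- weaning
    post <- days[days > 21L]
    for (d in post) {
      frac <- (d - 21) / (84 - 21)
      wk[, paste0("weight_d", d)] <- weaning + frac * (pre_fast - weaning) +
        if (d < 84L) rnorm(n, 0, 0.3) else 0
    }

    pct_a <- cfg$pct_a_mean + litter_x[li] + rnorm(n, 0, cfg$pct_a_sd)
    pct_a <- pmin(pmax(pct_a, 0), 100)
    a_meth <- cfg$baseline_meth + litter_m[li] +
      cfg$slope_prct * (pct_a - cfg$pct_a_mean) * (group == "PRCT") +
      rnorm(n, 0, cfg$meth_noise_sd)
    a_meth <- pmin(pmax(a_meth, 0), 100)

    out <- data.frame(
      mouse = paste0(litter, "_m", stats::ave(li, li, FUN = seq_along)),
      litter = litter,
      group = factor(group, levels = DIET_GROUPS),
      weaning_weight = weaning,
      pre_fast_weight = pre_fast,
      death_weight = death,
      liver_weight = 0.045 * death + rnorm(n, 0, 0.05),
      kidney_weight = 0.013 * death + rnorm(n, 0, 0.015),
      pct_a = pct_a,
      a_meth_pct = a_meth,
      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(wk))
  })
}
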