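#' Pipeline run configuration
#'
#' Assembles the nested configuration consumed by [run_pipeline()]. Each
#' section may be `NULL` to skip the corresponding stage (the report then
#' marks it skipped). The global `seed` is split deterministically into
#' independent per-stage seeds, so a run is reproducible end to end.
#'
#' @param seed Global integer seed (default 1).
#' @param cohort List of overrides for [cohort_sim_config()].
#' @param rdna List: overrides for [rdna_sim_config()] plus
#'   `mice_per_litter` (sperm samples assayed per litter, default 2) and
#'   `min_reads` (default 100).
#' @param smallrna List of overrides for [srna_sim_config()], plus
#'   optional `composition_method` ("group_mean" or "pooled").
#' @param out_dir Output directory for the JSON report and TSV
#'   side-tables, or `NULL` to skip writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, cohort = list(), rdna = list(),
                       smallrna = list(), out_dir = NULL) {
  check_count(abs(seed), "seed")
  structure(list(seed = as.integer(seed), cohort = cohort, rdna = rdna,
                 smallrna = smallrna, out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any of the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  run_config(seed = cfg$seed %||% 1L,
             cohort = cfg$cohort %||% list(),
             rdna = if (isFALSE(cfg$rdna)) NULL else cfg$rdna %||% list(),
             smallrna = if (isFALSE(cfg$smallrna)) NULL else
               cfg$smallrna %||% list(),
             out_dir = cfg$out_dir)
}

apply_overrides <- function(constructor, overrides, extra = character(0)) {
  overrides <- overrides %||% list()
  overrides <- overrides[setdiff(names(overrides), extra)]
  do.call(constructor, overrides)
}

#' Run the full simulated-study analysis pipeline
#'
#' Orchestrates the stages end to end on synthetic data: (1) simulate a
#' litter-structured four-diet-group cohort; (2) for a subset of mice per
#' litter, simulate bisulfite amplicon reads from each mouse's true %A
#' and A-meth%, call and tabulate them ([tabulate_reads()]), and summarise
#' per sample ([summarize_rdna()]); (3) run the %A vs A-meth% correlation
#' analysis with litter-cluster-robust models plus ANOVA across groups;
#' (4) phenotype models (weaning-weight Welch test on litter means,
#' death-weight and fasting-loss linear models); (5) simulate small-RNA
#' profiles, compute class composition, Fisher composition tests against
#' the control, tRF length-band summary and NB differential abundance.
#' Every figure-level quantity in the report is computed by one of the
#' exported module functions; the orchestrator only wires them together.
#'
#' @param config A [run_config()] (or a path to a YAML file).
#' @return A list of class `ribostress_report` (also written as JSON +
#'   TSVs when `out_dir` is set): sections `provenance`, `rdna`,
#'   `phenotype`, `smallrna`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  seed <- config$seed
  report <- list(provenance = list(
    seed = seed,
    package_version = as.character(utils::packageVersion("ribostress")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = config_hash(config)))

  # ---- cohort stage (always runs: downstream stages depend on it) ----
  cohort_cfg <- apply_overrides(cohort_sim_config, config$cohort)
  cohort_cfg$seed <- stage_seed(seed, "cohort")
  cohort <- tryCatch(simulate_cohort(cohort_cfg), error = function(e)
    stop("cohort stage failed: ", conditionMessage(e), call. = FALSE))

  # ---- phenotype statistics ----
  report$phenotype <- tryCatch({
    pre_pr <- cohort$group %in% c("PRCT", "PRPR")
    welch <- welch_on_litter_means(cohort$weaning_weight, cohort$litter,
                                   ifelse(pre_pr, "preweaning_PR",
                                          "preweaning_CT"))
    ratio <- mean(welch$litter_means$preweaning_PR) /
      mean(welch$litter_means$preweaning_CT)
    cohort$fasting_loss_pct <- fasting_loss(cohort$pre_fast_weight,
                                            cohort$death_weight)
    fits <- lapply(c("death_weight", "fasting_loss_pct"), function(ph)
      phenotype_lm(cohort, ph, n_tests = 3L))
    names(fits) <- c("death_weight", "fasting_loss_pct")
    list(
      weaning = list(pr_ct_ratio = ratio, t = welch$t, df = welch$df,
                     p = welch$p),
      group_means = lapply(
        split(cohort[c("death_weight", "fasting_loss_pct")], cohort$group),
        colMeans),
      lm = lapply(fits, function(f) f$coefficients))
  }, error = function(e)
    stop("phenotype stage failed: ", conditionMessage(e), call. = FALSE))

  # ---- rdna stage ----
  if (is.null(config$rdna)) {
    report$rdna <- list(skipped = TRUE)
  } else {
    report$rdna <- tryCatch({
      opts <- config$rdna %||% list()
      mice_per_litter <- opts$mice_per_litter %||% 2L
      min_reads <- opts$min_reads %||% 100L
      base_cfg <- apply_overrides(
        rdna_sim_config,
        modifyList(list(n_reads = 2000L), opts),
        extra = c("mice_per_litter", "min_reads"))
      ref <- synthetic_rdna_ref()
      idx <- unlist(lapply(split(seq_len(nrow(cohort)), cohort$litter),
                           function(i) head(i, mice_per_litter)),
                    use.names = FALSE)
      assayed <- cohort[sort(idx), ]
      rseed <- stage_seed(seed, "rdna")
      est <- lapply(seq_len(nrow(assayed)), function(i) {
        cfg <- base_cfg
        cfg$pct_a <- assayed$pct_a[i]
        cfg$meth_rate_a <- assayed$a_meth_pct[i] / 100
        cfg$seed <- (rseed + i) %% 2147483647L
        sim <- simulate_rdna_reads(ref, cfg)
        counts <- tabulate_reads(sim$reads, ref)
        s <- summarize_rdna(counts, min_reads = min_reads,
                            sample = assayed$mouse[i])
        c(pct_a = s$pct_a, a_meth_pct = s$a_meth_pct,
          c_meth_pct = s$c_meth_pct, n_accepted = s$n_accepted)
      })
      est <- as.data.frame(do.call(rbind, est))
      samples <- cbind(assayed[c("mouse", "litter", "group")],
                       true_pct_a = assayed$pct_a,
                       true_a_meth_pct = assayed$a_meth_pct, est)
      cors <- cor_meth_analysis(samples, n_tests = 4L)
      anova_pct_a <- one_way_anova(samples$pct_a, samples$group)
      anova_meth <- one_way_anova(samples$a_meth_pct, samples$group)
      list(samples = samples, correlations = cors,
           anova = list(pct_a = anova_pct_a, a_meth_pct = anova_meth))
    }, error = function(e)
      stop("rdna stage failed: ", conditionMessage(e), call. = FALSE))
  }

  # ---- small RNA stage ----
  if (is.null(config$smallrna)) {
    report$smallrna <- list(skipped = TRUE)
  } else {
    report$smallrna <- tryCatch({
      opts <- config$smallrna %||% list()
      comp_method <- opts$composition_method %||% "group_mean"
      scfg <- apply_overrides(srna_sim_config, opts,
                              extra = "composition_method")
      scfg$seed <- stage_seed(seed, "smallrna")
      sim <- simulate_smallrna(scfg)
      comp <- composition(sim$profiles)
      tests <- lapply(c("CTPR", "PRCT", "PRPR"), function(g) {
        ct <- composition_test(comp, g, "CTCT", n_tests = 3L,
                               method = comp_method)
        list(group = g, p = ct$p, p_adj = ct$p_adj, method = ct$method)
      })
      names(tests) <- c("CTPR", "PRCT", "PRPR")
      pooled_lh <- rowSums(sim$trf_length_hist)
      band <- trf_lengths(pooled_lh)
      de <- de_trf(sim$trf_counts, sim$trf_lib_sizes,
                   sim$profiles$group, reference_group = "CTCT")
      de_summary <- lapply(de, function(d) list(
        n_tested = nrow(d),
        n_nominal = sum(d$p < 0.05),
        n_fdr05 = sum(d$p_adj < 0.05),
        dispersion = attr(d, "dispersion")))
      list(group_mean_pct = comp$group_means, composition_tests = tests,
           trf_band = band, de = de_summary, de_tables = de)
    }, error = function(e)
      stop("smallrna stage failed: ", conditionMessage(e), call. = FALSE))
  }

  report <- structure(report, class = "ribostress_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir,
                                             cohort = cohort)
  report
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` plus TSV side-tables (per-sample rDNA estimates,
#' correlation table, composition group means, DE tables) into `dir`.
#'
#' @param report A `ribostress_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param cohort Optional cohort table to write alongside.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, cohort = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(d, name) write.table(
    d, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  slim <- report
  if (!is.null(slim$rdna$samples)) {
    tsv(slim$rdna$samples, "rdna_samples.tsv")
    tsv(slim$rdna$correlations, "rdna_correlations.tsv")
    slim$rdna$samples <- NULL
  }
  if (!is.null(slim$smallrna$de_tables)) {
    for (g in names(slim$smallrna$de_tables)) {
      tsv(slim$smallrna$de_tables[[g]], paste0("trf_de_", g, ".tsv"))
    }
    slim$smallrna$de_tables <- NULL
  }
  if (!is.null(slim$smallrna$group_mean_pct)) {
    gm <- slim$smallrna$group_mean_pct
    tsv(data.frame(group = rownames(gm), gm, check.names = FALSE),
        "composition_group_means.tsv")
  }
  if (!is.null(cohort)) tsv(cohort, "cohort.tsv")
  jsonlite::write_json(unclass(slim), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows", na = "null")
  invisible(dir)
}

#' @export
print.ribostress_report <- function(x, ...) {
  cat("ribostress pipeline report (seed", x$provenance$seed, ")\n")
  if (!is.null(x$rdna$correlations)) {
    cat("\n%A vs CpG -133 A meth % (cluster-robust, Bonferroni n=4):\n")
    print(x$rdna$correlations, digits = 3)
  } else if (isTRUE(x$rdna$skipped)) cat("\nrdna stage: skipped\n")
  if (!is.null(x$phenotype)) {
    cat(sprintf("\nweaning weight PR/CT ratio: %.3f (Welch on litter means p = %.3g)\n",
                x$phenotype$weaning$pr_ct_ratio, x$phenotype$weaning$p))
  }
  if (!is.null(x$smallrna$composition_tests)) {
    cat("\ncomposition tests vs CTCT (Bonferroni n=3):\n")
    for (t in x$smallrna$composition_tests) {
      cat(sprintf("  %s: p_adj = %.3g\n", t$group, t$p_adj))
    }
  } else if (isTRUE(x$smallrna$skipped)) cat("\nsmallrna stage: skipped\n")
  invisible(x)
}
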