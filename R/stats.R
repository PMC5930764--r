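#' Ordinary least squares with cluster-robust (CR1) standard errors
#'
#' Fits OLS and replaces the classical covariance with the cluster-robust
#' sandwich estimator
#' \deqn{V = c \, (X'X)^{-1} \Big[\sum_g X_g' \hat u_g \hat u_g' X_g\Big] (X'X)^{-1}}
#' with the CR1 small-sample factor
#' `c = G/(G-1) * (N-1)/(N-k)` (G clusters, N observations, k
#' coefficients), and tests coefficients against a t distribution on
#' `G - 1` degrees of freedom. This is the machinery that keeps type-I
#' error controlled when siblings within a litter are correlated; when
#' every cluster is a singleton it reduces to HC1 heteroskedasticity-
#' robust inference.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (include an intercept column if wanted); a
#'   data.frame is coerced.
#' @param cluster Cluster (litter) identifier per observation.
#' @param n_tests Bonferroni family size for adjusted p-values (default 1).
#' @return A list of class `lmfit_cr`: `coefficients` data.frame
#'   (estimate, se, t, p, p_adj), `vcov`, `n_obs`, `n_clusters`, `df`,
#'   `correction`, `residuals`, `fitted`.
#' @export
ols_cluster_robust <- function(y, X, cluster, n_tests = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), length(cluster) == nrow(X))
  ok <- stats::complete.cases(y, X, cluster)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; cluster <- cluster[ok]
  n <- nrow(X); k <- ncol(X)
  qr_x <- qr(X)
  if (qr_x$rank < k) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):k]]
    stop("singular design matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  cl <- as.character(cluster)
  G <- length(unique(cl))
  if (G < 2L) stop("cluster-robust inference needs >= 2 clusters")
  if (n <= k) stop("more coefficients than observations")
  xtx_inv <- chol2inv(qr.R(qr_x))
  beta <- drop(xtx_inv %*% crossprod(X, y))
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  u <- y - fitted
  scores <- rowsum(X * u, cl)           # X_g' u_g per cluster, stacked
  meat <- crossprod(as.matrix(scores))
  corr <- (G / (G - 1)) * ((n - 1) / (n - k))
  V <- corr * xtx_inv %*% meat %*% xtx_inv
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(V), 0))
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  df <- G - 1L
  p <- 2 * pt(-abs(tval), df = df)
  p[se == 0 & beta == 0] <- 1
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = beta, se = se,
                              t = tval, p = p,
                              p_adj = bonferroni(p, n_tests),
                              row.names = NULL),
    vcov = V, n_obs = n, n_clusters = G, df = df, correction = corr,
    residuals = u, fitted = fitted, n_tests = as.integer(n_tests)),
    class = "lmfit_cr")
}

#' @export
print.lmfit_cr <- function(x, ...) {
  cat(sprintf("cluster-robust OLS: %d obs, %d clusters (t on %d df, CR1 = %.4f)\n",
              x$n_obs, x$n_clusters, x$df, x$correction))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Per-group correlation of %A with CpG -133 A methylation
#'
#' Within each diet group, computes the Pearson correlation between the
#' fraction of A-variant rDNA copies (%A) and the percentage of A copies
#' methylated at CpG -133, and derives the p-value from a linear model of
#' A-meth% on %A with litter-cluster-robust standard errors
#' ([ols_cluster_robust()]), Bonferroni-adjusted for the four group
#' comparisons. Groups where %A has zero variance report `NA` correlation.
#'
#' @param table Cohort data.frame with columns `group`, `litter`,
#'   `pct_a`, `a_meth_pct` (e.g. from [simulate_cohort()]).
#' @param n_tests Bonferroni family size (default 4).
#' @param naive Also report the naive (non-clustered) OLS p-value for
#'   comparison (default FALSE).
#' @return A data.frame, one row per group: `group`, `n`, `n_litters`,
#'   `cor`, `slope`, `se`, `p`, `p_adj` (and `p_naive` if requested).
#' @export
cor_meth_analysis <- function(table, n_tests = 4L, naive = FALSE) {
  stopifnot(all(c("group", "litter", "pct_a", "a_meth_pct") %in% names(table)))
  groups <- intersect(DIET_GROUPS, unique(as.character(table$group)))
  rows <- lapply(groups, function(g) {
    d <- table[table$group == g, ]
    if (nrow(d) < 3L) stop("group ", g, " has fewer than 3 mice")
    if (length(unique(d$litter)) < 2L) stop("group ", g, " has < 2 litters")
    if (sd(d$pct_a) == 0) {
      return(data.frame(group = g, n = nrow(d),
                        n_litters = length(unique(d$litter)),
                        cor = NA_real_, slope = NA_real_, se = NA_real_,
                        p = NA_real_, p_adj = NA_real_,
                        p_naive = NA_real_))
    }
    r <- cor(d$pct_a, d$a_meth_pct)
    X <- cbind(`(Intercept)` = 1, pct_a = d$pct_a)
    fit <- ols_cluster_robust(d$a_meth_pct, X, d$litter, n_tests = n_tests)
    co <- fit$coefficients[fit$coefficients$term == "pct_a", ]
    p_naive <- suppressWarnings(
      summary(stats::lm(a_meth_pct ~ pct_a,
                        data = d))$coefficients["pct_a", 4])
    data.frame(group = g, n = nrow(d),
               n_litters = length(unique(d$litter)),
               cor = r, slope = co$estimate, se = co$se, p = co$p,
               p_adj = co$p_adj, p_naive = p_naive)
  })
  out <- do.call(rbind, rows)
  if (!naive) out$p_naive <- NULL
  out
}

#' Phenotype linear model against diet group with robust SEs
#'
#' Fits `phenotype ~ group` over all mice (control group as reference
#' level), with litter-cluster-robust standard errors and a Bonferroni
#' adjustment for the three non-control contrasts.
#'
#' @param table Cohort data.frame with `group`, `litter` and the
#'   phenotype column.
#' @param phenotype Name of the phenotype column.
#' @param n_tests Bonferroni family size (default 3).
#' @param reference Reference group (default "CTCT").
#' @return An `lmfit_cr`; the rows of `$coefficients` after the intercept
#'   are the group contrasts against the reference.
#' @export
phenotype_lm <- function(table, phenotype, n_tests = 3L, reference = "CTCT") {
  if (!phenotype %in% names(table)) {
    stop("phenotype column '", phenotype, "' not found")
  }
  g <- factor(as.character(table$group),
              levels = c(reference, setdiff(unique(as.character(table$group)),
                                            reference)))
  keep <- !is.na(table[[phenotype]])
  tab <- table[keep, ]
  g <- g[keep]
  per <- table(unique(data.frame(g = g, l = tab$litter))$g)
  if (any(per < 2L)) {
    stop("phenotype '", phenotype, "' needs >= 2 litters per group")
  }
  X <- model.matrix(~g)
  colnames(X) <- sub("^g", "", colnames(X))
  ols_cluster_robust(tab[[phenotype]], X, tab$litter, n_tests = n_tests)
}

#' Fasting weight loss as a percentage of pre-fast weight
#'
#' @param pre_fast Pre-fast weight (g), must be > 0.
#' @param death Weight at death (g); may exceed `pre_fast` (negative
#'   loss).
#' @return `100 * (pre_fast - death) / pre_fast`, vectorised.
#' @export
fasting_loss <- function(pre_fast, death) {
  if (any(pre_fast <= 0, na.rm = TRUE)) stop("pre_fast weights must be > 0")
  100 * (pre_fast - death) / pre_fast
}

#' Welch's t test on litter means
#'
#' Collapses values to litter means first (each litter contributes one
#' value) and applies Welch's unequal-variance t test with
#' Welch-Satterthwaite degrees of freedom between the two groups. When
#' both groups of litter means are exactly constant the test is
#' degenerate: equal means give t = 0, p = 1; separated means report the
#' limit p = 0 with a warning and `degenerate = TRUE`.
#'
#' @param values Numeric vector (e.g. weaning weights).
#' @param litters Litter id per value.
#' @param groups Group label per value; exactly two groups, and a litter
#'   must not span groups.
#' @return A list: `t`, `df`, `p`, `litter_means` (named list per group),
#'   `degenerate`.
#' @export
welch_on_litter_means <- function(values, litters, groups) {
  stopifnot(length(values) == length(litters),
            length(values) == length(groups))
  groups <- as.character(groups)
  span <- tapply(groups, as.character(litters),
                 function(g) length(unique(g)))
  if (any(span > 1L)) {
    stop("litter(s) spanning groups: ",
         paste(names(span)[span > 1L], collapse = ", "))
  }
  gl <- unique(groups)
  if (length(gl) != 2L) stop("welch_on_litter_means needs exactly 2 groups")
  means <- lapply(gl, function(g) {
    sel <- groups == g
    as.numeric(tapply(values[sel], as.character(litters[sel]), mean))
  })
  names(means) <- gl
  if (any(lengths(means) < 2L)) stop("each group needs >= 2 litters")
  v1 <- var(means[[1]]); v2 <- var(means[[2]])
  if (v1 == 0 && v2 == 0) {
    if (mean(means[[1]]) == mean(means[[2]])) {
      return(list(t = 0, df = NA_real_, p = 1, litter_means = means,
                  degenerate = TRUE))
    }
    warning("zero variance in both groups with separated means; ",
            "reporting the p = 0 limit")
    return(list(t = sign(mean(means[[1]]) - mean(means[[2]])) * Inf,
                df = NA_real_, p = 0, litter_means = means,
                degenerate = TRUE))
  }
  tt <- t.test(means[[1]], means[[2]], var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, litter_means = means, degenerate = FALSE)
}

#' One-way analysis of variance
#'
#' Standard equal-variance one-way F test across groups (used to compare
#' %A, %C and CpG -133 methylation levels between diet groups). A fully
#' constant response returns F = 0, p = 1 rather than failing.
#'
#' @param values Numeric vector.
#' @param groups Group label per value; >= 2 groups with >= 2 values each.
#' @return A list: `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("one_way_anova needs >= 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 values")
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  if (sd(values) == 0) {
    return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  }
  ow <- oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p = ow$p.value)
}

# all tables with the given margins, as rows of cell values (row-major);
# recursion over rows, each row a bounded composition of its margin
enumerate_tables <- function(row_margins, col_margins) {
  compositions <- function(total, caps) {
    k <- length(caps)
    if (k == 1L) {
      if (total <= caps[1]) return(matrix(total, 1L, 1L))
      return(matrix(integer(0), 0L, 1L))
    }
    out <- list()
    for (v in 0:min(total, caps[1])) {
      rest <- compositions(total - v, caps[-1])
      if (nrow(rest)) out[[length(out) + 1L]] <- cbind(v, rest)
    }
    if (!length(out)) return(matrix(integer(0), 0L, k))
    do.call(rbind, out)
  }
  recurse <- function(rows_left, cols_remaining) {
    if (length(rows_left) == 1L) {
      return(matrix(cols_remaining, 1L))
    }
    first <- compositions(rows_left[1], cols_remaining)
    out <- list()
    for (i in seq_len(nrow(first))) {
      rest <- recurse(rows_left[-1], cols_remaining - first[i, ])
      out[[i]] <- cbind(matrix(rep(first[i, ], each = nrow(rest)),
                               nrow(rest)), rest)
    }
    do.call(rbind, out)
  }
  recurse(row_margins, col_margins)
}

log_table_prob <- function(cells, row_margins, col_margins) {
  n <- sum(row_margins)
  sum(lgamma(row_margins + 1)) + sum(lgamma(col_margins + 1)) -
    lgamma(n + 1) - rowSums(lgamma(cells + 1))
}

#' Fisher's exact test for r x c contingency tables
#'
#' Two-sided exact test of independence: the p-value is the total
#' probability, under the multivariate hypergeometric null with fixed
#' margins, of tables no more probable than the observed one (with the
#' conventional 1e-7 relative tolerance on the probability comparison).
#' 2 x 2 tables use a closed-form hypergeometric sum; small r x c tables
#' (total <= `enumerate_limit`) use full own-code enumeration of all
#' tables with the observed margins; larger tables with total <= 500 use
#' the network algorithm of [stats::fisher.test()]; larger still fall
#' back to seeded Monte Carlo (`B` tables) with a reported standard
#' error.
#'
#' @param tab Matrix of non-negative integer counts (no all-zero margin).
#' @param enumerate_limit Largest table total for own enumeration
#'   (default 40).
#' @param B Monte-Carlo table count (default 1e5).
#' @param seed Seed for the Monte-Carlo fallback (default 1).
#' @return A list: `p`, `method` ("hypergeometric", "enumeration",
#'   "network", "montecarlo"), and `mc_se` (NA unless Monte Carlo).
#' @export
fisher_exact_rxc <- function(tab, enumerate_limit = 40L, B = 1e5L, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("fisher_exact_rxc needs non-negative integer counts ",
         "(round percentages before testing)")
  }
  storage.mode(tab) <- "integer"
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has an all-zero margin")
  }
  n <- sum(tab)
  tol <- 1 + 1e-7
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    m <- sum(tab[1, ]); k <- sum(tab[, 1])
    supp <- max(0L, k - sum(tab[2, ])):min(k, m)
    probs <- dhyper(supp, m, n - m, k)
    p_obs <- dhyper(tab[1, 1], m, n - m, k)
    return(list(p = min(1, sum(probs[probs <= p_obs * tol])),
                method = "hypergeometric", mc_se = NA_real_))
  }
  if (n <= enumerate_limit) {
    rm <- rowSums(tab); cm <- colSums(tab)
    if (nrow(tab) == 2L) {
      # two-row tables: the first row determines the table; enumerate its
      # bounded compositions in one vectorised sweep
      k <- ncol(tab)
      grid <- as.matrix(expand.grid(lapply(cm[-k], function(cj)
        0:min(cj, rm[1]))))
      last <- rm[1] - rowSums(grid)
      ok <- last >= 0 & last <= cm[k]
      first <- cbind(grid[ok, , drop = FALSE], last[ok])
      all_tabs <- cbind(first, matrix(cm, nrow(first), k, byrow = TRUE) -
                          first)
    } else {
      all_tabs <- enumerate_tables(rm, cm)
    }
    lp <- log_table_prob(all_tabs, rm, cm)
    lp_obs <- log_table_prob(matrix(as.vector(t(tab)), 1L), rm, cm)
    p <- sum(exp(lp[lp <= lp_obs + log(tol)]))
    return(list(p = min(1, p), method = "enumeration", mc_se = NA_real_))
  }
  if (n <= 500L) {
    p <- tryCatch(
      fisher.test(tab, workspace = 2e8)$p.value,
      error = function(e) NULL)
    if (!is.null(p)) {
      return(list(p = min(1, p), method = "network", mc_se = NA_real_))
    }
  }
  p <- with_seed(seed,
                 fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value)
  list(p = min(1, p), method = "montecarlo",
       mc_se = sqrt(p * (1 - p) / B))
}

#' Bonferroni adjustment
#'
#' `min(1, p * n_tests)`, vectorised over `p`. Monotone in `p` and
#' idempotent once capped.
#'
#' @param p P-value(s) in \[0, 1\].
#' @param n_tests Family size (>= 1).
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(p, n_tests) {
  check_prob(p[!is.na(p)], "p")
  if (n_tests < 1) stop("n_tests must be >= 1")
  pmin(1, p * n_tests)
}
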