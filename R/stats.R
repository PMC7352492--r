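# Group-comparison statistics, the multinomial dietary-pattern model, the
# cluster-sampling design effect and the Monte-Carlo power computation.

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis test across >= 2 groups followed by Dunn's
#' pairwise rank z-tests, Holm-adjusted over the pairs.
#'
#' @param data Data frame (or `NULL` when `values`/`groups` are vectors).
#' @param values Column (tidy-selected) or numeric vector of observations.
#' @param groups Column or vector of group labels.
#' @return Object of class `"nutrinet_comparison"`: list with `test`
#'   ("Kruskal-Wallis"), `statistic`, `df`, `p_value`, `pairwise` (tibble
#'   group1, group2, z, p_value, p_adjusted) and `summary` (per-group n,
#'   median, IQR).
#' @export
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 10, 11, 12), g = rep(c("a", "b"), each = 3))
#' kruskal_wallis_dunn(d, y, g)
kruskal_wallis_dunn <- function(data = NULL, values, groups) {
  if (is.data.frame(data)) {
    values <- rlang::eval_tidy(rlang::enquo(values), data)
    groups <- rlang::eval_tidy(rlang::enquo(groups), data)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (any(table(groups) < 1)) abort("every group needs >= 1 observation")

  all_equal <- length(unique(values)) == 1
  if (all_equal) {
    kw_stat <- 0
    kw_p <- 1
  } else {
    kw <- kruskal.test(values, groups)
    kw_stat <- unname(kw$statistic)
    kw_p <- kw$p.value
  }

  # Dunn z-tests on mean ranks with tie correction
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    sigma2 <- (N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]])
    z <- if (sigma2 <= 0) 0 else (mean_ranks[[i]] - mean_ranks[[j]]) / sqrt(sigma2)
    tibble(group1 = i, group2 = j, z = z, p_value = 2 * pnorm(-abs(z)))
  })
  pairwise$p_adjusted <- p.adjust(pairwise$p_value, method = "holm")

  summary_tab <- tibble(
    group = lev,
    n = as.integer(ns[lev]),
    median = as.numeric(tapply(values, groups, median)[lev]),
    q25 = as.numeric(tapply(values, groups, quantile, 0.25)[lev]),
    q75 = as.numeric(tapply(values, groups, quantile, 0.75)[lev])
  )
  structure(
    list(test = "Kruskal-Wallis", statistic = kw_stat,
         df = nlevels(groups) - 1, p_value = kw_p,
         pairwise = pairwise, summary = summary_tab),
    class = "nutrinet_comparison"
  )
}

#' @export
print.nutrinet_comparison <- function(x, ...) {
  cat("<", x$test, ">  chi2 =", format(x$statistic, digits = 4),
      " df =", x$df, " p =", format.pval(x$p_value), "\n")
  print(x$pairwise)
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Classic Pearson statistic sum((O - E)^2 / E) with df = (r-1)(c-1),
#' computed without continuity correction.
#'
#' @param counts Matrix or table of nonnegative counts, at least 2 x 2.
#' @param warn_low_expected Warn when any expected count < 5 (default TRUE).
#' @return List with `statistic`, `df`, `p_value`, `expected`,
#'   `low_expected`.
#' @export
#' @examples
#' chi_square_table(rbind(c(562, 153, 139), c(460, 141, 41)))
chi_square_table <- function(counts, warn_low_expected = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("counts must be finite and nonnegative")
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) abort("table must be at least 2 x 2")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("zero row/column marginal", class = "nutrinet_validation_error")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  statistic <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  low <- any(expected < 5)
  if (low && warn_low_expected) {
    warn("some expected counts are below 5; chi-square approximation may be poor")
  }
  list(
    statistic = statistic,
    df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
    expected = expected,
    low_expected = low
  )
}

#' Multinomial dietary-pattern regression
#'
#' Maximum-likelihood multinomial logit of pattern membership on DMPW
#' (reference Agreed) adjusted for sex and anthropometric status, with
#' dietary pattern 2 as the baseline outcome by default. Reports
#' exponentiated coefficients (odds ratios) with Wald 95% CIs. Supports
#' per-subject sampling weights (e.g. cluster-size-proportional weights for
#' a conglomerate design).
#'
#' @param data Tibble carrying the outcome and predictor columns.
#' @param outcome Name of the pattern column (default "pattern").
#' @param predictors Character vector of predictor columns (default
#'   `c("dmpw", "sex", "status")`, intersected with what is present).
#' @param baseline Baseline outcome level (default `"2"`).
#' @param weights Optional numeric vector of per-subject weights.
#' @param cluster Optional cluster-id column name: when given (and
#'   `weights` is NULL), cluster-size-proportional weights
#'   n/(K * n_cluster) are used and the design effect of the outcome is
#'   reported.
#' @param conf_level Wald CI level (default 0.95).
#' @return Object of class `"nutrinet_multifit"`: list with `fit`
#'   (the `nnet::multinom` object), `or_table` (tibble outcome, term, log_or,
#'   se, odds_ratio, conf_low, conf_high, p_value), `baseline`, `deff`,
#'   `converged`.
#' @export
fit_multinomial <- function(data, outcome = "pattern",
                            predictors = intersect(c("dmpw", "sex", "status"),
                                                   names(data)),
                            baseline = "2", weights = NULL, cluster = NULL,
                            conf_level = 0.95) {
  data <- as_tibble(data)
  y <- factor(as.character(data[[outcome]]))
  if (nlevels(y) < 2) abort("outcome needs >= 2 levels")
  if (!baseline %in% levels(y)) {
    abort(paste0("baseline level ", sQuote(baseline), " not found in outcome"))
  }
  y <- stats::relevel(y, ref = baseline)
  df <- data[, predictors, drop = FALSE]
  if ("dmpw" %in% predictors) {
    df$dmpw <- factor(as.character(df$dmpw), levels = dmpw_levels())
  }
  df$.outcome <- y

  deff <- NA_real_
  if (is.null(weights)) {
    if (!is.null(cluster)) {
      sizes <- table(data[[cluster]])
      weights <- as.numeric(nrow(data) / (length(sizes) * sizes[as.character(data[[cluster]])]))
      deff <- design_effect(data, outcome = outcome, cluster = cluster)$deff
    } else {
      weights <- rep(1, nrow(data))
    }
  }
  df$.w <- weights

  form <- as.formula(paste(".outcome ~", paste(predictors, collapse = " + ")))
  fit <- nnet::multinom(form, data = df, weights = df$.w,
                        trace = FALSE, maxit = 500)
  converged <- fit$convergence == 0
  if (!converged) {
    warn("multinomial fit did not converge; estimates may be unreliable")
  }

  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levels(y)[2], names(cf)))
  V <- vcov(fit)
  se_mat <- matrix(sqrt(diag(V)), nrow = nrow(cf), byrow = TRUE,
                   dimnames = dimnames(cf))
  if (any(se_mat > 50)) {
    warn("very large standard errors: possible separation in the multinomial fit")
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  or_table <- purrr::map_dfr(rownames(cf), function(lev) {
    b <- cf[lev, ]
    s <- se_mat[lev, ]
    tibble(
      outcome = lev,
      term = colnames(cf),
      log_or = b,
      se = s,
      odds_ratio = exp(b),
      conf_low = exp(b - zq * s),
      conf_high = exp(b + zq * s),
      p_value = 2 * pnorm(-abs(b / s))
    )
  })
  structure(
    list(fit = fit, or_table = or_table, baseline = baseline,
         deff = deff, converged = converged, conf_level = conf_level),
    class = "nutrinet_multifit"
  )
}

#' @export
print.nutrinet_multifit <- function(x, ...) {
  cat("<multinomial dietary-pattern fit>  baseline pattern:", x$baseline, "\n")
  if (!is.na(x$deff)) cat("  design effect (Deff):", round(x$deff, 3), "\n")
  print(dplyr::filter(x$or_table, .data$term != "(Intercept)"), n = Inf)
  invisible(x)
}

#' Design effect of cluster (conglomerate) sampling
#'
#' Deff = 1 + (mean cluster size - 1) * ICC, with the intra-cluster
#' correlation estimated from one-way ANOVA variance components (clamped at
#' 0). For a categorical outcome the ICC is the prevalence-weighted average
#' of the per-level indicator ICCs. Values above 3 are flagged as
#' sampling-influenced (high intra-conglomerate homogeneity).
#'
#' @param data Tibble with outcome and cluster-id columns.
#' @param outcome Outcome column name (numeric or categorical).
#' @param cluster Cluster-id column name.
#' @return List with `deff`, `icc`, `mean_cluster_size`, `n_clusters`,
#'   `sampling_influenced` (TRUE when Deff > 3).
#' @export
design_effect <- function(data, outcome, cluster) {
  cl <- factor(data[[cluster]])
  if (nlevels(cl) < 2) {
    abort("design effect undefined for a single cluster",
          class = "nutrinet_validation_error")
  }
  y <- data[[outcome]]
  icc_numeric <- function(v) {
    fit <- aov(v ~ cl)
    s <- summary(fit)[[1]]
    msb <- s$`Mean Sq`[1]
    msw <- s$`Mean Sq`[2]
    sizes <- table(cl)
    n0 <- (sum(sizes) - sum(sizes^2) / sum(sizes)) / (nlevels(cl) - 1)
    max(0, (msb - msw) / (msb + (n0 - 1) * msw))
  }
  if (is.numeric(y)) {
    icc <- icc_numeric(y)
  } else {
    y <- factor(as.character(y))
    prev <- prop.table(table(y))
    iccs <- vapply(levels(y), function(l) icc_numeric(as.numeric(y == l)),
                   numeric(1))
    icc <- sum(prev * iccs)
  }
  m_bar <- nrow(data) / nlevels(cl)
  deff <- 1 + (m_bar - 1) * icc
  list(
    deff = deff, icc = icc, mean_cluster_size = m_bar,
    n_clusters = nlevels(cl), sampling_influenced = deff > 3
  )
}

#' Monte-Carlo power of the food-group fold-change comparison
#'
#' Simulates `n_groups` groups of log-normal intakes with common coefficient
#' of variation, one group's median shifted by `fold_change`, and estimates
#' the power of the Kruskal-Wallis comparison at level `alpha`.
#'
#' @param n_per_group Subjects per group (default 50).
#' @param fold_change Multiplicative shift of the affected group (default 2).
#' @param alpha Significance level (default 0.01).
#' @param n_groups Number of groups compared (default 3).
#' @param cv Coefficient of variation of intake (default 0.8).
#' @param reps Monte-Carlo replicates (default 500; < 100 warns).
#' @param seed Seed.
#' @return List with `power`, `reps`, and the call parameters.
#' @export
power_simulation <- function(n_per_group = 50, fold_change = 2, alpha = 0.01,
                             n_groups = 3, cv = 0.8, reps = 500, seed = 1) {
  stopifnot(n_per_group > 0, fold_change > 0, n_groups >= 2, cv > 0)
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (reps < 100) warn("fewer than 100 replicates: power estimate is coarse")
  sdlog <- sqrt(log(1 + cv^2))
  hits <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(reps), function(r) {
      g <- rep(seq_len(n_groups), each = n_per_group)
      mu <- ifelse(g == 1, log(fold_change), 0)
      y <- stats::rlnorm(length(g), meanlog = mu, sdlog = sdlog)
      kruskal.test(y, factor(g))$p.value < alpha
    }, logical(1))
  })
  list(power = mean(hits), reps = reps, n_per_group = n_per_group,
       fold_change = fold_change, alpha = alpha, n_groups = n_groups, cv = cv)
}
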