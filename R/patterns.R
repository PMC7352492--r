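# Abundance-of-consumption transformation and dietary-pattern discovery.
# Dietary patterns are clusters of subjects with similar composition of
# intake, found by Ward hierarchical clustering on Euclidean distances over
# the abundance rows (ecology-style relative abundances of the diet).

#' Abundance-of-consumption transformation
#'
#' Divides each subject's food-group grams by their total intake, giving the
#' proportion of the diet contributed by each group. Rows sum to 1; the
#' transform is invariant to rescaling a subject's total intake.
#'
#' @param intake Wide intake tibble (`subject_id` + grams/day per group).
#' @return Tibble of the same shape with fractions in \[0, 1\].
#' @export
#' @examples
#' intake <- tibble::tibble(subject_id = 1, a = 100, b = 300)
#' abundance_transform(intake) # 0.25, 0.75
abundance_transform <- function(intake) {
  m <- intake_matrix(intake)
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("intakes must be finite and >= 0", class = "nutrinet_validation_error")
  }
  totals <- rowSums(m)
  zero <- which(totals <= 0)
  if (length(zero) > 0) {
    abort(
      paste0("zero total intake for subject(s): ",
             paste(intake$subject_id[zero], collapse = ", ")),
      class = "nutrinet_validation_error"
    )
  }
  dplyr::bind_cols(
    tibble(subject_id = intake$subject_id),
    as_tibble(m / totals)
  )
}

#' Dietary-pattern discovery by Ward hierarchical clustering
#'
#' Agglomerative clustering (Ward's criterion, `hclust` method `"ward.D2"`)
#' on Euclidean distances between abundance rows, cut into `k` patterns.
#' Abundance fractions are clustered directly, without further
#' standardization, unless `scale_groups = TRUE` z-scores each group first.
#'
#' @param abundance Abundance tibble from [abundance_transform()].
#' @param k Number of dietary patterns (default 4).
#' @param scale_groups Z-score food-group columns before clustering
#'   (default FALSE).
#' @return Object of class `"nutrinet_patterns"`: list with `assignment`
#'   (tibble subject_id, pattern), `tree` (the `hclust` object), `k`,
#'   and `column_tree` (food-group dendrogram, display only).
#' @export
cluster_patterns <- function(abundance, k = 4, scale_groups = FALSE) {
  m <- intake_matrix(abundance)
  n <- nrow(m)
  if (k < 2 || k > n) abort("k must lie in [2, n subjects]")
  mm <- if (scale_groups) scale(m) else m
  tree <- hclust(dist(mm, method = "euclidean"), method = "ward.D2")
  labels <- cutree(tree, k = k)
  column_tree <- if (ncol(mm) >= 3) {
    hclust(dist(t(mm), method = "euclidean"), method = "ward.D2")
  }
  structure(
    list(
      assignment = tibble(subject_id = abundance$subject_id,
                          pattern = as.integer(labels)),
      tree = tree,
      column_tree = column_tree,
      k = as.integer(k)
    ),
    class = "nutrinet_patterns"
  )
}

#' @export
print.nutrinet_patterns <- function(x, ...) {
  cat("<nutrinet dietary patterns>  k =", x$k, "\n")
  print(table(pattern = x$assignment$pattern))
  invisible(x)
}

#' Pattern profiles: mean and SD of abundance per pattern and group
#'
#' Per pattern x food group mean and SD of abundance, plus a per-group
#' one-way ANOVA across patterns with Holm adjustment over the G tests.
#'
#' @param abundance Abundance tibble.
#' @param patterns A `"nutrinet_patterns"` object (or an assignment tibble
#'   with `subject_id`, `pattern`).
#' @return Object of class `"nutrinet_profile"`: list with `profile`
#'   (tibble pattern, group, mean, sd, n) and `anova` (tibble group,
#'   statistic, df_between, df_within, p_value, p_adjusted). Singleton
#'   patterns get SD 0 and a warning.
#' @export
pattern_profile <- function(abundance, patterns) {
  assignment <- if (inherits(patterns, "nutrinet_patterns")) {
    patterns$assignment
  } else {
    as_tibble(patterns)
  }
  grp_levels <- setdiff(names(abundance), "subject_id")
  long <- abundance |>
    dplyr::inner_join(assignment, by = "subject_id") |>
    tidyr::pivot_longer(-c("subject_id", "pattern"),
                        names_to = "group", values_to = "abundance") |>
    dplyr::mutate(group = factor(.data$group, levels = grp_levels))
  profile <- long |>
    dplyr::group_by(.data$pattern, .data$group) |>
    dplyr::summarise(
      mean = mean(.data$abundance),
      sd = if (dplyr::n() > 1) sd(.data$abundance) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
  if (any(profile$n == 1)) {
    warn("singleton pattern(s): SD reported as 0")
  }
  anova_tab <- long |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      if (length(unique(df$pattern)) < 2 || var(df$abundance) == 0) {
        return(tibble(statistic = 0, df_between = NA_real_,
                      df_within = NA_real_, p_value = 1))
      }
      fit <- aov(abundance ~ factor(pattern), data = df)
      s <- summary(fit)[[1]]
      tibble(
        statistic = s$`F value`[1],
        df_between = s$Df[1],
        df_within = s$Df[2],
        p_value = s$`Pr(>F)`[1]
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p_value, method = "holm"))
  structure(list(profile = profile, anova = anova_tab),
            class = "nutrinet_profile")
}

#' @export
print.nutrinet_profile <- function(x, ...) {
  cat("<nutrinet pattern profile>\n")
  print(tidyr::pivot_wider(
    dplyr::mutate(x$profile,
                  cell = sprintf("%.3f ± %.3f", .data$mean, .data$sd)),
    id_cols = "group", names_from = "pattern", values_from = "cell",
    names_prefix = "pattern "
  ), n = Inf)
  invisible(x)
}

#' Pattern composition by categorical covariates
#'
#' Pattern x covariate contingency tables with Pearson chi-square tests,
#' for sex / anthropometric status / DMPW style composition panels.
#'
#' @param patterns A `"nutrinet_patterns"` object or assignment tibble.
#' @param cohort Cohort tibble carrying `subject_id` and the covariates.
#' @param covariates Character vector of categorical cohort columns.
#' @return Tibble with one row per covariate: `covariate`, `table` (list of
#'   contingency tables), `statistic`, `df`, `p_value`, `low_expected`
#'   (TRUE when any expected count < 5).
#' @export
pattern_composition <- function(patterns, cohort,
                                covariates = intersect(c("sex", "status", "dmpw"),
                                                       names(cohort))) {
  assignment <- if (inherits(patterns, "nutrinet_patterns")) {
    patterns$assignment
  } else {
    as_tibble(patterns)
  }
  joined <- dplyr::inner_join(assignment, cohort, by = "subject_id")
  purrr::map_dfr(covariates, function(cv) {
    tab <- table(pattern = joined$pattern, level = as.character(joined[[cv]]))
    keep <- colSums(tab) > 0
    tab <- tab[, keep, drop = FALSE]
    res <- chi_square_table(tab, warn_low_expected = FALSE)
    tibble(
      covariate = cv,
      table = list(tab),
      statistic = res$statistic,
      df = res$df,
      p_value = res$p_value,
      low_expected = res$low_expected
    )
  })
}
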