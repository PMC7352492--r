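# Cohort / FFQ generation with planted ground truth. All randomness is
# scoped with withr::with_seed on substreams of the config seed, so each
# stage is bit-reproducible and re-runnable in isolation.

#' Generate a synthetic adolescent cohort with planted truth
#'
#' Draws sex, DMPW label, anthropometric status, BMI-for-age percentile,
#' perceived weight, school-class cluster, dietary-pattern label and design
#' covariates per subject. Status is drawn from the configured marginals
#' restricted to statuses feasible for the subject's DMPW label (the ordinal
#' truth table leaves e.g. no room for an obese overestimator); the
#' percentile is drawn uniformly within the band of the assigned status; the
#' perceived-weight response is obtained by inverting the DMPW rule. Pattern
#' labels are drawn from cluster-level mixture weights perturbed around
#' `pattern_mixture_weights` with concentration `(1 - icc)/icc`, producing
#' the configured intra-conglomerate correlation of pattern membership.
#'
#' @param config A [generator_config()].
#' @return List with elements `cohort` (tibble: subject_id, sex, age_years,
#'   cluster, socioeconomic, pubertal_stage, weight_kg, height_m, bmi,
#'   bmi_for_age_percentile, status, perceived_weight, perceived_level,
#'   dmpw) and `truth` (class `"nutrinet_truth"`: per-subject labels plus
#'   the planted signed edge lists per DMPW group).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "nutrinet_config"))
  n <- config$n_subjects
  withr::with_seed(substream_seed(config$seed, "cohort"), {
    sex <- sample(c("female", "male"), n, replace = TRUE,
                  prob = c(config$sex_proportion_female,
                           1 - config$sex_proportion_female))
    cluster <- sort(rep_len(seq_len(config$n_clusters), n))

    # cluster-level pattern propensities: Dirichlet around the global
    # weights with concentration (1 - icc)/icc => indicator ICC ~ icc
    w <- config$pattern_mixture_weights
    if (config$icc > 0) {
      conc <- (1 - config$icc) / config$icc
      wc <- matrix(
        vapply(seq_len(config$n_clusters), function(cl) {
          g <- stats::rgamma(length(w), shape = conc * w)
          g / sum(g)
        }, numeric(length(w))),
        nrow = config$n_clusters, ncol = length(w), byrow = TRUE
      )
    } else {
      wc <- matrix(w, nrow = config$n_clusters, ncol = length(w), byrow = TRUE)
    }
    pattern <- vapply(seq_len(n), function(i) {
      sample.int(length(w), 1, prob = wc[cluster[i], ])
    }, integer(1))

    dmpw <- sample(dmpw_levels(), n, replace = TRUE,
                   prob = config$dmpw_proportions)

    feas <- dmpw_feasible_statuses()
    status <- vapply(dmpw, function(d) {
      p <- config$status_proportions[feas[[d]]]
      sample(names(p), 1, prob = p)
    }, character(1))

    band <- list(
      underweight = c(0, 3), normal = c(3, 85),
      overweight = c(85, 97), obese = c(97, 100)
    )
    lo <- vapply(status, function(s) band[[s]][1], numeric(1))
    hi <- vapply(status, function(s) band[[s]][2], numeric(1))
    percentile <- runif(n, lo, hi)

    # perceived level inverts the DMPW rule given the measured ordinal level
    m <- status_ordinal(status)
    p_lvl <- vapply(seq_len(n), function(i) {
      switch(dmpw[i],
        Agreed = m[i],
        Underestimated = sample.int(m[i], 1) - 1L,       # < m
        Overestimated = m[i] + sample.int(2L - m[i], 1)  # > m
      )
    }, numeric(1))
    perceived <- vapply(p_lvl, function(pl) {
      switch(as.character(pl),
        `0` = sample(c("thin", "very thin"), 1),
        `1` = "normal",
        `2` = sample(c("fat", "very fat"), 1)
      )
    }, character(1))

    # anthropometrics consistent with the percentile ordering
    height <- round(rnorm(n, 1.60, 0.08), 3)
    bmi <- qlnorm(pmin(pmax(percentile / 100, 1e-6), 1 - 1e-6),
                  meanlog = log(19), sdlog = 0.14)
    weight <- round(bmi * height^2 + 0.1, 2)

    age <- round(runif(n, 11, 17), 1)
    socio <- sample(c("good", "poor"), n, replace = TRUE)
    pubertal <- sample(c("pre-pubertal", "pubertal", "post-pubertal"), n,
                       replace = TRUE, prob = c(0.084, 0.218, 0.698))
  })

  cohort <- tibble(
    subject_id = seq_len(n),
    sex = sex,
    age_years = age,
    cluster = cluster,
    socioeconomic = socio,
    pubertal_stage = pubertal,
    weight_kg = weight,
    height_m = height,
    bmi_for_age_percentile = percentile,
    perceived_weight = perceived
  )
  cohort <- add_anthropometry(cohort)

  planted <- purrr::map(config$correlation_spec, planted_edge_list)
  truth <- structure(
    list(
      labels = tibble(
        subject_id = seq_len(n),
        pattern = pattern,
        dmpw = factor(dmpw, levels = dmpw_levels()),
        cluster = cluster
      ),
      planted_edges = dplyr::bind_rows(planted, .id = "dmpw"),
      config = config
    ),
    class = "nutrinet_truth"
  )
  if (!identical(as.character(truth$labels$dmpw), as.character(cohort$dmpw))) {
    abort("internal error: planted DMPW labels do not re-classify") # nocov
  }
  list(cohort = cohort, truth = truth)
}

#' @export
print.nutrinet_truth <- function(x, ...) {
  cat("<nutrinet planted truth>\n")
  cat("  subjects:", nrow(x$labels), "\n")
  cat("  planted |rho|>0.5 edges by DMPW group:\n")
  print(table(x$planted_edges$dmpw, x$planted_edges$sign))
  invisible(x)
}

#' Generate food-group daily intakes from planted structure
#'
#' Draws each subject's 14-group grams/day vector from a log-normal Gaussian
#' copula: within a DMPW group, latent normals have the Pearson correlation
#' `2 sin(pi rho_s / 6)` calibrated to the target Spearman matrix of that
#' group (rank correlations survive the monotone marginal transform, so
#' planted Spearman values are exact in expectation); marginal location is
#' the subject's pattern centroid and scale is `noise_scale`.
#'
#' @param cohort_bundle The list returned by [generate_cohort()] (or a
#'   cohort tibble together with `truth`).
#' @param config A [generator_config()]; defaults to the one recorded in the
#'   planted truth.
#' @return Wide intake tibble: `subject_id` + one grams/day column per food
#'   group.
#' @export
generate_ffq_intakes <- function(cohort_bundle, config = NULL) {
  truth <- cohort_bundle$truth
  stopifnot(inherits(truth, "nutrinet_truth"))
  config <- config %||% truth$config
  labels <- truth$labels
  n <- nrow(labels)
  G <- config$n_food_groups
  groups <- colnames(config$pattern_centroids) %||% food_groups()[seq_len(G)]

  intake <- matrix(NA_real_, n, G, dimnames = list(NULL, groups))
  withr::with_seed(substream_seed(config$seed, "intakes"), {
    for (d in dmpw_levels()) {
      idx <- which(labels$dmpw == d)
      if (length(idx) == 0) next
      R_p <- spearman_to_pearson_psd(config$correlation_spec[[d]],
                                     config$psd_tolerance)
      L <- chol(R_p + diag(1e-10, G))
      z <- matrix(rnorm(length(idx) * G), length(idx), G) %*% L
      u <- pnorm(z)
      mu <- config$pattern_centroids[labels$pattern[idx], , drop = FALSE]
      intake[idx, ] <- qlnorm(u, meanlog = mu, sdlog = config$noise_scale)
    }
  })
  dplyr::bind_cols(tibble(subject_id = labels$subject_id), as_tibble(intake))
}

#' Generate item-level FFQ responses from group intakes
#'
#' Inverse of the FFQ module, so the full pipeline can be exercised from raw
#' responses. Each group's daily grams are split evenly over its mapped
#' items; each item's implied occasions/day (target grams divided by the
#' reference portion) is snapped to the nearest frequency-grid multiplier,
#' and the portion is then set so that category x portion reproduces the
#' target exactly. The only loss is quantization to "never/rare" for targets
#' below half the monthly-category rate: at most
#' `reference_portion_g * (2/30.44) / 2` grams/day per item.
#'
#' @param intakes Wide intake tibble from [generate_ffq_intakes()] (or the
#'   ffq module).
#' @param group_map Item-to-group map; every group present in `intakes` must
#'   have at least one item.
#' @param config A [generator_config()] (supplies `reference_portion_g`).
#' @return FFQ response tibble: subject_id, item_id, frequency, portion_g.
#' @export
generate_ffq_responses <- function(intakes, group_map = default_group_map(),
                                   config = generator_config()) {
  groups <- setdiff(names(intakes), "subject_id")
  missing_groups <- setdiff(groups, unique(group_map$group))
  if (length(missing_groups) > 0) {
    abort(paste0("groups with no mapped items: ",
                 paste(sQuote(missing_groups), collapse = ", ")),
          class = "nutrinet_validation_error")
  }
  ref <- config$reference_portion_g
  factors <- ffq_frequency_factors()

  long <- tidyr::pivot_longer(intakes, -"subject_id",
                              names_to = "group", values_to = "grams")
  items <- group_map[group_map$group %in% groups, ]
  per_group <- split(items$item_id, items$group)

  resp <- long |>
    dplyr::mutate(items = purrr::map(.data$group, ~per_group[[.x]])) |>
    tidyr::unnest("items") |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::mutate(target = .data$grams / dplyr::n()) |>
    dplyr::ungroup()

  occ <- resp$target / ref
  cat_idx <- vapply(occ, function(o) which.min(abs(factors - o)), integer(1))
  frequency <- names(factors)[cat_idx]
  f <- unname(factors[cat_idx])
  portion <- ifelse(f > 0, resp$target / f, ref)

  tibble(
    subject_id = resp$subject_id,
    item_id = resp$items,
    frequency = frequency,
    portion_g = portion
  ) |>
    dplyr::arrange(.data$subject_id, .data$item_id)
}
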