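# Synthetic-cohort generator configuration and its defaults. The generator
# emulates a ~1,500-adolescent school-based cohort: marginal frequencies of
# sex, DMPW and anthropometric status; four dietary-pattern blocks on a
# realistic grams/day scale; and per-DMPW-group rank-correlation structure
# (all-positive in Agreed/Underestimated, partially negative in
# Overestimated). Planted structure is recorded so recovery can be tested.

#' Default marginal proportions of anthropometric status
#'
#' Eutrophic-dominant adolescent marginals: 77.2% normal, 8.8% overweight,
#' 5.9% obese, remainder underweight.
#' @return Named numeric vector over the four status levels.
#' @export
default_status_proportions <- function() {
  c(underweight = 0.081, normal = 0.772, overweight = 0.088, obese = 0.059)
}

#' Default dietary-pattern centroids (mean log-intakes)
#'
#' A k x G matrix of mean log grams/day. Row profiles mirror the qualitative
#' structure of the four observed dietary patterns: pattern 1 dominated by
#' coffee and tea with high beans; pattern 2 uniformly low with little
#' coffee; pattern 3 with sole predominance of beans and legumes; pattern 4
#' high across the board, led by sweetened beverages. Column magnitudes are
#' seeded from typical adolescent food-group medians (grams/day) so output
#' lands on a realistic scale.
#'
#' @param separation Multiplicative strength of the pattern-defining
#'   contrasts (1 = default realism; larger values give cleaner, benchmark
#'   -style separation for recovery studies).
#' @return 4 x 14 matrix of mean log-intakes, dimnames pattern x group.
#' @export
default_pattern_centroids <- function(separation = 1) {
  base <- c(
    sugar_sweets = 243, sweetened_beverages = 480, processed_meat = 11,
    fast_food = 170, brazilian_dishes = 97, oils = 29, milk_dairy = 166,
    meat = 123, rice_cereals = 461, roots = 25, beans_legumes = 149,
    vegetables = 67, fruits = 466, coffee_tea = 107
  )
  mult <- rbind(
    `1` = c(sugar_sweets = 1, sweetened_beverages = 1.2, processed_meat = 1,
            fast_food = 1, brazilian_dishes = 1, oils = 1, milk_dairy = 1,
            meat = 1, rice_cereals = 1, roots = 1, beans_legumes = 2.5,
            vegetables = 1, fruits = 1, coffee_tea = 8),
    `2` = c(sugar_sweets = 0.7, sweetened_beverages = 0.7, processed_meat = 0.7,
            fast_food = 0.7, brazilian_dishes = 0.7, oils = 0.5, milk_dairy = 0.5,
            meat = 0.6, rice_cereals = 0.5, roots = 0.6, beans_legumes = 0.35,
            vegetables = 0.7, fruits = 0.7, coffee_tea = 0.08),
    `3` = c(sugar_sweets = 0.9, sweetened_beverages = 0.8, processed_meat = 0.9,
            fast_food = 0.9, brazilian_dishes = 0.9, oils = 1, milk_dairy = 1,
            meat = 1.1, rice_cereals = 1.2, roots = 0.9, beans_legumes = 4,
            vegetables = 0.9, fruits = 0.8, coffee_tea = 0.7),
    `4` = c(sugar_sweets = 2.2, sweetened_beverages = 2.8, processed_meat = 2,
            fast_food = 2, brazilian_dishes = 2, oils = 1.5, milk_dairy = 2,
            meat = 1.6, rice_cereals = 1.3, roots = 2, beans_legumes = 1.6,
            vegetables = 2, fruits = 1.5, coffee_tea = 1.2)
  )
  mult <- mult[, names(base)]
  centro <- log(base)[col(mult)] + separation * log(mult)
  dim(centro) <- dim(mult)
  dimnames(centro) <- list(pattern = rownames(mult), group = names(base))
  centro
}

# Equicorrelated positive block helper on a G x G identity base.
add_block <- function(R, members, rho) {
  idx <- match(members, colnames(R))
  R[idx, idx] <- rho
  diag(R) <- 1
  R
}

#' Default per-DMPW-group target Spearman structure
#'
#' Named list of 14 x 14 symmetric unit-diagonal target Spearman matrices,
#' one per DMPW group. Agreed and Underestimated carry only positive planted
#' blocks (dense and moderately dense, respectively); Overestimated is
#' sparser and contains planted negative correlations, built from a
#' one-factor model in which roots loads negatively against oils, processed
#' meat and coffee/tea (so roots-oils = -0.7 and the matrix is positive
#' semi-definite by construction), plus a vegetables - sweetened-beverages
#' inverse pair and two positive pairs.
#'
#' @return Named list (`Agreed`, `Underestimated`, `Overestimated`) of
#'   matrices with dimnames [food_groups()].
#' @export
default_correlation_spec <- function() {
  g <- food_groups()
  eye <- diag(length(g))
  dimnames(eye) <- list(g, g)

  agreed <- eye |>
    add_block(c("brazilian_dishes", "vegetables", "beans_legumes", "meat",
                "rice_cereals"), 0.65) |>
    add_block(c("sugar_sweets", "sweetened_beverages", "fast_food"), 0.6)

  under <- eye |>
    add_block(c("milk_dairy", "sugar_sweets", "sweetened_beverages",
                "fast_food"), 0.65) |>
    add_block(c("meat", "rice_cereals", "beans_legumes"), 0.6) |>
    add_block(c("fruits", "vegetables"), 0.6)

  # one-factor negative star: rho_ij = lambda_i * lambda_j
  over <- eye
  lambda <- c(roots = -0.88, oils = 0.795, processed_meat = 0.682,
              coffee_tea = 0.682)
  idx <- match(names(lambda), g)
  over[idx, idx] <- tcrossprod(lambda)
  diag(over) <- 1
  over <- over |>
    add_block(c("vegetables", "sweetened_beverages"), -0.6) |>
    add_block(c("fruits", "rice_cereals"), 0.65) |>
    add_block(c("meat", "milk_dairy"), 0.6)

  list(Agreed = agreed, Underestimated = under, Overestimated = over)
}

#' Generator configuration
#'
#' Validates and assembles the configuration driving [generate_cohort()],
#' [generate_ffq_intakes()] and [generate_ffq_responses()]. Defaults emulate
#' the study conditions of a 1,496-adolescent school cohort.
#'
#' @param n_subjects Cohort size (default 1496).
#' @param sex_proportion_female Fraction female (default 0.571).
#' @param dmpw_proportions 3-vector (Agreed, Underestimated, Overestimated);
#'   default `c(0.683, 0.197, 0.120)`.
#' @param status_proportions Named 4-vector of status marginals; default
#'   [default_status_proportions()].
#' @param n_food_groups Number of food groups G (default 14; must match the
#'   centroid/correlation dimensions).
#' @param n_patterns Number of dietary patterns k (default 4).
#' @param pattern_mixture_weights k-vector of pattern prevalences (default
#'   uniform).
#' @param pattern_centroids k x G matrix of mean log-intakes (default
#'   [default_pattern_centroids()]).
#' @param correlation_spec Named list of per-DMPW G x G target Spearman
#'   matrices (default [default_correlation_spec()]). Symmetric with unit
#'   diagonal; repaired towards the nearest positive semi-definite matrix if
#'   needed (error beyond `psd_tolerance`).
#' @param noise_scale Log-scale intake SD (sdlog of the marginal log-normal;
#'   default 0.5).
#' @param n_clusters Number of school-class "conglomerates" (default 50).
#' @param icc Intra-cluster correlation of pattern membership in \[0, 1)
#'   (default 0.004, i.e. a design effect near 1.12 at ~30 subjects/cluster).
#' @param reference_portion_g Per-occasion reference portion used when
#'   quantizing intakes onto the FFQ frequency grid (default 100 g).
#' @param psd_tolerance Maximum absolute entry change tolerated during
#'   nearest-PSD repair (default 0.05).
#' @param seed Integer master seed (mandatory for generation).
#' @return Object of class `"nutrinet_config"` (a validated list).
#' @export
generator_config <- function(n_subjects = 1496,
                             sex_proportion_female = 0.571,
                             dmpw_proportions = c(0.683, 0.197, 0.120),
                             status_proportions = default_status_proportions(),
                             n_food_groups = 14,
                             n_patterns = 4,
                             pattern_mixture_weights = rep(1 / n_patterns, n_patterns),
                             pattern_centroids = default_pattern_centroids(),
                             correlation_spec = default_correlation_spec(),
                             noise_scale = 0.5,
                             n_clusters = 50,
                             icc = 0.004,
                             reference_portion_g = 100,
                             psd_tolerance = 0.05,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_food_groups >= 2, n_patterns >= 1,
            n_clusters >= 1, noise_scale > 0, reference_portion_g > 0)
  if (sex_proportion_female < 0 || sex_proportion_female > 1) {
    abort("sex_proportion_female must lie in [0, 1]")
  }
  if (length(dmpw_proportions) != 3) abort("dmpw_proportions must have length 3")
  check_proportions(dmpw_proportions, "dmpw_proportions")
  names(dmpw_proportions) <- dmpw_levels()
  if (!all(status_levels() %in% names(status_proportions))) {
    abort("status_proportions must be named over the four status levels")
  }
  status_proportions <- status_proportions[status_levels()]
  check_proportions(status_proportions, "status_proportions")
  check_proportions(pattern_mixture_weights, "pattern_mixture_weights")
  if (length(pattern_mixture_weights) != n_patterns) {
    abort("pattern_mixture_weights must have length n_patterns")
  }
  if (icc < 0 || icc >= 1) abort("icc must lie in [0, 1)")
  if (!is.matrix(pattern_centroids) ||
      nrow(pattern_centroids) != n_patterns ||
      ncol(pattern_centroids) != n_food_groups) {
    abort("pattern_centroids must be an n_patterns x n_food_groups matrix")
  }
  if (any(!is.finite(exp(pattern_centroids))) || any(exp(pattern_centroids) <= 0)) {
    abort("pattern_centroids must be finite log-intakes (positive grams)")
  }
  if (!all(dmpw_levels() %in% names(correlation_spec))) {
    abort("correlation_spec must be a named list over the DMPW levels")
  }
  for (d in dmpw_levels()) {
    R <- correlation_spec[[d]]
    if (!is.matrix(R) || nrow(R) != n_food_groups || ncol(R) != n_food_groups) {
      abort(paste0("correlation_spec$", d, " must be ", n_food_groups, " x ",
                   n_food_groups))
    }
    if (max(abs(R - t(R))) > 1e-8 || any(abs(diag(R) - 1) > 1e-8) ||
        any(abs(R) > 1 + 1e-8)) {
      abort(paste0("correlation_spec$", d,
                   " must be symmetric with unit diagonal and entries in [-1, 1]"))
    }
  }
  # DMPW feasibility against the status marginals: overestimation needs mass
  # on {underweight, normal}; underestimation on {normal, overweight, obese}.
  feas <- dmpw_feasible_statuses()
  for (d in dmpw_levels()) {
    if (dmpw_proportions[[d]] > 0 && sum(status_proportions[feas[[d]]]) <= 0) {
      abort(
        paste0("infeasible configuration: DMPW ", sQuote(d),
               " requested but the status marginals put no mass on its ",
               "feasible statuses (", paste(feas[[d]], collapse = ", "), ")"),
        class = "nutrinet_config_error"
      )
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      sex_proportion_female = sex_proportion_female,
      dmpw_proportions = dmpw_proportions,
      status_proportions = status_proportions,
      n_food_groups = as.integer(n_food_groups),
      n_patterns = as.integer(n_patterns),
      pattern_mixture_weights = pattern_mixture_weights,
      pattern_centroids = pattern_centroids,
      correlation_spec = correlation_spec,
      noise_scale = noise_scale,
      n_clusters = as.integer(n_clusters),
      icc = icc,
      reference_portion_g = reference_portion_g,
      psd_tolerance = psd_tolerance,
      seed = as.integer(seed)
    ),
    class = "nutrinet_config"
  )
}

#' Benchmark configurations with recoverable planted structure
#'
#' Two preset study conditions used by the recovery test suite.
#'
#' `pattern_recovery_config()` strengthens the pattern-defining centroid
#' contrasts (separation 2.5 on the log scale) and tightens within-pattern
#' noise (`noise_scale` 0.3) so the four planted dietary patterns are
#' well-separated Gaussian blobs in abundance space — the regime in which
#' Ward clustering is expected to recover the labels (ARI at or above 0.9).
#'
#' `network_recovery_config()` isolates the planted per-DMPW-group
#' correlation structure: it draws equal-sized DMPW groups and holds the
#' dietary-pattern centroid fixed (a single mixture component), because the
#' pooled rank correlation of a subgroup equals the copula target exactly
#' only when all its subjects share one marginal location; with widely
#' separated pattern centroids the between-pattern variation dilutes the
#' within-pattern correlations.
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed.
#' @param ... Further arguments passed to [generator_config()].
#' @return A [generator_config()].
#' @export
pattern_recovery_config <- function(n_subjects = 600, seed = 1L, ...) {
  generator_config(
    n_subjects = n_subjects,
    pattern_centroids = default_pattern_centroids(separation = 2.5),
    noise_scale = 0.3,
    seed = seed,
    ...
  )
}

#' @rdname pattern_recovery_config
#' @export
network_recovery_config <- function(n_subjects = 900, seed = 1L, ...) {
  generator_config(
    n_subjects = n_subjects,
    dmpw_proportions = rep(1 / 3, 3),
    n_patterns = 1,
    pattern_mixture_weights = 1,
    pattern_centroids = default_pattern_centroids()[2, , drop = FALSE],
    seed = seed,
    ...
  )
}

# Statuses compatible with each DMPW label under the ordinal rule
# (perceived in {0,1,2}; measured underweight 0, normal 1, over/obese 2).
dmpw_feasible_statuses <- function() {
  list(
    Agreed = status_levels(),
    Underestimated = c("normal", "overweight", "obese"),
    Overestimated = c("underweight", "normal")
  )
}

#' @export
print.nutrinet_config <- function(x, ...) {
  cat("<nutrinet generator config>\n")
  cat("  subjects:", x$n_subjects, " clusters:", x$n_clusters,
      " icc:", x$icc, "\n")
  cat("  food groups:", x$n_food_groups, " patterns:", x$n_patterns, "\n")
  cat("  DMPW proportions:",
      paste(sprintf("%s %.3f", names(x$dmpw_proportions), x$dmpw_proportions),
            collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Spearman target -> Pearson-on-normal-scores calibration for the Gaussian
# copula: rho_pearson = 2 sin(pi rho_s / 6). Repaired to the nearest PSD
# correlation matrix when needed; entry changes beyond `tol` are an error.
spearman_to_pearson_psd <- function(R_s, tol = 0.05) {
  R_p <- 2 * sin(pi * R_s / 6)
  diag(R_p) <- 1
  ev <- eigen(R_p, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    rep_ <- as.matrix(Matrix::nearPD(R_p, corr = TRUE, keepDiag = TRUE)$mat)
    if (max(abs(rep_ - R_p)) > tol) {
      abort("correlation_spec is not positive semi-definite within repair tolerance",
            class = "nutrinet_config_error")
    }
    R_p <- rep_
  }
  dimnames(R_p) <- dimnames(R_s)
  R_p
}

# Planted |rho| > 0.5 signed edge list of one target matrix.
planted_edge_list <- function(R, threshold = 0.5) {
  g <- colnames(R)
  idx <- which(upper.tri(R) & abs(R) > threshold, arr.ind = TRUE)
  rho <- R[idx]
  tibble(
    group1 = g[idx[, 1]],
    group2 = g[idx[, 2]],
    rho = rho,
    sign = c("negative", "positive")[(rho > 0) + 1L]
  )
}
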