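# Anthropometric status and divergence between measured and perceived weight
# (DMPW). Status comes from BMI-for-age percentile bands; DMPW compares the
# measured status (collapsed to a 3-level ordinal scale) with the subject's
# self-perceived weight.

#' Body-mass index with uniform-weight correction
#'
#' BMI = (measured weight - uniform mass) / height^2. Subjects are weighed in
#' school uniform; the uniform's mass (default 100 g) is subtracted before
#' the BMI computation.
#'
#' @param weight_kg Measured weight, kg.
#' @param height_m Height, m.
#' @param uniform_mass Mass of clothing subtracted, kg (default 0.1).
#' @return Numeric vector, kg/m^2.
#' @export
#' @examples
#' compute_bmi(50.1, 1.60) # 19.531
compute_bmi <- function(weight_kg, height_m, uniform_mass = 0.1) {
  corrected <- weight_kg - uniform_mass
  if (any(!is.finite(corrected)) || any(corrected <= 0)) {
    abort("corrected weight (weight - uniform mass) must be positive",
          class = "nutrinet_validation_error")
  }
  if (any(!is.finite(height_m)) || any(height_m <= 0)) {
    abort("height must be positive", class = "nutrinet_validation_error")
  }
  corrected / height_m^2
}

#' Classify anthropometric status from BMI-for-age percentile
#'
#' WHO 2007-style percentile bands, closed on the left:
#' underweight \[0, 3), normal \[3, 85), overweight \[85, 97), obese
#' \[97, 100\]. The percentile itself is an input (computed externally
#' against a growth reference, or via [lms_percentile()] from a
#' user-supplied LMS table).
#'
#' @param percentile Numeric vector in \[0, 100\].
#' @return Factor with levels underweight < normal < overweight < obese.
#' @export
#' @examples
#' classify_status(c(2.9, 3, 85, 97))
classify_status <- function(percentile) {
  if (any(!is.finite(percentile)) || any(percentile < 0) || any(percentile > 100)) {
    abort("percentile must lie in [0, 100]", class = "nutrinet_validation_error")
  }
  cut(
    percentile,
    breaks = c(-Inf, 3, 85, 97, Inf),
    labels = status_levels(),
    right = FALSE
  )
}

#' Collapse the raw perceived-weight response to three levels
#'
#' Maps \{very thin, thin\} to thin and \{fat, very fat\} to fat, leaving
#' normal; the result carries the ordinal coding thin = 0, normal = 1,
#' fat = 2.
#'
#' @param response Character/factor vector over
#'   `c("very thin", "thin", "normal", "fat", "very fat")` (already-collapsed
#'   values are also accepted).
#' @return Factor thin < normal < fat.
#' @export
collapse_perception <- function(response) {
  response <- as.character(response)
  ok <- response %in% c(perception_levels_raw(), perception_levels())
  if (any(!ok)) {
    abort(
      paste0("unknown perceived-weight response: ",
             paste(sQuote(unique(response[!ok])), collapse = ", ")),
      class = "nutrinet_parse_error"
    )
  }
  collapsed <- dplyr::case_when(
    response %in% c("very thin", "thin") ~ "thin",
    response %in% c("fat", "very fat") ~ "fat",
    TRUE ~ "normal"
  )
  factor(collapsed, levels = perception_levels())
}

# Ordinal coding of measured status used by the DMPW rule. Overweight and
# obese share level 2 because the perception scale tops out at "fat/very
# fat"; this is the only reading under which the classification is a total
# function of (status, perception).
status_ordinal <- function(status) {
  unname(c(underweight = 0, normal = 1, overweight = 2, obese = 2)[as.character(status)])
}

perception_ordinal <- function(level) {
  unname(c(thin = 0, normal = 1, fat = 2)[as.character(level)])
}

#' Classify divergence between measured and perceived weight (DMPW)
#'
#' Measured status is mapped to an ordinal level (underweight 0, normal 1,
#' overweight/obese 2) and compared with the collapsed perceived level
#' (thin 0, normal 1, fat 2): Agreed when equal, Underestimated when the
#' perceived level is below the measured one, Overestimated when above.
#' Structurally, overestimation can only occur among underweight or normal
#' subjects, and underestimation never among the underweight.
#'
#' @param status Factor/character of anthropometric status
#'   (see [classify_status()]).
#' @param perceived Collapsed perceived level (see [collapse_perception()]),
#'   or a raw 5-level response (collapsed on the fly).
#' @return Factor with levels Agreed, Underestimated, Overestimated.
#' @export
#' @examples
#' classify_dmpw("overweight", "normal")  # Underestimated
#' classify_dmpw("normal", "fat")         # Overestimated
classify_dmpw <- function(status, perceived) {
  status <- as.character(status)
  bad <- setdiff(unique(status), status_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown status: ", paste(sQuote(bad), collapse = ", ")),
          class = "nutrinet_parse_error")
  }
  perceived <- collapse_perception(perceived)
  m <- status_ordinal(status)
  p <- perception_ordinal(perceived)
  lab <- dplyr::case_when(
    p == m ~ "Agreed",
    p < m ~ "Underestimated",
    TRUE ~ "Overestimated"
  )
  factor(lab, levels = dmpw_levels())
}

#' Add derived anthropometry columns to a cohort table
#'
#' Convenience wrapper: computes BMI (if weight/height present), classifies
#' status from `bmi_for_age_percentile`, collapses `perceived_weight`, and
#' derives the DMPW label.
#'
#' @param cohort Tibble with at least `bmi_for_age_percentile` and
#'   `perceived_weight`; optionally `weight_kg`, `height_m`.
#' @param uniform_mass Passed to [compute_bmi()].
#' @return The cohort with `bmi` (when computable), `status`,
#'   `perceived_level`, `dmpw` columns appended/overwritten.
#' @export
add_anthropometry <- function(cohort, uniform_mass = 0.1) {
  cohort <- as_tibble(cohort)
  if (all(c("weight_kg", "height_m") %in% names(cohort))) {
    cohort$bmi <- compute_bmi(cohort$weight_kg, cohort$height_m, uniform_mass)
  }
  cohort$status <- classify_status(cohort$bmi_for_age_percentile)
  cohort$perceived_level <- collapse_perception(cohort$perceived_weight)
  cohort$dmpw <- classify_dmpw(cohort$status, cohort$perceived_level)
  cohort
}

#' DMPW frequency table
#'
#' Counts and percentages of subjects by DMPW label, overall or crossed with
#' grouping columns (e.g. sex, status) for frequency-panel summaries.
#'
#' @param cohort Tibble with a `dmpw` column (factor or character over
#'   [dmpw_levels()]).
#' @param by Optional character vector of cohort columns to stratify by;
#'   percentages are then within stratum.
#' @return Tibble with columns `by...`, `dmpw`, `n`, `pct` (percent, 1
#'   decimal not applied — full precision; round for display). Class
#'   `"nutrinet_dmpw_table"`.
#' @export
#' @examples
#' cohort <- tibble::tibble(
#'   dmpw = rep(dmpw_levels(), c(1022, 294, 180))
#' )
#' dmpw_frequency_table(cohort)
dmpw_frequency_table <- function(cohort, by = NULL) {
  if (nrow(cohort) == 0) abort("empty cohort", class = "nutrinet_validation_error")
  if (!"dmpw" %in% names(cohort)) abort("cohort lacks a dmpw column")
  cohort <- dplyr::mutate(
    as_tibble(cohort),
    dmpw = factor(as.character(.data$dmpw), levels = dmpw_levels())
  )
  tab <- cohort |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::count(.data$dmpw, .drop = FALSE) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  class(tab) <- c("nutrinet_dmpw_table", class(tab))
  tab
}

#' BMI-for-age percentile from an LMS growth reference
#'
#' Computes percentiles via the standard LMS z-score transform
#' z = ((bmi/M)^L - 1) / (L S) (or log(bmi/M)/S when L = 0) against a
#' user-supplied reference table; growth references are external inputs and
#' are not bundled.
#'
#' @param bmi BMI values, kg/m^2.
#' @param sex Sex per subject, matching the reference's `sex` coding.
#' @param age_months Age in months per subject; matched to the nearest
#'   reference row within sex.
#' @param reference Tibble with columns `sex`, `age_months`, `L`, `M`, `S`.
#' @return Percentiles in \[0, 100\].
#' @export
lms_percentile <- function(bmi, sex, age_months, reference) {
  needed <- c("sex", "age_months", "L", "M", "S")
  if (!all(needed %in% names(reference))) {
    abort("reference needs columns sex, age_months, L, M, S")
  }
  n <- length(bmi)
  z <- numeric(n)
  for (i in seq_len(n)) {
    ref <- reference[reference$sex == sex[i], ]
    if (nrow(ref) == 0) abort(paste0("no reference rows for sex ", sQuote(sex[i])))
    row <- ref[which.min(abs(ref$age_months - age_months[i])), ]
    z[i] <- if (abs(row$L) < 1e-12) {
      log(bmi[i] / row$M) / row$S
    } else {
      ((bmi[i] / row$M)^row$L - 1) / (row$L * row$S)
    }
  }
  100 * pnorm(z)
}
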