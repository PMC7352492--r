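# Internal helpers shared across modules.

#' Canonical food-group labels
#'
#' The 14 food groups used throughout the package. They mirror the grouping
#' of a 97-item semi-quantitative FFQ for adolescents in Northeast Brazil by
#' similarity in nutritional composition; the item-to-group membership is
#' user-supplied data, only the group labels are fixed defaults.
#'
#' @return Character vector of length 14.
#' @export
#' @examples
#' food_groups()
food_groups <- function() {
  c(
    "sugar_sweets", "sweetened_beverages", "processed_meat", "fast_food",
    "brazilian_dishes", "oils", "milk_dairy", "meat", "rice_cereals",
    "roots", "beans_legumes", "vegetables", "fruits", "coffee_tea"
  )
}

#' DMPW level labels
#' @return Character vector `c("Agreed", "Underestimated", "Overestimated")`.
#' @export
dmpw_levels <- function() c("Agreed", "Underestimated", "Overestimated")

status_levels <- function() c("underweight", "normal", "overweight", "obese")

perception_levels_raw <- function() {
  c("very thin", "thin", "normal", "fat", "very fat")
}

perception_levels <- function() c("thin", "normal", "fat")

# Deterministic per-stage substream seed derived from a single master seed,
# so pipeline stages can be rerun in isolation with identical draws.
# Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Extract the subject-by-group numeric matrix from a wide intake/abundance
# tibble (subject_id + one column per food group).
intake_matrix <- function(x, groups = NULL) {
  stopifnot(is.data.frame(x), "subject_id" %in% names(x))
  if (is.null(groups)) groups <- setdiff(names(x), "subject_id")
  m <- as.matrix(x[, groups, drop = FALSE])
  if (!is.numeric(m)) abort("intake columns must be numeric")
  rownames(m) <- as.character(x$subject_id)
  m
}

# Adjusted Rand index between two partitions; used to score recovery of
# planted pattern labels. Hubert & Arabie chance-corrected form.
#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to measure recovery of planted dietary-pattern labels.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Validate that p is a probability vector summing to 1.
check_proportions <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(paste0(what, " must lie in [0, 1]"))
  }
  if (abs(sum(p) - 1) > 1e-8) {
    abort(paste0(what, " must sum to 1 (got ", format(sum(p)), ")"))
  }
  invisible(p)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
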