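# FFQ processing: frequency categories -> occasions/day -> grams/day -> food
# groups. The instrument records, per food item, a frequency-of-consumption
# category and a portion size in grams (volumes in mL are treated as grams,
# density 1).

#' FFQ frequency categories
#'
#' The closed set of frequency-of-consumption responses of the
#' semi-quantitative FFQ, ordered from least to most frequent.
#'
#' @return Character vector of the five category labels.
#' @export
ffq_frequency_levels <- function() {
  c("never/rare", "1-3/month", "1/week", "2-4/week", ">=4/week")
}

#' Default frequency-to-daily multipliers
#'
#' Occasions-per-day factor for each frequency category. Published FFQ
#' conventions vary for the interval categories, so the defaults use interval
#' midpoints: 2 occasions/month for "1-3/month" (month = 365.25/12 = 30.44
#' days), 3/week for "2-4/week", and 5.5/week for the open-ended top category.
#' All are overridable via the `factors` argument of
#' [frequency_to_daily_factor()].
#'
#' @return Named numeric vector over [ffq_frequency_levels()].
#' @export
#' @examples
#' ffq_frequency_factors()["1/week"] # 1/7
ffq_frequency_factors <- function() {
  c(
    "never/rare" = 0,
    "1-3/month"  = 2 / 30.44,
    "1/week"     = 1 / 7,
    "2-4/week"   = 3 / 7,
    ">=4/week"   = 5.5 / 7
  )
}

#' Convert a frequency category to an occasions-per-day multiplier
#'
#' @param category Character vector of categories from
#'   [ffq_frequency_levels()].
#' @param factors Named multiplier vector; defaults to
#'   [ffq_frequency_factors()].
#' @return Numeric vector of occasions/day.
#' @export
#' @examples
#' frequency_to_daily_factor(c("never/rare", "1/week"))
frequency_to_daily_factor <- function(category, factors = ffq_frequency_factors()) {
  category <- as.character(category)
  unknown <- setdiff(unique(category), names(factors))
  if (length(unknown) > 0) {
    abort(
      paste0(
        "unknown FFQ frequency category: ",
        paste(sQuote(unknown), collapse = ", "),
        "; expected one of ", paste(sQuote(names(factors)), collapse = ", ")
      ),
      class = "nutrinet_parse_error"
    )
  }
  unname(factors[category])
}

#' Daily grams contributed by each FFQ response
#'
#' Multiplies the portion size by the occasions-per-day factor of the
#' frequency category.
#'
#' @param responses Tibble with columns `subject_id`, `item_id`,
#'   `frequency` (a category from [ffq_frequency_levels()]) and `portion_g`
#'   (grams, or mL treated as grams, per consumption occasion).
#' @param factors Frequency multipliers, see [ffq_frequency_factors()].
#' @return The input tibble with a `grams_per_day` column appended.
#' @export
#' @examples
#' resp <- tibble::tibble(
#'   subject_id = 1, item_id = "rice", frequency = "1/week", portion_g = 70
#' )
#' item_daily_grams(resp)$grams_per_day # 10
item_daily_grams <- function(responses, factors = ffq_frequency_factors()) {
  needed <- c("subject_id", "item_id", "frequency", "portion_g")
  missing_cols <- setdiff(needed, names(responses))
  if (length(missing_cols) > 0) {
    abort(paste0("responses lack columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(responses$portion_g)) || any(responses$portion_g < 0)) {
    abort("portion_g must be finite and >= 0", class = "nutrinet_validation_error")
  }
  dplyr::mutate(
    as_tibble(responses),
    grams_per_day = .data$portion_g * frequency_to_daily_factor(.data$frequency, factors)
  )
}

#' Aggregate item-level daily grams into food-group intakes
#'
#' Sums [item_daily_grams()] over the items mapped to each food group,
#' yielding the subject-by-group daily intake table used by all downstream
#' analyses. Subjects contribute 0 to groups for which they report no items.
#'
#' @param responses FFQ response tibble (see [item_daily_grams()]).
#' @param group_map Tibble with columns `item_id`, `group` mapping every item
#'   to exactly one food group; see [default_group_map()].
#' @param factors Frequency multipliers.
#' @return Wide tibble: `subject_id` plus one grams/day column per food group
#'   (all groups of `group_map` present, in its order).
#' @export
aggregate_food_groups <- function(responses, group_map,
                                  factors = ffq_frequency_factors()) {
  if (!all(c("item_id", "group") %in% names(group_map))) {
    abort("group_map needs columns item_id and group")
  }
  if (anyDuplicated(group_map$item_id) > 0) {
    abort("group_map maps some items more than once")
  }
  unmapped <- setdiff(unique(responses$item_id), group_map$item_id)
  if (length(unmapped) > 0) {
    abort(
      paste0("unmapped item ids: ", paste(sQuote(unmapped), collapse = ", ")),
      class = "nutrinet_validation_error"
    )
  }
  groups <- unique(group_map$group)
  daily <- item_daily_grams(responses, factors)
  long <- daily |>
    dplyr::left_join(group_map, by = "item_id") |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(grams = sum(.data$grams_per_day), .groups = "drop")
  wide <- long |>
    dplyr::mutate(group = factor(.data$group, levels = groups)) |>
    tidyr::pivot_wider(
      names_from = "group", values_from = "grams",
      values_fill = 0, names_expand = TRUE
    ) |>
    dplyr::arrange(.data$subject_id)
  wide[, c("subject_id", groups)]
}

#' Default item-to-group map
#'
#' A compact synthetic mapping with `items_per_group` items per food group,
#' item ids `"<group>_item<j>"`. The validated 97-item instrument is not
#' reproduced; real analyses supply their own map (delimited text or YAML
#' with columns/keys `item_id`, `group`).
#'
#' @param items_per_group Items per group (default 2).
#' @param groups Group labels (default [food_groups()]).
#' @return Tibble with columns `item_id`, `group`.
#' @export
default_group_map <- function(items_per_group = 2, groups = food_groups()) {
  stopifnot(items_per_group >= 1)
  tibble(
    item_id = paste0(rep(groups, each = items_per_group), "_item",
                     rep(seq_len(items_per_group), length(groups))),
    group = rep(groups, each = items_per_group)
  )
}

#' Read an item-to-group map from delimited text or YAML
#'
#' @param path File path. `.yml`/`.yaml` files are read as a named list
#'   (item id -> group); anything else as delimited text with columns
#'   `item_id`, `group`.
#' @return Tibble with columns `item_id`, `group`.
#' @export
read_group_map <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    m <- yaml::read_yaml(path)
    tibble(item_id = names(m), group = unlist(m, use.names = FALSE))
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}
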