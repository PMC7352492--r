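# broom-style tidiers for the package's fitted/derived objects.

#' Tidy a stable network into its edge list
#' @param x A `"nutrinet_network"`.
#' @param ... Unused.
#' @return Tibble group1, group2, sign, median_rho, persistence.
#' @exportS3Method generics::tidy
tidy.nutrinet_network <- function(x, ...) x$edges

#' One-row network summary
#' @param x A `"nutrinet_network"`.
#' @param ... Unused.
#' @return Tibble nodes, edges, density, n_negative, max_degree.
#' @exportS3Method generics::glance
glance.nutrinet_network <- function(x, ...) {
  tibble(
    nodes = length(x$nodes),
    edges = x$L,
    density = x$density,
    n_negative = sum(x$edges$sign == "negative"),
    max_degree = if (length(x$degrees)) max(x$degrees) else 0L
  )
}

#' Tidy a multinomial dietary-pattern fit
#' @param x A `"nutrinet_multifit"`.
#' @param exponentiate Return odds ratios (default TRUE) or log-odds.
#' @param ... Unused.
#' @return Tibble outcome, term, estimate, std.error, conf.low, conf.high,
#'   p.value.
#' @exportS3Method generics::tidy
tidy.nutrinet_multifit <- function(x, exponentiate = TRUE, ...) {
  out <- x$or_table
  if (exponentiate) {
    tibble(
      outcome = out$outcome, term = out$term, estimate = out$odds_ratio,
      std.error = out$se, conf.low = out$conf_low, conf.high = out$conf_high,
      p.value = out$p_value
    )
  } else {
    tibble(
      outcome = out$outcome, term = out$term, estimate = out$log_or,
      std.error = out$se,
      conf.low = out$log_or - qnorm(0.975) * out$se,
      conf.high = out$log_or + qnorm(0.975) * out$se,
      p.value = out$p_value
    )
  }
}

#' One-row multinomial fit summary
#' @param x A `"nutrinet_multifit"`.
#' @param ... Unused.
#' @return Tibble baseline, deff, converged, n_terms.
#' @exportS3Method generics::glance
glance.nutrinet_multifit <- function(x, ...) {
  tibble(
    baseline = x$baseline,
    deff = x$deff,
    converged = x$converged,
    n_terms = nrow(x$or_table)
  )
}

#' Tidy a group comparison (Kruskal-Wallis + Dunn)
#' @param x A `"nutrinet_comparison"`.
#' @param ... Unused.
#' @return The pairwise Dunn tibble.
#' @exportS3Method generics::tidy
tidy.nutrinet_comparison <- function(x, ...) x$pairwise

#' One-row comparison summary
#' @param x A `"nutrinet_comparison"`.
#' @param ... Unused.
#' @return Tibble test, statistic, df, p.value.
#' @exportS3Method generics::glance
glance.nutrinet_comparison <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, df = x$df,
         p.value = x$p_value)
}

#' Tidy a dietary-pattern clustering
#' @param x A `"nutrinet_patterns"`.
#' @param ... Unused.
#' @return The assignment tibble (subject_id, pattern).
#' @exportS3Method generics::tidy
tidy.nutrinet_patterns <- function(x, ...) x$assignment

#' One-row clustering summary
#' @param x A `"nutrinet_patterns"`.
#' @param ... Unused.
#' @return Tibble k, n, and per-pattern sizes.
#' @exportS3Method generics::glance
glance.nutrinet_patterns <- function(x, ...) {
  sizes <- table(x$assignment$pattern)
  tibble(k = x$k, n = nrow(x$assignment),
         smallest = min(sizes), largest = max(sizes))
}
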