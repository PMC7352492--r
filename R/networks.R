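# Bootstrap-stabilized signed Spearman correlation networks of food-group
# co-consumption. For each subject subgroup (e.g. a DMPW group) the
# food-group x food-group Spearman matrix is bootstrapped B times; an edge
# enters the stable network only if, with a consistent sign, it satisfies
# the significance and |rho| criteria in at least a `persistence` fraction
# of replicates. Density = L / (N (N - 1) / 2).

#' Spearman correlation matrix with p-values
#'
#' Tie-corrected Spearman rho (Pearson correlation of ranks) over the
#' food-group columns, with two-sided p-values from the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)). A constant column makes its
#' correlations undefined; these are recorded as rho 0 with p 1 and flagged.
#'
#' @param intake Wide intake tibble (`subject_id` + grams/day per group),
#'   typically one DMPW subgroup.
#' @return List of class `"nutrinet_cormat"`: `rho`, `p` (G x G matrices),
#'   `n`, `degenerate` (logical matrix marking undefined pairs).
#' @export
spearman_matrix <- function(intake) {
  m <- intake_matrix(intake)
  n <- nrow(m)
  if (n < 4) abort("need at least 4 subjects", class = "nutrinet_validation_error")
  if (ncol(m) < 2) abort("need at least 2 food groups")
  ranks <- apply(m, 2, rank)
  sds <- apply(ranks, 2, sd)
  constant <- sds == 0
  rho <- suppressWarnings(cor(ranks))
  degenerate <- outer(constant, constant, `|`)
  rho[degenerate] <- 0
  diag(rho) <- 1
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[degenerate] <- 1
  diag(p) <- 0
  structure(list(rho = rho, p = p, n = n, degenerate = degenerate),
            class = "nutrinet_cormat")
}

#' Bootstrap ensemble of Spearman matrices
#'
#' Draws `B` bootstrap resamples (with replacement, original size) of the
#' subjects and computes the Spearman matrix of each.
#'
#' @param intake Wide intake tibble for one subgroup.
#' @param B Number of replicates (default 100).
#' @param seed Seed for the resampling.
#' @return Object of class `"nutrinet_ensemble"`: list with `matrices`
#'   (list of B `"nutrinet_cormat"`), `indices` (list of resampled row
#'   indices), `n`, `groups`, `B`, `seed`.
#' @export
bootstrap_ensemble <- function(intake, B = 100, seed = 1) {
  if (B < 1) abort("B must be >= 1")
  n <- nrow(intake)
  idx <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE))
  })
  mats <- lapply(idx, function(i) spearman_matrix(intake[i, , drop = FALSE]))
  structure(
    list(matrices = mats, indices = idx, n = n,
         groups = setdiff(names(intake), "subject_id"),
         B = as.integer(B), seed = as.integer(seed)),
    class = "nutrinet_ensemble"
  )
}

# Per-replicate edge qualification under criteria (i)-(ii): significance
# (Holm-adjusted across the G(G-1)/2 tests by default) and |rho| above the
# threshold. Returns qualification and rho for the upper-triangle pairs.
qualify_replicates <- function(ensemble, rho_threshold, alpha, adjust_p) {
  G <- length(ensemble$groups)
  ut <- which(upper.tri(matrix(0, G, G)))
  rho_mat <- vapply(ensemble$matrices, function(m) m$rho[ut],
                    numeric(length(ut)))
  p_mat <- vapply(ensemble$matrices, function(m) m$p[ut],
                  numeric(length(ut)))
  if (length(ut) == 1) {
    rho_mat <- matrix(rho_mat, nrow = 1)
    p_mat <- matrix(p_mat, nrow = 1)
  }
  if (adjust_p) {
    p_mat <- apply(p_mat, 2, p.adjust, method = "holm")
    if (is.null(dim(p_mat))) p_mat <- matrix(p_mat, nrow = length(ut))
  }
  qualifies <- p_mat < alpha & abs(rho_mat) > rho_threshold
  list(ut = ut, rho = rho_mat, qualifies = qualifies, G = G)
}

#' Stable network from a bootstrap ensemble
#'
#' Applies the three edge criteria: within each replicate an edge qualifies
#' when its (Holm-adjusted) p-value is below `alpha` and |rho| exceeds
#' `rho_threshold`; an edge is retained when it qualifies with a consistent
#' sign in at least `persistence` of the B replicates. Edge sign and rho are
#' the sign and median rho over the qualifying replicates of the majority
#' sign.
#'
#' @param ensemble A [bootstrap_ensemble()].
#' @param rho_threshold Strict |rho| cut (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @param persistence Minimum fraction of replicates (default 0.5; the
#'   boundary counts, i.e. exactly 50 of 100 retains).
#' @param adjust_p Holm-adjust p-values within each replicate's G(G-1)/2
#'   tests (default TRUE).
#' @return Object of class `"nutrinet_network"`: list with `edges` (tibble
#'   group1, group2, sign, median_rho, persistence), `nodes`, `L`,
#'   `density`, `degrees` (named vector), `B` and the thresholds used.
#' @export
stable_edges <- function(ensemble, rho_threshold = 0.5, alpha = 0.05,
                         persistence = 0.5, adjust_p = TRUE) {
  stopifnot(inherits(ensemble, "nutrinet_ensemble"))
  if (length(ensemble$matrices) == 0) abort("empty ensemble")
  q <- qualify_replicates(ensemble, rho_threshold, alpha, adjust_p)
  B <- ensemble$B
  G <- q$G
  groups <- ensemble$groups
  arr <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)

  edges <- purrr::map_dfr(seq_along(q$ut), function(e) {
    qual <- q$qualifies[e, ]
    rhos <- q$rho[e, ]
    pos <- sum(qual & rhos > 0)
    neg <- sum(qual & rhos < 0)
    count <- max(pos, neg)
    if (count < persistence * B) return(NULL)
    sgn <- if (pos >= neg) "positive" else "negative"
    keep <- qual & (if (sgn == "positive") rhos > 0 else rhos < 0)
    tibble(
      group1 = groups[arr[e, 1]],
      group2 = groups[arr[e, 2]],
      sign = sgn,
      median_rho = median(rhos[keep]),
      persistence = count / B
    )
  })
  if (nrow(edges) == 0) {
    edges <- tibble(group1 = character(), group2 = character(),
                    sign = character(), median_rho = numeric(),
                    persistence = numeric())
  }
  L <- nrow(edges)
  degrees <- setNames(integer(G), groups)
  if (L > 0) {
    tab <- table(factor(c(edges$group1, edges$group2), levels = groups))
    degrees <- setNames(as.integer(tab), groups)
  }
  structure(
    list(
      edges = edges, nodes = groups, L = L,
      density = network_density(L, G),
      degrees = degrees, B = B,
      rho_threshold = rho_threshold, alpha = alpha,
      persistence_threshold = persistence, adjust_p = adjust_p
    ),
    class = "nutrinet_network"
  )
}

#' @export
print.nutrinet_network <- function(x, ...) {
  cat("<nutrinet stable network>  nodes:", length(x$nodes),
      " edges:", x$L, " density:", round(x$density, 4), "\n")
  if (x$L > 0) print(x$edges, n = Inf)
  invisible(x)
}

#' Network density
#'
#' Number of retained correlations over the number of conceivable pairs:
#' L / (N (N - 1) / 2).
#'
#' @param L Edge count.
#' @param N Node count (>= 2).
#' @return Density in \[0, 1\].
#' @export
#' @examples
#' network_density(14, 14) # 14/91
network_density <- function(L, N) {
  if (N < 2) abort("need at least 2 nodes")
  total <- N * (N - 1) / 2
  if (L < 0 || L > total) {
    abort(paste0("edge count must lie in [0, ", total, "]"),
          class = "nutrinet_validation_error")
  }
  L / total
}

#' Node degrees of a stable network
#'
#' Number of retained correlations incident to each food group, ranked.
#'
#' @param network A `"nutrinet_network"`.
#' @return Tibble `group`, `degree`, sorted by decreasing degree.
#' @export
node_degrees <- function(network) {
  stopifnot(inherits(network, "nutrinet_network"))
  tibble(group = names(network$degrees),
         degree = as.integer(network$degrees)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$group)
}

#' Per-replicate network densities of an ensemble
#'
#' Applies criteria (i)-(ii) within each bootstrap replicate and returns the
#' resulting density per replicate — the within-group distribution used for
#' the between-group density comparison.
#'
#' @inheritParams stable_edges
#' @return Numeric vector of B densities.
#' @export
replicate_densities <- function(ensemble, rho_threshold = 0.5, alpha = 0.05,
                                adjust_p = TRUE) {
  q <- qualify_replicates(ensemble, rho_threshold, alpha, adjust_p)
  total <- q$G * (q$G - 1) / 2
  colSums(q$qualifies) / total
}

#' Compare network densities between DMPW groups
#'
#' Kruskal-Wallis with Dunn post-hoc (Holm-adjusted) on the per-replicate
#' bootstrap densities of each group.
#'
#' @param ensembles Named list of [bootstrap_ensemble()] objects (one per
#'   DMPW group), or a named list of numeric density vectors.
#' @inheritParams stable_edges
#' @return A `"nutrinet_comparison"` (see [kruskal_wallis_dunn()]) with an
#'   extra `densities` element (tibble group, replicate, density).
#' @export
compare_densities <- function(ensembles, rho_threshold = 0.5, alpha = 0.05,
                              adjust_p = TRUE) {
  if (length(ensembles) < 2) abort("need at least 2 groups")
  dens <- purrr::imap(ensembles, function(e, nm) {
    d <- if (inherits(e, "nutrinet_ensemble")) {
      replicate_densities(e, rho_threshold, alpha, adjust_p)
    } else {
      as.numeric(e)
    }
    if (length(d) < 2) abort("each group needs >= 2 replicate densities")
    tibble(group = nm, replicate = seq_along(d), density = d)
  })
  dens <- dplyr::bind_rows(dens)
  res <- kruskal_wallis_dunn(dens, .data$density, .data$group)
  res$densities <- dens
  res
}
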