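# End-to-end orchestration: generate (or load) -> FFQ processing ->
# anthropometric/DMPW classification -> abundance + patterns -> multinomial
# model -> per-DMPW-group networks. One master seed derives per-stage
# substreams so stages are individually reproducible.

#' Pipeline run configuration
#'
#' @param output_dir Directory for stage outputs (`NULL` = don't write).
#' @param generator A [generator_config()] for synthetic mode, or `NULL`
#'   when `cohort`/`responses` paths are supplied.
#' @param cohort_path,responses_path,group_map_path Paths to user-supplied
#'   delimited tables (ignored in synthetic mode).
#' @param k Number of dietary patterns (default 4).
#' @param network_B Bootstrap replicates per DMPW group (default 100).
#' @param rho_threshold,alpha,persistence Network edge criteria.
#' @param seed Master seed (mandatory; overrides the generator seed).
#' @return List of class `"nutrinet_run_config"`.
#' @export
run_config <- function(output_dir = NULL, generator = generator_config(),
                       cohort_path = NULL, responses_path = NULL,
                       group_map_path = NULL, k = 4, network_B = 100,
                       rho_threshold = 0.5, alpha = 0.05, persistence = 0.5,
                       seed = 1L) {
  stopifnot(k >= 2, network_B >= 1, rho_threshold >= 0, rho_threshold <= 1,
            alpha > 0, alpha < 1, persistence > 0, persistence <= 1)
  if (is.null(generator) && (is.null(cohort_path) || is.null(responses_path))) {
    abort("supply either a generator config (synthetic mode) or cohort/responses paths")
  }
  if (!is.null(generator)) {
    generator$seed <- as.integer(seed)
  }
  structure(
    list(output_dir = output_dir, generator = generator,
         cohort_path = cohort_path, responses_path = responses_path,
         group_map_path = group_map_path, k = as.integer(k),
         network_B = as.integer(network_B), rho_threshold = rho_threshold,
         alpha = alpha, persistence = persistence, seed = as.integer(seed)),
    class = "nutrinet_run_config"
  )
}

#' Run the full systems-nutrology pipeline
#'
#' Executes generate/load -> FFQ aggregation -> DMPW classification ->
#' abundance transform -> Ward pattern clustering -> pattern profiles and
#' composition -> multinomial regression with design effect -> per-DMPW
#' bootstrap networks -> density comparison, returning every stage result
#' plus a reproducibility manifest. When `config$output_dir` is set, stage
#' tables are written as tab-delimited text and the manifest plus planted
#' truth as JSON.
#'
#' @param config A [run_config()].
#' @return List of class `"nutrinet_run"` with elements `cohort`, `truth`
#'   (synthetic mode only), `responses`, `intake`, `abundance`, `dmpw_table`,
#'   `patterns`, `profile`, `composition`, `multinomial`, `deff`, `networks`
#'   (named list per DMPW group), `density_comparison`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "nutrinet_run_config"))
  synthetic <- !is.null(config$generator) && is.null(config$cohort_path)

  group_map <- if (!is.null(config$group_map_path)) {
    read_group_map(config$group_map_path)
  } else {
    default_group_map()
  }

  if (synthetic) {
    gen <- config$generator
    bundle <- generate_cohort(gen)
    cohort <- bundle$cohort
    truth <- bundle$truth
    intake_true <- generate_ffq_intakes(bundle, gen)
    responses <- generate_ffq_responses(intake_true, group_map, gen)
  } else {
    cohort <- readr::read_tsv(config$cohort_path, show_col_types = FALSE,
                              progress = FALSE)
    cohort <- add_anthropometry(cohort)
    responses <- readr::read_tsv(config$responses_path, show_col_types = FALSE,
                                 progress = FALSE)
    truth <- NULL
  }

  intake <- aggregate_food_groups(responses, group_map)
  dmpw_tab <- dmpw_frequency_table(cohort)
  abundance <- abundance_transform(intake)
  patterns <- cluster_patterns(abundance, k = config$k)
  profile <- pattern_profile(abundance, patterns)
  composition <- pattern_composition(patterns, cohort)

  model_data <- dplyr::inner_join(patterns$assignment, cohort, by = "subject_id")
  baseline <- pick_baseline_pattern(profile)
  multinomial <- fit_multinomial(model_data, baseline = baseline,
                                 cluster = if ("cluster" %in% names(cohort)) "cluster")
  deff <- if ("cluster" %in% names(cohort)) {
    design_effect(model_data, "pattern", "cluster")
  }

  groups_split <- split(seq_len(nrow(cohort)), cohort$dmpw)
  networks <- list()
  ensembles <- list()
  for (d in names(groups_split)) {
    sub <- intake[intake$subject_id %in% cohort$subject_id[groups_split[[d]]], ]
    if (nrow(sub) < 4) next
    ens <- bootstrap_ensemble(sub, B = config$network_B,
                              seed = substream_seed(config$seed, paste0("net_", d)))
    ensembles[[d]] <- ens
    networks[[d]] <- stable_edges(ens, config$rho_threshold, config$alpha,
                                  config$persistence)
  }
  density_comparison <- if (length(ensembles) >= 2) {
    compare_densities(ensembles, config$rho_threshold, config$alpha)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nutrinet")),
    seed = config$seed,
    synthetic = synthetic,
    n_subjects = nrow(cohort),
    k = config$k,
    network = list(B = config$network_B, rho_threshold = config$rho_threshold,
                   alpha = config$alpha, persistence = config$persistence),
    baseline_pattern = baseline
  )

  run <- structure(
    list(cohort = cohort, truth = truth, responses = responses,
         intake = intake, abundance = abundance, dmpw_table = dmpw_tab,
         patterns = patterns, profile = profile, composition = composition,
         multinomial = multinomial, deff = deff, networks = networks,
         density_comparison = density_comparison, manifest = manifest),
    class = "nutrinet_run"
  )
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

# Baseline pattern for the regression: the pattern with the lowest overall
# mean abundance (no clear predominance), mirroring the rationale for using
# the uniformly-low pattern as reference. Defaults to the discovered
# pattern whose profile mean is smallest in spread and level.
pick_baseline_pattern <- function(profile) {
  means <- profile$profile |>
    dplyr::group_by(.data$pattern) |>
    dplyr::summarise(spread = max(.data$mean) - min(.data$mean),
                     .groups = "drop")
  as.character(means$pattern[which.min(means$spread)])
}

#' @export
print.nutrinet_run <- function(x, ...) {
  cat("<nutrinet pipeline run>  n =", nrow(x$cohort),
      " seed =", x$manifest$seed, "\n")
  cat("DMPW distribution:\n")
  print(as.data.frame(x$dmpw_table))
  cat("patterns:\n")
  print(table(x$patterns$assignment$pattern))
  for (d in names(x$networks)) {
    nw <- x$networks[[d]]
    cat(sprintf("network %-14s L = %2d  density = %.4f  negative = %d\n",
                d, nw$L, nw$density, sum(nw$edges$sign == "negative")))
  }
  invisible(x)
}

#' Write pipeline outputs as plain text
#'
#' Stage tables as tab-delimited text, manifest and planted truth as JSON.
#'
#' @param run A `"nutrinet_run"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(dir, paste0(name, ".tsv")))
  }
  w(run$cohort, "cohort")
  w(run$responses, "ffq_responses")
  w(run$intake, "food_group_intake")
  w(run$abundance, "abundance")
  w(as_tibble(run$dmpw_table), "dmpw_table")
  w(run$patterns$assignment, "pattern_assignment")
  w(run$profile$profile, "pattern_profile")
  w(run$profile$anova, "pattern_anova")
  w(run$multinomial$or_table, "multinomial_or")
  for (d in names(run$networks)) {
    w(run$networks[[d]]$edges, paste0("network_edges_", d))
    w(node_degrees(run$networks[[d]]), paste0("node_degrees_", d))
  }
  if (!is.null(run$density_comparison)) {
    w(run$density_comparison$densities, "replicate_densities")
    w(run$density_comparison$pairwise, "density_dunn")
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(run$truth)) {
    jsonlite::write_json(
      list(labels = run$truth$labels, planted_edges = run$truth$planted_edges),
      file.path(dir, "planted_truth.json"), auto_unbox = TRUE
    )
  }
  invisible(dir)
}

#' Write a generator config as YAML
#' @param config A [generator_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  x$pattern_centroids <- apply(config$pattern_centroids, 1, as.list,
                               simplify = FALSE)
  x$correlation_spec <- lapply(config$correlation_spec, function(m) {
    apply(m, 1, as.list, simplify = FALSE)
  })
  yaml::write_yaml(x, path)
  invisible(path)
}
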