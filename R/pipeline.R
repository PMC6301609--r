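#' Run the full diet-reconstruction pipeline
#'
#' Orchestrates correct -> characterise -> geometry-check -> fit (per TEF
#' scenario) -> diagnose -> aggregate -> report from a single YAML config
#' (or an equivalent R list). Outputs are written under the configured
#' output directory: corrected sources, the group-statistics table, the
#' mixing-polygon plausibility report per scenario, per-consumer posterior
#' summaries per scenario, per-fit convergence status, and a JSON
#' manifest recording versions, seeds and all config values.
#'
#' Config keys: `seed` (required — the pipeline refuses to run without
#' one), `out_dir`; either `synthetic: true` (with optional
#' `n_sources_per_group`, `n_consumers`) or `sources`/`consumers` CSV
#' paths plus optional `atmosphere` and `offsets` paths; `scenarios`
#' (vector of scenario names, default all four), `prior_alpha`,
#' `mcmc` (list: `chain_length`, `burn_in`, `thin`, `n_chains`) or
#' `use_ladder: true` for the escalating-run protocol, and
#' `allow_nonconverged` (default FALSE: any non-converged model is an
#' error).
#'
#' @param config Path to a YAML file or a named list.
#' @return Invisibly, the manifest list (paths of all artifacts plus a
#'   `converged` flag per fit).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) abort("config must set a seed (reproducibility contract)")
  seed <- as.integer(cfg$seed)
  out_dir <- cfg$out_dir %||% tempfile("coastmix_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- inputs -------------------------------------------------------------
  if (isTRUE(cfg$synthetic)) {
    design <- synthetic_design(
      n_sources_per_group = cfg$n_sources_per_group %||% 30,
      n_consumers = cfg$n_consumers %||% 35,
      seed = seed
    )
    sources <- generate_sources(design)
    consumers <- generate_consumers(design, sources = sources)$consumers
    atmosphere <- NULL
  } else {
    if (is.null(cfg$sources) || is.null(cfg$consumers)) {
      abort("config must give sources and consumers paths (or synthetic: true)")
    }
    sources <- read_sources(cfg$sources)
    consumers <- read_consumers(cfg$consumers)
    atmosphere <- if (!is.null(cfg$atmosphere)) read_atmosphere(cfg$atmosphere)
  }

  # --- corrections --------------------------------------------------------
  offsets <- if (!is.null(cfg$offsets)) read_offsets(cfg$offsets)
  if (!is.null(atmosphere)) {
    sources <- apply_corrections(sources, atmosphere, offsets)
    readr::write_csv(correction_audit(sources),
                     file.path(out_dir, "correction_audit.csv"))
  }
  readr::write_csv(sources, file.path(out_dir, "sources_corrected.csv"))

  # --- characterisation ---------------------------------------------------
  stats_tbl <- pairwise_group_tests(sources)
  readr::write_csv(stats_tbl, file.path(out_dir, "group_stats.csv"))
  kw <- dplyr::bind_rows(
    dplyr::mutate(kruskal_wallis(sources$d13C, sources$group), element = "d13C"),
    dplyr::mutate(kruskal_wallis(sources$d15N, sources$group), element = "d15N")
  )
  readr::write_csv(dplyr::select(kw, -"n_per_group"),
                   file.path(out_dir, "kruskal_wallis.csv"))
  knn <- knnr_test(sources[, c("d13C", "d15N")], sources$group,
                   n_perm = cfg$knnr_perm %||% 999, seed = seed)
  reg <- correlate_and_regress(consumers)
  readr::write_csv(glance.iso_regression(reg),
                   file.path(out_dir, "consumer_regression.csv"))

  # --- scenarios: geometry + fits ----------------------------------------
  scen_names <- cfg$scenarios %||%
    c("low_C_low_N", "low_C_high_N", "high_C_low_N", "high_C_high_N")
  dist <- source_distributions(sources)
  mc <- if (!is.null(cfg$mcmc)) {
    mcmc_config(cfg$mcmc$chain_length %||% 10000, cfg$mcmc$burn_in %||% 5000,
                cfg$mcmc$thin %||% 5, cfg$mcmc$n_chains %||% 3, seed)
  } else mcmc_config(seed = seed)
  ladder <- if (isTRUE(cfg$use_ladder)) mcmc_ladder(seed)

  mcp <- list(); all_summaries <- list(); converged <- logical(0)
  for (sn in scen_names) {
    sc <- tef_scenario(sn)
    tp <- tef_plausibility(consumers, sources, sc)
    mcp[[sn]] <- tibble::tibble(
      scenario = sn, n_consumers = tp$n_consumers,
      n_inside_raw = tp$n_inside_raw, n_inside_mean = tp$n_inside_mean
    )
    sm <- fit_consumers(consumers, dist, sc, mcmc = mc, ladder = ladder)
    readr::write_csv(sm, file.path(out_dir, paste0("posterior_", sn, ".csv")))
    conv <- dplyr::distinct(sm, .data$consumer_id, .data$converged,
                            .data$escalation_level)
    jsonlite::write_json(conv, file.path(out_dir, paste0("convergence_", sn, ".json")))
    converged <- c(converged, setNames(conv$converged,
                                       paste(sn, conv$consumer_id, sep = ":")))
    all_summaries[[sn]] <- sm
  }
  mcp_tbl <- dplyr::bind_rows(mcp)
  readr::write_csv(mcp_tbl, file.path(out_dir, "mcp_plausibility.csv"))

  if (!all(converged) && !isTRUE(cfg$allow_nonconverged)) {
    abort(paste0("non-converged fits: ",
                 paste(names(converged)[!converged], collapse = ", ")))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("coastmix")),
    r_version = R.version.string,
    seed = seed, config = cfg, out_dir = out_dir,
    knnr_p = knn$p_value,
    artifacts = list.files(out_dir),
    n_nonconverged = sum(!converged)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
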