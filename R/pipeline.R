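#' Study configuration
#'
#' One configuration drives the whole workflow: either a scenario to
#' simulate from, or sample/transect file paths to ingest, plus the
#' baseline taxon, scaling parameters, TEF, source pooling map, MCMC
#' settings and a master seed. Can be read from a YAML file with the
#' same field names.
#'
#' @param scenario a [reef_scenario()] (simulate) or NULL (ingest).
#' @param samples_path,transect_points_path,transect_chains_path input
#'   CSVs used when no scenario is given.
#' @param baseline_taxon baseline consumer label; defaults to the
#'   scenario's.
#' @param params [scaling_constants()].
#' @param tef [tef()].
#' @param source_grouping named character vector pooling source taxa
#'   into mixing end members (NULL: one end member per source taxon).
#' @param mcmc list of [fit_mixing()] chain settings.
#' @param seed master seed for every stochastic stage.
#' @return object of class `"analysis_config"`.
#' @export
analysis_config <- function(scenario = NULL, samples_path = NULL,
                            transect_points_path = NULL,
                            transect_chains_path = NULL,
                            baseline_taxon = NULL,
                            params = scaling_constants(),
                            tef = isonicheweb::tef(),
                            source_grouping = NULL,
                            mcmc = list(iterations = 20000, burnin = 4000,
                                        thin = 4),
                            seed = 1) {
  if (is.null(scenario) && is.null(samples_path))
    stop_domain("config needs a scenario or a samples_path")
  if (!is.null(samples_path) && !file.exists(samples_path))
    stop_domain("samples_path does not exist: ", samples_path)
  baseline_taxon <- baseline_taxon %||% scenario$baseline_taxon
  if (is.null(baseline_taxon)) stop_domain("baseline_taxon is required")
  structure(list(scenario = scenario, samples_path = samples_path,
                 transect_points_path = transect_points_path,
                 transect_chains_path = transect_chains_path,
                 baseline_taxon = baseline_taxon, params = params,
                 tef = tef, source_grouping = source_grouping,
                 mcmc = mcmc, seed = seed),
            class = "analysis_config")
}

#' Read a study configuration from YAML
#'
#' The YAML fields mirror the [analysis_config()] arguments. `scenario`
#' may be the name of a packaged scenario (`"default"` or `"mixing"`)
#' with optional `scenario_args`; `params` and `tef` may be given as
#' argument lists for [scaling_constants()] and [tef()];
#' `source_grouping` as a mapping of taxon to pooled label. Relative
#' input paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return an [analysis_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file not found: ", path)
  y <- yaml::read_yaml(path)
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(dirname(path), p) else p
  }
  scenario <- NULL
  if (!is.null(y$scenario)) {
    maker <- switch(as.character(y$scenario),
                    default = default_scenario, mixing = mixing_scenario,
                    stop_domain("unknown scenario name: ", y$scenario))
    scenario <- do.call(maker, y$scenario_args %||% list())
  }
  params <- if (is.null(y$params)) scaling_constants()
            else do.call(scaling_constants, y$params)
  tef_ <- if (is.null(y$tef)) tef() else do.call(tef, y$tef)
  grouping <- if (is.null(y$source_grouping)) NULL
              else unlist(y$source_grouping)
  analysis_config(
    scenario = scenario,
    samples_path = rel(y$samples_path),
    transect_points_path = rel(y$transect_points_path),
    transect_chains_path = rel(y$transect_chains_path),
    baseline_taxon = y$baseline_taxon, params = params, tef = tef_,
    source_grouping = grouping,
    mcmc = y$mcmc %||% list(iterations = 20000, burnin = 4000, thin = 4),
    seed = y$seed %||% 1)
}

config_fingerprint <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the complete two-reef study workflow
#'
#' Sequences the full analysis behind one configuration: data
#' simulation or ingestion, benthic survey statistics, per-species
#' scaled trophic positions with between-site tests and cross-site
#' correlations, niche metrics with between-site SEAc overlaps, and the
#' per-category Bayesian mixing model — then writes a JSON report
#' bundle plus a manifest (package version, seeds, config fingerprint,
#' aggregated warnings). Deterministic given the config seed. On any
#' stage error the partially written bundle is removed and the error is
#' re-raised with the stage name.
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory (created; must not already contain a
#'   manifest from another run unless `overwrite`).
#' @param overwrite replace an existing bundle.
#' @return invisibly, a list with every stage result and the manifest.
#' @export
run_study <- function(config, out_dir, overwrite = FALSE) {
  if (!inherits(config, "analysis_config")) stop_domain("not an analysis_config")
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "manifest.json")) &&
      !overwrite)
    stop_domain("output bundle already exists: ", out_dir)
  tmp <- tempfile("bundle_")
  dir.create(tmp, recursive = TRUE)
  stage <- "setup"
  warnings_log <- character(0)
  note <- function(w) { warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning") }
  result <- tryCatch(withCallingHandlers({
    stage <- "data"
    ds <- if (!is.null(config$scenario)) {
      generate_dataset(config$scenario, seed = config$seed)
    } else {
      samples <- read_samples(config$samples_path)
      transects <- if (!is.null(config$transect_points_path))
        read_transects(config$transect_points_path,
                       config$transect_chains_path) else list()
      study_dataset(samples, config$baseline_taxon, transects)
    }
    write_samples(ds$samples, file.path(tmp, "samples.csv"))
    sites <- sort(unique(ds$samples$site))

    stage <- "survey"
    survey <- NULL
    if (length(ds$transects) >= 2) {
      survey <- survey_report(ds$transects)
      write_report_json(list(
        cover = survey$cover[c("site", "component", "n_transects",
                               "mean_pct", "ci_pct")],
        cover_tests = survey$cover_tests,
        rugosity_means = lapply(survey$rugosity$values, mean),
        rugosity_test = survey$rugosity$test,
        macroalgae = survey$macroalgae[c("mean", "test")]),
        file.path(tmp, "survey.json"))
    }

    stage <- "trophic_position"
    tp_table <- estimate_species_tp(ds$samples, config$baseline_taxon,
                                    params = config$params)
    tp_tests <- NULL; correlations <- NULL
    if (length(sites) == 2) {
      tp_tests <- compare_species_between_sites(
        ds$samples, "TP", sites, config$baseline_taxon, config$params)
      d13c_tests <- compare_species_between_sites(ds$samples, "d13C", sites)
      by_site <- function(metric_col) {
        lapply(sites, function(s) {
          t <- tp_table[tp_table$site == s, ]
          stats::setNames(t[[metric_col]], t$taxon)
        })
      }
      tp_vals <- by_site("tp_mean")
      mean13 <- lapply(sites, function(s) {
        cs <- ds$samples[ds$samples$role == "consumer" &
                           ds$samples$site == s, ]
        tapply(cs$d13C, cs$taxon, mean)
      })
      correlations <- list(
        tp = cross_site_correlation(tp_vals[[1]], tp_vals[[2]]),
        d13C = cross_site_correlation(mean13[[1]], mean13[[2]]))
      tp_tests <- list(TP = tp_tests, d13C = d13c_tests)
    }
    write_report_json(list(params = unclass(config$params),
                           estimates = tp_table,
                           tests = tp_tests,
                           correlations = correlations),
                      file.path(tmp, "trophic_position.json"))

    stage <- "niche_metrics"
    niche <- category_metrics(ds$samples, n_draws = 2000, seed = config$seed)
    overlaps <- if (length(sites) == 2) overlap_between_sites(niche) else NULL
    niche_flat <- niche[c("site", "trophic_category", "n", "NR", "CR",
                          "TA", "SEA", "SEAc")]
    niche_flat$SEA_B_median <- vapply(niche$sea_b, stats::median, 0)
    write_report_json(list(metrics = niche_flat, overlap = overlaps),
                      file.path(tmp, "niche.json"))

    stage <- "mixing_model"
    src_samples <- ds$samples[ds$samples$role == "source", , drop = FALSE]
    grouping <- config$source_grouping %||%
      stats::setNames(unique(src_samples$taxon), unique(src_samples$taxon))
    sources <- lapply(stats::setNames(sites, sites), function(s)
      pool_sources(src_samples[src_samples$site == s, ], grouping))
    fits <- do.call(fit_by_category,
                    c(list(ds$samples, sources, config$tef,
                           seed = config$seed), config$mcmc))
    mix_summaries <- lapply(fits, summarize_posterior)
    write_report_json(mix_summaries, file.path(tmp, "mixing.json"))

    stage <- "manifest"
    manifest <- list(
      package = "isonicheweb",
      version = as.character(utils::packageVersion("isonicheweb")),
      r_version = R.version.string,
      seed = config$seed,
      config_fingerprint = config_fingerprint(config),
      outputs = list.files(tmp),
      warnings = warnings_log)
    write_report_json(manifest, file.path(tmp, "manifest.json"))
    list(dataset = ds, survey = survey, tp = tp_table, tp_tests = tp_tests,
         correlations = correlations, niche = niche, overlaps = overlaps,
         mixing = fits, mixing_summaries = mix_summaries,
         manifest = manifest)
  }, warning = note), error = function(e) {
    unlink(tmp, recursive = TRUE)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in list.files(tmp)) {
    file.copy(file.path(tmp, f), file.path(out_dir, f), overwrite = TRUE)
  }
  unlink(tmp, recursive = TRUE)
  invisible(result)
}
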