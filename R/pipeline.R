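#' Configure an end-to-end pipeline run
#'
#' Either file paths (sightings + nests CSV, optional habitats GeoJSON) or
#' a simulation specification must be given, not neither. Distances and
#' radii are metres; dates are day-resolution ISO-8601.
#'
#' @param sightings_path,nests_path,habitats_path input files.
#' @param simulation list with optional `config` ([population_config()]),
#'   `design` ([survey_design()]) and `truth` ([ground_truth()]); used
#'   when no input paths are given.
#' @param season_start data.frame year/season_start; required with file
#'   inputs, derived automatically for simulations.
#' @param analyses character vector of [analysis_registry()] ids to run.
#' @param n_perm randomisations per permutation test.
#' @param seed global integer seed.
#' @param exclusion_days pre-season exclusion window (14, or 30 for the
#'   sensitivity variant).
#' @param drop_may drop May sightings (sensitivity variant).
#' @param chain_distance chain-rule threshold in metres (default 20).
#' @param neighbourhood_radius nest neighbourhood radius (default 100 m).
#' @param mixed fit mixed models for observed fits.
#' @param output_dir directory for result tables and the manifest (NULL
#'   for no file output).
#' @return object of class `run_config`.
#' @export
run_config <- function(sightings_path = NULL, nests_path = NULL,
                       habitats_path = NULL, simulation = NULL,
                       season_start = NULL,
                       analyses = c("A2", "A7", "A9"), n_perm = 1000,
                       seed = 1, exclusion_days = 14, drop_may = FALSE,
                       chain_distance = 20, neighbourhood_radius = 100,
                       mixed = TRUE, output_dir = NULL) {
  has_files <- !is.null(sightings_path) && !is.null(nests_path)
  if (!has_files && is.null(simulation)) {
    stop("provide either input file paths or a simulation specification")
  }
  if (has_files && is.null(season_start)) {
    stop("season_start (year, season_start) is required with file inputs")
  }
  bad <- setdiff(analyses, names(analysis_registry()))
  if (length(bad) > 0L) {
    stop("unknown analysis id(s): ", paste(bad, collapse = ", "))
  }
  structure(list(sightings_path = sightings_path, nests_path = nests_path,
                 habitats_path = habitats_path, simulation = simulation,
                 season_start = season_start, analyses = analyses,
                 n_perm = n_perm, seed = as.integer(seed),
                 exclusion_days = exclusion_days, drop_may = drop_may,
                 chain_distance = chain_distance,
                 neighbourhood_radius = neighbourhood_radius,
                 mixed = mixed, output_dir = output_dir),
            class = "run_config")
}

#' Validate input tables
#'
#' Schema, date-order, coordinate-finiteness, sex-consistency and
#' habitat-membership checks. Report-only: every violation is listed with
#' its table, row, field and severity; [run_pipeline()] stops on
#' error-severity violations.
#'
#' @param sightings sightings table (or NULL).
#' @param nests nests table (or NULL).
#' @param habitats optional habitat table; enables habitat-label and
#'   point-membership checks.
#' @return data.frame `table`, `row`, `field`, `severity`, `message`.
#' @export
validate_inputs <- function(sightings = NULL, nests = NULL,
                            habitats = NULL) {
  v <- list()
  add <- function(table, row, field, severity, message) {
    v[[length(v) + 1L]] <<- data.frame(table = table, row = row,
                                       field = field, severity = severity,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  known_hab <- if (!is.null(habitats)) habitats$habitat else NULL
  if (!is.null(sightings)) {
    for (cl in setdiff(.sighting_cols, names(sightings))) {
      add("sightings", NA_integer_, cl, "error", "missing required column")
    }
    if (all(.sighting_cols %in% names(sightings))) {
      for (i in which(!is.finite(sightings$x) | !is.finite(sightings$y))) {
        add("sightings", i, "x/y", "error", "non-finite coordinate")
      }
      for (i in which(!sightings$sex %in% c("M", "F"))) {
        add("sightings", i, "sex", "error", "sex must be 'M' or 'F'")
      }
      for (i in which(is.na(as.Date(sightings$date)))) {
        add("sightings", i, "date", "error", "unparseable date")
      }
      sx <- unique(sightings[, c("individual_id", "sex")])
      for (id in unique(sx$individual_id[duplicated(sx$individual_id)])) {
        add("sightings", NA_integer_, "sex", "error",
            paste0("conflicting sex records for ", id))
      }
      if (!is.null(known_hab)) {
        for (i in which(!sightings$habitat %in% known_hab)) {
          add("sightings", i, "habitat", "error",
              paste0("unknown habitat label '", sightings$habitat[i], "'"))
        }
        ok <- is.finite(sightings$x) & is.finite(sightings$y) &
          sightings$habitat %in% known_hab
        at <- habitat_of_point(habitats, sightings$x, sightings$y)
        for (i in which(ok & !is.na(at) & at != sightings$habitat)) {
          add("sightings", i, "habitat", "warning",
              sprintf("labelled '%s' but located in '%s' polygon",
                      sightings$habitat[i], at[i]))
        }
      }
    }
  }
  if (!is.null(nests)) {
    for (cl in setdiff(.nest_cols, names(nests))) {
      add("nests", NA_integer_, cl, "error", "missing required column")
    }
    if (all(.nest_cols %in% names(nests))) {
      bad_date <- is.na(as.Date(nests$laid_date)) |
        is.na(as.Date(nests$incubation_end))
      for (i in which(bad_date)) {
        add("nests", i, "laid_date/incubation_end", "error",
            "unparseable date")
      }
      late <- !bad_date &
        as.Date(nests$laid_date) > as.Date(nests$incubation_end)
      for (i in which(late)) {
        add("nests", i, "laid_date", "error",
            paste0("laid_date after incubation_end for nest ",
                   nests$nest_id[i]))
      }
      for (i in which(!is.finite(nests$x) | !is.finite(nests$y))) {
        add("nests", i, "x/y", "error", "non-finite coordinate")
      }
      if (!is.null(known_hab)) {
        for (i in which(!nests$habitat %in% known_hab)) {
          add("nests", i, "habitat", "error",
              paste0("unknown habitat label '", nests$habitat[i], "'"))
        }
      }
    }
  }
  if (length(v) == 0L) {
    return(data.frame(table = character(), row = integer(),
                      field = character(), severity = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline: simulate/load, build networks, analyse, report
#'
#' Executes the requested stages in dependency order, writes every output
#' table alongside a JSON run manifest sufficient to reproduce the run
#' (config echo, package version, per-stage row counts, seeds, warnings),
#' and returns the result bundle.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `data` (the `plover_data` bundle),
#'   `networks`, `results` (per-analysis summary table), `analysis_objects`
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character()
  counts <- list()

  if (!is.null(config$sightings_path)) {
    sightings <- read_sightings(config$sightings_path)
    nests <- read_nests(config$nests_path)
    habitats <- if (!is.null(config$habitats_path)) {
      read_habitats_geojson(config$habitats_path)
    } else NULL
    season_start <- config$season_start
  } else {
    sim_cfg <- config$simulation$config %||% population_config(
      seed = config$seed)
    sim <- simulate_dataset(
      config = sim_cfg,
      design = config$simulation$design %||% survey_design(),
      truth = config$simulation$truth %||% ground_truth())
    sightings <- sim$sightings; nests <- sim$nests
    habitats <- sim$habitats; season_start <- sim$season_start
  }
  counts$sightings_raw <- nrow(sightings)
  counts$nests <- nrow(nests)

  report <- validate_inputs(sightings, nests, habitats)
  if (any(report$severity == "error")) {
    stop("input validation failed:\n",
         paste(sprintf("  [%s row %s] %s", report$table, report$row,
                       report$message)[report$severity == "error"],
               collapse = "\n"))
  }
  warnings_log <- c(warnings_log, report$message[report$severity == "warning"])

  pd <- prepare_analysis_data(
    list(sightings = sightings, nests = nests,
         season_start = season_start),
    exclusion_days = config$exclusion_days, drop_may = config$drop_may,
    chain_distance = config$chain_distance,
    radius = config$neighbourhood_radius)
  counts$sightings_prebreeding <- nrow(pd$prebreeding)
  counts$network_years <- length(pd$networks)
  counts$pairs <- nrow(pd$pairs)

  results <- list(); objects <- list()
  for (id in config$analyses) {
    res <- run_analysis(id, pd, n_perm = config$n_perm,
                        seed = config$seed, mixed = config$mixed)
    objects[[id]] <- res
    results[[id]] <- data.frame(
      analysis = id, description = res$description,
      focal_term = res$spec$focal_term,
      estimate = focal_estimate(res$fit),
      lrt_chi_sq = res$lrt$chi_sq, lrt_df = res$lrt$df, lrt_p = res$lrt$p,
      p_rand = if (!is.null(res$perm)) res$perm$p_two_tailed else NA_real_,
      n_perm = if (!is.null(res$perm)) res$perm$n_perm else 0L,
      n_perm_failed = if (!is.null(res$perm)) res$perm$n_failed else 0L,
      n_obs = res$n_obs, stringsAsFactors = FALSE
    )
    counts[[paste0("n_obs_", id)]] <- res$n_obs
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL

  manifest <- list(
    package_version = as.character(packageVersion("ploversoc")),
    seed = config$seed, n_perm = config$n_perm,
    exclusion_days = config$exclusion_days, drop_may = config$drop_may,
    chain_distance = config$chain_distance,
    neighbourhood_radius = config$neighbourhood_radius,
    analyses = config$analyses, simulated = is.null(config$sightings_path),
    row_counts = counts, warnings = warnings_log
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    if (is.null(config$sightings_path)) {
      write_table_csv(sightings, out("sightings.csv"))
      write_table_csv(nests, out("nests.csv"))
      write_habitats_geojson(habitats, out("habitats.geojson"))
    }
    for (nw in pd$networks) {
      write_table_csv(network_edges(nw),
                      out(sprintf("edges_%s.csv", nw$year)))
      write_table_csv(node_metrics(nw),
                      out(sprintf("node_metrics_%s.csv", nw$year)))
    }
    if (!is.null(results)) write_table_csv(results, out("analysis_results.csv"))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(data = pd, networks = pd$networks, results = results,
                 analysis_objects = objects, manifest = manifest))
}
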