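#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (typically read from YAML) with a
#' `seed`, an `out_dir`, and one block per requested stage:
#'
#' * `simulate`: parameters forwarded to [climate_config()], plus
#'   optional `envelope` (`mean_T`, `mean_P`, `cov` as a length-4 vector,
#'   row-major), `boxes` path or inline list, `n_per_box`,
#'   `age_uncertainty`.
#' * `zooms`: `peaks` (path), `markers` (path), `tol`, `min_markers`.
#' * `calibrate`: `age`, `sigma`, `curve` (path), `levels`.
#' * `mtdist`: `aln` (path), `focal`.
#' * `niche`: `occurrences` (path), `climate` (path), `boxes` (path),
#'   `k_per_box`, `n_members`, `distance_mode`.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config (invisibly classed `run_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("Config must be a list or a YAML file path.",
                              class = "paleotrail_validation_error")
  problems <- character()
  if (is.null(config$out_dir)) problems <- c(problems, "out_dir: missing")
  if (is.null(config$seed)) {
    problems <- c(problems, "seed: missing")
  } else if (length(config$seed) != 1 || !is.numeric(config$seed)) {
    problems <- c(problems, "seed: must be a single integer")
  }
  stages <- intersect(names(config), c("simulate", "zooms", "calibrate", "mtdist", "niche"))
  if (!length(stages)) problems <- c(problems, "stages: no stage block present")

  need_path <- function(stage, field, allow_generated = FALSE) {
    val <- config[[stage]][[field]]
    if (is.null(val)) {
      problems <<- c(problems, sprintf("%s.%s: missing", stage, field))
    } else if (is.character(val) && !file.exists(val) &&
               !(allow_generated && !is.null(config$simulate))) {
      problems <<- c(problems, sprintf("%s.%s: file '%s' does not exist", stage, field, val))
    }
  }
  if ("zooms" %in% stages) {
    need_path("zooms", "peaks", allow_generated = TRUE)
    need_path("zooms", "markers")
  }
  if ("calibrate" %in% stages) {
    for (f in c("age", "sigma")) {
      if (is.null(config$calibrate[[f]])) {
        problems <- c(problems, sprintf("calibrate.%s: missing", f))
      }
    }
    need_path("calibrate", "curve", allow_generated = TRUE)
  }
  if ("mtdist" %in% stages) {
    need_path("mtdist", "aln", allow_generated = TRUE)
    if (is.null(config$mtdist$focal)) problems <- c(problems, "mtdist.focal: missing")
  }
  if ("niche" %in% stages) {
    need_path("niche", "occurrences", allow_generated = TRUE)
    need_path("niche", "climate", allow_generated = TRUE)
    need_path("niche", "boxes", allow_generated = TRUE)
  }
  if (length(problems)) {
    abort(paste0("Invalid run configuration:\n",
                 paste0("  - ", problems, collapse = "\n")),
          class = "paleotrail_validation_error")
  }
  class(config) <- c("run_config", class(config))
  invisible(config)
}

resolve_boxes <- function(spec) {
  if (is.null(spec)) return(study_region_boxes())
  if (is.character(spec)) return(read_region_boxes(spec))
  purrr::map_dfr(spec, ~ region_box(.x$label, .x$lon_min, .x$lon_max,
                                    .x$lat_min, .x$lat_max))
}

#' Execute a pipeline run from a configuration
#'
#' Runs the requested stages in dependency order (`simulate` first, so
#' later stages can consume freshly generated inputs), writes standard
#' outputs under `out_dir` via [write_outputs()], and returns a manifest
#' recording the seed, per-stage output paths, and any warnings raised
#' (age-bound swaps, covariance regularizations, clamped ages).
#' Re-running the same configuration and seed reproduces the outputs
#' byte for byte.
#'
#' @param config Named list or YAML path (see [validate_config()]).
#' @return A `run_manifest` list: `seed`, `out_dir`, `stages` (named list
#'   of output path vectors), `warnings`, `versions`.
#' @export
run_config <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  results <- list()
  warnings_log <- character()
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  withCallingHandlers({
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      cfg_args <- sim[intersect(names(sim), names(formals(climate_config)))]
      cfg_args$seed <- cfg_args$seed %||% seed
      climate <- make_climate(do.call(climate_config, cfg_args))
      results$simulate <- list(climate = climate)
      if (!is.null(sim$envelope)) {
        tr <- envelope_truth(sim$envelope$mean_T, sim$envelope$mean_P,
                             matrix(unlist(sim$envelope$cov), 2, 2, byrow = TRUE))
        boxes <- resolve_boxes(sim$boxes)
        occ <- make_occurrences(climate, tr, boxes,
                                n_per_box = sim$n_per_box %||% 10,
                                age_uncertainty = sim$age_uncertainty %||% 4000,
                                seed = seed + 1L)
        results$simulate$occurrences <- occ
        results$simulate$boxes <- boxes
      }
    }
    if (!is.null(config$zooms)) {
      markers <- read_marker_table(config$zooms$markers)
      peaks <- read_peaklist(config$zooms$peaks)
      results$zooms <- list(
        assignment = classify_spectrum(peaks, markers,
                                       tol = config$zooms$tol %||% 0.2,
                                       min_markers = config$zooms$min_markers %||% 4))
    }
    if (!is.null(config$calibrate)) {
      curve <- read_calcurve(config$calibrate$curve)
      dens <- calibrate_date(config$calibrate$age, config$calibrate$sigma, curve,
                             lab_code = config$calibrate$lab_code)
      levels <- config$calibrate$levels %||% c(0.683, 0.954)
      results$calibrate <- list(
        density = dens,
        intervals = purrr::map_dfr(levels, ~ hpd_intervals(dens, .x)))
    }
    if (!is.null(config$mtdist)) {
      aln <- read_alignment_fasta(config$mtdist$aln)
      results$mtdist <- list(ranking = rank_dissimilarity(aln, config$mtdist$focal))
    }
    if (!is.null(config$niche)) {
      nc <- config$niche
      climate <- if (!is.null(nc$climate) && is.character(nc$climate) && file.exists(nc$climate)) {
        read_climate_nc(nc$climate)
      } else results$simulate$climate
      occ <- if (!is.null(nc$occurrences) && is.character(nc$occurrences) && file.exists(nc$occurrences)) {
        read_fossil_table(nc$occurrences)
      } else results$simulate$occurrences
      boxes <- if (!is.null(nc$boxes) && is.character(nc$boxes) && file.exists(nc$boxes)) {
        read_region_boxes(nc$boxes)
      } else results$simulate$boxes %||% study_region_boxes()
      results$niche <- list(
        ensemble = run_monte_carlo(occ, boxes,
                                   k_per_box = nc$k_per_box %||% 2,
                                   field = climate,
                                   n_members = nc$n_members %||% 5000,
                                   seed = seed,
                                   distance_mode = nc$distance_mode %||% "quadratic"),
        boxes = boxes)
    }
  }, warning = log_warning)

  manifest <- write_outputs(results, out_dir)
  manifest$seed <- seed
  manifest$warnings <- warnings_log
  manifest$versions <- list(
    paleotrail = as.character(utils::packageVersion("paleotrail")),
    R = paste(R.version$major, R.version$minor, sep = "."))
  yaml::write_yaml(manifest[c("seed", "stages", "warnings", "versions")],
                   file.path(out_dir, "manifest.yaml"))
  class(manifest) <- "run_manifest"
  manifest
}

#' Write pipeline stage results to standard formats
#'
#' CSVs carry headers; gridded fields go to NetCDF with coordinate
#' metadata. Empty results produce a manifest only.
#'
#' @param results Named list of stage results (as built by [run_config()]).
#' @param out_dir Writable output directory.
#' @return A manifest list with per-stage output paths.
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("Output directory '%s' is not writable.", out_dir),
          class = "paleotrail_io_error")
  }
  stages <- list()
  emit <- function(stage, name, path) {
    stages[[stage]] <<- c(stages[[stage]], setNames(path, name))
  }
  if (!is.null(results$simulate)) {
    p <- file.path(out_dir, "climate.nc")
    write_climate_nc(results$simulate$climate, p); emit("simulate", "climate", p)
    if (!is.null(results$simulate$occurrences)) {
      p <- file.path(out_dir, "occurrences.csv")
      write_fossil_table(results$simulate$occurrences, p)
      emit("simulate", "occurrences", p)
    }
  }
  if (!is.null(results$zooms)) {
    p <- file.path(out_dir, "zooms_assignment.csv")
    readr::write_csv(dplyr::select(results$zooms$assignment, -"matched_mz"), p)
    emit("zooms", "assignment", p)
  }
  if (!is.null(results$calibrate)) {
    p <- file.path(out_dir, "hpd_intervals.csv")
    write_hpd_csv(results$calibrate$intervals, p); emit("calibrate", "intervals", p)
    p <- file.path(out_dir, "calibrated_density.csv")
    readr::write_csv(tibble::as_tibble(results$calibrate$density), p)
    emit("calibrate", "density", p)
  }
  if (!is.null(results$mtdist)) {
    p <- file.path(out_dir, "pairwise_differences.csv")
    readr::write_csv(results$mtdist$ranking, p); emit("mtdist", "ranking", p)
  }
  if (!is.null(results$niche)) {
    p <- file.path(out_dir, "suitability_mean.nc")
    write_suitability_nc(results$niche$ensemble, p); emit("niche", "suitability", p)
    p <- file.path(out_dir, "box_timeseries.csv")
    series <- purrr::map_dfr(results$niche$boxes$label,
                             ~ box_timeseries(results$niche$ensemble, .x))
    readr::write_csv(series, p); emit("niche", "box_timeseries", p)
  }
  list(out_dir = out_dir, stages = stages)
}
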