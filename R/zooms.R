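#' Read a ZooMS peptide-marker reference table
#'
#' A marker table maps each taxon to the monoisotopic \[M+H\]+ masses of
#' its named collagen peptide markers (A–G). Missing markers (masses not
#' established for a taxon) may be left absent or blank.
#'
#' @param path CSV with columns `taxon, marker, mz`.
#' @return A `marker_table` tibble.
#' @export
read_marker_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(taxon = "c", marker = "c", mz = "d"))
  as_marker_table(df)
}

#' @rdname read_marker_table
#' @param df A data frame with columns `taxon, marker, mz`.
#' @export
as_marker_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("taxon", "marker", "mz") %in% names(df))) {
    abort("Marker table needs columns: taxon, marker, mz.",
          class = "paleotrail_parse_error")
  }
  df <- dplyr::filter(df, !is.na(.data$mz))
  if (any(df$mz <= 0)) abort("Marker m/z must be positive.", class = "paleotrail_parse_error")
  dup <- dplyr::count(df, .data$taxon, .data$marker)
  if (any(dup$n > 1)) {
    abort("Marker names must be unique within each taxon.", class = "paleotrail_parse_error")
  }
  class(df) <- c("marker_table", class(df))
  df
}

#' Bundled example ZooMS marker library
#'
#' The bundled reference library used in examples and tests. The
#' Hominidae row holds the six published marker masses observed for the
#' Starosele hominin spectrum (markers A–D, F, G; marker E's mass is not
#' established and is absent). The remaining taxa carry illustrative
#' masses chosen to be mutually separable at ±0.2 Da — a synthetic
#' stand-in for a full curated ZooMS library, suitable for demonstrating
#' and testing the matching logic, not for identifying real spectra.
#'
#' @return A `marker_table` tibble.
#' @export
example_marker_table <- function() {
  read_marker_table(path_extdata("zooms_markers_synthetic_library.csv"))
}

#' Read a MALDI peak list
#'
#' Accepts two-column CSV (`mz, intensity`) or whitespace-separated text;
#' a one-column input is read as masses with unit intensities. Peaks are
#' sorted ascending in m/z on load.
#'
#' @param path Peak-list file.
#' @return A `peak_list` tibble with columns `mz`, `intensity`.
#' @export
read_peaklist <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^[a-zA-Z]", trimws(first))
  if (grepl(",", first)) {
    df <- readr::read_csv(path, show_col_types = FALSE, col_names = has_header)
  } else {
    df <- readr::read_table(path, show_col_types = FALSE, col_names = has_header)
  }
  if (!"mz" %in% names(df)) {
    names(df)[1] <- "mz"
    if (ncol(df) >= 2) names(df)[2] <- "intensity"
  }
  if (!"intensity" %in% names(df)) df$intensity <- 1
  as_peaklist(df[c("mz", "intensity")])
}

#' @rdname read_peaklist
#' @param df A data frame with column `mz` (and optionally `intensity`).
#' @export
as_peaklist <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"mz" %in% names(df)) abort("Peak list needs an `mz` column.",
                                  class = "paleotrail_parse_error")
  if (!"intensity" %in% names(df)) df$intensity <- 1
  if (any(df$mz <= 0)) abort("Peak m/z must be strictly positive.",
                             class = "paleotrail_parse_error")
  df <- dplyr::arrange(df, .data$mz)
  class(df) <- c("peak_list", class(df))
  df
}

#' Write a peak list to two-column CSV
#'
#' @param peaks A `peak_list`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  readr::write_csv(tibble::as_tibble(peaks)[c("mz", "intensity")], path)
  invisible(path)
}

#' The published peak masses of the Starosele hominin spectrum
#'
#' Six peptide-marker peaks (A–D, F and G) read off the MALDI spectrum of
#' the Star 1 bone fragment; marker E is missing from the spectrum.
#'
#' @return A `peak_list` tibble.
#' @export
star1_peaklist <- function() {
  read_peaklist(path_extdata("star1_peaks.csv"))
}

#' Generate a synthetic MALDI peak list for a taxon
#'
#' Takes the taxon's reference marker masses, applies Gaussian mass
#' jitter, drops named markers (emulating degraded or absent peptides),
#' and adds uniform noise peaks over the instrument's mass range.
#'
#' @param taxon Taxon label present in `markers`.
#' @param markers A `marker_table`.
#' @param jitter_sd Mass jitter standard deviation, Da.
#' @param dropout Character vector of marker names to drop.
#' @param n_noise_peaks Number of uniform noise peaks to add.
#' @param mz_range Instrument mass range for noise peaks, Da.
#' @param seed Integer seed.
#' @return A `peak_list` tibble.
#' @export
make_peaklist <- function(taxon, markers, jitter_sd = 0.05, dropout = character(),
                          n_noise_peaks = 0, mz_range = c(800, 3600), seed = 1L) {
  stopifnot(inherits(markers, "marker_table"))
  rows <- dplyr::filter(markers, .data$taxon == !!taxon)
  if (!nrow(rows)) {
    abort(sprintf("Taxon '%s' is not in the marker table.", taxon),
          class = "paleotrail_lookup_error")
  }
  rows <- dplyr::filter(rows, !.data$marker %in% dropout)
  with_seed(seed, {
    mz <- rows$mz + if (jitter_sd > 0) rnorm(nrow(rows), 0, jitter_sd) else 0
    intensity <- runif(nrow(rows), 40, 100)
    if (n_noise_peaks > 0) {
      mz <- c(mz, runif(n_noise_peaks, mz_range[1], mz_range[2]))
      intensity <- c(intensity, runif(n_noise_peaks, 1, 20))
    }
    as_peaklist(tibble::tibble(mz = mz, intensity = intensity))
  })
}

#' Match observed peaks against one taxon's markers
#'
#' A marker is matched when some observed peak lies within ± `tol` of its
#' reference mass; the closest peak is reported for each matched marker.
#'
#' @param peaks A `peak_list` (or data frame with `mz`).
#' @param taxon_markers Named numeric vector of marker masses (names are
#'   marker names), or a one-taxon slice of a `marker_table`.
#' @param tol Match tolerance, Da (> 0). Default ±0.2 Da.
#' @return A tibble with one row per matched marker: `marker`, `mz_ref`,
#'   `mz_obs`, `delta`.
#' @examples
#' tbl <- example_marker_table()
#' hom <- dplyr::filter(tbl, taxon == "Hominidae")
#' match_markers(star1_peaklist(), hom)
#' @export
match_markers <- function(peaks, taxon_markers, tol = 0.2) {
  if (tol <= 0) abort("`tol` must be positive.", class = "paleotrail_config_error")
  if (is.data.frame(taxon_markers)) {
    taxon_markers <- setNames(taxon_markers$mz, taxon_markers$marker)
  }
  if (!length(taxon_markers)) {
    abort("Empty marker map.", class = "paleotrail_config_error")
  }
  mz_obs <- if (is.data.frame(peaks)) peaks$mz else as.numeric(peaks)
  empty <- tibble::tibble(marker = character(), mz_ref = numeric(),
                          mz_obs = numeric(), delta = numeric())
  if (!length(mz_obs)) return(empty)
  hits <- purrr::imap_dfr(taxon_markers, function(m, name) {
    d <- mz_obs - m
    best <- which.min(abs(d))
    tibble::tibble(marker = name, mz_ref = m, mz_obs = mz_obs[best], delta = d[best])
  })
  out <- dplyr::filter(hits, abs(.data$delta) <= tol)
  if (!nrow(out)) empty else dplyr::arrange(out, .data$marker)
}

#' Assign a taxon to a MALDI spectrum
#'
#' Matches the peak list against every taxon in the reference table and
#' reports the taxon with the most matched markers, provided at least
#' `min_markers` markers match; otherwise `"unidentified"`. A tie between
#' taxa is reported as the composite label joining them with `/` (shared
#' collagen peptides make composite categories like `"Cervidae/Bovidae"`
#' genuinely irresolvable at the peptide level). One peak may satisfy
#' markers of several taxa; no peak exclusivity is enforced.
#'
#' @inheritParams match_markers
#' @param table A `marker_table`.
#' @param min_markers Minimum matched markers required for an
#'   identification (default 4).
#' @return A one-row tibble: `taxon`, `n_matched`, `matched_markers`
#'   (comma-joined), `matched_mz` (list column).
#' @export
classify_spectrum <- function(peaks, table, tol = 0.2, min_markers = 4) {
  stopifnot(inherits(table, "marker_table"))
  if (min_markers < 1) abort("`min_markers` must be >= 1.",
                             class = "paleotrail_config_error")
  per_taxon <- table |>
    dplyr::group_by(.data$taxon) |>
    dplyr::group_map(function(rows, key) {
      m <- match_markers(peaks, setNames(rows$mz, rows$marker), tol = tol)
      tibble::tibble(taxon = key$taxon, n_matched = nrow(m), matches = list(m))
    }) |>
    dplyr::bind_rows()
  best <- max(per_taxon$n_matched, 0)
  if (!nrow(per_taxon) || best < min_markers) {
    return(tibble::tibble(taxon = "unidentified", n_matched = 0L,
                          matched_markers = "", matched_mz = list(numeric())))
  }
  top <- dplyr::filter(per_taxon, .data$n_matched == best) |>
    dplyr::arrange(.data$taxon)
  label <- paste(top$taxon, collapse = "/")
  m <- top$matches[[1]]
  tibble::tibble(taxon = label, n_matched = as.integer(best),
                 matched_markers = paste(m$marker, collapse = ","),
                 matched_mz = list(m$mz_obs))
}

#' Summarize taxon assignments by stratigraphic context
#'
#' Computes, per context, the percentage of identified specimens assigned
#' to each taxon (identified specimens as denominator), plus the overall
#' identification success rate.
#'
#' @param assignments A data frame with one row per analyzed specimen and
#'   columns `context` and `taxon` (`"unidentified"` for failures), e.g.
#'   built by binding [classify_spectrum()] rows.
#' @return A tibble `context, taxon, n, pct` restricted to identified
#'   specimens, with attribute `success_rate` (percent identified of all
#'   analyzed) also available through [glance()].
#' @export
summarize_assemblage <- function(assignments) {
  assignments <- tibble::as_tibble(assignments)
  if (!nrow(assignments)) abort("Need at least one assignment.",
                                class = "paleotrail_config_error")
  if (!all(c("context", "taxon") %in% names(assignments))) {
    abort("`assignments` needs columns `context` and `taxon`.",
          class = "paleotrail_parse_error")
  }
  n_total <- nrow(assignments)
  identified <- dplyr::filter(assignments, .data$taxon != "unidentified")
  out <- identified |>
    dplyr::count(.data$context, .data$taxon, name = "n") |>
    dplyr::group_by(.data$context) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  attr(out, "success_rate") <- 100 * nrow(identified) / n_total
  attr(out, "n_analyzed") <- n_total
  attr(out, "n_identified") <- nrow(identified)
  class(out) <- c("assemblage_summary", class(out))
  out
}

#' @exportS3Method generics::glance
glance.assemblage_summary <- function(x, ...) {
  tibble::tibble(n_analyzed = attr(x, "n_analyzed"),
                 n_identified = attr(x, "n_identified"),
                 success_rate = attr(x, "success_rate"))
}

#' Stacked-bar plot of an assemblage summary by context
#'
#' @param object An `assemblage_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.assemblage_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$context, .data$pct, fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Context", y = "% of identified specimens", fill = "Taxon") +
    ggplot2::theme_minimal()
}
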