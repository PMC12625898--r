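#' Extract climate at the nearest spatiotemporal grid point
#'
#' For each (latitude, longitude, age) point, returns the temperature and
#' precipitation at the nearest cell center (nearest independently on
#' each axis; longitude distance is wrap-aware across the dateline) and
#' the nearest time slice. Ages outside the field's time span are clamped
#' to the nearest end with a warning.
#'
#' @param points A data frame with columns `latitude`, `longitude`, `age`
#'   (years BP), or a numeric vector `c(latitude, longitude, age)`.
#' @param field A [climate_field()].
#' @return A tibble with one row per point: `latitude`, `longitude`,
#'   `age`, `T`, `P` (plus a `cell_*` index triple for downstream reuse).
#' @export
extract_climate <- function(points, field) {
  stopifnot(inherits(field, "climate_field"))
  if (is.numeric(points) && is.null(dim(points))) {
    points <- tibble::tibble(latitude = points[1], longitude = points[2],
                             age = points[3])
  }
  points <- tibble::as_tibble(points)
  lon <- normalize_lon(points$longitude)
  if (any(abs(points$latitude) > 90)) {
    abort("Latitude outside [-90, 90]: point is off the spatial grid.",
          class = "paleotrail_domain_error")
  }
  i <- vapply(lon, function(x) which.min(lon_distance(x, field$lon)), 1L)
  j <- vapply(points$latitude, function(x) which.min(abs(x - field$lat)), 1L)
  age <- points$age
  out_of_span <- age < min(field$time) | age > max(field$time)
  if (any(out_of_span)) {
    warn(sprintf("%d age(s) outside the field's time span [%s, %s] yr BP; clamped.",
                 sum(out_of_span),
                 format(min(field$time), big.mark = ","),
                 format(max(field$time), big.mark = ",")))
    age <- pmin(pmax(age, min(field$time)), max(field$time))
  }
  k <- vapply(age, function(x) which.min(abs(x - field$time)), 1L)
  idx <- cbind(i, j, k)
  tibble::tibble(latitude = points$latitude, longitude = points$longitude,
                 age = points$age,
                 T = field$T[idx], P = field$P[idx],
                 cell_lon = i, cell_lat = j, cell_time = k)
}

#' Draw one balanced ensemble member from a dated fossil table
#'
#' Samples an equal number `k_per_box` of records from each region box
#' uniformly without replacement (a box holding exactly `k_per_box`
#' records therefore always contributes all of them), and draws each
#' sampled record's age uniformly within its age-uncertainty bracket.
#' Consumes the current RNG state; seed management belongs to the caller
#' (see [run_monte_carlo()]).
#'
#' @param records A `fossil_records` tibble.
#' @param boxes Region-box tibble; `label` values must appear in
#'   `records$location`.
#' @param k_per_box Records to draw per box.
#' @return The sampled rows with an added `drawn_age` column.
#' @export
sample_ensemble_member <- function(records, boxes, k_per_box = 2) {
  records <- tibble::as_tibble(records)
  purrr::map_dfr(boxes$label, function(lab) {
    in_box <- dplyr::filter(records, .data$location == lab)
    if (nrow(in_box) < k_per_box) {
      abort(sprintf("Region box '%s' holds %d record(s), fewer than k_per_box = %d.",
                    lab, nrow(in_box), k_per_box),
            class = "paleotrail_sampling_error")
    }
    pick <- in_box[sample.int(nrow(in_box), k_per_box), ]
    pick$drawn_age <- runif(k_per_box, pick$younger_age, pick$older_age)
    pick
  })
}

#' Fit a climate envelope (mean and inverse covariance)
#'
#' Computes the mean vector and inverse sample covariance (unbiased,
#' n−1 denominator) of an n×2 matrix of (T, P) conditions. A singular or
#' severely ill-conditioned covariance (condition number > 1e12) is
#' ridge-regularized as `S + eps * I` with `eps = 1e-6 * trace(S) / 2`
#' (plus a tiny absolute floor when the trace itself vanishes), with a
#' warning.
#'
#' @param C Numeric n×2 matrix (or data frame with columns `T`, `P`);
#'   n >= 3.
#' @return A `climate_envelope` list with elements `mean` (length 2),
#'   `sigma` (2×2), `sigma_inv` (2×2), `n`, `regularized` (logical).
#' @export
fit_envelope <- function(C) {
  if (is.data.frame(C)) C <- as.matrix(C[, c("T", "P")])
  C <- matrix(as.numeric(C), ncol = 2L,
              dimnames = list(NULL, c("T", "P")))
  n <- nrow(C)
  if (n < 3) {
    abort("Need at least 3 condition rows to estimate a 2-D covariance.",
          class = "paleotrail_insufficient_sample_error")
  }
  m <- colMeans(C)
  S <- cov(C)
  regularized <- FALSE
  cond <- tryCatch(suppressWarnings(kappa(S, exact = TRUE)),
                   error = function(e) Inf)
  sigma_inv <- NULL
  if (is.finite(cond) && cond >= 1 && cond <= 1e12) {
    sigma_inv <- tryCatch(solve(S), error = function(e) NULL)
  }
  if (is.null(sigma_inv)) {
    eps <- 1e-6 * sum(diag(S)) / 2
    if (eps <= 0) eps <- 1e-8
    S <- S + diag(eps, 2)
    regularized <- TRUE
    warn("Sample covariance is singular or ill-conditioned; ridge-regularized before inversion.")
    sigma_inv <- solve(S)
  }
  structure(list(mean = m, sigma = S, sigma_inv = sigma_inv, n = n,
                 regularized = regularized),
            class = "climate_envelope")
}

#' Map habitat suitability across a climate field
#'
#' Evaluates, at every grid cell and time slice, the Mahalanobis
#' statistic of the cell's climate `c = (T, P)` against a fitted envelope
#' — the quadratic form `d = (c - m)' S^{-1} (c - m)` by default, or its
#' square root with `distance_mode = "root"` — and converts it to
#' suitability `s = exp(-d)`, so `s = 1` exactly where the climate equals
#' the envelope mean and decays towards 0 with climatic distance.
#'
#' @param envelope A `climate_envelope` from [fit_envelope()] (or a list
#'   with `mean` and `sigma_inv`).
#' @param field A [climate_field()].
#' @param distance_mode `"quadratic"` (default; exponential decay of the
#'   quadratic form) or `"root"` (conventional Mahalanobis distance).
#' @return A `suitability_field`: list with the field's `lon`, `lat`,
#'   `time` axes and an `s` array in (0, 1]. Non-finite climate cells
#'   propagate as `NA` suitability and are flagged via the `n_missing`
#'   attribute.
#' @export
suitability_map <- function(envelope, field,
                            distance_mode = c("quadratic", "root")) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(inherits(field, "climate_field"))
  d <- maha_quad(cbind(as.vector(field$T), as.vector(field$P)),
                 envelope$mean, envelope$sigma_inv)
  d[d < 0] <- 0  # guard against negative round-off near zero
  if (distance_mode == "root") d <- sqrt(d)
  s <- exp(-d)
  n_missing <- sum(!is.finite(s))
  if (n_missing > 0) {
    warn(sprintf("%d grid values have non-finite climate; suitability set to NA there.",
                 n_missing))
    s[!is.finite(s)] <- NA_real_
  }
  structure(list(lon = field$lon, lat = field$lat, time = field$time,
                 s = array(s, dim(field$T))),
            class = "suitability_field", n_missing = n_missing)
}

# Indices (into the lon x lat cell grid, column-major) of cell centers
# inside a region box.
box_cell_index <- function(lon, lat, box) {
  ii <- which(lon >= box$lon_min & lon <= box$lon_max)
  jj <- which(lat >= box$lat_min & lat <= box$lat_max)
  if (!length(ii) || !length(jj)) {
    abort(sprintf("Region box '%s' contains no grid cell centers.", box$label),
          class = "paleotrail_domain_error")
  }
  as.vector(outer(ii, (jj - 1L) * length(lon), `+`))
}

#' Run the Monte Carlo habitat suitability ensemble
#'
#' Repeats `n_members` times: draw a balanced ensemble member
#' ([sample_ensemble_member()]), extract the nearest-gridpoint climate at
#' each sampled record's location and drawn age, fit the climate envelope
#' ([fit_envelope()]), and map suitability over the whole climate grid
#' ([suitability_map()]). Accumulates the ensemble-average suitability
#' grid and per-member regional time series for `series_boxes`.
#'
#' A master seed derives one independent stream seed per member, so the
#' member set is reproducible and independent of scheduling. Members whose
#' envelope fit fails are skipped with a warning; if more than 10% of
#' members fail the run errors.
#'
#' @inheritParams sample_ensemble_member
#' @param field A [climate_field()].
#' @param n_members Ensemble size (the primary study configuration uses
#'   5,000).
#' @param seed Master seed.
#' @param distance_mode Passed to [suitability_map()].
#' @param series_boxes Boxes for which per-member time series are stored
#'   (default: `boxes`).
#' @param keep_members Keep every member's full suitability grid (memory
#'   heavy; only sensible for small ensembles).
#' @return A `suitability_ensemble`: `mean_s` (lon × lat × time ensemble
#'   average), `box_series` (tibble: `member`, `box`, `time`,
#'   `suitability`), `envelopes` (per-member mean/covariance summaries),
#'   `n_members`, `n_failed`, `seed`, axes, and optionally `members`.
#' @export
run_monte_carlo <- function(records, boxes, k_per_box, field,
                            n_members = 5000, seed = 1L,
                            distance_mode = c("quadratic", "root"),
                            series_boxes = boxes, keep_members = FALSE) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(inherits(field, "climate_field"))
  records <- tibble::as_tibble(records)
  records$.row <- seq_len(nrow(records))

  # Record positions never change across members: pre-resolve each
  # record's grid cell and keep its full climate time series at hand.
  cell <- extract_climate(
    tibble::tibble(latitude = records$latitude, longitude = records$longitude,
                   age = pmin(pmax((records$older_age + records$younger_age) / 2,
                                   min(field$time)), max(field$time))),
    field)
  nlon <- length(field$lon); nlat <- length(field$lat); nt <- length(field$time)
  ncell <- nlon * nlat
  Tmat <- matrix(field$T, ncell, nt)
  Pmat <- matrix(field$P, ncell, nt)
  rec_cell <- cell$cell_lon + (cell$cell_lat - 1L) * nlon
  time_axis <- field$time
  t0 <- time_axis[1]; dt <- if (nt > 1) time_axis[2] - time_axis[1] else 1
  uniform_time <- nt < 2 || max(abs(diff(time_axis) - dt)) < 1e-6 * abs(dt)
  Gt <- as.vector(Tmat); Gp <- as.vector(Pmat)

  box_idx <- purrr::map(seq_len(nrow(series_boxes)),
                        ~ box_cell_index(field$lon, field$lat, series_boxes[.x, ]))
  names(box_idx) <- series_boxes$label

  box_rows <- purrr::map(boxes$label, ~ which(records$location == .x))
  short <- which(lengths(box_rows) < k_per_box)
  if (length(short)) {
    abort(sprintf("Region box '%s' holds %d record(s), fewer than k_per_box = %d.",
                  boxes$label[short[1]], lengths(box_rows)[short[1]], k_per_box),
          class = "paleotrail_sampling_error")
  }

  stream_seeds <- derive_stream_seeds(seed, n_members)
  sum_s <- matrix(0, ncell, nt)
  series <- array(NA_real_, c(n_members, nt, length(box_idx)))
  env_log <- vector("list", n_members)
  members <- if (keep_members) vector("list", n_members) else NULL
  n_failed <- 0L

  for (m in seq_len(n_members)) {
    res <- tryCatch({
      # Fast balanced draw; same RNG call sequence as sample_ensemble_member()
      # (per box in order: sample.int then runif), so results are identical.
      drawn <- with_seed(stream_seeds[m], {
        rows <- integer(0); ages <- numeric(0)
        for (b in seq_along(box_rows)) {
          take <- box_rows[[b]][sample.int(length(box_rows[[b]]), k_per_box)]
          rows <- c(rows, take)
          ages <- c(ages, runif(k_per_box, records$younger_age[take],
                                records$older_age[take]))
        }
        list(rows = rows, ages = ages)
      })
      k <- if (uniform_time) {
        pmin(pmax(as.integer(round((drawn$ages - t0) / dt)) + 1L, 1L), nt)
      } else {
        vapply(drawn$ages, function(a) which.min(abs(a - time_axis)), 1L)
      }
      cidx <- cbind(rec_cell[drawn$rows], k)
      C <- cbind(T = Tmat[cidx], P = Pmat[cidx])
      env <- fit_envelope(C)
      si <- env$sigma_inv
      d1 <- Gt - env$mean[1]; d2 <- Gp - env$mean[2]
      d <- si[1, 1] * d1 * d1 + 2 * si[1, 2] * d1 * d2 + si[2, 2] * d2 * d2
      d[d < 0] <- 0
      if (distance_mode == "root") d <- sqrt(d)
      s <- exp(-d)
      dim(s) <- c(ncell, nt)
      list(s = s, env = env)
    }, error = function(e) {
      if (inherits(e, "paleotrail_sampling_error")) stop(e)
      warn(sprintf("Member %d skipped: %s", m, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    sum_s <- sum_s + res$s
    for (b in seq_along(box_idx)) {
      series[m, , b] <- colMeans(res$s[box_idx[[b]], , drop = FALSE])
    }
    env_log[[m]] <- tibble::tibble(
      member = m, mean_T = res$env$mean[1], mean_P = res$env$mean[2],
      regularized = res$env$regularized)
    if (keep_members) members[[m]] <- array(res$s, c(nlon, nlat, nt))
  }
  if (n_failed > 0.1 * n_members) {
    abort(sprintf("%d of %d ensemble members failed (> 10%%); aborting run.",
                  n_failed, n_members),
          class = "paleotrail_run_error")
  }
  n_ok <- n_members - n_failed
  box_series <- purrr::map_dfr(seq_along(box_idx), function(b) {
    ok <- which(!is.na(series[, 1, b]))
    tidyr::expand_grid(member = ok, time = time_axis) |>
      dplyr::mutate(box = names(box_idx)[b],
                    suitability = as.vector(t(series[ok, , b, drop = TRUE])))
  }) |>
    dplyr::relocate("member", "box", "time", "suitability")

  structure(list(
    lon = field$lon, lat = field$lat, time = time_axis,
    mean_s = array(sum_s / n_ok, c(nlon, nlat, nt)),
    box_series = box_series,
    envelopes = dplyr::bind_rows(env_log),
    n_members = n_members, n_failed = n_failed,
    seed = seed, distance_mode = distance_mode,
    k_per_box = k_per_box,
    members = members
  ), class = "suitability_ensemble")
}

#' @export
print.suitability_ensemble <- function(x, ...) {
  cat(sprintf("<suitability_ensemble> %d members (%d failed), %d x %d x %d grid\n",
              x$n_members, x$n_failed,
              length(x$lon), length(x$lat), length(x$time)))
  cat(sprintf("  distance_mode: %s   k_per_box: %d   seed: %s\n",
              x$distance_mode, x$k_per_box, format(x$seed)))
  cat(sprintf("  box series stored for: %s\n",
              paste(unique(x$box_series$box), collapse = ", ")))
  invisible(x)
}

#' Regional suitability time series of an ensemble
#'
#' Per time slice, the unweighted mean suitability over the cells whose
#' centers fall inside the box — for every ensemble member plus the
#' ensemble mean.
#'
#' @param ensemble A `suitability_ensemble`.
#' @param box A region-box row (see [region_box()]) or a stored box label.
#' @return A tibble `member, box, time, suitability`; `member = 0` rows
#'   hold the ensemble-mean series.
#' @export
box_timeseries <- function(ensemble, box) {
  stopifnot(inherits(ensemble, "suitability_ensemble"))
  label <- if (is.character(box)) box else box$label
  stored <- dplyr::filter(ensemble$box_series, .data$box == label)
  if (!nrow(stored)) {
    if (is.character(box)) {
      abort(sprintf("No stored series for box '%s'; pass the box definition and keep_members = TRUE, or list it in series_boxes when running the ensemble.",
                    label),
            class = "paleotrail_domain_error")
    }
    if (is.null(ensemble$members)) {
      abort(sprintf("Box '%s' was not in series_boxes and member grids were not kept.",
                    label),
            class = "paleotrail_domain_error")
    }
    idx <- box_cell_index(ensemble$lon, ensemble$lat, box)
    nt <- length(ensemble$time)
    stored <- purrr::imap_dfr(ensemble$members, function(s, m) {
      if (is.null(s)) return(NULL)
      smat <- matrix(s, length(ensemble$lon) * length(ensemble$lat), nt)
      tibble::tibble(member = m, box = label, time = ensemble$time,
                     suitability = colMeans(smat[idx, , drop = FALSE]))
    })
  }
  mean_series <- stored |>
    dplyr::group_by(.data$box, .data$time) |>
    dplyr::summarise(suitability = mean(.data$suitability), .groups = "drop") |>
    dplyr::mutate(member = 0L) |>
    dplyr::relocate("member", "box", "time", "suitability")
  dplyr::bind_rows(mean_series, stored)
}

#' @exportS3Method generics::tidy
tidy.suitability_ensemble <- function(x, ...) {
  grid <- tidyr::expand_grid(time = x$time, lat = x$lat, lon = x$lon)
  tibble::tibble(lon = grid$lon, lat = grid$lat, time = grid$time,
                 suitability = as.vector(x$mean_s))
}

#' @exportS3Method generics::glance
glance.suitability_ensemble <- function(x, ...) {
  tibble::tibble(n_members = x$n_members, n_failed = x$n_failed,
                 k_per_box = x$k_per_box, distance_mode = x$distance_mode,
                 seed = x$seed,
                 mean_suitability = mean(x$mean_s, na.rm = TRUE),
                 max_suitability = max(x$mean_s, na.rm = TRUE))
}

#' Plot a regional suitability time series
#'
#' Individual ensemble members are drawn in grey with the ensemble mean
#' on top, time running from the past towards the present.
#'
#' @param object A `suitability_ensemble`.
#' @param box Box label or region-box row (default: first stored box).
#' @param max_members Thin the plotted member lines to at most this many.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.suitability_ensemble <- function(object,
                                          box = unique(object$box_series$box)[1],
                                          max_members = 200, ...) {
  ts <- box_timeseries(object, box)
  members <- dplyr::filter(ts, .data$member > 0)
  keep <- unique(members$member)
  if (length(keep) > max_members) {
    members <- dplyr::filter(members, .data$member %in% keep[seq_len(max_members)])
  }
  ggplot2::ggplot(members,
                  ggplot2::aes(.data$time, .data$suitability, group = .data$member)) +
    ggplot2::geom_line(colour = "grey70", linewidth = 0.2, alpha = 0.5) +
    ggplot2::geom_line(data = dplyr::filter(ts, .data$member == 0),
                       colour = "steelblue", linewidth = 1) +
    ggplot2::scale_x_reverse(labels = function(x) format(x, big.mark = ",")) +
    ggplot2::labs(x = "Age (yr BP)", y = "Mean suitability",
                  title = sprintf("Habitat suitability, %s",
                                  if (is.character(box)) box else box$label)) +
    ggplot2::theme_minimal()
}

#' Write a suitability grid to NetCDF
#'
#' Writes the ensemble-average suitability on `lon`/`lat`/`time`
#' dimensions.
#'
#' @param ensemble A `suitability_ensemble`.
#' @param path Output `.nc` path.
#' @return `path`, invisibly.
#' @export
write_suitability_nc <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "suitability_ensemble"))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", ensemble$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", ensemble$lat)
  dim_time <- ncdf4::ncdim_def("time", "years BP", ensemble$time)
  var_s <- ncdf4::ncvar_def("suitability", "1", list(dim_lon, dim_lat, dim_time),
                            missval = NA_real_, prec = "double",
                            longname = "ensemble mean habitat suitability exp(-d)")
  nc <- ncdf4::nc_create(path, list(var_s))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, var_s, ensemble$mean_s)
  invisible(path)
}
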