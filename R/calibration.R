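#' Construct a radiocarbon calibration curve
#'
#' @param cal_bp Calendar ages, years cal BP (any order; stored ascending).
#' @param c14_age Conventional radiocarbon age of the curve at each
#'   calendar age, 14C yr BP.
#' @param error 1-sigma curve uncertainty, 14C yr (>= 0).
#' @return A `cal_curve` tibble with ascending `cal_bp`.
#' @export
cal_curve <- function(cal_bp, c14_age, error) {
  if (length(cal_bp) != length(c14_age) || length(cal_bp) != length(error)) {
    abort("cal_bp, c14_age and error must have equal lengths.",
          class = "paleotrail_format_error")
  }
  if (any(error < 0)) abort("Curve errors must be non-negative.",
                            class = "paleotrail_format_error")
  o <- order(cal_bp)
  cal_bp <- cal_bp[o]
  if (any(duplicated(cal_bp))) {
    abort("Calibration curve has repeated cal BP values (non-monotone grid).",
          class = "paleotrail_format_error")
  }
  out <- tibble::tibble(cal_bp = cal_bp, c14_age = c14_age[o], error = error[o])
  class(out) <- c("cal_curve", class(out))
  out
}

#' Generate a synthetic calibration curve
#'
#' Builds a curve whose mean is the identity (`mu(t) = t`) plus smooth,
#' seeded, zero-mean sinusoidal wiggles — monotone on average, emulating
#' the wiggly but increasing shape of real atmospheric curves — with a
#' constant 1-sigma curve error.
#'
#' @param t_min,t_max Curve support, cal BP (`t_min < t_max`).
#' @param step Grid spacing, cal yr (default 10, matching the resolution
#'   of published curves in this age range).
#' @param wiggle_amplitude Amplitude of the wiggles, 14C yr. Zero gives
#'   the exact identity curve.
#' @param curve_error Constant curve error, 14C yr.
#' @param seed Integer seed (controls wiggle phases and wavelengths).
#' @return A `cal_curve`.
#' @export
make_calcurve <- function(t_min, t_max, step = 10, wiggle_amplitude = 50,
                          curve_error = 20, seed = 1L) {
  if (t_min >= t_max) abort("`t_min` must be < `t_max`.",
                            class = "paleotrail_config_error")
  t <- seq(t_min, t_max, by = step)
  wig <- 0
  if (wiggle_amplitude > 0) {
    wig <- with_seed(seed, {
      wavelength <- runif(3, 500, 3000)
      phase <- runif(3, 0, 2 * pi)
      weight <- c(1, 0.5, 0.25)
      Reduce(`+`, purrr::map(1:3, function(i) {
        weight[i] * sin(2 * pi * t / wavelength[i] + phase[i])
      })) * wiggle_amplitude / sum(weight)
    })
  }
  cal_curve(t, t + wig, rep(curve_error, length(t)))
}

#' Read a calibration curve in IntCal text format
#'
#' Parses the standard IntCal dialect: header/comment lines starting with
#' `#`, then comma- or whitespace-separated rows whose first three columns
#' are calendar age (cal BP), 14C age, and 1-sigma curve error. Both
#' ascending and descending cal BP orderings are accepted (published
#' curves list the oldest age first); the curve is stored ascending.
#'
#' @param path Curve file path.
#' @return A `cal_curve`.
#' @export
read_calcurve <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(body_idx)) {
    abort(sprintf("No data rows found in curve file '%s'.", path),
          class = "paleotrail_parse_error")
  }
  rows <- purrr::map(body_idx, function(i) {
    parts <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 3 || anyNA(vals[1:3])) {
      abort(sprintf("Malformed curve row at line %d of '%s': %s", i, path, lines[i]),
            class = "paleotrail_parse_error")
    }
    vals[1:3]
  })
  m <- do.call(rbind, rows)
  # duplicated cal BP values are what "non-monotone" means after sorting
  cal_curve(m[, 1], m[, 2], m[, 3])
}

#' Write a calibration curve in IntCal text format
#'
#' Writes `# comment` header lines then `CAL BP, 14C age, error` rows,
#' oldest age first, comma-separated — round-trips exactly through
#' [read_calcurve()].
#'
#' @param curve A `cal_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calcurve <- function(curve, path) {
  stopifnot(inherits(curve, "cal_curve"))
  o <- order(curve$cal_bp, decreasing = TRUE)
  lines <- c(
    "# Radiocarbon calibration curve",
    "# CAL BP, 14C age, Error",
    sprintf("%.17g,%.17g,%.17g",
            curve$cal_bp[o], curve$c14_age[o], curve$error[o])
  )
  writeLines(lines, path)
  invisible(path)
}

# Interpolate a curve onto a 1-yr calendar grid over its support.
curve_on_grid <- function(curve) {
  t <- seq(min(curve$cal_bp), max(curve$cal_bp), by = 1)
  list(t = t,
       mu = approx(curve$cal_bp, curve$c14_age, t)$y,
       sig = approx(curve$cal_bp, curve$error, t)$y)
}

#' Calibrate a radiocarbon determination
#'
#' Converts a conventional radiocarbon age `age ± sigma` into a posterior
#' probability distribution over calendar age, using the standard
#' single-determination model with a uniform calendar prior: on a 1-yr
#' calendar grid over the curve's support,
#' `p(t) ∝ exp(-(age - mu(t))^2 / (2 (sigma^2 + sig_c(t)^2)))`,
#' with the measurement and curve errors combined in quadrature, then
#' normalized to unit mass.
#'
#' @param age Conventional radiocarbon age, 14C yr BP.
#' @param sigma 1-sigma measurement error, 14C yr (> 0).
#' @param curve A `cal_curve`.
#' @param lab_code Optional laboratory code carried in the result.
#' @return A `cal_density` tibble with columns `cal_bp` (1-yr grid) and
#'   `p` (probability mass per year, summing to 1).
#' @examples
#' ident <- make_calcurve(5000, 15000, wiggle_amplitude = 0, curve_error = 0)
#' post <- calibrate_date(10000, 100, ident)
#' post$cal_bp[which.max(post$p)]
#' @export
calibrate_date <- function(age, sigma, curve, lab_code = NULL) {
  stopifnot(inherits(curve, "cal_curve"))
  if (sigma <= 0) abort("`sigma` must be positive.", class = "paleotrail_config_error")
  g <- curve_on_grid(curve)
  if (age < min(g$mu) || age > max(g$mu)) {
    warn(sprintf("14C age %s lies outside the curve's 14C range [%s, %s]; the posterior may be truncated.",
                 format(age, big.mark = ","),
                 format(round(min(g$mu)), big.mark = ","),
                 format(round(max(g$mu)), big.mark = ",")))
  }
  var_tot <- sigma^2 + g$sig^2
  logp <- -(age - g$mu)^2 / (2 * var_tot)
  logp_max <- max(logp)
  if (!is.finite(logp_max)) {
    abort("Calibrated density is numerically zero everywhere: date is out of curve.",
          class = "paleotrail_out_of_curve_error")
  }
  p <- exp(logp - logp_max)
  if (!any(p > 0)) {
    abort("Calibrated density is numerically zero everywhere: date is out of curve.",
          class = "paleotrail_out_of_curve_error")
  }
  out <- tibble::tibble(cal_bp = g$t, p = p / sum(p))
  attr(out, "age") <- age
  attr(out, "sigma") <- sigma
  attr(out, "lab_code") <- lab_code
  class(out) <- c("cal_density", class(out))
  out
}

#' Highest-posterior-density intervals of a calibrated date
#'
#' Finds the smallest set of 1-yr grid points holding at least `level`
#' probability mass by descending-density threshold search, merges the
#' selected years into contiguous intervals, and rounds the endpoints
#' outward to the nearest 10 cal yr (the reporting convention for dates
#' with multi-decade errors). Multimodal densities yield several disjoint
#' intervals.
#'
#' @param density A `cal_density` (from [calibrate_date()]).
#' @param level Probability level in (0, 1), e.g. 0.683 or 0.954.
#' @param round_to Outward endpoint rounding step, cal yr; 0 disables
#'   rounding.
#' @return An `hpd_intervals` tibble with columns `level`, `older`,
#'   `younger`, `mass` (unrounded enclosed mass per interval), ordered
#'   oldest interval first.
#' @export
hpd_intervals <- function(density, level = 0.954, round_to = 10) {
  stopifnot(inherits(density, "cal_density"))
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).",
                                      class = "paleotrail_config_error")
  o <- order(density$p, decreasing = TRUE)
  cum <- cumsum(density$p[o])
  n_in <- which(cum >= level)[1]
  if (is.na(n_in)) n_in <- length(o)
  sel <- sort(o[seq_len(n_in)])
  runs <- split(sel, cumsum(c(1, diff(sel) != 1)))
  out <- purrr::map_dfr(runs, function(idx) {
    tibble::tibble(older = max(density$cal_bp[idx]),
                   younger = min(density$cal_bp[idx]),
                   mass = sum(density$p[idx]))
  })
  if (round_to > 0) {
    out$older <- ceiling(out$older / round_to) * round_to
    out$younger <- floor(out$younger / round_to) * round_to
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$older))
  out <- tibble::tibble(level = level, out)
  class(out) <- c("hpd_intervals", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.cal_density <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.cal_density <- function(x, ...) {
  mode_i <- which.max(x$p)
  cum <- cumsum(x$p)
  tibble::tibble(
    age = attr(x, "age"), sigma = attr(x, "sigma"),
    lab_code = attr(x, "lab_code") %||% NA_character_,
    mode_cal_bp = x$cal_bp[mode_i],
    median_cal_bp = x$cal_bp[which(cum >= 0.5)[1]],
    mean_cal_bp = sum(x$cal_bp * x$p)
  )
}

#' Plot a calibrated posterior with its HPD intervals
#'
#' @param object A `cal_density`.
#' @param levels HPD levels to shade.
#' @param ... Unused.
#' @return A ggplot (calendar age decreasing to the right, as
#'   conventionally drawn).
#' @exportS3Method ggplot2::autoplot
autoplot.cal_density <- function(object, levels = c(0.683, 0.954), ...) {
  ints <- purrr::map_dfr(levels, ~ hpd_intervals(object, .x, round_to = 0))
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$cal_bp, .data$p)) +
    ggplot2::geom_rect(
      data = ints, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$younger, xmax = .data$older,
                   ymin = 0, ymax = Inf, alpha = factor(.data$level)),
      fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_alpha_manual(values = setNames(c(0.35, 0.15), levels),
                                name = "HPD level") +
    ggplot2::labs(x = "Calendar age (cal BP)", y = "Probability / yr") +
    ggplot2::theme_minimal()
}

#' Write HPD intervals to CSV
#'
#' @param intervals An `hpd_intervals` tibble (possibly row-bound over
#'   several levels).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hpd_csv <- function(intervals, path) {
  readr::write_csv(tibble::as_tibble(intervals), path)
  invisible(path)
}
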