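#' Configuration for the synthetic paleoclimate generator
#'
#' Defines the grid, time window, and process parameters of the synthetic
#' glacial–interglacial climate emulator. The defaults reproduce the study
#' conditions the niche model is run under: a coarse global grid at
#' 5.75° × 3.75° resolution and 1,000-year time steps spanning the
#' MIS6–MIS3 window, ~150 to 30 ka BP (121 slices).
#'
#' Temperature at a cell is
#' `T_base + lat_gradient_T * lat + cycle_amplitude_T * sin(2 * pi * t / cycle_period) + noise`,
#' and precipitation analogously with its own baseline, gradient and
#' amplitude (clamped at zero). With the default 100-ky period the sine is
#' at its warm maximum near 125 ka BP — a stand-in for the Last
#' Interglacial (MIS5e) — and at its cold minimum near 75 ka BP (MIS4).
#'
#' @param lon_step,lat_step Grid spacing in degrees. Longitude cell centers
#'   run from -180°E, latitude centers from -90°N, inclusive.
#' @param time_start_ka,time_end_ka Window bounds in kiloyears BP;
#'   `time_start_ka` must be the older bound (the BP axis runs into the past).
#' @param time_step Time step in years (default 1,000).
#' @param T_base Global-mean baseline temperature at latitude 0, °C.
#' @param lat_gradient_T Linear temperature trend, °C per degree latitude.
#' @param cycle_amplitude_T Amplitude of the glacial–interglacial
#'   temperature cycle, °C.
#' @param cycle_period Period of the glacial cycle, years.
#' @param P_base Baseline annual precipitation, mm/yr.
#' @param lat_gradient_P Linear precipitation trend, mm/yr per degree latitude.
#' @param cycle_amplitude_P Amplitude of the precipitation cycle, mm/yr
#'   (wetter interglacials).
#' @param noise_sd_T,noise_sd_P Standard deviation of i.i.d. cell noise in
#'   °C and mm/yr respectively.
#' @param seed Integer seed; fully determines the generated field.
#'
#' @return A `climate_config` list.
#' @seealso [make_climate()]
#' @export
climate_config <- function(lon_step = 5.75, lat_step = 3.75,
                           time_start_ka = 150, time_end_ka = 30,
                           time_step = 1000,
                           T_base = 10, lat_gradient_T = -0.25,
                           cycle_amplitude_T = 4, cycle_period = 100000,
                           P_base = 600, lat_gradient_P = -2,
                           cycle_amplitude_P = 150,
                           noise_sd_T = 0.5, noise_sd_P = 30,
                           seed = 1L) {
  if (lon_step <= 0 || lat_step <= 0 || time_step <= 0) {
    abort("Grid and time steps must all be positive.", class = "paleotrail_config_error")
  }
  if (time_start_ka <= time_end_ka) {
    abort("`time_start_ka` must exceed `time_end_ka`: the BP axis runs into the past.",
          class = "paleotrail_config_error")
  }
  structure(
    list(lon_step = lon_step, lat_step = lat_step,
         time_start_ka = time_start_ka, time_end_ka = time_end_ka,
         time_step = time_step,
         T_base = T_base, lat_gradient_T = lat_gradient_T,
         cycle_amplitude_T = cycle_amplitude_T, cycle_period = cycle_period,
         P_base = P_base, lat_gradient_P = lat_gradient_P,
         cycle_amplitude_P = cycle_amplitude_P,
         noise_sd_T = noise_sd_T, noise_sd_P = noise_sd_P,
         seed = seed),
    class = "climate_config"
  )
}

#' Construct a gridded climate field
#'
#' Low-level constructor used by [make_climate()] and [read_climate_nc()].
#'
#' @param lon,lat Cell-center coordinate vectors (degrees E in
#'   \[-180, 180), degrees N).
#' @param time Time axis in calendar years BP, strictly increasing.
#' @param T,P Arrays of dimension `c(length(lon), length(lat), length(time))`
#'   holding annual-mean temperature (°C) and precipitation (mm/yr).
#' @return A `climate_field` object.
#' @export
climate_field <- function(lon, lat, time, T, P) {
  dims <- c(length(lon), length(lat), length(time))
  if (!identical(dim(T), as.integer(dims)) || !identical(dim(P), as.integer(dims))) {
    abort("T and P must be lon x lat x time arrays matching the coordinate axes.")
  }
  if (is.unsorted(time, strictly = TRUE)) {
    abort("`time` must be strictly increasing (years BP).")
  }
  structure(list(lon = lon, lat = lat, time = time, T = T, P = P),
            class = "climate_field")
}

#' Generate a synthetic glacial–interglacial climate field
#'
#' Emulates 1,000-year averages of annual-mean temperature and
#' precipitation from a long transient climate simulation: a latitudinal
#' gradient plus a sinusoidal glacial–interglacial cycle plus seeded
#' white noise, on a coarse global lon/lat grid.
#'
#' @param config A [climate_config()].
#' @return A [climate_field()] with CF-style coordinates (`lon` degrees_east,
#'   `lat` degrees_north, `time` years BP ascending).
#' @examples
#' field <- make_climate(climate_config(noise_sd_T = 0, noise_sd_P = 0))
#' dim(field$T)
#' @export
make_climate <- function(config = climate_config()) {
  stopifnot(inherits(config, "climate_config"))
  lon <- normalize_lon(-180 + config$lon_step * seq_len(ceiling(360 / config$lon_step)) - config$lon_step)
  lat <- -90 + config$lat_step * (seq_len(floor(180 / config$lat_step) + 1L) - 1L)
  time <- seq(config$time_end_ka * 1000, config$time_start_ka * 1000,
              by = config$time_step)
  nlon <- length(lon); nlat <- length(lat); nt <- length(time)

  cyc_T <- config$cycle_amplitude_T * sin(2 * pi * time / config$cycle_period)
  cyc_P <- config$cycle_amplitude_P * sin(2 * pi * time / config$cycle_period)
  base_T <- outer(rep(1, nlon), config$T_base + config$lat_gradient_T * lat)
  base_P <- outer(rep(1, nlon), config$P_base + config$lat_gradient_P * lat)

  Tarr <- outer(base_T, cyc_T, `+`)
  Parr <- outer(base_P, cyc_P, `+`)
  with_seed(config$seed, {
    if (config$noise_sd_T > 0) {
      Tarr <- Tarr + array(rnorm(length(Tarr), 0, config$noise_sd_T), dim(Tarr))
    }
    if (config$noise_sd_P > 0) {
      Parr <- Parr + array(rnorm(length(Parr), 0, config$noise_sd_P), dim(Parr))
    }
  })
  Parr[Parr < 0] <- 0
  climate_field(lon, lat, time, Tarr, Parr)
}

#' @export
print.climate_field <- function(x, ...) {
  cat(sprintf("<climate_field> %d lon x %d lat x %d time slices\n",
              length(x$lon), length(x$lat), length(x$time)))
  cat(sprintf("  lon  %.2f .. %.2f degE   lat %.2f .. %.2f degN\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  cat(sprintf("  time %s .. %s yr BP (step %s)\n",
              format(min(x$time), big.mark = ","),
              format(max(x$time), big.mark = ","),
              format(diff(x$time[1:2]), big.mark = ",")))
  cat(sprintf("  T: %.1f .. %.1f degC   P: %.0f .. %.0f mm/yr\n",
              min(x$T), max(x$T), min(x$P), max(x$P)))
  invisible(x)
}

#' Tidy a climate field into a long tibble
#'
#' @param x A `climate_field`.
#' @param ... Unused.
#' @return A tibble with columns `lon`, `lat`, `time`, `T`, `P` — one row
#'   per grid cell and time slice.
#' @exportS3Method tibble::as_tibble
as_tibble.climate_field <- function(x, ...) {
  grid <- tidyr::expand_grid(time = x$time, lat = x$lat, lon = x$lon)
  # expand_grid varies the last column fastest, matching array storage order
  # for dims (lon, lat, time).
  tibble::tibble(lon = grid$lon, lat = grid$lat, time = grid$time,
                 T = as.vector(x$T), P = as.vector(x$P))
}

#' @exportS3Method generics::tidy
tidy.climate_field <- function(x, ...) as_tibble.climate_field(x, ...)

#' Write a climate field to NetCDF
#'
#' Writes `T` and `P` on `lon`/`lat`/`time` dimensions with CF-style units
#' (`degrees_east`, `degrees_north`, `years BP`).
#'
#' @param field A [climate_field()].
#' @param path Output path (`.nc`).
#' @return `path`, invisibly.
#' @export
write_climate_nc <- function(field, path) {
  stopifnot(inherits(field, "climate_field"))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  dim_time <- ncdf4::ncdim_def("time", "years BP", field$time)
  var_T <- ncdf4::ncvar_def("T", "degC", list(dim_lon, dim_lat, dim_time),
                            missval = NA_real_, prec = "double",
                            longname = "annual mean temperature")
  var_P <- ncdf4::ncvar_def("P", "mm/yr", list(dim_lon, dim_lat, dim_time),
                            missval = NA_real_, prec = "double",
                            longname = "annual precipitation")
  nc <- ncdf4::nc_create(path, list(var_T, var_P))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, var_T, field$T)
  ncdf4::ncvar_put(nc, var_P, field$P)
  invisible(path)
}

#' Read a climate field from NetCDF
#'
#' @param path A NetCDF file with `T` and `P` variables on
#'   `lon`/`lat`/`time` dimensions, as written by [write_climate_nc()].
#' @return A [climate_field()].
#' @export
read_climate_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  climate_field(
    lon = as.vector(nc$dim$lon$vals),
    lat = as.vector(nc$dim$lat$vals),
    time = as.vector(nc$dim$time$vals),
    T = ncdf4::ncvar_get(nc, "T", collapse_degen = FALSE),
    P = ncdf4::ncvar_get(nc, "P", collapse_degen = FALSE)
  )
}

#' Map one time slice of a climate field
#'
#' @param object A `climate_field`.
#' @param time_bp Time slice to plot, years BP (nearest slice is used).
#' @param variable `"T"` or `"P"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.climate_field <- function(object, time_bp = max(object$time),
                                   variable = c("T", "P"), ...) {
  variable <- match.arg(variable)
  k <- which.min(abs(object$time - time_bp))
  df <- tidyr::expand_grid(lat = object$lat, lon = object$lon)
  df <- tibble::tibble(lon = df$lon, lat = df$lat,
                       value = as.vector(object[[variable]][, , k]))
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (variable == "T") "T (degC)" else "P (mm/yr)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude (degE)", y = "Latitude (degN)",
                  title = sprintf("%s at %s yr BP", variable,
                                  format(object$time[k], big.mark = ","))) +
    ggplot2::theme_minimal()
}
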