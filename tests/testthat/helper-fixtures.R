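# Shared small fixtures, built in code.

# Deterministic flat climate: no gradient, no cycle, no noise.
flat_climate <- function(value_T = 5, value_P = 500) {
  make_climate(climate_config(
    T_base = value_T, lat_gradient_T = 0, cycle_amplitude_T = 0,
    P_base = value_P, lat_gradient_P = 0, cycle_amplitude_P = 0,
    noise_sd_T = 0, noise_sd_P = 0))
}

# Coarse noisy climate centred on (T0, P0): climate availability is
# symmetric around the envelope truth used in recovery tests.
noisy_flat_climate <- function(T0 = 0, P0 = 800, seed = 42L,
                               noise_sd_T = 6, noise_sd_P = 150) {
  make_climate(climate_config(
    T_base = T0, lat_gradient_T = 0, cycle_amplitude_T = 0,
    P_base = P0, lat_gradient_P = 0, cycle_amplitude_P = 0,
    noise_sd_T = noise_sd_T, noise_sd_P = noise_sd_P, seed = seed))
}

# Hand-built tiny climate field with explicit values.
toy_field <- function() {
  lon <- c(0, 10); lat <- c(40, 50); time <- c(1000, 2000)
  Tv <- array(seq(1, 8), c(2, 2, 2))
  Pv <- array(seq(101, 108), c(2, 2, 2))
  climate_field(lon, lat, time, Tv, Pv)
}

# A density object on a 1-yr grid from arbitrary unnormalized weights.
manual_density <- function(cal_bp, w) {
  out <- tibble::tibble(cal_bp = cal_bp, p = w / sum(w))
  class(out) <- c("cal_density", class(out))
  out
}

# Independent HPD oracle: highest-density region by threshold scan over
# all observed density values (no cumulative-sort shortcut).
hpd_oracle <- function(cal_bp, p, level) {
  thresholds <- sort(unique(p), decreasing = TRUE)
  for (thr in thresholds) {
    sel <- which(p >= thr)
    if (sum(p[sel]) >= level) {
      runs <- split(sel, cumsum(c(1, diff(sel) != 1)))
      return(lapply(runs, function(idx) range(cal_bp[idx])))
    }
  }
  list(range(cal_bp))
}
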