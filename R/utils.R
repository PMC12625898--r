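# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed; NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive one independent stream seed per ensemble member from a master seed.
# Drawing the whole vector up-front makes member m's stream a function of
# (master, m) only, so any scheduling of members yields identical results.
derive_stream_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Normalize longitudes to [-180, 180); cell-center convention everywhere.
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

# Smallest angular separation between two longitudes, in degrees.
lon_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Bivariate normal density; mu length-2, sigma 2x2 SPD.
dmvnorm2 <- function(x, mu, sigma) {
  x <- matrix(x, ncol = 2L)
  si <- solve(sigma)
  dx <- sweep(x, 2L, mu)
  q <- si[1, 1] * dx[, 1]^2 + 2 * si[1, 2] * dx[, 1] * dx[, 2] + si[2, 2] * dx[, 2]^2
  exp(-q / 2) / (2 * pi * sqrt(det(sigma)))
}

# Mahalanobis quadratic form for n x 2 points against (mu, sigma_inv).
maha_quad <- function(x, mu, sigma_inv) {
  x <- matrix(x, ncol = 2L)
  d1 <- x[, 1] - mu[1]
  d2 <- x[, 2] - mu[2]
  sigma_inv[1, 1] * d1^2 + 2 * sigma_inv[1, 2] * d1 * d2 + sigma_inv[2, 2] * d2^2
}

path_extdata <- function(...) {
  system.file("extdata", ..., package = "paleotrail", mustWork = TRUE)
}
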