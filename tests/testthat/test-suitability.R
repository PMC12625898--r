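test_that("climate extraction picks the nearest cell, wrapping the dateline", {
  f <- toy_field()
  # exact cell center and slice time
  at <- extract_climate(tibble::tibble(latitude = 50, longitude = 10, age = 2000), f)
  expect_equal(at$T, f$T[2, 2, 2])
  expect_equal(at$P, f$P[2, 2, 2])
  # hand-picked nearest neighbour on the toy grid
  near <- extract_climate(tibble::tibble(latitude = 43, longitude = 6, age = 1400), f)
  expect_equal(near$T, f$T[2, 1, 1])

  g <- make_climate(climate_config(noise_sd_T = 0, noise_sd_P = 0))
  # 179.9 degE wraps to the -180 column, 0.1 deg away across the dateline
  wrap <- extract_climate(tibble::tibble(latitude = 0, longitude = 179.9,
                                         age = 50000), g)
  expect_equal(wrap$cell_lon, 1L)
  expect_error(
    extract_climate(tibble::tibble(latitude = 95, longitude = 0, age = 50000), g),
    class = "paleotrail_domain_error")
  expect_warning(
    clamped <- extract_climate(tibble::tibble(latitude = 0, longitude = 0,
                                              age = 10), g),
    regexp = "clamped")
  expect_equal(clamped$cell_time, 1L)
})

test_that("ensemble members are balanced draws with uniform ages in bounds", {
  recs <- study_fossil_records()
  boxes <- study_region_boxes()
  withr::with_seed(5, {
    m <- sample_ensemble_member(recs, boxes, k_per_box = 2)
    expect_equal(nrow(m), 6)  # 3 boxes x 2
    expect_equal(as.vector(table(m$location)[boxes$label]), c(2, 2, 2))
    expect_true(all(m$drawn_age >= m$younger_age & m$drawn_age <= m$older_age))
    # Box 2 holds exactly two records: both always selected
    for (i in 1:20) {
      m2 <- sample_ensemble_member(recs, boxes, 2)
      expect_setequal(m2$specimen[m2$location == "Box 2"],
                      c("Star 1", "Mezmaiskaya 2"))
    }
    expect_error(sample_ensemble_member(recs, boxes, 3),
                 regexp = "Box 2", class = "paleotrail_sampling_error")
  })
})

test_that("drawn ages follow the uniform law over the bracket", {
  one <- suppressWarnings(as_fossil_records(tibble::tibble(
    specimen = "x", latitude = 45, longitude = 20,
    min_age = 50000, max_age = 40000, location = "B", method = "t")))
  box <- region_box("B", 10, 30, 40, 50)
  draws <- withr::with_seed(77, {
    replicate(1000, sample_ensemble_member(one, box, 1)$drawn_age)
  })
  expect_true(all(draws >= 40000 & draws <= 50000))
  expect_equal(mean(draws), 45000, tolerance = 0.005)
  expect_equal(var(draws), 10000^2 / 12, tolerance = 0.1)
})

test_that("envelope fitting matches hand computation and flags degeneracy", {
  C <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  env <- fit_envelope(C)
  expect_equal(unname(env$mean), c(1, 1))
  expect_equal(unname(env$sigma), diag(c(4 / 3, 4 / 3)))
  expect_equal(unname(env$sigma_inv), diag(c(3 / 4, 3 / 4)))
  expect_false(env$regularized)

  expect_error(fit_envelope(C[1:2, ]),
               class = "paleotrail_insufficient_sample_error")
  expect_warning(degen <- fit_envelope(rbind(c(1, 2), c(1, 2), c(1, 2))),
                 regexp = "regularized")
  expect_true(degen$regularized)
  expect_true(all(is.finite(degen$sigma_inv)))
})

test_that("envelope estimates converge to the generating parameters", {
  withr::with_seed(10, {
    mu <- c(2, 700); sds <- c(3, 120); rho <- 0.4
    S <- diag(sds) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sds)
    L <- chol(S)
    C <- matrix(rnorm(2 * 10000), ncol = 2) %*% L + rep(mu, each = 10000)
    env <- fit_envelope(C)
    se_mean <- sds / sqrt(10000)
    expect_lt(abs(env$mean[1] - mu[1]), 3 * se_mean[1])
    expect_lt(abs(env$mean[2] - mu[2]), 3 * se_mean[2])
    expect_equal(unname(env$sigma), unname(S), tolerance = 0.1)
  })
})

test_that("suitability obeys the closed form and its bounds", {
  f <- toy_field()
  env <- list(mean = c(0, 0), sigma_inv = diag(2))
  f$T[] <- 1; f$P[] <- 1
  s <- suitability_map(env, f)
  expect_equal(as.vector(s$s), rep(exp(-2), 8), tolerance = 1e-12)
  sr <- suitability_map(env, f, distance_mode = "root")
  expect_equal(as.vector(sr$s), rep(exp(-sqrt(2)), 8), tolerance = 1e-12)

  # s = 1 exactly at the envelope mean, in (0, 1] elsewhere
  g <- noisy_flat_climate(seed = 14)
  envg <- fit_envelope(cbind(T = c(0, 1, -1, 2), P = c(800, 700, 900, 820)))
  sg <- suitability_map(envg, g)
  expect_true(all(sg$s > 0 & sg$s <= 1))
  f2 <- toy_field(); f2$T[] <- envg$mean[1]; f2$P[] <- envg$mean[2]
  expect_equal(as.vector(suitability_map(envg, f2)$s), rep(1, 8))
})

test_that("with identity inverse covariance the distance is squared Euclidean", {
  withr::with_seed(8, {
    f <- toy_field()
    f$T[] <- rnorm(8, 0, 2); f$P[] <- rnorm(8, 0, 2)
    mu <- c(0.5, -0.3)
    s <- suitability_map(list(mean = mu, sigma_inv = diag(2)), f)
    sq_euclid <- (as.vector(f$T) - mu[1])^2 + (as.vector(f$P) - mu[2])^2
    expect_equal(as.vector(s$s), exp(-sq_euclid), tolerance = 1e-12)
  })
})

test_that("Mahalanobis distance is invariant under invertible affine maps", {
  withr::with_seed(30, {
    C <- cbind(rnorm(40, 5, 2), rnorm(40, 600, 90))
    f <- toy_field()
    f$T[] <- rnorm(8, 5, 2); f$P[] <- rnorm(8, 600, 90)
    env <- fit_envelope(C)
    d0 <- -log(suitability_map(env, f)$s)
    for (i in 1:5) {
      A <- matrix(rnorm(4), 2)
      while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2)
      b <- rnorm(2)
      Ct <- C %*% t(A) + rep(b, each = nrow(C))
      ft <- f
      ft$T[] <- A[1, 1] * as.vector(f$T) + A[1, 2] * as.vector(f$P) + b[1]
      ft$P[] <- A[2, 1] * as.vector(f$T) + A[2, 2] * as.vector(f$P) + b[2]
      dt <- -log(suitability_map(fit_envelope(Ct), ft)$s)
      expect_equal(as.vector(dt), as.vector(d0), tolerance = 1e-8)
    }
  })
})

test_that("the Monte Carlo ensemble is deterministic and balanced", {
  f <- noisy_flat_climate()
  recs <- study_fossil_records()
  boxes <- study_region_boxes()
  e1 <- run_monte_carlo(recs, boxes, 2, f, n_members = 3, seed = 42)
  e2 <- run_monte_carlo(recs, boxes, 2, f, n_members = 3, seed = 42)
  expect_identical(e1$mean_s, e2$mean_s)
  expect_identical(e1$box_series, e2$box_series)
  expect_equal(e1$n_failed, 0)
  expect_true(all(e1$mean_s > 0 & e1$mean_s <= 1))
  e3 <- run_monte_carlo(recs, boxes, 2, f, n_members = 3, seed = 43)
  expect_false(identical(e1$mean_s, e3$mean_s))
})

test_that("member stream seeds make draws identical to sequential sampling", {
  f <- noisy_flat_climate()
  recs <- study_fossil_records()
  boxes <- study_region_boxes()
  ens <- run_monte_carlo(recs, boxes, 2, f, n_members = 4, seed = 9,
                         keep_members = TRUE)
  seeds <- paleotrail:::derive_stream_seeds(9, 4)
  for (m in 1:4) {
    member <- withr::with_seed(seeds[m], sample_ensemble_member(recs, boxes, 2))
    cl <- extract_climate(
      tibble::tibble(latitude = member$latitude, longitude = member$longitude,
                     age = member$drawn_age), f)
    env <- fit_envelope(cbind(T = cl$T, P = cl$P))
    s <- suitability_map(env, f)
    expect_equal(ens$members[[m]], s$s, tolerance = 1e-12)
  }
})

test_that("box time series average the right cells, members and ensemble mean", {
  f <- toy_field()
  recs <- suppressWarnings(as_fossil_records(tibble::tibble(
    specimen = c("a", "b", "c"), latitude = c(42, 48, 51),
    longitude = c(2, 8, 9), min_age = c(1900, 1800, 2000),
    max_age = c(1100, 1200, 1500), location = "B", method = "t")))
  box <- region_box("B", -5, 15, 35, 55)
  # 3 records on a 2x2x2 toy grid: degenerate member covariances are
  # expected and regularized; this test targets the series averaging.
  ens <- suppressWarnings(run_monte_carlo(recs, box, 3, f, n_members = 5, seed = 1,
                                          keep_members = TRUE))
  ts <- box_timeseries(ens, "B")
  # ensemble-mean series equals the member-mean at every slice
  mean_series <- ts[ts$member == 0, ]
  member_series <- ts[ts$member > 0, ]
  agg <- dplyr::summarise(dplyr::group_by(member_series, time),
                          s = mean(suitability))
  expect_equal(mean_series$suitability, agg$s)
  # and equals the unweighted cell mean of the stored grids
  m1 <- ens$members[[1]]
  expect_equal(member_series$suitability[member_series$member == 1],
               c(mean(m1[, , 1]), mean(m1[, , 2])))

  # spatially uniform suitability gives a constant series
  u <- ens
  u$mean_s[] <- 0.4
  u$box_series$suitability <- 0.4
  tsu <- box_timeseries(u, "B")
  expect_true(all(tsu$suitability == 0.4))

  # a box covering only two known cells averages exactly those cells
  half_box <- region_box("half", -5, 5, 35, 55)  # lon 0 column only
  ens2 <- suppressWarnings(run_monte_carlo(recs, box, 3, f, n_members = 2, seed = 2,
                                           series_boxes = dplyr::bind_rows(box, half_box),
                                           keep_members = TRUE))
  ts_half <- box_timeseries(ens2, "half")
  m <- ens2$members[[1]]
  expect_equal(ts_half$suitability[ts_half$member == 1],
               c(mean(m[1, , 1]), mean(m[1, , 2])))

  expect_error(box_timeseries(ens, region_box("off", 100, 120, 60, 70)),
               class = "paleotrail_domain_error")
})

test_that("suitability peaks inside warm phases when samples come from them", {
  # climate with a glacial cycle; occurrences drawn from warm-phase climate
  cfg <- climate_config(noise_sd_T = 0.3, noise_sd_P = 20, seed = 4)
  f <- make_climate(cfg)
  boxes <- study_region_boxes()
  # warm-phase climate near the box latitudes: baseline minus gradient plus
  # positive cycle amplitude
  warm_T <- 10 - 0.25 * 48 + 3
  truth <- envelope_truth(warm_T, 600 - 2 * 48 + 110, diag(c(1, 900)))
  occ <- make_occurrences(f, truth, boxes, n_per_box = 8,
                          age_uncertainty = 3000, seed = 6)
  ens <- run_monte_carlo(occ, boxes, 4, f, n_members = 30, seed = 3)
  warm <- sin(2 * pi * ens$time / cfg$cycle_period) > 0
  for (lab in boxes$label) {
    ts <- box_timeseries(ens, lab)
    m <- ts[ts$member == 0, ]
    expect_true(warm[which.max(m$suitability)],
                label = sprintf("peak of %s in warm phase", lab))
  }
})

test_that("ensembles fail loudly when too many members are degenerate", {
  f <- flat_climate()  # constant climate: every envelope fit is singular
  recs <- study_fossil_records()
  boxes <- study_region_boxes()
  # constant field -> zero covariance -> regularized but not failed
  expect_warning(ens <- run_monte_carlo(recs, boxes, 2, f, n_members = 2, seed = 1),
                 regexp = "regularized")
  expect_equal(ens$n_failed, 0)
})

test_that("suitability grids write to NetCDF and read back", {
  f <- noisy_flat_climate()
  ens <- run_monte_carlo(study_fossil_records(), study_region_boxes(), 2, f,
                         n_members = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".nc")
  write_suitability_nc(ens, path)
  nc <- ncdf4::nc_open(path)
  vals <- ncdf4::ncvar_get(nc, "suitability", collapse_degen = FALSE)
  ncdf4::nc_close(nc)
  expect_equal(vals, ens$mean_s, ignore_attr = TRUE, tolerance = 1e-12)
})
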