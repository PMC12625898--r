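identity_curve <- function(t_min = 5000, t_max = 15000) {
  make_calcurve(t_min, t_max, wiggle_amplitude = 0, curve_error = 0)
}

test_that("synthetic curves are identity when unwiggled and reproducible", {
  ident <- identity_curve()
  expect_equal(ident$c14_age, ident$cal_bp)
  a <- make_calcurve(1000, 2000, wiggle_amplitude = 40, seed = 5)
  expect_identical(a, make_calcurve(1000, 2000, wiggle_amplitude = 40, seed = 5))
  expect_error(make_calcurve(2000, 1000), class = "paleotrail_config_error")
})

test_that("curves round-trip bit-exactly through the text format", {
  curve <- make_calcurve(40000, 50000, wiggle_amplitude = 60, curve_error = 25,
                         seed = 7)
  path <- withr::local_tempfile(fileext = ".14c")
  write_calcurve(curve, path)
  back <- read_calcurve(path)
  expect_identical(back$cal_bp, curve$cal_bp)
  expect_identical(back$c14_age, curve$c14_age)
  expect_identical(back$error, curve$error)
})

test_that("the curve parser handles dialects and rejects malformed input", {
  # whitespace-separated with header comments
  path <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# header", "# CAL BP, 14C age, error",
               "3000 3100 20", "2000 2050 15", "1000 990 10"), path)
  curve <- read_calcurve(path)
  expect_equal(curve$cal_bp, c(1000, 2000, 3000))
  # linear interpolation at the midpoint of a 3-row toy curve
  g <- paleotrail:::curve_on_grid(curve)
  expect_equal(g$mu[g$t == 1500], (990 + 2050) / 2)
  expect_equal(g$mu[g$t == 2500], (2050 + 3100) / 2)

  empty <- withr::local_tempfile(fileext = ".14c")
  writeLines("# only comments", empty)
  expect_error(read_calcurve(empty), class = "paleotrail_parse_error")

  bad <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("1000,990,10", "2000,abc,15"), bad)
  expect_error(read_calcurve(bad), regexp = "line 2", class = "paleotrail_parse_error")

  dup <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("1000,990,10", "1000,995,10"), dup)
  expect_error(read_calcurve(dup), class = "paleotrail_format_error")
})

test_that("identity-curve posterior is the sampling Gaussian", {
  post <- calibrate_date(10000, 100, identity_curve())
  expect_equal(post$cal_bp[which.max(post$p)], 10000)
  expect_equal(sum(post$p), 1, tolerance = 1e-9)
  # mass within +-1 sigma of a Gaussian
  in_1s <- sum(post$p[post$cal_bp >= 9900 & post$cal_bp <= 10100])
  expect_equal(in_1s, 0.683, tolerance = 0.005)
  # total-variation distance against the closed form
  gauss <- dnorm(post$cal_bp, 10000, 100)
  gauss <- gauss / sum(gauss)
  expect_lt(0.5 * sum(abs(post$p - gauss)), 1e-6)
})

test_that("curve error adds in quadrature to the measurement error", {
  curve <- make_calcurve(5000, 15000, wiggle_amplitude = 0, curve_error = 60)
  post <- calibrate_date(10000, 80, curve)
  gauss <- dnorm(post$cal_bp, 10000, sqrt(80^2 + 60^2))
  gauss <- gauss / sum(gauss)
  expect_lt(0.5 * sum(abs(post$p - gauss)), 1e-6)
})

test_that("shifting the curve shifts the posterior mode exactly", {
  base <- make_calcurve(5000, 15000, wiggle_amplitude = 80, curve_error = 20,
                        seed = 13)
  shifted <- cal_curve(base$cal_bp + 500, base$c14_age + 500, base$error)
  p0 <- calibrate_date(9000, 120, base)
  p1 <- calibrate_date(9000 + 500, 120, shifted)
  expect_equal(p1$cal_bp[which.max(p1$p)], p0$cal_bp[which.max(p0$p)] + 500)
})

test_that("out-of-range ages warn", {
  expect_warning(calibrate_date(40000, 100, identity_curve(5000, 15000)),
                 regexp = "outside")
  expect_error(calibrate_date(10000, 0, identity_curve()),
               class = "paleotrail_config_error")
})

test_that("HPD intervals of a Gaussian posterior sit at 1 and 2 sigma", {
  post <- calibrate_date(10000, 100, identity_curve())
  h68 <- hpd_intervals(post, 0.683, round_to = 0)
  expect_equal(nrow(h68), 1)
  expect_equal(h68$older, 10100, tolerance = 0.0005)
  expect_equal(h68$younger, 9900, tolerance = 0.0005)
  h95 <- hpd_intervals(post, 0.954, round_to = 0)
  expect_equal(h95$older, 10200, tolerance = 0.0005)
  expect_equal(h95$younger, 9800, tolerance = 0.0005)
  expect_gte(sum(h95$mass), 0.954)
})

test_that("HPD sets are nested and endpoints round outward to 10 years", {
  post <- calibrate_date(9975, 87, identity_curve())
  h68 <- hpd_intervals(post, 0.683)
  h95 <- hpd_intervals(post, 0.954)
  expect_lte(h68$older, h95$older)
  expect_gte(h68$younger, h95$younger)
  expect_true(all(c(h68$older, h68$younger, h95$older, h95$younger) %% 10 == 0))
  # rounding is outward: the rounded interval contains the unrounded one
  raw <- hpd_intervals(post, 0.683, round_to = 0)
  expect_gte(h68$older, raw$older)
  expect_lte(h68$younger, raw$younger)
})

test_that("a bimodal density yields two disjoint intervals matching a threshold-scan oracle", {
  t <- seq(1000, 9000, by = 1)
  w <- dnorm(t, 3000, 150) + 0.8 * dnorm(t, 7000, 120)
  dens <- manual_density(t, w)
  h <- hpd_intervals(dens, 0.90, round_to = 0)
  expect_equal(nrow(h), 2)
  # disjoint: each interval's younger bound is older than the next older bound
  expect_true(all(head(h$younger, -1) > tail(h$older, -1)))
  oracle <- hpd_oracle(t, dens$p, 0.90)
  oracle_df <- do.call(rbind, lapply(oracle, function(r) data.frame(lo = r[1], hi = r[2])))
  oracle_df <- oracle_df[order(-oracle_df$hi), ]
  expect_equal(h$older, oracle_df$hi, tolerance = 2)
  expect_equal(h$younger, oracle_df$lo, tolerance = 2)
})

test_that("tidy and glance expose the posterior summaries", {
  post <- calibrate_date(10000, 100, identity_curve(), lab_code = "LAB-1")
  g <- glance(post)
  expect_equal(g$lab_code, "LAB-1")
  expect_equal(g$mode_cal_bp, 10000)
  expect_equal(g$mean_cal_bp, 10000, tolerance = 0.5)
  expect_s3_class(tidy(post), "tbl_df")
})
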