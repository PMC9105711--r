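test_that("radiometric calibration is the stated affine map", {
  expect_equal(dn_to_radiance(100, gain = 0.1, offset = 1, tdi_stage = 2), 6)
  expect_equal(dn_to_radiance(matrix(7, 2, 2), gain = 0, offset = 3),
               matrix(3, 2, 2))
  expect_equal(dn_to_radiance(0, gain = 2, offset = 0), 0)
  expect_error(dn_to_radiance(1, 1, 1, tdi_stage = 0), ">= 1")
})

test_that("band-window maximum selects exactly the in-window bands", {
  wl <- c(500, 530, 550, 570)
  cube <- array(0, c(2, 2, 4))
  cube[, , 1] <- 0.9   # out of window: must be ignored
  cube[, , 2] <- 0.10
  cube[, , 3] <- 0.12
  cube[, , 4] <- 0.8
  attr(cube, "wavelengths") <- wl
  got <- band_window_max(cube)
  # brute-force per-pixel oracle over the two in-window bands
  expect_equal(got, pmax(cube[, , 2], cube[, , 3]))
  # nodata propagates
  cube[1, 1, 2] <- NA
  attr(cube, "wavelengths") <- wl
  expect_true(is.na(band_window_max(cube)[1, 1]))
  expect_error(band_window_max(cube, lo_nm = 600, hi_nm = 650), "available")
})

test_that("the empirical retrieval line reproduces its worked values", {
  expect_equal(retrieve_agb(0)$equation_value, 4.8574)
  r <- retrieve_agb(0.1)
  expect_equal(r$equation_value, 3.2715)
  expect_equal(r$agb, 3271.5)
  # root of the line retrieves zero biomass
  expect_equal(retrieve_agb(4.8574 / 15.859)$agb, 0, tolerance = 1e-9)
  # bright pixels clamp at zero and are counted
  r <- retrieve_agb(c(0.1, 0.4, 0.5))
  expect_equal(r$agb[2:3], c(0, 0))
  expect_equal(r$n_clamped, 2)
  expect_true(r$equation_value[2] < 0)   # raw value keeps the sign
  # affine and strictly decreasing before clamping
  x <- seq(0, 0.3, by = 0.05)
  ev <- retrieve_agb(x)$equation_value
  expect_equal(diff(ev), rep(-15.859 * 0.05, length(x) - 1))
})

test_that("zonal statistics use sample sd and interpolated quartiles", {
  r <- matrix(c(1, 2, 3, 4, 9, 9), 2, 3)
  mask <- matrix(c(1, 1, 1, 1, 2, 2), 2, 3)
  z <- zonal_stats(r, mask, 1)
  expect_equal(z$mean, 2.5)
  expect_equal(z$sd, sd(1:4))
  expect_equal(z$q25, 1.75)
  expect_equal(z$q75, 3.25)
  expect_equal(z$n, 4)
  # constant class
  z2 <- zonal_stats(r, mask, 2)
  expect_equal(z2$sd, 0)
  expect_equal(z2$q25, z2$q75)
  # order invariance under pixel permutation
  set.seed(1)
  v <- runif(24)
  perm <- sample(24)
  za <- zonal_stats(matrix(v, 4, 6), matrix(1L, 4, 6), 1)
  zb <- zonal_stats(matrix(v[perm], 4, 6), matrix(1L, 4, 6), 1)
  expect_equal(za[c("mean", "sd", "q25", "q75")],
               zb[c("mean", "sd", "q25", "q75")])
  expect_error(zonal_stats(r, mask, 99), "no unmasked pixel")
})

test_that("separability metrics match the 1-D closed form and stay in [0,2]", {
  set.seed(42)
  a <- matrix(rnorm(400, 0, 1), ncol = 1)
  b <- matrix(rnorm(400, 3, 2), ncol = 1)
  got <- sample_separability(a, b)
  s1 <- var(a)[1]
  s2 <- var(b)[1]
  d <- mean(a) - mean(b)
  B <- d^2 / (4 * (s1 + s2)) + 0.5 * log((s1 + s2) / (2 * sqrt(s1 * s2)))
  expect_equal(got$bhattacharyya, B, tolerance = 1e-9)
  expect_equal(got$jm, 2 * (1 - exp(-B)), tolerance = 1e-9)
  # identical classes are inseparable
  same <- sample_separability(a, a)
  expect_equal(same$jm, 0, tolerance = 1e-9)
  expect_equal(same$td, 0, tolerance = 1e-9)
  # widely separated tight classes saturate toward 2
  far <- sample_separability(matrix(rnorm(100, 0, 0.01), ncol = 1),
                             matrix(rnorm(100, 10, 0.01), ncol = 1))
  expect_gt(far$jm, 1.99)
  expect_gt(far$td, 1.99)
  # bounds hold across random multivariate draws
  for (i in 1:15) {
    x <- matrix(rnorm(60, 0, runif(1, 0.5, 2)), ncol = 3)
    y <- matrix(rnorm(60, runif(1, -2, 2), runif(1, 0.5, 2)), ncol = 3)
    m <- sample_separability(x, y)
    expect_true(m$jm >= 0 && m$jm <= 2)
    expect_true(m$td >= 0 && m$td <= 2)
  }
  expect_error(sample_separability(a[1, , drop = FALSE], b), "2 samples")
})

test_that("confusion metrics reproduce the standard worked cases", {
  d <- confusion_metrics(diag(c(10, 20, 30)))
  expect_equal(d$oa, 1)
  expect_equal(d$kappa, 1)
  expect_equal(unname(d$pa), rep(1, 3))
  expect_equal(unname(d$ua), rep(1, 3))
  m <- confusion_metrics(matrix(c(40, 10, 10, 40), 2, byrow = TRUE))
  expect_equal(m$oa, 0.8)
  expect_equal(m$kappa, 0.6)
  # uniform counts carry only chance agreement
  u <- confusion_metrics(matrix(5, 3, 3))
  expect_equal(u$kappa, 0, tolerance = 1e-12)
  expect_error(confusion_metrics(matrix(0, 2, 2)), "no observations")
  expect_error(confusion_metrics(matrix(1, 2, 3)), "square")
})
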