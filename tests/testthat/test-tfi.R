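test_that("dispersion lookup reproduces the anchor and table nodes", {
  expect_equal(as.numeric(refractive_index_ice(550, 109)), 1.28,
               tolerance = 1e-5)
  # query at table nodes is the interpolation identity
  tab <- utils::read.csv(system.file("extdata",
                                     "asw_refractive_index_synthetic.csv",
                                     package = "lamellometer"))
  pick <- tab[c(3, 40, 100), ]
  got <- refractive_index_ice(pick$wavelength_nm, pick$temperature_K)
  expect_equal(as.numeric(got), pick$n2, tolerance = 1e-12)
  # interpolated values stay within the table range
  lam <- seq(401, 699, by = 7)
  n <- as.numeric(refractive_index_ice(lam, 112))
  expect_true(all(n >= min(tab$n2) & n <= max(tab$n2)))
  expect_true(all(diff(n) < 0))  # normal dispersion: n falls with lambda
})

test_that("out-of-range dispersion queries are clamped and flagged", {
  expect_warning(n <- refractive_index_ice(c(550, 900), 109), "clamped")
  expect_identical(attr(n, "extrapolated"), c(FALSE, TRUE))
})

test_that("reflectivity has the destructive-interference value at d = 0", {
  for (env in c("exponential", "gaussian")) {
    p <- tfi_params(r_mea = 1.3, r_A = 0.4, envelope = env)
    expect_equal(reflectivity(0, p), 1.3 - 0.4)
  }
})

test_that("first cosine maximum sits at a quarter wavelength in the film", {
  p <- default_tfi()
  d_qw <- p$wavelength_nm / (4 * p$n2)  # phase 4*pi*d*n2/lambda = pi
  # the cosine factor alone is maximal there: verify on a dense scan of
  # the undamped model (envelope disabled via huge L)
  p_flat <- tfi_params(wavelength_nm = p$wavelength_nm, n2 = p$n2,
                       L_nm = 1e12)
  d <- seq(0, 200, by = 0.01)
  r <- reflectivity(d, p_flat)
  expect_equal(d[which.max(r)], d_qw, tolerance = 0.02)
})

test_that("successive extrema are spaced by lambda / (2 n2)", {
  p <- default_tfi()
  d <- seq(200, 1600, by = 0.01)
  r <- reflectivity(d, p)
  peaks <- which(diff(sign(diff(r))) < 0) + 1L
  spacing <- diff(d[peaks])
  expect_equal(mean(spacing), tfi_period(p), tolerance = 0.5 / 180)
  expect_true(all(abs(spacing - tfi_period(p)) < 0.5))
  expect_equal(tfi_period(p), 463 / (2 * p$n2))
})

test_that("trace fitting recovers a known thickness offset", {
  p <- default_tfi()
  tt <- seq(0, 900, by = 5)
  d_true <- 390 + 2.4 * (max(tt) - tt)
  intensity <- reflectivity(d_true, p)

  # noiseless: global search recovers the offset to grid resolution
  f0 <- fit_trace(intensity, tt, 2.4, p, c(0, 2000))
  expect_equal(f0$offset_nm, 390, tolerance = 0.5)
  expect_equal(f0$d_nm, d_true, tolerance = 0.5)

  # 2% of r_A noise: recovery within +-10 nm on the branch anchored by
  # the geometric estimate
  set.seed(9)
  noisy <- intensity + rnorm(length(intensity), sd = 0.02 * p$r_A)
  f1 <- fit_trace(noisy, tt, 2.4, p, c(330, 450))
  expect_equal(f1$offset_nm, 390, tolerance = 10)
})

test_that("trace fitting is invariant to affine intensity transforms", {
  p <- default_tfi()
  tt <- seq(0, 400, by = 4)
  set.seed(2)
  intensity <- reflectivity(150 + 2.4 * (max(tt) - tt), p) +
    rnorm(length(tt), sd = 0.005)
  f1 <- fit_trace(intensity, tt, 2.4, p, c(50, 350))
  f2 <- fit_trace(7 * intensity + 3, tt, 2.4, p, c(50, 350))
  expect_equal(f1$offset_nm, f2$offset_nm, tolerance = 1e-6)
})

test_that("under-sampled or constant traces raise ambiguous-offset errors", {
  p <- default_tfi()
  tt <- seq(0, 30, by = 5)  # 72 nm of milling < one 181 nm period
  expect_error(fit_trace(rep(1, 7), tt, 2.4, p), "ambiguous")
  tt2 <- seq(0, 900, by = 100)
  expect_error(fit_trace(rep(1, 10), tt2, 2.4, p), "constant intensity")
})

test_that("map fitting is exact on noiseless self-consistent input", {
  p <- default_tfi()
  d_true <- matrix(seq(150, 260, length.out = 32), 32, 24)
  P <- tfi_period(p)
  # per-pixel envelope over the searched branch, as a milling series
  # would provide
  lo <- hi <- d_true
  for (i in seq_along(d_true)) {
    rr <- range(reflectivity(
      pmax(seq(d_true[i] - P / 2, d_true[i] + P / 2, by = 0.5), 0), p))
    lo[i] <- rr[1L]; hi[i] <- rr[2L]
  }
  v <- (reflectivity(d_true, p) - lo) / (hi - lo)
  fit <- fit_thickness_map(v, d_true, p)
  # exact up to the 0.5 nm pre-scan grid and its parabolic refinement
  expect_lt(max(abs(fit$values_nm - d_true)), 0.5)
  expect_lt(max(fit$residual, na.rm = TRUE), 1e-4)
})

test_that("an initial estimate one period off lands one period off", {
  p <- default_tfi()
  P <- tfi_period(p)
  d_true <- matrix(420, 8, 8)
  v <- matrix(0.5, 8, 8)
  d0 <- d_true
  v[] <- local({
    rr <- range(reflectivity(seq(420 - P / 2, 420 + P / 2, by = 0.5), p))
    (reflectivity(420, p) - rr[1L]) / (rr[2L] - rr[1L])
  })
  good <- fit_thickness_map(v, d0, p)
  aliased <- fit_thickness_map(v, d0 + P, p)
  expect_equal(mean(good$values_nm), 420, tolerance = 1)
  expect_equal(mean(aliased$values_nm) - mean(good$values_nm), P,
               tolerance = 2)
})

test_that("pixels without an initial estimate are flagged, not fitted", {
  p <- default_tfi()
  init <- matrix(300, 6, 6)
  init[2, 3] <- NA
  v <- matrix(0.4, 6, 6)
  fit <- fit_thickness_map(v, init, p, mask = matrix(TRUE, 6, 6))
  expect_identical(fit$flag[2, 3], "no_init")
  expect_true(is.na(fit$values_nm[2, 3]))
  expect_identical(sum(fit$flag == "ok"), 35L)
})

test_that("pixels above the interference validity limit keep their init", {
  p <- default_tfi()
  init <- matrix(c(300, 2000), 2, 2)
  v <- matrix(0.4, 2, 2)
  fit <- fit_thickness_map(v, init, p)
  expect_identical(fit$flag[1, 1], "ok")
  expect_identical(fit$flag[2, 1], "above_validity")
  expect_equal(fit$values_nm[2, 1], 2000)
})

test_that("uniformity sigma is the population standard deviation", {
  expect_equal(uniformity_sigma(matrix(c(180, 190, 200), 1, 3)),
               sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(uniformity_sigma(matrix(5.5, 10, 10)), 0)
  expect_error(uniformity_sigma(matrix(1, 2, 2), roi = matrix(FALSE, 2, 2)),
               "empty")
  set.seed(31)
  m <- matrix(rnorm(10000, 500, 5), 100, 100)
  expect_equal(uniformity_sigma(m), 5, tolerance = 0.2)
})

test_that("multi-wavelength map fits agree on shared ground truth", {
  d_true <- matrix(seq(200, 250, length.out = 24), 24, 16)
  means <- vapply(c(463, 542, 632), function(wl) {
    p <- tfi_params(wavelength_nm = wl)
    P <- tfi_period(p)
    lo <- hi <- d_true
    for (i in seq_along(d_true)) {
      rr <- range(reflectivity(
        pmax(seq(d_true[i] - P / 2, d_true[i] + P / 2, by = 0.5), 0), p))
      lo[i] <- rr[1L]; hi[i] <- rr[2L]
    }
    set.seed(as.integer(wl))
    v <- (reflectivity(d_true, p) - lo) / (hi - lo) +
      rnorm(length(d_true), sd = 0.02)
    fit <- fit_thickness_map(v, d_true, p)
    mean(fit$values_nm)
  }, numeric(1L))
  expect_lt(max(means) - min(means), 5)
  expect_equal(means, rep(mean(d_true), 3L), tolerance = 0.02)
})
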