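test_that("scintillator radius converts to scattering angle", {
  g <- test_geometry()
  expect_equal(pixel_to_angle(33, g), atan(33 / 300) * 1000)
  expect_gt(pixel_to_angle(33, g), 109)
  expect_lt(pixel_to_angle(33, g), 110)
  expect_equal(pixel_to_angle(0, g), 0)
  expect_equal(pixel_to_angle(300, g), 1000 * pi / 4)
})

test_that("radial binning matches a brute-force per-pixel oracle and conserves counts", {
  g <- test_geometry()
  set.seed(5)
  img <- matrix(rexp(129 * 129), 129, 129)
  pat <- scatter_pattern(img, g)
  prof <- radial_profile(pat, n_bins = 32)

  # independent oracle: loop over pixels, assign to bins directly
  width <- g$max_angle_mrad / 32
  oracle <- numeric(32)
  for (i in seq_len(129)) {
    for (j in seq_len(129)) {
      r <- sqrt((i - 65)^2 + (j - 65)^2) * g$pixel_size_um
      a <- atan(r / g$specimen_to_scintillator_um) * 1000
      if (a <= g$max_angle_mrad) {
        b <- min(floor(a / width) + 1, 32)
        oracle[b] <- oracle[b] + img[i, j]
      }
    }
  }
  expect_equal(prof$intensity, oracle, tolerance = 1e-12)
  expect_equal(sum(prof$intensity), sum(oracle), tolerance = 1e-12)
})

test_that("a delta ring lands in a single bin at its angle", {
  g <- test_geometry()
  r_px <- 31  # 31 um -> 103.1 mrad
  pat <- scatter_pattern(ring_image(radius_px = r_px), g)
  prof <- radial_profile(pat, n_bins = 64)
  hot <- which(prof$intensity > 0)
  expect_length(hot, 1L)
  true_angle <- atan(r_px / 300) * 1000
  expect_lt(abs(prof$angle_mrad[hot] - true_angle), prof$bin_width_mrad)
  expect_equal(sum(prof$intensity), 8)
})

test_that("a uniform image fills bins in proportion to annulus pixel counts", {
  g <- test_geometry()
  pat <- scatter_pattern(matrix(1, 129, 129), g)
  prof <- radial_profile(pat, n_bins = 16)
  width <- g$max_angle_mrad / 16
  counts <- numeric(16)
  for (i in seq_len(129)) {
    for (j in seq_len(129)) {
      r <- sqrt((i - 65)^2 + (j - 65)^2)
      a <- atan(r / 300) * 1000
      if (a <= g$max_angle_mrad) {
        counts[min(floor(a / width) + 1, 16)] <-
          counts[min(floor(a / width) + 1, 16)] + 1
      }
    }
  }
  expect_equal(prof$intensity, counts)

  zero <- radial_profile(scatter_pattern(matrix(0, 129, 129), g))
  expect_true(all(zero$intensity == 0))
})

test_that("beam center outside the image is rejected", {
  g <- detector_geometry(1, c(500, 500))
  expect_error(scatter_pattern(matrix(1, 10, 10), g), "center")
})

test_that("DF/BF ratio follows its defining sums and scale invariance", {
  prof <- structure(list(angle_mrad = c(10, 30, 50, 90),
                         intensity = c(70, 0, 10, 20),
                         bf_cutoff_mrad = 20, bin_width_mrad = 20),
                    class = "radial_profile")
  expect_equal(df_bf_ratio(prof), 30 / 70)
  prof$intensity <- prof$intensity * 123.4
  expect_equal(df_bf_ratio(prof), 30 / 70, tolerance = 1e-12)
  prof$intensity <- c(40, 0, 10, 30)
  expect_equal(df_bf_ratio(prof), 1)
  prof$intensity <- c(100, 0, 0, 0)
  expect_equal(df_bf_ratio(prof), 0)
  prof$intensity <- c(0, 0, 5, 5)
  expect_error(df_bf_ratio(prof), "infinite ratio")
})

test_that("most common angle finds a ring, ties break low, flat is undefined", {
  g <- test_geometry()
  pat <- scatter_pattern(ring_image(radius_px = 31), g)
  prof <- radial_profile(pat, n_bins = 64)
  mca <- most_common_angle(prof)
  expect_lt(abs(as.numeric(mca) - atan(31 / 300) * 1000),
            prof$bin_width_mrad)
  expect_false(attr(mca, "ambiguous"))

  # unscattered beam: everything below the bright-field cutoff
  ctr <- matrix(0, 129, 129); ctr[65, 65] <- 100
  p2 <- radial_profile(scatter_pattern(ctr, g), bf_cutoff_mrad = 60)
  expect_lt(as.numeric(most_common_angle(p2)), 60)

  # two exactly equal per-solid-angle peaks: lower angle + ambiguity flag
  th <- (seq_len(8) - 0.5) * 10 / 1000
  omega <- 2 * pi * (cos(th - 0.005) - cos(th + 0.005))
  intens <- rep(0, 8); intens[3] <- omega[3]; intens[6] <- omega[6]
  tie <- structure(list(angle_mrad = th * 1000, intensity = intens,
                        bf_cutoff_mrad = 10, bin_width_mrad = 10),
                   class = "radial_profile")
  mtie <- most_common_angle(tie)
  expect_equal(as.numeric(mtie), 25)
  expect_true(attr(mtie, "ambiguous"))

  flat <- structure(list(angle_mrad = th * 1000, intensity = omega,
                         bf_cutoff_mrad = 10, bin_width_mrad = 10),
                    class = "radial_profile")
  expect_true(attr(most_common_angle(flat), "undefined"))
})

test_that("zero thickness transmits every electron unscattered at full energy", {
  mc <- mc_simulate(0, 30, 500, seed = 4)
  expect_true(all(mc$fate == "transmitted"))
  expect_true(all(mc$exit_angle_mrad == 0))
  expect_true(all(mc$exit_energy_keV == 30))
  expect_identical(nrow(mc$deposit), 0L)
})

test_that("energy is conserved to bookkeeping precision", {
  for (d in c(100, 1000)) {
    mc <- mc_simulate(d, 30, 3000, seed = 7)
    budget <- mc_energy_budget(mc)
    expect_lt(abs(budget$closure_rel), 1e-6)
    expect_gt(budget$deposited_keV, 0)
  }
})

test_that("fixed seeds make transport runs bit-identical", {
  a <- mc_simulate(300, 30, 1000, seed = 42)
  b <- mc_simulate(300, 30, 1000, seed = 42)
  expect_identical(a$exit_angle_mrad, b$exit_angle_mrad)
  expect_identical(a$deposit, b$deposit)
  c <- mc_simulate(300, 30, 1000, seed = 43)
  expect_false(identical(a$exit_angle_mrad, c$exit_angle_mrad))
})

test_that("one-collision angular distribution follows screened Rutherford", {
  # slab much thinner than the mean free path isolates single scattering
  mc <- mc_simulate(8, 30, 60000, seed = 12)
  one <- mc$fate == "transmitted" & mc$n_collisions == 1L
  theta <- mc$exit_angle_mrad[one] / 1000

  # mixture CDF over O and 2 H from the sampling inverse
  sig_o <- screened_rutherford_sigma(8, 30)
  sig_h <- screened_rutherford_sigma(1, 30)
  p_o <- sig_o / (sig_o + 2 * sig_h)
  cdf <- function(th) {
    u <- function(a) {
      x <- cos(th)
      (1 - x) * (1 + a) / (2 * a + (1 - x))
    }
    a_o <- 3.4e-3 * 8^0.67 / 30
    a_h <- 3.4e-3 * 1^0.67 / 30
    p_o * u(a_o) + (1 - p_o) * u(a_h)
  }
  edges <- c(5, 10, 20, 40, 80, 150, 300, 700) / 1000
  probs <- diff(c(0, vapply(edges, cdf, numeric(1L)), 1))
  obs <- table(cut(theta, c(0, edges, pi), include.lowest = TRUE))
  expected <- probs * length(theta)
  keep <- expected >= 5
  x2 <- sum((as.numeric(obs)[keep] - expected[keep])^2 / expected[keep])
  p_val <- pchisq(x2, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p_val, 1e-3)
})

test_that("deposited-energy containment radius grows with thickness", {
  r95 <- vapply(c(250, 500, 1000), function(d)
    energy_containment_radius(mc_simulate(d, 30, 4000, seed = 21)),
    numeric(1L))
  expect_true(all(diff(r95) > 0))
})

test_that("lookup tables are monotone and reproducible across seeds", {
  grid <- c(0, 100, 300, 600, 900)
  tab <- build_table(grid, n_electrons = 8000, seed = 2)
  expect_equal(tab$df_bf_ratio[1L], 0)
  expect_true(all(diff(tab$df_bf_ratio) > 0))
  expect_gt(tab$df_bf_ratio[4L], tab$df_bf_ratio[2L])  # 600 vs 100 nm

  tab2 <- build_table(grid, n_electrons = 8000, seed = 77)
  for (i in 2:5) {
    se <- sqrt(tab$ratio_se[i]^2 + tab2$ratio_se[i]^2)
    expect_lt(abs(tab$df_bf_ratio[i] - tab2$df_bf_ratio[i]), 3 * se)
  }
})

test_that("statistically hopeless table resolution is rejected with advice", {
  rejected <- FALSE
  for (s in 1:5) {
    got <- tryCatch(
      build_table(c(1000, 1001, 1002), n_electrons = 300, seed = s),
      error = function(e) e)
    if (inherits(got, "error")) {
      rejected <- TRUE
      expect_match(conditionMessage(got), "increase n_electrons")
      break
    }
  }
  expect_true(rejected)
})

test_that("table inversion applies the incidence correction on path length", {
  tab <- toy_table()
  img <- matrix(0, 129, 129)
  img[65, 65] <- 100           # bright field
  img <- img + ring_image(radius_px = 31, value = 50)  # 4 px = 200 dark field
  pat <- scatter_pattern(img, test_geometry())
  res52 <- thickness_from_pattern(pat, tab, incidence_deg = 52)
  res0 <- thickness_from_pattern(pat, tab, incidence_deg = 0)
  expect_equal(res0$df_bf_ratio, 2)
  expect_equal(res0$path_nm, 325)
  expect_equal(res0$d_nm, 325)
  expect_equal(res52$d_nm, 325 * cos(52 * pi / 180), tolerance = 1e-9)
  expect_equal(round(res52$d_nm, 1), 200.1)
})

test_that("ratios outside the table range raise out-of-range errors", {
  tab <- toy_table()
  img <- matrix(0, 129, 129); img[65, 65] <- 100
  pat <- scatter_pattern(img, test_geometry())  # ratio 0: too thin
  expect_error(thickness_from_pattern(pat, tab), "too thin")
  img2 <- ring_image(radius_px = 31, value = 100)
  img2[65, 65] <- 10           # ratio 40: too thick
  pat2 <- scatter_pattern(img2, test_geometry())
  expect_error(thickness_from_pattern(pat2, tab), "too thick")
})

test_that("round trip through rendered patterns recovers the thickness", {
  tab <- build_table(seq(100, 500, by = 50), n_electrons = 10000, seed = 3)
  ph <- make_phantom(30, 8, 300, pixel_size_um = 0.2)
  g <- detector_geometry(pixel_size_um = 0.5,
                         center_px = c(140.5, 140.5))
  rp <- render_scatter_patterns(ph, cbind(c(70, 75), c(15, 25)), g,
                                image_px = 280, dose = 8000, seed = 9)
  expect_equal(rp$truth_nm, c(300, 300))
  for (pat in rp$patterns) {
    res <- thickness_from_pattern(pat, tab, incidence_deg = 0)
    i <- which.min(abs(tab$thickness_nm - res$path_nm))
    slope <- diff(tab$thickness_nm[c(i - 1, i + 1)]) /
      diff(tab$df_bf_ratio[c(i - 1, i + 1)])
    se_nm <- tab$ratio_se[i] * abs(slope) * sqrt(2)  # table + pattern noise
    expect_lt(abs(res$path_nm - 300), 3 * se_nm + 2)
  }
})

test_that("line scans map a thickness ramp and flag failures", {
  tab <- build_table(c(100, 200, 300, 400, 500), n_electrons = 8000, seed = 6)
  ph <- make_phantom(30, 8, 450, pixel_size_um = 0.2, ramp_nm = 150)
  g <- detector_geometry(pixel_size_um = 0.5, center_px = c(128.5, 128.5))
  rows <- round(seq(55, 95, length.out = 5))
  rp <- render_scatter_patterns(ph, cbind(rows, 20), g, image_px = 280,
                                dose = 6000, seed = 14)
  scan <- thickness_line_scan(rp$patterns, tab, incidence_deg = 0)
  ok <- scan$flag == "ok"
  expect_true(all(ok))
  expect_lt(max(abs(scan$d_nm - rp$truth_nm)), 25)
  expect_error(thickness_line_scan(list(), tab), "empty")
})

test_that("doubling the dose shrinks the ratio error like one over root N", {
  reps <- function(dose) {
    vapply(1:6, function(k) {
      mc <- mc_simulate(300, 30, dose, seed = 100 + k)
      obs <- lamellometer:::mc_observables(mc, 60)
      obs$df_bf_ratio
    }, numeric(1L))
  }
  sd_small <- sd(reps(1500))
  sd_big <- sd(reps(6000))
  # fourfold dose: expect close to a factor-2 reduction
  expect_lt(sd_big, sd_small)
  expect_lt(sd_big / sd_small, 1.1)
  expect_gt(sd_big / sd_small, 0.2)
})
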