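test_that("fascicle and muscle lengths are Euclidean distances with masking", {
  m1 <- rbind(c(0, 0, 0), c(0, 0, 0), c(NA, 0, 0))
  m2 <- rbind(c(0, 3, 4), c(0, 0, 0), c(1, 1, 1))
  expect_warning(l <- fascicle_length(m1, m2), "degenerate")
  expect_equal(l[1], 5)
  expect_equal(l[2], 0)
  expect_true(is.na(l[3]))

  tip <- rbind(c(0, 0, 0), c(1, 0, 0))
  m3 <- rbind(c(0, 0, 10), c(1, 0, 10))
  expect_equal(muscle_length(tip, m3), c(10, 10))
  expect_error(muscle_length(tip, m3[1, , drop = FALSE]), "equal length")
})

test_that("planar fascicle angles match hand-projected values and fold to [0,90]", {
  fr <- anatomical_frame()  # AP = x, SI = z, ML = -y
  th <- 20 * pi / 180
  # fascicle tilted 20 deg toward ML within the coronal plane
  m1 <- matrix(0, 1, 3)
  m2 <- matrix(c(0, sin(th), cos(th)), 1, 3)
  m3 <- matrix(c(0, 0, 1), 1, 3)
  a <- fascicle_angles(m1, m2, m3, fr)
  expect_equal(a$coronal, 20, tolerance = 1e-9)
  expect_equal(a$sagittal, 0, tolerance = 1e-9)

  # parallel vectors: zero in both planes; antiparallel folds to 0 too
  a2 <- fascicle_angles(m1, m3, m3, fr)
  expect_equal(a2$sagittal, 0, tolerance = 1e-9)
  a3 <- fascicle_angles(m1, -m3, m3, fr)
  expect_equal(a3$sagittal, 0, tolerance = 1e-9)

  # degenerate projection masked
  m2p <- matrix(c(0, 1, 0), 1, 3)  # pure ML: sagittal projection vanishes
  a4 <- fascicle_angles(m1, m2p, m3, fr)
  expect_true(is.na(a4$sagittal))
  expect_equal(a4$coronal, 90, tolerance = 1e-9)

  # generator with prescribed theta confined to the sagittal plane
  sc <- synthetic_scenario(mode = "prescribed_theta",
                           theta_fun = function(g) 25 - g,
                           n_cycles = 2)
  rec <- simulate_recording(sc)
  ang <- fascicle_angles(marker_traj(rec$dataset, "m1"),
                         marker_traj(rec$dataset, "m2"),
                         marker_traj(rec$dataset, "m3"), fr)
  expect_lt(max(abs(ang$sagittal - rec$truth$theta_deg)), 1e-6)
  expect_lt(max(ang$coronal), 1e-6)
})

test_that("instantaneous velocity uses central differences within Taylor bounds", {
  expect_equal(instantaneous_velocity(rep(2, 10), 150), rep(0, 10))
  ramp <- instantaneous_velocity(seq(0, 18, by = 2), 150)
  expect_equal(ramp, rep(300, 10))

  f <- 4
  t <- (0:299) / 150
  x <- sin(2 * pi * f * t)
  v <- instantaneous_velocity(x, 150)
  truth <- 2 * pi * f * cos(2 * pi * f * t)
  bound <- (2 * pi * f)^3 * (1 / 150)^2 / 6
  expect_lt(max(abs(v - truth)[2:299]), bound * 1.001)

  # a masked frame masks the frames whose central difference needs it
  x[5] <- NA
  v2 <- instantaneous_velocity(x, 150)
  expect_true(all(is.na(v2[c(4, 6)])))
  expect_false(anyNA(v2[7:100]))
})

test_that("LOESS smoothing reproduces lines exactly and denoises a sinusoid", {
  x <- seq(0, 100, length.out = 60)
  y <- 3 + 0.5 * x
  expect_equal(loess_smooth(x, y, 0.25), y, tolerance = 1e-9)
  expect_equal(loess_smooth(x, y, 1), y, tolerance = 1e-9)

  set.seed(3)
  sigma <- 0.5
  truth <- sin(x / 8)
  rmse <- replicate(10, {
    ys <- loess_smooth(x, truth + rnorm(60, 0, sigma), 0.25)
    sqrt(mean((ys - truth)^2))
  })
  expect_lt(mean(rmse), sigma)

  expect_error(loess_smooth(x[1:3], y[1:3]), "at least 4")
  expect_error(loess_smooth(x, y, span = 0), "span")
})

test_that("AGR is the masked velocity ratio with scale invariance", {
  v <- c(-3, -2, -0.1, 0.1, 2, 3)
  r <- compute_agr(v, v, epsilon = 0.5)
  expect_equal(r$agr[r$mask], rep(1, 4))
  expect_equal(r$mask, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))

  mv <- c(-2, -1, 1, 2)
  fv <- c(-4, -2, 2, 4)
  r2 <- compute_agr(mv, fv, 0.5)
  expect_equal(r2$agr, rep(0.5, 4))
  r3 <- compute_agr(7 * mv, 7 * fv, 0.5)
  expect_equal(r3$agr, r2$agr)

  # opposite-sign frames masked
  r4 <- compute_agr(c(1, -1), c(1, 1), 0.5)
  expect_equal(r4$mask, c(TRUE, FALSE))
  expect_error(compute_agr(mv, fv, 0), "epsilon")
})

test_that("normalization shifts extrema to zero without changing shape", {
  expect_equal(normalize_to_zero(c(3, 4, 5)), c(0, 1, 2))
  expect_equal(normalize_to_zero(c(3, 4, 5), "max"), c(-2, -1, 0))
  x <- cumsum(rnorm(30))
  expect_equal(instantaneous_velocity(normalize_to_zero(x), 150),
               instantaneous_velocity(x, 150))
  expect_error(normalize_to_zero(c(NA_real_, NA_real_)), "finite")
})

test_that("bulging reports per-axis ranges of the superficial marker", {
  fr <- anatomical_frame()
  still <- matrix(1, 20, 3)
  b <- bulging(still, fr, 1:20)
  expect_equal(c(b$ap_range, b$ml_range), c(0, 0))

  osc <- matrix(1, 20, 3)
  osc[, 1] <- 1 + 2 * sin(pi / 2 * (0:19))  # AP axis = x, hits +/-2 exactly
  b2 <- bulging(osc, fr, 1:20)
  expect_equal(b2$ap_range, 4, tolerance = 1e-9)
  expect_equal(b2$ml_range, 0)
  expect_error(bulging(osc, fr, integer(0)), "empty")
})

test_that("gape-controlled residuals remove the within-half gape trend", {
  set.seed(8)
  gape <- runif(200, 0, 10)
  closing <- rep(c(TRUE, FALSE), each = 100)
  y <- ifelse(closing, 2 * gape, -1 * gape) + rnorm(200, 0, 0.1)
  res <- gape_control_residuals(y, gape, closing)
  expect_lt(abs(cor(res[closing], gape[closing])), 0.05)
  expect_lt(abs(cor(res[!closing], gape[!closing])), 0.05)
})

test_that("pipeline output tables are consistent and errors are staged", {
  sc <- synthetic_scenario(n_cycles = 3)
  rec <- simulate_recording(sc)
  res <- run_pipeline(rec$config, rec$dataset, rec$landmarks)
  expect_s3_class(res, "chew_pipeline_result")
  lt <- res$long_table
  expect_setequal(unique(lt$variable),
                  c("gape", "fascicle_length", "muscle_length",
                    "sagittal_angle", "coronal_angle",
                    "fascicle_velocity", "muscle_velocity"))
  expect_true(all(lt$pct_cycle >= 0 & lt$pct_cycle <= 100))
  expect_true(all(res$cycle_table$duration_s > 0))
  expect_true(all(res$cycle_table$fc_sc > res$cycle_table$start_frame))
  expect_true(all(res$cycle_table$so_fo < res$cycle_table$end_frame))
  # masked AGR fraction is reported
  expect_true(is.finite(res$food_average$agr_masked_fraction))

  # long table survives the disk round trip
  p <- tempfile(fileext = ".csv")
  write_long_table(lt, p)
  back <- read_long_table(p)
  expect_equal(back$value, lt$value, tolerance = 1e-10)

  # empty marker file: clean staged error
  p2 <- tempfile(fileext = ".csv")
  writeLines("", p2)
  expect_error(run_pipeline(rec$config, p2, rec$landmarks),
               "read_markers")
})

test_that("lengths shrink and angles grow toward minimum gape on generator data", {
  sc <- synthetic_scenario(mode = "constant_thickness", n_cycles = 3,
                           coronal_tilt_deg = 26)
  rec <- simulate_recording(sc)
  res <- run_pipeline(rec$config, rec$dataset, rec$landmarks)
  fa <- res$food_average
  at_min <- smooth_argmin(fa$gape)
  expect_lte(abs(smooth_argmin(fa$fascicle_length) - at_min), 1)
  expect_lte(abs(smooth_argmin(fa$muscle_length) - at_min), 1)
  expect_lte(abs(smooth_argmax(fa$sagittal_angle) - at_min), 1)
  expect_lte(abs(smooth_argmax(fa$coronal_angle) - at_min), 1)
  # fascicle shorter at minimum gape than at maximum gape
  expect_lt(min(fa$fascicle_length), fa$fascicle_length[1])
})
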