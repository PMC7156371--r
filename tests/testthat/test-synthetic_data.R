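test_that("gape trajectory hits its amplitude, zero minima and C1 junctions", {
  sc <- synthetic_scenario(n_cycles = 3, max_gape = 10)
  gt <- build_gape_trajectory(sc)
  tr <- gt$transitions
  expect_equal(nrow(tr), 3)
  expect_equal(max(gt$gape), 10)
  expect_equal(gt$gape[tr$min_gape], rep(0, 3))
  expect_equal(gt$gape[tr$start], rep(10, 3))
  # velocity is continuous (zero) at every junction: first differences on
  # either side of each junction are small and of matching sign pattern
  v <- diff(gt$gape)
  for (j in c(tr$fc_sc, tr$so_fo)) {
    expect_lt(abs(v[j] - v[j - 1]), 0.5)
  }
  # numerical acceleration extremum sits at the junctions
  a <- diff(gt$gape, differences = 2)
  cyc <- tr[1, ]
  win <- (cyc$start + 2):(cyc$min_gape - 2)
  expect_lte(abs(win[which.min(diff(a)[win - 1])] - cyc$fc_sc), 1)
  expect_error(synthetic_scenario(phase_durations = c(fc = 1, sc = 13,
                                                      so = 13, fo = 12)),
               "phase durations")
})

test_that("jaw scene satisfies the chord relation and round-trips gape", {
  sc <- synthetic_scenario(n_cycles = 2)
  gt <- build_gape_trajectory(sc)
  scene <- build_jaw_scene(gt$gape, sc)
  # chord relation: phi = 2 asin(gape / 2r)
  p_ant <- sc$mandibular_markers$mand_ant
  r <- sqrt(p_ant[1]^2 + p_ant[3]^2)  # distance to the ML axis
  expect_equal(scene$phi, 2 * asin(gt$gape / (2 * r)), tolerance = 1e-12)
  # anterior-marker displacement reproduces the gape exactly
  ant <- marker_traj(scene$dataset, "mand_ant")
  occ <- which(gt$gape == 0)[1]
  d <- sqrt(rowSums(sweep(ant, 2, ant[occ, ])^2))
  expect_lt(max(abs(d - gt$gape)), 1e-9)
  # gape 0 -> static scene
  static <- build_jaw_scene(rep(0, 20), sc)
  for (nm in names(static$dataset$markers))
    expect_equal(stats::sd(marker_traj(static$dataset, nm)[, 1]), 0)
  # unreachable gape errors
  expect_error(build_jaw_scene(rep(2 * r + 1, 10), sc), "unreachable")
})

test_that("muscle marker geometry is exact and AGR closed forms hold", {
  expect_error(synthetic_scenario(mode = "constant_pinnation",
                                  theta0_deg = 0), "theta0")

  # near-parallel-fibered limit: markers collinear, AGR -> 1
  sc0 <- synthetic_scenario(mode = "constant_pinnation", theta0_deg = 1e-7,
                            n_cycles = 2)
  rec0 <- simulate_recording(sc0)
  expect_equal(unique(rec0$truth$agr), 1, tolerance = 1e-9)
  v <- marker_traj(rec0$dataset, "m2") - marker_traj(rec0$dataset, "m1")
  r <- marker_traj(rec0$dataset, "m3") - marker_traj(rec0$dataset, "m1")
  cr <- abs(v[, 1] * r[, 3] - v[, 3] * r[, 1])
  expect_lt(max(cr), 1e-4)  # collinear in the sagittal plane

  for (mode in c("constant_pinnation", "constant_thickness")) {
    sc <- synthetic_scenario(mode = mode, theta0_deg = 20, n_cycles = 3)
    rec <- simulate_recording(sc)
    tru <- rec$truth
    m1 <- marker_traj(rec$dataset, "m1")
    m2 <- marker_traj(rec$dataset, "m2")
    m3 <- marker_traj(rec$dataset, "m3")
    # geometry consistency by construction
    expect_lt(max(abs(fascicle_length(m1, m2) - tru$l)), 1e-9)
    ang <- fascicle_angles(m1, m2, m3, anatomical_frame())
    expect_lt(max(abs(ang$sagittal - tru$theta_deg)), 1e-6)
    # finite-difference AGR from emitted lengths matches the closed form
    dl <- diff(tru$l); dL <- diff(tru$L)
    use <- abs(dl) > 1e-4
    fd <- (dL / dl)[use]
    cf <- ((tru$agr[-1] + tru$agr[-length(tru$agr)]) / 2)[use]
    expect_lt(max(abs(fd - cf) / cf), 0.01)
    if (mode == "constant_pinnation")
      expect_equal(unique(round(tru$agr, 12)), round(cos(pi / 9), 12))
    else
      expect_equal(tru$agr, 1 / cos(tru$theta_deg * pi / 180),
                   tolerance = 1e-12)
  }

  # tendon slack guard
  expect_error(
    simulate_recording(synthetic_scenario(tendon_length = 46)),
    "tendon")
})

test_that("marker noise is seeded, unbiased and sized as requested", {
  sc <- synthetic_scenario(n_cycles = 2)
  rec <- simulate_recording(sc)
  expect_identical(add_noise(rec$dataset, 0), rec$dataset)
  a <- add_noise(rec$dataset, 0.15, seed = 42)
  b <- add_noise(rec$dataset, 0.15, seed = 42)
  expect_identical(a, b)
  big <- marker_dataset(list(m = matrix(0, 4000, 3)))
  noisy <- add_noise(big, 0.2, seed = 1)
  sds <- apply(marker_traj(noisy, "m"), 2, stats::sd)
  expect_true(all(abs(sds - 0.2) / 0.2 < 0.05))
})

test_that("scene round-trip: kinematics recovers generator transforms to 1e-9", {
  sc <- synthetic_scenario(n_cycles = 2, drift_rot_deg = 1.5,
                           drift_trans_mm = 2)
  rec <- simulate_recording(sc)
  ds <- fix_cranial_frame(rec$dataset, names(sc$cranial_markers))
  tf <- mandible_transforms(ds, names(sc$mandibular_markers),
                            reference_points =
                              do.call(rbind, sc$mandibular_markers))
  for (f in seq(1, ds$n_frames, by = 7)) {
    expect_lt(max(abs(tf$R[, , f] - rec$truth$transforms$R[, , f])), 1e-9)
    expect_lt(max(abs(tf$t[f, ] - rec$truth$transforms$t[f, ])), 1e-9)
  }
})

test_that("study builder produces the full design with recoverable FMP effect", {
  st <- make_study(n_cycles = 4, seed = 3)
  expect_equal(nrow(st$index), 15)
  expect_equal(length(unique(st$index$subject)), 3)
  expect_equal(length(unique(st$index$food)), 5)
  expect_setequal(st$index$fmp[st$index$food %in% c("popcorn", "cashew")],
                  "high")
  expect_true(all(st$index$agr_mode[st$index$fmp == "high"] ==
                    "constant_pinnation"))

  # written fixture set pairs marker, truth and transitions files
  dir <- tempfile()
  st2 <- make_study(n_cycles = 3, seed = 5, dir = dir)
  files <- list.files(dir)
  expect_equal(sum(grepl("_markers.csv$", files)), 15)
  expect_equal(sum(grepl("_truth.csv$", files)), 15)
  expect_equal(sum(grepl("_transitions.csv$", files)), 15)
  one <- read_marker_csv(file.path(dir, files[grepl("_markers", files)][1]))
  expect_equal(length(one$markers), 11)  # 4 cranial + 4 mandibular + 3 muscle

  # end-to-end: the built-in FMP AGR difference is detected
  res <- study_fmp_test(make_study(n_cycles = 8, seed = 11))
  expect_lt(res$p_fmp, 0.01)
  med <- tapply(res$agr_table$agr_median, res$agr_table$fmp, stats::median)
  expect_lt(med[["high"]], 1)
  expect_gt(med[["low"]], 1)
})

test_that("null study carries no FMP difference in its ground truth", {
  st <- make_study(n_cycles = 3, seed = 2, null_effect = TRUE)
  expect_true(all(st$index$agr_mode == "constant_pinnation"))
  agrs <- sapply(st$recordings, function(r) r$truth$agr[1])
  # identical AGR for all foods of a given subject
  expect_equal(length(unique(round(agrs, 10))), 3)
})
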