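test_that("zero-phase Butterworth matches the analytic two-pass response", {
  fs <- 150
  t <- (0:599) / fs
  # constant series: DC gain 1
  expect_equal(butterworth_lowpass(rep(3.7, 100), 30, 4, fs), rep(3.7, 100),
               tolerance = 1e-9)

  # 5 Hz passband tone: amplitude within 1% of 1, peak unshifted
  x <- sin(2 * pi * 5 * t)
  y <- butterworth_lowpass(x, 30, 4, fs)
  mid <- 100:500
  expect_lt(abs(max(abs(y[mid])) - 1), 0.01)
  cc <- stats::ccf(y[mid], x[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # 60 Hz stopband tone: two-pass residual |H|^2 = 1/257 ~ 0.004 < 0.01
  x2 <- sin(2 * pi * 60 * t)
  y2 <- butterworth_lowpass(x2, 30, 4, fs)
  expect_lt(max(abs(y2[mid])), 0.01)

  expect_error(butterworth_lowpass(x, 80, 4, fs), "Nyquist")
  expect_error(butterworth_lowpass(x[1:10], 30, 4, fs), "too short")
})

test_that("Kabsch registration recovers exact transforms and errors on degeneracy", {
  set.seed(1)
  P <- matrix(rnorm(12, sd = 10), 4, 3)
  # identity and pure translation
  tf <- fit_rigid_transform(P, P)
  expect_equal(tf$R, diag(3), tolerance = 1e-12)
  expect_equal(tf$t, c(0, 0, 0), tolerance = 1e-12)
  tf <- fit_rigid_transform(P, sweep(P, 2, c(-1, -2, -3)))
  expect_equal(tf$t, c(1, 2, 3), tolerance = 1e-12)

  # 30 deg rotation about SI axis plus translation: exact recovery
  Rz <- rotation_about_axis(c(0, 0, 1), 30 * pi / 180)
  Q <- t(Rz %*% t(P)) + rep(c(5, -2, 1), each = 4)
  tf <- fit_rigid_transform(P, Q)
  expect_lt(max(abs(tf$R - Rz)), 1e-9)
  expect_lt(max(abs(tf$t - c(5, -2, 1))), 1e-9)
  expect_lt(registration_rmsd(tf, P, Q), 1e-9)

  expect_error(fit_rigid_transform(P[1:2, ], P[1:2, ]), "3 paired points")
  coll <- cbind(1:4, 2 * (1:4), -1 * (1:4))
  expect_error(fit_rigid_transform(coll, coll), "collinear")
})

test_that("Kabsch agrees with Horn's quaternion oracle on 3-point instances", {
  set.seed(7)
  for (i in 1:25) {
    P <- matrix(rnorm(9, sd = 5), 3, 3)
    R0 <- random_rotation()
    Q <- t(R0 %*% t(P)) + rep(rnorm(3), each = 3) +
      matrix(rnorm(9, sd = 0.05), 3, 3)
    tf <- fit_rigid_transform(P, Q)
    orc <- horn_registration(P, Q)
    expect_lt(max(abs(tf$R - orc$R)), 1e-6)
    expect_lt(max(abs(tf$t - orc$t)), 1e-6)
  }
})

test_that("cranial fixing makes the cranium stationary and is drift-exact", {
  # stationary cranium: output equals input
  sc <- synthetic_scenario(n_cycles = 2)
  rec <- simulate_recording(sc)
  fixed <- fix_cranial_frame(rec$dataset, names(sc$cranial_markers))
  expect_equal(fixed$coordinate_frame_tag, "cranial")
  for (nm in names(sc$cranial_markers))
    expect_lt(max(abs(sweep(marker_traj(fixed, nm), 2,
                            sc$cranial_markers[[nm]]))), 1e-9)

  # whole-scene rigid drift removed to numerical precision (noiseless)
  sc2 <- synthetic_scenario(n_cycles = 2, drift_rot_deg = 2,
                            drift_trans_mm = 3)
  rec2 <- simulate_recording(sc2)
  fixed2 <- fix_cranial_frame(rec2$dataset, names(sc2$cranial_markers),
                              reference_frame_index = 1)
  for (nm in names(sc2$cranial_markers)) {
    traj <- marker_traj(fixed2, nm)
    dev <- sweep(traj, 2, traj[1, ])
    expect_lt(max(abs(dev)), 1e-9)
  }

  # with marker noise the cranial residual stays at the noise scale
  sc3 <- synthetic_scenario(n_cycles = 3, drift_rot_deg = 2,
                            drift_trans_mm = 3, noise_sigma = 0.15)
  rec3 <- simulate_recording(sc3)
  fixed3 <- fix_cranial_frame(rec3$dataset, names(sc3$cranial_markers))
  rms <- sapply(names(sc3$cranial_markers), function(nm) {
    traj <- marker_traj(fixed3, nm)
    sqrt(mean(sweep(traj, 2, colMeans(traj))^2))
  })
  expect_true(all(rms <= 0.3))
})

test_that("mandibular transforms reproduce the generator's rotation", {
  sc <- synthetic_scenario(n_cycles = 2)
  rec <- simulate_recording(sc)
  ds <- fix_cranial_frame(rec$dataset, names(sc$cranial_markers))
  tf <- mandible_transforms(ds, names(sc$mandibular_markers),
                            reference_points =
                              do.call(rbind, sc$mandibular_markers))
  # rotation angle equals the prescribed jaw angle phi at every frame
  ang <- sapply(seq_len(ds$n_frames), function(f)
    rotation_angle(transform_at(tf, f)))
  expect_lt(max(abs(ang - rec$truth$phi)), 1e-9)
  # marker reconstruction residual is numerically zero (noiseless)
  ref <- do.call(rbind, sc$mandibular_markers)
  rmsd <- sapply(seq_len(ds$n_frames), function(f)
    registration_rmsd(transform_at(tf, f), ref,
                      marker_block(ds, names(sc$mandibular_markers), f)))
  expect_lt(max(rmsd), 1e-9)
  # reference frame variant: identity at the reference frame
  tf2 <- mandible_transforms(ds, names(sc$mandibular_markers),
                             reference_frame_index = 5)
  id <- transform_at(tf2, 5)
  expect_equal(id$R, diag(3), tolerance = 1e-9)
  expect_equal(id$t, c(0, 0, 0), tolerance = 1e-9)
})

test_that("landmark trajectories follow the transforms exactly", {
  sc <- synthetic_scenario(n_cycles = 2)
  rec <- simulate_recording(sc)
  ds <- fix_cranial_frame(rec$dataset, names(sc$cranial_markers))
  tf <- mandible_transforms(ds, names(sc$mandibular_markers),
                            reference_points =
                              do.call(rbind, sc$mandibular_markers))
  traj <- transform_landmarks(rec$landmarks, tf)
  # coronoid tip reproduces the generator trajectory
  expect_lt(max(abs(traj$coronoid_R - rec$truth$tip)), 1e-9)
  # isometry: a landmark at distance r from the rotation center keeps r
  r0 <- sqrt(sum((rec$landmarks$gonial_R - sc$rotation_center)^2))
  d <- sqrt(rowSums(sweep(traj$gonial_R, 2, sc$rotation_center)^2))
  expect_lt(max(abs(d - r0)), 1e-9)
  # identity transforms leave landmarks at their reference positions
  n <- ds$n_frames
  tf_id <- structure(list(R = array(diag(3), c(3, 3, n)),
                          t = matrix(0, n, 3), valid = rep(TRUE, n),
                          reference_frame = 1L),
                     class = "transform_series")
  traj_id <- transform_landmarks(rec$landmarks, tf_id)
  expect_equal(traj_id$coronoid_R[n, ], rec$landmarks$coronoid_R,
               ignore_attr = TRUE)
})

test_that("gape distance is exact on generator data and obeys Pythagoras", {
  sc <- synthetic_scenario(n_cycles = 3)
  rec <- simulate_recording(sc)
  ds <- fix_cranial_frame(rec$dataset, names(sc$cranial_markers))
  g <- gape_distance(ds, "mand_ant")
  expect_lt(max(abs(g$gape - rec$truth$gape)), 1e-9)
  expect_equal(g$gape[g$occlusion_frame], 0)

  # synthetic displacement (3,4,0) -> 5 mm
  traj <- matrix(0, 10, 3)
  traj[6, ] <- c(3, 4, 0)
  ds2 <- marker_dataset(list(ant = traj))
  g2 <- gape_distance(ds2, "ant", occlusion_frame = 1)
  expect_equal(g2$gape[6], 5)
  expect_equal(g2$gape[1], 0)
})

test_that("registration pipeline is equivariant under global rigid motion", {
  sc <- synthetic_scenario(n_cycles = 2)
  rec <- simulate_recording(sc)
  set.seed(99)
  G <- random_rotation()
  shift <- c(12, -7, 30)
  moved <- rec$dataset
  moved$markers <- lapply(moved$markers, function(m)
    t(G %*% t(m)) + rep(shift, each = nrow(m)))
  run <- function(d) {
    dc <- fix_cranial_frame(d, names(sc$cranial_markers),
                            reference_points =
                              do.call(rbind, sc$cranial_markers))
    tf <- mandible_transforms(dc, names(sc$mandibular_markers),
                              reference_points =
                                do.call(rbind, sc$mandibular_markers))
    tip <- transform_landmarks(rec$landmarks, tf)$coronoid_R
    list(gape = gape_distance(dc, "mand_ant")$gape,
         l = fascicle_length(marker_traj(dc, "m1"), marker_traj(dc, "m2")),
         L = muscle_length(tip, marker_traj(dc, "m3")))
  }
  a <- run(rec$dataset)
  b <- run(moved)
  expect_lt(max(abs(a$gape - b$gape)), 1e-8)
  expect_lt(max(abs(a$l - b$l)), 1e-8)
  expect_lt(max(abs(a$L - b$L)), 1e-8)
})

test_that("transform table export carries rotation and translation entries", {
  sc <- synthetic_scenario(n_cycles = 2)
  rec <- simulate_recording(sc)
  ds <- fix_cranial_frame(rec$dataset, names(sc$cranial_markers))
  tf <- mandible_transforms(ds, names(sc$mandibular_markers))
  tab <- transforms_as_table(tf)
  expect_equal(nrow(tab), ds$n_frames)
  f <- tf$reference_frame
  expect_equal(unlist(tab[f, c("r11", "r22", "r33")]), c(1, 1, 1),
               ignore_attr = TRUE, tolerance = 1e-9)
})
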