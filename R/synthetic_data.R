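#' Synthetic chewing-recording scenario
#'
#' Declares a fully parameterized synthetic recording: a four-phase gape
#' trajectory, a mandible rotating about a mediolateral axis, four cranial
#' and four mandibular bone markers, and a pinnate fascicle (three muscle
#' markers) whose length, pinnation angle and architectural gear ratio are
#' known in closed form. Defaults emulate the study conditions: 150 fps,
#' ~10 mm maximum gape over ~0.33 s cycles, 0.1-0.2 mm class marker noise
#' (off by default; set `noise_sigma = 0.15`).
#'
#' The gape at the FC/SC and SO/FO junctions is `junction_gape_frac` of the
#' amplitude (default 20%, tooth-food contact at moderate gape): the
#' fast/slow junctions then carry the dominant acceleration steps while the
#' occlusal gape minimum stays sharply curved enough to localize under
#' marker noise.
#'
#' @param frame_rate frames/s.
#' @param n_cycles number of full gape cycles.
#' @param phase_durations named integer vector `c(fc=, sc=, so=, fo=)` of
#'   per-phase durations in frames (each >= 2).
#' @param max_gape maximum gape amplitude, mm.
#' @param junction_gape_frac gape at the fast/slow junctions as a fraction
#'   of `max_gape`.
#' @param duration_jitter,amplitude_jitter per-cycle multiplicative jitter
#'   (uniform in `1 +/- jitter`), applied under `seed`.
#' @param rotation_center 3-vector: jaw rotation center (mm, cranial frame).
#' @param cranial_markers,mandibular_markers named lists of reference 3-vector
#'   positions; `mandibular_markers` must contain `anterior_mandible` and the
#'   positions are the occlusion (minimum-gape) pose.
#' @param anterior_mandible name of the anterior mandibular marker.
#' @param coronoid_tip 3-vector: coronoid-process tip at occlusion.
#' @param m3_position 3-vector: superior-attachment marker (cranium side,
#'   static).
#' @param tendon_length central-tendon length `L_tendon` (mm); whole-muscle
#'   length must exceed it at every frame.
#' @param cmj_frac fraction of the muscle belly from m3 at which the CMJ
#'   marker rides the central tendon.
#' @param mode `"constant_thickness"` (fascicle rotates, `l sin(theta)`
#'   constant: AGR = 1/(k cos theta(t))), `"constant_pinnation"` (theta
#'   fixed: AGR = cos(theta0)/k) or `"prescribed_theta"`.
#' @param theta0_deg pinnation angle (deg) for `constant_pinnation`, and the
#'   occlusion-pose angle from which the thickness `t0` is derived for
#'   `constant_thickness`.
#' @param thickness_t0 muscle thickness `t0 = l sin(theta)` (mm) for
#'   `constant_thickness`; derived from `theta0_deg` at occlusion when `NULL`.
#' @param theta_fun function(gape_mm) -> theta deg, for `prescribed_theta`.
#' @param k tendon-to-muscle transmission factor (1 = inextensible tendon).
#' @param coronal_tilt_deg tilt of the fascicle plane out of the sagittal
#'   plane toward mediolateral, so both planar angle projections move.
#' @param noise_sigma Gaussian marker noise SD per coordinate, mm.
#' @param drift_rot_deg,drift_trans_mm amplitude of a slow rigid whole-scene
#'   drift (head motion in lab space); 0 disables.
#' @param seed integer seed for jitter and noise.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(
    frame_rate = 150,
    n_cycles = 5,
    phase_durations = c(fc = 12, sc = 13, so = 13, fo = 12),
    max_gape = 10,
    junction_gape_frac = 0.2,
    duration_jitter = 0,
    amplitude_jitter = 0,
    rotation_center = c(0, 0, 0),
    cranial_markers = list(cr1 = c(0, -15, 40), cr2 = c(0, 15, 40),
                           cr3 = c(-20, 0, 30), cr4 = c(32, 0, 48)),
    mandibular_markers = list(mand_ant = c(45, 0, -5),
                              mand2 = c(40, -8, -6),
                              mand3 = c(15, -10, -2),
                              mand4 = c(15, 10, 3)),
    anterior_mandible = "mand_ant",
    coronoid_tip = c(25, 8, 15),
    m3_position = c(20, 8, 60),
    tendon_length = 35,
    cmj_frac = 0.75,
    mode = c("constant_thickness", "constant_pinnation",
             "prescribed_theta"),
    theta0_deg = 20,
    thickness_t0 = NULL,
    theta_fun = NULL,
    k = 1,
    coronal_tilt_deg = 0,
    noise_sigma = 0,
    drift_rot_deg = 0,
    drift_trans_mm = 0,
    seed = 1L) {
  mode <- match.arg(mode)
  phase_durations <- phase_durations[c("fc", "sc", "so", "fo")]
  if (any(is.na(phase_durations)) || any(phase_durations < 2))
    stop("phase durations must be named fc/sc/so/fo, each >= 2 frames")
  if (theta0_deg <= 0 || theta0_deg >= 60)
    stop("'theta0_deg' must lie in (0, 60)")
  if (mode == "prescribed_theta" && !is.function(theta_fun))
    stop("'theta_fun' is required for mode 'prescribed_theta'")
  if (max_gape <= 0) stop("'max_gape' must be positive")
  stopifnot(k > 0, cmj_frac > 0, cmj_frac < 1, noise_sigma >= 0)
  for (set in list(cranial_markers, mandibular_markers)) {
    P <- do.call(rbind, set)
    sv <- svd(sweep(P, 2, colMeans(P)))$d
    if (sv[2] <= sv[1] * 1e-8)
      stop("marker set is collinear; markers must span a plane")
  }
  if (!anterior_mandible %in% names(mandibular_markers))
    stop("'anterior_mandible' must name a mandibular marker")
  structure(list(
    frame_rate = frame_rate, n_cycles = as.integer(n_cycles),
    phase_durations = stats::setNames(as.integer(phase_durations),
                                      c("fc", "sc", "so", "fo")),
    max_gape = max_gape, junction_gape_frac = junction_gape_frac,
    duration_jitter = duration_jitter, amplitude_jitter = amplitude_jitter,
    rotation_center = as.numeric(rotation_center),
    cranial_markers = cranial_markers,
    mandibular_markers = mandibular_markers,
    anterior_mandible = anterior_mandible,
    coronoid_tip = as.numeric(coronoid_tip),
    m3_position = as.numeric(m3_position),
    tendon_length = tendon_length, cmj_frac = cmj_frac, mode = mode,
    theta0_deg = theta0_deg, thickness_t0 = thickness_t0,
    theta_fun = theta_fun, k = k, coronal_tilt_deg = coronal_tilt_deg,
    noise_sigma = noise_sigma, drift_rot_deg = drift_rot_deg,
    drift_trans_mm = drift_trans_mm, seed = as.integer(seed)),
    class = "synthetic_scenario")
}

cos_segment <- function(v0, v1, d) {
  # C1 half-cosine ramp from v0 to v1 over d frames (frames 1..d, the
  # endpoint value v1 belongs to the next segment's start)
  s <- (seq_len(d) - 1) / d
  v0 + (v1 - v0) * (1 - cos(pi * s)) / 2
}

#' Build the four-phase synthetic gape trajectory
#'
#' Piecewise half-cosine gape: fast close from maximum gape to the junction
#' gape, slow close to zero, slow open to the junction gape, fast open back
#' to maximum gape. Velocity is continuous (zero) at every junction while
#' acceleration jumps there, giving the acceleration-based phase detector a
#' well-defined target. A slow-open/fast-open lead-in and a close lead-out
#' are prepended/appended so every cycle boundary is an interior gape
#' maximum.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `gape` (mm), `transitions` (data.frame: per-cycle
#'   absolute frames `start`, `fc_sc`, `min_gape`, `so_fo`, `end`), and
#'   `n_frames`.
#' @export
build_gape_trajectory <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  d0 <- sc$phase_durations
  g1f <- sc$junction_gape_frac
  amp <- function() sc$max_gape *
    (1 + stats::runif(1, -sc$amplitude_jitter, sc$amplitude_jitter))
  jit <- function(d) {
    if (sc$duration_jitter == 0) return(d)
    stats::setNames(pmax(2L, as.integer(round(
      d * (1 + stats::runif(length(d), -sc$duration_jitter,
                            sc$duration_jitter))))), names(d))
  }
  A0 <- amp()
  # lead-in: rise from occlusion to the first cycle's starting maximum
  lead <- c(cos_segment(0, g1f * A0, d0[["so"]]),
            cos_segment(g1f * A0, A0, d0[["fo"]]))
  gape <- lead
  trans <- NULL
  A_prev <- A0
  for (ci in seq_len(sc$n_cycles)) {
    d <- jit(d0)
    A_next <- amp()
    start <- length(gape) + 1L
    g1 <- g1f * A_prev
    g2 <- g1f * A_next
    gape <- c(gape,
              cos_segment(A_prev, g1, d[["fc"]]),
              cos_segment(g1, 0, d[["sc"]]),
              cos_segment(0, g2, d[["so"]]),
              cos_segment(g2, A_next, d[["fo"]]))
    trans <- rbind(trans, data.frame(
      start = start,
      fc_sc = start + d[["fc"]],
      min_gape = start + d[["fc"]] + d[["sc"]],
      so_fo = start + d[["fc"]] + d[["sc"]] + d[["so"]],
      end = start + sum(d)))
    A_prev <- A_next
  }
  # lead-out: descend to the junction gape so the last maximum is interior
  gape <- c(gape, cos_segment(A_prev, g1f * A_prev, d0[["fc"]]),
            g1f * A_prev)
  list(gape = gape, transitions = trans, n_frames = length(gape))
}

rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Build the rigid jaw scene for a gape trajectory
#'
#' Rotates the mandible about the mediolateral axis through the rotation
#' center by the angle `phi(t) = 2 asin(gape / (2 r))` (chord relation),
#' where `r` is the distance of the anterior mandibular marker from the
#' rotation axis, so that the marker's displacement from its occlusion
#' position equals the prescribed gape exactly. Cranial markers are static
#' in the cranial frame; an optional slow rigid drift moves the whole scene
#' in lab space.
#'
#' @param gape gape series, mm (e.g. from [build_gape_trajectory()]).
#' @param scenario a [synthetic_scenario()].
#' @return list with `dataset` (lab-frame [marker_dataset()], bones only),
#'   `transforms` (true mandibular `transform_series`, cranial frame),
#'   `phi` (radians), `tip` (true cranial-frame coronoid-tip trajectory),
#'   and `drift` (per-frame lab drift as a `transform_series`).
#' @export
build_jaw_scene <- function(gape, scenario) {
  sc <- scenario
  n <- length(gape)
  ml <- c(0, 1, 0)
  ctr <- sc$rotation_center
  p_ant <- sc$mandibular_markers[[sc$anterior_mandible]]
  rel <- p_ant - ctr
  r <- sqrt(sum((rel - sum(rel * ml) * ml)^2))
  if (any(gape > 2 * r + 1e-12))
    stop("gape exceeds 2r = ", round(2 * r, 2),
         " mm: unreachable by jaw rotation")
  phi <- 2 * asin(pmin(1, gape / (2 * r)))
  Rs <- array(NA_real_, c(3, 3, n))
  ts <- matrix(NA_real_, n, 3)
  tip <- matrix(NA_real_, n, 3)
  mand <- lapply(sc$mandibular_markers, function(p) matrix(NA_real_, n, 3))
  for (f in seq_len(n)) {
    R <- rotation_about_axis(ml, phi[f])
    Rs[, , f] <- R
    ts[f, ] <- ctr - as.numeric(R %*% ctr)
    tip[f, ] <- as.numeric(R %*% (sc$coronoid_tip - ctr)) + ctr
    for (nm in names(mand))
      mand[[nm]][f, ] <- as.numeric(
        R %*% (sc$mandibular_markers[[nm]] - ctr)) + ctr
  }
  markers <- c(lapply(sc$cranial_markers, function(p)
    matrix(rep(p, each = n), n, 3)), mand)
  drift <- scene_drift(n, sc)
  markers <- lapply(markers, function(m) apply_drift(m, drift))
  list(dataset = marker_dataset(markers, frame_rate = sc$frame_rate,
                                coordinate_frame_tag = "lab"),
       transforms = structure(list(R = Rs, t = ts, valid = rep(TRUE, n),
                                   reference_frame = NA_integer_),
                              class = "transform_series"),
       phi = phi, tip = tip, drift = drift)
}

scene_drift <- function(n, scenario) {
  sc <- scenario
  Rs <- array(NA_real_, c(3, 3, n))
  ts <- matrix(NA_real_, n, 3)
  ax <- c(1, 1, 1) / sqrt(3)
  t_rel <- (seq_len(n) - 1) / max(1, n - 1)
  for (f in seq_len(n)) {
    ang <- sc$drift_rot_deg * pi / 180 * sin(2 * pi * 0.7 * t_rel[f])
    Rs[, , f] <- rotation_about_axis(ax, ang)
    ts[f, ] <- sc$drift_trans_mm *
      c(sin(2 * pi * 0.5 * t_rel[f]), cos(2 * pi * 0.3 * t_rel[f]) - 1,
        sin(2 * pi * 0.9 * t_rel[f]))
  }
  structure(list(R = Rs, t = ts, valid = rep(TRUE, n),
                 reference_frame = 1L), class = "transform_series")
}

apply_drift <- function(traj, drift) {
  n <- nrow(traj)
  out <- traj
  for (f in seq_len(n))
    out[f, ] <- as.numeric(drift$R[, , f] %*% traj[f, ]) + drift$t[f, ]
  out
}

#' Build the muscle markers and ground truth for a jaw scene
#'
#' Places the three muscle markers: m3 static at the superior attachment;
#' m1 (CMJ) riding the central tendon at `cmj_frac` of the muscle belly
#' `L(t) - L_tendon` along the muscle line from m3 toward the coronoid tip;
#' m2 at the far end of a fascicle of length `l(t)` inclined at the
#' pinnation angle `theta(t)` to the muscle line, in the (optionally
#' tilted) sagittal fascicle plane. `l` and `theta` follow the scenario's
#' constraint mode, so the architectural gear ratio is known in closed
#' form: `cos(theta0)/k` for constant pinnation, `1/(k cos theta(t))` for
#' constant thickness.
#'
#' @param scene output of [build_jaw_scene()].
#' @param scenario the same [synthetic_scenario()].
#' @param gape the gape series the scene was built from.
#' @return list with `dataset` (lab-frame m1/m2/m3 [marker_dataset()]) and
#'   `truth` (class `synthetic_ground_truth`: per-frame `gape`, `l`,
#'   `theta_deg`, `L`, `agr`, plus the true `tip` trajectory).
#' @export
build_muscle_markers <- function(scene, scenario, gape) {
  sc <- scenario
  tip <- scene$tip
  n <- nrow(tip)
  m3 <- sc$m3_position
  dvec <- sweep(tip, 2, m3)
  L <- sqrt(rowSums(dvec^2))
  if (any(L <= sc$tendon_length))
    stop("whole-muscle length drops to the tendon length (",
         round(min(L), 2), " <= ", sc$tendon_length,
         " mm): tendon slack undefined")
  u <- dvec / L
  belly <- L - sc$tendon_length
  if (sc$mode == "constant_pinnation") {
    theta <- rep(sc$theta0_deg * pi / 180, n)
    l <- sc$k * belly / cos(theta)
    agr <- rep(cos(sc$theta0_deg * pi / 180) / sc$k, n)
  } else if (sc$mode == "constant_thickness") {
    t0 <- sc$thickness_t0
    if (is.null(t0))
      t0 <- tan(sc$theta0_deg * pi / 180) * sc$k * min(belly)
    l <- sqrt((sc$k * belly)^2 + t0^2)
    theta <- atan2(t0, sc$k * belly)
    agr <- 1 / (sc$k * cos(theta))
  } else {
    theta <- sc$theta_fun(gape) * pi / 180
    l <- sc$k * belly / cos(theta)
    dl <- c(NA, (l[3:n] - l[1:(n - 2)]) / 2, NA)
    dL <- c(NA, (L[3:n] - L[1:(n - 2)]) / 2, NA)
    agr <- ifelse(abs(dl) > 1e-9, dL / dl, NA_real_)
  }
  ml <- c(0, 1, 0)
  tau <- sc$coronal_tilt_deg * pi / 180
  m1 <- m2 <- matrix(NA_real_, n, 3)
  for (f in seq_len(n)) {
    uf <- u[f, ]
    w0 <- c(uf[3], 0, -uf[1])  # ml x u; in-plane orthonormal complement
    w0 <- w0 - sum(w0 * uf) * uf
    w0 <- w0 / sqrt(sum(w0^2))
    w <- cos(tau) * w0 + sin(tau) * ml
    w <- w - sum(w * uf) * uf
    w <- w / sqrt(sum(w^2))
    m1[f, ] <- m3 + sc$cmj_frac * belly[f] * uf
    m2[f, ] <- m1[f, ] + l[f] * (cos(theta[f]) * uf + sin(theta[f]) * w)
  }
  m3_traj <- matrix(rep(m3, each = n), n, 3)
  markers <- list(m1 = apply_drift(m1, scene$drift),
                  m2 = apply_drift(m2, scene$drift),
                  m3 = apply_drift(m3_traj, scene$drift))
  truth <- structure(list(gape = gape, l = l, theta_deg = theta * 180 / pi,
                          L = L, agr = agr, tip = tip),
                     class = "synthetic_ground_truth")
  list(dataset = marker_dataset(markers, frame_rate = sc$frame_rate,
                                coordinate_frame_tag = "lab"),
       truth = truth)
}

#' Add Gaussian marker noise
#'
#' Adds iid zero-mean Gaussian noise to every coordinate of every frame,
#' emulating finite marker spatial precision (0.1-0.2 mm for the recording
#' setup emulated here). Reproducible under `seed`; `sigma = 0` is the
#' identity.
#'
#' @param dataset a [marker_dataset()].
#' @param sigma noise SD per coordinate, mm.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return noisy [marker_dataset()].
#' @export
add_noise <- function(dataset, sigma, seed = NULL) {
  stopifnot(inherits(dataset, "marker_dataset"), sigma >= 0)
  if (sigma == 0) return(dataset)
  if (!is.null(seed)) set.seed(seed)
  dataset$markers <- lapply(dataset$markers, function(m)
    m + matrix(stats::rnorm(length(m), 0, sigma), nrow(m), 3))
  dataset
}

#' Simulate one complete recording with ground truth
#'
#' Composes [build_gape_trajectory()], [build_jaw_scene()],
#' [build_muscle_markers()] and [add_noise()] into one lab-frame marker
#' dataset (4 cranial + 4 mandibular + 3 muscle markers) plus its ground
#' truth.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `dataset`, `truth` (incl. `transitions` and the true
#'   mandibular `transforms`), `landmarks` (a [landmark_set()] with the
#'   coronoid tip and contralateral/gonial filler landmarks in
#'   reference-pose coordinates), and `config` (a matching
#'   [pipeline_config()]).
#' @export
simulate_recording <- function(scenario) {
  sc <- scenario
  gt <- build_gape_trajectory(sc)
  scene <- build_jaw_scene(gt$gape, sc)
  mus <- build_muscle_markers(scene, sc, gt$gape)
  all_markers <- c(scene$dataset$markers, mus$dataset$markers)
  ds <- marker_dataset(all_markers, frame_rate = sc$frame_rate,
                       coordinate_frame_tag = "lab")
  ds <- add_noise(ds, sc$noise_sigma, seed = sc$seed + 104729L)
  truth <- mus$truth
  truth$transitions <- gt$transitions
  truth$transforms <- scene$transforms
  truth$phi <- scene$phi
  tipref <- sc$coronoid_tip
  landmarks <- landmark_set(list(
    coronoid_R = tipref,
    coronoid_L = tipref * c(1, -1, 1),
    gonial_R = c(tipref[1] + 10, tipref[2], -8),
    gonial_L = c(tipref[1] + 10, -tipref[2], -8)))
  config <- pipeline_config(
    cranial = names(sc$cranial_markers),
    mandibular = names(sc$mandibular_markers),
    muscle = list(m1 = "m1", m2 = "m2", m3 = "m3"),
    anterior_mandible = sc$anterior_mandible,
    coronoid_landmark = "coronoid_R",
    mandibular_reference = do.call(rbind, sc$mandibular_markers),
    cranial_reference = do.call(rbind, sc$cranial_markers),
    frame_rate = sc$frame_rate)
  list(dataset = ds, truth = truth, landmarks = landmarks, config = config)
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat(sprintf("<synthetic_ground_truth> %d frames; gape 0-%.1f mm; theta %.1f-%.1f deg; AGR %.3f-%.3f\n",
              length(x$gape), max(x$gape), min(x$theta_deg),
              max(x$theta_deg), min(x$agr, na.rm = TRUE),
              max(x$agr, na.rm = TRUE)))
  invisible(x)
}

#' Write a simulated recording to disk
#'
#' Emits the marker CSV (XMALab dialect), the landmark CSV, a truth CSV
#' (frame, gape, l, theta_deg, L, agr) and a transitions CSV.
#'
#' @param recording output of [simulate_recording()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return named character vector of the written paths, invisibly.
#' @export
write_recording <- function(recording, dir, stem = "recording") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    markers = file.path(dir, paste0(stem, "_markers.csv")),
    landmarks = file.path(dir, paste0(stem, "_landmarks.csv")),
    truth = file.path(dir, paste0(stem, "_truth.csv")),
    transitions = file.path(dir, paste0(stem, "_transitions.csv")))
  write_marker_csv(recording$dataset, paths[["markers"]])
  write_landmarks(recording$landmarks, paths[["landmarks"]])
  tr <- recording$truth
  utils::write.csv(data.frame(frame = seq_along(tr$gape), gape = tr$gape,
                              l = tr$l, theta_deg = tr$theta_deg, L = tr$L,
                              agr = tr$agr),
                   paths[["truth"]], row.names = FALSE)
  utils::write.csv(tr$transitions, paths[["transitions"]],
                   row.names = FALSE)
  invisible(paths)
}

#' Simulate a complete feeding study
#'
#' Builds the default study design: 3 subjects x 5 foods. The two
#' mechanically challenging ("high-FMP") foods — popcorn seed and cashew —
#' are generated in constant-pinnation (reduced-rotation) mode, giving low
#' gear ratios (`AGR = cos(theta0) < 1`); the three compliant ("low-FMP")
#' foods — grape, marshmallow, apple — in constant-thickness
#' (fascicle-rotation) mode, giving high gear ratios (`1/cos(theta) > 1`).
#' Subjects differ deterministically in pinnation and gape amplitude;
#' per-cycle timing/amplitude jitter and marker noise are seeded.
#'
#' @param n_cycles cycles per recording (default 30).
#' @param noise_sigma marker noise SD, mm (default 0.15).
#' @param seed study seed; every recording derives its own sub-seed.
#' @param null_effect if `TRUE`, all foods use the high-FMP generator so
#'   the built-in FMP difference is exactly zero (type-I error checks).
#' @param dir if non-`NULL`, recordings are also written there via
#'   [write_recording()].
#' @return object of class `chew_study`: list with `index` (data.frame:
#'   subject, food, fmp, true_agr_mode) and `recordings` (list of
#'   [simulate_recording()] outputs, in index order).
#' @export
make_study <- function(n_cycles = 30, noise_sigma = 0.15, seed = 1L,
                       null_effect = FALSE, dir = NULL) {
  foods <- c(popcorn = "high", cashew = "high", grape = "low",
             marshmallow = "low", apple = "low")
  subjects <- c("capA", "capB", "capC")
  theta0 <- c(capA = 18, capB = 20, capC = 22)
  amp <- c(capA = 9, capB = 10, capC = 11)
  set.seed(seed)
  sub_seeds <- sample.int(1e7L, length(subjects) * length(foods))
  index <- NULL
  recordings <- list()
  i <- 0L
  for (s in subjects) for (fd in names(foods)) {
    i <- i + 1L
    high <- !null_effect && foods[[fd]] == "high"
    scen <- synthetic_scenario(
      n_cycles = n_cycles,
      max_gape = amp[[s]],
      mode = if (high || null_effect) "constant_pinnation"
             else "constant_thickness",
      theta0_deg = theta0[[s]],
      duration_jitter = 0.15, amplitude_jitter = 0.1,
      noise_sigma = noise_sigma,
      seed = sub_seeds[i])
    rec <- simulate_recording(scen)
    rec$config$subject <- s
    rec$config$food <- fd
    recordings[[i]] <- rec
    index <- rbind(index, data.frame(
      subject = s, food = fd, fmp = foods[[fd]],
      agr_mode = scen$mode, seed = sub_seeds[i]))
    if (!is.null(dir))
      write_recording(rec, dir, stem = paste0(s, "_", fd))
  }
  structure(list(index = index, recordings = recordings, seed = seed),
            class = "chew_study")
}

#' @export
print.chew_study <- function(x, ...) {
  cat("<chew_study> ", nrow(x$index), " recordings (",
      length(unique(x$index$subject)), " subjects x ",
      length(unique(x$index$food)), " foods)\n", sep = "")
  invisible(x)
}

#' Per-cycle AGR summaries for a processed recording
#'
#' Computes, for each gape cycle of a pipeline result, the LOESS-smoothed
#' per-cycle AGR series on the standardized grid and summarizes it by its
#' median over unmasked frames.
#'
#' @param result a [run_pipeline()] result.
#' @return data.frame with subject, food, cycle, agr_median,
#'   masked_fraction.
#' @export
cycle_agr_summary <- function(result) {
  cfg <- result$config
  pct <- seq(0, 100, length.out = cfg$n_standard)
  rows <- NULL
  for (i in seq_along(result$architecture)) {
    per <- result$architecture[[i]]
    fv <- standardize_cycle(per$fascicle_velocity, cfg$n_standard)
    mv <- standardize_cycle(per$muscle_velocity, cfg$n_standard)
    fvs <- loess_smooth(pct, fv, cfg$loess_span)
    mvs <- loess_smooth(pct, mv, cfg$loess_span)
    eps <- cfg$agr_epsilon_frac * max(abs(fvs), na.rm = TRUE)
    agr <- compute_agr(mvs, fvs, eps)
    rows <- rbind(rows, data.frame(
      subject = cfg$subject, food = cfg$food, cycle = i,
      agr_median = stats::median(agr$agr, na.rm = TRUE),
      masked_fraction = mean(!agr$mask)))
  }
  rows
}

#' Process a simulated study and test the FMP effect on AGR
#'
#' Runs [run_pipeline()] on every recording of a [make_study()] study,
#' summarizes per-cycle AGR, and fits the nested mixed model
#' `agr_median ~ fmp` with the study's subject/food/cycle nesting.
#'
#' @param study a `chew_study`.
#' @return list with `agr_table` (per-cycle AGR rows with the fmp label),
#'   `fit` (an `lme_result`) and `p_fmp` (the FMP term p-value).
#' @export
study_fmp_test <- function(study) {
  tabs <- lapply(study$recordings, function(rec) {
    res <- run_pipeline(rec$config, rec$dataset, rec$landmarks)
    cycle_agr_summary(res)
  })
  agr <- do.call(rbind, tabs)
  agr <- merge(agr, study$index[, c("subject", "food", "fmp")],
               by = c("subject", "food"))
  fit <- suppressWarnings(
    fit_lme(agr, lme_spec("agr_median", fixed = "fmp")))
  list(agr_table = agr, fit = fit, p_fmp = fit$anova$p[1])
}
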