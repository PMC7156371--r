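row_norm <- function(a, b) sqrt(rowSums((b - a)^2))

#' Fascicle length series
#'
#' Per-frame Euclidean distance between the central myotendinous junction
#' marker (m1) and the superficial fascicle termination marker (m2), in mm.
#' Frames where either marker is missing are `NA`; coincident markers give 0
#' and are flagged with a warning (degenerate).
#'
#' @param m1_traj,m2_traj n x 3 trajectory matrices.
#' @return numeric vector of lengths, mm.
#' @export
fascicle_length <- function(m1_traj, m2_traj) {
  if (nrow(m1_traj) != nrow(m2_traj))
    stop("trajectories must have equal length")
  l <- row_norm(m1_traj, m2_traj)
  if (any(l == 0, na.rm = TRUE))
    warning("degenerate fascicle length (coincident markers) at ",
            sum(l == 0, na.rm = TRUE), " frame(s)")
  as.numeric(l)
}

#' Whole-muscle length series
#'
#' Per-frame distance from the coronoid-process tip (a CT landmark moved
#' with the mandible) to the superior-attachment marker (m3), in mm.
#'
#' @param coronoid_tip_traj,m3_traj n x 3 trajectory matrices.
#' @return numeric vector of lengths, mm.
#' @export
muscle_length <- function(coronoid_tip_traj, m3_traj) {
  if (nrow(coronoid_tip_traj) != nrow(m3_traj))
    stop("trajectories must have equal length")
  as.numeric(row_norm(coronoid_tip_traj, m3_traj))
}

planar_angle <- function(v, r, ax1, ax2) {
  # angle between the projections of v and r onto span(ax1, ax2), folded
  # into [0, 90] degrees (pinnation is reported acute)
  v2 <- cbind(v %*% ax1, v %*% ax2)
  r2 <- cbind(r %*% ax1, r %*% ax2)
  nv <- sqrt(rowSums(v2^2))
  nr <- sqrt(rowSums(r2^2))
  ct <- abs(rowSums(v2 * r2)) / (nv * nr)
  ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  ang[nv < 1e-9 | nr < 1e-9] <- NA_real_
  as.numeric(ang)
}

#' Sagittal and coronal fascicle angles
#'
#' The fascicle vector (m2 - m1) and the muscle-line reference vector
#' (m3 - m1) are each projected onto the sagittal plane (anteroposterior and
#' superoinferior axes) and the coronal plane (mediolateral and
#' superoinferior axes) of the anatomical frame; the planar fascicle angle
#' is the angle between the two projections, folded into [0, 90] degrees.
#' Frames where a projection (or either 3D vector) shrinks below 1e-9 mm
#' are masked `NA`.
#'
#' @param m1,m2,m3 n x 3 trajectories of the CMJ, superficial-termination
#'   and superior-attachment markers.
#' @param frame an [anatomical_frame()].
#' @return list with numeric vectors `sagittal` and `coronal`, degrees.
#' @export
fascicle_angles <- function(m1, m2, m3, frame) {
  stopifnot(inherits(frame, "anatomical_frame"))
  v <- m2 - m1
  r <- m3 - m1
  list(sagittal = planar_angle(v, r, frame$axis_ap, frame$axis_si),
       coronal = planar_angle(v, r, frame$axis_ml, frame$axis_si))
}

#' Instantaneous velocity of a length series
#'
#' Temporal derivative by central differences on interior frames and
#' one-sided differences at the series ends, in mm/s: shortening is
#' negative, lengthening positive. Frames with a missing neighbour are
#' masked.
#'
#' @param length_series numeric vector, mm; length >= 3.
#' @param frame_rate frames/s.
#' @return numeric vector of velocities, mm/s.
#' @export
instantaneous_velocity <- function(length_series, frame_rate) {
  x <- as.numeric(length_series)
  n <- length(x)
  if (n < 3L) stop("need at least 3 frames for a velocity estimate")
  v <- rep(NA_real_, n)
  i <- 2:(n - 1)
  v[i] <- (x[i + 1] - x[i - 1]) / 2 * frame_rate
  v[1] <- (x[2] - x[1]) * frame_rate
  v[n] <- (x[n] - x[n - 1]) * frame_rate
  v
}

#' LOESS smoothing of a velocity curve
#'
#' Local linear regression with tricube weights over the nearest
#' `ceiling(span * n)` neighbours (via [stats::loess()] with `degree = 1`,
#' exact `"direct"` surface computation), evaluated on the input grid.
#' Deterministic; reproduces exactly linear data exactly.
#'
#' @param x_percent_cycle predictor grid (e.g. percent of gape cycle).
#' @param y response values.
#' @param span smoothing span in (0, 1]; default 0.25.
#' @return smoothed y on the same grid.
#' @export
loess_smooth <- function(x_percent_cycle, y, span = 0.25) {
  ok <- is.finite(x_percent_cycle) & is.finite(y)
  if (sum(ok) < 4L)
    stop("need at least 4 finite points for LOESS smoothing")
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
  fit <- stats::loess(y ~ x, data = data.frame(x = x_percent_cycle[ok],
                                               y = y[ok]),
                      span = span, degree = 1, family = "gaussian",
                      surface = "direct")
  out <- rep(NA_real_, length(y))
  out[ok] <- stats::predict(fit, newdata = data.frame(x = x_percent_cycle[ok]))
  out
}

#' Architectural gear ratio (AGR)
#'
#' The AGR is whole-muscle velocity divided by fascicle velocity. The ratio
#' is undefined near fascicle-velocity zero crossings (minimum and maximum
#' gape), so frames are masked unless the fascicle speed reaches `epsilon`
#' and the two velocities share sign; masked frames are reported, never
#' silently dropped.
#'
#' @param muscle_velocity,fascicle_velocity co-registered (smoothed)
#'   velocity series, mm/s.
#' @param epsilon positive fascicle-speed threshold, mm/s.
#' @return list with `agr` (numeric, `NA` where masked) and `mask` (logical,
#'   `TRUE` where the AGR is defined).
#' @export
compute_agr <- function(muscle_velocity, fascicle_velocity, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("'epsilon' must be a single positive number")
  if (length(muscle_velocity) != length(fascicle_velocity))
    stop("velocity series must be co-registered (equal length)")
  mask <- is.finite(muscle_velocity) & is.finite(fascicle_velocity) &
    abs(fascicle_velocity) >= epsilon &
    sign(muscle_velocity) == sign(fascicle_velocity)
  agr <- rep(NA_real_, length(mask))
  agr[mask] <- muscle_velocity[mask] / fascicle_velocity[mask]
  list(agr = agr, mask = mask)
}

#' Scale a series so its minimum (or maximum) is zero
#'
#' Subtracting the extremum preserves shape and derivatives and makes
#' architectural variables comparable between animals.
#'
#' @param series numeric vector (NA allowed).
#' @param mode `"min"` (default) or `"max"`.
#' @return shifted series.
#' @export
normalize_to_zero <- function(series, mode = c("min", "max")) {
  mode <- match.arg(mode)
  if (all(!is.finite(series))) stop("series has no finite values")
  ref <- if (mode == "min") min(series, na.rm = TRUE)
         else max(series, na.rm = TRUE)
  series - ref
}

#' Muscle bulging within a gape cycle
#'
#' Shape change of the muscle measured from the superficial fascicle marker
#' (m2): the range of its anteroposterior and mediolateral coordinates
#' within one gape cycle (the maximum excursion along each axis).
#'
#' @param m2_traj n x 3 trajectory of the superficial fascicle marker.
#' @param frame an [anatomical_frame()].
#' @param cycle_span integer vector of frame indices of one cycle.
#' @return list with `ap_range` and `ml_range`, mm (both >= 0).
#' @export
bulging <- function(m2_traj, frame, cycle_span) {
  stopifnot(inherits(frame, "anatomical_frame"))
  cycle_span <- as.integer(cycle_span)
  if (length(cycle_span) == 0L) stop("empty cycle span")
  seg <- m2_traj[cycle_span, , drop = FALSE]
  ap <- as.numeric(seg %*% frame$axis_ap)
  ml <- as.numeric(seg %*% frame$axis_ml)
  list(ap_range = diff(range(ap, na.rm = TRUE)),
       ml_range = diff(range(ml, na.rm = TRUE)))
}

#' Gape-controlled residuals
#'
#' Removes the pooled linear effect of gape distance from a variable,
#' separately within the jaw-closing and jaw-opening halves of the cycle
#' (the variable-gape relationship differs between halves). The alternative
#' route — gape as a fixed covariate in the mixed model — is available via
#' [fit_lme()].
#'
#' @param values numeric response.
#' @param gape gape distance, mm, same length.
#' @param closing logical, `TRUE` for jaw-closing frames.
#' @return residual series, same length.
#' @export
gape_control_residuals <- function(values, gape, closing) {
  stopifnot(length(values) == length(gape),
            length(values) == length(closing))
  out <- rep(NA_real_, length(values))
  for (half in c(TRUE, FALSE)) {
    idx <- which(closing == half & is.finite(values) & is.finite(gape))
    if (length(idx) >= 3L)
      out[idx] <- stats::residuals(stats::lm(values[idx] ~ gape[idx]))
  }
  out
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full marker-to-architecture pipeline
#'
#' Composition of the processing stages in their canonical order: gap
#' interpolation, zero-phase low-pass filtering, cranial-frame fixing,
#' mandibular rigid-body transforms, landmark animation, gape distance,
#' cycle segmentation and phase detection, architectural variables and
#' velocities (computed in real time, then standardized to the %cycle
#' grid), per-food averaging, LOESS smoothing and the AGR. Deterministic
#' given its inputs.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param markers a [marker_dataset()] or path to a marker CSV.
#' @param landmarks a [landmark_set()] or path to a landmark CSV; must
#'   contain the configured coronoid landmark.
#' @return list of class `chew_pipeline_result` with elements:
#'   \describe{
#'     \item{long_table}{tidy rows (subject, food, cycle, phase, pct_cycle,
#'       variable, value) on the standardized grid}
#'     \item{cycle_table}{one row per cycle: boundaries, transitions,
#'       duration, bulging ranges}
#'     \item{architecture}{per-cycle data.frames of per-frame variables}
#'     \item{food_average}{standardized per-food mean curves, the
#'       LOESS-smoothed velocities, the AGR series and its validity mask,
#'       and the masked-frame fraction}
#'     \item{gape, cycles, transforms}{intermediate objects}
#'   }
#' @export
run_pipeline <- function(config, markers, landmarks) {
  if (is.character(config)) config <- with_stage("config", read_config(config))
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(markers))
    markers <- with_stage("read_markers",
                          read_marker_csv(markers, config$frame_rate))
  if (is.character(landmarks))
    landmarks <- with_stage("read_landmarks", read_landmarks(landmarks))
  with_stage("roles", validate_roles(config, markers))
  if (!config$coronoid_landmark %in% names(landmarks))
    stop("[roles] coronoid landmark '", config$coronoid_landmark,
         "' not in landmark set")

  ds <- with_stage("interpolate", interpolate_gaps(markers,
                                                   config$max_gap_frames))
  ds <- with_stage("filter",
                   filter_dataset(ds, config$filter_cutoff_hz,
                                  config$filter_order))
  ds <- with_stage("cranial_frame",
                   fix_cranial_frame(ds, config$cranial,
                                     reference_points =
                                       config$cranial_reference))
  gape <- with_stage("gape", gape_distance(ds, config$anterior_mandible,
                                           axis_si = config$frame$axis_si))
  # register the mandible against the CT marker configuration when given
  # (landmarks then ride exact material points); otherwise against the
  # occlusion frame, which is the reference pose and sits mid-recording,
  # clear of filter edge effects
  tf <- with_stage("mandible_transforms",
                   mandible_transforms(ds, config$mandibular,
                                       reference_frame_index =
                                         gape$occlusion_frame,
                                       reference_points =
                                         config$mandibular_reference))
  lm_traj <- with_stage("landmarks", transform_landmarks(landmarks, tf))
  tip <- lm_traj[[config$coronoid_landmark]]
  cycles <- with_stage("cycles", build_cycles(
    gape, min_prominence = config$min_prominence_frac *
      diff(range(gape$gape, na.rm = TRUE))))
  if (length(cycles) == 0L)
    warning("no complete gape cycles found in recording")

  m1 <- marker_traj(ds, config$muscle$m1)
  m2 <- marker_traj(ds, config$muscle$m2)
  m3 <- marker_traj(ds, config$muscle$m3)
  fl <- with_stage("architecture", fascicle_length(m1, m2))
  ml <- with_stage("architecture", muscle_length(tip, m3))
  ang <- with_stage("architecture", fascicle_angles(m1, m2, m3,
                                                    config$frame))
  fv <- with_stage("architecture",
                   instantaneous_velocity(fl, config$frame_rate))
  mv <- with_stage("architecture",
                   instantaneous_velocity(ml, config$frame_rate))

  ns <- config$n_standard
  pct <- seq(0, 100, length.out = ns)
  std_vars <- c(gape = "gape", fascicle_length = "fascicle_length",
                muscle_length = "muscle_length",
                sagittal_angle = "sagittal_angle",
                coronal_angle = "coronal_angle",
                fascicle_velocity = "fascicle_velocity",
                muscle_velocity = "muscle_velocity")
  arch <- list()
  cyc_rows <- list()
  long_rows <- list()
  std <- list()
  for (v in names(std_vars)) std[[v]] <- list()
  for (i in seq_along(cycles)) {
    cy <- cycles[[i]]
    span <- cy$start_frame:cy$end_frame
    per_frame <- data.frame(
      frame = span,
      gape = gape$gape[span],
      fascicle_length = fl[span], muscle_length = ml[span],
      sagittal_angle = ang$sagittal[span], coronal_angle = ang$coronal[span],
      fascicle_velocity = fv[span], muscle_velocity = mv[span],
      phase = cy$phase)
    arch[[i]] <- per_frame
    bl <- bulging(m2, config$frame, span)
    cyc_rows[[i]] <- data.frame(
      subject = config$subject, food = config$food, cycle_index = i,
      start_frame = cy$start_frame, fc_sc = cy$fc_sc_frame,
      min_gape = cy$min_gape_frame, so_fo = cy$so_fo_frame,
      end_frame = cy$end_frame,
      duration_s = (cy$end_frame - cy$start_frame) / config$frame_rate,
      bulge_ap_mm = bl$ap_range, bulge_ml_mm = bl$ml_range)
    # standardized phase label: carry each original frame's label to the
    # nearest standardized position
    src_pos <- seq(1, length(span), length.out = ns)
    std_phase <- cy$phase[round(src_pos)]
    for (v in names(std_vars)) {
      sv <- standardize_cycle(per_frame[[v]], ns)
      std[[v]][[i]] <- sv
      long_rows[[length(long_rows) + 1L]] <- data.frame(
        subject = config$subject, food = config$food, cycle = i,
        phase = std_phase, pct_cycle = pct, variable = v, value = sv)
    }
  }

  food_average <- NULL
  if (length(cycles) > 0L) {
    avg <- function(v) colMeans(do.call(rbind, std[[v]]))
    fvm <- avg("fascicle_velocity")
    mvm <- avg("muscle_velocity")
    fvs <- loess_smooth(pct, fvm, config$loess_span)
    mvs <- loess_smooth(pct, mvm, config$loess_span)
    eps <- config$agr_epsilon_frac * max(abs(fvs), na.rm = TRUE)
    agr <- compute_agr(mvs, fvs, eps)
    food_average <- list(
      pct_cycle = pct,
      n_cycles = length(cycles),
      gape = avg("gape"),
      fascicle_length = avg("fascicle_length"),
      muscle_length = avg("muscle_length"),
      sagittal_angle = avg("sagittal_angle"),
      coronal_angle = avg("coronal_angle"),
      fascicle_velocity = fvm, muscle_velocity = mvm,
      fascicle_velocity_smooth = fvs, muscle_velocity_smooth = mvs,
      agr = agr$agr, agr_mask = agr$mask,
      agr_epsilon = eps,
      agr_masked_fraction = mean(!agr$mask))
  }

  structure(list(
    long_table = if (length(long_rows)) do.call(rbind, long_rows)
                 else NULL,
    cycle_table = if (length(cyc_rows)) do.call(rbind, cyc_rows) else NULL,
    architecture = arch,
    food_average = food_average,
    gape = gape, cycles = cycles, transforms = tf,
    dataset_cranial = ds, landmark_trajectories = lm_traj,
    config = config), class = "chew_pipeline_result")
}

#' @export
print.chew_pipeline_result <- function(x, ...) {
  cat("<chew_pipeline_result> subject ", x$config$subject, ", food ",
      x$config$food, ": ", length(x$cycles), " gape cycles\n", sep = "")
  if (!is.null(x$food_average))
    cat(sprintf("  AGR defined on %.0f%% of the standardized cycle (mask fraction %.2f)\n",
                100 * mean(x$food_average$agr_mask),
                x$food_average$agr_masked_fraction))
  invisible(x)
}
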