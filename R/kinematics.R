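#' Zero-phase low-pass Butterworth filter
#'
#' Two-pass (forward-backward) Butterworth filtering of a uniformly sampled
#' series, with odd-reflection edge padding of `3 * order` samples on each
#' side. The two passes cancel phase lag exactly (the effective magnitude
#' response is the squared one-pass response), so peaks are not shifted in
#' time — a prerequisite for acceleration-based phase-transition timing.
#' DC gain is 1: a constant series passes through unchanged.
#'
#' @param series finite numeric vector (or matrix: columns filtered
#'   independently).
#' @param cutoff_hz cutoff frequency in Hz, below Nyquist.
#' @param order filter order (default 4).
#' @param frame_rate sampling rate in frames/s.
#' @return filtered series, same shape as the input.
#' @export
butterworth_lowpass <- function(series, cutoff_hz, order = 4,
                                frame_rate = 150) {
  if (is.matrix(series)) {
    for (k in seq_len(ncol(series)))
      series[, k] <- butterworth_lowpass(series[, k], cutoff_hz, order,
                                         frame_rate)
    return(series)
  }
  if (cutoff_hz >= frame_rate / 2)
    stop("cutoff (", cutoff_hz, " Hz) must be below the Nyquist frequency (",
         frame_rate / 2, " Hz)")
  n <- length(series)
  pad <- 3L * order
  if (n <= pad)
    stop("series too short to filter: need more than ", pad, " samples")
  if (!all(is.finite(series)))
    stop("series contains non-finite values; interpolate gaps first")
  bf <- signal::butter(order, cutoff_hz / (frame_rate / 2), type = "low")
  xp <- c(2 * series[1] - series[(pad + 1):2],
          series,
          2 * series[n] - series[(n - 1):(n - pad)])
  # subtract the leading value before each pass so the filter's implicit
  # zero history sees no step (DC gain is 1, so the offset passes through)
  one_pass <- function(x) {
    as.numeric(signal::filter(bf, x - x[1])) + x[1]
  }
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Low-pass filter every marker coordinate of a dataset
#'
#' Applies [butterworth_lowpass()] to each coordinate of each marker over
#' contiguous observed (non-`NA`) runs; runs too short to filter are left
#' missing. Gap interpolation ([interpolate_gaps()]) should be run first.
#'
#' @param dataset a [marker_dataset()].
#' @param cutoff_hz,order filter settings.
#' @return filtered [marker_dataset()].
#' @export
filter_dataset <- function(dataset, cutoff_hz = 30, order = 4) {
  stopifnot(inherits(dataset, "marker_dataset"))
  pad <- 3L * order
  dataset$markers <- lapply(dataset$markers, function(m) {
    for (k in 1:3) {
      x <- m[, k]
      r <- rle(!is.na(x))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in seq_along(r$values)) {
        if (!r$values[j]) next
        idx <- starts[j]:ends[j]
        if (length(idx) > pad)
          x[idx] <- butterworth_lowpass(x[idx], cutoff_hz, order,
                                        dataset$frame_rate)
        else
          x[idx] <- NA_real_  # too short to filter reliably
      }
      m[, k] <- x
    }
    m
  })
  dataset
}

#' Rigid-body transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1 within 1e-8).
#' @param translation 3-vector, mm.
#' @return object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal (within 1e-8)")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation matrix must have determinant +1")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang * 180 / pi, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Rotation angle of a rigid transform
#' @param transform a [rigid_transform()].
#' @return rotation angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(transform) {
  tr <- sum(diag(transform$R))
  acos(min(1, max(-1, (tr - 1) / 2)))
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix or 3-vector.
#' @return transformed points, same shape.
#' @export
apply_transform <- function(transform, points) {
  if (is.null(dim(points)))
    return(as.numeric(transform$R %*% points + transform$t))
  t(transform$R %*% t(points) + transform$t)
}

#' Least-squares rigid registration of paired point sets (Kabsch/SVD)
#'
#' Finds the rotation `R` (det +1) and translation `t` minimizing
#' `sum_i || R p_i + t - q_i ||^2` over paired points `p` (reference) and
#' `q` (frame), via singular value decomposition of the cross-covariance of
#' the centered sets, with the reflection case corrected by sign flip of the
#' smallest singular direction.
#'
#' @param reference_points n x 3 matrix, n >= 3, non-collinear.
#' @param frame_points n x 3 matrix, paired row-wise with
#'   `reference_points`.
#' @return a [rigid_transform()] mapping reference coordinates to frame
#'   coordinates.
#' @export
fit_rigid_transform <- function(reference_points, frame_points) {
  P <- as.matrix(reference_points)
  Q <- as.matrix(frame_points)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stop("point sets must be paired n x 3 matrices")
  if (nrow(P) < 3L)
    stop("degenerate configuration: at least 3 paired points are required")
  if (!all(is.finite(P)) || !all(is.finite(Q)))
    stop("point sets contain non-finite coordinates")
  pbar <- colMeans(P)
  qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar)
  Qc <- sweep(Q, 2, qbar)
  sv_p <- svd(Pc)$d
  if (sv_p[2] <= max(sv_p[1] * 1e-8, 1e-12))
    stop("degenerate configuration: reference points are (near-)collinear")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- qbar - as.numeric(R %*% pbar)
  rigid_transform(R, t)
}

#' Root-mean-square registration residual
#' @param transform a [rigid_transform()] mapping `reference_points` onto
#'   `frame_points`.
#' @param reference_points,frame_points paired n x 3 matrices.
#' @return RMSD in mm.
#' @export
registration_rmsd <- function(transform, reference_points, frame_points) {
  pred <- apply_transform(transform, as.matrix(reference_points))
  sqrt(mean(rowSums((pred - as.matrix(frame_points))^2)))
}

marker_block <- function(dataset, roles, frame) {
  do.call(rbind, lapply(roles, function(nm) dataset$markers[[nm]][frame, ]))
}

#' Fix the cranial reference frame
#'
#' Registers the cranial markers of every frame onto their configuration at
#' a reference frame and applies the per-frame corrective transform to all
#' markers, so that the cranium becomes stationary (up to residual marker
#' noise) and all motion is expressed in a cranium-fixed coordinate system.
#'
#' @param dataset a [marker_dataset()] in lab coordinates.
#' @param cranial_roles names of the 4 cranial markers.
#' @param reference_frame_index frame index whose cranial configuration
#'   defines the fixed frame; default: first frame at which all cranial and
#'   mandibular markers are observed (here, all markers). Ignored when
#'   `reference_points` is given.
#' @param reference_points optional matrix of the cranial marker positions
#'   in the CT/landmark coordinate system (rownames matching
#'   `cranial_roles`); when supplied, all output coordinates live directly
#'   in that anatomical coordinate system.
#' @return a [marker_dataset()] tagged `"cranial"`. Frames with a missing
#'   cranial marker are emitted as missing for every marker.
#' @export
fix_cranial_frame <- function(dataset, cranial_roles,
                              reference_frame_index = NULL,
                              reference_points = NULL) {
  stopifnot(inherits(dataset, "marker_dataset"))
  missing_roles <- setdiff(cranial_roles, names(dataset$markers))
  if (length(missing_roles) > 0)
    stop("cranial marker(s) not in dataset: ",
         paste(missing_roles, collapse = ", "))
  cr_complete <- rep(TRUE, dataset$n_frames)
  for (nm in cranial_roles)
    cr_complete <- cr_complete & stats::complete.cases(dataset$markers[[nm]])
  if (!is.null(reference_points)) {
    reference_points <- as.matrix(reference_points)
    if (is.null(rownames(reference_points)) ||
        !all(cranial_roles %in% rownames(reference_points)))
      stop("'reference_points' must have rownames covering the cranial roles")
    ref <- reference_points[cranial_roles, , drop = FALSE]
  } else {
    complete <- rep(TRUE, dataset$n_frames)
    for (nm in names(dataset$markers))
      complete <- complete & stats::complete.cases(dataset$markers[[nm]])
    if (is.null(reference_frame_index)) {
      if (!any(complete)) stop("no frame with all markers observed")
      reference_frame_index <- which(complete)[1]
    }
    if (!cr_complete[reference_frame_index])
      stop("cranial markers missing at reference frame ",
           reference_frame_index)
    ref <- marker_block(dataset, cranial_roles, reference_frame_index)
  }
  out <- dataset$markers
  for (f in seq_len(dataset$n_frames)) {
    if (!cr_complete[f]) {
      for (nm in names(out)) out[[nm]][f, ] <- NA_real_
      next
    }
    cur <- marker_block(dataset, cranial_roles, f)
    tf <- tryCatch(fit_rigid_transform(cur, ref), error = function(e)
      stop("degenerate cranial configuration at frame ", f, ": ",
           conditionMessage(e)))
    for (nm in names(out))
      out[[nm]][f, ] <- apply_transform(tf, dataset$markers[[nm]][f, ])
  }
  marker_dataset(out, frame_rate = dataset$frame_rate,
                 coordinate_frame_tag = "cranial")
}

#' Per-frame mandibular rigid-body transforms
#'
#' Fits, for every frame of a cranium-fixed dataset, the rigid transform
#' carrying the mandibular markers from their reference-frame configuration
#' to their current configuration. The transform at the reference frame is
#' the identity; CT landmarks expressed in reference-pose coordinates can be
#' moved with the mandible via [transform_landmarks()].
#'
#' @param dataset_cranial a cranium-fixed [marker_dataset()].
#' @param mandibular_roles names of the 4 mandibular markers.
#' @param reference_frame_index reference frame; default: first frame with
#'   all mandibular markers observed. Ignored when `reference_points` is
#'   given.
#' @param reference_points optional matrix of the mandibular marker
#'   positions in the CT/landmark coordinate system (one row per marker,
#'   rownames matching `mandibular_roles`). When supplied, transforms map
#'   CT coordinates directly onto each frame, so CT landmarks ride the
#'   correct material points even if the cranial frame is a rigid offset
#'   away from the CT frame.
#' @return object of class `transform_series`: list with `R` (3 x 3 x n
#'   array), `t` (n x 3 matrix), `valid` (logical), `reference_frame`.
#' @export
mandible_transforms <- function(dataset_cranial, mandibular_roles,
                                reference_frame_index = NULL,
                                reference_points = NULL) {
  stopifnot(inherits(dataset_cranial, "marker_dataset"))
  n <- dataset_cranial$n_frames
  ok <- rep(TRUE, n)
  for (nm in mandibular_roles) {
    if (!nm %in% names(dataset_cranial$markers))
      stop("mandibular marker '", nm, "' not in dataset")
    ok <- ok & stats::complete.cases(dataset_cranial$markers[[nm]])
  }
  if (!is.null(reference_points)) {
    reference_points <- as.matrix(reference_points)
    if (is.null(rownames(reference_points)) ||
        !all(mandibular_roles %in% rownames(reference_points)))
      stop("'reference_points' must have rownames covering the mandibular roles")
    ref <- reference_points[mandibular_roles, , drop = FALSE]
    reference_frame_index <- NA_integer_
  } else {
    if (is.null(reference_frame_index)) {
      if (!any(ok)) stop("no frame with all mandibular markers observed")
      reference_frame_index <- which(ok)[1]
    }
    if (!ok[reference_frame_index])
      stop("mandibular markers missing at reference frame ",
           reference_frame_index)
    ref <- marker_block(dataset_cranial, mandibular_roles,
                        reference_frame_index)
  }
  Rs <- array(NA_real_, c(3, 3, n))
  ts <- matrix(NA_real_, n, 3)
  for (f in seq_len(n)) {
    if (!ok[f]) next
    cur <- marker_block(dataset_cranial, mandibular_roles, f)
    tf <- tryCatch(fit_rigid_transform(ref, cur), error = function(e)
      stop("degenerate mandibular configuration at frame ", f, ": ",
           conditionMessage(e)))
    Rs[, , f] <- tf$R
    ts[f, ] <- tf$t
  }
  structure(list(R = Rs, t = ts, valid = ok,
                 reference_frame = reference_frame_index),
            class = "transform_series")
}

#' @export
print.transform_series <- function(x, ...) {
  cat("<transform_series> ", dim(x$R)[3], " frames (",
      sum(x$valid), " valid), reference frame ", x$reference_frame, "\n",
      sep = "")
  invisible(x)
}

#' Extract one frame of a transform series
#' @param series a `transform_series`.
#' @param frame frame index.
#' @return a [rigid_transform()].
#' @export
transform_at <- function(series, frame) {
  if (!series$valid[frame]) stop("no valid transform at frame ", frame)
  rigid_transform(series$R[, , frame], series$t[frame, ])
}

#' Move reference-pose landmarks with the mandible
#'
#' @param landmarks a [landmark_set()] in reference-pose coordinates.
#' @param transforms a `transform_series` from [mandible_transforms()].
#' @return named list of n x 3 trajectory matrices, `NA` rows at invalid
#'   frames.
#' @export
transform_landmarks <- function(landmarks, transforms) {
  n <- dim(transforms$R)[3]
  lapply(landmarks, function(p) {
    p <- as.numeric(p)
    traj <- matrix(NA_real_, n, 3)
    for (f in seq_len(n)) {
      if (!transforms$valid[f]) next
      traj[f, ] <- as.numeric(transforms$R[, , f] %*% p + transforms$t[f, ])
    }
    colnames(traj) <- c("X", "Y", "Z")
    traj
  })
}

#' Locate the maximum-occlusion frame of a recording
#'
#' The closed-jaw (maximum occlusion) reference is found from the anterior
#' mandibular marker alone: frames are scored along the first principal
#' axis of the trajectory (which gape motion dominates); of the two
#' trajectory ends, the one lying superior along the superoinferior axis is
#' the closed jaw (jaw depression lowers the anterior mandible); and the
#' occlusion frame is the extreme of the lightly smoothed score at that end
#' — the jaw retraces the same arc through occlusion, so the reference must
#' be an arc vertex, not merely a point near the closed cluster.
#'
#' @param traj n x 3 trajectory of the anterior mandibular marker (cranial
#'   frame).
#' @param axis_si unit superoinferior axis (pointing superior) used to tell
#'   the closed end from the open end.
#' @return frame index of maximum occlusion.
#' @export
find_occlusion_frame <- function(traj, axis_si = c(0, 0, 1)) {
  obs <- which(stats::complete.cases(traj))
  if (length(obs) < 3L) stop("too few observed frames to locate occlusion")
  X <- traj[obs, , drop = FALSE]
  ctr <- colMeans(X)
  s <- svd(sweep(X, 2, ctr), nu = 0, nv = 1)
  score <- as.numeric(sweep(X, 2, ctr) %*% s$v[, 1])
  rng <- range(score)
  tol <- 0.05 * (rng[2] - rng[1])
  if (tol == 0) return(obs[1])  # stationary marker: any frame is occlusion
  lo <- score <= rng[1] + tol
  hi <- score >= rng[2] - tol
  si <- as.numeric(X %*% axis_si)
  closed_lo <- mean(si[lo]) >= mean(si[hi])
  ssm <- score
  if (length(score) >= 5)
    ssm <- stats::filter(score, rep(1 / 5, 5), sides = 2)
  ssm[is.na(ssm)] <- score[is.na(ssm)]
  obs[if (closed_lo) which.min(ssm) else which.max(ssm)]
}

#' Gape distance series
#'
#' Gape distance is the Euclidean displacement of the anterior mandibular
#' marker from its position at maximum occlusion, computed in the
#' cranium-fixed frame.
#'
#' @param dataset_cranial cranium-fixed [marker_dataset()].
#' @param anterior_mandible_role marker name.
#' @param occlusion_frame occlusion frame index; found with
#'   [find_occlusion_frame()] when `NULL`.
#' @param axis_si superoinferior axis passed to [find_occlusion_frame()].
#' @return object of class `gape_series`: list with `gape` (mm, `NA` at
#'   missing frames), `frame_rate`, `occlusion_frame`,
#'   `occlusion_reference` (3-vector).
#' @export
gape_distance <- function(dataset_cranial, anterior_mandible_role,
                          occlusion_frame = NULL, axis_si = c(0, 0, 1)) {
  traj <- marker_traj(dataset_cranial, anterior_mandible_role)
  if (is.null(occlusion_frame))
    occlusion_frame <- find_occlusion_frame(traj, axis_si)
  ref <- traj[occlusion_frame, ]
  if (any(is.na(ref)))
    stop("anterior mandibular marker missing at occlusion frame ",
         occlusion_frame)
  g <- sqrt(rowSums(sweep(traj, 2, ref)^2))
  structure(list(gape = as.numeric(g),
                 frame_rate = dataset_cranial$frame_rate,
                 occlusion_frame = occlusion_frame,
                 occlusion_reference = as.numeric(ref)),
            class = "gape_series")
}

#' @export
print.gape_series <- function(x, ...) {
  cat(sprintf("<gape_series> %d frames @ %g fps, range %.2f-%.2f mm, occlusion frame %d\n",
              length(x$gape), x$frame_rate, min(x$gape, na.rm = TRUE),
              max(x$gape, na.rm = TRUE), x$occlusion_frame))
  invisible(x)
}

#' Export a transform series as a plain table
#' @param transforms a `transform_series`.
#' @return data.frame with frame, row-major rotation entries r11..r33 and
#'   translation tx, ty, tz.
#' @export
transforms_as_table <- function(transforms) {
  n <- dim(transforms$R)[3]
  m <- t(vapply(seq_len(n), function(f) {
    c(as.numeric(t(transforms$R[, , f])), transforms$t[f, ])
  }, numeric(12)))
  colnames(m) <- c("r11", "r12", "r13", "r21", "r22", "r23",
                   "r31", "r32", "r33", "tx", "ty", "tz")
  data.frame(frame = seq_len(n), m)
}
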