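#' Local maxima with topographic prominence
#'
#' Internal helper for cycle segmentation: strict local maxima (first frame
#' of any plateau) whose prominence — height above the higher of the two
#' lowest points separating the peak from higher terrain (or the series
#' ends) — reaches a threshold.
#'
#' @param x numeric vector (NA allowed; NA frames cannot host a peak).
#' @param min_prominence prominence threshold, same units as `x`.
#' @return integer vector of peak indices.
#' @keywords internal
find_peaks <- function(x, min_prominence) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (is.na(x[i]) || is.na(x[i - 1]) || is.na(x[i + 1])) next
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) {
      # plateau: require a strict drop after the plateau
      j <- i
      while (j < n && !is.na(x[j + 1]) && x[j + 1] == x[i]) j <- j + 1L
      if (j < n && !is.na(x[j + 1]) && x[j + 1] < x[i]) cand <- c(cand, i)
    }
  }
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    lo_l <- x[i]
    j <- i - 1L
    while (j >= 1L && !is.na(x[j]) && x[j] <= x[i]) {
      lo_l <- min(lo_l, x[j]); j <- j - 1L
    }
    lo_r <- x[i]
    j <- i + 1L
    while (j <= n && !is.na(x[j]) && x[j] <= x[i]) {
      lo_r <- min(lo_r, x[j]); j <- j + 1L
    }
    keep[k] <- (x[i] - max(lo_l, lo_r)) >= min_prominence
  }
  cand[keep]
}

#' Segment a gape series into gape cycles
#'
#' A gape cycle runs from one gape maximum to the next ("sequential
#' departure from, and return to, the point of maximum gape"). Cycle
#' boundaries are local gape maxima with prominence at least
#' `min_prominence`; cycles containing missing frames are dropped, and
#' because boundaries must be interior maxima, cycles touching the recording
#' boundaries are never produced.
#'
#' @param gape_series a [gape_distance()] result, or a numeric vector.
#' @param min_prominence minimum peak prominence in mm; default 20% of the
#'   observed gape range.
#' @return data.frame with columns `start_frame`, `end_frame` (both at
#'   maximum gape), possibly empty.
#' @export
segment_cycles <- function(gape_series, min_prominence = NULL) {
  g <- if (inherits(gape_series, "gape_series")) gape_series$gape
       else as.numeric(gape_series)
  if (is.null(min_prominence))
    min_prominence <- 0.2 * diff(range(g, na.rm = TRUE))
  pk <- find_peaks(g, min_prominence)
  if (length(pk) < 2L)
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  spans <- data.frame(start_frame = pk[-length(pk)], end_frame = pk[-1])
  ok <- vapply(seq_len(nrow(spans)), function(i) {
    !anyNA(g[spans$start_frame[i]:spans$end_frame[i]])
  }, logical(1))
  spans[ok, , drop = FALSE]
}

box_smooth <- function(x, k) {
  # centered moving average; the window shrinks near the series ends
  n <- length(x)
  k <- as.integer(k)
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  half <- (k - 1L) %/% 2L
  s <- stats::filter(x, rep(1 / k, k), sides = 2)
  for (j in seq_len(half)) {
    s[j] <- mean(x[1:(j + half)])
    s[n - j + 1L] <- mean(x[(n - j + 1L - half):n])
  }
  as.numeric(s)
}

#' Detect the four gape-cycle phases from jaw acceleration
#'
#' Within one max-gape-to-max-gape cycle, the transitions are read off
#' instantaneous changes in jaw vertical acceleration (the second derivative
#' of gape, central differences, lightly smoothed): minimum gape (the SC/SO
#' transition) is the argmin of the smoothed gape; the FC/SC transition is
#' the strongest abrupt drop in acceleration during jaw closing (jaw
#' elevation braking as the teeth meet the food), located as the extremum of
#' the acceleration's derivative; the SO/FO transition is the strongest
#' abrupt rise in acceleration during jaw opening. Acceleration steps are
#' searched within a mid-gape band (8-60% of the half-cycle's gape
#' excursion): the gape extrema at maximum gape and at occlusion carry their
#' own acceleration corners that are not phase transitions. Ties take the
#' earliest frame.
#'
#' @param cycle_gape numeric gape vector spanning max -> min -> max gape.
#' @param frame_rate frames/s (kept for interface symmetry; detection is
#'   frame-based).
#' @param accel_smooth odd width (frames) of the centered moving average
#'   applied to gape and acceleration before localization; default 5.
#' @return list with integer elements `fc_sc_frame`, `min_gape_frame`,
#'   `so_fo_frame` (indices within the cycle, strictly ordered).
#' @export
detect_phases <- function(cycle_gape, frame_rate = 150, accel_smooth = 5) {
  g <- as.numeric(cycle_gape)
  n <- length(g)
  if (n < 8L) stop("cycle too short for phase detection (need >= 8 frames)")
  if (anyNA(g)) stop("cycle contains missing gape frames")
  i <- 2:(n - 1)
  gs <- box_smooth(g, accel_smooth)
  d1 <- c(NA, (gs[i + 1] - gs[i - 1]) / 2, NA)
  d1[1] <- gs[2] - gs[1]; d1[n] <- gs[n] - gs[n - 1]
  d2 <- c(NA, g[i + 1] - 2 * g[i] + g[i - 1], NA)
  d2[1] <- d2[2]; d2[n] <- d2[n - 1]
  d2 <- box_smooth(d2, accel_smooth)
  jerk <- c(NA, (d2[i + 1] - d2[i - 1]) / 2, NA)
  jerk[1] <- jerk[2]; jerk[n] <- jerk[n - 1]
  min_gape <- which.min(gs)
  if (min_gape <= 2L || min_gape >= n - 1L)
    stop("minimum gape at cycle boundary; not a max->min->max cycle")
  band <- function(idx) {
    lo <- gs[min_gape]
    rng <- max(gs[idx]) - lo
    w <- idx[gs[idx] >= lo + 0.08 * rng & gs[idx] <= lo + 0.6 * rng]
    if (length(w) == 0L) w <- idx  # degenerate profile: fall back
    w
  }
  w1 <- band(2:(min_gape - 1L))
  fc_sc <- w1[which.min(jerk[w1])]
  w2 <- band((min_gape + 1L):(n - 1L))
  so_fo <- w2[which.max(jerk[w2])]
  list(fc_sc_frame = fc_sc, min_gape_frame = min_gape,
       so_fo_frame = so_fo)
}

#' Per-frame phase labels for a segmented cycle
#'
#' @param n cycle length in frames.
#' @param fc_sc_frame,min_gape_frame,so_fo_frame transition frames from
#'   [detect_phases()].
#' @return character vector of length `n` with labels FC, SC, SO, FO; the
#'   four phases partition the cycle.
#' @export
phase_labels <- function(n, fc_sc_frame, min_gape_frame, so_fo_frame) {
  stopifnot(1 < fc_sc_frame, fc_sc_frame < min_gape_frame,
            min_gape_frame < so_fo_frame, so_fo_frame <= n)
  lab <- character(n)
  lab[1:(fc_sc_frame - 1L)] <- "FC"
  lab[fc_sc_frame:(min_gape_frame - 1L)] <- "SC"
  lab[min_gape_frame:(so_fo_frame - 1L)] <- "SO"
  lab[so_fo_frame:n] <- "FO"
  lab
}

#' Assemble gape cycles with detected phase boundaries
#'
#' Convenience composition of [segment_cycles()] and [detect_phases()].
#'
#' @param gape_series a [gape_distance()] result.
#' @param min_prominence passed to [segment_cycles()].
#' @param accel_smooth passed to [detect_phases()].
#' @return list of `gape_cycle` objects: each has `start_frame`,
#'   `end_frame`, `fc_sc_frame`, `min_gape_frame`, `so_fo_frame` (absolute
#'   frame indices), `gape` (the cycle's gape vector), `phase` (per-frame
#'   labels) and `frame_rate`. Cycles whose phase detection fails are
#'   skipped with a warning.
#' @export
build_cycles <- function(gape_series, min_prominence = NULL,
                         accel_smooth = 5) {
  spans <- segment_cycles(gape_series, min_prominence)
  out <- list()
  for (i in seq_len(nrow(spans))) {
    s <- spans$start_frame[i]; e <- spans$end_frame[i]
    g <- gape_series$gape[s:e]
    ph <- tryCatch(detect_phases(g, gape_series$frame_rate, accel_smooth),
                   error = function(err) NULL)
    if (is.null(ph)) {
      warning("phase detection failed for cycle ", i, "; cycle skipped")
      next
    }
    out[[length(out) + 1L]] <- structure(list(
      start_frame = s, end_frame = e,
      fc_sc_frame = s + ph$fc_sc_frame - 1L,
      min_gape_frame = s + ph$min_gape_frame - 1L,
      so_fo_frame = s + ph$so_fo_frame - 1L,
      gape = g,
      phase = phase_labels(length(g), ph$fc_sc_frame, ph$min_gape_frame,
                           ph$so_fo_frame),
      frame_rate = gape_series$frame_rate), class = "gape_cycle")
  }
  out
}

#' @export
print.gape_cycle <- function(x, ...) {
  cat(sprintf("<gape_cycle> frames %d-%d (%.0f ms), FC/SC %d, min gape %d, SO/FO %d\n",
              x$start_frame, x$end_frame,
              1000 * (x$end_frame - x$start_frame) / x$frame_rate,
              x$fc_sc_frame, x$min_gape_frame, x$so_fo_frame))
  invisible(x)
}

#' Resample a per-frame variable onto a standardized cycle grid
#'
#' Linear interpolation onto `n_out` equally spaced points spanning the full
#' cycle (0-100% of cycle); the first and last values are preserved exactly.
#'
#' @param series numeric vector, length >= 2.
#' @param n_out output length; default 50.
#' @return numeric vector of length `n_out`.
#' @export
standardize_cycle <- function(series, n_out = 50) {
  if (n_out < 2L) stop("'n_out' must be at least 2")
  x <- as.numeric(series)
  if (length(x) < 2L) stop("series must have at least 2 frames")
  stats::approx(seq_along(x), x, xout = seq(1, length(x),
                                            length.out = n_out))$y
}

#' Pointwise mean and SD curves of standardized cycles by group
#'
#' @param standardized_cycles list of equal-length numeric vectors (or a
#'   matrix with one cycle per row).
#' @param group_labels one label per cycle; a single group when omitted.
#' @return named list, one element per non-empty group, each with `mean`,
#'   `sd` (pointwise, `sd` is `NA` for singleton groups) and `n`. Empty
#'   groups are dropped with a warning.
#' @export
average_cycles <- function(standardized_cycles, group_labels = NULL) {
  if (is.matrix(standardized_cycles))
    standardized_cycles <- asplit(standardized_cycles, 1)
  len <- unique(lengths(standardized_cycles))
  if (length(len) != 1L)
    stop("all standardized cycles must have the same length")
  if (is.null(group_labels))
    group_labels <- rep("all", length(standardized_cycles))
  if (length(group_labels) != length(standardized_cycles))
    stop("one group label per cycle is required")
  out <- list()
  for (gr in unique(as.character(group_labels))) {
    idx <- which(as.character(group_labels) == gr)
    if (length(idx) == 0L) {
      warning("empty group '", gr, "' excluded")
      next
    }
    m <- do.call(rbind, standardized_cycles[idx])
    out[[gr]] <- list(mean = colMeans(m),
                      sd = apply(m, 2, stats::sd),
                      n = length(idx))
  }
  if (length(out) == 0L) warning("no non-empty groups")
  out
}
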