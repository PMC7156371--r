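#' Marker trajectory dataset
#'
#' Container for named 3D marker trajectories sampled at a fixed frame rate
#' in a common coordinate system. Each trajectory is an `n_frames` x 3 matrix
#' in mm; occluded frames are carried as `NA` rows (or cells) and flagged by
#' downstream operations rather than dropped.
#'
#' @param markers named list of numeric matrices, one per marker, each with 3
#'   columns (X, Y, Z in mm) and a common number of rows.
#' @param frame_rate sampling rate in frames per second (default 150).
#' @param coordinate_frame_tag free label for the coordinate system the
#'   positions live in, conventionally `"lab"` for raw digitized data and
#'   `"cranial"` after the cranial reference frame has been fixed.
#' @return an object of class `marker_dataset` with elements `markers`,
#'   `frame_rate`, `n_frames`, `coordinate_frame_tag`.
#' @export
marker_dataset <- function(markers, frame_rate = 150,
                           coordinate_frame_tag = "lab") {
  if (!is.list(markers) || length(markers) == 0L)
    stop("'markers' must be a non-empty named list of n x 3 matrices")
  nms <- names(markers)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("marker names must be present and unique")
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each marker trajectory must have 3 columns")
    storage.mode(m) <- "double"
    colnames(m) <- c("X", "Y", "Z")
    m
  })
  nf <- unique(vapply(markers, nrow, integer(1)))
  if (length(nf) != 1L)
    stop("all markers must have the same number of frames")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("'frame_rate' must be a single positive number")
  bad <- vapply(markers, function(m) any(is.infinite(m)), logical(1))
  if (any(bad))
    stop("non-finite (infinite) coordinates in marker(s): ",
         paste(nms[bad], collapse = ", "))
  structure(
    list(markers = markers, frame_rate = as.numeric(frame_rate),
         n_frames = nf, coordinate_frame_tag = coordinate_frame_tag),
    class = "marker_dataset")
}

#' @export
print.marker_dataset <- function(x, ...) {
  cat("<marker_dataset> ", length(x$markers), " markers x ", x$n_frames,
      " frames @ ", x$frame_rate, " fps [", x$coordinate_frame_tag, "]\n",
      sep = "")
  miss <- vapply(x$markers, function(m) sum(!stats::complete.cases(m)),
                 integer(1))
  cat("  markers:", paste(names(x$markers), collapse = ", "), "\n")
  if (any(miss > 0))
    cat("  frames with missing data:",
        paste0(names(miss)[miss > 0], " (", miss[miss > 0], ")",
               collapse = ", "), "\n")
  invisible(x)
}

#' Extract one marker trajectory
#'
#' @param dataset a [marker_dataset()].
#' @param name marker name.
#' @return n_frames x 3 numeric matrix.
#' @export
marker_traj <- function(dataset, name) {
  stopifnot(inherits(dataset, "marker_dataset"))
  if (!name %in% names(dataset$markers))
    stop("no marker named '", name, "' in dataset")
  dataset$markers[[name]]
}

#' Read an XMALab-style 3D marker CSV
#'
#' Parses the comma-separated 3D-points export dialect: one row per frame and
#' header columns `<name>_X`, `<name>_Y`, `<name>_Z` per marker, coordinates
#' in mm. Blank cells (occluded markers) become `NA` and are flagged as
#' missing frames for that marker; column order within and across triplets is
#' irrelevant.
#'
#' @param path CSV file path.
#' @param frame_rate frames per second of the recording (default 150).
#' @return a [marker_dataset()] tagged `"lab"`.
#' @export
read_marker_csv <- function(path, frame_rate = 150) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (ncol(raw) == 0L || nrow(raw) == 0L)
    stop("marker CSV '", path, "' is empty")
  cols <- names(raw)
  m <- regmatches(cols, regexec("^(.*)_([XYZ])$", cols))
  ok <- lengths(m) == 3L
  if (!all(ok))
    stop("marker CSV columns not of the form <name>_X/_Y/_Z: ",
         paste(cols[!ok], collapse = ", "))
  base <- vapply(m, `[`, character(1), 2L)
  axis <- vapply(m, `[`, character(1), 3L)
  markers <- list()
  for (nm in unique(base)) {
    idx <- which(base == nm)
    have <- axis[idx]
    missing_axes <- setdiff(c("X", "Y", "Z"), have)
    if (length(missing_axes) > 0)
      stop("marker '", nm, "' is missing column(s): ",
           paste0(nm, "_", missing_axes, collapse = ", "))
    if (anyDuplicated(have))
      stop("marker '", nm, "' has duplicated coordinate columns")
    tri <- matrix(NA_real_, nrow(raw), 3L)
    for (k in 1:3) {
      col <- raw[[idx[match(c("X", "Y", "Z")[k], have)]]]
      blank <- is.na(col) | col == ""
      val <- suppressWarnings(as.numeric(col))
      badrow <- which(!blank & is.na(val))
      if (length(badrow) > 0)
        stop("non-numeric value in column '", cols[idx[k]], "' at data row ",
             badrow[1])
      tri[, k] <- val
    }
    markers[[nm]] <- tri
  }
  marker_dataset(markers, frame_rate = frame_rate,
                 coordinate_frame_tag = "lab")
}

#' Write a marker dataset in the XMALab-style CSV dialect
#'
#' Inverse of [read_marker_csv()]: missing (`NA`) coordinates become blank
#' cells.
#'
#' @param dataset a [marker_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "marker_dataset"))
  cols <- list()
  for (nm in names(dataset$markers)) {
    m <- dataset$markers[[nm]]
    for (k in 1:3)
      cols[[paste0(nm, "_", c("X", "Y", "Z")[k])]] <- m[, k]
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read CT-derived anatomical landmarks
#'
#' Landmark CSV dialect: `name,x,y,z`, coordinates in mm in the reference-pose
#' coordinate system (the same space as the marker reference frame), e.g.
#' right/left coronoid tips and gonial angles.
#'
#' @param path CSV file path.
#' @return a named list of 3-vectors of class `landmark_set`; empty file
#'   yields an empty set.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, header = TRUE, strip.white = TRUE)
  if (nrow(df) == 0L) return(landmark_set(list()))
  if (ncol(df) < 4L)
    stop("landmark CSV must have columns name,x,y,z")
  pts <- lapply(seq_len(nrow(df)), function(i) {
    v <- suppressWarnings(as.numeric(df[i, 2:4]))
    if (any(is.na(v)))
      stop("landmark '", df[i, 1], "' has fewer than 3 numeric coordinates")
    v
  })
  names(pts) <- as.character(df[[1]])
  landmark_set(pts)
}

#' Construct a landmark set
#'
#' @param points named list of numeric 3-vectors (mm).
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(points) {
  if (length(points) > 0) {
    nms <- names(points)
    if (is.null(nms) || any(nms == "")) stop("landmarks must be named")
    if (anyDuplicated(nms))
      stop("duplicate landmark name: ",
           nms[anyDuplicated(nms)][1])
    lapply(points, function(p) {
      if (length(p) != 3L || !all(is.finite(p)))
        stop("each landmark must be a finite 3-vector")
    })
    points <- lapply(points, as.numeric)
  }
  structure(points, class = "landmark_set")
}

#' Write landmarks in the name,x,y,z dialect
#' @param landmarks a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(name = names(landmarks),
                   x = vapply(landmarks, `[`, 0, 1),
                   y = vapply(landmarks, `[`, 0, 2),
                   z = vapply(landmarks, `[`, 0, 3))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Anatomical coordinate frame
#'
#' Right-handed orthonormal frame giving the anteroposterior (AP),
#' superoinferior (SI) and mediolateral (ML) axes in which planar fascicle
#' angles are measured: the sagittal plane is span(AP, SI), the coronal plane
#' span(ML, SI).
#'
#' @param origin 3-vector, mm.
#' @param axis_ap,axis_si,axis_ml unit 3-vectors; must be pairwise orthogonal
#'   and right-handed (`ap x si = ml`) within 1e-8.
#' @return object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin = c(0, 0, 0),
                             axis_ap = c(1, 0, 0),
                             axis_si = c(0, 0, 1),
                             axis_ml = c(0, -1, 0)) {
  ax <- list(axis_ap = axis_ap, axis_si = axis_si, axis_ml = axis_ml)
  for (nm in names(ax)) {
    v <- as.numeric(ax[[nm]])
    if (length(v) != 3L || !all(is.finite(v)))
      stop("'", nm, "' must be a finite 3-vector")
    if (abs(sqrt(sum(v^2)) - 1) > 1e-8)
      stop("'", nm, "' must have unit norm (within 1e-8)")
    ax[[nm]] <- v
  }
  dots <- c(sum(ax$axis_ap * ax$axis_si), sum(ax$axis_ap * ax$axis_ml),
            sum(ax$axis_si * ax$axis_ml))
  if (any(abs(dots) > 1e-8))
    stop("anatomical axes must be pairwise orthogonal (within 1e-8)")
  cr <- c(ax$axis_ap[2] * ax$axis_si[3] - ax$axis_ap[3] * ax$axis_si[2],
          ax$axis_ap[3] * ax$axis_si[1] - ax$axis_ap[1] * ax$axis_si[3],
          ax$axis_ap[1] * ax$axis_si[2] - ax$axis_ap[2] * ax$axis_si[1])
  if (max(abs(cr - ax$axis_ml)) > 1e-8)
    stop("anatomical frame must be right-handed: AP x SI must equal ML")
  structure(c(list(origin = as.numeric(origin)), ax),
            class = "anatomical_frame")
}

#' Pipeline configuration
#'
#' Declares marker roles, the anatomical frame, and the numeric settings of
#' the processing pipeline. Defaults follow the standard recording protocol:
#' 150 fps, 30 Hz 4th-order zero-phase Butterworth, 25% LOESS span, 50-frame
#' cycle standardization.
#'
#' @param cranial character vector of 4 cranial marker names.
#' @param mandibular character vector of 4 mandibular marker names.
#' @param muscle named character vector/list with entries `m1` (central
#'   myotendinous junction), `m2` (superficial fascicle termination), `m3`
#'   (superior attachment).
#' @param anterior_mandible name of the anterior mandibular marker used for
#'   gape distance (must be one of `mandibular`).
#' @param coronoid_landmark name of the coronoid-tip landmark used for
#'   whole-muscle length.
#' @param mandibular_reference optional matrix of mandibular marker
#'   positions in the CT/landmark coordinate system (rownames = marker
#'   names); when given, mandibular transforms are registered against it so
#'   CT landmarks ride the correct material points.
#' @param cranial_reference optional matrix of cranial marker positions in
#'   the same CT/landmark coordinate system; when given, the cranial frame
#'   is fixed directly in that anatomical coordinate system.
#' @param frame anatomical frame, an [anatomical_frame()].
#' @param frame_rate frames/s.
#' @param filter_cutoff_hz low-pass cutoff (must be below Nyquist).
#' @param filter_order Butterworth order.
#' @param loess_span LOESS smoothing span for velocity curves.
#' @param n_standard frames per standardized cycle.
#' @param agr_epsilon_frac velocity threshold for the AGR mask, as a fraction
#'   of each cycle's peak absolute fascicle velocity.
#' @param min_prominence_frac cycle-maximum prominence threshold as a
#'   fraction of the recording's gape range.
#' @param max_gap_frames longest occlusion gap (frames) bridged by linear
#'   interpolation.
#' @param subject,food free labels attached to output tables.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cranial, mandibular, muscle,
                            anterior_mandible,
                            coronoid_landmark = "coronoid_R",
                            mandibular_reference = NULL,
                            cranial_reference = NULL,
                            frame = anatomical_frame(),
                            frame_rate = 150,
                            filter_cutoff_hz = 30,
                            filter_order = 4,
                            loess_span = 0.25,
                            n_standard = 50,
                            agr_epsilon_frac = 0.02,
                            min_prominence_frac = 0.2,
                            max_gap_frames = 5,
                            subject = "subject1",
                            food = "food1") {
  muscle <- as.list(muscle)
  if (!all(c("m1", "m2", "m3") %in% names(muscle)))
    stop("'muscle' must name markers m1, m2 and m3")
  if (length(cranial) != 4L) stop("exactly 4 cranial markers are required")
  if (length(mandibular) != 4L)
    stop("exactly 4 mandibular markers are required")
  if (!anterior_mandible %in% mandibular)
    stop("'anterior_mandible' must be one of the mandibular markers")
  if (filter_cutoff_hz >= frame_rate / 2)
    stop("filter cutoff must be below the Nyquist frequency")
  if (!is.null(mandibular_reference)) {
    mandibular_reference <- as.matrix(mandibular_reference)
    if (is.null(rownames(mandibular_reference)) ||
        !all(mandibular %in% rownames(mandibular_reference)))
      stop("'mandibular_reference' needs rownames covering the mandibular markers")
  }
  if (!is.null(cranial_reference)) {
    cranial_reference <- as.matrix(cranial_reference)
    if (is.null(rownames(cranial_reference)) ||
        !all(cranial %in% rownames(cranial_reference)))
      stop("'cranial_reference' needs rownames covering the cranial markers")
  }
  stopifnot(inherits(frame, "anatomical_frame"),
            loess_span > 0, loess_span <= 1, n_standard >= 2,
            agr_epsilon_frac > 0, max_gap_frames >= 0)
  structure(list(
    cranial = as.character(cranial), mandibular = as.character(mandibular),
    muscle = lapply(muscle, as.character),
    anterior_mandible = anterior_mandible,
    coronoid_landmark = coronoid_landmark,
    mandibular_reference = mandibular_reference,
    cranial_reference = cranial_reference,
    frame = frame, frame_rate = frame_rate,
    filter_cutoff_hz = filter_cutoff_hz, filter_order = filter_order,
    loess_span = loess_span, n_standard = n_standard,
    agr_epsilon_frac = agr_epsilon_frac,
    min_prominence_frac = min_prominence_frac,
    max_gap_frames = max_gap_frames,
    subject = subject, food = food), class = "pipeline_config")
}

#' Check that every configured marker role exists in a dataset
#' @param config a [pipeline_config()].
#' @param dataset a [marker_dataset()].
#' @return invisibly `TRUE`; errors naming the first unresolved role.
#' @export
validate_roles <- function(config, dataset) {
  roles <- c(config$cranial, config$mandibular,
             unlist(config$muscle), config$anterior_mandible)
  missing <- setdiff(roles, names(dataset$markers))
  if (length(missing) > 0)
    stop("configured marker role(s) not present in dataset: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching the arguments of
#'   [pipeline_config()]; the anatomical frame is given as lists
#'   `frame: {origin: [...], axis_ap: [...], axis_si: [...], axis_ml: [...]}`.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$frame))
    y$frame <- do.call(anatomical_frame, lapply(y$frame, as.numeric))
  for (fld in c("mandibular_reference", "cranial_reference")) {
    if (!is.null(y[[fld]])) {
      m <- do.call(rbind, lapply(y[[fld]], as.numeric))
      rownames(m) <- names(y[[fld]])
      y[[fld]] <- m
    }
  }
  do.call(pipeline_config, y)
}

#' Write a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  y <- unclass(config)
  y$frame <- lapply(unclass(config$frame), as.numeric)
  for (fld in c("mandibular_reference", "cranial_reference")) {
    if (!is.null(y[[fld]])) {
      m <- y[[fld]]
      y[[fld]] <- stats::setNames(
        lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])),
        rownames(m))
    }
  }
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Write the tidy long-format results table
#'
#' One row per (subject, food, cycle, phase, %cycle, variable) with a single
#' `value` column; this is the exchange format between the measurement
#' pipeline and the statistics layer. Non-finite values are written as empty
#' cells and read back as `NA`.
#'
#' @param records data.frame with columns `subject`, `food`, `cycle`,
#'   `phase`, `pct_cycle`, `variable`, `value`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(records, path) {
  req <- c("subject", "food", "cycle", "phase", "pct_cycle", "variable",
           "value")
  if (!all(req %in% names(records)))
    stop("long table must have columns: ", paste(req, collapse = ", "))
  records <- records[, req]
  records$value[!is.finite(records$value)] <- NA_real_
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read the tidy long-format results table
#' @param path CSV written by [write_long_table()].
#' @return data.frame; empty cells become `NA`.
#' @export
read_long_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  df$pct_cycle <- as.numeric(df$pct_cycle)
  df$cycle <- as.integer(df$cycle)
  df
}

#' Bridge short occlusion gaps by linear interpolation
#'
#' Runs of missing frames no longer than `max_gap` are filled per coordinate
#' by linear interpolation between the flanking observed frames; longer runs
#' (and missing runs touching the recording boundary) are left `NA`, so the
#' frames are later excluded from cycles.
#'
#' @param dataset a [marker_dataset()].
#' @param max_gap longest gap length (frames) to bridge; default 5.
#' @return a [marker_dataset()] with short gaps filled.
#' @export
interpolate_gaps <- function(dataset, max_gap = 5) {
  stopifnot(inherits(dataset, "marker_dataset"))
  fill <- function(x) {
    isna <- is.na(x)
    if (!any(isna) || all(isna)) return(x)
    r <- rle(isna)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j] || r$lengths[j] > max_gap) next
      a <- starts[j] - 1L
      b <- ends[j] + 1L
      if (a < 1L || b > length(x)) next  # boundary gap: leave missing
      idx <- starts[j]:ends[j]
      x[idx] <- x[a] + (x[b] - x[a]) * (idx - a) / (b - a)
    }
    x
  }
  dataset$markers <- lapply(dataset$markers, function(m) {
    for (k in 1:3) m[, k] <- fill(m[, k])
    m
  })
  dataset
}
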