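# Per-frame facial-analysis records: reading, quality filtering, aggregation.
#
# A `landmark_frames` object holds every frame of one subject's video in
# column-major form: scalar tracker outputs as vectors, landmark clouds as
# n_frames x n_points x 3 arrays. This mirrors the OpenFace 2.0 CSV layout
# (one row per frame) while keeping the geometry directly indexable.

#' OpenFace 2.0 CSV column dialect
#'
#' Column names used by [read_frames()] and [write_cohort()]. The defaults
#' follow the OpenFace 2.0 convention: `confidence`, `pose_Rx/Ry/Rz` (head
#' rotation, radians), `gaze_0_*`/`gaze_1_*` (left/right eye gaze vectors),
#' `X_0..X_67`/`Y_*`/`Z_*` (the 68 3D facial landmarks in the scaled face
#' space), optional `p_scale` (face normalization factor) and optional
#' `eye_lmk_X_0..55` etc. (the 56-point eye-region scheme, 28 per eye).
#'
#' @return A named list of column names, one entry per record field.
#' @export
openface_dialect <- function() {
  list(
    frame      = "frame",
    confidence = "confidence",
    pose       = c("pose_Rx", "pose_Ry", "pose_Rz"),
    scale      = "p_scale",
    gaze_left  = c("gaze_0_x", "gaze_0_y", "gaze_0_z"),
    gaze_right = c("gaze_1_x", "gaze_1_y", "gaze_1_z"),
    face       = list(x = sprintf("X_%d", 0:67),
                      y = sprintf("Y_%d", 0:67),
                      z = sprintf("Z_%d", 0:67)),
    eye        = list(x = sprintf("eye_lmk_X_%d", 0:55),
                      y = sprintf("eye_lmk_Y_%d", 0:55),
                      z = sprintf("eye_lmk_Z_%d", 0:55))
  )
}

new_landmark_frames <- function(subject_id, frame_index, confidence, pose, scale,
                                gaze_left, gaze_right, face, eye = NULL) {
  n <- length(frame_index)
  stopifnot(length(confidence) == n, nrow(pose) == n, length(scale) == n,
            nrow(gaze_left) == n, nrow(gaze_right) == n, dim(face)[1] == n,
            dim(face)[2] == 68, dim(face)[3] == 3)
  structure(list(subject_id = subject_id,
                 frame_index = as.integer(frame_index),
                 confidence = confidence, pose = pose, scale = scale,
                 gaze_left = gaze_left, gaze_right = gaze_right,
                 face = face, eye = eye),
            class = "landmark_frames")
}

#' Number of frames in a `landmark_frames` object
#' @param frames A `landmark_frames` object.
#' @return Integer frame count.
#' @export
n_frames <- function(frames) length(frames$frame_index)

#' @export
print.landmark_frames <- function(x, ...) {
  cat(sprintf("<landmark_frames> subject '%s': %d frames, 68 face points%s\n",
              x$subject_id, n_frames(x),
              if (is.null(x$eye)) "" else ", 56 eye points"))
  invisible(x)
}

#' @export
`[.landmark_frames` <- function(x, i) {
  new_landmark_frames(x$subject_id, x$frame_index[i], x$confidence[i],
                      x$pose[i, , drop = FALSE], x$scale[i],
                      x$gaze_left[i, , drop = FALSE], x$gaze_right[i, , drop = FALSE],
                      x$face[i, , , drop = FALSE],
                      if (!is.null(x$eye)) x$eye[i, , , drop = FALSE])
}

# pull a block of columns into a numeric matrix, with per-cell parse errors
.numeric_block <- function(df, cols, path) {
  out <- matrix(NA_real_, nrow(df), length(cols))
  for (j in seq_along(cols)) {
    v <- df[[cols[j]]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !(trimws(v) %in% c("NA", "NaN", "nan", "")))
      if (length(bad))
        stop_idscreen("idscreen_parse_error",
                      "%s: non-numeric value '%s' at data row %d, column '%s'",
                      basename(path), v[bad[1]], bad[1], cols[j])
      v <- num
    }
    out[, j] <- v
  }
  out
}

#' Read per-frame facial-analysis records
#'
#' Parses an OpenFace-2.0-style CSV into a `landmark_frames` object. Rows whose
#' landmark coordinates contain `NA`/`NaN` (tracker dropout) are dropped with a
#' message before any filtering; they carry no usable geometry.
#'
#' @param path Path to a CSV file with a header row.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param dialect Column naming, see [openface_dialect()].
#' @return A `landmark_frames` object (frames in file order).
#' @export
read_frames <- function(path, subject_id = NULL, dialect = openface_dialect()) {
  if (!file.exists(path))
    stop_idscreen("idscreen_io_error", "file does not exist: %s", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- trimws(names(df))

  required <- c(dialect$confidence, dialect$pose,
                dialect$gaze_left, dialect$gaze_right,
                unlist(dialect$face, use.names = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_idscreen("idscreen_schema_error",
                  "%s: missing required column%s: %s", basename(path),
                  if (length(missing) > 1L) "s" else "",
                  paste(missing, collapse = ", "))

  confidence <- drop(.numeric_block(df, dialect$confidence, path))
  pose   <- .numeric_block(df, dialect$pose, path)
  gaze_l <- .numeric_block(df, dialect$gaze_left, path)
  gaze_r <- .numeric_block(df, dialect$gaze_right, path)
  fx <- .numeric_block(df, dialect$face$x, path)
  fy <- .numeric_block(df, dialect$face$y, path)
  fz <- .numeric_block(df, dialect$face$z, path)
  n <- nrow(df)
  face <- array(c(fx, fy, fz), dim = c(n, 68, 3))

  eye <- NULL
  if (all(unlist(dialect$eye, use.names = FALSE) %in% names(df))) {
    ex <- .numeric_block(df, dialect$eye$x, path)
    ey <- .numeric_block(df, dialect$eye$y, path)
    ez <- .numeric_block(df, dialect$eye$z, path)
    eye <- array(c(ex, ey, ez), dim = c(n, 56, 3))
  }
  scale <- if (dialect$scale %in% names(df))
    drop(.numeric_block(df, dialect$scale, path)) else rep(1, n)
  frame_index <- if (dialect$frame %in% names(df))
    drop(.numeric_block(df, dialect$frame, path)) else seq_len(n) - 1

  # drop tracker-dropout rows (any non-finite coordinate) before validation
  ok <- apply(is.finite(face), 1, all)
  if (!is.null(eye)) ok <- ok & apply(is.finite(eye), 1, all)
  if (any(!ok)) {
    message(sprintf("read_frames: dropped %d row(s) with missing coordinates in %s",
                    sum(!ok), basename(path)))
    keep <- which(ok)
    confidence <- confidence[keep]; pose <- pose[keep, , drop = FALSE]
    gaze_l <- gaze_l[keep, , drop = FALSE]; gaze_r <- gaze_r[keep, , drop = FALSE]
    face <- face[keep, , , drop = FALSE]
    if (!is.null(eye)) eye <- eye[keep, , , drop = FALSE]
    scale <- scale[keep]; frame_index <- frame_index[keep]
  }

  bad_conf <- which(!is.finite(confidence) | confidence < 0 | confidence > 1)
  if (length(bad_conf))
    stop_idscreen("idscreen_parse_error",
                  "%s: confidence outside [0, 1] at data row(s) %s", basename(path),
                  paste(utils::head(bad_conf, 5), collapse = ", "))
  bad_scale <- which(!is.finite(scale) | scale <= 0)
  if (length(bad_scale))
    stop_idscreen("idscreen_parse_error",
                  "%s: non-positive p_scale at data row(s) %s", basename(path),
                  paste(utils::head(bad_scale, 5), collapse = ", "))
  zero_gaze <- which(rowSums(gaze_l^2) == 0 | rowSums(gaze_r^2) == 0)
  if (length(zero_gaze))
    stop_idscreen("idscreen_parse_error",
                  "%s: zero-norm gaze vector at data row(s) %s", basename(path),
                  paste(utils::head(zero_gaze, 5), collapse = ", "))

  new_landmark_frames(subject_id, frame_index, confidence, pose, scale,
                      gaze_l, gaze_r, face, eye)
}

#' Frame-quality filter thresholds
#'
#' The default thresholds retain frames with tracker confidence at least 0.98
#' and head-pose rotations (radians) satisfying |rx| <= 0.5, |ry| <= 0.25 and
#' |rz| <= 0.5, so that only near-frontal, confidently tracked frames
#' contribute to a subject's landmark geometry.
#'
#' @param confidence_min Minimum tracker confidence.
#' @param max_abs_rx,max_abs_ry,max_abs_rz Maximum absolute head rotation per axis.
#' @return A `filter_config` list.
#' @export
filter_config <- function(confidence_min = 0.98, max_abs_rx = 0.5,
                          max_abs_ry = 0.25, max_abs_rz = 0.5) {
  structure(list(confidence_min = assert_number(confidence_min, "confidence_min", 0, 1),
                 max_abs_rx = assert_number(max_abs_rx, "max_abs_rx", 0),
                 max_abs_ry = assert_number(max_abs_ry, "max_abs_ry", 0),
                 max_abs_rz = assert_number(max_abs_rz, "max_abs_rz", 0)),
            class = "filter_config")
}

#' Filter frames on confidence and head pose
#'
#' Keeps exactly the frames with `confidence >= confidence_min` and all three
#' head-pose rotations within their absolute bounds; order is preserved and an
#' empty result is legal.
#'
#' @param frames A `landmark_frames` object.
#' @param thresholds A [filter_config()].
#' @return A `landmark_frames` object containing the retained subsequence.
#' @export
filter_frames <- function(frames, thresholds = filter_config()) {
  stopifnot(inherits(frames, "landmark_frames"))
  keep <- frames$confidence >= thresholds$confidence_min &
    abs(frames$pose[, 1]) <= thresholds$max_abs_rx &
    abs(frames$pose[, 2]) <= thresholds$max_abs_ry &
    abs(frames$pose[, 3]) <= thresholds$max_abs_rz
  frames[which(keep)]
}

#' Aggregate retained frames into one landmark set per subject
#'
#' Coordinate-wise mean of the facial landmarks, eye-region landmarks and gaze
#' vectors over the retained frames. One subject-level landmark set is the unit
#' of analysis downstream (subject-level classification avoids leaking frames
#' of the same subject across cross-validation folds).
#'
#' @param frames A non-empty, filtered `landmark_frames` object.
#' @return A `subject_landmarks` object with fields `subject_id`, `face`
#'   (68 x 3), `eye` (56 x 3 or `NULL`), `gaze_left`, `gaze_right` and
#'   `n_frames_used`.
#' @export
aggregate_subject <- function(frames) {
  stopifnot(inherits(frames, "landmark_frames"))
  n <- n_frames(frames)
  if (n < 1L)
    stop_idscreen("idscreen_empty_error",
                  "no frames survived filtering for subject '%s'", frames$subject_id)
  new_subject_landmarks(
    subject_id = frames$subject_id,
    face = colMeans(array(frames$face, dim = c(n, 68 * 3))) |> matrix(68, 3),
    eye = if (!is.null(frames$eye))
      matrix(colMeans(array(frames$eye, dim = c(n, 56 * 3))), 56, 3),
    gaze_left = colMeans(frames$gaze_left),
    gaze_right = colMeans(frames$gaze_right),
    n_frames_used = n)
}

new_subject_landmarks <- function(subject_id, face, eye = NULL, gaze_left,
                                  gaze_right, n_frames_used = 1L) {
  stopifnot(nrow(face) == 68, ncol(face) == 3, is.null(eye) || nrow(eye) == 56)
  colnames(face) <- c("x", "y", "z")
  if (!is.null(eye)) colnames(eye) <- c("x", "y", "z")
  structure(list(subject_id = subject_id, face = face, eye = eye,
                 gaze_left = as.numeric(gaze_left),
                 gaze_right = as.numeric(gaze_right),
                 n_frames_used = as.integer(n_frames_used)),
            class = "subject_landmarks")
}

#' @export
print.subject_landmarks <- function(x, ...) {
  cat(sprintf("<subject_landmarks> '%s' (mean of %d frame%s)\n", x$subject_id,
              x$n_frames_used, if (x$n_frames_used == 1L) "" else "s"))
  invisible(x)
}
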