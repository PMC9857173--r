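# Synthetic cohorts: a fixed template face, per-subject shape deviations,
# per-frame tracker jitter, and group-mean-shifted phonetic matrices. The
# generator reproduces the statistical structure the screening analysis
# assumes -- a positive group whose craniofacial measurements scatter more
# widely around the norms and whose phonetic features are mean-shifted --
# so every pipeline stage is testable without clinical recordings.

# mirror permutation of the 68-point scheme (left/right landmark swap)
face68_mirror_permutation <- function() {
  swap <- rbind(
    cbind(0:7, 16:9),                      # jaw
    cbind(17:21, 26:22),                   # brows
    cbind(c(31, 32), c(35, 34)),           # nostrils
    cbind(c(36, 37, 38, 39, 40, 41), c(45, 44, 43, 42, 47, 46)),  # eyes
    cbind(c(48, 49, 50), c(54, 53, 52)),   # outer lips
    cbind(c(55, 56), c(59, 58)),
    cbind(c(60, 61), c(64, 63)),           # inner lips
    cbind(65, 67))
  perm <- 0:67
  perm[swap[, 1] + 1L] <- swap[, 2]
  perm[swap[, 2] + 1L] <- swap[, 1]
  perm
}

# one eye-region block of 28 points (iris ring 0-7, eyelid ring 8-19 with
# in-image ordering: 8 = leftmost corner, 11 = top mid, 14 = rightmost
# corner, 17 = bottom mid, pupil ring 20-27); `tilt` raises the temporal
# canthus relative to the nasal one
.eye_block <- function(cx, tilt) {
  a_iris <- 2 * pi * (0:7) / 8
  iris <- cbind(cx + 4.5 * cos(a_iris), -4.5 * sin(a_iris), rep(8, 8))
  t_lid <- pi - (0:11) * pi / 6
  lid <- cbind(cx + 11 * cos(t_lid), -5 * sin(t_lid) + tilt * cos(t_lid), rep(9, 12))
  a_pup <- 2 * pi * (0:7) / 8
  pupil <- cbind(cx + 2 * cos(a_pup), -2 * sin(a_pup), rep(8, 8))
  rbind(iris, lid, pupil)
}

#' The canonical template face
#'
#' A fixed, hand-constructed 68-point 3D face (plus the 56-point eye-region
#' scheme and a gaze-vector pair) in scaled face space, units roughly
#' millimetres: x left-to-right across the image (bilaterally symmetric about
#' x = 0), y downward, z depth away from the camera. Topology follows the
#' standard 68-point layout (jaw 0-16, brows 17-26, nose 27-35, eyes 36-47,
#' mouth 48-67); the subnasale (33) lies vertically between the nasion (27)
#' and the gnathion (8), and the lips are slightly parted so the inner-lip
#' vertex angles are non-degenerate.
#'
#' @return A `subject_landmarks` object (`subject_id = "template"`).
#' @export
make_template_face <- function() {
  face <- matrix(NA_real_, 68, 3)
  th <- pi * (0:16) / 16
  face[1:17, ] <- cbind(-70 * cos(th), 10 + 55 * sin(th), 45 - 35 * sin(th))
  brow_l <- cbind(c(-55, -43, -31, -20, -10), c(-14, -18, -20, -18, -15),
                  c(15, 12, 10, 10, 11))
  brow_r <- brow_l[5:1, ]; brow_r[, 1] <- -brow_r[, 1]
  face[18:22, ] <- brow_l
  face[23:27, ] <- brow_r
  face[28:31, ] <- cbind(0, c(-10, 2, 14, 25), c(8, 4, 0, -6))       # nose bridge
  face[32:36, ] <- cbind(c(-14, -7, 0, 7, 14), c(30, 32, 33, 32, 30),
                         c(4, 0, -2, 0, 4))                          # nostrils
  face[37:42, ] <- cbind(c(-45, -38, -30, -23, -30, -38), c(0, -4, -4, 0, 4, 4),
                         c(10, 8, 8, 9, 8, 8))                       # left eye
  face[43:48, ] <- cbind(c(23, 30, 38, 45, 38, 30), c(0, -4, -4, 0, 4, 4),
                         c(9, 8, 8, 10, 8, 8))                       # right eye
  face[49:60, ] <- cbind(c(-25, -15, -6, 0, 6, 15, 25, 15, 6, 0, -6, -15),
                         c(48, 44, 42, 41, 42, 44, 48, 53, 55, 55.5, 55, 53),
                         c(5, 2, 1, 0, 1, 2, 5, 2, 1, 0, 1, 2))      # outer lips
  face[61:68, ] <- cbind(c(-20, -8, 0, 8, 20, 8, 0, -8),
                         c(48, 46, 45.5, 46, 48, 50, 50.5, 50),
                         c(4, 2, 1.5, 2, 4, 2, 1.5, 2))              # inner lips
  face[abs(face) < 1e-12] <- 0          # exact midline (cos(pi/2) residue)
  eye <- rbind(.eye_block(-34, tilt = 1.5), .eye_block(34, tilt = -1.5))
  eye[abs(eye) < 1e-12] <- 0
  g <- function(v) v / sqrt(sum(v^2))
  new_subject_landmarks("template", face, eye,
                        gaze_left = g(c(0.06, 0, -1)),
                        gaze_right = g(c(-0.06, 0, -1)))
}

#' Specification of a synthetic cohort
#'
#' Group sizes default to the study composition (33 positive, 37 control).
#' Positive subjects receive per-landmark shape deviations scaled by
#' `geometric_deviation_scale`, so their measurements scatter more widely
#' around the control norms and the CVI shifts upward by construction;
#' `phonetic_shift` (in within-group SD units) is added to `n_shifted_dims`
#' randomly chosen phonetic dimensions of the positive group. Tracker
#' confidence is Beta-distributed and head pose normal, so a predictable
#' fraction of frames fails the quality filter.
#'
#' @param n_positive,n_control Group sizes (>= 2 each).
#' @param frames_per_subject Frames simulated per subject video.
#' @param geometric_deviation_scale Multiplier (>= 1) on positive-group shape
#'   deviations.
#' @param phonetic_shift Group mean shift on the selected phonetic dimensions,
#'   in SD units.
#' @param n_shifted_dims Number of shifted phonetic dimensions.
#' @param shape_sd Per-landmark, per-coordinate SD (mm) of the subject-level
#'   shape deviation.
#' @param frame_jitter_sd Per-frame landmark jitter SD (mm).
#' @param pose_jitter_sd SD (radians) of the per-frame head-pose rotations.
#' @param confidence_beta Length-2 Beta parameters of the tracker confidence.
#' @param rho First-order autocorrelation of neighbouring phonetic columns.
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_positive = 33L, n_control = 37L,
                        frames_per_subject = 50L,
                        geometric_deviation_scale = 1,
                        phonetic_shift = 0, n_shifted_dims = 10L,
                        shape_sd = 1.5, frame_jitter_sd = 0.3,
                        pose_jitter_sd = 0.12, confidence_beta = c(40, 1),
                        rho = 0.3, seed = 20230116L) {
  spec <- list(n_positive = as.integer(n_positive),
               n_control = as.integer(n_control),
               frames_per_subject = as.integer(frames_per_subject),
               geometric_deviation_scale = geometric_deviation_scale,
               phonetic_shift = phonetic_shift,
               n_shifted_dims = as.integer(n_shifted_dims),
               shape_sd = shape_sd, frame_jitter_sd = frame_jitter_sd,
               pose_jitter_sd = pose_jitter_sd,
               confidence_beta = as.numeric(confidence_beta),
               rho = rho, seed = as.integer(seed))
  if (spec$n_positive < 2L || spec$n_control < 2L)
    stop_idscreen("idscreen_contract_error", "each group needs >= 2 subjects")
  if (spec$frames_per_subject < 1L)
    stop_idscreen("idscreen_contract_error", "frames_per_subject must be >= 1")
  if (spec$geometric_deviation_scale < 1)
    stop_idscreen("idscreen_contract_error", "geometric_deviation_scale must be >= 1")
  assert_number(spec$shape_sd, "shape_sd", 0)
  assert_number(spec$frame_jitter_sd, "frame_jitter_sd", 0)
  assert_number(spec$pose_jitter_sd, "pose_jitter_sd", 0)
  assert_number(spec$rho, "rho", -1, 1)
  stopifnot(length(spec$confidence_beta) == 2L, all(spec$confidence_beta > 0))
  structure(spec, class = "cohort_spec")
}

#' Simulate one subject's frame stream
#'
#' Frames are `template + subject-level shape deviation + per-frame jitter`;
#' the subject deviation is isotropic Gaussian per landmark coordinate
#' (`shape_sd`, eye-region points at half that scale), multiplied by
#' `geometric_deviation_scale` for positive subjects. Per frame, confidence
#' is Beta-distributed, head pose isotropic normal, and the gaze vectors get
#' small jitter. Draws come from the current RNG stream: seed it (or use
#' [simulate_cohort()]) for reproducibility.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"` or `"positive"`.
#' @param subject_id Subject identifier.
#' @param template Template face, see [make_template_face()].
#' @return A `landmark_frames` object with `frames_per_subject` frames.
#' @export
simulate_subject <- function(spec, group = c("control", "positive"),
                             subject_id, template = make_template_face()) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  dev_scale <- if (group == "positive") spec$geometric_deviation_scale else 1
  nf <- spec$frames_per_subject

  face_base <- template$face +
    dev_scale * matrix(rnorm(68 * 3, 0, spec$shape_sd), 68, 3)
  eye_base <- template$eye +
    dev_scale * matrix(rnorm(56 * 3, 0, spec$shape_sd / 2), 56, 3)
  p_scale_subject <- exp(rnorm(1, 0, 0.05))

  face <- array(rep(face_base, each = nf), dim = c(nf, 68, 3)) +
    array(rnorm(nf * 68 * 3, 0, spec$frame_jitter_sd), dim = c(nf, 68, 3))
  eye <- array(rep(eye_base, each = nf), dim = c(nf, 56, 3)) +
    array(rnorm(nf * 56 * 3, 0, spec$frame_jitter_sd), dim = c(nf, 56, 3))
  pose <- matrix(rnorm(nf * 3, 0, spec$pose_jitter_sd), nf, 3)
  confidence <- rbeta(nf, spec$confidence_beta[1], spec$confidence_beta[2])
  scale <- p_scale_subject * exp(rnorm(nf, 0, 0.005))
  gaze_l <- matrix(template$gaze_left, nf, 3, byrow = TRUE) +
    matrix(rnorm(nf * 3, 0, 0.02), nf, 3)
  gaze_r <- matrix(template$gaze_right, nf, 3, byrow = TRUE) +
    matrix(rnorm(nf * 3, 0, 0.02), nf, 3)

  new_landmark_frames(subject_id, seq_len(nf) - 1L, confidence, pose, scale,
                      gaze_l, gaze_r, face, eye)
}

#' Simulate a subject-level phonetic feature matrix
#'
#' Rows are subjects, columns the 1582 schema features with unit marginal
#' variance and first-order autocorrelation `rho` between neighbouring
#' columns; `phonetic_shift` SD units are added to `n_shifted_dims` randomly
#' chosen columns of the positive rows. Draws come from the current RNG
#' stream.
#'
#' @param spec A [cohort_spec()].
#' @param groups Character vector of row groups (`"control"`/`"positive"`);
#'   defaults to positives first, using the cohort specification's group sizes.
#' @param subject_ids Row names.
#' @param schema An [is2010_schema()].
#' @return List: `X` (validated matrix), `shifted_dims` (column indices).
#' @export
simulate_phonetics <- function(spec, groups = NULL, subject_ids = NULL,
                               schema = is2010_schema()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(groups))
    groups <- rep(c("positive", "control"), c(spec$n_positive, spec$n_control))
  n <- length(groups)
  d <- schema$n_features
  E <- matrix(rnorm(n * d), n, d)
  X <- E
  for (j in 2:d) X[, j] <- spec$rho * X[, j - 1] + sqrt(1 - spec$rho^2) * E[, j]
  shifted <- sort(sample.int(d, spec$n_shifted_dims))
  X[groups == "positive", shifted] <- X[groups == "positive", shifted] +
    spec$phonetic_shift
  colnames(X) <- schema_feature_names(schema)
  rownames(X) <- subject_ids %||% as.character(seq_len(n))
  list(X = validate_phonetic_matrix(X, schema), shifted_dims = shifted)
}

#' Simulate a full synthetic cohort
#'
#' Seeds one RNG stream from `spec$seed` (restoring the caller's stream
#' afterwards) and draws, in a fixed order, every positive subject's frame
#' stream, every control's, and the phonetic matrix -- so a fixed spec yields
#' a byte-identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @param template Template face.
#' @return A `synthetic_cohort` list: `spec`, `subjects` (named list of
#'   `landmark_frames`), `labels` (data frame `subject_id`, `group`),
#'   `phonetic` (matrix), `shifted_dims`.
#' @export
simulate_cohort <- function(spec, template = make_template_face()) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- c(sprintf("pos_%02d", seq_len(spec$n_positive)),
           sprintf("ctl_%02d", seq_len(spec$n_control)))
  groups <- rep(c("positive", "control"), c(spec$n_positive, spec$n_control))
  out <- with_local_seed(spec$seed, {
    subjects <- Map(function(id, g) simulate_subject(spec, g, id, template),
                    ids, groups)
    phon <- simulate_phonetics(spec, groups, ids)
    list(subjects = subjects, phon = phon)
  })
  structure(list(spec = spec, subjects = out$subjects,
                 labels = data.frame(subject_id = ids, group = groups),
                 phonetic = out$phon$X, shifted_dims = out$phon$shifted_dims),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d positive / %d control, %d frames/subject, deviation x%.2g, phonetic shift %.2g sd on %d dims (seed %d)\n",
              x$spec$n_positive, x$spec$n_control, x$spec$frames_per_subject,
              x$spec$geometric_deviation_scale, x$spec$phonetic_shift,
              x$spec$n_shifted_dims, x$spec$seed))
  invisible(x)
}

# landmark_frames -> OpenFace-dialect data frame (inverse of read_frames)
frames_to_dataframe <- function(frames, dialect = openface_dialect()) {
  n <- n_frames(frames)
  df <- data.frame(check.names = FALSE, row.names = NULL,
                   matrix(nrow = n, ncol = 0))
  df[[dialect$frame]] <- frames$frame_index
  df[[dialect$confidence]] <- frames$confidence
  for (j in 1:3) df[[dialect$pose[j]]] <- frames$pose[, j]
  df[[dialect$scale]] <- frames$scale
  for (j in 1:3) df[[dialect$gaze_left[j]]] <- frames$gaze_left[, j]
  for (j in 1:3) df[[dialect$gaze_right[j]]] <- frames$gaze_right[, j]
  for (ax in 1:3) for (p in 1:68)
    df[[dialect$face[[ax]][p]]] <- frames$face[, p, ax]
  if (!is.null(frames$eye))
    for (ax in 1:3) for (p in 1:56)
      df[[dialect$eye[[ax]][p]]] <- frames$eye[, p, ax]
  df
}

#' Write a synthetic cohort to disk
#'
#' One OpenFace-dialect CSV per subject, plus `phonetic.csv`, `labels.csv`
#' and `spec.yaml` (subjects + 3 files); everything round-trips through
#' [read_frames()], [read_phonetic_matrix()] and [read_cohort()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$subjects))
    write.csv(frames_to_dataframe(cohort$subjects[[id]]),
              file.path(outdir, paste0(id, ".csv")), row.names = FALSE)
  phon <- data.frame(subject_id = rownames(cohort$phonetic),
                     cohort$phonetic, check.names = FALSE)
  write.csv(phon, file.path(outdir, "phonetic.csv"), row.names = FALSE)
  write.csv(cohort$labels, file.path(outdir, "labels.csv"), row.names = FALSE)
  yaml::write_yaml(c(unclass(cohort$spec),
                     list(shifted_dims = cohort$shifted_dims)),
                   file.path(outdir, "spec.yaml"))
  invisible(outdir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `synthetic_cohort`-shaped list (`spec`, `subjects`, `labels`,
#'   `phonetic`, `shifted_dims`).
#' @export
read_cohort <- function(dir) {
  labels <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  y <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  shifted <- y$shifted_dims
  y$shifted_dims <- NULL
  spec <- do.call(cohort_spec, y)
  subjects <- lapply(labels$subject_id, function(id)
    read_frames(file.path(dir, paste0(id, ".csv")), subject_id = id))
  names(subjects) <- labels$subject_id
  structure(list(spec = spec, subjects = subjects, labels = labels,
                 phonetic = read_phonetic_matrix(file.path(dir, "phonetic.csv")),
                 shifted_dims = shifted),
            class = "synthetic_cohort")
}

#' Expected quality-filter pass fraction under a cohort spec
#'
#' Analytic tail probability: `P(Beta(a, b) >= confidence_min)` times the
#' product of the three normal-tail probabilities for the pose bounds.
#'
#' @param spec A [cohort_spec()].
#' @param thresholds A [filter_config()].
#' @return Scalar probability.
#' @export
expected_pass_fraction <- function(spec, thresholds = filter_config()) {
  p_conf <- stats::pbeta(thresholds$confidence_min, spec$confidence_beta[1],
                         spec$confidence_beta[2], lower.tail = FALSE)
  p_pose <- function(bound)
    2 * stats::pnorm(bound / spec$pose_jitter_sd) - 1
  p_conf * p_pose(thresholds$max_abs_rx) * p_pose(thresholds$max_abs_ry) *
    p_pose(thresholds$max_abs_rz)
}
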