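# Independent oracles used across tests. These re-derive expected values by
# a different route than the package code: the geometric features are written
# out formula by formula from the printed measurement table (atan2-based
# angles instead of clamped arccos), kernels are built by explicit loops, and
# metrics are recomputed from raw confusion counts.

# angle in degrees via atan2(|u x v|, u.v) -- no arccos, no clamping needed
oracle_angle <- function(u, v) {
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}

# all 30 features, straight-line transcription (0-based indices +1); eye
# symbols resolved in the 56-point eye-region scheme
oracle_features <- function(subj, h_re_as_printed = TRUE) {
  fp <- function(i) subj$face[i + 1, ]
  ep <- function(i) subj$eye[i + 1, ]
  d <- function(a, b) sqrt(sum((a - b)^2))
  va <- function(a, b, c) oracle_angle(a - b, c - b)
  c(F01 = d(ep(8), ep(42)),
    F02 = d(ep(14), ep(36)),
    F03 = d(fp(1), fp(15)),
    F04 = d(fp(2), fp(14)),
    F05 = d(fp(31), fp(35)),
    F06 = d(fp(1), fp(33)) + d(fp(33), fp(15)),
    F07 = d(fp(3), fp(13)),
    F08 = d(fp(48), fp(54)),
    F09 = d(fp(1), fp(8)) + d(fp(8), fp(15)),
    F10 = d(fp(27), fp(33)),
    F11 = d(fp(27), fp(8)),
    F12 = d(ep(8), ep(14)),
    F13 = d(ep(36), ep(42)),
    F14 = va(ep(17), ep(8), ep(11)),
    F15 = va(ep(17), ep(14), ep(11)),
    F16 = va(ep(45), ep(36), ep(39)),
    F17 = va(ep(45), ep(42), ep(39)),
    F18 = va(ep(8), ep(14), ep(36)),
    F19 = va(ep(42), ep(36), ep(14)),
    F20 = d(ep(17), ep(11)),
    F21 = if (h_re_as_printed) d(ep(17), ep(11)) else d(ep(45), ep(39)),
    F22 = d(fp(31), fp(32)) + d(fp(32), fp(33)) + d(fp(33), fp(34)) + d(fp(34), fp(35)),
    F23 = d(fp(27), fp(28)) + d(fp(28), fp(29)) + d(fp(29), fp(30)),
    F24 = va(fp(31), fp(30), fp(35)),
    F25 = va(fp(61), fp(60), fp(67)),
    F26 = va(fp(49), fp(48), fp(59)),
    F27 = va(fp(63), fp(64), fp(65)),
    F28 = va(fp(53), fp(54), fp(55)),
    F29 = oracle_angle(ep(14) - ep(8), ep(36) - ep(42)),
    F30 = oracle_angle(subj$gaze_left, subj$gaze_right))
}

# a random non-degenerate face: template plus modest landmark noise
random_face <- function(sd = 1.2, id = "random") {
  tf <- make_template_face()
  idscreen:::new_subject_landmarks(
    id,
    tf$face + matrix(rnorm(68 * 3, 0, sd), 68, 3),
    tf$eye + matrix(rnorm(56 * 3, 0, sd / 2), 56, 3),
    tf$gaze_left + rnorm(3, 0, 0.03),
    tf$gaze_right + rnorm(3, 0, 0.03))
}

# apply a rigid motion (rotation R, translation t) to every point source
transform_subject <- function(subj, R, t) {
  move <- function(P) sweep(P %*% t(R), 2, -t, "-")
  idscreen:::new_subject_landmarks(
    subj$subject_id, move(subj$face), move(subj$eye),
    as.numeric(R %*% subj$gaze_left), as.numeric(R %*% subj$gaze_right),
    subj$n_frames_used)
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

scale_subject <- function(subj, k) {
  idscreen:::new_subject_landmarks(
    subj$subject_id, subj$face * k, subj$eye * k,
    subj$gaze_left, subj$gaze_right, subj$n_frames_used)
}

# mirror about the sagittal plane x = 0: negate x, permute left/right indices
mirror_subject <- function(subj) {
  perm_face <- idscreen:::face68_mirror_permutation()
  # eye-region: within-block index swap k -> sigma(k), then left <-> right
  ring12 <- function(k) ((14 - k) %% 12) + 8      # lid ring 8..19
  ring8 <- function(k, base) ((base + 4 - k) %% 8) + base  # iris 0..7 / pupil 20..27
  sigma <- function(k) {
    ifelse(k %in% 0:7, ring8(k, 0),
           ifelse(k %in% 8:19, ring12(k), ring8(k, 20)))
  }
  k <- 0:27
  perm_eye <- c(28L + sigma(k), sigma(k))          # left block <- right, right <- left
  face <- subj$face[perm_face + 1, ]
  face[, 1] <- -face[, 1]
  eye <- subj$eye[perm_eye + 1, ]
  eye[, 1] <- -eye[, 1]
  gl <- subj$gaze_right * c(-1, 1, 1)
  gr <- subj$gaze_left * c(-1, 1, 1)
  idscreen:::new_subject_landmarks(subj$subject_id, face, eye, gl, gr,
                                   subj$n_frames_used)
}

# single-frame landmark_frames wrapper around a subject_landmarks
frames_from_subject <- function(subj, confidence = 1, pose = c(0, 0, 0)) {
  idscreen:::new_landmark_frames(
    subj$subject_id, 0L, confidence, matrix(pose, 1, 3), 1,
    matrix(subj$gaze_left, 1, 3), matrix(subj$gaze_right, 1, 3),
    array(subj$face, dim = c(1, 68, 3)), array(subj$eye, dim = c(1, 56, 3)))
}
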