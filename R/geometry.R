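# Geometric primitives and the registry of the 30 facial phenotype features.
#
# Four primitives cover every feature class: Euclidean distance between two
# landmarks, polyline arc length through three or more landmarks (classical
# facial arcs such as tragion-subnasale-tragion), the angle at the middle
# vertex of a landmark triple, and the angle between two free vectors (eye
# axes, gaze directions). Multi-point |A - B - C| notation is read as arc
# length, the sum of consecutive segment lengths: that is the only reading
# under which the t-sn-t and t-gn-t entries are lengths at all.

#' Euclidean distance between two 3D points
#' @param a,b Numeric length-3 coordinates.
#' @return Non-negative scalar.
#' @export
point_distance <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L, is.finite(a), is.finite(b))
  sqrt(sum((a - b)^2))
}

#' Arc length of a polyline through three or more points
#' @param points Numeric matrix, one row per point (>= 3 rows), 3 columns.
#' @return Non-negative scalar: the sum of consecutive segment lengths.
#' @export
polyline_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop_idscreen("idscreen_contract_error",
                  "polyline_length needs at least 3 points, got %d", nrow(points))
  stopifnot(ncol(points) == 3L, is.finite(points))
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

.angle_deg <- function(u, v, context = "vector_angle") {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop_idscreen("idscreen_degenerate_error",
                  "degenerate geometry in %s: zero-length vector", context)
  # clamp: floating-point dot products can leave [-1, 1] by ~1e-16
  ct <- min(1, max(-1, sum(u * v) / (nu * nv)))
  acos(ct) * 180 / pi
}

#' Angle at the middle point of a landmark triple
#'
#' The angle, in degrees within \[0, 180\], between rays `b -> a` and `b -> c`.
#' @param a,b,c Numeric length-3 coordinates; `b` is the vertex.
#' @param context Label used in degenerate-geometry errors.
#' @return Angle in degrees.
#' @export
vertex_angle <- function(a, b, c, context = "vertex_angle") {
  stopifnot(length(a) == 3L, length(b) == 3L, length(c) == 3L)
  .angle_deg(a - b, c - b, context)
}

#' Angle between two free 3D vectors
#' @param u,v Numeric length-3 vectors with nonzero norm.
#' @param context Label used in degenerate-geometry errors.
#' @return Angle in degrees within \[0, 180\].
#' @export
vector_angle <- function(u, v, context = "vector_angle") {
  stopifnot(length(u) == 3L, length(v) == 3L)
  .angle_deg(u, v, context)
}

# ---------------------------------------------------------------------------
# Feature registry: F01..F30, each resolved to point sources by a landmark
# index map. Point symbols are (scheme, 0-based index) pairs; scheme "face" is
# the 68-point facial scheme, scheme "eye" the 56-point OpenFace eye-region
# scheme (28 per eye, eyelid rings at 8-19 and 36-47, in-image ordering).

.eye_to_face68 <- c(`8` = 36, `14` = 39, `36` = 42, `42` = 45,
                    `11` = 38, `17` = 40, `39` = 43, `45` = 46)

.pt <- function(scheme, index) list(scheme = scheme, index = as.integer(index))

#' Registry of the 30 geometric features of the facial phenotype
#'
#' Returns the ordered feature definitions F01..F30: bilateral and midline
#' distances (ex-ex, en-en, t-t, zy-zy, al-al, go-go, mu-mu, n-sn, n-gn, eye
#' and nose-bridge widths/heights), facial arcs (t-sn-t, t-gn-t, nostril and
#' nose-bridge polylines), eyelid and mouth-corner vertex angles, the angle
#' between the two eye axes and the angle between the two gaze vectors. The
#' first 11 features (F01-F11) feed the craniofacial variability index.
#'
#' @param eye_scheme Where the eye-region point symbols are resolved:
#'   `"eye"` (default) uses the 56-point eye-region landmarks; `"face"` maps
#'   them onto the 68-point scheme's eye corners and lid midpoints, for data
#'   without eye-region output.
#' @param h_re_as_printed The right-eye height feature F21 shares its printed
#'   formula with the left-eye height F20 (likely a transcription slip in the
#'   source table). `TRUE` (default) implements it as printed; `FALSE`
#'   substitutes the mirrored right-eye point pair.
#' @return A named list of 30 feature definitions (id, name, kind, points, unit).
#' @export
feature_registry <- function(eye_scheme = c("eye", "face"),
                             h_re_as_printed = TRUE) {
  eye_scheme <- match.arg(eye_scheme)
  e <- function(i) {
    if (eye_scheme == "eye") return(.pt("eye", i))
    m <- .eye_to_face68[as.character(i)]
    if (is.na(m))
      stop_idscreen("idscreen_config_error",
                    "eye point %d has no 68-point equivalent", i)
    .pt("face", m)
  }
  f <- function(i) .pt("face", i)
  dist2 <- function(id, name, p1, p2)
    list(id = id, name = name, kind = "distance", points = list(p1, p2), unit = "length")
  poly <- function(id, name, ...)
    list(id = id, name = name, kind = "polyline", points = list(...), unit = "length")
  vang <- function(id, name, a, b, c)
    list(id = id, name = name, kind = "vertex_angle", points = list(a, b, c), unit = "degrees")

  h_re_pts <- if (h_re_as_printed) list(e(17), e(11)) else list(e(45), e(39))
  defs <- list(
    dist2("F01", "ex-ex", e(8), e(42)),
    dist2("F02", "en-en", e(14), e(36)),
    dist2("F03", "t-t",   f(1), f(15)),
    dist2("F04", "zy-zy", f(2), f(14)),
    dist2("F05", "al-al", f(31), f(35)),
    poly("F06", "t-sn-t", f(1), f(33), f(15)),
    dist2("F07", "go-go", f(3), f(13)),
    dist2("F08", "mu-mu", f(48), f(54)),
    poly("F09", "t-gn-t", f(1), f(8), f(15)),
    dist2("F10", "n-sn",  f(27), f(33)),
    dist2("F11", "n-gn",  f(27), f(8)),
    dist2("F12", "w-le",  e(8), e(14)),
    dist2("F13", "w-re",  e(36), e(42)),
    vang("F14", "la-le", e(17), e(8), e(11)),
    vang("F15", "ra-le", e(17), e(14), e(11)),
    vang("F16", "la-re", e(45), e(36), e(39)),
    vang("F17", "ra-re", e(45), e(42), e(39)),
    vang("F18", "a-le-nb", e(8), e(14), e(36)),
    vang("F19", "a-re-nb", e(42), e(36), e(14)),
    dist2("F20", "h-le", e(17), e(11)),
    list(id = "F21", name = "h-re", kind = "distance", points = h_re_pts, unit = "length"),
    poly("F22", "w-nb", f(31), f(32), f(33), f(34), f(35)),
    poly("F23", "h-nb", f(27), f(28), f(29), f(30)),
    vang("F24", "a-nb", f(31), f(30), f(35)),
    vang("F25", "ia-lm", f(61), f(60), f(67)),
    vang("F26", "oa-lm", f(49), f(48), f(59)),
    vang("F27", "ia-rm", f(63), f(64), f(65)),
    vang("F28", "oa-rm", f(53), f(54), f(55)),
    list(id = "F29", name = "a-2e", kind = "vector_angle",
         points = list(e(14), e(8), e(36), e(42)), unit = "degrees"),
    list(id = "F30", name = "a-s", kind = "gaze_angle", points = list(),
         unit = "degrees")
  )
  names(defs) <- vapply(defs, `[[`, "", "id")
  structure(defs, class = "feature_registry",
            eye_scheme = eye_scheme, h_re_as_printed = h_re_as_printed)
}

#' @export
print.feature_registry <- function(x, ...) {
  cat(sprintf("<feature_registry> %d geometric features (eye scheme: %s)\n",
              length(x), attr(x, "eye_scheme")))
  invisible(x)
}

#' Units of each registry feature
#' @param registry A [feature_registry()].
#' @return Named character vector, `"length"` or `"degrees"` per feature.
#' @export
feature_units <- function(registry = feature_registry()) {
  vapply(registry, `[[`, "", "unit")
}

.resolve_point <- function(subj, sym, feature_id) {
  if (sym$scheme == "face") {
    if (sym$index < 0L || sym$index > 67L)
      stop_idscreen("idscreen_config_error",
                    "feature %s: face index %d outside 0..67", feature_id, sym$index)
    return(subj$face[sym$index + 1L, ])
  }
  if (is.null(subj$eye))
    stop_idscreen("idscreen_config_error",
                  "feature %s needs eye-region landmark %d but the subject has no eye points (use eye_scheme = \"face\")",
                  feature_id, sym$index)
  if (sym$index < 0L || sym$index > 55L)
    stop_idscreen("idscreen_config_error",
                  "feature %s: eye index %d outside 0..55", feature_id, sym$index)
  subj$eye[sym$index + 1L, ]
}

#' Compute the 30 geometric features for one subject
#'
#' @param subj A `subject_landmarks` object (see [aggregate_subject()]).
#' @param registry A [feature_registry()].
#' @return A named numeric vector F01..F30 with a `units` attribute; distances
#'   are in scaled-face-space length units, angles in degrees within \[0, 180\].
#' @export
compute_features <- function(subj, registry = feature_registry()) {
  stopifnot(inherits(subj, "subject_landmarks"))
  out <- vapply(registry, function(def) {
    pts <- lapply(def$points, .resolve_point, subj = subj, feature_id = def$id)
    val <- switch(def$kind,
      distance     = point_distance(pts[[1]], pts[[2]]),
      polyline     = polyline_length(do.call(rbind, pts)),
      vertex_angle = vertex_angle(pts[[1]], pts[[2]], pts[[3]],
                                  context = sprintf("feature %s (%s)", def$id, def$name)),
      vector_angle = vector_angle(pts[[1]] - pts[[2]], pts[[3]] - pts[[4]],
                                  context = sprintf("feature %s (%s)", def$id, def$name)),
      gaze_angle   = vector_angle(subj$gaze_left, subj$gaze_right,
                                  context = sprintf("feature %s (%s)", def$id, def$name)),
      stop_idscreen("idscreen_config_error", "unknown feature kind '%s'", def$kind))
    if (!is.finite(val))
      stop_idscreen("idscreen_degenerate_error",
                    "feature %s (%s) is not finite", def$id, def$name)
    val
  }, numeric(1))
  structure(out, units = feature_units(registry))
}

#' Compute the geometric feature table for a list of subjects
#'
#' @param subjects A list of `subject_landmarks` objects.
#' @param registry A [feature_registry()].
#' @return A data frame with `subject_id` and one column per feature F01..F30.
#' @export
compute_features_cohort <- function(subjects, registry = feature_registry()) {
  stopifnot(length(subjects) > 0L)
  rows <- t(vapply(subjects, compute_features, numeric(length(registry)),
                   registry = registry))
  data.frame(subject_id = vapply(subjects, `[[`, "", "subject_id"),
             rows, check.names = FALSE, row.names = NULL)
}

#' Write or read a landmark index map
#'
#' Serializes the point-resolution side of a [feature_registry()] (feature id
#' to a list of scheme/index pairs) as YAML, so alternative eye-region schemes
#' can be shipped as data.
#'
#' @param registry A [feature_registry()].
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_landmark_map <- function(registry, path) {
  m <- lapply(unclass(registry), function(def)
    list(name = def$name, kind = def$kind,
         points = lapply(def$points, function(p)
           list(scheme = p$scheme, index = p$index))))
  yaml::write_yaml(m, path)
  invisible(path)
}
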