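# Craniofacial variability index: per-measurement z-scores against a
# normative reference, summarized by their standard deviation (sigma_z).
# Larger sigma_z means the subject's facial measurements scatter more widely
# around the norms, i.e. a more atypical craniofacial morphology.

#' Names of the measurements that feed the CVI
#'
#' The craniofacial variability index is computed from the first 11 geometric
#' features (F01-F11): the facial subset of the classical head-and-face
#' measurement battery, chosen because interview video captures the face only.
#'
#' @return Character vector `c("F01", ..., "F11")`.
#' @export
cvi_measurements <- function() sprintf("F%02d", 1:11)

#' Fit a normative reference from control subjects
#'
#' Per-measurement mean and (sample, n-1) standard deviation over the control
#' group. Published anthropometric norm tables can be supplied instead via
#' [as_normative_reference()].
#'
#' @param controls Data frame or matrix of control-subject measurements
#'   containing the columns named in `measurements`; at least 2 rows.
#' @param measurements Measurement names; defaults to [cvi_measurements()].
#' @return A `normative_reference` data frame (measurement, mean, sd) with a
#'   `provenance` attribute `"fitted-from-controls"`.
#' @export
fit_normative_reference <- function(controls, measurements = cvi_measurements()) {
  controls <- as.data.frame(controls)
  missing <- setdiff(measurements, names(controls))
  if (length(missing))
    stop_idscreen("idscreen_contract_error",
                  "controls lack measurement column(s): %s",
                  paste(missing, collapse = ", "))
  if (nrow(controls) < 2L)
    stop_idscreen("idscreen_contract_error",
                  "need at least 2 control subjects, got %d", nrow(controls))
  mu <- vapply(measurements, function(m) mean(controls[[m]]), numeric(1))
  s  <- vapply(measurements, function(m) sd(controls[[m]]), numeric(1))
  degenerate <- measurements[!is.finite(s) | s <= 0]
  if (length(degenerate))
    stop_idscreen("idscreen_degenerate_error",
                  "zero variance in measurement(s): %s",
                  paste(degenerate, collapse = ", "))
  as_normative_reference(
    data.frame(measurement = measurements, mean = mu, sd = s, row.names = NULL),
    provenance = "fitted-from-controls")
}

#' Mark a mean/SD table as a normative reference
#'
#' @param ref Data frame with columns `measurement`, `mean`, `sd` (`sd > 0`).
#' @param provenance `"fitted-from-controls"` or `"external-table"`.
#' @return A `normative_reference` object.
#' @export
as_normative_reference <- function(ref, provenance = "external-table") {
  ref <- as.data.frame(ref)
  stopifnot(all(c("measurement", "mean", "sd") %in% names(ref)))
  if (any(!is.finite(ref$sd) | ref$sd <= 0))
    stop_idscreen("idscreen_contract_error", "all reference SDs must be positive")
  structure(ref, class = c("normative_reference", "data.frame"),
            provenance = provenance)
}

#' Read / write a normative reference as YAML
#' @param path YAML file path.
#' @return For `read_normative_reference`, a `normative_reference`; for the
#'   writer, `path` invisibly.
#' @export
read_normative_reference <- function(path) {
  y <- yaml::read_yaml(path)
  as_normative_reference(
    data.frame(measurement = vapply(y$measurements, `[[`, "", "measurement"),
               mean = vapply(y$measurements, `[[`, 0, "mean"),
               sd = vapply(y$measurements, `[[`, 0, "sd")),
    provenance = y$provenance %||% "external-table")
}

#' @rdname read_normative_reference
#' @param ref A `normative_reference`.
#' @export
write_normative_reference <- function(ref, path) {
  yaml::write_yaml(list(
    provenance = attr(ref, "provenance"),
    measurements = lapply(seq_len(nrow(ref)), function(i)
      list(measurement = ref$measurement[i], mean = ref$mean[i], sd = ref$sd[i]))),
    path, precision = 12)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize measurements against a normative reference
#'
#' @param mv Named numeric vector (or one-row data frame) of a subject's
#'   measurements, covering every reference measurement.
#' @param ref A `normative_reference`.
#' @return Named numeric vector of z-scores `(x - mean) / sd`.
#' @export
z_scores <- function(mv, ref) {
  stopifnot(inherits(ref, "normative_reference"))
  if (is.data.frame(mv)) mv <- unlist(mv[1, , drop = TRUE])
  missing <- setdiff(ref$measurement, names(mv))
  if (length(missing))
    stop_idscreen("idscreen_contract_error",
                  "subject lacks measurement(s): %s", paste(missing, collapse = ", "))
  z <- (as.numeric(mv[ref$measurement]) - ref$mean) / ref$sd
  names(z) <- ref$measurement
  z
}

#' Craniofacial variability index of a z-score vector
#'
#' The standard deviation of the measurement z-scores. The population
#' denominator (n) is the default; the sample denominator (n-1) is available
#' because the classical definition does not pin it.
#'
#' @param z Numeric vector of z-scores, length >= 2.
#' @param denominator `"population"` (divide by n, default) or `"sample"` (n-1).
#' @return Non-negative scalar sigma_z.
#' @export
cvi_score <- function(z, denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  if (length(z) < 2L)
    stop_idscreen("idscreen_contract_error",
                  "cvi_score needs at least 2 z-scores, got %d", length(z))
  stopifnot(is.finite(z))
  if (denominator == "sample") return(sd(z))
  sqrt(mean((z - mean(z))^2))
}

#' CVI for every subject of a measurement table
#'
#' @param measurements Data frame with `subject_id` and the reference's
#'   measurement columns.
#' @param ref A `normative_reference`.
#' @param denominator Passed to [cvi_score()].
#' @return A data frame `subject_id`, `cvi`, with the z-score matrix attached
#'   as attribute `"z"`.
#' @export
cvi_cohort <- function(measurements, ref, denominator = "population") {
  z <- t(apply(measurements[ref$measurement], 1, function(x)
    (as.numeric(x) - ref$mean) / ref$sd))
  colnames(z) <- ref$measurement
  out <- data.frame(subject_id = measurements$subject_id,
                    cvi = apply(z, 1, cvi_score, denominator = denominator),
                    row.names = NULL)
  attr(out, "z") <- z
  out
}

#' Empirical percentile table of CVI scores by group
#'
#' @param scores_by_group Named list of numeric CVI vectors, one per group.
#' @param levels Percentile levels in percent (default: the classical 12-level
#'   layout 5, 10, 15, 20, 25, 50, 70, 75, 80, 85, 90, 95).
#' @return Data frame `group`, `percentile`, `cvi`, non-decreasing in level
#'   within each group; the interpolation rule is recorded in attribute
#'   `"interpolation"` (linear between closest ranks, `quantile` type 7).
#' @export
percentile_table <- function(scores_by_group,
                             levels = c(5, 10, 15, 20, 25, 50, 70, 75, 80, 85, 90, 95)) {
  stopifnot(is.list(scores_by_group), length(scores_by_group) >= 1L,
            !is.null(names(scores_by_group)))
  rows <- lapply(names(scores_by_group), function(g) {
    s <- scores_by_group[[g]]
    if (length(s) < 1L)
      stop_idscreen("idscreen_empty_error", "group '%s' has no CVI scores", g)
    data.frame(group = g, percentile = levels,
               cvi = unname(quantile(s, probs = levels / 100, type = 7)))
  })
  structure(do.call(rbind, rows), interpolation = "linear (quantile type 7)")
}

#' Screening risk flag
#'
#' `TRUE` when the CVI strictly exceeds the cutoff. The suggested cutoff is
#' the control-group 95th percentile (a screening convention, not taken from
#' any norm table).
#'
#' @param cvi Numeric CVI score(s).
#' @param cutoff Scalar cutoff.
#' @return Logical vector.
#' @export
risk_flag <- function(cvi, cutoff) {
  assert_number(cutoff, "cutoff")
  cvi > cutoff
}
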