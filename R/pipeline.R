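# End-to-end screening pipeline: frame filtering and aggregation, geometric
# features, CVI against control-fitted norms, phonetic reduction, and
# cross-validated evaluation of the three feature sets.

#' Filter, aggregate and measure one subject's frames
#'
#' @param frames A `landmark_frames` object.
#' @param thresholds A [filter_config()].
#' @param registry A [feature_registry()].
#' @return Named numeric vector of the 30 geometric features.
#' @export
process_subject <- function(frames, thresholds = filter_config(),
                            registry = feature_registry()) {
  compute_features(aggregate_subject(filter_frames(frames, thresholds)),
                   registry)
}

#' Measurement table of a cohort of frame streams
#'
#' @param subjects Named list of `landmark_frames` objects.
#' @param thresholds A [filter_config()].
#' @param registry A [feature_registry()].
#' @return Data frame `subject_id` + F01..F30, plus the per-subject retained
#'   frame count as column `n_frames_used`.
#' @export
cohort_measurements <- function(subjects, thresholds = filter_config(),
                                registry = feature_registry()) {
  agg <- lapply(subjects, function(fr)
    aggregate_subject(filter_frames(fr, thresholds)))
  out <- compute_features_cohort(agg, registry)
  out$n_frames_used <- vapply(agg, `[[`, integer(1), "n_frames_used")
  out
}

#' Run the full screening analysis on a cohort
#'
#' Filters and aggregates every subject's frames, computes the 30 geometric
#' features, fits the normative reference on the control group and scores
#' every subject's CVI, builds the cohort percentile table, reduces the
#' phonetic matrix to 38 kernel principal components, and evaluates the
#' configured classifiers on the three feature sets with stratified k-fold
#' cross-validation.
#'
#' With `kpca_mode = "fold"` (default) the phonetic reduction is refit inside
#' each training fold, so test subjects never influence it; `"global"` fits
#' it once on the whole cohort before cross-validation (the conventional but
#' leakage-prone variant, kept for comparability).
#'
#' @param cohort A `synthetic_cohort` (or [read_cohort()] result): `subjects`,
#'   `labels`, `phonetic`.
#' @param classifiers,k,seed,averaging Passed to [evaluate()].
#' @param kpca_components Phonetic dimensionality after reduction.
#' @param kpca_mode `"fold"` or `"global"`.
#' @param thresholds A [filter_config()].
#' @param registry A [feature_registry()].
#' @param cvi_denominator Passed to [cvi_cohort()].
#' @return A `screening_result` list: `measurements`, `reference`, `cvi`,
#'   `percentiles`, `risk_cutoff` (control 95th percentile), `tables`
#'   (the geometric30 / geometric_cvi31 feature tables), `report`
#'   (rbind of the three evaluation reports).
#' @export
run_screening_pipeline <- function(cohort,
                                   classifiers = c("random_forest", "adaboost", "gaussian_nb"),
                                   k = 5L, seed = 20230116L,
                                   averaging = "weighted",
                                   kpca_components = 38L,
                                   kpca_mode = c("fold", "global"),
                                   thresholds = filter_config(),
                                   registry = feature_registry(),
                                   cvi_denominator = "population") {
  kpca_mode <- match.arg(kpca_mode)
  labels <- cohort$labels
  meas <- cohort_measurements(cohort$subjects, thresholds, registry)

  controls <- meas[match(labels$subject_id[labels$group == "control"],
                         meas$subject_id), ]
  ref <- fit_normative_reference(controls)
  cvi <- cvi_cohort(meas, ref, denominator = cvi_denominator)
  scores_by_group <- split(cvi$cvi, labels$group[match(cvi$subject_id, labels$subject_id)])
  percentiles <- percentile_table(scores_by_group)
  risk_cutoff <- unname(quantile(scores_by_group$control, 0.95, type = 7))

  phon <- validate_phonetic_matrix(cohort$phonetic)
  phon_name <- paste0("phonetic", kpca_components)

  reduced <- kpca_reduce(phon, n_components = kpca_components)
  tables <- assemble_feature_tables(meas, cvi, reduced, labels)
  if (kpca_mode == "global") {
    rep_phon <- evaluate(tables[[phon_name]], classifiers, k = k, seed = seed,
                         averaging = averaging)
  } else {
    # the evaluated phonetic route refits KPCA inside each training fold;
    # the globally reduced table above is kept for inspection only
    raw_table <- feature_table(phon, labels$group, "phonetic_raw",
                               labels$subject_id)
    rep_phon <- evaluate(raw_table, classifiers, k = k, seed = seed,
                         averaging = averaging,
                         preprocess = kpca_preprocess(kpca_components),
                         feature_set_name = phon_name)
  }
  rep_geo <- evaluate(tables$geometric30, classifiers, k = k, seed = seed,
                      averaging = averaging)
  rep_cvi <- evaluate(tables$geometric_cvi31, classifiers, k = k, seed = seed,
                      averaging = averaging)
  report <- rbind(as.data.frame(rep_geo), as.data.frame(rep_cvi),
                  as.data.frame(rep_phon))
  structure(list(measurements = meas, reference = ref, cvi = cvi,
                 percentiles = percentiles, risk_cutoff = risk_cutoff,
                 tables = tables, report = report,
                 cv = list(scheme = "stratified k-fold", k = k, seed = seed,
                           kpca_mode = kpca_mode,
                           kpca_components = kpca_components,
                           averaging = averaging)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %d subjects; CVI risk cutoff %.3f (control 95th pct)\n",
              nrow(x$cvi), x$risk_cutoff))
  print(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}
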