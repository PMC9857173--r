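# The INTERSPEECH 2010 paralinguistic feature-set schema and validation of
# subject-level phonetic feature matrices against it. Acoustic low-level
# descriptor (LLD) extraction from audio is out of scope: matrices arrive
# from an external front-end (openSMILE-style CSV export) or from the
# synthetic generator.

#' The INTERSPEECH 2010 paralinguistic feature-set schema
#'
#' Block structure of the 1582-dimensional feature set: 34 low-level
#' descriptors (loudness, 15 MFCCs, 8 log mel-frequency bands, 8 LSP
#' frequencies, smoothed F0 envelope, final voicing probability) plus their 34
#' delta contours, each summarized by 21 functionals (1428 features); 4
#' pitch-based LLDs (final F0, local jitter, delta-delta jitter, local
#' shimmer) plus their 4 deltas, each summarized by 19 functionals (152
#' features); and 2 appended values (number of pitch onsets, total duration).
#' Functional names beyond the documented core follow the published challenge
#' set's configuration.
#'
#' @return An `is2010_schema` list with the name blocks and the derived counts
#'   `n_main` (1428), `n_pitch` (152), `n_appended` (2) and `n_features` (1582).
#' @export
is2010_schema <- function() {
  lld <- c("pcm_loudness",
           sprintf("mfcc[%d]", 0:14),
           sprintf("logMelFreqBand[%d]", 0:7),
           sprintf("lspFreq[%d]", 0:7),
           "F0finEnv", "voicingFinalUnclipped")
  functionals_main <- c("maxPos", "minPos", "amean", "linregc1", "linregc2",
                        "linregerrA", "linregerrQ", "stddev", "skewness",
                        "kurtosis", "quartile1", "quartile2", "quartile3",
                        "iqr1-2", "iqr2-3", "iqr1-3", "percentile1.0",
                        "percentile99.0", "pctlrange0-1", "upleveltime75",
                        "upleveltime90")
  pitch_lld <- c("F0final", "jitterLocal", "jitterDDP", "shimmerLocal")
  functionals_pitch <- setdiff(functionals_main, c("maxPos", "minPos"))
  schema <- list(
    lld_names = paste0(lld, "_sma"),
    delta_names = paste0(lld, "_sma_de"),
    functionals_main = functionals_main,
    pitch_lld_names = paste0(pitch_lld, "_sma"),
    pitch_delta_names = paste0(pitch_lld, "_sma_de"),
    functionals_pitch = functionals_pitch,
    appended = c("F0final_nnz_numOnsets", "totalDuration"))
  schema$n_main <- (length(schema$lld_names) + length(schema$delta_names)) *
    length(schema$functionals_main)
  schema$n_pitch <- (length(schema$pitch_lld_names) + length(schema$pitch_delta_names)) *
    length(schema$functionals_pitch)
  schema$n_appended <- length(schema$appended)
  schema$n_features <- schema$n_main + schema$n_pitch + schema$n_appended
  structure(schema, class = "is2010_schema")
}

#' @export
print.is2010_schema <- function(x, ...) {
  cat(sprintf("<is2010_schema> %d features = %d (main: %d contours x %d functionals) + %d (pitch: %d contours x %d functionals) + %d appended\n",
              x$n_features, x$n_main,
              length(x$lld_names) + length(x$delta_names), length(x$functionals_main),
              x$n_pitch,
              length(x$pitch_lld_names) + length(x$pitch_delta_names),
              length(x$functionals_pitch), x$n_appended))
  invisible(x)
}

#' Full ordered feature names of a schema
#' @param schema An [is2010_schema()].
#' @return Character vector of `n_features` unique names (contour_functional,
#'   main block first, then pitch block, then the appended pair).
#' @export
schema_feature_names <- function(schema = is2010_schema()) {
  cross <- function(contours, funcs)
    as.vector(t(outer(contours, funcs, paste, sep = "_")))
  c(cross(c(schema$lld_names, schema$delta_names), schema$functionals_main),
    cross(c(schema$pitch_lld_names, schema$pitch_delta_names), schema$functionals_pitch),
    schema$appended)
}

#' Validate a phonetic feature matrix against a schema
#'
#' Passes iff the column count equals the schema total and every entry is
#' finite; otherwise the error names the offending dimension or cells.
#'
#' @param X Numeric matrix (rows = subjects, rownames = subject ids) or data
#'   frame coercible to one.
#' @param schema An [is2010_schema()].
#' @return `X` as a numeric matrix, invisibly usable downstream.
#' @export
validate_phonetic_matrix <- function(X, schema = is2010_schema()) {
  X <- as.matrix(X)
  if (!is.numeric(X))
    stop_idscreen("idscreen_parse_error", "phonetic matrix is not numeric")
  if (ncol(X) != schema$n_features)
    stop_idscreen("idscreen_schema_error",
                  "phonetic matrix has %d columns, schema requires %d",
                  ncol(X), schema$n_features)
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- apply(utils::head(bad, 5), 1, function(rc)
      sprintf("[%s, column %d]",
              rownames(X)[rc[1]] %||% as.character(rc[1]), rc[2]))
    stop_idscreen("idscreen_parse_error",
                  "phonetic matrix has %d non-finite cell(s), e.g. %s",
                  nrow(bad), paste(cells, collapse = ", "))
  }
  X
}

#' Read a phonetic feature matrix from delimited text
#'
#' Expects a header row, a `subject_id` column and one column per schema
#' feature.
#'
#' @param path CSV file path.
#' @param schema An [is2010_schema()].
#' @return Validated numeric matrix with subject ids as rownames.
#' @export
read_phonetic_matrix <- function(path, schema = is2010_schema()) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop_idscreen("idscreen_schema_error", "%s: missing 'subject_id' column",
                  basename(path))
  ids <- df$subject_id
  df$subject_id <- NULL
  X <- as.matrix(df)
  rownames(X) <- ids
  validate_phonetic_matrix(X, schema)
}
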