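# Feature-table assembly, stratified CV, metrics, boosting, chance bar.

toy_table <- function(n_pos = 10, n_ctl = 12, p = 5, sep = 0, seed = 1,
                      name = "toy") {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_pos * p, sep), n_pos, p),
               matrix(rnorm(n_ctl * p, 0), n_ctl, p))
    rownames(X) <- sprintf("s%02d", seq_len(n_pos + n_ctl))
    feature_table(X, rep(c("positive", "control"), c(n_pos, n_ctl)), name)
  })
}

test_that("stratified folds keep both classes in every fold and are seed-stable", {
  labels <- factor(rep(c("positive", "control"), c(33, 37)))
  f1 <- stratified_folds(labels, k = 5, seed = 99)
  f2 <- stratified_folds(labels, k = 5, seed = 99)
  expect_identical(f1, f2)
  for (k in 1:5) {
    expect_true(all(table(labels[f1 == k]) >= 1))
    expect_true(abs(sum(f1 == k) - 14) <= 1)
  }
  expect_false(identical(f1, stratified_folds(labels, k = 5, seed = 100)))
  expect_error(stratified_folds(factor(rep(c("a", "b"), c(3, 40))), k = 5),
               class = "idscreen_stratification_error")
})

test_that("metrics match hand-computed values on a fixed confusion", {
  # 10 subjects: 4 positive (3 found), 6 control (5 found)
  truth <- factor(rep(c("positive", "control"), c(4, 6)),
                  levels = c("control", "positive"))
  pred <- factor(c("positive", "positive", "positive", "control",
                   "control", "control", "control", "control", "positive",
                   "control"), levels = c("control", "positive"))
  m <- classification_metrics(truth, pred, "weighted")
  # confusion: TPpos=3 FNpos=1, TNctl=5 FPctl=1
  # precision: ctl 5/6, pos 3/4; recall: ctl 5/6, pos 3/4
  # weighted by support (6, 4)/10
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["precision"]), 0.6 * 5 / 6 + 0.4 * 3 / 4)
  expect_equal(unname(m["recall"]), 0.6 * 5 / 6 + 0.4 * 3 / 4)
  expect_equal(unname(m["f1"]), 0.6 * (5 / 6) + 0.4 * (3 / 4))  # prec == rec per class
  mp <- classification_metrics(truth, pred, "positive")
  expect_equal(unname(mp["precision"]), 3 / 4)
  expect_equal(unname(mp["recall"]), 3 / 4)
  mm <- classification_metrics(truth, pred, "macro")
  expect_equal(unname(mm["recall"]), (5 / 6 + 3 / 4) / 2)
})

test_that("identical feature rows yield majority-class accuracy", {
  n_pos <- 8; n_ctl <- 14
  X <- matrix(1, n_pos + n_ctl, 4)
  tab <- feature_table(X, rep(c("positive", "control"), c(n_pos, n_ctl)), "flat")
  rep <- evaluate(tab, k = 2, seed = 5)
  expect_true(all(abs(rep$accuracy - n_ctl / (n_pos + n_ctl)) < 0.15))
})

test_that("widely separated Gaussian clusters are classified perfectly by GNB", {
  tab <- toy_table(n_pos = 12, n_ctl = 12, sep = 10, seed = 2)
  rep <- evaluate(tab, classifiers = "gaussian_nb", k = 4, seed = 3)
  expect_equal(rep$accuracy, 1.0)
  expect_equal(rep$f1, 1.0)
  expect_true(rep$above_chance)
})

test_that("evaluation is bit-identical for a fixed seed", {
  tab <- toy_table(sep = 1.2, seed = 4)
  r1 <- evaluate(tab, k = 3, seed = 777)
  r2 <- evaluate(tab, k = 3, seed = 777)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "cv")$folds, attr(r2, "cv")$folds)
})

test_that("the AdaBoost ensemble learns a separable rule and weights its stumps", {
  withr::with_seed(31, {
    x <- matrix(rnorm(60 * 2), 60, 2)
    y <- factor(ifelse(x[, 1] + x[, 2] > 0, "positive", "control"))
    fit <- ada_boost(x, y, n_rounds = 30)
    expect_gt(length(fit$stumps), 3)
    expect_true(all(fit$alphas > 0))
    expect_gt(mean(predict(fit, x) == y), 0.9)
  })
  expect_error(ada_boost(matrix(1, 4, 2), factor(c("a", "b", "c", "a"))),
               class = "idscreen_contract_error")
})

test_that("the chance bar is a strict comparison at 0.646", {
  rep <- data.frame(classifier = "gaussian_nb",
                    feature_set = c("a", "b", "c"),
                    accuracy = c(0.796, 0.646, 0.5))
  flags <- chance_comparison(rep)
  expect_equal(unname(flags), c(TRUE, FALSE, FALSE))
})

test_that("feature tables validate their shape and labels", {
  X <- matrix(0, 4, 30)
  expect_error(feature_table(X, c("positive", "control", "x", "control"), "geometric30"),
               class = "idscreen_contract_error")
  expect_error(feature_table(matrix(0, 4, 29), rep(c("positive", "control"), 2),
                             "geometric30"),
               class = "idscreen_schema_error")
  tab <- feature_table(X, rep(c("positive", "control"), 2), "geometric30")
  expect_equal(levels(tab$labels), c("control", "positive"))
})

test_that("the three assembled tables align subjects and recompute consistently", {
  spec <- cohort_spec(n_positive = 5, n_control = 6, frames_per_subject = 5,
                      seed = 17L)
  coh <- simulate_cohort(spec)
  meas <- cohort_measurements(coh$subjects)
  ctl <- meas[match(coh$labels$subject_id[coh$labels$group == "control"],
                    meas$subject_id), ]
  ref <- fit_normative_reference(ctl)
  cvi <- cvi_cohort(meas, ref)
  reduced <- kpca_reduce(coh$phonetic, n_components = 10)
  colnames(reduced) <- NULL
  tabs <- assemble_feature_tables(meas, cvi, cbind(reduced, matrix(0, 11, 28)),
                                  coh$labels)
  expect_equal(ncol(tabs$geometric30$X), 30L)
  expect_equal(ncol(tabs$geometric_cvi31$X), 31L)
  expect_equal(ncol(tabs$phonetic38$X), 38L)
  expect_equal(tabs$geometric30$subject_ids, tabs$phonetic38$subject_ids)
  expect_equal(tabs$geometric30$subject_ids, coh$labels$subject_id)
  # the CVI column equals sigma_z recomputed per subject from scratch
  for (i in seq_len(nrow(meas))) {
    z <- z_scores(unlist(meas[i, cvi_measurements()]), ref)
    expect_equal(unname(tabs$geometric_cvi31$X[meas$subject_id[i], "CVI"]),
                 cvi_score(z))
  }
  # orphaned ids are reported
  bad_labels <- rbind(coh$labels, data.frame(subject_id = "ghost", group = "control"))
  expect_error(assemble_feature_tables(meas, cvi, cbind(reduced, matrix(0, 11, 28)),
                                       bad_labels),
               "ghost", class = "idscreen_contract_error")
})
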