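# z-scoring against a normative reference and the sigma_z dispersion index.

fake_measurements <- function(n, mu = NULL, s = NULL, seed = 1) {
  m <- cvi_measurements()
  mu <- mu %||% seq(20, 120, length.out = 11)
  s <- s %||% rep(4, 11)
  withr::with_seed(seed, {
    df <- as.data.frame(lapply(seq_along(m), function(i) rnorm(n, mu[i], s[i])))
    names(df) <- m
    df$subject_id <- sprintf("s%03d", seq_len(n))
    df
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the CVI consumes exactly the first 11 measurements", {
  expect_equal(cvi_measurements(), sprintf("F%02d", 1:11))
  expect_length(cvi_measurements(), 11L)
})

test_that("the normative reference is the control-group mean and SD", {
  df <- fake_measurements(2)
  df[1, cvi_measurements()] <- 1
  df[2, cvi_measurements()] <- 3
  ref <- fit_normative_reference(df)
  expect_equal(ref$mean, rep(2, 11))
  expect_equal(ref$sd, rep(sd(c(1, 3)), 11))
  expect_equal(attr(ref, "provenance"), "fitted-from-controls")
})

test_that("identical controls trigger a zero-variance error naming the measurement", {
  df <- fake_measurements(5)
  df$F04 <- 7
  err <- tryCatch(fit_normative_reference(df), error = identity)
  expect_s3_class(err, "idscreen_degenerate_error")
  expect_match(conditionMessage(err), "F04")
})

test_that("fitting 200 simulated controls recovers the true parameters within 3 SE", {
  n <- 200
  mu_true <- seq(30, 130, length.out = 11)
  s_true <- seq(2, 8, length.out = 11)
  df <- fake_measurements(n, mu_true, s_true, seed = 2024)
  ref <- fit_normative_reference(df)
  se_mean <- s_true / sqrt(n)
  se_sd <- s_true / sqrt(2 * (n - 1))
  expect_true(all(abs(ref$mean - mu_true) < 3 * se_mean))
  expect_true(all(abs(ref$sd - s_true) < 3 * se_sd))
})

test_that("z-scores standardize exactly", {
  df <- fake_measurements(20)
  ref <- fit_normative_reference(df)
  at_mean <- setNames(ref$mean, ref$measurement)
  expect_equal(z_scores(at_mean, ref), setNames(rep(0, 11), ref$measurement))
  plus_sd <- setNames(ref$mean + ref$sd, ref$measurement)
  expect_equal(z_scores(plus_sd, ref), setNames(rep(1, 11), ref$measurement))
  withr::with_seed(8, {
    x <- setNames(rnorm(11, 50, 10), ref$measurement)
    expect_equal(z_scores(x, ref),
                 setNames((as.numeric(x) - ref$mean) / ref$sd, ref$measurement))
  })
  expect_error(z_scores(at_mean[-3], ref), "F03",
               class = "idscreen_contract_error")
})

test_that("sigma_z of a constant vector is zero; alternating signs match a two-pass oracle", {
  expect_equal(cvi_score(rep(2.7, 11)), 0)
  z <- rep(c(1, -1), length.out = 11)
  two_pass <- sqrt(sum((z - mean(z))^2) / length(z))
  expect_equal(cvi_score(z), two_pass)
  expect_equal(cvi_score(z, "sample"), sqrt(sum((z - mean(z))^2) / (length(z) - 1)))
  expect_error(cvi_score(1), class = "idscreen_contract_error")
})

test_that("sigma_z is translation-invariant and absolutely homogeneous", {
  withr::with_seed(77, {
    for (i in 1:20) {
      z <- rnorm(11)
      c0 <- rnorm(1, 0, 5)
      k <- rnorm(1, 0, 3)
      expect_equal(cvi_score(z + c0), cvi_score(z), tolerance = 1e-12)
      expect_equal(cvi_score(k * z), abs(k) * cvi_score(z), tolerance = 1e-12)
    }
  })
})

test_that("subjects from the normative distribution score below 2x-inflated subjects", {
  df <- fake_measurements(400, seed = 31)
  ref <- fit_normative_reference(df[1:200, ])
  typical <- cvi_cohort(df[201:400, ], ref)$cvi
  inflated_df <- df[201:400, ]
  for (m in cvi_measurements())
    inflated_df[[m]] <- ref$mean[match(m, ref$measurement)] +
      2 * (inflated_df[[m]] - ref$mean[match(m, ref$measurement)])
  inflated <- cvi_cohort(inflated_df, ref)$cvi
  expect_lt(median(typical), median(inflated))
})

test_that("percentile tables are monotone, shift-equivariant and oracle-consistent", {
  expect_equal(percentile_table(list(g = 5))$cvi, rep(5, 12))
  tab <- percentile_table(list(g = 1:100), levels = 50)
  expect_equal(tab$cvi, unname(quantile(1:100, 0.5, type = 7)))
  withr::with_seed(55, {
    s <- rexp(40)
    tab2 <- percentile_table(list(a = s))
    expect_true(all(diff(tab2$cvi) >= -1e-12))
    tab3 <- percentile_table(list(a = s + 10))
    expect_equal(tab3$cvi, tab2$cvi + 10, tolerance = 1e-12)
  })
  expect_error(percentile_table(list(a = numeric(0))),
               class = "idscreen_empty_error")
})

test_that("a positive group with inflated deviations dominates at every percentile", {
  df <- fake_measurements(120, seed = 99)
  ref <- fit_normative_reference(df[1:60, ])
  pos_df <- df[61:120, ]
  for (m in cvi_measurements())
    pos_df[[m]] <- ref$mean[match(m, ref$measurement)] +
      2.5 * (pos_df[[m]] - ref$mean[match(m, ref$measurement)])
  tab <- percentile_table(list(control = cvi_cohort(df[1:60, ], ref)$cvi,
                               positive = cvi_cohort(pos_df, ref)$cvi))
  wide <- split(tab$cvi, tab$group)
  expect_true(all(wide$positive >= wide$control))
})

test_that("the risk flag is a strict comparison and a 95th-percentile cutoff flags ~5% of controls", {
  expect_false(risk_flag(0, 1))
  expect_false(risk_flag(1, 1))
  expect_true(risk_flag(1.0001, 1))
  df <- fake_measurements(200, seed = 12)
  ref <- fit_normative_reference(df)
  scores <- cvi_cohort(df, ref)$cvi
  cutoff <- unname(quantile(scores, 0.95, type = 7))
  frac <- mean(risk_flag(scores, cutoff))
  expect_lte(frac, 0.05 + 1e-9)   # by construction of the empirical percentile
  expect_gte(frac, 0.03)
})

test_that("normative references round-trip through YAML", {
  df <- fake_measurements(10)
  ref <- fit_normative_reference(df)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_normative_reference(ref, path)
  back <- read_normative_reference(path)
  expect_equal(back$mean, ref$mean, tolerance = 1e-9)
  expect_equal(back$sd, ref$sd, tolerance = 1e-9)
  expect_equal(attr(back, "provenance"), "fitted-from-controls")
})
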