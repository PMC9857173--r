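# Geometric primitives and the 30-feature registry.

test_that("primitives reproduce closed-form cases", {
  expect_equal(point_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(point_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), 2)
  expect_error(polyline_length(rbind(c(0, 0, 0), c(1, 0, 0))),
               class = "idscreen_contract_error")
  expect_equal(vertex_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  eq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(vertex_angle(eq[2, ], eq[1, ], eq[3, ]), 60)
  expect_equal(vector_angle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(vector_angle(c(1, 2, 3), -c(1, 2, 3)), 180)
  expect_error(vertex_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               class = "idscreen_degenerate_error")
  expect_error(vector_angle(c(0, 0, 0), c(1, 0, 0)),
               class = "idscreen_degenerate_error")
})

test_that("primitives match independent component-wise oracles on random input", {
  withr::with_seed(101, {
    for (i in 1:200) {
      a <- rnorm(3, 0, 10); b <- rnorm(3, 0, 10); c <- rnorm(3, 0, 10)
      expect_equal(point_distance(a, b), sqrt(sum((a - b)^2)), tolerance = 1e-12)
      P <- matrix(rnorm(15, 0, 5), 5, 3)
      expect_equal(polyline_length(P),
                   sum(vapply(1:4, function(j) sqrt(sum((P[j + 1, ] - P[j, ])^2)), 0)),
                   tolerance = 1e-12)
      expect_equal(vertex_angle(a, b, c), oracle_angle(a - b, c - b),
                   tolerance = 1e-9)
      expect_equal(vector_angle(a, c), oracle_angle(a, c), tolerance = 1e-9)
      # triangle inequality: any 3-point arc at least the endpoint chord
      expect_gte(polyline_length(rbind(a, b, c)) - point_distance(a, c), -1e-12)
    }
  })
})

test_that("the registry defines 30 features with the published identities", {
  reg <- feature_registry()
  expect_length(reg, 30L)
  expect_equal(names(reg), sprintf("F%02d", 1:30))
  expect_equal(unname(vapply(reg, `[[`, "", "name")[c("F01", "F06", "F09", "F30")]),
               c("ex-ex", "t-sn-t", "t-gn-t", "a-s"))
  units <- feature_units(reg)
  expect_equal(sum(units == "length"), 17L)   # F01-F13, F20-F23
  expect_equal(sum(units == "degrees"), 13L)  # F14-F19, F24-F30
})

test_that("every feature matches the straight-line transcription oracle on random faces", {
  withr::with_seed(202, {
    for (i in 1:50) {
      subj <- random_face()
      expect_equal(unclass(compute_features(subj))[1:30],
                   oracle_features(subj), tolerance = 1e-9, ignore_attr = TRUE)
    }
  })
})

test_that("features are invariant under rigid motion and covariant under scaling", {
  reg <- feature_registry()
  units <- feature_units(reg)
  withr::with_seed(303, {
    for (i in 1:10) {
      subj <- random_face()
      f0 <- compute_features(subj, reg)
      moved <- transform_subject(subj, random_rotation(), rnorm(3, 0, 30))
      expect_equal(compute_features(moved, reg), f0, tolerance = 1e-9)
      k <- runif(1, 0.3, 3)
      fs <- compute_features(scale_subject(subj, k), reg)
      expect_equal(fs[units == "length"], f0[units == "length"] * k,
                   tolerance = 1e-9, ignore_attr = TRUE)
      expect_equal(fs[units == "degrees"], f0[units == "degrees"],
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  })
})

test_that("arcs through an interior landmark dominate the endpoint chord", {
  withr::with_seed(404, {
    for (i in 1:25) {
      f <- compute_features(random_face())
      expect_gte(f[["F06"]], f[["F03"]] - 1e-12)
      expect_gte(f[["F09"]], f[["F03"]] - 1e-12)
    }
  })
})

test_that("angle outputs stay in [0, 180] and all features stay finite", {
  withr::with_seed(505, {
    for (i in 1:25) {
      f <- compute_features(random_face(sd = 2))
      expect_true(all(is.finite(f)))
      ang <- f[feature_units() == "degrees"]
      expect_true(all(ang >= 0 & ang <= 180))
      expect_true(all(f[feature_units() == "length"] >= 0))
    }
  })
})

test_that("mirroring about the sagittal plane leaves the features unchanged", {
  tf <- make_template_face()
  expect_equal(compute_features(mirror_subject(tf)), compute_features(tf),
               tolerance = 1e-9)
  withr::with_seed(606, {
    subj <- random_face()
    f0 <- compute_features(subj)
    fm <- compute_features(mirror_subject(subj))
    # bilateral distances are exactly preserved under relabeled reflection
    for (id in c("F01", "F03", "F04", "F07", "F08", "F05"))
      expect_equal(fm[[id]], f0[[id]], tolerance = 1e-9)
  })
})

test_that("the 68-point fallback eye scheme works without eye-region landmarks", {
  tf <- make_template_face()
  noeye <- idscreen:::new_subject_landmarks("noeye", tf$face, NULL,
                                            tf$gaze_left, tf$gaze_right)
  reg_face <- feature_registry(eye_scheme = "face")
  f <- compute_features(noeye, reg_face)
  expect_true(all(is.finite(f)))
  expect_equal(f[["F01"]], point_distance(tf$face[37, ], tf$face[46, ]))  # ex-ex = outer corners
  # the default eye scheme must refuse to run without eye points
  expect_error(compute_features(noeye, feature_registry()),
               class = "idscreen_config_error")
})

test_that("the printed right-eye height duplicates the left; the override mirrors it", {
  tf <- make_template_face()
  printed <- compute_features(tf, feature_registry(h_re_as_printed = TRUE))
  fixed <- compute_features(tf, feature_registry(h_re_as_printed = FALSE))
  expect_equal(printed[["F21"]], printed[["F20"]])
  expect_equal(fixed[["F21"]], point_distance(tf$eye[46, ], tf$eye[40, ]))
})

test_that("landmark maps serialize to YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_landmark_map(feature_registry(), path)
  m <- yaml::read_yaml(path)
  expect_length(m, 30L)
  expect_equal(m$F01$points[[1]]$scheme, "eye")
  expect_equal(m$F01$points[[1]]$index, 8L)
})
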