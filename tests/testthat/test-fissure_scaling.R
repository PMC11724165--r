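test_that("survey length-range means are unweighted per-fault means", {
  expect_equal(mean_length_range(table2_survey()),
               c(mean_min = 76.6, mean_max = 942))
  one <- data.frame(fault_name = "F", fissure_count = 1L,
                    length_min_m = 10, length_max_m = 10)
  expect_equal(mean_length_range(one), c(mean_min = 10, mean_max = 10))
  two <- data.frame(fault_name = c("A", "B"), fissure_count = c(1L, 1L),
                    length_min_m = c(0.5, 1.5), length_max_m = c(1, 3))
  expect_equal(mean_length_range(two), c(mean_min = 1, mean_max = 2))
  expect_error(mean_length_range(two[0, ]), "non-empty")
})

test_that("Maduo total length is unit length times fissure count", {
  expect_equal(maduo_total_length(942, 653), 615126)
  expect_equal(maduo_total_length(1, 5), 5)
  # cross-check the non-integer case by repeated addition
  expect_equal(maduo_total_length(76.6, 653), sum(rep(76.6, 653)))
})

test_that("magnitude inversions hit their exact anchor points", {
  expect_equal(rupture_length_from_magnitude(5.92), 1)
  expect_equal(rupture_length_from_magnitude(6.80), 10)
  # frozen from the exact inversion; forward substitution recovers 7.4
  expect_equal(rupture_length_from_magnitude(7.4), 48.0638086, tolerance = 1e-8)
  expect_equal(width_from_magnitude(6.81), 1)
  expect_equal(width_from_magnitude(7.59), 10)
  expect_equal(width_from_magnitude(6.9), 1.30432139, tolerance = 1e-8)
})

test_that("both scaling inversions round-trip and increase with magnitude", {
  m <- seq(5, 9.5, by = 0.05)
  expect_equal(magnitude_from_rupture_length(rupture_length_from_magnitude(m)),
               m, tolerance = 1e-9)
  expect_equal(magnitude_from_width(width_from_magnitude(m)),
               m, tolerance = 1e-9)
  expect_true(all(diff(rupture_length_from_magnitude(m)) > 0))
  expect_true(all(diff(width_from_magnitude(m)) > 0))
})

test_that("total fissure length scales linearly with rupture length", {
  cst <- model_constants()
  lM <- cst$maduo_rupture_length_lM
  expect_equal(total_fissure_length(lM, cst), 615126)
  expect_equal(total_fissure_length(0, cst), 0)
  expect_equal(2 * total_fissure_length(lM / 2, cst), 615126)
})

test_that("event geometry composes the scaling chain", {
  cst <- model_constants()
  # recorded rupture length takes precedence over the inversion
  g_rec <- geometry_for_event(list(magnitude = 7.4, rupture_length_km = 70),
                              cst)
  expect_equal(g_rec$rupture_length_km, 70)
  expect_equal(g_rec$initial_total_length_m,
               total_fissure_length(70, cst))
  # frozen from the exact composed chain (both inversions + scaling)
  g <- geometry_for_event(list(magnitude = 6.9, rupture_length_km = NA), cst)
  expect_equal(g$initial_total_length_m, 166257.89, tolerance = 1e-6)
  expect_equal(g$initial_width_m, 1.304321, tolerance = 1e-5)
  expect_equal(g$recovery_time_a, 942 / 0.49)
  expect_error(geometry_for_event(list(magnitude = 6.8,
                                       rupture_length_km = NA), cst),
               "below the threshold")
})

test_that("derived geometry grows strictly with magnitude", {
  cst <- model_constants()
  mags <- seq(6.9, 8.5, by = 0.1)
  L0 <- vapply(mags, function(m) {
    geometry_for_event(list(magnitude = m), cst)$initial_total_length_m
  }, numeric(1))
  W0 <- vapply(mags, function(m) {
    geometry_for_event(list(magnitude = m), cst)$initial_width_m
  }, numeric(1))
  expect_true(all(diff(L0) > 0))
  expect_true(all(diff(W0) > 0))
})
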