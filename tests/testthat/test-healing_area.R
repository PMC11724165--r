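test_that("fissure length decays linearly to zero at recovery time", {
  cst <- model_constants()
  g <- make_geometry(615126, 1.4, cst)
  t_rec <- recovery_time(cst)
  expect_equal(length_at_age(g, 0, cst), 615126)
  expect_equal(length_at_age(g, t_rec, cst), 0)
  expect_equal(length_at_age(g, t_rec + 100, cst), 0)
  expect_equal(length_at_age(g, t_rec / 2, cst), 615126 / 2, tolerance = 1e-9)
})

test_that("fissure width widens linearly then closes at recovery", {
  cst <- model_constants()
  g <- make_geometry(1000, 1.304, cst)
  expect_equal(width_at_age(g, 0, cst), 1.304)
  expect_equal(width_at_age(g, 10, cst), 1.804)
  expect_equal(width_at_age(g, recovery_time(cst), cst), 0)
})

test_that("instantaneous areas follow the U-shaped cross-section", {
  cst <- model_constants()
  g <- make_geometry(615126, 1.4, cst)
  a0 <- instantaneous_areas(g, 0, cst)
  expect_equal(a0[["sidewall_m2"]], 2 * 3 * 615126)  # both walls, D = 3
  expect_equal(a0[["bottom_m2"]], 615126 * 1.4)
  expect_equal(unname(instantaneous_areas(g, recovery_time(cst) + 1, cst)),
               c(0, 0))
  unit <- instantaneous_areas(make_geometry(1, 2, cst), 0, cst)
  expect_equal(unname(unit), c(6, 2))
})

test_that("time-averaged areas have the expected analytic limits", {
  cst <- model_constants()
  g <- make_geometry(615126, 1.4, cst)
  # no healing: geometry is constant, averages equal the initial areas
  frozen <- model_constants(length_heal_rate_rL = 0,
                            width_widen_rate_rW = 0)
  g0 <- make_geometry(615126, 1.4, frozen)
  b <- time_averaged_areas(g0, 500, frozen)
  expect_equal(b$sidewall_area_m2, 2 * 3 * 615126)
  expect_equal(b$bottom_area_m2, 615126 * 1.4)
  # T -> 0+: average tends to the initial sidewall area
  b0 <- time_averaged_areas(g, 1e-6, cst)
  expect_equal(b0$sidewall_area_m2, 2 * 3 * 615126, tolerance = 1e-4)
  # averaged over exactly the recovery time, the linear decay halves Sw
  bh <- time_averaged_areas(g, recovery_time(cst), cst)
  expect_equal(bh$sidewall_area_m2, 3 * 615126, tolerance = 1e-9)
  expect_error(time_averaged_areas(g, 0, cst), "positive")
  expect_error(time_averaged_areas(g, -5, cst), "positive")
})

test_that("closed-form averages match numeric quadrature on random geometries", {
  cst <- model_constants()
  set.seed(42)
  for (i in 1:100) {
    g <- make_geometry(stats::runif(1, 1e3, 1e6),
                       stats::runif(1, 0.1, 5), cst)
    elapsed <- stats::runif(1, 1, 4000)  # straddles the recovery time
    b <- time_averaged_areas(g, elapsed, cst)
    q <- quadrature_avg_areas(g, elapsed, cst)
    expect_equal(b$sidewall_area_m2, q[["sidewall"]], tolerance = 1e-6)
    expect_equal(b$bottom_area_m2, q[["bottom"]], tolerance = 1e-6)
    expect_equal(b$total_area_m2,
                 b$sidewall_area_m2 + b$bottom_area_m2, tolerance = 1e-9)
  }
})

test_that("the total-length healing variant matches its own quadrature", {
  cst <- model_constants()
  g <- make_geometry(5000, 1.2, cst)
  for (elapsed in c(100, 5000 / 0.49, 2e4)) {
    b <- time_averaged_areas(g, elapsed, cst, healing_model = "total_length")
    t <- seq(0, elapsed, length.out = 1e5 + 1)
    L <- length_at_age(g, t, cst, healing_model = "total_length")
    W <- width_at_age(g, t, cst, healing_model = "total_length")
    expect_equal(b$sidewall_area_m2, trapz(t, 2 * 3 * L) / elapsed,
                 tolerance = 1e-6)
    expect_equal(b$bottom_area_m2, trapz(t, L * W) / elapsed,
                 tolerance = 1e-6)
  }
})

test_that("averaged sidewall area is non-increasing in elapsed time", {
  cst <- model_constants()
  g <- make_geometry(2e5, 1.3, cst)
  Ts <- c(1, 10, 100, 1000, 1922, 3000, 10000)
  sw <- vapply(Ts, function(T) {
    time_averaged_areas(g, T, cst)$sidewall_area_m2
  }, numeric(1))
  expect_true(all(diff(sw) <= 0))
  expect_true(all(sw > 0))  # finite T keeps a positive averaged contribution
})

test_that("catalog budgets are additive and permutation-invariant", {
  cst <- model_constants()
  events <- data.frame(
    event_id = c("A", "B"), year = c(2000L, 1900L),
    magnitude = c(7.0, 7.5), rupture_length_km = c(NA, NA)
  )
  both <- catalog_area_budget(events, cst)
  singles <- lapply(1:2, function(i) {
    catalog_area_budget(events[i, ], cst)$totals
  })
  expect_equal(both$totals$sidewall_area_m2,
               singles[[1]]$sidewall_area_m2 + singles[[2]]$sidewall_area_m2)
  expect_equal(both$totals$bottom_area_m2,
               singles[[1]]$bottom_area_m2 + singles[[2]]$bottom_area_m2)
  # duplicating one event doubles its totals
  dup <- suppressWarnings(
    catalog_area_budget(events[c(1, 1), ], cst)$totals
  )
  expect_equal(dup$sidewall_area_m2, 2 * singles[[1]]$sidewall_area_m2)
  # permuting rows changes nothing in the totals
  perm <- catalog_area_budget(events[2:1, ], cst)
  expect_equal(perm$totals$total_area_m2, both$totals$total_area_m2)
  # empty catalog: nothing to sum
  empty <- catalog_area_budget(events[0, ], cst)
  expect_equal(empty$totals$total_area_m2, 0)
})

test_that("catalog validation rejects future events and unfiltered input", {
  cst <- model_constants()
  future <- data.frame(event_id = "F", year = 2100L, magnitude = 7.0,
                       rupture_length_km = NA)
  expect_error(catalog_area_budget(future, cst), "postdates")
  low <- data.frame(event_id = "L", year = 2000L, magnitude = 6.0,
                    rupture_length_km = NA)
  expect_error(catalog_area_budget(low, cst), "filter_by_threshold")
  # an event in the reference year contributes its initial areas
  now <- data.frame(event_id = "N", year = 2022L, magnitude = 7.0,
                    rupture_length_km = NA)
  b <- catalog_area_budget(now, cst)
  g <- geometry_for_event(now, cst)
  expect_equal(b$totals$sidewall_area_m2,
               2 * cst$depth_D * g$initial_total_length_m)
})
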