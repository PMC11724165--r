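flux_df <- function(flux, group = "control", hour = 10,
                    date = "2022-04-01", campaign = "maduo") {
  n <- length(flux)
  data.frame(campaign = campaign, group = group, date = date, hour = hour,
             replicate = seq_len(n), flux_umol_m2_s = flux,
             stringsAsFactors = FALSE)
}

test_that("replicates collapse to per-timepoint means", {
  tp <- collapse_replicates(flux_df(c(2, 3, 4)))
  expect_equal(nrow(tp), 1)
  expect_equal(tp$flux_umol_m2_s, 3)
  expect_equal(tp$n_replicates, 3L)
  expect_warning(one <- collapse_replicates(flux_df(5)), "fewer than 3")
  expect_equal(one$flux_umol_m2_s, 5)
  four <- rbind(flux_df(c(1, 2, 3)), flux_df(9))
  four$replicate <- c(1, 2, 3, 3)
  expect_error(collapse_replicates(four), "more than 3")
})

test_that("record validation enforces the measurement protocol", {
  bad_hour <- flux_df(c(1, 2, 3)); bad_hour$hour <- 19
  expect_error(collapse_replicates(bad_hour), "measurement window")
  neg <- flux_df(c(1, -2, 3))
  expect_error(collapse_replicates(neg), "negative flux")
})

test_that("campaign timepoint counts are preserved through collapsing", {
  # two campaigns sized like the field design: 530 + 325 timepoint-groups
  camp1 <- generate_campaign(n_days = 18, noise_cv = 0.1, seed = 11,
                             campaign = "maduo")
  # drop the whole control series on day 1: 18*10*3 - 10 = 530 timepoints
  camp1 <- camp1[!(camp1$group == "control" & camp1$date == min(camp1$date)), ]
  camp2 <- generate_campaign(n_days = 11, noise_cv = 0.1, seed = 12,
                             campaign = "menyuan")
  # drop five bottom-group timepoints on day 1: 11*10*3 - 5 = 325
  camp2 <- camp2[!(camp2$group == "bottom" & camp2$date == min(camp2$date) &
                     camp2$hour <= 12), ]
  tp <- collapse_replicates(rbind(camp1, camp2))
  expect_equal(sum(tp$campaign == "maduo"), 530)
  expect_equal(sum(tp$campaign == "menyuan"), 325)
  expect_equal(nrow(tp), 855)
  expect_true(all(tp$n_replicates == 3L))
})

test_that("annualization converts umol/m2/s to g CO2/m2/a", {
  expect_equal(annualize_flux(0), 0)
  # frozen by dimensional analysis: 44.01e-6 g/umol x 31,536,000 s/a
  expect_equal(annualize_flux(1), 1387.8994, tolerance = 1e-7)
  # the mean flux that annualizes to the uncracked-surface rate
  expect_equal(annualize_flux(1.0987468), 1524.95, tolerance = 1e-6)
  expect_equal(annualize_flux(2), 2 * annualize_flux(1))  # linearity
})

test_that("group summaries report annualized rates and control ratios", {
  records <- generate_campaign(n_days = 3, noise_cv = 0, seed = 1)
  s <- summarize_groups(records)
  expect_setequal(s$group, c("control", "sidewall", "bottom"))
  expect_equal(s$ratio_to_control[s$group == "control"], 1)
  expect_equal(100 * s$ratio_to_control[s$group == "sidewall"], 63.51)
  expect_equal(100 * s$ratio_to_control[s$group == "bottom"], 33.76)
  expect_equal(s$annual_rate_g_m2_a,
               annualize_flux(s$mean_flux_umol_m2_s))
  no_control <- records[records$group != "control", ]
  expect_error(summarize_groups(no_control), "control")
})

test_that("group summaries are invariant to record order", {
  records <- generate_campaign(n_days = 2, noise_cv = 0.15, seed = 7)
  s1 <- summarize_groups(records)
  set.seed(99)
  shuffled <- records[sample(nrow(records)), ]
  s2 <- summarize_groups(shuffled)
  s2 <- s2[match(s1$group, s2$group), ]
  rownames(s2) <- NULL
  expect_equal(s1, s2)
})
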