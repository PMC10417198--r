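test_that("percent error is 100*error/concentration with a guarded domain", {
  expect_equal(percent_error(300, 30), 10)
  expect_equal(percent_error(1000, 50), 5)
  expect_warning(v <- percent_error(0, 5),
                 class = "sep_undefined_percent_error")
  expect_true(is.na(v))
  expect_error(percent_error(10, -1), ">= 0")
})

test_that("detection rule is strict and zero readings abstain", {
  x <- matrix(c(300, 300, 0), 3, 1, dimnames = list(NULL, "P"))
  tab <- profile_from_matrix(x)
  tab$P_err <- c(99, 100, 0)
  expect_warning(det <- detection_filter(tab), "empty roster")
  expect_equal(unname(det$pass[, "P"]), c(TRUE, FALSE, NA))
  expect_equal(det$summary$n_nonzero, 2L)
  # 1 pass of 2 nonzero readings is not a strict majority -> excluded
  expect_equal(det$roster, character(0))
})

test_that("inclusion needs a strict majority of nonzero readings", {
  x <- matrix(100, 5, 2, dimnames = list(NULL, c("P", "S")))
  tab <- profile_from_matrix(x)
  tab$P_err <- c(10, 10, 10, 50, 50)   # 3/5 pass
  tab$S_err <- c(10, 10, 50, 50, 50)   # 2/5 pass
  expect_equal(detection_filter(tab)$roster, "P")
})

test_that("a well-behaved synthetic table keeps the full 14-element roster", {
  cfg <- generator_config(seed = 2)
  tab <- generate_profile_table(cfg)
  expect_equal(detection_filter(tab)$roster, SEP_ELEMENTS)
})

test_that("slope-improvement rule selects 60 s on the 1/sqrt(t) curve", {
  t <- c(15, 30, 45, 60, 75, 90)
  pe <- 1 / sqrt(t)
  sel <- select_exposure_time(t, pe)
  # oracle: recompute the consecutive-slope improvement rates directly
  sl <- diff(pe) / diff(t)
  rates <- 100 * abs(diff(sl)) / abs(sl[-length(sl)])
  expect_equal(sel$improvement_rates, rates)
  expect_equal(which(rates < 33)[1], 3L)   # stop between slope 3 and 4
  expect_equal(sel$stop_pair, 3L)
  expect_equal(sel$time_s, 60)
  expect_true(sel$converged)
})

test_that("degenerate series stop at the first boundary", {
  t <- c(10, 20, 30, 40)
  const <- select_exposure_time(t, rep(5, 4))
  expect_equal(const$time_s, 20)
  expect_true(const$zero_slope)
  lin <- select_exposure_time(t, c(40, 30, 20, 10))
  expect_equal(lin$improvement_rates, c(0, 0))
  expect_equal(lin$time_s, 20)
  expect_error(select_exposure_time(c(10, 20), c(1, 2)), "insufficient")
})

test_that("selection is invariant to positive rescaling of the series", {
  set.seed(31)
  for (i in 1:10) {
    t <- sort(runif(6, 5, 100))
    pe <- 3 / sqrt(t) * exp(rnorm(6, 0, 0.1))
    a <- select_exposure_time(t, pe)
    b <- select_exposure_time(t, 17.3 * pe)
    expect_equal(a$time_s, b$time_s)
    expect_equal(a$improvement_rates, b$improvement_rates, tolerance = 1e-10)
  }
})

test_that("non-converging series return the last time flagged", {
  # percent errors engineered so every improvement rate stays >= 33%
  pe <- c(100, 40, 16, 6.4)
  sel <- select_exposure_time(c(10, 20, 30, 40), pe)
  expect_false(sel$converged)
  expect_equal(sel$time_s, 40)
})

test_that("repeatability delta matches hand computation", {
  r <- repeatability_delta(c(100, 102, 98, 101, 99), rep(2, 5))
  expect_equal(r$se, sd(c(100, 102, 98, 101, 99)) / sqrt(5))
  expect_equal(round(r$se, 4), 0.7071)
  expect_equal(round(r$delta, 4), 1.2929)
  r0 <- repeatability_delta(rep(7, 5), rep(3, 5))
  expect_equal(r0$se, 0)
  expect_equal(r0$delta, 3)
  expect_error(repeatability_delta(5, 1), "insufficient")
})

test_that("delta is invariant to location shifts of the readings", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(5, 100, 3)
    e <- runif(5, 1, 4)
    expect_equal(repeatability_delta(x, e)$delta,
                 repeatability_delta(x + 123.4, e)$delta,
                 tolerance = 1e-10)
  }
})

test_that("repeatability summary preserves the delta identity per element", {
  reps <- generate_repeat_exposures(generator_config(seed = 4), n_rep = 5)
  sm <- repeatability_summary(reps)
  expect_equal(sm$element, SEP_ELEMENTS)
  expect_equal(sm$delta, sm$average_instrument_error - sm$se,
               tolerance = 1e-12)
  expect_true(all(sm$se >= 0))
  expect_true(all(sm$n_rep == 5L))
})

test_that("exposure-time report selects per element", {
  es <- generate_exposure_series(generator_config(seed = 1),
                                 c(15, 30, 45, 60, 75, 90))
  rep_ <- exposure_time_report(es)
  expect_equal(sort(rep_$element), sort(c("P", "S", "Cl", "K", "Ca")))
  expect_true(all(rep_$selected_time_s == 60))
})
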