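test_that("default design emits 8 groups x 5 samples with planted As zeros", {
  cfg <- generator_config(seed = 1)
  tab <- generate_profile_table(cfg)
  expect_equal(nrow(tab), 40L)
  expect_equal(sort(unique(tab$group)), sort(cfg$group_defs$group))
  expect_true(all(table(tab$group) == 5L))
  expect_equal(sum(tab$As_ppm > 0), 3L)
  expect_true(all(tab$As_err[tab$As_ppm == 0] == 0))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(seed = 7)
  expect_identical(generate_profile_table(cfg), generate_profile_table(cfg))
  expect_false(identical(
    generate_profile_table(cfg),
    generate_profile_table(generator_config(seed = 8))))
})

test_that("degenerate noise reproduces the baseline exactly", {
  cfg <- null_config(seed = 2, noise_cv = 0)
  tab <- generate_profile_table(cfg)
  for (el in cfg$element_roster) {
    expect_equal(tab[[paste0(el, "_ppm")]],
                 rep(cfg$baseline_ppm[[el]], nrow(tab)),
                 tolerance = 1e-12)
  }
})

test_that("unknown elements in effect maps raise configuration errors", {
  expect_error(generator_config(cooking_effects = c(Xx = 2)), "Xx")
  expect_error(generator_config(zero_inflation = c(Qq = 0.5)), "Qq")
  expect_error(
    generator_config(correlation_partners = list(Zz = c(P = 0.5))), "Zz")
})

test_that("concentrations and errors are non-negative across seeds", {
  for (s in 1:5) {
    tab <- generate_profile_table(generator_config(seed = s))
    m <- as.matrix(tab[, grep("_(ppm|err)$", names(tab))])
    expect_true(all(m >= 0))
  }
})

test_that("effect directions show up in generated group means", {
  up <- c("Cl", "Zn", "Th", "Cu", "Mn")
  for (s in 1:5) {
    tab <- generate_profile_table(
      generator_config(seed = s, site_effect_scale = 0,
                       collection_effect_scale = 0))
    cooked <- tab$preparation == "cooked"
    for (el in up) {
      expect_gt(mean(tab[[paste0(el, "_ppm")]][cooked]),
                mean(tab[[paste0(el, "_ppm")]][!cooked]))
    }
    expect_lt(mean(tab$Zr_ppm[cooked]), mean(tab$Zr_ppm[!cooked]))
    wild <- tab$production == "wild"
    expect_gt(mean(tab$S_ppm[wild]), mean(tab$S_ppm[!wild]))
  }
})

test_that("paired calibration sets follow the planted bias", {
  cfg <- generator_config(seed = 3, bias_slope = c(S = 2))
  ps <- generate_paired_calibration_set(cfg, "S", n = 10, noise_cv = 0)
  expect_equal(ps$instrument_ppm, ps$reference_ppm / 2, tolerance = 1e-12)
  expect_error(generate_paired_calibration_set(cfg, "S", n = 2),
               "insufficient")
  # default world: Zr/Th have no reference assay
  expect_error(
    generate_paired_calibration_set(generator_config(seed = 3), "Zr", n = 10),
    "bias_slope")
})

test_that("exposure series matches the closed form 1/sqrt(t)", {
  cfg <- generator_config(seed = 1)
  es <- generate_exposure_series(cfg, c(15, 30, 45, 60, 75, 90),
                                 coeffs = c(X = 1))
  expect_equal(round(es$percent_error, 4),
               c(0.2582, 0.1826, 0.1491, 0.1291, 0.1155, 0.1054))
  es2 <- generate_exposure_series(cfg, c(10, 40), coeffs = c(X = 2))
  expect_equal(round(es2$percent_error, 4), c(0.6325, 0.3162))
  es3 <- generate_exposure_series(cfg, 25, coeffs = c(X = 1))
  expect_equal(es3$percent_error, 1 / 5)
  expect_error(generate_exposure_series(cfg, c(-5, 10)), "domain")
  expect_error(generate_exposure_series(cfg, c(30, 15)), "domain")
})

test_that("repeat exposures honour the scatter scale and preconditions", {
  cfg <- generator_config(seed = 5)
  r0 <- generate_repeat_exposures(cfg, n_rep = 5, scatter_scale = 0)
  spread <- tapply(r0$reading_ppm, r0$element, function(v) max(v) - min(v))
  expect_true(all(spread == 0))
  expect_error(generate_repeat_exposures(cfg, n_rep = 1), "insufficient")
})

test_that("profile CSV round-trips", {
  tab <- generate_profile_table(generator_config(seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(tab, path)
  back <- read_profile_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  expect_equal(profile_elements(back), SEP_ELEMENTS)
})

test_that("generator configuration loads from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 4",
               "element_roster: [P, S, Cl]",
               "baseline_ppm: {P: 100, S: 200, Cl: 300}",
               "noise_cv: 0.1",
               "zero_inflation: {Cl: 0.5}",
               "correlation_partners: {}",
               "cooking_effects: {Cl: 1.5}",
               "production_effects: {S: 1.2}"), path)
  cfg <- read_generator_config(path)
  expect_s3_class(cfg, "sep_config")
  expect_equal(cfg$element_roster, c("P", "S", "Cl"))
  expect_equal(cfg$baseline_ppm[["S"]], 200)
  tab <- generate_profile_table(cfg)
  expect_equal(nrow(tab), 40L)
})
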