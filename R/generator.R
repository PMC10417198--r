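# Synthetic-data generator: emulates the statistical structure of a
# multi-element pXRF prawn profile study (8 provenance groups x 5 samples,
# 14-element roster, counting-statistics instrument errors, zero-inflated As,
# planted instrument biases) so every downstream stage is testable without
# the confidential source data.

#' Default 14-element profile roster
#'
#' Five major elements (P, S, Cl, K, Ca; tissue concentrations above
#' 1000 ppm) followed by nine minor elements (below 100 ppm).
#' @export
SEP_ELEMENTS <- c("P", "S", "Cl", "K", "Ca", "Mn", "Fe", "Ni", "Cu",
                  "Zn", "As", "Sr", "Zr", "Th")

.sep_default_baseline <- c(
  P = 8000, S = 7000, Cl = 6000, K = 9000, Ca = 3000,
  Mn = 6, Fe = 30, Ni = 2.5, Cu = 20, Zn = 55,
  As = 0.8, Sr = 45, Zr = 3, Th = 1.2
)

# Planted instrument biases b (instrument reading = true/b before noise), so
# a correction-factor fit has a known truth. Negative entries model elements
# the instrument's factory calibration inverts; NA entries model elements
# with no reference assay (below the reference detection limit).
.sep_default_bias <- c(
  P = 0.7196, S = 0.3138, Cl = 0.6894, K = 0.7977, Ca = 1.1036,
  Mn = 2.2247, Fe = 0.4202, Ni = -1.625, Cu = 0.4114, Zn = 0.1765,
  As = -21.486, Sr = 1.3978, Zr = NA_real_, Th = NA_real_
)

.sep_default_groups <- function() {
  data.frame(
    group = c("1fr", "2fr", "2fc", "3fcJ", "3fcF", "4fc", "5wr", "6wc"),
    site = c(1L, 2L, 2L, 3L, 3L, 4L, 5L, 6L),
    production = c("farmed", "farmed", "farmed", "farmed", "farmed",
                   "farmed", "wild", "wild"),
    preparation = c("raw", "raw", "cooked", "cooked", "cooked",
                    "cooked", "raw", "cooked"),
    n_samples = 5L,
    stringsAsFactors = FALSE
  )
}

# Fixed effect patterns: deterministic log-multipliers drawn once from a
# frozen stream so the "world" does not move with the user's seed; scaled by
# `site_effect_scale` / `collection_effect_scale`.
.sep_frozen_pattern <- function(n_rows, elements, frozen_seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(frozen_seed)
  matrix(rnorm(n_rows * length(elements)), n_rows, length(elements),
         dimnames = list(NULL, elements))
}

# Share the latent log-effects of correlated partner elements, so planted
# cross-element correlations survive between-group variation (coupled
# elements carry a coupled provenance signal).
.mix_pattern <- function(pat, partners) {
  for (el in names(partners)) {
    w <- partners[[el]]
    if (!all(names(w) %in% colnames(pat))) next
    s2 <- sum(w^2)
    pat[, el] <- as.vector(pat[, names(w), drop = FALSE] %*% w) +
      sqrt(max(0, 1 - s2)) * pat[, el]
  }
  pat
}

.named_full <- function(x, elements, default, what) {
  out <- rep(default, length(elements))
  names(out) <- elements
  if (is.null(x)) return(out)
  if (is.null(names(x)) && length(x) == 1L) {
    out[] <- x
    return(out)
  }
  unknown <- setdiff(names(x), elements)
  if (length(unknown) > 0L) {
    stop("configuration error: unknown element(s) in ", what, ": ",
         paste(unknown, collapse = ", "))
  }
  out[names(x)] <- x
  out
}

#' Build a synthetic-profile generator configuration
#'
#' The defaults encode the study design being emulated: 8 provenance groups
#' of 5 prawns across 6 sites, a 14-element roster with major elements above
#' 1000 ppm and minors below 100 ppm, cooking raising Cl/Zn/Th/Cu/Mn and
#' lowering Zr, wild production raising S and lowering Ni, counting-statistics
#' instrument errors decaying as 1/sqrt(exposure time), and zero-inflated As
#' (exactly 3 of 40 readings nonzero under the default design).
#'
#' @param seed integer master seed; all sub-generators derive independent
#'   streams from it.
#' @param element_roster ordered element symbols.
#' @param baseline_ppm named per-element mean concentration (ppm).
#' @param group_defs data frame with columns `group`, `site`, `production`
#'   (`"farmed"`/`"wild"`), `preparation` (`"raw"`/`"cooked"`), `n_samples`.
#' @param site_effect_scale scale of deterministic per-site log-multipliers
#'   (0 disables site effects).
#' @param site_effects optional explicit site-by-element multiplier matrix
#'   (rows indexed by site number); overrides `site_effect_scale`.
#' @param collection_effect_scale scale of deterministic per-group
#'   log-multipliers modelling collection-batch (e.g. seasonal) shifts; this
#'   is what distinguishes two groups sharing a site and preparation.
#' @param collection_effects optional explicit group-by-element multiplier
#'   matrix (rows in `group_defs` order); overrides
#'   `collection_effect_scale`.
#' @param cooking_effects named multipliers applied to cooked samples.
#' @param production_effects named multipliers applied to wild samples.
#' @param noise_cv per-element coefficient of variation of the lognormal
#'   biological scatter (scalar recycled).
#' @param instrument_error_coeff named per-element constant `k` in
#'   `error = k * sqrt(concentration) / sqrt(t)`; the default yields ~3%
#'   relative error for major and ~10% for minor elements at 60 s.
#' @param exposure_time_s seconds per beam used for the error model.
#' @param zero_inflation named per-element probability of a zero reading.
#' @param zero_exact if `TRUE` (default) the number of zeroed readings is
#'   planted exactly as `round(p * n)` at seeded random indices rather than
#'   drawn binomially.
#' @param correlation_partners named list: for an element, a named numeric
#'   vector of latent-noise loadings on other elements (plants high
#'   correlations, e.g. Ca on K and Fe on S by default).
#' @param bias_slope named per-element true instrument bias `b`
#'   (instrument reading = truth / b before noise); `NA` marks elements with
#'   no reference assay.
#' @return an object of class `sep_config`.
#' @export
generator_config <- function(seed = 1L,
                             element_roster = SEP_ELEMENTS,
                             baseline_ppm = NULL,
                             group_defs = NULL,
                             site_effect_scale = 0.15,
                             site_effects = NULL,
                             collection_effect_scale = 0.1,
                             collection_effects = NULL,
                             cooking_effects = c(Cl = 1.5, Zn = 1.5, Th = 1.5,
                                                 Cu = 1.5, Mn = 1.5, Zr = 0.6),
                             production_effects = c(S = 1.3, Ni = 0.7),
                             noise_cv = 0.2,
                             instrument_error_coeff = NULL,
                             exposure_time_s = 60,
                             zero_inflation = c(As = 37 / 40),
                             zero_exact = TRUE,
                             correlation_partners = list(
                               Ca = c(K = 0.92, P = 0.25),
                               Fe = c(S = 0.92, K = 0.25)),
                             bias_slope = NULL) {
  elements <- as.character(element_roster)
  if (anyDuplicated(elements)) stop("element_roster contains duplicates")
  if (is.null(baseline_ppm)) {
    baseline_ppm <- .named_full(.sep_default_baseline[
      intersect(elements, names(.sep_default_baseline))],
      elements, 100, "baseline_ppm")
  } else {
    baseline_ppm <- .named_full(baseline_ppm, elements, 100, "baseline_ppm")
  }
  if (any(baseline_ppm <= 0)) stop("baseline_ppm must be positive")
  if (is.null(group_defs)) group_defs <- .sep_default_groups()
  need <- c("group", "site", "production", "preparation", "n_samples")
  if (!all(need %in% names(group_defs))) {
    stop("group_defs must have columns: ", paste(need, collapse = ", "))
  }
  if (any(group_defs$n_samples < 2L)) {
    stop("each group needs n_samples >= 2")
  }
  unknown <- setdiff(names(correlation_partners), elements)
  if (length(unknown) > 0L) {
    stop("configuration error: unknown element(s) in correlation_partners: ",
         paste(unknown, collapse = ", "))
  }
  for (w in correlation_partners) {
    bad <- setdiff(names(w), elements)
    if (length(bad) > 0L) {
      stop("configuration error: unknown partner element(s): ",
           paste(bad, collapse = ", "))
    }
  }
  if (is.null(site_effects)) {
    pat <- .mix_pattern(.sep_frozen_pattern(max(group_defs$site), elements,
                                            20230728),
                        correlation_partners)
    site_effects <- exp(site_effect_scale * pat)
  }
  if (is.null(collection_effects)) {
    pat <- .mix_pattern(.sep_frozen_pattern(nrow(group_defs), elements,
                                            20230729),
                        correlation_partners)
    collection_effects <- exp(collection_effect_scale * pat)
  }
  if (is.null(instrument_error_coeff)) {
    target_pct <- ifelse(baseline_ppm > 1000, 3, 10)
    instrument_error_coeff <-
      target_pct / 100 * sqrt(baseline_ppm * exposure_time_s)
  } else {
    instrument_error_coeff <-
      .named_full(instrument_error_coeff, elements, 1, "instrument_error_coeff")
  }
  if (is.null(bias_slope)) {
    bias_slope <- .named_full(
      .sep_default_bias[intersect(elements, names(.sep_default_bias))],
      elements, 1, "bias_slope")
  } else {
    bias_slope <- .named_full(bias_slope, elements, 1, "bias_slope")
  }
  cfg <- list(
    seed = as.integer(seed),
    element_roster = elements,
    baseline_ppm = baseline_ppm,
    group_defs = group_defs,
    site_effects = site_effects,
    collection_effects = collection_effects,
    cooking_effects = .named_full(cooking_effects, elements, 1,
                                  "cooking_effects"),
    production_effects = .named_full(production_effects, elements, 1,
                                     "production_effects"),
    noise_cv = .named_full(noise_cv, elements, 0.2, "noise_cv"),
    instrument_error_coeff = instrument_error_coeff,
    exposure_time_s = exposure_time_s,
    zero_inflation = .named_full(zero_inflation, elements, 0,
                                 "zero_inflation"),
    zero_exact = isTRUE(zero_exact),
    correlation_partners = correlation_partners,
    bias_slope = bias_slope
  )
  class(cfg) <- "sep_config"
  cfg
}

# Latent standard-normal matrix with planted cross-element loadings.
.latent_noise <- function(n, config) {
  elements <- config$element_roster
  z <- matrix(rnorm(n * length(elements)), n, length(elements),
              dimnames = list(NULL, elements))
  for (el in names(config$correlation_partners)) {
    w <- config$correlation_partners[[el]]
    bad <- setdiff(names(w), elements)
    if (length(bad) > 0L) {
      stop("configuration error: unknown partner element(s): ",
           paste(bad, collapse = ", "))
    }
    s2 <- sum(w^2)
    if (s2 > 1) stop("correlation_partners loadings for ", el,
                     " have sum of squares > 1")
    z[, el] <- as.vector(z[, names(w), drop = FALSE] %*% w) +
      sqrt(1 - s2) * z[, el]
  }
  z
}

#' Generate a synthetic profile table
#'
#' One row per sample with provenance labels and, per element, a
#' concentration (`<El>_ppm`) and an instrument error (`<El>_err`).
#' Concentrations are `baseline * site * cooking * production` multipliers
#' under lognormal biological scatter; instrument errors follow the
#' counting-statistics model `k * sqrt(concentration) / sqrt(t)`. Zero
#' inflation is applied after noise and zeroes both the reading and its
#' error.
#'
#' @param config a [generator_config()].
#' @param apply_bias if `TRUE`, readings are divided by the planted
#'   instrument bias (`bias_slope`) so they are on the uncalibrated
#'   instrument scale; the default `FALSE` returns true-scale
#'   concentrations.
#' @return a data frame (`sep_profile`) with columns `sample_id`, `group`,
#'   `site`, `production`, `preparation`, then `<El>_ppm`, `<El>_err`.
#' @export
generate_profile_table <- function(config, apply_bias = FALSE) {
  stopifnot(inherits(config, "sep_config"))
  set.seed(.stream_seed(config$seed, 1))
  gd <- config$group_defs
  elements <- config$element_roster
  n <- sum(gd$n_samples)
  gidx <- rep(seq_len(nrow(gd)), gd$n_samples)
  lab <- gd[gidx, c("group", "site", "production", "preparation")]
  rownames(lab) <- NULL

  mean_mult <- matrix(config$baseline_ppm, n, length(elements), byrow = TRUE,
                      dimnames = list(NULL, elements))
  mean_mult <- mean_mult * config$site_effects[lab$site, , drop = FALSE]
  mean_mult <- mean_mult * config$collection_effects[gidx, , drop = FALSE]
  cooked <- lab$preparation == "cooked"
  wild <- lab$production == "wild"
  mean_mult[cooked, ] <- sweep(mean_mult[cooked, , drop = FALSE], 2,
                               config$cooking_effects, `*`)
  mean_mult[wild, ] <- sweep(mean_mult[wild, , drop = FALSE], 2,
                             config$production_effects, `*`)

  z <- .latent_noise(n, config)
  sigma <- sqrt(log(1 + config$noise_cv^2))
  conc <- mean_mult *
    exp(sweep(z, 2, sigma, `*`) - matrix(sigma^2 / 2, n, length(elements),
                                         byrow = TRUE))
  err <- sweep(sqrt(conc), 2,
               config$instrument_error_coeff / sqrt(config$exposure_time_s),
               `*`)
  if (apply_bias) {
    b <- config$bias_slope
    bb <- ifelse(is.na(b), 1, b)
    conc <- sweep(conc, 2, bb, `/`)
    err <- sweep(err, 2, abs(bb), `/`)
  }
  for (el in elements) {
    p <- config$zero_inflation[[el]]
    if (p <= 0) next
    if (config$zero_exact) {
      nz <- round(p * n)
      idx <- if (nz > 0) sample.int(n, nz) else integer(0)
    } else {
      idx <- which(runif(n) < p)
    }
    conc[idx, el] <- 0
    err[idx, el] <- 0
  }
  out <- cbind(data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                          stringsAsFactors = FALSE),
               lab)
  for (el in elements) {
    out[[.ppm(el)]] <- conc[, el]
    out[[.err(el)]] <- err[, el]
  }
  class(out) <- c("sep_profile", "data.frame")
  out
}

#' Generate a paired reference-vs-instrument calibration set
#'
#' Reference concentrations are drawn lognormally around the element's
#' baseline with a wide spread (`reference_cv`, default 0.5: calibration
#' samples deliberately span a concentration range); instrument readings are
#' `reference / bias_slope` with centred multiplicative noise.
#'
#' @param config a [generator_config()].
#' @param element element symbol with a defined (non-`NA`) `bias_slope`.
#' @param n number of pairs (>= 3).
#' @param noise_cv relative noise on the instrument readings.
#' @param reference_cv spread of the reference concentrations.
#' @param seed optional override of the derived stream seed.
#' @return list with `element`, `reference_ppm`, `instrument_ppm`, `n`
#'   (class `sep_pairs`).
#' @export
generate_paired_calibration_set <- function(config, element, n = 6L,
                                            noise_cv = 0.05,
                                            reference_cv = 0.5,
                                            seed = NULL) {
  stopifnot(inherits(config, "sep_config"))
  if (!element %in% config$element_roster) {
    stop("configuration error: unknown element: ", element)
  }
  b <- config$bias_slope[[element]]
  if (is.na(b)) {
    stop("no bias_slope defined for ", element,
         " (reference below detection limit)")
  }
  if (n < 3L) stop("insufficient pairs: n must be >= 3")
  if (is.null(seed)) {
    seed <- .stream_seed(config$seed,
                         200 + match(element, config$element_roster))
  }
  set.seed(seed)
  mu <- config$baseline_ppm[[element]]
  s <- sqrt(log(1 + reference_cv^2))
  ref <- mu * exp(rnorm(n, -s^2 / 2, s))
  instr <- ref / b * (1 + rnorm(n, 0, noise_cv))
  structure(list(element = element, reference_ppm = ref,
                 instrument_ppm = instr, n = as.integer(n)),
            class = "sep_pairs")
}

#' Generate per-element percent-error curves over exposure time
#'
#' Percent error follows the counting-statistics form `c / sqrt(t)` with an
#' optional multiplicative lognormal jitter. The per-element coefficient is
#' derived from the instrument error model at the element's baseline
#' (`c = 100 * k / sqrt(baseline)`), or supplied directly.
#'
#' @param config a [generator_config()].
#' @param times_s strictly increasing positive exposure times (s).
#' @param elements elements to include; default the major elements
#'   (baseline > 1000 ppm).
#' @param coeffs optional named per-element coefficients `c`, overriding the
#'   derived ones.
#' @param jitter_cv multiplicative jitter CV (0 = noiseless, analytic form).
#' @return long data frame: `element`, `time_s`, `percent_error`
#'   (class `sep_exposure`).
#' @export
generate_exposure_series <- function(config, times_s, elements = NULL,
                                     coeffs = NULL, jitter_cv = 0) {
  stopifnot(inherits(config, "sep_config"))
  times_s <- as.numeric(times_s)
  if (any(times_s <= 0)) stop("domain error: exposure times must be > 0")
  if (length(times_s) > 1L && any(diff(times_s) <= 0)) {
    stop("domain error: exposure times must be strictly increasing")
  }
  if (is.null(coeffs)) {
    if (is.null(elements)) {
      elements <- config$element_roster[config$baseline_ppm > 1000]
    }
    coeffs <- 100 * config$instrument_error_coeff[elements] /
      sqrt(config$baseline_ppm[elements])
    names(coeffs) <- elements
  }
  set.seed(.stream_seed(config$seed, 5))
  out <- do.call(rbind, lapply(names(coeffs), function(el) {
    pe <- coeffs[[el]] / sqrt(times_s)
    if (jitter_cv > 0) {
      s <- sqrt(log(1 + jitter_cv^2))
      pe <- pe * exp(rnorm(length(pe), -s^2 / 2, s))
    }
    data.frame(element = el, time_s = times_s, percent_error = pe,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("sep_exposure", "data.frame")
  out
}

#' Generate repeated exposures of one specimen
#'
#' Emulates consecutive pXRF exposures of a powdered specimen: per element,
#' `n_rep` readings scattered around the baseline at the instrument-error
#' scale (`reading = mean + scatter_scale * error * N(0,1)`), each with its
#' own instrument-error estimate.
#'
#' @param config a [generator_config()].
#' @param n_rep number of consecutive exposures (>= 2).
#' @param scatter_scale multiple of the instrument error governing the true
#'   reading scatter; 1 = scatter matched to the error model, 0 = identical
#'   readings.
#' @param seed optional override of the derived stream seed.
#' @return long data frame: `element`, `rep`, `reading_ppm`, `error_ppm`.
#' @export
generate_repeat_exposures <- function(config, n_rep = 5L, scatter_scale = 1,
                                      seed = NULL) {
  stopifnot(inherits(config, "sep_config"))
  if (n_rep < 2L) stop("insufficient replicates: n_rep must be >= 2")
  if (is.null(seed)) seed <- .stream_seed(config$seed, 3)
  set.seed(seed)
  elements <- config$element_roster
  out <- do.call(rbind, lapply(elements, function(el) {
    mu <- config$baseline_ppm[[el]]
    e0 <- config$instrument_error_coeff[[el]] * sqrt(mu) /
      sqrt(config$exposure_time_s)
    reading <- pmax(0, mu + scatter_scale * e0 * rnorm(n_rep))
    err <- config$instrument_error_coeff[[el]] * sqrt(pmax(reading, 0)) /
      sqrt(config$exposure_time_s)
    data.frame(element = el, rep = seq_len(n_rep), reading_ppm = reading,
               error_ppm = err, stringsAsFactors = FALSE)
  }))
  out
}

#' Generate a paired drying-treatment table
#'
#' Emulates the moisture assessment: each sample is measured once after
#' treatment A (towel dry) and once after treatment B (heat gun), in raw and
#' cooked strata. Under the default `treatment_effect = 1` the two
#' treatments differ only by measurement noise (the null world). As is
#' zeroed in the cooked stratum (detectable only in raw samples).
#'
#' @param config a [generator_config()].
#' @param n_raw,n_cooked stratum sizes.
#' @param treatment_effect named per-element multipliers applied to
#'   treatment B.
#' @param measurement_cv relative measurement noise per reading.
#' @param seed optional override of the derived stream seed.
#' @return wide data frame: `sample_id`, `preparation`, then `<El>_A`,
#'   `<El>_B`.
#' @export
generate_paired_treatment_table <- function(config, n_raw = 5L,
                                            n_cooked = 10L,
                                            treatment_effect = NULL,
                                            measurement_cv = 0.05,
                                            seed = NULL) {
  stopifnot(inherits(config, "sep_config"))
  if (n_raw + n_cooked < 2L) stop("need at least 2 samples")
  elements <- config$element_roster
  eff <- .named_full(treatment_effect, elements, 1, "treatment_effect")
  if (is.null(seed)) seed <- .stream_seed(config$seed, 4)
  set.seed(seed)
  n <- n_raw + n_cooked
  prep <- rep(c("raw", "cooked"), c(n_raw, n_cooked))
  sigma <- sqrt(log(1 + config$noise_cv^2))
  out <- data.frame(sample_id = sprintf("M%03d", seq_len(n)),
                    preparation = prep, stringsAsFactors = FALSE)
  for (el in elements) {
    mu <- config$baseline_ppm[[el]] *
      ifelse(prep == "cooked", config$cooking_effects[[el]], 1)
    true <- mu * exp(rnorm(n, -sigma[[el]]^2 / 2, sigma[[el]]))
    a <- true * (1 + rnorm(n, 0, measurement_cv))
    b <- true * eff[[el]] * (1 + rnorm(n, 0, measurement_cv))
    if (el == "As") {
      a[prep == "cooked"] <- 0
      b[prep == "cooked"] <- 0
    }
    out[[paste0(el, "_A")]] <- pmax(a, 0)
    out[[paste0(el, "_B")]] <- pmax(b, 0)
  }
  out
}

#' Write / read a profile table as CSV
#'
#' Comma-separated, UTF-8, header row, `NA` literal for missing values.
#' @param table profile table.
#' @param path file path.
#' @return `read_profile_csv` returns the profile table.
#' @export
write_profile_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("sep_profile", "data.frame")
  out
}

#' Read a generator configuration from a YAML or JSON file
#'
#' Recognised keys mirror the arguments of [generator_config()];
#' `group_defs` may be given as a list of records.
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `sep_config`.
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$group_defs) && !is.data.frame(raw$group_defs)) {
    raw$group_defs <- do.call(rbind, lapply(raw$group_defs, as.data.frame))
  }
  numeric_maps <- c("baseline_ppm", "cooking_effects", "production_effects",
                    "noise_cv", "instrument_error_coeff", "zero_inflation",
                    "bias_slope")
  for (key in intersect(numeric_maps, names(raw))) {
    raw[[key]] <- unlist(raw[[key]])
  }
  if (!is.null(raw$correlation_partners)) {
    raw$correlation_partners <- lapply(raw$correlation_partners, unlist)
  }
  if (!is.null(raw$element_roster)) {
    raw$element_roster <- unlist(raw$element_roster)
  }
  known <- names(formals(generator_config))
  do.call(generator_config, raw[intersect(names(raw), known)])
}
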