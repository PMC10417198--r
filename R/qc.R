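# Protocol QC statistics: the detection-inclusion rule, the exposure-time
# slope-improvement rule, and the repeatability delta.

#' Percent error of a reading
#'
#' `100 * error / concentration`. Non-positive concentrations have no
#' defined percent error: the value is `NA` and a warning of class
#' `sep_undefined_percent_error` is signalled so the caller can decide on
#' exclusion.
#'
#' @param concentration reading (ppm), vectorised.
#' @param error instrument error (ppm), vectorised.
#' @return numeric percent errors.
#' @export
percent_error <- function(concentration, error) {
  if (any(error < 0, na.rm = TRUE)) stop("error must be >= 0")
  out <- ifelse(concentration > 0, 100 * error / concentration, NA_real_)
  if (any(concentration <= 0, na.rm = TRUE)) {
    warning(warningCondition(
      "percent error undefined for non-positive concentration",
      class = "sep_undefined_percent_error"))
  }
  out
}

#' Detection-inclusion rule
#'
#' A reading is confidently quantified iff its instrument error is strictly
#' less than `ratio` times its concentration (default one-third). Zero
#' readings are neither pass nor fail (`NA`). An element enters the profile
#' roster iff it passes in more than `min_pass_fraction` of its nonzero
#' readings (strict majority by default); an element with no nonzero
#' readings is excluded.
#'
#' @param table profile table with `<El>_ppm` / `<El>_err` columns.
#' @param ratio error-to-concentration cut-off.
#' @param min_pass_fraction fraction of nonzero readings that must pass.
#' @return list: `pass` (samples x elements logical matrix, `NA` at zero
#'   readings), `roster` (included elements, table order), `summary`
#'   (per-element counts).
#' @export
detection_filter <- function(table, ratio = 1 / 3, min_pass_fraction = 0.5) {
  elements <- profile_elements(table)
  pass <- sapply(elements, function(el) {
    conc <- table[[.ppm(el)]]
    err <- table[[.err(el)]]
    ifelse(conc > 0, err < ratio * conc, NA)
  })
  pass <- matrix(pass, nrow = nrow(table),
                 dimnames = list(table$sample_id, elements))
  n_nonzero <- colSums(!is.na(pass))
  n_pass <- colSums(pass, na.rm = TRUE)
  included <- n_nonzero > 0 & n_pass > min_pass_fraction * n_nonzero
  roster <- elements[included]
  if (length(roster) == 0L) warning("detection filter produced an empty roster")
  list(pass = pass, roster = roster,
       summary = data.frame(element = elements, n_nonzero = n_nonzero,
                            n_pass = n_pass, included = included,
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Exposure-time selection by the slope-improvement rule
#'
#' Consecutive slopes of the percent-error-vs-time curve are compared: the
#' improvement rate between slopes `S_k` and `S_{k+1}` is
#' `100 * |S_k - S_{k+1}| / |S_k|`. The selected exposure time is the time
#' point shared by the first consecutive slope pair whose improvement rate
#' falls strictly below the threshold; if no pair does, the last time is
#' returned with `converged = FALSE`. A leading slope of exactly zero
#' defines a 0% improvement (immediate stop) and is flagged.
#'
#' @param times_s strictly increasing exposure times (>= 3 points).
#' @param pct_error percent errors at those times.
#' @param improvement_threshold stopping threshold in percent (default 33).
#' @return list: `time_s` (selected), `slopes`, `improvement_rates`,
#'   `stop_pair` (index k of the stopping pair, `NA` if none),
#'   `converged`, `zero_slope` flag.
#' @export
select_exposure_time <- function(times_s, pct_error,
                                 improvement_threshold = 33) {
  times_s <- as.numeric(times_s)
  pct_error <- as.numeric(pct_error)
  if (length(times_s) < 3L) {
    stop("insufficient series: need at least 3 time points")
  }
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
  if (length(pct_error) != length(times_s)) stop("length mismatch")
  slopes <- diff(pct_error) / diff(times_s)
  k <- length(slopes) - 1L
  zero_slope <- FALSE
  rates <- numeric(k)
  for (i in seq_len(k)) {
    if (slopes[i] == 0) {
      rates[i] <- 0
      zero_slope <- TRUE
    } else {
      rates[i] <- 100 * abs(slopes[i] - slopes[i + 1]) / abs(slopes[i])
    }
  }
  hit <- which(rates < improvement_threshold)
  if (length(hit) == 0L) {
    list(time_s = times_s[length(times_s)], slopes = slopes,
         improvement_rates = rates, stop_pair = NA_integer_,
         converged = FALSE, zero_slope = zero_slope)
  } else {
    k1 <- hit[1L]
    list(time_s = times_s[k1 + 1L], slopes = slopes,
         improvement_rates = rates, stop_pair = k1,
         converged = TRUE, zero_slope = zero_slope)
  }
}

#' Per-element exposure-time report
#'
#' Applies [select_exposure_time()] to each element of an exposure series.
#' @param series long data frame: `element`, `time_s`, `percent_error`.
#' @param improvement_threshold stopping threshold in percent.
#' @return data frame: `element`, `selected_time_s`, `converged`,
#'   `zero_slope`.
#' @export
exposure_time_report <- function(series, improvement_threshold = 33) {
  out <- do.call(rbind, lapply(split(series, series$element), function(d) {
    d <- d[order(d$time_s), ]
    sel <- select_exposure_time(d$time_s, d$percent_error,
                                improvement_threshold)
    data.frame(element = d$element[1L], selected_time_s = sel$time_s,
               converged = sel$converged, zero_slope = sel$zero_slope,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Repeatability delta of replicate readings
#'
#' For `n` consecutive exposures of the same specimen:
#' `se = sd(readings) / sqrt(n)` (sample standard deviation) and
#' `delta = mean(instrument errors) - se`. A positive delta means the
#' replicate scatter is accounted for by the instrument's self-reported
#' error; a negative delta flags unexplained scatter.
#'
#' @param readings replicate concentration readings (>= 2).
#' @param errors per-reading instrument errors, same length.
#' @return one-row data frame: `average_instrument_error`, `se`, `delta`,
#'   `n_rep`.
#' @export
repeatability_delta <- function(readings, errors) {
  n <- length(readings)
  if (n < 2L) stop("insufficient replicates: need n >= 2")
  if (length(errors) != n) stop("readings and errors must pair")
  se <- sd(readings) / sqrt(n)
  avg <- mean(errors)
  data.frame(average_instrument_error = avg, se = se, delta = avg - se,
             n_rep = n)
}

#' Per-element repeatability summary
#'
#' @param repeats long data frame from [generate_repeat_exposures()]:
#'   `element`, `rep`, `reading_ppm`, `error_ppm`.
#' @return data frame: `element`, `average_instrument_error`, `se`, `delta`,
#'   `n_rep` (class `sep_repeatability`).
#' @export
repeatability_summary <- function(repeats) {
  out <- do.call(rbind, lapply(split(repeats, repeats$element), function(d) {
    cbind(data.frame(element = d$element[1L], stringsAsFactors = FALSE),
          repeatability_delta(d$reading_ppm, d$error_ppm))
  }))
  rownames(out) <- NULL
  out <- out[match(unique(repeats$element), out$element), ]
  rownames(out) <- NULL
  class(out) <- c("sep_repeatability", "data.frame")
  out
}
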