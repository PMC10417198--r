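# Instrument calibration: per-element correction factors fitted as the slope
# of a linear regression of reference-assay concentrations on instrument
# readings, then applied multiplicatively to profile tables.

#' Fit per-element correction factors
#'
#' Ordinary least squares of the reference concentrations (response) on the
#' instrument readings (predictor), with an intercept by default; the slope
#' is the element's correction factor. Elements whose paired set is `NULL`
#' (no reference assay) are marked `NA` with status `"no_reference"`;
#' constant instrument readings give status `"degenerate"` while the other
#' elements still fit.
#'
#' @param pairs a single `sep_pairs` object or a named list of them (or
#'   `NULL` entries for elements lacking a reference).
#' @param through_origin if `TRUE`, fit without an intercept.
#' @return data frame of class `sep_factors`: `element`, `factor`, `fit_n`,
#'   `fit_r2`, `status` (`"ok"`, `"no_reference"`, `"degenerate"`).
#' @export
fit_correction_factors <- function(pairs, through_origin = FALSE) {
  if (inherits(pairs, "sep_pairs")) {
    pairs <- setNames(list(pairs), pairs$element)
  }
  rows <- lapply(names(pairs), function(el) {
    p <- pairs[[el]]
    if (is.null(p)) {
      return(data.frame(element = el, factor = NA_real_, fit_n = NA_integer_,
                        fit_r2 = NA_real_, status = "no_reference",
                        stringsAsFactors = FALSE))
    }
    x <- p$instrument_ppm
    y <- p$reference_ppm
    if (length(x) != length(y)) stop("unpaired vectors for ", el)
    if (length(x) < 3L) stop("insufficient pairs for ", el, " (n < 3)")
    if (isTRUE(all.equal(var(x), 0)) || var(x) == 0) {
      return(data.frame(element = el, factor = NA_real_,
                        fit_n = length(x), fit_r2 = NA_real_,
                        status = "degenerate", stringsAsFactors = FALSE))
    }
    fit <- if (through_origin) lm(y ~ x - 1) else lm(y ~ x)
    slope <- unname(coef(fit)[["x"]])
    r2 <- summary(fit)$r.squared
    data.frame(element = el, factor = slope, fit_n = length(x),
               fit_r2 = r2, status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sep_factors", "data.frame")
  out
}

#' Apply correction factors to a profile table
#'
#' Corrected concentration = factor x raw reading; instrument errors are
#' scaled by `|factor|`. Elements with an `NA` factor pass through unchanged
#' and are flagged `"uncalibrated"`. Negative factors are applied as-is with
#' a warning; resulting negative concentrations are floored at zero and
#' counted.
#'
#' @param table profile table.
#' @param factors a `sep_factors` data frame covering every element of the
#'   table (possibly as `NA`).
#' @return the corrected table, with attributes `uncalibrated` (element
#'   names passed through) and `n_floored` (readings floored at zero).
#' @export
apply_correction <- function(table, factors) {
  elements <- profile_elements(table)
  missing <- setdiff(elements, factors$element)
  if (length(missing) > 0L) {
    stop("no correction-factor entry for element(s): ",
         paste(missing, collapse = ", "))
  }
  f <- setNames(factors$factor, factors$element)[elements]
  uncal <- elements[is.na(f)]
  neg <- elements[!is.na(f) & f < 0]
  if (length(neg) > 0L) {
    warning("negative correction factor applied for: ",
            paste(neg, collapse = ", "))
  }
  out <- table
  n_floored <- 0L
  for (el in elements) {
    if (is.na(f[[el]])) next
    conc <- table[[.ppm(el)]] * f[[el]]
    bad <- conc < 0
    n_floored <- n_floored + sum(bad)
    conc[bad] <- 0
    out[[.ppm(el)]] <- conc
    out[[.err(el)]] <- table[[.err(el)]] * abs(f[[el]])
  }
  attr(out, "uncalibrated") <- uncal
  attr(out, "n_floored") <- n_floored
  out
}

#' Serialize correction factors as CSV
#'
#' Columns `element`, `factor`, `fit_n`, `fit_r2`, `status`; absent factors
#' are written as the literal `NA`.
#' @param factors `sep_factors` data frame.
#' @param path file path.
#' @export
write_factors_csv <- function(factors, path) {
  write.csv(as.data.frame(factors), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_factors_csv
#' @export
read_factors_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("sep_factors", "data.frame")
  out
}
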