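# Chemometric pre-treatment, in the fixed order the provenance analysis
# assumes: zero-fraction filter -> correlation filter -> z-scaling.

#' Zero-fraction filter
#'
#' Removes elements whose fraction of zero readings strictly exceeds the
#' threshold (default 0.8: "more than 80% zeros").
#'
#' @param table profile table.
#' @param threshold maximum tolerated zero fraction.
#' @return list: `table` (reduced), `removed` (element names),
#'   `zero_fraction` (named, all elements).
#' @export
zero_fraction_filter <- function(table, threshold = 0.8) {
  if (nrow(table) == 0L) stop("empty table")
  elements <- profile_elements(table)
  zf <- vapply(elements, function(el) mean(table[[.ppm(el)]] == 0),
               numeric(1))
  removed <- elements[zf > threshold]
  list(table = .drop_elements(table, removed), removed = removed,
       zero_fraction = zf)
}

.drop_elements <- function(table, removed) {
  if (length(removed) == 0L) return(table)
  drop <- c(.ppm(removed), .err(removed))
  table[, setdiff(names(table), drop), drop = FALSE]
}

#' Correlation filter
#'
#' Computes the Pearson correlation matrix of the element concentrations
#' and, while any pair has `|r| >=` the threshold (inclusive: "0.8 or
#' higher"), drops the element with the largest mean absolute correlation
#' to all remaining elements (ties broken by dropping the later element in
#' table order). Constant columns have no defined correlation; they are
#' treated as uncorrelated and a warning is given.
#'
#' @param table profile table (apply after [zero_fraction_filter()]).
#' @param r_threshold inclusive absolute-correlation threshold.
#' @return list: `table` (reduced), `removed` (data frame: `element`,
#'   `kept_partner`, `r`), `correlation` (the full starting matrix).
#' @export
correlation_filter <- function(table, r_threshold = 0.8) {
  elements <- profile_elements(table)
  if (nrow(table) < 2L) stop("need at least 2 samples")
  x <- .concentration_matrix(table, elements)
  colnames(x) <- elements
  const <- apply(x, 2, function(v) var(v) == 0)
  if (any(const)) {
    warning("constant column(s) treated as uncorrelated: ",
            paste(elements[const], collapse = ", "))
  }
  r_full <- suppressWarnings(cor(x))
  r_full[is.na(r_full)] <- 0
  keep <- elements
  removed <- data.frame(element = character(0), kept_partner = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  repeat {
    r <- abs(r_full[keep, keep, drop = FALSE])
    diag(r) <- 0
    if (length(keep) < 2L || max(r) < r_threshold) break
    linked <- rowSums(r >= r_threshold) > 0
    mean_r <- rowMeans(r)
    cand <- names(which(linked))
    # largest mean |r|; ties -> the later element in table order
    best <- max(mean_r[cand])
    tied <- cand[mean_r[cand] >= best - 1e-12]
    drop_el <- tied[which.max(match(tied, elements))]
    partners <- keep[r[drop_el, ] >= r_threshold]
    partner <- partners[which.max(r[drop_el, partners])]
    removed <- rbind(removed, data.frame(
      element = drop_el, kept_partner = partner,
      r = r_full[drop_el, partner], stringsAsFactors = FALSE))
    keep <- setdiff(keep, drop_el)
  }
  list(table = .drop_elements(table, removed$element), removed = removed,
       correlation = r_full)
}

#' Z-scale element concentrations
#'
#' Centres each element at zero and divides by its sample standard
#' deviation; instrument-error columns are dropped (scaled concentrations
#' are the modelling input). The stored parameters allow an exact inverse.
#'
#' @param table profile table.
#' @return list: `table` (label columns + scaled `<El>_ppm` columns),
#'   `params` (data frame `element`, `mean`, `sd`).
#' @export
scale_elements <- function(table) {
  elements <- profile_elements(table)
  x <- .concentration_matrix(table, elements)
  colnames(x) <- elements
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  if (any(s == 0)) {
    stop("zero standard deviation for element(s): ",
         paste(elements[s == 0], collapse = ", "),
         " (should have been filtered)")
  }
  scaled <- sweep(sweep(x, 2, mu), 2, s, `/`)
  out <- table[, setdiff(names(table),
                         c(.ppm(elements), .err(elements))), drop = FALSE]
  for (el in elements) out[[.ppm(el)]] <- scaled[, el]
  list(table = out,
       params = data.frame(element = elements, mean = mu, sd = s,
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Invert a z-scaling
#'
#' @param table scaled table from [scale_elements()].
#' @param params the scaling parameters it returned.
#' @return table on the original concentration scale.
#' @export
inverse_scale_elements <- function(table, params) {
  out <- table
  for (i in seq_len(nrow(params))) {
    el <- params$element[i]
    out[[.ppm(el)]] <- table[[.ppm(el)]] * params$sd[i] + params$mean[i]
  }
  out
}

#' Full pre-treatment pipeline
#'
#' Fixed order: zero-fraction filter, correlation filter, z-scaling.
#'
#' @param table profile table.
#' @param zero_threshold zero-fraction threshold (strict `>`).
#' @param r_threshold correlation threshold (inclusive `>=`).
#' @return list: `table` (scaled, reduced), `report` of class
#'   `sep_preprocess_report` with `removed_by_zero_filter`,
#'   `removed_by_correlation`, `scaling_params`.
#' @export
preprocess_profile <- function(table, zero_threshold = 0.8,
                               r_threshold = 0.8) {
  zf <- zero_fraction_filter(table, zero_threshold)
  cf <- correlation_filter(zf$table, r_threshold)
  sc <- scale_elements(cf$table)
  report <- list(removed_by_zero_filter = zf$removed,
                 removed_by_correlation = cf$removed,
                 scaling_params = sc$params)
  class(report) <- "sep_preprocess_report"
  list(table = sc$table, report = report)
}
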