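# Moisture assessment: paired Wilcoxon signed-rank comparison of two drying
# treatments per element, stratified by preparation (raw / cooked).
#
# The signed-rank test is implemented here rather than delegated to
# stats::wilcox.test because the exact sign-flip distribution is needed even
# under tied |differences| (e.g. five pairs all differing by +1 has exact
# two-sided p = 2/32 = 0.0625, which a normal approximation cannot return).

# Exact null distribution of W = sum of ranks of positive differences,
# by dynamic programming over the (possibly tied, average) ranks. Ranks are
# doubled so midranks become integers.
.signed_rank_p <- function(d) {
  n <- length(d)
  r2 <- as.integer(round(2 * rank(abs(d))))
  w2 <- sum(r2[d > 0])
  tot <- sum(r2)
  # counts[s + 1] = number of sign assignments with doubled rank sum s
  counts <- numeric(tot + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts <- counts / 2^n
  p_le <- sum(counts[seq_len(w2 + 1)])
  p_ge <- sum(counts[seq.int(w2 + 1, tot + 1)])
  min(1, 2 * min(p_le, p_ge))
}

# Normal approximation with tie correction and continuity correction,
# for n beyond exact enumeration.
.signed_rank_p_normal <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of paired samples. Zero differences are dropped before
#' ranking. The p-value is exact (full sign-flip distribution, valid under
#' tied absolute differences) when the number of nonzero differences is at
#' most `exact_limit`; otherwise a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param a,b paired measurement vectors.
#' @param exact_limit largest n for the exact distribution (default 25).
#' @return list: `p_value`, `n_used` (nonzero differences), `statistic`
#'   (rank sum of positive differences), `exact` flag.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 25L) {
  if (length(a) != length(b)) stop("a and b must pair")
  d <- b - a
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 2L) {
    return(list(p_value = NA_real_, n_used = n, statistic = NA_real_,
                exact = NA))
  }
  exact <- n <= exact_limit
  p <- if (exact) .signed_rank_p(d) else .signed_rank_p_normal(d)
  list(p_value = p, n_used = n, statistic = sum(rank(abs(d))[d > 0]),
       exact = exact)
}

#' Per-element paired treatment comparison within a stratum
#'
#' Compares treatment A and B concentrations element by element with the
#' paired Wilcoxon signed-rank test, within one preparation stratum.
#' Elements whose readings are all zero in the stratum (non-detects under
#' both treatments) are flagged `"all_zero"` — the table convention `"*"` —
#' instead of tested. Identical A and B vectors give the
#' `"all_zero_diff"` flag; fewer than 2 usable pairs gives
#' `"insufficient"`.
#'
#' @param pairs wide data frame from [generate_paired_treatment_table()]:
#'   `sample_id`, `preparation`, `<El>_A`, `<El>_B`.
#' @param stratum `"raw"` or `"cooked"`.
#' @param alpha significance level for the flag (default 0.05).
#' @param p_adjust `"none"` (default, mirroring raw per-element reporting)
#'   or `"holm"`.
#' @return data frame: `element`, `n_pairs`, `p_value`, `flag`
#'   (`"ok"`/`"all_zero"`/`"all_zero_diff"`/`"insufficient"`),
#'   `significant`.
#' @export
paired_wilcoxon_by_element <- function(pairs, stratum,
                                       alpha = 0.05,
                                       p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  d <- pairs[pairs$preparation == stratum, , drop = FALSE]
  if (nrow(d) < 2L) stop("insufficient pairs in stratum '", stratum, "'")
  elements <- sub("_A$", "", grep("_A$", names(pairs), value = TRUE))
  rows <- lapply(elements, function(el) {
    a <- d[[paste0(el, "_A")]]
    b <- d[[paste0(el, "_B")]]
    if (all(a == 0) && all(b == 0)) {
      return(data.frame(element = el, n_pairs = nrow(d),
                        p_value = NA_real_, flag = "all_zero",
                        stringsAsFactors = FALSE))
    }
    if (all(b - a == 0)) {
      return(data.frame(element = el, n_pairs = nrow(d),
                        p_value = NA_real_, flag = "all_zero_diff",
                        stringsAsFactors = FALSE))
    }
    w <- wilcoxon_signed_rank(a, b)
    if (w$n_used < 2L) {
      return(data.frame(element = el, n_pairs = nrow(d),
                        p_value = NA_real_, flag = "insufficient",
                        stringsAsFactors = FALSE))
    }
    data.frame(element = el, n_pairs = nrow(d), p_value = w$p_value,
               flag = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "holm") {
    ok <- out$flag == "ok"
    out$p_value[ok] <- stats::p.adjust(out$p_value[ok], method = "holm")
  }
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Two-stratum moisture comparison table
#'
#' Runs [paired_wilcoxon_by_element()] on the raw and cooked strata and
#' lays the p-values out side by side, with the literal `"*"` for all-zero
#' strata.
#'
#' @param pairs paired treatment table.
#' @param alpha significance level.
#' @return data frame: `element`, `p_raw`, `p_cooked` (character columns,
#'   `"*"` for all-zero strata).
#' @export
moisture_comparison_table <- function(pairs, alpha = 0.05) {
  fmt <- function(res) {
    ifelse(res$flag == "all_zero", "*",
           ifelse(is.na(res$p_value), NA_character_,
                  formatC(res$p_value, format = "f", digits = 2)))
  }
  raw <- paired_wilcoxon_by_element(pairs, "raw", alpha)
  cooked <- paired_wilcoxon_by_element(pairs, "cooked", alpha)
  data.frame(element = raw$element, p_raw = fmt(raw),
             p_cooked = fmt(cooked), stringsAsFactors = FALSE)
}
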