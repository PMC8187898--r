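check_margins <- function(tab) {
  m <- as.matrix(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate 2x2 table: empty row or column margin", call. = FALSE)
  }
  m
}

#' Pearson chi-square test on a carrier table
#'
#' The uncorrected 2-by-2 chi-square comparison of carrier rates between
#' cases and controls (1 df, two-sided).
#'
#' @param table A [carrier_table()] or numeric vector
#'   \code{c(a, case_total, c, control_total)}.
#' @return List with \code{statistic} and \code{p}.
#' @examples
#' pearson_chi2(carrier_table(56, 253, 48, 308))
#' @export
pearson_chi2 <- function(table) {
  m <- check_margins(as_carrier_table(table))
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Continuity-corrected (Yates) chi-square test
#'
#' Subtracts 0.5 from each |observed - expected| before squaring (floored at
#' zero), the standard small-sample correction for sparse 2x2 tables.
#'
#' @inheritParams pearson_chi2
#' @return List with \code{statistic} and \code{p}.
#' @examples
#' yates_chi2(carrier_table(8, 51, 1, 94))
#' @export
yates_chi2 <- function(table) {
  m <- check_margins(as_carrier_table(table))
  ht <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Fisher's exact test on a carrier table
#'
#' Two-sided p by summing hypergeometric probabilities no larger than that
#' of the observed table. Provided as the diagnostic alternative for very
#' sparse tables.
#'
#' @inheritParams pearson_chi2
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  m <- check_margins(as_carrier_table(table))
  stats::fisher.test(m)$p.value
}

#' Expected cell counts of a 2x2 table under independence
#'
#' @inheritParams pearson_chi2
#' @return 2x2 matrix of expected counts.
#' @export
expected_counts <- function(table) {
  m <- as.matrix(as_carrier_table(table))
  outer(rowSums(m), colSums(m)) / sum(m)
}

#' Choose between the Pearson and Yates chi-square tests
#'
#' Continuity correction is applied iff any expected cell count is below 5,
#' the convention that reproduces small-sample carrier-rate p-values such as
#' the sparse DRB1*04:06 table.
#'
#' @inheritParams pearson_chi2
#' @return \code{"yates"} or \code{"pearson"}.
#' @export
select_test <- function(table) {
  if (min(expected_counts(table)) < 5) "yates" else "pearson"
}

#' Carrier-rate test with automatic small-sample correction
#'
#' Applies [select_test()] and runs the chosen chi-square variant.
#'
#' @inheritParams pearson_chi2
#' @return List with \code{test_used}, \code{statistic}, \code{p}.
#' @export
carrier_test <- function(table) {
  test <- select_test(table)
  res <- if (test == "yates") yates_chi2(table) else pearson_chi2(table)
  c(list(test_used = test), res)
}

#' Odds ratio with Woolf (log-scale) confidence interval
#'
#' OR = ad/bc with CI \code{exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))}.
#' If any cell is zero, 0.5 is added to all four cells (Haldane-Anscombe)
#' for both the point estimate and the interval, and the result is flagged.
#' A marker absent from both arms (a = c = 0) has no defined OR and returns
#' \code{NA} with \code{undefined = TRUE} rather than a corrected value.
#'
#' @inheritParams pearson_chi2
#' @param z Normal quantile for the interval; the default 1.959964
#'   corresponds to the 95% level.
#' @return List with \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{log_or}, \code{var_log_or}, and flags \code{haldane},
#'   \code{undefined}.
#' @examples
#' odds_ratio_woolf(carrier_table(8, 51, 1, 94))
#' @export
odds_ratio_woolf <- function(table, z = 1.959964) {
  tab <- as_carrier_table(table)
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if ((tab$a == 0 && tab$c == 0) || (tab$b == 0 && tab$d == 0)) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                log_or = NA_real_, var_log_or = NA_real_,
                haldane = FALSE, undefined = TRUE))
  }
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  lor <- log(cells[1L] * cells[4L] / (cells[2L] * cells[3L]))
  v <- sum(1 / cells)
  list(or = exp(lor),
       ci_low = exp(lor - z * sqrt(v)),
       ci_high = exp(lor + z * sqrt(v)),
       log_or = lor, var_log_or = v,
       haldane = haldane, undefined = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies a raw p-value by the number of alleles tested at the locus,
#' capped at 1.
#'
#' @param p_raw Raw p-value(s).
#' @param multiplicity Number of comparisons (distinct alleles observed at
#'   the locus in that drug cohort).
#' @return Corrected p-value(s).
#' @examples
#' bonferroni(0.002, 19)
#' @export
bonferroni <- function(p_raw, multiplicity) {
  stopifnot(multiplicity >= 1)
  pmin(1, multiplicity * p_raw)
}

#' Association scan of one locus
#'
#' Tests every allele observed at the locus (cases + controls) with at least
#' \code{min_carriers} pooled carriers: carrier-rate chi-square with
#' automatic continuity correction, Woolf odds ratio and 95% CI, and
#' per-locus Bonferroni correction. The Bonferroni multiplicity is the full
#' number of distinct alleles enumerated at the locus, not the filtered
#' count. Protective alleles (OR < 1) are retained.
#'
#' @param cohort An [hla_cohort()].
#' @param locus One of \code{"A"}, \code{"B"}, \code{"C"}, \code{"DRB1"}.
#' @param min_carriers Minimum pooled carrier count for an allele to be
#'   tested (default 3; rarer alleles contribute to the multiplicity only).
#' @return Data frame of class \code{hla_scan}, one row per tested allele,
#'   sorted by raw p: columns \code{allele, a, case_total, c, control_total,
#'   or, ci_low, ci_high, p, p_corrected, test, multiplicity, haldane}.
#' @export
scan_locus <- function(cohort, locus, min_carriers = 3L) {
  locus <- match.arg(locus, HLA_LOCI)
  enum <- enumerate_alleles(cohort, locus)
  multiplicity <- nrow(enum)
  tested <- enum[enum$carriers >= min_carriers, , drop = FALSE]
  rows <- lapply(tested$allele, function(al) {
    tab <- build_carrier_table(cohort, al)
    # a universally carried allele yields a degenerate table: no contrast
    tst <- tryCatch(carrier_test(tab), error = function(e) {
      list(test_used = NA_character_, statistic = NA_real_, p = NA_real_)
    })
    orr <- odds_ratio_woolf(tab)
    data.frame(allele = al, locus = locus,
               a = tab$a, case_total = tab$case_total,
               c = tab$c, control_total = tab$control_total,
               or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
               p = tst$p, p_corrected = bonferroni(tst$p, max(1L, multiplicity)),
               test = tst$test_used, multiplicity = multiplicity,
               haldane = orr$haldane, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(allele = character(0), locus = character(0),
               a = integer(0), case_total = integer(0), c = integer(0),
               control_total = integer(0), or = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0), p = numeric(0),
               p_corrected = numeric(0), test = character(0),
               multiplicity = integer(0), haldane = logical(0))
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hla_scan", "data.frame")
  out
}

#' Association scan over several loci
#'
#' @inheritParams scan_locus
#' @param loci Loci to scan (default all four).
#' @return A combined \code{hla_scan} data frame, sorted by raw p within
#'   locus blocks concatenated in the given order.
#' @export
scan_cohort <- function(cohort, loci = HLA_LOCI, min_carriers = 3L) {
  out <- do.call(rbind, lapply(loci, function(l) {
    scan_locus(cohort, l, min_carriers = min_carriers)
  }))
  rownames(out) <- NULL
  class(out) <- c("hla_scan", "data.frame")
  out
}
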