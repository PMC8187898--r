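#' Compare a baseline variable between cases and controls
#'
#' Numeric variables are compared by an unequal-variance (Welch) t-test;
#' binary variables (logical, 0/1, or two-level factor/character) by a
#' Pearson chi-square test without continuity correction. This is the usual
#' "Table 1" comparison of demographic and exposure variables.
#'
#' @param cases,controls Vectors of per-individual observations.
#' @param variable Optional variable name carried into the output.
#' @return A one-row data frame: per-arm estimate (mean or proportion),
#'   difference, p-value, the method used, and a \code{degenerate} flag set
#'   when the p-value is undefined (e.g. zero variance in both arms).
#' @examples
#' cohort_characteristics(rnorm(50, 25, 17), rnorm(80, 27, 17), "age")
#' @export
cohort_characteristics <- function(cases, controls, variable = NA_character_) {
  is_binary <- function(x) {
    is.logical(x) ||
      (is.numeric(x) && all(x %in% c(0, 1))) ||
      ((is.character(x) || is.factor(x)) && length(unique(x)) <= 2L)
  }
  if (is_binary(cases) && is_binary(controls) &&
      !(is.numeric(cases) && !all(c(cases, controls) %in% c(0, 1)))) {
    lv <- unique(c(as.character(cases), as.character(controls)))
    x1 <- sum(as.character(cases) == lv[1L])
    x2 <- sum(as.character(controls) == lv[1L])
    p1 <- x1 / length(cases)
    p2 <- x2 / length(controls)
    m <- matrix(c(x1, length(cases) - x1, x2, length(controls) - x2),
                nrow = 2, byrow = TRUE)
    degenerate <- any(colSums(m) == 0)
    p <- if (degenerate) NA_real_ else
      suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
    return(data.frame(variable = variable, method = "chi-square",
                      estimate_case = p1, estimate_control = p2,
                      difference = p1 - p2, p = p,
                      degenerate = degenerate,
                      stringsAsFactors = FALSE))
  }
  if (length(cases) < 2L || length(controls) < 2L) {
    stop("numeric comparison needs at least 2 observations per arm",
         call. = FALSE)
  }
  degenerate <- stats::var(cases) == 0 && stats::var(controls) == 0
  m1 <- mean(cases); m2 <- mean(controls)
  p <- if (degenerate) {
    if (m1 == m2) 1 else NA_real_
  } else {
    stats::t.test(cases, controls, var.equal = FALSE)$p.value
  }
  data.frame(variable = variable, method = "welch-t",
             estimate_case = m1, estimate_control = m2,
             difference = m1 - m2, p = p, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Welch t-test from summary statistics
#'
#' Published cohorts often report only mean, SD and n per arm; this computes
#' the unequal-variance t-test (Welch-Satterthwaite degrees of freedom)
#' directly from those summaries.
#'
#' @param mean1,sd1,n1 Summary of arm 1.
#' @param mean2,sd2,n2 Summary of arm 2.
#' @return List with \code{t}, \code{df} and two-sided \code{p}.
#' @examples
#' welch_test_summary(347.86, 174.13, 70, 540.17, 289.41, 175)
#' @export
welch_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    return(list(t = NA_real_, df = NA_real_,
                p = if (mean1 == mean2) 1 else NA_real_))
  }
  tstat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}
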