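#' Sensitivity and specificity of a carrier marker
#'
#' Sensitivity is the carrier rate among cases (\code{a / case_total});
#' specificity is one minus the carrier rate among controls
#' (\code{1 - c / control_total}).
#'
#' @param table A [carrier_table()] or numeric
#'   \code{c(a, case_total, c, control_total)}.
#' @return List with \code{sensitivity} and \code{specificity}.
#' @examples
#' sensitivity_specificity(carrier_table(8, 51, 1, 94))
#' @export
sensitivity_specificity <- function(table) {
  tab <- as_carrier_table(table)
  list(sensitivity = tab$a / tab$case_total,
       specificity = 1 - tab$c / tab$control_total)
}

#' Positive and negative predictive values at an external prevalence
#'
#' Bayes inversion of sensitivity and specificity at a stated population
#' prevalence of the reaction:
#' \deqn{PPV = \frac{se \cdot \pi}{se \cdot \pi + (1-sp)(1-\pi)}, \quad
#'       NPV = \frac{sp (1-\pi)}{sp (1-\pi) + (1-se)\pi}.}
#' Published tables typically combine the 2-dp-rounded percentage
#' sensitivity/specificity; set \code{digits = 4} (proportion scale) to
#' reproduce that printed arithmetic. The default combines the exact inputs.
#'
#' @param sensitivity,specificity Fractions in \code{[0, 1]}.
#' @param prevalence External prevalence, in \code{(0, 1)}.
#' @param digits Optional number of decimals (on the proportion scale) to
#'   which sensitivity and specificity are rounded before combination.
#' @return List with \code{ppv}, \code{npv} and an \code{undefined} flag set
#'   when a denominator is zero (marker never positive / never negative).
#' @examples
#' predictive_values(8 / 51, 93 / 94, 0.09, digits = 4)
#' @export
predictive_values <- function(sensitivity, specificity, prevalence,
                              digits = NULL) {
  stopifnot(prevalence > 0, prevalence < 1,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  se <- sensitivity
  sp <- specificity
  if (!is.null(digits)) {
    se <- round(se, digits)
    sp <- round(sp, digits)
  }
  pos <- se * prevalence + (1 - sp) * (1 - prevalence)
  neg <- sp * (1 - prevalence) + (1 - se) * prevalence
  list(ppv = if (pos > 0) se * prevalence / pos else NA_real_,
       npv = if (neg > 0) sp * (1 - prevalence) / neg else NA_real_,
       undefined = pos == 0 || neg == 0)
}

#' Number needed to test to prevent one case
#'
#' The expected number of individuals screened (and the marker-positive ones
#' switched to another drug) per reaction prevented:
#' \code{1 / (prevalence * sensitivity)}, reported as the next whole person
#' (ceiling). The unrounded value is returned alongside.
#'
#' @param sensitivity Fraction in \code{(0, 1]}.
#' @param prevalence External prevalence in \code{(0, 1)}.
#' @return List with integer \code{nnt} and the unrounded \code{nnt_raw}.
#' @examples
#' number_needed_to_test(8 / 51, 0.09)
#' @export
number_needed_to_test <- function(sensitivity, prevalence) {
  if (sensitivity <= 0 || prevalence <= 0) {
    return(list(nnt = NA_integer_, nnt_raw = NA_real_, undefined = TRUE))
  }
  raw <- 1 / (prevalence * sensitivity)
  list(nnt = as.integer(ceiling(raw)), nnt_raw = raw, undefined = FALSE)
}

#' Carrier table for an allele set screened jointly
#'
#' "Positive" means carrying at least one allele of the set (the and/or
#' union rule). An individual untyped at some relevant loci still counts as
#' a carrier if a typed locus shows carriage; an individual who carries none
#' of the set at the typed loci but is untyped at one or more relevant loci
#' has indeterminate status (carriage there cannot be ruled out) and is
#' excluded from the denominators, as is anyone untyped at every relevant
#' locus.
#'
#' @param cohort An [hla_cohort()].
#' @param alleles A non-empty list/vector of [hla_allele()] objects or
#'   allele names.
#' @return A [carrier_table()].
#' @examples
#' \dontrun{combined_screen(cbz, c("HLA-A*24:02", "HLA-B*38:02"))}
#' @export
combined_screen <- function(cohort, alleles) {
  if (inherits(alleles, "hla_allele")) alleles <- list(alleles)
  if (length(alleles) == 0L) {
    stop("allele set must be non-empty", call. = FALSE)
  }
  status <- vapply(alleles, function(al) carrier_status(cohort, al),
                   character(cohort_size(cohort)))
  status <- matrix(status, nrow = cohort_size(cohort))
  combined <- apply(status, 1L, function(s) {
    if (any(s == "carrier")) "carrier"
    else if (any(s == "unknown")) "unknown"
    else "non-carrier"
  })
  grp <- cohort$records$group
  known <- combined != "unknown"
  if (!any(known & grp == "case") || !any(known & grp == "control")) {
    stop("no usable individuals in one arm for the combined screen",
         call. = FALSE)
  }
  carrier_table(sum(combined == "carrier" & grp == "case"),
                sum(known & grp == "case"),
                sum(combined == "carrier" & grp == "control"),
                sum(known & grp == "control"))
}

#' Full screening report for a marker at an external prevalence
#'
#' Convenience wrapper combining [sensitivity_specificity()],
#' [predictive_values()] and [number_needed_to_test()].
#'
#' @param table A [carrier_table()].
#' @param prevalence External prevalence of the reaction.
#' @param digits Optional rounding convention passed to
#'   [predictive_values()].
#' @return One-row data frame: \code{sensitivity, specificity, prevalence,
#'   ppv, npv, nnt, nnt_raw}.
#' @export
screen_performance <- function(table, prevalence, digits = NULL) {
  ss <- sensitivity_specificity(table)
  pv <- predictive_values(ss$sensitivity, ss$specificity, prevalence,
                          digits = digits)
  nn <- number_needed_to_test(ss$sensitivity, prevalence)
  data.frame(sensitivity = ss$sensitivity, specificity = ss$specificity,
             prevalence = prevalence, ppv = pv$ppv, npv = pv$npv,
             nnt = nn$nnt, nnt_raw = nn$nnt_raw)
}

#' Default external prevalences of drug-induced maculopapular exanthema
#'
#' Literature estimates of the incidence of the reaction per drug, used as
#' the external prevalence in screening metrics: 3.7% for carbamazepine,
#' 4.8% for lamotrigine, 9% for oxcarbazepine, and 2.8% overall for aromatic
#' antiepileptic drugs pooled.
#'
#' @export
MPE_PREVALENCE <- c(CBZ = 0.037, LTG = 0.048, OXC = 0.09, pooled = 0.028)
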