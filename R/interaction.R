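#' Cross-classified joint carrier table for two alleles
#'
#' Counts cases and controls in the four carrier strata of two alleles at
#' different loci: both carried (\code{pp}), first only (\code{pn}), second
#' only (\code{np}), neither (\code{nn}). Individuals untyped at either
#' locus are excluded.
#'
#' @param cohort An [hla_cohort()].
#' @param allele_a,allele_b [hla_allele()] objects or allele names; must be
#'   at different loci (two alleles at the same locus cannot be carried
#'   jointly in the required sense).
#' @return Object of class \code{joint_carrier_table}: a 2x4 integer matrix
#'   (rows \code{case}, \code{control}; columns \code{pp, pn, np, nn}) with
#'   the allele names as attributes.
#' @export
build_joint_table <- function(cohort, allele_a, allele_b) {
  allele_a <- parse_allele(allele_a)
  allele_b <- parse_allele(allele_b)
  if (allele_a$locus == allele_b$locus) {
    stop("interaction decomposition needs alleles at different loci, got ",
         format(allele_a), " and ", format(allele_b), call. = FALSE)
  }
  sa <- carrier_status(cohort, allele_a)
  sb <- carrier_status(cohort, allele_b)
  keep <- sa != "unknown" & sb != "unknown"
  grp <- cohort$records$group[keep]
  ca <- sa[keep] == "carrier"
  cb <- sb[keep] == "carrier"
  stratum <- ifelse(ca & cb, "pp",
                    ifelse(ca, "pn", ifelse(cb, "np", "nn")))
  m <- matrix(0L, nrow = 2, ncol = 4,
              dimnames = list(group = c("case", "control"),
                              stratum = c("pp", "pn", "np", "nn")))
  tab <- table(factor(grp, levels = c("case", "control")),
               factor(stratum, levels = c("pp", "pn", "np", "nn")))
  m[] <- as.integer(tab)
  structure(m, class = c("joint_carrier_table", class(m)),
            allele_a = format(allele_a), allele_b = format(allele_b))
}

#' Joint carrier table from the eight stratum counts
#'
#' For working directly from a published cross-classification.
#'
#' @param cases,controls Length-4 integer vectors of counts in strata
#'   \code{pp, pn, np, nn} (both carried, first only, second only, neither).
#' @param allele_a,allele_b Optional allele names for labelling.
#' @return A \code{joint_carrier_table}.
#' @examples
#' joint_carrier_table(c(5, 26, 13, 96), c(1, 27, 9, 140))
#' @export
joint_carrier_table <- function(cases, controls, allele_a = "A",
                                allele_b = "B") {
  stopifnot(length(cases) == 4L, length(controls) == 4L,
            all(c(cases, controls) >= 0),
            all(c(cases, controls) == round(c(cases, controls))))
  m <- matrix(as.integer(rbind(cases, controls)), nrow = 2, byrow = FALSE,
              dimnames = list(group = c("case", "control"),
                              stratum = c("pp", "pn", "np", "nn")))
  structure(m, class = c("joint_carrier_table", class(m)),
            allele_a = allele_a, allele_b = allele_b)
}

#' Stratum odds ratios against the double-negative reference
#'
#' Each OR is the cross-product ratio of a carrier stratum against the
#' neither-allele stratum (whose OR is 1 by construction). Zero cells in a
#' contrast receive the Haldane-Anscombe 0.5 correction, flagged.
#'
#' @param table A \code{joint_carrier_table}.
#' @return List with \code{or_joint} (both alleles), \code{or_a_only},
#'   \code{or_b_only}, and a logical \code{haldane} flag per contrast.
#' @examples
#' stratum_odds_ratios(joint_carrier_table(c(5, 26, 13, 96), c(1, 27, 9, 140)))
#' @export
stratum_odds_ratios <- function(table) {
  stopifnot(inherits(table, "joint_carrier_table"))
  ref_case <- table["case", "nn"]
  ref_ctrl <- table["control", "nn"]
  if (ref_case == 0L || ref_ctrl == 0L) {
    stop("empty double-negative reference stratum", call. = FALSE)
  }
  one <- function(stratum) {
    cells <- c(table["case", stratum], ref_case,
               table["control", stratum], ref_ctrl)
    haldane <- any(cells == 0)
    if (haldane) cells <- cells + 0.5
    list(or = cells[1L] * cells[4L] / (cells[2L] * cells[3L]),
         haldane = haldane)
  }
  pp <- one("pp"); pn <- one("pn"); np <- one("np")
  list(or_joint = pp$or, or_a_only = pn$or, or_b_only = np$or,
       haldane = c(joint = pp$haldane, a_only = pn$haldane,
                   b_only = np$haldane))
}

#' Multiplicative and additive interaction decomposition
#'
#' Contrasts the observed joint odds ratio with its expectation under no
#' interaction on two scales: multiplicative
#' (\code{expected = or_a * or_b}, \code{interaction_ratio =
#' or_joint / expected}) and additive
#' (\code{expected = or_a + or_b - 1}, \code{excess_risk = or_joint -
#' expected}). With \code{rounding} set, the three component ORs are rounded
#' to that many decimals before combination, reproducing the arithmetic of
#' published tables that combine rounded ORs; the default combines the exact
#' values.
#'
#' @param ors Output of [stratum_odds_ratios()], or a numeric vector
#'   \code{c(or_joint, or_a_only, or_b_only)}.
#' @param rounding Optional number of decimals for the printed-arithmetic
#'   convention.
#' @return List with \code{or_joint, or_a_only, or_b_only,
#'   expected_multiplicative, interaction_ratio, expected_additive,
#'   excess_risk}.
#' @examples
#' decompose_interaction(c(7.29, 1.40, 2.11), rounding = 2)
#' @export
decompose_interaction <- function(ors, rounding = NULL) {
  if (is.list(ors)) ors <- c(ors$or_joint, ors$or_a_only, ors$or_b_only)
  stopifnot(is.numeric(ors), length(ors) == 3L, all(ors > 0))
  if (!is.null(rounding)) ors <- round(ors, rounding)
  or_joint <- ors[1L]; or_a <- ors[2L]; or_b <- ors[3L]
  em <- or_a * or_b
  ea <- or_a + or_b - 1
  out <- list(or_joint = or_joint, or_a_only = or_a, or_b_only = or_b,
              expected_multiplicative = em,
              interaction_ratio = or_joint / em,
              expected_additive = ea,
              excess_risk = or_joint - ea)
  if (!is.null(rounding)) out <- lapply(out, round, digits = rounding)
  out
}

#' Logistic model with a product term on the grouped joint table
#'
#' Fits case status on indicator main effects for the two alleles and their
#' product, by maximum likelihood on the grouped (binomial per stratum)
#' data. With four strata and four parameters the model is saturated, so the
#' fitted ORs equal the empirical stratum cross-product ratios. Perfect
#' separation (a non-empty stratum with only cases or only controls) is
#' flagged rather than reported as converged.
#'
#' @param table A \code{joint_carrier_table}.
#' @return List of class \code{logistic_interaction_fit}:
#'   \code{coefficients} (data frame with term, estimate, se, z, p, or),
#'   \code{converged}, \code{iterations}, \code{separation}.
#' @export
fit_logistic_interaction <- function(table) {
  stopifnot(inherits(table, "joint_carrier_table"))
  df <- data.frame(carrier_a = c(1, 1, 0, 0), carrier_b = c(1, 0, 1, 0),
                   cases = table["case", c("pp", "pn", "np", "nn")],
                   controls = table["control", c("pp", "pn", "np", "nn")])
  occupied <- df$cases + df$controls > 0
  separation <- any(occupied & (df$cases == 0 | df$controls == 0))
  fit <- suppressWarnings(stats::glm(
    cbind(cases, controls) ~ carrier_a * carrier_b,
    family = stats::binomial(), data = df,
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  sm <- summary(fit)$coefficients
  # an empty stratum aliases the product term; keep all rows, NA-filled
  labels <- c("(Intercept)" = "intercept", "carrier_a" = "carrier_a",
              "carrier_b" = "carrier_b",
              "carrier_a:carrier_b" = "carrier_a:carrier_b")
  idx <- match(names(labels), rownames(sm))
  coefs <- data.frame(
    term = unname(labels),
    estimate = sm[idx, 1L], se = sm[idx, 2L], z = sm[idx, 3L],
    p = sm[idx, 4L], or = exp(sm[idx, 1L]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  aliased <- is.na(coefs$estimate)
  structure(list(coefficients = coefs,
                 converged = fit$converged && !separation && !any(aliased),
                 iterations = fit$iter,
                 separation = separation),
            class = "logistic_interaction_fit")
}

#' @export
print.logistic_interaction_fit <- function(x, ...) {
  cat("grouped logistic fit with product term",
      if (!x$converged) "(NOT converged)" else
        sprintf("(%d IRLS iterations)", x$iterations), "\n")
  if (x$separation) cat("warning: perfect separation detected\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}
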