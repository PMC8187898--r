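#' Assemble a per-study table for meta-analysis
#'
#' @param study_id,population,drug Character vectors (recycled if length 1).
#' @param case_carriers,case_total,control_carriers,control_total Integer
#'   vectors of per-study carrier counts and totals.
#' @return Data frame of class \code{meta_studies}.
#' @export
meta_studies <- function(study_id, population = "NA", drug = "mixed",
                         case_carriers, case_total,
                         control_carriers, control_total) {
  df <- data.frame(study_id = as.character(study_id),
                   population = population, drug = drug,
                   case_carriers = as.integer(case_carriers),
                   case_total = as.integer(case_total),
                   control_carriers = as.integer(control_carriers),
                   control_total = as.integer(control_total),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    carrier_table(df$case_carriers[i], df$case_total[i],
                  df$control_carriers[i], df$control_total[i])
  }
  class(df) <- c("meta_studies", "data.frame")
  df
}

#' Read per-study carrier tables from a CSV
#'
#' Expected columns: \code{study_id, population, drug, allele,
#' case_carriers, case_total, control_carriers, control_total}.
#'
#' @param path Path to the CSV.
#' @return Data frame of class \code{meta_studies} (with the \code{allele}
#'   column retained for per-allele splitting).
#' @export
read_studies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study_id", "case_carriers", "case_total",
                "control_carriers", "control_total")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("study table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"population" %in% names(df)) df$population <- NA_character_
  if (!"drug" %in% names(df)) df$drug <- "mixed"
  out <- meta_studies(df$study_id, df$population, df$drug,
                      df$case_carriers, df$case_total,
                      df$control_carriers, df$control_total)
  if ("allele" %in% names(df)) out$allele <- df$allele
  out
}

# internal: cells a, b, c, d per study
study_cells <- function(studies) {
  data.frame(a = studies$case_carriers,
             b = studies$case_total - studies$case_carriers,
             c = studies$control_carriers,
             d = studies$control_total - studies$control_carriers)
}

#' Per-study Woolf log odds ratio and variance
#'
#' Log-OR with variance \code{1/a + 1/b + 1/c + 1/d}; studies containing a
#' zero cell get 0.5 added to all four cells (flagged). Studies with an arm
#' that is entirely carriers and non-carriers absent (zero total) are
#' rejected at construction, so every retained study has finite effects.
#'
#' @param studies A \code{meta_studies} data frame.
#' @return Data frame: \code{study_id, log_or, var_log_or, haldane}.
#' @export
study_effects <- function(studies) {
  cells <- study_cells(studies)
  haldane <- apply(cells, 1L, function(r) any(r == 0))
  cc <- cells + ifelse(haldane, 0.5, 0)
  data.frame(study_id = studies$study_id,
             log_or = log(cc$a * cc$d / (cc$b * cc$c)),
             var_log_or = 1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d,
             haldane = haldane, stringsAsFactors = FALSE)
}

#' Mantel-Haenszel fixed-effect pooled odds ratio
#'
#' Pooled OR = sum(a_i d_i / n_i) / sum(b_i c_i / n_i) on the uncorrected
#' counts; the variance of the log pooled OR uses the
#' Robins-Breslow-Greenland estimator. Wald CI and two-sided test.
#'
#' @param studies A \code{meta_studies} data frame.
#' @param z Normal quantile for the CI (default 95% level).
#' @return List: \code{or, ci_low, ci_high, log_or, se_log_or, z, p}.
#' @export
pool_fixed_mh <- function(studies, z = 1.959964) {
  cells <- study_cells(studies)
  n <- cells$a + cells$b + cells$c + cells$d
  R <- cells$a * cells$d / n
  S <- cells$b * cells$c / n
  if (sum(S) == 0) {
    stop("Mantel-Haenszel pooled OR undefined: sum of b*c/n is zero",
         call. = FALSE)
  }
  or <- sum(R) / sum(S)
  P <- (cells$a + cells$d) / n
  Q <- (cells$b + cells$c) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  se <- sqrt(v)
  zstat <- log(or) / se
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       log_or = log(or), se_log_or = se,
       z = zstat, p = 2 * stats::pnorm(-abs(zstat)))
}

#' Cochran's Q, I-squared and the DerSimonian-Laird tau-squared
#'
#' Q is the inverse-variance weighted sum of squared deviations of the
#' per-study log-ORs from their fixed-effect (inverse-variance) pooled
#' value; its null distribution is chi-square with k - 1 df.
#' \code{I2 = max(0, (Q - (k-1)) / Q) * 100} and the DerSimonian-Laird
#' moment estimator \code{tau2 = max(0, (Q - (k-1)) / (sum(w) -
#' sum(w^2)/sum(w)))}. A single study gives Q = 0, I2 = 0, tau2 = 0 with an
#' undefined Q p-value.
#'
#' @param studies A \code{meta_studies} data frame.
#' @return List: \code{q, q_p, i2, tau2, k}.
#' @export
heterogeneity <- function(studies) {
  eff <- study_effects(studies)
  k <- nrow(eff)
  if (k < 2L) {
    return(list(q = 0, q_p = NA_real_, i2 = 0, tau2 = 0, k = k))
  }
  w <- 1 / eff$var_log_or
  theta_fe <- sum(w * eff$log_or) / sum(w)
  q <- sum(w * (eff$log_or - theta_fe)^2)
  q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  list(q = q, q_p = q_p, i2 = i2, tau2 = tau2, k = k)
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Inverse-variance pooling of per-study log-ORs with weights
#' \code{1 / (v_i + tau2)}; reduces to inverse-variance fixed pooling when
#' tau2 = 0.
#'
#' @param studies A \code{meta_studies} data frame.
#' @param tau2 Between-study variance; computed by [heterogeneity()] if
#'   missing.
#' @param z Normal quantile for the CI.
#' @return List: \code{or, ci_low, ci_high, log_or, se_log_or, z, p, tau2}.
#' @export
pool_random_dl <- function(studies, tau2 = NULL, z = 1.959964) {
  eff <- study_effects(studies)
  if (is.null(tau2)) tau2 <- heterogeneity(studies)$tau2
  w <- 1 / (eff$var_log_or + tau2)
  lor <- sum(w * eff$log_or) / sum(w)
  se <- sqrt(1 / sum(w))
  zstat <- lor / se
  list(or = exp(lor), ci_low = exp(lor - z * se),
       ci_high = exp(lor + z * se), log_or = lor, se_log_or = se,
       z = zstat, p = 2 * stats::pnorm(-abs(zstat)), tau2 = tau2)
}

#' Heterogeneity-driven model choice
#'
#' The random-effects model is selected iff the heterogeneity test is
#' significant at the 0.1 level AND I-squared exceeds 50%; otherwise the
#' fixed-effect model is used. Both sub-conditions are reported so the rule
#' can be audited.
#'
#' @param q_p P-value of Cochran's Q (NA counts as not significant).
#' @param i2 I-squared percentage.
#' @return List: \code{model} (\code{"fixed"}/\code{"random"}),
#'   \code{q_significant}, \code{i2_high}.
#' @export
select_model <- function(q_p, i2) {
  q_sig <- !is.na(q_p) && q_p < 0.1
  i2_high <- i2 > 50
  list(model = if (q_sig && i2_high) "random" else "fixed",
       q_significant = q_sig, i2_high = i2_high)
}

#' Full meta-analysis of per-study carrier tables
#'
#' Computes per-study effects, the Mantel-Haenszel fixed-effect and
#' DerSimonian-Laird random-effects pooled odds ratios, heterogeneity
#' statistics, and applies the model-selection rule.
#'
#' @param studies A \code{meta_studies} data frame.
#' @param z Normal quantile for all CIs.
#' @return List of class \code{meta_result}: \code{k, studies, effects,
#'   fixed, random, q, q_p, i2, tau2, model_selected, selected} (the pooled
#'   result under the selected model).
#' @export
meta_analyze <- function(studies, z = 1.959964) {
  stopifnot(nrow(studies) >= 1L)
  het <- heterogeneity(studies)
  fixed <- pool_fixed_mh(studies, z = z)
  random <- pool_random_dl(studies, tau2 = het$tau2, z = z)
  sel <- select_model(het$q_p, het$i2)
  structure(list(k = het$k, studies = studies,
                 effects = study_effects(studies),
                 fixed = fixed, random = random,
                 q = het$q, q_p = het$q_p, i2 = het$i2, tau2 = het$tau2,
                 model_selected = sel$model,
                 q_significant = sel$q_significant, i2_high = sel$i2_high,
                 selected = if (sel$model == "random") random else fixed,
                 methods = c(fixed = "Mantel-Haenszel",
                             random = "DerSimonian-Laird")),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta-analysis of %d studies\n", x$k))
  cat(sprintf("  fixed (MH):  OR %.3f (%.3f-%.3f)\n",
              x$fixed$or, x$fixed$ci_low, x$fixed$ci_high))
  cat(sprintf("  random (DL): OR %.3f (%.3f-%.3f), tau2 %.4f\n",
              x$random$or, x$random$ci_low, x$random$ci_high, x$tau2))
  cat(sprintf("  Q %.3f (p %s), I2 %.1f%% -> %s model, p %.4g\n",
              x$q, format(x$q_p, digits = 3), x$i2,
              x$model_selected, x$selected$p))
  invisible(x)
}

#' Forest-plot data export
#'
#' Per-study odds ratios, CIs and percentage weights under the selected
#' model (weights sum to 100), followed by the pooled diamond row.
#'
#' @param meta A \code{meta_result} from [meta_analyze()].
#' @param z Normal quantile for per-study CIs.
#' @return Data frame: \code{study_id, or, ci_low, ci_high, weight,
#'   pooled}.
#' @export
forest_data <- function(meta, z = 1.959964) {
  eff <- meta$effects
  w <- if (meta$model_selected == "random") {
    1 / (eff$var_log_or + meta$tau2)
  } else {
    1 / eff$var_log_or
  }
  weight <- 100 * w / sum(w)
  rows <- data.frame(study_id = eff$study_id,
                     or = exp(eff$log_or),
                     ci_low = exp(eff$log_or - z * sqrt(eff$var_log_or)),
                     ci_high = exp(eff$log_or + z * sqrt(eff$var_log_or)),
                     weight = weight, pooled = FALSE,
                     stringsAsFactors = FALSE)
  pooled <- meta$selected
  rbind(rows, data.frame(study_id = sprintf("pooled (%s)",
                                            meta$model_selected),
                         or = pooled$or, ci_low = pooled$ci_low,
                         ci_high = pooled$ci_high, weight = 100,
                         pooled = TRUE, stringsAsFactors = FALSE))
}
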