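#' Cochran's Q heterogeneity test
#'
#' `Q = sum over j of (beta_outcome_j - intercept - b * beta_exposure_j)^2
#' / se_outcome_j^2`, which equals the inverse-variance weighted sum of
#' squared deviations of the per-SNP Wald ratios from the fitted effect
#' (first-order weights `beta_exposure^2 / se_outcome^2`). Under
#' homogeneity Q is chi-squared with `nSNP - df_loss` degrees of freedom
#' (`df_loss` 1 for IVW, 2 for the Egger intercept model). Heterogeneity is
#' indicated when the test's p-value falls below 0.05.
#'
#' @param h A [harmonized_set()].
#' @param fitted_b Fitted causal effect (e.g. the IVW estimate).
#' @param df_loss Degrees of freedom absorbed by the fit (default 1).
#' @param intercept Fitted intercept (0 for IVW; for the Egger variant use
#'   [mr_egger()], which reports its own `q`, since the intercept applies on
#'   the orientation-flipped scale).
#' @return A list with `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(h, fitted_b, df_loss = 1L, intercept = 0) {
  r <- h$records
  df <- nrow(r) - df_loss
  if (df < 1L) stop("insufficient instruments for a heterogeneity test")
  resid <- r$beta_outcome - intercept - fitted_b * r$beta_exposure
  q <- sum(resid^2 / r$se_outcome^2)
  list(q = q, df = df,
       pvalue = stats::pchisq(q, df = df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Extracts the intercept of an [mr_egger()] fit with its standard error and
#' two-sided t(nSNP - 2) p-value; a nonzero intercept indicates directional
#' horizontal pleiotropy (flagged at p < 0.05).
#'
#' @param egger_fit An `mr_egger_fit` object.
#' @return A list with `intercept`, `se`, `pvalue`, `pleiotropy` (logical).
#' @export
egger_intercept_test <- function(egger_fit) {
  if (!inherits(egger_fit, "mr_egger_fit")) stop("expected an mr_egger_fit")
  ic <- egger_fit$intercept
  list(intercept = ic$b, se = ic$se, pvalue = ic$pvalue,
       pleiotropy = ic$pvalue < 0.05)
}

#' Steiger directionality test
#'
#' Compares the exposure variance explained by the instruments with the
#' outcome variance they explain, to detect reverse causation. The exposure
#' side sums the per-SNP `2 * EAF * (1 - EAF) * beta^2` (standardized-trait
#' formula); the outcome side sums squared per-SNP correlations approximated
#' from z statistics, `r = z / sqrt(z^2 + N)`, which for binary outcomes is
#' an observed-scale approximation. The inferred direction is
#' exposure -> outcome (`TRUE`) iff the exposure r-squared is larger; the
#' p-value compares the two Fisher-z-transformed multiple correlations with
#' a two-sided normal test.
#'
#' @param h A [harmonized_set()] with non-missing `eaf_exposure`.
#' @param n_exposure,n_outcome GWAS sample sizes (default: taken from `h`).
#' @param outcome_type `"binary"` or `"continuous"`; recorded in the result
#'   (the observed-scale z approximation is used for both).
#' @return A list with `direction` (logical), `pvalue`, `r2_exposure`,
#'   `r2_outcome`.
#' @export
steiger_test <- function(h, n_exposure = h$n_exposure,
                         n_outcome = h$n_outcome,
                         outcome_type = c("binary", "continuous")) {
  outcome_type <- match.arg(outcome_type)
  r <- h$records
  if (nrow(r) == 0L) stop("no instruments")
  if (any(is.na(r$eaf_exposure))) {
    stop("steiger_test requires exposure EAF for every instrument")
  }
  if (is.na(n_exposure) || is.na(n_outcome)) {
    stop("steiger_test requires both sample sizes")
  }
  r2_exp <- sum(2 * r$eaf_exposure * (1 - r$eaf_exposure) * r$beta_exposure^2)
  z <- r$beta_outcome / r$se_outcome
  r2_out <- sum(z^2 / (z^2 + n_outcome))
  cap <- function(x) min(x, 1 - 1e-12)
  rx <- sqrt(cap(r2_exp))
  ry <- sqrt(cap(r2_out))
  zstat <- (atanh(rx) - atanh(ry)) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  list(direction = r2_exp > r2_out,
       pvalue = 2 * stats::pnorm(-abs(zstat)),
       r2_exposure = r2_exp, r2_outcome = r2_out,
       outcome_type = outcome_type)
}

#' Category-wise Bonferroni correction schemes
#'
#' Default divisors per exposure category: order 1, family 3, genus 15,
#' metabolite 9, pathway 20, each applied to a base alpha of 0.05.
#'
#' @param divisors Named integer vector (category -> number of comparisons).
#' @param alpha Base significance level; default 0.05.
#' @return A data frame with columns `category`, `divisor`, `alpha`.
#' @export
correction_schemes <- function(divisors = c(order = 1, family = 3, genus = 15,
                                            metabolite = 9, pathway = 20),
                               alpha = 0.05) {
  if (any(divisors < 1)) stop("divisors must be >= 1")
  data.frame(category = names(divisors), divisor = unname(divisors),
             alpha = alpha, stringsAsFactors = FALSE)
}

#' Apply a Bonferroni correction by exposure category
#'
#' The corrected threshold is `alpha / divisor` for the exposure's category;
#' an exposure passes when its p-value is strictly below the threshold.
#'
#' @param pvalues Named numeric vector of per-exposure p-values.
#' @param categories Character vector (recycled if length 1) assigning each
#'   exposure to a category of `schemes`.
#' @param schemes A [correction_schemes()] data frame.
#' @return A data frame with `exposure`, `category`, `pvalue`, `threshold`,
#'   `passes`.
#' @export
bonferroni <- function(pvalues, categories,
                       schemes = correction_schemes()) {
  if (length(categories) == 1L) {
    categories <- rep(categories, length(pvalues))
  }
  idx <- match(categories, schemes$category)
  if (anyNA(idx)) {
    stop("unknown correction category: ",
         paste(unique(categories[is.na(idx)]), collapse = ", "))
  }
  threshold <- schemes$alpha[idx] / schemes$divisor[idx]
  data.frame(exposure = if (is.null(names(pvalues)))
               as.character(seq_along(pvalues)) else names(pvalues),
             category = categories,
             pvalue = unname(pvalues),
             threshold = threshold,
             passes = unname(pvalues) < threshold,
             stringsAsFactors = FALSE)
}

#' Full sensitivity report for one instrument set
#'
#' Bundles the Cochran's Q tests (IVW and Egger variants), the Egger
#' intercept, and the Steiger directionality test.
#'
#' @param h A [harmonized_set()] with at least 3 SNPs.
#' @param ivw_b The fitted IVW effect (computed if missing).
#' @param outcome_type Passed to [steiger_test()].
#' @return A list with components `q_ivw`, `q_egger`, `egger_intercept`,
#'   `steiger`.
#' @export
sensitivity_report <- function(h, ivw_b = NULL,
                               outcome_type = c("binary", "continuous")) {
  outcome_type <- match.arg(outcome_type)
  if (is.null(ivw_b)) ivw_b <- mr_ivw(h)$b
  eg <- mr_egger(h)
  list(q_ivw = cochran_q(h, ivw_b, df_loss = 1L),
       q_egger = list(q = eg$q, df = eg$q_df, pvalue = eg$q_pvalue),
       egger_intercept = egger_intercept_test(eg),
       steiger = steiger_test(h, outcome_type = outcome_type))
}
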