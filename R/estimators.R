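# Per-SNP Wald ratios and inverse-variance weights; the shared intermediate
# of the median and mode estimators.
ratio_estimates <- function(h) {
  r <- h$records
  if (any(r$beta_exposure == 0)) {
    stop("degenerate instrument: beta_exposure = 0")
  }
  ratio <- r$beta_outcome / r$beta_exposure
  se <- r$se_outcome / abs(r$beta_exposure)
  w <- r$beta_exposure^2 / r$se_outcome^2
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("ratio weights must be positive and finite")
  }
  data.frame(snp = r$snp, ratio = ratio, se = se, w = w,
             stringsAsFactors = FALSE)
}

mr_estimate <- function(method, b, se, pvalue, n_snp, level = 0.95) {
  orci <- to_odds_ratio(b, se, level)
  data.frame(method = method, n_snp = n_snp, b = b, se = se, pvalue = pvalue,
             or = orci$or, ci_low = orci$ci_low, ci_high = orci$ci_high,
             stringsAsFactors = FALSE)
}

#' Odds ratio and confidence interval from a log-odds effect
#'
#' @param b Log-odds causal effect.
#' @param se Its standard error (`>= 0`).
#' @param level Two-sided confidence level in (0, 1); default 0.95.
#' @return A data frame with `or = exp(b)` and
#'   `ci = exp(b -/+ z * se)` where `z` is the normal quantile for `level`.
#' @export
to_odds_ratio <- function(b, se, level = 0.95) {
  stopifnot(all(se >= 0), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(or = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se))
}

#' Wald ratio estimate from a single instrument
#'
#' `b = beta_outcome / beta_exposure`, first-order
#' `se = se_outcome / |beta_exposure|`, two-sided normal p-value.
#'
#' @param h A [harmonized_set()] with exactly one SNP.
#' @return A one-row estimate data frame (method "Wald ratio").
#' @export
wald_ratio <- function(h) {
  if (nrow(h$records) != 1L) stop("wald_ratio expects a single instrument")
  re <- ratio_estimates(h)
  p <- 2 * stats::pnorm(-abs(re$ratio / re$se))
  mr_estimate("Wald ratio", re$ratio, re$se, p, 1L)
}

#' Inverse-variance weighted estimate
#'
#' Fixed-effect meta-analysis of the per-SNP Wald ratios with weights
#' `beta_exposure^2 / se_outcome^2`:
#' `b = sum(bx * by / sey^2) / sum(bx^2 / sey^2)`,
#' `se = sqrt(1 / sum(bx^2 / sey^2))`, two-sided normal p. With
#' `random_effects = TRUE` the standard error is inflated multiplicatively
#' by `sqrt(Q / (nSNP - 1))`, floored at 1.
#'
#' @param h A [harmonized_set()] with at least two SNPs (a single SNP is
#'   routed to [wald_ratio()] with a warning).
#' @param random_effects Use multiplicative random effects? Default `FALSE`.
#' @return A one-row estimate data frame (method "IVW").
#' @export
mr_ivw <- function(h, random_effects = FALSE) {
  r <- h$records
  n <- nrow(r)
  if (n < 2L) {
    warning("fewer than 2 instruments; returning Wald ratio")
    return(wald_ratio(h))
  }
  w <- 1 / r$se_outcome^2
  sxy <- sum(r$beta_exposure * r$beta_outcome * w)
  sxx <- sum(r$beta_exposure^2 * w)
  b <- sxy / sxx
  se <- sqrt(1 / sxx)
  if (random_effects) {
    q <- sum(w * (r$beta_outcome - b * r$beta_exposure)^2)
    se <- se * max(1, sqrt(q / (n - 1)))
  }
  p <- 2 * stats::pnorm(-abs(b / se))
  mr_estimate("IVW", b, se, p, n)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome on exposure effects with a
#' free intercept, weights `1 / se_outcome^2`, after orienting every pair so
#' that `beta_exposure >= 0` (the usual identification convention). Both
#' coefficient standard errors use multiplicative residual inflation floored
#' at 1, and p-values come from a t distribution with `nSNP - 2` degrees of
#' freedom. The intercept estimates the mean directional pleiotropic effect;
#' the slope is the causal estimate, consistent under InSIDE.
#'
#' @param h A [harmonized_set()] with at least three SNPs.
#' @return A list of class `mr_egger_fit` with elements `slope` (estimate
#'   data frame, method "MR Egger"), `intercept` (list `b`, `se`, `pvalue`),
#'   and the regression heterogeneity statistic `q`, `q_df`, `q_pvalue`.
#' @export
mr_egger <- function(h) {
  r <- h$records
  n <- nrow(r)
  if (n < 3L) stop("MR-Egger requires at least 3 instruments")
  flip <- ifelse(r$beta_exposure < 0, -1, 1)
  bx <- r$beta_exposure * flip
  by <- r$beta_outcome * flip
  w <- 1 / r$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  est <- stats::coef(fit)
  q <- sum(w * stats::residuals(fit)^2)
  sigma2 <- max(1, q / (n - 2))          # residual scale floored at 1
  # unit-scale coefficient variances from (X' W X)^{-1}
  xtwx_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * diag(xtwx_inv))
  names(se) <- names(est)
  pv <- 2 * stats::pt(-abs(est / se), df = n - 2)
  structure(list(
    slope = mr_estimate("MR Egger", est[["bx"]], se[["bx"]], pv[["bx"]], n),
    intercept = list(b = est[["(Intercept)"]], se = se[["(Intercept)"]],
                     pvalue = pv[["(Intercept)"]]),
    q = q, q_df = n - 2,
    q_pvalue = stats::pchisq(q, df = n - 2, lower.tail = FALSE)),
    class = "mr_egger_fit")
}

# weighted empirical quantile with the cumulative-weight-minus-half rule and
# linear interpolation between order statistics
weighted_quantile <- function(x, w, q = 0.5) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = q, rule = 2, ties = "ordered")$y
}

# parametric bootstrap of any ratio-based point estimator: redraw per-SNP
# effects from normals centred on the observations
boot_se <- function(h, statistic, n_boot, seed) {
  r <- h$records
  n <- nrow(r)
  set.seed(seed)
  est <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(n, r$beta_exposure, r$se_exposure)
    by <- stats::rnorm(n, r$beta_outcome, r$se_outcome)
    statistic(bx, by, r$se_outcome)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted median estimate
#'
#' Median of the per-SNP Wald ratio distribution weighted by
#' `beta_exposure^2 / se_outcome^2` (normalized), using linear interpolation
#' of the weighted empirical quantile at 0.5. Consistent when at least half
#' of the weight comes from valid instruments. The standard error is a
#' seeded parametric bootstrap that redraws `beta_exposure` and
#' `beta_outcome` from normal distributions with their reported standard
#' errors; p-value two-sided normal.
#'
#' @param h A [harmonized_set()] with at least three SNPs.
#' @param n_boot Bootstrap replicates (>= 100); default 1000.
#' @param seed Integer seed for the bootstrap (mandatory: no silent
#'   nondeterminism).
#' @return A one-row estimate data frame (method "Weighted median").
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  if (nrow(h$records) < 3L) stop("weighted median requires >= 3 instruments")
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (missing(seed)) stop("a bootstrap seed is required")
  re <- ratio_estimates(h)
  b <- weighted_quantile(re$ratio, re$w, 0.5)
  se <- boot_se(h, function(bx, by, sey) {
    weighted_quantile(by / bx, bx^2 / sey^2, 0.5)
  }, n_boot, seed)
  p <- 2 * stats::pnorm(-abs(b / se))
  mr_estimate("Weighted median", b, se, p, nrow(h$records))
}

# mode of the (optionally weighted) Gaussian kernel density of the ratios;
# bandwidth is the modified Silverman rule on the ratio vector
kde_mode <- function(ratio, w, phi) {
  n <- length(ratio)
  spread <- c(stats::sd(ratio), stats::mad(ratio))
  spread <- spread[is.finite(spread) & spread > 0]
  if (length(spread) == 0L) return(ratio[1])  # all ratios identical
  h_bw <- phi * 0.9 * min(spread) * n^(-1 / 5)
  w <- w / sum(w)
  d <- stats::density(ratio, weights = w, bw = h_bw, n = 2048)
  d$x[which.max(d$y)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The mode of the smoothed empirical density of the per-SNP Wald ratios
#' (Gaussian kernel, bandwidth `phi * 0.9 * min(sd, mad) * n^(-1/5)` with
#' the MAD scaled to be sd-consistent). The weighted variant weights each
#' ratio's kernel by its inverse-variance weight
#' `beta_exposure^2 / se_outcome^2`; the simple variant weights equally.
#' Consistent when the largest group of instruments sharing a causal
#' estimate is valid (ZEMPA). Standard error by the same parametric
#' bootstrap as the weighted median; p-value two-sided t with `nSNP - 1`
#' degrees of freedom.
#'
#' @param h A [harmonized_set()] with at least three SNPs.
#' @param weighted Use inverse-variance kernel weights? Default `FALSE`.
#' @param phi Bandwidth multiplier (> 0); default 1.
#' @param n_boot Bootstrap replicates (>= 100); default 1000.
#' @param seed Integer seed for the bootstrap.
#' @return A one-row estimate data frame (method "Simple mode" or
#'   "Weighted mode").
#' @export
mr_mode <- function(h, weighted = FALSE, phi = 1, n_boot = 1000, seed) {
  r <- h$records
  n <- nrow(r)
  if (n < 3L) stop("mode estimators require >= 3 instruments")
  if (phi <= 0) stop("phi must be > 0")
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (missing(seed)) stop("a bootstrap seed is required")
  re <- ratio_estimates(h)
  wts <- if (weighted) re$w else rep(1, n)
  b <- kde_mode(re$ratio, wts, phi)
  se <- boot_se(h, function(bx, by, sey) {
    ratio <- by / bx
    kde_mode(ratio, if (weighted) bx^2 / sey^2 else rep(1, length(ratio)), phi)
  }, n_boot, seed)
  p <- 2 * stats::pt(-abs(b / se), df = n - 1)
  mr_estimate(if (weighted) "Weighted mode" else "Simple mode",
              b, se, p, n)
}

#' All five causal estimators on one instrument set
#'
#' Runs IVW, MR-Egger (slope), weighted median, simple mode and weighted
#' mode, in the row order used by the report tables. Instrument sets of one
#' SNP return a single Wald-ratio row; sets of two return IVW only.
#'
#' @param h A [harmonized_set()].
#' @param n_boot,phi,seed Passed to the median/mode estimators.
#' @return A data frame with one row per method.
#' @export
mr_all <- function(h, n_boot = 1000, phi = 1, seed) {
  n <- nrow(h$records)
  if (n == 1L) return(wald_ratio(h))
  if (n == 2L) return(mr_ivw(h))
  rbind(mr_ivw(h),
        mr_egger(h)$slope,
        mr_weighted_median(h, n_boot = n_boot, seed = seed),
        mr_mode(h, weighted = FALSE, phi = phi, n_boot = n_boot, seed = seed + 1L),
        mr_mode(h, weighted = TRUE, phi = phi, n_boot = n_boot, seed = seed + 2L))
}
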