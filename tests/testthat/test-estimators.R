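test_that("Wald ratio arithmetic and IVW single-SNP equivalence", {
  h <- make_hset(bx = 0.1, sx = 0.01, by = 0.05, sy = 0.01)
  w <- wald_ratio(h)
  expect_equal(w$b, 0.5)
  expect_equal(w$se, 0.1)

  h0 <- make_hset(bx = 0.1, sx = 0.01, by = 0, sy = 0.01)
  expect_equal(wald_ratio(h0)$b, 0)

  expect_warning(one <- mr_ivw(h), "Wald")
  expect_equal(one$b, w$b)
  expect_equal(one$se, w$se)

  hz <- make_hset(bx = 0, sx = 0.01, by = 0.05, sy = 0.01)
  expect_error(wald_ratio(hz), "degenerate")
})

test_that("IVW on identical instruments equals their common Wald ratio", {
  h <- make_hset(bx = c(0.1, 0.1), sx = 0.01, by = c(0.05, 0.05), sy = 0.02)
  expect_equal(mr_ivw(h)$b, 0.5)
})

test_that("IVW equals a fixed-effect meta-analysis of the Wald ratios", {
  skip_if_not_installed("metafor")
  for (seed in 1:10) {
    h <- random_hset(sample(3:30, 1), theta = 0.15, seed = seed)
    got <- mr_ivw(h)
    r <- h$records
    fit <- metafor::rma(yi = r$beta_outcome / r$beta_exposure,
                        sei = r$se_outcome / abs(r$beta_exposure),
                        method = "FE")
    expect_equal(got$b, as.numeric(fit$beta), tolerance = 1e-10)
    expect_equal(got$se, as.numeric(fit$se), tolerance = 1e-10)
    expect_equal(got$pvalue, as.numeric(fit$pval), tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers the noiseless linear model exactly", {
  bx <- c(0.05, 0.1, 0.2, 0.4)
  h <- make_hset(bx = bx, sx = 0.01, by = 0.3 * bx, sy = 0.02)
  eg <- mr_egger(h)
  expect_equal(eg$slope$b, 0.3, tolerance = 1e-12)
  expect_equal(eg$intercept$b, 0, tolerance = 1e-12)
  expect_equal(mr_ivw(h)$b, 0.3, tolerance = 1e-12)

  # with a constant pleiotropic offset the intercept absorbs it
  h2 <- make_hset(bx = bx, sx = 0.01, by = 0.02 + 0.3 * bx, sy = 0.02)
  eg2 <- mr_egger(h2)
  expect_equal(eg2$slope$b, 0.3, tolerance = 1e-12)
  expect_equal(eg2$intercept$b, 0.02, tolerance = 1e-12)

  expect_error(mr_egger(make_hset(bx = c(0.1, 0.2), sx = 0.01,
                                  by = c(0.1, 0.2), sy = 0.01)),
               "at least 3")
})

test_that("MR-Egger matches a closed-form weighted regression oracle", {
  for (seed in 1:10) {
    h <- random_hset(sample(4:40, 1), theta = -0.1, seed = 100 + seed)
    r <- h$records
    flip <- sign(r$beta_exposure)
    x <- r$beta_exposure * flip
    y <- r$beta_outcome * flip
    w <- 1 / r$se_outcome^2
    # weighted normal equations, written out
    sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
    sxx <- sum(w * x^2); sxy <- sum(w * x * y)
    slope <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
    intercept <- (sy - slope * sx) / sw
    n <- length(x)
    rss <- sum(w * (y - intercept - slope * x)^2)
    sigma2 <- max(1, rss / (n - 2))
    se_slope <- sqrt(sigma2 * sw / (sw * sxx - sx^2))
    eg <- mr_egger(h)
    expect_equal(eg$slope$b, slope, tolerance = 1e-10)
    expect_equal(eg$slope$se, se_slope, tolerance = 1e-10)
    expect_equal(eg$slope$pvalue, 2 * pt(-abs(slope / se_slope), n - 2),
                 tolerance = 1e-10)
  }
})

test_that("weighted median interpolates the weighted quantile at 0.5", {
  # all ratios equal -> that ratio, with vanishing bootstrap se
  h <- make_hset(bx = c(0.1, 0.2, 0.4), sx = 1e-6,
                 by = 0.25 * c(0.1, 0.2, 0.4), sy = 1e-6)
  wm <- mr_weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(wm$b, 0.25, tolerance = 1e-9)
  expect_lt(wm$se, 1e-4)

  # equal weights, ratios {1, 2, 100}: median robust to the outlier
  h2 <- make_hset(bx = c(0.1, 0.1, 0.1), sx = 0.001,
                  by = c(0.1, 0.2, 10), sy = 0.01)
  expect_equal(mr_weighted_median(h2, n_boot = 100, seed = 1)$b, 2,
               tolerance = 1e-9)

  # randomized weighted-quantile oracle
  for (seed in 1:20) {
    h3 <- random_hset(sample(3:25, 1), theta = 0.3, seed = 200 + seed)
    r <- h3$records
    got <- mr_weighted_median(h3, n_boot = 100, seed = seed)$b
    want <- oracle_weighted_median(r$beta_outcome / r$beta_exposure,
                                   r$beta_exposure^2 / r$se_outcome^2)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("mode estimators match a dense-grid density argmax oracle", {
  # ratios {1,1,1,5}: the mode ignores the minority
  h <- make_hset(bx = rep(0.1, 4), sx = 0.001,
                 by = c(0.1, 0.1, 0.1, 0.5), sy = 0.01)
  expect_equal(mr_mode(h, n_boot = 100, seed = 1)$b, 1, tolerance = 0.05)

  # simple mode equals weighted mode when all weights are equal
  h2 <- make_hset(bx = rep(0.2, 5), sx = 0.001,
                  by = c(0.02, 0.04, 0.05, 0.06, 0.09), sy = 0.01)
  sm <- mr_mode(h2, weighted = FALSE, n_boot = 100, seed = 2)
  wm <- mr_mode(h2, weighted = TRUE, n_boot = 100, seed = 2)
  expect_equal(sm$b, wm$b, tolerance = 1e-6)

  # randomized grid-search oracle, simple and weighted
  for (seed in 1:10) {
    h3 <- random_hset(sample(5:25, 1), theta = 0.2, seed = 300 + seed)
    r <- h3$records
    ratio <- r$beta_outcome / r$beta_exposure
    w <- r$beta_exposure^2 / r$se_outcome^2
    got_s <- mr_mode(h3, weighted = FALSE, n_boot = 100, seed = seed)$b
    got_w <- mr_mode(h3, weighted = TRUE, n_boot = 100, seed = seed)$b
    expect_equal(got_s, oracle_mode(ratio, rep(1, length(ratio))),
                 tolerance = 0.005)
    expect_equal(got_w, oracle_mode(ratio, w), tolerance = 0.005)
  }

  # identical ratios: zero bandwidth degenerates to the common ratio
  h4 <- make_hset(bx = c(0.1, 0.2, 0.4), sx = 0.001,
                  by = 0.3 * c(0.1, 0.2, 0.4), sy = 0.01)
  expect_equal(mr_mode(h4, n_boot = 100, seed = 3)$b, 0.3)
})

test_that("odds-ratio transformation matches published report rows", {
  # family Lactobacillaceae IVW row: b -0.118 (0.039) -> OR 0.889, CI to 0.959
  o <- to_odds_ratio(-0.118, 0.039)
  expect_equal(o$or, 0.889, tolerance = 5e-4)
  expect_equal(o$ci_high, 0.959, tolerance = 5e-4)
  expect_equal(o$ci_low, 0.824, tolerance = 1e-3)
  # Family XIII AD3011 MR Egger row: b 0.125 -> OR 1.133
  expect_equal(to_odds_ratio(0.125, 0.208)$or, 1.133, tolerance = 5e-4)
  # null effect: OR 1, CI symmetric on the log scale
  o0 <- to_odds_ratio(0, 0.1)
  expect_equal(o0$or, 1)
  expect_equal(o0$ci_low * o0$ci_high, 1, tolerance = 1e-12)
})

test_that("all estimators are sign-equivariant and scale-equivariant", {
  h <- random_hset(20, theta = 0.25, seed = 77)
  r <- h$records
  fit <- function(hh, seed = 5) {
    eg <- mr_egger(hh)
    rbind(mr_ivw(hh)[c("b", "se")],
          eg$slope[c("b", "se")],
          mr_weighted_median(hh, n_boot = 100, seed = seed)[c("b", "se")],
          mr_mode(hh, weighted = FALSE, n_boot = 100, seed = seed)[c("b", "se")],
          mr_mode(hh, weighted = TRUE, n_boot = 100, seed = seed)[c("b", "se")])
  }
  base <- fit(h)

  neg <- h
  neg$records$beta_outcome <- -r$beta_outcome
  flipped <- fit(neg)
  expect_equal(flipped$b, -base$b, tolerance = 1e-9)
  # analytic SEs (IVW, Egger) are exactly invariant; bootstrap SEs
  # (median, modes) are invariant in distribution only
  expect_equal(flipped$se[1:2], base$se[1:2], tolerance = 1e-9)
  expect_true(all(abs(flipped$se[3:5] - base$se[3:5]) / base$se[3:5] < 0.5))

  # rescaling the exposure divides every estimate by the same factor;
  # exposure SEs scale along so the bootstrap perturbation is equivariant
  c0 <- 2.5
  sc <- h
  sc$records$beta_exposure <- c0 * r$beta_exposure
  sc$records$se_exposure <- c0 * r$se_exposure
  scaled <- fit(sc)
  expect_equal(scaled$b, base$b / c0, tolerance = 1e-9)
})

test_that("mr_all returns the five methods in report order", {
  h <- random_hset(10, seed = 9)
  est <- mr_all(h, n_boot = 100, seed = 4)
  expect_equal(est$method, c("IVW", "MR Egger", "Weighted median",
                             "Simple mode", "Weighted mode"))
  expect_true(all(est$ci_low <= est$or & est$or <= est$ci_high))
  expect_equal(est$or, exp(est$b))
  expect_equal(est$n_snp, rep(10L, 5))
})
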