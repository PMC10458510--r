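# Small in-code fixtures shared across test files.

# a well-formed summary-statistics data frame
make_sumstats <- function(snp = c("rs1", "rs2", "rs3"),
                          chr = c("1", "1", "2"),
                          pos = c(1e6, 2e6, 1e6),
                          effect_allele = c("A", "T", "C"),
                          other_allele = c("G", "C", "A"),
                          eaf = c(0.3, 0.4, 0.2),
                          beta = c(0.1, -0.05, 0.02),
                          se = c(0.01, 0.02, 0.015),
                          pval = 2 * pnorm(-abs(beta / se)),
                          n = 10000) {
  data.frame(snp = snp, chr = chr, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

# harmonized set built directly from effect vectors
make_hset <- function(bx, sx, by, sy, eaf = rep(0.3, length(bx)),
                      n_exposure = 20000, n_outcome = 50000) {
  harmonized_set(data.frame(
    snp = sprintf("rs%d", seq_along(bx)),
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy,
    eaf_exposure = eaf, stringsAsFactors = FALSE),
    n_exposure = n_exposure, n_outcome = n_outcome)
}

# random instrument set with a known causal effect, for oracle comparisons
random_hset <- function(n, theta = 0.2, seed = 1) {
  set.seed(seed)
  bx <- abs(rnorm(n, 0, 0.1)) + 0.05
  sx <- runif(n, 0.005, 0.02)
  sy <- runif(n, 0.005, 0.03)
  by <- theta * bx + rnorm(n, 0, sy)
  make_hset(bx, sx, by, sy, eaf = runif(n, 0.1, 0.9))
}

# independent weighted-quantile oracle: explicit sort + hand interpolation
oracle_weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(x[1])
  if (0.5 >= cw[length(cw)]) return(x[length(x)])
  k <- max(which(cw <= 0.5))
  x[k] + (x[k + 1] - x[k]) * (0.5 - cw[k]) / (cw[k + 1] - cw[k])
}

# independent kernel-density argmax oracle on a dense grid (no FFT)
oracle_mode <- function(x, w, phi = 1) {
  n <- length(x)
  h <- phi * 0.9 * min(sd(x), mad(x)) * n^(-1 / 5)
  w <- w / sum(w)
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = 20000)
  dens <- vapply(grid, function(g) sum(w * dnorm(g, x, h)), numeric(1))
  grid[which.max(dens)]
}

# independent greedy-clump oracle: literal restatement of the rule with an
# O(n^2) marking pass over the p-sorted order
oracle_clump <- function(records, config, ld_r2 = NULL) {
  get_r2 <- function(a, b) {
    if (is.null(ld_r2)) return(1)
    hit <- (ld_r2$snp_a == a & ld_r2$snp_b == b) |
      (ld_r2$snp_a == b & ld_r2$snp_b == a)
    if (any(hit)) ld_r2$r2[which(hit)[1]] else 0
  }
  x <- records[order(records$pval, records$snp), ]
  status <- rep("open", nrow(x))
  for (i in seq_len(nrow(x))) {
    if (status[i] != "open") next
    status[i] <- "kept"
    if (i == nrow(x)) break
    for (j in seq(i + 1, nrow(x))) {
      if (status[j] != "open") next
      if (x$chr[j] == x$chr[i] &&
          abs(x$pos[j] - x$pos[i]) <= config$window_kb * 1000 &&
          get_r2(x$snp[i], x$snp[j]) > config$r2_threshold) {
        status[j] <- "removed"
      }
    }
  }
  sort(x$snp[status == "kept"])
}

# upper-tail chi-square oracle by direct numeric integration of the density
oracle_chisq_upper <- function(q, df) {
  stats::integrate(function(x) stats::dchisq(x, df), q, Inf,
                   rel.tol = 1e-12)$value
}
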