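# Non-palindromic effect/other allele pairs, so that letter matching alone
# resolves orientation during harmonization (palindromic handling is
# exercised with purpose-built records instead).
NONPAL_PAIRS <- rbind(c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
                      c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T"))

#' Define a simulation scenario for two-sample GWAS summary statistics
#'
#' Generative parameters for one exposure/outcome pair: `n_instruments` true
#' instruments with half-normal per-allele effects on the exposure (scale
#' `gamma_sd`; the half-normal encodes the convention of orienting the
#' effect allele to increase the exposure), `n_null_snps` background SNPs
#' with no effect, a causal log-odds effect `theta`, optional horizontal
#' pleiotropy (`pleiotropy_mean` directional, `pleiotropy_sd` balanced;
#' `inside_violation` adds a term proportional to instrument strength,
#' breaking InSIDE), GWAS sample sizes, the outcome case fraction (set
#' `NA` for a continuous outcome), and the allele-frequency range.
#' `reverse = TRUE` swaps the generative roles: SNPs act on the outcome
#' first and the exposure responds with coefficient `theta`.
#'
#' @param n_instruments Number of true instruments (J >= 1).
#' @param n_null_snps Number of null background SNPs.
#' @param theta True causal effect, log-odds per unit exposure.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of per-SNP direct
#'   effects on the outcome.
#' @param inside_violation Correlate pleiotropy with instrument strength?
#' @param gamma_sd Scale of SNP-to-exposure effects.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param case_fraction Outcome case fraction in (0, 1), or `NA` for a
#'   continuous outcome.
#' @param eaf_range Effect-allele frequency range within (0, 1).
#' @param reverse Generate under reverse causation?
#' @param seed Integer seed; all draws are deterministic given it.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_instruments = 100, n_null_snps = 0,
                                theta = 0, pleiotropy_mean = 0,
                                pleiotropy_sd = 0, inside_violation = FALSE,
                                gamma_sd = 0.05,
                                n_exposure = 18340, n_outcome = 218792,
                                case_fraction = 35847 / 218792,
                                eaf_range = c(0.1, 0.9),
                                reverse = FALSE, seed = 1L) {
  stopifnot(n_instruments >= 1, n_null_snps >= 0,
            pleiotropy_sd >= 0, gamma_sd >= 0,
            n_exposure > 1, n_outcome > 1,
            length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] <= eaf_range[2],
            is.na(case_fraction) ||
              (case_fraction > 0 && case_fraction < 1))
  structure(list(n_instruments = as.integer(n_instruments),
                 n_null_snps = as.integer(n_null_snps),
                 theta = theta, pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 inside_violation = isTRUE(inside_violation),
                 gamma_sd = gamma_sd,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 case_fraction = case_fraction, eaf_range = eaf_range,
                 reverse = isTRUE(reverse), seed = as.integer(seed)),
            class = "simulation_scenario")
}

# synthetic genomic coordinates: cycle over autosomes with 20 Mb spacing so
# every SNP falls outside every other's 10,000 kb clumping window
synthetic_positions <- function(idx) {
  chr <- ((idx - 1L) %% 22L) + 1L
  slot <- (idx - 1L) %/% 22L
  list(chr = as.character(chr), pos = 1e6 + slot * 2e7)
}

simulate_block <- function(scn, n_snp, idx, gamma, seed) {
  set.seed(seed)
  eaf <- stats::runif(n_snp, scn$eaf_range[1], scn$eaf_range[2])
  het <- 2 * eaf * (1 - eaf)
  se_x <- 1 / sqrt(het * scn$n_exposure)
  vf <- if (is.na(scn$case_fraction)) 1 else
    scn$case_fraction * (1 - scn$case_fraction)
  se_y <- 1 / sqrt(het * scn$n_outcome * vf)
  alpha <- scn$pleiotropy_mean + stats::rnorm(n_snp, 0, scn$pleiotropy_sd)
  if (scn$inside_violation) alpha <- alpha + 0.3 * gamma
  if (scn$reverse) {
    true_y <- gamma
    true_x <- scn$theta * gamma + alpha
  } else {
    true_x <- gamma
    true_y <- scn$theta * gamma + alpha
  }
  beta_x <- true_x + stats::rnorm(n_snp, 0, se_x)
  beta_y <- true_y + stats::rnorm(n_snp, 0, se_y)
  pair <- NONPAL_PAIRS[sample.int(nrow(NONPAL_PAIRS), n_snp, replace = TRUE), ,
                       drop = FALSE]
  coords <- synthetic_positions(idx)
  make <- function(beta, se, n) {
    data.frame(snp = sprintf("rs%07d", idx),
               chr = coords$chr, pos = coords$pos,
               effect_allele = pair[, 1], other_allele = pair[, 2],
               eaf = eaf, beta = beta, se = se,
               pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
               n = n, stringsAsFactors = FALSE)
  }
  list(exposure = make(beta_x, se_x, scn$n_exposure),
       outcome = make(beta_y, se_y, scn$n_outcome),
       gamma = gamma, alpha = alpha)
}

#' Simulate a two-sample GWAS summary-statistics pair
#'
#' Draws per-SNP exposure and outcome associations under the scenario's
#' generative model. For instrument j: `eaf_j ~ U(eaf_range)`;
#' `gamma_j = |N(0, gamma_sd^2)|`; `se_X = 1 / sqrt(2 eaf (1-eaf) N_X)`;
#' `beta_X = gamma + N(0, se_X^2)`;
#' `alpha_j = pleiotropy_mean + N(0, pleiotropy_sd^2)` (plus
#' `0.3 * gamma_j` under `inside_violation`);
#' `se_Y = 1 / sqrt(2 eaf (1-eaf) N_Y cf (1-cf))` for a binary outcome with
#' case fraction cf (the observed-scale variance approximation on the
#' log-odds scale); `beta_Y = theta * gamma + alpha + N(0, se_Y^2)`. Null
#' SNPs use `gamma = 0`. Reverse scenarios swap the generative roles of the
#' two traits. P-values are two-sided normal. The global seed expands into
#' one substream per block, so adding null SNPs never changes the
#' instrument draws.
#'
#' @param scenario A [simulation_scenario()].
#' @return A list with validated `exposure` and `outcome` summary-statistic
#'   data frames (instruments first, then null SNPs) and `truth`, a list
#'   recording the generating parameters and per-SNP `gamma`/`alpha`.
#' @export
simulate_pair <- function(scenario) {
  if (!inherits(scenario, "simulation_scenario")) {
    stop("scenario must be built with simulation_scenario()")
  }
  scn <- scenario
  set.seed(scn$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)
  set.seed(sub[1])
  gamma <- abs(stats::rnorm(scn$n_instruments, 0, scn$gamma_sd))
  inst <- simulate_block(scn, scn$n_instruments,
                         seq_len(scn$n_instruments), gamma, sub[2])
  exposure <- inst$exposure
  outcome <- inst$outcome
  truth <- list(theta = scn$theta, reverse = scn$reverse,
                gamma = inst$gamma, alpha = inst$alpha,
                instrument_snps = exposure$snp,
                scenario = unclass(scn))
  if (scn$n_null_snps > 0L) {
    idx <- scn$n_instruments + seq_len(scn$n_null_snps)
    nul <- simulate_block(scn, scn$n_null_snps, idx,
                          rep(0, scn$n_null_snps), sub[3])
    exposure <- rbind(exposure, nul$exposure)
    outcome <- rbind(outcome, nul$outcome)
  }
  list(exposure = validate_sumstats(exposure),
       outcome = validate_sumstats(outcome),
       truth = truth)
}

#' Named scenario presets
#'
#' Ready-made scenarios at the cohort scale of a microbiome-exposure MR
#' study (exposure GWAS n = 18,340; binary outcome GWAS n = 218,792 with
#' case fraction 0.164): `null` (theta 0), `causal` (theta 0.1),
#' `directional_pleiotropy` (theta 0.1, mean pleiotropy 0.02, J = 200),
#' `heterogeneous` (balanced pleiotropy sd 0.02), `reverse` (outcome-first
#' generation, theta 0.2) and `weak_instruments` (gamma_sd 0.01).
#'
#' @param seed Integer master seed; each preset receives its own substream
#'   so adding a preset never shifts another's draws.
#' @return A named list of [simulation_scenario()] objects.
#' @export
scenario_presets <- function(seed = 1L) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 6L)
  list(
    null = simulation_scenario(theta = 0, seed = s[1]),
    causal = simulation_scenario(theta = 0.1, seed = s[2]),
    directional_pleiotropy = simulation_scenario(
      theta = 0.1, n_instruments = 200,
      pleiotropy_mean = 0.02, pleiotropy_sd = 0.005, seed = s[3]),
    heterogeneous = simulation_scenario(
      theta = 0.1, pleiotropy_sd = 0.02, seed = s[4]),
    reverse = simulation_scenario(theta = 0.2, reverse = TRUE, seed = s[5]),
    weak_instruments = simulation_scenario(
      theta = 0.1, gamma_sd = 0.01, seed = s[6])
  )
}

#' Write a simulated pair to disk
#'
#' Writes `<prefix>_exposure.tsv` and `<prefix>_outcome.tsv` in the
#' canonical format plus `<prefix>_truth.json` with the generating
#' parameters.
#'
#' @param sim Result of [simulate_pair()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; default "sim".
#' @return Invisibly, the three paths.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_exposure.tsv", "_outcome.tsv",
                                           "_truth.json")))
  write_summary_stats(sim$exposure, paths[1])
  write_summary_stats(sim$outcome, paths[2])
  jsonlite::write_json(sim$truth, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
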