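#' Read a study configuration file
#'
#' YAML configuration describing a full study: `seed`; `exposures` (list of
#' `label`, `category`, `path`, optional `column_map`); `outcomes` (list of
#' `label`, `path`, optional `n`, `case_fraction`, `column_map`); optional
#' `clump` block (`p_threshold`, `maf_min`, `r2_threshold`, `window_kb`);
#' optional `f_min` (default 10), `palindromic_eaf_limit` (default 0.42),
#' `correction` (category -> divisor map), `estimators` block (`n_boot`,
#' `phi`), `confounder_file`, `ld_file`.
#'
#' @param path Path to a YAML file.
#' @return A validated config list for [run_study()].
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_study_config(cfg)
}

validate_study_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("study config must set a seed")
  if (length(cfg$exposures) == 0L) stop("study config lists no exposures")
  if (length(cfg$outcomes) == 0L) stop("study config lists no outcomes")
  labels <- vapply(cfg$exposures, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("exposure labels must be unique")
  for (ex in cfg$exposures) {
    if (is.null(ex$path) || !file.exists(ex$path)) {
      stop("exposure file not readable: ", ex$path)
    }
  }
  for (ou in cfg$outcomes) {
    if (is.null(ou$path) || !file.exists(ou$path)) {
      stop("outcome file not readable: ", ou$path)
    }
  }
  cfg$clump <- do.call(clump_config, as.list(cfg$clump))
  if (is.null(cfg$f_min)) cfg$f_min <- 10
  if (is.null(cfg$palindromic_eaf_limit)) cfg$palindromic_eaf_limit <- 0.42
  if (is.null(cfg$estimators)) cfg$estimators <- list()
  if (is.null(cfg$estimators$n_boot)) cfg$estimators$n_boot <- 1000
  if (is.null(cfg$estimators$phi)) cfg$estimators$phi <- 1
  if (is.null(cfg$correction)) {
    cfg$correction <- correction_schemes()
  } else if (!is.data.frame(cfg$correction)) {
    cfg$correction <- correction_schemes(unlist(cfg$correction))
  }
  cfg
}

empty_row <- function(exposure, category, outcome, status) {
  data.frame(exposure = exposure, category = category, outcome = outcome,
             n_snp = 0L, method = NA_character_, b = NA_real_, se = NA_real_,
             pvalue = NA_real_, or = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, q = NA_real_, q_df = NA_integer_,
             q_pvalue = NA_real_, egger_intercept = NA_real_,
             egger_intercept_se = NA_real_, egger_intercept_pvalue = NA_real_,
             steiger_direction = NA, steiger_pvalue = NA_real_,
             f_statistic = NA_real_, initial_positive = NA,
             bonferroni_threshold = NA_real_, passes_correction = NA,
             status = status, stringsAsFactors = FALSE)
}

# instrument selection for one exposure: thresholds, clumping, confounder
# exclusion, then per-SNP F screening (each SNP's own R2 with i = 1)
select_instruments <- function(records, cfg, confounders = NULL,
                               ld_r2 = NULL) {
  steps <- list(input = nrow(records))
  sel <- threshold_filter(records, cfg$clump)
  steps$after_threshold <- nrow(sel)
  sel <- ld_clump(sel, cfg$clump, ld_r2 = ld_r2)
  steps$after_clump <- nrow(sel)
  if (!is.null(confounders)) {
    sel <- filter_confounders(sel, confounders)
    steps$after_confounders <- nrow(sel)
  }
  if (nrow(sel) > 0L && cfg$f_min > 0) {
    r2 <- compute_r2(sel, i = nrow(sel))
    f_per_snp <- vapply(r2, compute_f, numeric(1),
                        n = stats::median(sel$n), i = 1L)
    sel <- sel[f_per_snp >= cfg$f_min, , drop = FALSE]
    steps$after_f_filter <- nrow(sel)
  }
  attr(sel, "steps") <- steps
  sel
}

#' Run a full two-sample MR study
#'
#' For every exposure x outcome pair: select instruments (significance and
#' MAF thresholds, LD clumping, optional confounder exclusion, F-statistic
#' screening), harmonize, estimate with all applicable methods, run the
#' sensitivity analyses and the Steiger directionality test, and apply the
#' Bonferroni correction of the exposure's category to the IVW p-value.
#' Exposures yielding zero surviving instruments, or failing at any stage,
#' produce a status row rather than disappearing; the study always covers
#' every configured pair.
#'
#' @param config A config list from [read_study_config()] or built in code
#'   (validated either way).
#' @return A data frame with one row per (exposure, outcome, method), plus
#'   attributes `"log"` (per-pair selection step counts) and `"failures"`
#'   (pairs whose status is not "ok").
#' @export
run_study <- function(config) {
  cfg <- validate_study_config(config)
  confounders <- if (!is.null(cfg$confounder_file)) {
    utils::read.table(cfg$confounder_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = "character")
  } else NULL
  ld_r2 <- if (!is.null(cfg$ld_file)) {
    utils::read.table(cfg$ld_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL

  rows <- list()
  log <- list()
  pair_id <- 0L
  for (ou in cfg$outcomes) {
    outcome_stats <- read_summary_stats(ou$path, column_map = ou$column_map)
    for (ex in cfg$exposures) {
      pair_id <- pair_id + 1L
      label <- paste(ex$label, ou$label, sep = " -> ")
      category <- if (is.null(ex$category)) "order" else ex$category
      row <- tryCatch({
        exposure_stats <- read_summary_stats(ex$path,
                                             column_map = ex$column_map)
        sel <- select_instruments(exposure_stats, cfg,
                                  confounders = confounders, ld_r2 = ld_r2)
        log[[label]] <- attr(sel, "steps")
        if (nrow(sel) == 0L) {
          empty_row(ex$label, category, ou$label, "no_instruments")
        } else {
          h <- harmonize(sel, outcome_stats,
                         palindromic_eaf_limit = cfg$palindromic_eaf_limit,
                         exposure_label = ex$label, outcome_label = ou$label)
          if (!is.null(ou$n)) h$n_outcome <- ou$n
          est <- mr_all(h, n_boot = cfg$estimators$n_boot,
                        phi = cfg$estimators$phi,
                        seed = cfg$seed + 7L * pair_id)
          nsnp <- nrow(h$records)
          ivw_row <- est[est$method %in% c("IVW", "Wald ratio"), ][1, ]
          outcome_type <- if (is.null(ou$case_fraction) ||
                              is.na(ou$case_fraction))
            "continuous" else "binary"
          q <- rep(NA_real_, nrow(est))
          q_df <- rep(NA_integer_, nrow(est))
          q_p <- rep(NA_real_, nrow(est))
          ic <- list(intercept = NA_real_, se = NA_real_, pvalue = NA_real_)
          if (nsnp >= 3L) {
            sr <- sensitivity_report(h, ivw_b = ivw_row$b,
                                     outcome_type = outcome_type)
            q[est$method == "IVW"] <- sr$q_ivw$q
            q_df[est$method == "IVW"] <- sr$q_ivw$df
            q_p[est$method == "IVW"] <- sr$q_ivw$pvalue
            q[est$method == "MR Egger"] <- sr$q_egger$q
            q_df[est$method == "MR Egger"] <- sr$q_egger$df
            q_p[est$method == "MR Egger"] <- sr$q_egger$pvalue
            ic <- sr$egger_intercept
            st <- sr$steiger
          } else {
            if (nsnp == 2L) {
              qi <- cochran_q(h, ivw_row$b, df_loss = 1L)
              q[est$method == "IVW"] <- qi$q
              q_df[est$method == "IVW"] <- qi$df
              q_p[est$method == "IVW"] <- qi$pvalue
            }
            st <- steiger_test(h, outcome_type = outcome_type)
          }
          r2_tot <- min(sum(compute_r2(data.frame(
            eaf = h$records$eaf_exposure, beta = h$records$beta_exposure,
            se = h$records$se_exposure, n = h$n_exposure), i = nsnp)),
            1 - 1e-12)
          fstat <- compute_f(r2_tot, h$n_exposure, nsnp)
          bf <- bonferroni(stats::setNames(ivw_row$pvalue, ex$label),
                           category, cfg$correction)
          data.frame(exposure = ex$label, category = category,
                     outcome = ou$label, n_snp = est$n_snp,
                     method = est$method, b = est$b, se = est$se,
                     pvalue = est$pvalue, or = est$or, ci_low = est$ci_low,
                     ci_high = est$ci_high, q = q, q_df = q_df,
                     q_pvalue = q_p,
                     egger_intercept = ic$intercept,
                     egger_intercept_se = ic$se,
                     egger_intercept_pvalue = ic$pvalue,
                     steiger_direction = st$direction,
                     steiger_pvalue = st$pvalue,
                     f_statistic = fstat,
                     initial_positive = ivw_row$pvalue < 0.05,
                     bonferroni_threshold = bf$threshold,
                     passes_correction = bf$passes,
                     status = "ok", stringsAsFactors = FALSE)
        }
      }, error = function(e) {
        empty_row(ex$label, category, ou$label,
                  paste0("error: ", conditionMessage(e)))
      })
      rows[[label]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  failures <- unique(out[out$status != "ok", c("exposure", "outcome", "status")])
  rownames(failures) <- NULL
  attr(out, "log") <- log
  attr(out, "failures") <- failures
  out
}

#' Write study results as a tidy TSV and a readable report
#'
#' Writes `path` as a full-precision tab-separated table (one row per
#' exposure, outcome and method) and, alongside it, `<path>.txt`: a
#' human-readable rendering grouped in exposure blocks with the five method
#' rows and the Q / Egger-intercept / direction columns, rounded to three
#' decimals for display. Rounding never touches the TSV.
#'
#' @param rows Result of [run_study()].
#' @param path Output TSV path.
#' @return Invisibly, the two paths.
#' @export
write_report <- function(rows, path) {
  if (nrow(rows) == 0L) stop("no rows to report")
  out <- rows
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           sprintf("%.17g", out[[col]]))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)

  txt <- file.path(paste0(path, ".txt"))
  con <- file(txt, "w")
  on.exit(close(con))
  fmt <- function(x, digits = 3) {
    ifelse(is.na(x), "", formatC(x, digits = digits, format = "f"))
  }
  blocks <- unique(rows[c("exposure", "outcome")])
  for (i in seq_len(nrow(blocks))) {
    blk <- rows[rows$exposure == blocks$exposure[i] &
                  rows$outcome == blocks$outcome[i], ]
    first <- blk[1, ]
    writeLines(sprintf("%s -> %s  [%s]", first$exposure, first$outcome,
                       first$category), con)
    if (first$status != "ok") {
      writeLines(paste0("  status: ", first$status), con)
      next
    }
    writeLines(sprintf(
      "  nSNP %d | F %s | Egger intercept %s (p %s) | direction %s | Bonferroni p<%s%s",
      first$n_snp, fmt(first$f_statistic, 1), fmt(first$egger_intercept, 4),
      fmt(first$egger_intercept_pvalue), first$steiger_direction,
      fmt(first$bonferroni_threshold, 4),
      if (isTRUE(first$passes_correction)) " PASS" else ""), con)
    for (j in seq_len(nrow(blk))) {
      r <- blk[j, ]
      writeLines(sprintf(
        "    %-16s b %8s  SE %7s  p %6s  OR %6s (%s-%s)%s",
        r$method, fmt(r$b), fmt(r$se), fmt(r$pvalue), fmt(r$or),
        fmt(r$ci_low), fmt(r$ci_high),
        if (!is.na(r$q)) sprintf("  Q %s (df %d, p %s)", fmt(r$q), r$q_df,
                                 fmt(r$q_pvalue)) else ""), con)
    }
  }
  invisible(c(path, txt))
}

#' Reload a study report TSV
#'
#' Reads a TSV written by [write_report()] back into the exact row layout of
#' [run_study()] output (full precision, so reloads are bit-equal).
#'
#' @param path Path to the TSV.
#' @return The study rows data frame.
#' @export
read_report <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "\"")
  x$n_snp <- as.integer(x$n_snp)
  if ("q_df" %in% names(x)) x$q_df <- as.integer(x$q_df)
  x
}
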