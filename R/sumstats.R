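#' @keywords internal
"_PACKAGE"

# Canonical column order for summary-statistic tables.
SUMSTAT_COLS <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")

VALID_ALLELES <- c("A", "C", "G", "T")

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Validate a table of GWAS summary statistics
#'
#' Checks one SNP-association record per row against the invariants every
#' downstream step assumes: single-nucleotide alleles with
#' `effect_allele != other_allele`, `se > 0`, `eaf` in \[0, 1\] (may be `NA`,
#' e.g. in outcome exports that omit frequencies), `pval` in (0, 1\],
#' `n > 0` and `pos >= 1`.
#'
#' @param x A data frame with the canonical columns (see
#'   [read_summary_stats()] for the list).
#' @return A data frame of the valid rows with canonical columns and types.
#'   Invalid rows are dropped; attribute `"rejected"` holds a data frame with
#'   columns `line` (1-based data row) and `reason`.
#' @export
validate_sumstats <- function(x) {
  missing <- setdiff(SUMSTAT_COLS, names(x))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  x <- x[SUMSTAT_COLS]
  num_cols <- c("pos", "eaf", "beta", "se", "pval", "n")
  for (col in num_cols) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  x$snp <- as.character(x$snp)
  x$chr <- as.character(x$chr)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))

  reasons <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(bad & is.na(reasons), why, reasons)
  }
  reasons <- flag(!(x$effect_allele %in% VALID_ALLELES) |
                    !(x$other_allele %in% VALID_ALLELES), "invalid allele")
  reasons <- flag(x$effect_allele == x$other_allele, "identical alleles")
  reasons <- flag(is.na(x$beta), "unparsable beta")
  reasons <- flag(!(x$se > 0), "se not > 0")
  reasons <- flag(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf outside [0,1]")
  # eaf may be NA; all other numerics are mandatory
  reasons[is.na(reasons) & is.na(x$pval)] <- "unparsable pval"
  reasons <- flag(!(x$pval > 0 & x$pval <= 1), "pval outside (0,1]")
  reasons <- flag(!(x$n > 0), "n not > 0")
  reasons <- flag(!(x$pos >= 1), "pos < 1")

  bad <- !is.na(reasons)
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(line = which(bad),
                                      reason = reasons[bad],
                                      stringsAsFactors = FALSE)
  out
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-separated table with a header row, optionally
#' renaming foreign headers (e.g. MiBioGen- or OpenGWAS-style exports) to the
#' canonical fields, and validates every row.
#'
#' Canonical fields: `snp`, `chr`, `pos` (1-based), `effect_allele`,
#' `other_allele`, `eaf`, `beta` (log-odds for binary traits), `se`, `pval`,
#' `n`.
#'
#' @param path Path to the file.
#' @param column_map Optional named character vector mapping canonical field
#'   name -> column name in the file, for files with foreign headers.
#' @return A validated data frame (see [validate_sumstats()]); rows failing
#'   validation are skipped, collected in attribute `"rejected"`, and counted
#'   in a message.
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, colClasses = "character",
                         check.names = FALSE, comment.char = "", quote = "\"")
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(x))
    if (length(miss) > 0L) {
      stop("column_map refers to absent column(s): ",
           paste(miss, collapse = ", "))
    }
    for (std in names(column_map)) {
      names(x)[names(x) == column_map[[std]]] <- std
    }
  }
  out <- validate_sumstats(x)
  nrej <- nrow(attr(out, "rejected"))
  if (nrej > 0L) {
    message(nrej, " row(s) skipped in ", path, " (see attr 'rejected')")
  }
  out
}

#' Write GWAS summary statistics to a canonical TSV
#'
#' Writes a tab-separated file with the canonical header
#' `snp chr pos effect_allele other_allele eaf beta se pval n`; floating
#' values are written at full double precision so that read/write round-trips
#' are exact.
#'
#' @param records A validated summary-statistics data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(records, path) {
  out <- records[SUMSTAT_COLS]
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  unname(ALLELE_COMPLEMENT[a1] == a2)
}

# Keep the smallest-p record per SNP id; returns indices kept plus a log of
# the duplicates removed.
dedup_smallest_p <- function(x) {
  ord <- order(x$pval, x$snp)
  keep <- ord[!duplicated(x$snp[ord])]
  keep <- sort(keep)
  dropped <- setdiff(seq_len(nrow(x)), keep)
  list(records = x[keep, , drop = FALSE],
       dropped = x$snp[dropped])
}

#' Construct a harmonized instrument set
#'
#' Container pairing exposure and outcome per-SNP effects expressed on the
#' exposure's effect allele, as produced by [harmonize()]. Exposed so that
#' instrument sets can also be built directly (e.g. from simulations).
#'
#' @param records Data frame with columns `snp`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`; optionally `eaf_exposure`,
#'   `chr`, `pos`, `pval_exposure`, `pval_outcome`.
#' @param exposure_label,outcome_label Trait labels.
#' @param n_exposure,n_outcome Sample sizes of the two GWAS.
#' @return An object of class `harmonized_set`.
#' @export
harmonized_set <- function(records, exposure_label = "exposure",
                           outcome_label = "outcome",
                           n_exposure = NA_real_, n_outcome = NA_real_) {
  needed <- c("snp", "beta_exposure", "se_exposure",
              "beta_outcome", "se_outcome")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L) {
    stop("harmonized records lack column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(records) < 1L) stop("a harmonized set needs at least one SNP")
  if (anyDuplicated(records$snp)) stop("duplicate SNP ids in harmonized set")
  if (any(records$se_exposure <= 0) || any(records$se_outcome <= 0)) {
    stop("standard errors must be positive")
  }
  for (opt in c("eaf_exposure", "chr", "pos", "pval_exposure", "pval_outcome")) {
    if (!opt %in% names(records)) records[[opt]] <- NA
  }
  rownames(records) <- NULL
  structure(list(records = records,
                 exposure_label = exposure_label,
                 outcome_label = outcome_label,
                 n_exposure = n_exposure,
                 n_outcome = n_outcome),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized instrument set:", x$exposure_label, "->", x$outcome_label,
      "\n  ", nrow(x$records), "SNP(s); n_exposure =", x$n_exposure,
      "; n_outcome =", x$n_outcome, "\n")
  invisible(x)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Pairs the two tables on SNP id and expresses every outcome effect relative
#' to the exposure's effect allele. Outcome records whose alleles are swapped
#' have their beta negated and eaf replaced by 1 - eaf; records on the
#' opposite strand are complemented before matching. Palindromic SNPs (A/T or
#' G/C) cannot be strand-resolved from the letters, so strand is inferred
#' from allele frequency: they are kept (as aligned) only when both traits'
#' EAFs lie on the same side of 0.5 and both minor-allele frequencies are
#' below `palindromic_eaf_limit`; palindromic SNPs with a missing outcome EAF
#' are always dropped. Duplicate SNP ids within one trait keep the
#' smallest-p record. Every drop is recorded with a reason code in attribute
#' `"log"` of the returned set.
#'
#' @param exposure,outcome Validated summary-statistics data frames.
#' @param palindromic_eaf_limit Frequency ambiguity limit in (0, 0.5);
#'   default 0.42.
#' @param exposure_label,outcome_label Trait labels carried into the result.
#' @return A [harmonized_set()] whose sample sizes are the per-trait median
#'   `n` of the retained SNPs.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_limit = 0.42,
                      exposure_label = "exposure", outcome_label = "outcome") {
  if (!(palindromic_eaf_limit > 0 && palindromic_eaf_limit < 0.5)) {
    stop("palindromic_eaf_limit must lie in (0, 0.5)")
  }
  log <- data.frame(snp = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  note <- function(snp, reason) {
    rbind(log, data.frame(snp = snp, reason = rep(reason, length(snp)),
                          stringsAsFactors = FALSE))
  }
  de <- dedup_smallest_p(exposure)
  do <- dedup_smallest_p(outcome)
  if (length(de$dropped)) log <- note(de$dropped, "duplicate_in_exposure")
  if (length(do$dropped)) log <- note(do$dropped, "duplicate_in_outcome")
  exposure <- de$records
  outcome <- do$records

  only_e <- setdiff(exposure$snp, outcome$snp)
  if (length(only_e)) log <- note(only_e, "absent_in_outcome")
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0L) stop("no instruments after harmonization")

  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]

  n <- length(shared)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  beta_o <- ou$beta
  eaf_o <- ou$eaf

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  # non-palindromic: direct, swapped, complemented, complemented-swapped
  oe <- ou$effect_allele
  oo <- ou$other_allele
  ce <- unname(ALLELE_COMPLEMENT[oe])
  co <- unname(ALLELE_COMPLEMENT[oo])
  aligned <- (oe == ex$effect_allele & oo == ex$other_allele) |
    (ce == ex$effect_allele & co == ex$other_allele)
  swapped <- (oe == ex$other_allele & oo == ex$effect_allele) |
    (ce == ex$other_allele & co == ex$effect_allele)
  for (j in which(!pal)) {
    if (aligned[j]) {
      # nothing to do
    } else if (swapped[j]) {
      beta_o[j] <- -beta_o[j]
      if (!is.na(eaf_o[j])) eaf_o[j] <- 1 - eaf_o[j]
    } else {
      keep[j] <- FALSE
      reason[j] <- "allele_mismatch"
    }
  }
  for (j in which(pal)) {
    # outcome alleles must still be the same palindromic pair in some order
    same_pair <- aligned[j] || swapped[j]
    if (!same_pair) {
      keep[j] <- FALSE
      reason[j] <- "allele_mismatch"
    } else if (is.na(eaf_o[j])) {
      keep[j] <- FALSE
      reason[j] <- "palindromic_missing_eaf"
    } else {
      same_side <- (ex$eaf[j] - 0.5) * (ou$eaf[j] - 0.5) > 0
      informative <- min(ex$eaf[j], 1 - ex$eaf[j]) < palindromic_eaf_limit &&
        min(ou$eaf[j], 1 - ou$eaf[j]) < palindromic_eaf_limit
      if (!(same_side && informative)) {
        keep[j] <- FALSE
        reason[j] <- "palindromic_ambiguous"
      }
      # kept palindromic SNPs are taken as already aligned: eaf decides strand
      beta_o[j] <- ou$beta[j]
      eaf_o[j] <- ou$eaf[j]
    }
  }
  if (any(!keep)) log <- note(ex$snp[!keep], reason[!keep])
  if (!any(keep)) stop("no instruments after harmonization")

  rec <- data.frame(snp = ex$snp[keep],
                    chr = ex$chr[keep],
                    pos = ex$pos[keep],
                    eaf_exposure = ex$eaf[keep],
                    beta_exposure = ex$beta[keep],
                    se_exposure = ex$se[keep],
                    pval_exposure = ex$pval[keep],
                    eaf_outcome = eaf_o[keep],
                    beta_outcome = beta_o[keep],
                    se_outcome = ou$se[keep],
                    pval_outcome = ou$pval[keep],
                    stringsAsFactors = FALSE)
  out <- harmonized_set(rec, exposure_label = exposure_label,
                        outcome_label = outcome_label,
                        n_exposure = stats::median(ex$n[keep]),
                        n_outcome = stats::median(ou$n[keep]))
  attr(out, "log") <- log
  out
}
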