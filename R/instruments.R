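#' Instrument selection configuration
#'
#' Bundles the selection thresholds applied to exposure summary statistics:
#' genome-wide suggestive significance `p_threshold` (default 1e-5, strict
#' less-than), minimum minor-allele frequency `maf_min` (default 0.01),
#' LD-clumping `r2_threshold` (default 0.001) and clumping window `window_kb`
#' (default 10,000 kb).
#'
#' @param p_threshold Significance cutoff for instrument inclusion.
#' @param maf_min Minimum minor-allele frequency.
#' @param r2_threshold Pairwise r-squared above which a SNP is clumped away.
#' @param window_kb Clumping window in kilobases.
#' @return An object of class `clump_config`.
#' @export
clump_config <- function(p_threshold = 1e-5, maf_min = 0.01,
                         r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            maf_min >= 0, maf_min <= 0.5,
            r2_threshold > 0, r2_threshold < 1,
            window_kb > 0)
  structure(list(p_threshold = p_threshold, maf_min = maf_min,
                 r2_threshold = r2_threshold, window_kb = window_kb),
            class = "clump_config")
}

#' Significance and MAF threshold filter
#'
#' Retains records with `pval < p_threshold` (strict) and
#' `min(eaf, 1 - eaf) >= maf_min`; records with missing EAF fail the MAF
#' condition. Input order is preserved.
#'
#' @param records Validated summary-statistics data frame.
#' @param config A [clump_config()].
#' @return The filtered data frame (possibly empty).
#' @export
threshold_filter <- function(records, config = clump_config()) {
  maf <- pmin(records$eaf, 1 - records$eaf)
  ok <- records$pval < config$p_threshold & !is.na(maf) & maf >= config$maf_min
  out <- records[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Look up pairwise r2 from a long-format table (snp_a, snp_b, r2); absent
# pairs count as r2 = 0 (unlinked). Asymmetric duplicates are an error.
ld_lookup <- function(ld_r2) {
  key <- paste(ld_r2$snp_a, ld_r2$snp_b, sep = "\r")
  rkey <- paste(ld_r2$snp_b, ld_r2$snp_a, sep = "\r")
  both <- match(rkey, key)
  hit <- !is.na(both)
  if (any(abs(ld_r2$r2[hit] - ld_r2$r2[both[hit]]) > 1e-12)) {
    stop("ld_r2 table is asymmetric")
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(ld_r2))) {
    assign(key[i], ld_r2$r2[i], envir = env)
    assign(rkey[i], ld_r2$r2[i], envir = env)
  }
  function(a, b) {
    v <- mget(paste(a, b, sep = "\r"), envir = env, ifnotfound = 0)
    unlist(v, use.names = FALSE)
  }
}

#' Greedy LD clumping
#'
#' Sorts records by ascending p-value, repeatedly accepts the best remaining
#' SNP, and removes every remaining SNP on the same chromosome within
#' `window_kb` kilobases whose pairwise r-squared with the accepted SNP
#' exceeds `r2_threshold`. When no `ld_r2` table is supplied, distance-only
#' mode removes all same-chromosome SNPs within the window (a stricter
#' approximation, appropriate when no reference-panel LD is available).
#'
#' @param records Validated summary statistics with `chr` and `pos`.
#' @param config A [clump_config()].
#' @param ld_r2 Optional data frame `snp_a, snp_b, r2` of pairwise LD; must
#'   be symmetric where both orientations appear.
#' @return The accepted records in genomic order (chromosome, then position).
#' @export
ld_clump <- function(records, config = clump_config(), ld_r2 = NULL) {
  if (nrow(records) == 0L) return(records)
  lookup <- if (!is.null(ld_r2) && nrow(ld_r2) > 0L) ld_lookup(ld_r2) else NULL
  window_bp <- config$window_kb * 1000
  ord <- order(records$pval, records$snp)
  x <- records[ord, , drop = FALSE]
  remaining <- seq_len(nrow(x))
  accepted <- integer(0)
  while (length(remaining) > 0L) {
    best <- remaining[1L]
    accepted <- c(accepted, best)
    remaining <- remaining[-1L]
    if (length(remaining) == 0L) break
    near <- x$chr[remaining] == x$chr[best] &
      abs(x$pos[remaining] - x$pos[best]) <= window_bp
    if (!is.null(lookup)) {
      linked <- rep(FALSE, length(remaining))
      linked[near] <- lookup(x$snp[best],
                             x$snp[remaining[near]]) > config$r2_threshold
    } else {
      linked <- near
    }
    remaining <- remaining[!linked]
  }
  out <- x[accepted, , drop = FALSE]
  chr_num <- suppressWarnings(as.numeric(out$chr))
  ord2 <- if (anyNA(chr_num)) order(out$chr, out$pos) else order(chr_num, out$pos)
  out <- out[ord2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP variance explained in the exposure
#'
#' R-squared of one instrument, with the branch depending on the number of
#' valid instruments `i` for the trait: for `i < 10`,
#' `R2 = 2 * EAF * (1 - EAF) * beta^2` (assumes a variance-standardized
#' trait); for `i >= 10`,
#' `R2 = 2ef(1-ef)b^2 / (2ef(1-ef)b^2 + 2ef(1-ef) N se^2)`, which reduces
#' algebraically to `b^2 / (b^2 + N se^2)` and is bounded in \[0, 1).
#'
#' @param record Summary-statistics row(s) with `eaf`, `beta`, `se`, `n`.
#' @param i Number of instruments for the trait (selects the formula branch).
#' @return Numeric vector of per-SNP R-squared values.
#' @export
compute_r2 <- function(record, i) {
  eaf <- record$eaf
  if (any(is.na(eaf)) || any(eaf <= 0 | eaf >= 1)) {
    stop("compute_r2 requires eaf strictly inside (0, 1)")
  }
  het <- 2 * eaf * (1 - eaf)
  if (i < 10) {
    het * record$beta^2
  } else {
    num <- het * record$beta^2
    num / (num + het * record$n * record$se^2)
  }
}

#' Multi-instrument F statistic
#'
#' Instrument-strength F for `i` instruments jointly explaining `r2_total`
#' of the exposure variance in a GWAS of `n` individuals:
#' `F = [R2 / (1 - R2)] * [(N - 1 - i) / i]`. Instruments with `F < 10` are
#' conventionally flagged as weak and excluded (strict less-than; `F = 10`
#' is retained).
#'
#' @param r2_total Total variance explained, in \[0, 1).
#' @param n Exposure GWAS sample size; must exceed `i + 1`.
#' @param i Number of instruments.
#' @return The F statistic (nonnegative scalar or vector).
#' @export
compute_f <- function(r2_total, n, i) {
  if (any(r2_total < 0 | r2_total >= 1)) stop("r2_total must lie in [0, 1)")
  if (any(n <= i + 1)) stop("compute_f requires n > i + 1")
  (r2_total / (1 - r2_total)) * ((n - 1 - i) / i)
}

#' Remove instruments annotated to known confounders
#'
#' Drops records whose SNP id appears in a local exclusion table (e.g. one
#' assembled from a PhenoScanner export) mapping SNPs to confounder traits
#' such as HDL cholesterol, smoking, body mass index or body fat percentage.
#'
#' @param records Validated summary-statistics data frame.
#' @param exclusion_table Data frame with columns `snp` and `trait`, or a
#'   path to a TSV with that header. Rows with an empty trait are ignored.
#' @return The filtered records; attribute `"removed"` logs each removed SNP
#'   with the trait(s) that triggered removal.
#' @export
filter_confounders <- function(records, exclusion_table) {
  if (is.character(exclusion_table)) {
    exclusion_table <- utils::read.table(exclusion_table, header = TRUE,
                                         sep = "\t", stringsAsFactors = FALSE,
                                         colClasses = "character")
  }
  if (is.null(exclusion_table) || nrow(exclusion_table) == 0L) {
    attr(records, "removed") <- data.frame(snp = character(0),
                                           trait = character(0),
                                           stringsAsFactors = FALSE)
    return(records)
  }
  tab <- exclusion_table[!is.na(exclusion_table$trait) &
                           nzchar(exclusion_table$trait), , drop = FALSE]
  hit <- records$snp %in% tab$snp
  removed <- tab[tab$snp %in% records$snp, c("snp", "trait"), drop = FALSE]
  rownames(removed) <- NULL
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}
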