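# Population-genetic annotation: allele-frequency differentiation and Fst.

#' Two-population Fst from allele frequencies
#'
#' Default is Hudson's estimator,
#' `((p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)) /
#'  (p1 (1 - p2) + p2 (1 - p1))`,
#' which is well behaved for two populations with small, equal sample
#' sizes. The Weir-Cockerham theta (with Hardy-Weinberg heterozygosity) is
#' available via `estimator = "wc"` for sensitivity analysis. The raw
#' estimate is reported alongside a value truncated into \[0, 1\] (sampling
#' noise can drive raw estimates slightly negative). When both populations
#' are fixed for the same allele the denominator vanishes and Fst is
#' defined as 0 (with a message).
#'
#' @param p1,p2 Allele frequencies in the two populations (same allele).
#' @param n1,n2 Number of diploid individuals sampled per population
#'   (>= 2); haploid sample sizes are `2 n`.
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return A list of class `fst_result`: `fst` (truncated), `fst_raw`,
#'   `estimator`.
#' @export
fst_two_pop <- function(p1, p2, n1, n2 = n1,
                        estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 >= 2, n2 >= 2)
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    # Weir-Cockerham (1984) theta for r = 2 populations, HWE heterozygosity
    nh1 <- 2 * n1; nh2 <- 2 * n2
    nbar <- (nh1 + nh2) / 2
    nc <- (nh1 + nh2 - (nh1^2 + nh2^2) / (nh1 + nh2))
    pbar <- (nh1 * p1 + nh2 * p2) / (nh1 + nh2)
    s2 <- (nh1 * (p1 - pbar)^2 + nh2 * (p2 - pbar)^2) / nbar
    hbar <- (nh1 * 2 * p1 * (1 - p1) + nh2 * 2 * p2 * (1 - p2)) / (nh1 + nh2)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- a
    den <- a + b + cc
  }
  if (isTRUE(all.equal(den, 0)) || den == 0) {
    message("both populations fixed for the same allele; Fst defined as 0")
    raw <- 0
  } else {
    raw <- num / den
  }
  structure(list(fst = min(1, max(0, raw)), fst_raw = raw,
                 estimator = estimator),
            class = "fst_result")
}

#' Absolute allele-frequency difference between two populations
#'
#' Computed on the shared alternate-allele frequency scale (not folded
#' minor-allele frequency, which is ambiguous near 0.5).
#'
#' @param p1,p2 Alternate-allele frequencies in \[0, 1\] (vectorised).
#' @return `|p1 - p2|` in \[0, 1\].
#' @export
maf_diff <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  abs(p1 - p2)
}

#' Fst and MAF_diff over a table of SNPs
#'
#' @param freqs Data.frame with columns `snp_id`, `p1`, `p2` (alternate
#'   allele frequencies) and optional `n1`, `n2` (diploid sample sizes,
#'   default 18 each).
#' @param estimator Passed to [fst_two_pop()].
#' @return A list with `per_snp` (data.frame of `snp_id`, `maf_diff`,
#'   `fst_raw`, `fst`), `mean_fst` and `sd_fst` (over truncated values).
#' @export
fst_summary <- function(freqs, estimator = "hudson") {
  stopifnot(all(c("snp_id", "p1", "p2") %in% names(freqs)))
  n1 <- freqs$n1 %||% rep(18L, nrow(freqs))
  n2 <- freqs$n2 %||% rep(18L, nrow(freqs))
  res <- Map(function(p1, p2, n1, n2)
    suppressMessages(fst_two_pop(p1, p2, n1, n2, estimator)),
    freqs$p1, freqs$p2, n1, n2)
  per_snp <- data.frame(
    snp_id = freqs$snp_id,
    maf_diff = maf_diff(freqs$p1, freqs$p2),
    fst_raw = vapply(res, `[[`, 0, "fst_raw"),
    fst = vapply(res, `[[`, 0, "fst"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_snp = per_snp,
       mean_fst = mean(per_snp$fst), sd_fst = stats::sd(per_snp$fst))
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Fst (", x$estimator, "): ", signif(x$fst, 4),
      if (x$fst_raw != x$fst) paste0(" (raw ", signif(x$fst_raw, 4), ")"),
      "\n", sep = "")
  invisible(x)
}
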