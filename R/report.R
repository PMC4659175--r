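# Per-probe verdict: true-methylation candidate vs SNP-confounded.

# Table-driven verdict logic. "differential" covers both the pop_diff and
# weak_diff categories; multimodal or flattened patterns of individual
# beta values point at genotype structure rather than methylation, cloudy
# patterns at (possibly SNP-masked) real methylation variability. A
# multimodal pattern without an annotated SNP calls for genotyping: the
# variant may simply not be in the annotation yet.
VERDICTS <- data.frame(
  differential = c(FALSE, rep(TRUE, 10)),
  label = c("any",
            "trimodal", "bimodal", "flattened_high",
            "trimodal", "bimodal", "flattened_high",
            "cloud", "cloud", "clean_unimodal", "clean_unimodal"),
  snp_in_cpg = c(NA, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                 TRUE, FALSE, TRUE, FALSE),
  verdict = c("not_differential",
              "snp_confounded", "snp_confounded", "snp_confounded",
              "suspected_snp", "suspected_snp", "suspected_snp",
              "ambiguous_snp_present", "methylation_candidate",
              "ambiguous_snp_present", "methylation_candidate"),
  stringsAsFactors = FALSE)

#' Verdict for one probe from its differential category, beta pattern and
#' SNP annotation
#'
#' Pure, table-driven decision:
#' * not differential -> `not_differential`;
#' * differential with a tri-modal, bi-modal or flattened-high pattern ->
#'   `snp_confounded` when a SNP is annotated in the interrogated CpG (the
#'   pattern reflects genotype classes or collapsed signals, not
#'   methylation), else `suspected_snp` (the same patterns should prompt
#'   genotyping for variation the annotation has missed);
#' * differential with a cloud or tight unimodal pattern ->
#'   `methylation_candidate` when no SNP is annotated in the interrogated
#'   CpG, else `ambiguous_snp_present` (a SNP may mask or mimic a real
#'   difference; genotype confirmation advised).
#'
#' @param category `pop_diff`, `weak_diff` or `ns`.
#' @param label A [classify_beta_pattern()] label.
#' @param snp_in_cpg Is a SNP annotated in the interrogated CpG?
#' @return Verdict string (vectorised over the inputs).
#' @export
probe_verdict <- function(category, label, snp_in_cpg) {
  stopifnot(all(category %in% c("pop_diff", "weak_diff", "ns")),
            all(label %in% c("trimodal", "bimodal", "flattened_high",
                             "cloud", "clean_unimodal")))
  mapply(function(cat, lab, snp) {
    differential <- cat != "ns"
    hit <- VERDICTS$differential == differential &
      (VERDICTS$label == "any" | VERDICTS$label == lab) &
      (is.na(VERDICTS$snp_in_cpg) | VERDICTS$snp_in_cpg == snp)
    VERDICTS$verdict[which(hit)[1L]]
  }, as.character(category), label, as.logical(snp_in_cpg),
  USE.NAMES = FALSE)
}

#' Join differential results, pattern calls and SNP annotation into a
#' per-probe report
#'
#' @param diff A [differential_methylation()] result.
#' @param patterns A [classify_cohort()] result (or data.frame with
#'   `probe_id`, `label`, `genotype_concordance`).
#' @param manifest Optional manifest data.frame with `probe_id`,
#'   `snp_in_cpg` and, when present, per-population frequency columns
#'   `freq_<pop>` used to add `maf_diff` and Hudson `fst`
#'   (`n_per_pop` diploid samples each).
#' @param n_per_pop Diploid sample size per population for the Fst
#'   annotation (default 18).
#' @return Data.frame with one row per probe: category, pattern label,
#'   SNP annotation, optional `maf_diff`/`fst`, and `verdict`.
#' @export
confound_report <- function(diff, patterns, manifest = NULL,
                            n_per_pop = 18) {
  out <- merge(as.data.frame(diff)[, c("probe_id", "m_av_diff", "q",
                                       "category")],
               patterns[, c("probe_id", "label", "genotype_concordance")],
               by = "probe_id", sort = FALSE)
  if (!is.null(manifest)) {
    freq_cols <- grep("^freq_", names(manifest), value = TRUE)
    keep <- c("probe_id", "snp_in_cpg", freq_cols)
    out <- merge(out, manifest[, keep], by = "probe_id", sort = FALSE)
    out$snp_in_cpg <- as.logical(out$snp_in_cpg)
    if (length(freq_cols) >= 2L) {
      p1 <- out[[freq_cols[1L]]]
      p2 <- out[[freq_cols[2L]]]
      out$maf_diff <- out$fst <- NA_real_
      has <- out$snp_in_cpg & !is.na(p1) & !is.na(p2)
      out$maf_diff[has] <- maf_diff(p1[has], p2[has])
      out$fst[has] <- vapply(which(has), function(i)
        suppressMessages(fst_two_pop(p1[i], p2[i], n_per_pop,
                                     n_per_pop))$fst, 0)
    }
  } else {
    out$snp_in_cpg <- FALSE
  }
  out$verdict <- probe_verdict(out$category, out$label, out$snp_in_cpg)
  out
}
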