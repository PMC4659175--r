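# Synthetic two-population cohort generator with known genotype and
# methylation truth.

#' Configuration of a synthetic two-population cohort
#'
#' Mirrors a two-population comparative design: two labelled populations
#' of equal size (default 18 samples each, as in a typical cell-line
#' panel), a set of interrogated loci with per-population alternate-allele
#' frequencies, shared chemistry/noise parameters, and a seed.
#'
#' @param loci A single [locus_spec()] or a list of them.
#' @param n_per_pop Samples per population (>= 2).
#' @param populations Character vector of two population labels.
#' @param params A [chem_params()].
#' @param seed Integer seed recorded in all outputs.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(loci, n_per_pop = 18,
                          populations = c("EUR", "EAS"),
                          params = chem_params(), seed = 1L) {
  if (inherits(loci, "locus_spec")) loci <- list(loci)
  stopifnot(length(loci) >= 1, all(vapply(loci, inherits, TRUE, "locus_spec")),
            n_per_pop >= 2, length(populations) == 2,
            inherits(params, "chem_params"))
  ids <- vapply(loci, `[[`, "", "locus_id")
  if (anyDuplicated(ids)) stop("duplicate locus ids in cohort config")
  names(loci) <- ids
  structure(list(loci = loci, n_per_pop = as.integer(n_per_pop),
                 populations = populations, params = params,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' Each sample draws two alleles independently with alternate-allele
#' probability `freq_alt`; the genotype is coded as the number of non-CpG
#' allele copies (0, 1 or 2).
#'
#' @param freq_alt Alternate allele frequency in \[0, 1\].
#' @param n Number of samples.
#' @return Integer vector of length `n` with values in 0:2.
#' @export
sample_genotypes <- function(freq_alt, n) {
  if (length(freq_alt) != 1 || is.na(freq_alt) || freq_alt < 0 || freq_alt > 1)
    stop("freq_alt must be a single frequency in [0, 1]")
  stopifnot(n >= 1)
  stats::rbinom(n, size = 2L, prob = freq_alt)
}

# Per-population methylation level of the CpG allele at one locus.
locus_meth_level <- function(locus, population) {
  m <- locus$meth_cpg_allele
  if (length(m) == 1L && is.null(names(m))) return(unname(m))
  if (!population %in% names(m))
    stop("locus ", locus$locus_id, " has no methylation level for population ",
         population)
  unname(m[[population]])
}

# Per-sample realised methylation fraction: Beta draw with mean m and sd s
# (method-of-moments shapes) when s > 0, else exactly m.
draw_meth_frac <- function(m, s, n) {
  if (s <= 0 || m %in% c(0, 1)) return(rep(m, n))
  v <- min(s^2, 0.95 * m * (1 - m))
  k <- m * (1 - m) / v - 1
  stats::rbeta(n, shape1 = m * k, shape2 = (1 - m) * k)
}

#' Simulate a two-population methylation cohort
#'
#' For every locus and sample, draws a Hardy-Weinberg genotype from the
#' population's alternate-allele frequency, a per-sample methylation
#' fraction, and mechanistic fluorescence signals from the probe chemistry;
#' derives beta and M matrices.
#'
#' @param config A [cohort_config()].
#' @param noise Apply lognormal signal noise (default TRUE)?
#' @return A list of class `snp_cohort` with elements `signal_meth`,
#'   `signal_unmeth`, `beta`, `m` (loci x samples matrices), `samples`
#'   (data.frame of sample id and population) and `truth` (genotype
#'   matrix, per-locus per-population methylation levels, per-sample
#'   methylation fractions, seed).
#' @export
simulate_cohort <- function(config, noise = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_per_pop
  pops <- config$populations
  sample_pop <- rep(pops, each = n)
  sample_id <- paste0(sample_pop, "_", sprintf("%02d", rep(seq_len(n), 2)))
  loci <- config$loci
  L <- length(loci)
  dn <- list(names(loci), sample_id)
  sig_m <- sig_u <- geno <- frac <- matrix(NA_real_, L, 2L * n, dimnames = dn)
  meth_levels <- matrix(NA_real_, L, 2L, dimnames = list(names(loci), pops))
  for (i in seq_len(L)) {
    locus <- loci[[i]]
    basis <- locus_channel_basis(locus, config$params)
    for (p in seq_along(pops)) {
      cols <- which(sample_pop == pops[p])
      freq <- if (is.null(locus$snp)) 0 else {
        fa <- locus$snp$freq_alt
        if (!pops[p] %in% names(fa))
          stop("locus ", locus$locus_id, " has no alternate-allele frequency ",
               "for population ", pops[p])
        unname(fa[[pops[p]]])
      }
      g <- sample_genotypes(freq, n)
      m_level <- locus_meth_level(locus, pops[p])
      f <- draw_meth_frac(m_level, locus$meth_sd, n)
      sig <- signals_from_basis(basis, g, f, config$params, noise)
      sig_m[i, cols] <- sig["meth", ]
      sig_u[i, cols] <- sig["unmeth", ]
      geno[i, cols] <- g
      frac[i, cols] <- f
      meth_levels[i, p] <- m_level
    }
  }
  beta <- compute_beta(sig_m, sig_u, offset = config$params$beta_offset)
  structure(list(signal_meth = sig_m, signal_unmeth = sig_u,
                 beta = beta, m = compute_m(beta),
                 samples = data.frame(sample_id = sample_id,
                                      population = sample_pop,
                                      stringsAsFactors = FALSE),
                 truth = list(genotypes = geno, meth_levels = meth_levels,
                              meth_frac = frac, seed = config$seed)),
            class = "snp_cohort")
}

#' @export
print.snp_cohort <- function(x, ...) {
  cat("snp_cohort:", nrow(x$beta), "loci x", ncol(x$beta), "samples (",
      paste(unique(x$samples$population), collapse = " vs "), ")\n")
  invisible(x)
}

#' Canonical SNP-artifact locus scenarios
#'
#' Ready-made [locus_spec()]s for the archetypal confounding scenarios:
#'
#' * `"trimodal"`: type II probe, C>T in position 1, methylated CpG allele.
#'   Beta values split into three genotype bands (high CpG/CpG,
#'   intermediate heterozygote, low TpG/TpG).
#' * `"bimodal"`: type I probe, G>A in position 2, methylated CpG allele.
#'   Heterozygotes are indistinguishable from CpG homozygotes; TpA
#'   homozygotes collapse to background in both channels and show low,
#'   background-inflated beta values.
#' * `"flattened"`: type I probe, C>T in position 1, methylated CpG allele
#'   with three methylated under-a-probe CpGs. TpG alleles mismatch both
#'   probes; both signals collapse and beta values are inflated into the
#'   mid/high range.
#' * `"cloud"`: clean non-polymorphic CpG with partial, between-sample
#'   variable methylation.
#'
#' @param scenario Scenario name.
#' @param freq_alt Named per-population alternate-allele frequencies
#'   (ignored for `"cloud"`). The default strongly differentiates the two
#'   populations (MAF_diff = 0.5).
#' @param meth Mean methylation level of the CpG allele.
#' @return A [locus_spec()].
#' @export
scenario_locus <- function(scenario = c("trimodal", "bimodal", "flattened",
                                        "cloud"),
                           freq_alt = c(EUR = 0.2, EAS = 0.7),
                           meth = if (scenario == "cloud") 0.5 else 1) {
  scenario <- match.arg(scenario)
  switch(scenario,
    trimodal = locus_spec(paste0("sim_", scenario), infinium_type = "II",
                          snp = snp_spec(1, "T", freq_alt),
                          meth_cpg_allele = meth),
    bimodal = locus_spec(paste0("sim_", scenario), infinium_type = "I",
                         snp = snp_spec(2, "A", freq_alt),
                         meth_cpg_allele = meth),
    flattened = locus_spec(paste0("sim_", scenario), infinium_type = "I",
                           snp = snp_spec(1, "T", freq_alt),
                           under_probe_cpg_offsets = c(3, 6, 9),
                           meth_cpg_allele = meth),
    cloud = locus_spec(paste0("sim_", scenario), infinium_type = "II",
                       meth_cpg_allele = meth, meth_sd = 0.15))
}
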