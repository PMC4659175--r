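# Independent oracles and small scenario helpers used across the suite.

# Brute-force Benjamini-Hochberg step-up, straight from the definition:
# q for the i-th smallest p is min over k >= i of m * p_(k) / k, capped at 1.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Dichotomize a noise-free signal against half the per-copy scale.
dichotomize <- function(signal, scale = 1000) {
  ifelse(signal > scale / 2, "high", "low")
}

# Simulate one canonical scenario cohort.
scenario_cohort <- function(scenario, n_per_pop = 200, seed = 1,
                            params = chem_params(), ...) {
  simulate_cohort(cohort_config(scenario_locus(scenario, ...),
                                n_per_pop = n_per_pop, params = params,
                                seed = seed))
}

# Classify the single probe of a one-locus cohort.
classify_first_probe <- function(cohort, params = pattern_params()) {
  suppressMessages(classify_beta_pattern(
    cohort$beta[1, ],
    total_intensity = cohort$signal_meth[1, ] + cohort$signal_unmeth[1, ],
    params = params,
    genotypes = cohort$truth$genotypes[1, ]))
}

# Enumerate every (probe type x SNP x allele x methylation x under-probe
# context) combination of the predicted-readout tables, returning both the
# hand-coded oracle and the dichotomized noise-free simulator output.
enumerate_readout_checks <- function() {
  combos <- expand.grid(
    type = c("I", "II"),
    snp = c("none", "1T", "1A", "1G", "2A", "2T", "2C"),
    allele = c("cpg", "alt"),
    methylated = c(TRUE, FALSE),
    under_cpgs = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  combos <- combos[!(combos$snp == "none" & combos$allele == "alt"), ]
  noise_free <- chem_params(background = 0, sdlog = 0)
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    cb <- combos[r, ]
    snp <- if (cb$snp == "none") NULL else
      snp_spec(as.integer(substr(cb$snp, 1, 1)), substr(cb$snp, 2, 2))
    locus <- locus_spec("enum", snp = snp,
                        under_probe_cpg_offsets =
                          if (cb$under_cpgs) c(3, 7) else integer(),
                        infinium_type = cb$type, meth_cpg_allele = 1)
    sig <- simulate_locus_signals(locus,
                                  genotype = if (cb$allele == "alt") 2L else 0L,
                                  meth_frac = as.numeric(cb$methylated),
                                  params = noise_free, noise = FALSE)
    oracle <- expected_readout(cb$type, snp, cb$allele,
                               cpg_methylated = cb$methylated,
                               comethylated_context =
                                 cb$under_cpgs && cb$methylated)
    cbind(cb,
          sim_meth = dichotomize(sig[["meth"]]),
          sim_unmeth = dichotomize(sig[["unmeth"]]),
          oracle_meth = oracle$signal_meth_level,
          oracle_unmeth = oracle$signal_unmeth_level)
  })
  do.call(rbind, rows)
}
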