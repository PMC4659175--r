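# Bisulfite conversion, probe design, hybridization and signal simulation.

test_that("bisulfite conversion preserves methylated Cs and converts the rest", {
  expect_equal(bisulfite_convert("ACGT", 2), "ACGT")
  expect_equal(bisulfite_convert("ACGT"), "ATGT")
  expect_equal(bisulfite_convert("CCGC", 2), "TCGT")
  expect_equal(nchar(bisulfite_convert("CCCCC")), 5L)
})

test_that("bisulfite conversion rejects bad input with explicit messages", {
  expect_error(bisulfite_convert("ACNG"), "non-ACGT")
  expect_error(bisulfite_convert("ACGT", 9), "out of range")
  expect_error(bisulfite_convert("ACGT", 1), "do not hold a C")
})

test_that("bisulfite conversion is idempotent given the same methylated set", {
  set.seed(42)
  for (i in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    chars <- strsplit(seq, "")[[1]]
    cg_c <- which(chars == "C" & c(chars[-1], "") == "G")
    meth <- cg_c[seq_along(cg_c) %% 2 == 0]
    once <- bisulfite_convert(seq, meth)
    expect_equal(bisulfite_convert(once, meth), once)
  }
})

test_that("type I probe pairs differ at the 3' terminus and at under-probe CpGs", {
  plain <- design_probes(locus_spec("a", infinium_type = "I"))
  d_plain <- which(strsplit(plain$seq_m, "")[[1]] !=
                     strsplit(plain$seq_u, "")[[1]])
  expect_equal(d_plain, nchar(plain$seq_m))  # only the 3'-terminal base

  two <- design_probes(locus_spec("b", under_probe_cpg_offsets = c(5, 11),
                                  infinium_type = "I"))
  d_two <- strsplit(two$seq_m, "")[[1]] != strsplit(two$seq_u, "")[[1]]
  expect_equal(sum(d_two), 3L)               # terminus + two CpG positions
})

test_that("type II probes are degenerate exactly at under-probe CpG Cs", {
  deg <- design_probes(locus_spec("c", under_probe_cpg_offsets = c(5, 11),
                                  infinium_type = "II"))
  expect_equal(sum(strsplit(deg$seq_deg, "")[[1]] == "R"), 2L)
  none <- design_probes(locus_spec("d", infinium_type = "II"))
  expect_equal(sum(strsplit(none$seq_deg, "")[[1]] == "R"), 0L)
  # 3'-most base pairs the G of the interrogated CpG
  expect_equal(substring(none$seq_deg, nchar(none$seq_deg)), "C")
})

test_that("probe design rejects malformed loci", {
  expect_error(locus_spec("x", context_seq = "ATCGATA"), "center")
  expect_error(locus_spec("x", context_seq = synth_context(len = 101),
                          under_probe_cpg_offsets = 4),
               "does not point at a CG")
  short <- locus_spec("x", context_seq = synth_context(len = 21),
                      probe_len = 50)
  expect_error(design_probes(short), "too short")
})

test_that("hybridization efficiency follows the mismatch penalty model", {
  params <- chem_params()
  locus <- locus_spec("e", infinium_type = "II")
  design <- design_probes(locus)
  probe <- design$seq_deg
  tmpl_chars <- strsplit(bisulfite_convert(locus$context_seq), "")[[1]]
  template <- paste(tmpl_chars[design$footprint], collapse = "")
  expect_equal(hybridization_efficiency(probe, template, params), 1.0)

  # single 3'-terminal mismatch
  mut <- paste0("T", substring(template, 2))
  expect_equal(hybridization_efficiency(probe, mut, params),
               params$eps_terminal)

  # multiplicativity: two mismatches give the product of the singles
  mut_a <- paste0(substring(template, 1, 4), "C", substring(template, 6))
  mut_b <- paste0(substring(template, 1, 19), "C", substring(template, 21))
  e_a <- hybridization_efficiency(probe, mut_a, params)
  e_b <- hybridization_efficiency(probe, mut_b, params)
  mut_ab <- paste0(substring(mut_a, 1, 19), "C", substring(mut_a, 21))
  expect_equal(hybridization_efficiency(probe, mut_ab, params), e_a * e_b)

  expect_error(hybridization_efficiency("ACGT", "ACGTT"), "length")
})

test_that("the degenerate base R pairs both C and T templates at full efficiency", {
  expect_equal(hybridization_efficiency("R", "C"), 1.0)
  expect_equal(hybridization_efficiency("R", "T"), 1.0)
  expect_lt(hybridization_efficiency("R", "A"), 1.0)
})

test_that("mismatch penalty is monotone in distance from the 3' end", {
  pen <- mismatch_penalty(0:49)
  expect_true(all(diff(pen) >= 0))
  expect_equal(pen[1], chem_params()$eps_terminal)
})

test_that("predicted readouts match the documented anchor cases", {
  # type II, C>T allele: strong red, no green - mimics unmethylated status
  r <- expected_readout("II", snp_spec(1, "T"), "alt")
  expect_equal(c(r$signal_meth_level, r$signal_unmeth_level),
               c("low", "high"))
  # type I, G>A in position 2: both M and U signals very low
  r <- expected_readout("I", snp_spec(2, "A"), "alt", cpg_methylated = TRUE,
                        comethylated_context = TRUE)
  expect_equal(c(r$signal_meth_level, r$signal_unmeth_level), c("low", "low"))
  # type I, C>T with methylated under-probe CpGs: both signals extremely low
  r <- expected_readout("I", snp_spec(1, "T"), "alt",
                        comethylated_context = TRUE)
  expect_equal(c(r$signal_meth_level, r$signal_unmeth_level), c("low", "low"))
  # canonical methylated CpG
  r <- expected_readout("II", NULL, "cpg", cpg_methylated = TRUE)
  expect_equal(c(r$signal_meth_level, r$signal_unmeth_level),
               c("high", "low"))
  # type II C>G mimics the methylated status (green ddC ~ ddG)
  r <- expected_readout("II", snp_spec(1, "G"), "alt")
  expect_equal(c(r$signal_meth_level, r$signal_unmeth_level),
               c("high", "low"))
})

test_that("noise-free signals reproduce the worked single-sample cases", {
  off <- chem_params(background = 0, sdlog = 0)
  # methylated CpG homozygote, type II: all signal in the green channel
  locus <- locus_spec("f", infinium_type = "II", meth_cpg_allele = 1)
  expect_equal(simulate_locus_signals(locus, 0L, 1, off, noise = FALSE),
               c(meth = 2000, unmeth = 0))
  # CpG/TpG heterozygote, methylated CpG allele: equal red and green
  het <- locus_spec("g", snp = snp_spec(1, "T"), infinium_type = "II")
  expect_equal(simulate_locus_signals(het, 1L, 1, off, noise = FALSE),
               c(meth = 1000, unmeth = 1000))
  # TpA homozygote, type I G>A: neither probe extends appreciably; the M
  # channel sits at background, the U channel keeps only a weak residual
  # from its single internal mismatch; both dichotomize low
  bg <- chem_params(background = 50, sdlog = 0)
  flat <- locus_spec("h", snp = snp_spec(2, "A"), infinium_type = "I")
  sig <- simulate_locus_signals(flat, 2L, 1, bg, noise = FALSE)
  expect_lt(sig[["meth"]], 1.1 * bg$background)
  expect_gte(sig[["meth"]], bg$background)
  expect_lt(sig[["unmeth"]], bg$scale / 2)
  expect_equal(dichotomize(sig), c(meth = "low", unmeth = "low"))
})

test_that("genotypes inconsistent with the locus SNP are rejected", {
  clean <- locus_spec("i")
  expect_error(simulate_locus_signals(clean, 1L), "no SNP")
  expect_error(simulate_locus_signals(clean, 3L), "genotype")
  expect_equal(sum(simulate_locus_signals(
    locus_spec("j", snp = snp_spec(1, "T")), c("cpg", "alt"), 1,
    chem_params(background = 0, sdlog = 0), noise = FALSE)), 2000)
})

test_that("swapping the methylation state swaps the channel pair on clean loci", {
  off <- chem_params(background = 0, sdlog = 0)
  for (type in c("I", "II")) {
    locus <- locus_spec("k", infinium_type = type)
    m_state <- simulate_locus_signals(locus, 0L, 1, off, noise = FALSE)
    u_state <- simulate_locus_signals(locus, 0L, 0, off, noise = FALSE)
    expect_equal(unname(m_state), unname(rev(u_state)))
  }
})

test_that("beta is inflated monotonically in background for non-extending genotypes", {
  locus <- locus_spec("l", snp = snp_spec(2, "A"), infinium_type = "I")
  betas <- vapply(c(5, 20, 50, 100, 200, 500), function(b) {
    sig <- simulate_locus_signals(locus, 2L, 1,
                                  chem_params(background = b, sdlog = 0),
                                  noise = FALSE)
    compute_beta(sig[["meth"]], sig[["unmeth"]])
  }, 0)
  expect_true(all(diff(betas) > 0))
})
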