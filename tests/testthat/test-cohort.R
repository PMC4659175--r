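# Two-population cohort generation: HWE genotypes, truth, reproducibility.

test_that("genotype sampling respects Hardy-Weinberg expectations", {
  expect_equal(sample_genotypes(0, 50), rep(0L, 50))
  expect_equal(sample_genotypes(1, 50), rep(2L, 50))
  set.seed(11)
  g <- sample_genotypes(0.5, 10000)
  expect_lt(abs(mean(g == 1) - 0.5), 0.015)   # 2pq = 0.5, binomial SE 0.005
  expect_lt(abs(mean(g) / 2 - 0.5), 0.015)
  expect_error(sample_genotypes(1.2, 10), "frequency")
})

test_that("identical seeds reproduce bit-identical cohorts", {
  cfg <- cohort_config(list(scenario_locus("trimodal"),
                            scenario_locus("cloud")),
                       n_per_pop = 10, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$signal_meth, b$signal_meth)
  expect_identical(a$beta, b$beta)
  expect_identical(a$truth$genotypes, b$truth$genotypes)
})

test_that("cohort matrices have the configured shape and labels", {
  ch <- simulate_cohort(cohort_config(scenario_locus("trimodal"),
                                      n_per_pop = 5, seed = 3))
  expect_equal(dim(ch$beta), c(1L, 10L))
  expect_equal(table(ch$samples$population),
               table(factor(c(rep("EUR", 5), rep("EAS", 5)))))
  expect_true(all(ch$beta >= 0 & ch$beta <= 1))
})

test_that("a fully methylated clean locus gives beta 1 without noise or background", {
  cfg <- cohort_config(locus_spec("clean", meth_cpg_allele = 1),
                       n_per_pop = 5,
                       params = chem_params(background = 0, sdlog = 0),
                       seed = 1)
  ch <- simulate_cohort(cfg)
  expect_equal(unname(ch$beta[1, ]), rep(1, 10))
})

test_that("cohort mean beta recovers the true methylation level on clean loci", {
  for (m in c(0.2, 0.5, 0.8)) {
    for (type in c("I", "II")) {
      ch <- simulate_cohort(cohort_config(
        locus_spec("clean", meth_cpg_allele = m, infinium_type = type),
        n_per_pop = 100, seed = 7 + round(100 * m)))
      expect_lt(abs(mean(ch$beta) - m), 0.03)
    }
  }
})

test_that("the tri-modal scenario yields three genotype-aligned beta bands", {
  ch <- scenario_cohort("trimodal", n_per_pop = 200, seed = 5)
  beta <- ch$beta[1, ]
  g <- ch$truth$genotypes[1, ]
  band_means <- tapply(beta, g, mean)          # descending in alt copies
  expect_true(all(diff(band_means) < 0))
  # bands do not overlap: every CpG hom above every het above every alt hom
  expect_gt(min(beta[g == 0]), max(beta[g == 1]))
  expect_gt(min(beta[g == 1]), max(beta[g == 2]))
  # the intermediate band sits midway between the outer bands
  expect_lt(abs(band_means[["1"]] -
                  (band_means[["0"]] + band_means[["2"]]) / 2), 0.1)
})

test_that("position-2 SNPs make heterozygotes look like CpG homozygotes", {
  ch <- scenario_cohort("bimodal", n_per_pop = 200, seed = 6)
  beta <- ch$beta[1, ]
  g <- ch$truth$genotypes[1, ]
  expect_lt(abs(mean(beta[g == 1]) - mean(beta[g == 0])), 0.15)
  # alt homozygotes collapse far below the CpG-homozygote totals
  total <- (ch$signal_meth + ch$signal_unmeth)[1, ]
  expect_lt(mean(total[g == 2]), 0.2 * mean(total[g == 0]))
  expect_gt(mean(total[g == 0]), 30 * chem_params()$background)
})

test_that("per-population methylation levels flow into the truth and the betas", {
  locus <- locus_spec("dm", meth_cpg_allele = c(EUR = 0.8, EAS = 0.2))
  ch <- simulate_cohort(cohort_config(locus, n_per_pop = 50, seed = 8))
  pop <- ch$samples$population
  expect_equal(unname(ch$truth$meth_levels[1, ]), c(0.8, 0.2))
  expect_gt(mean(ch$beta[1, pop == "EUR"]), mean(ch$beta[1, pop == "EAS"]) + 0.4)
})
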