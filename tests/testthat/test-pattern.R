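# Beta-distribution pattern classification and genotype concordance.

test_that("low-intensity flagging compares totals to the cohort median", {
  expect_equal(unname(low_intensity_flag(c(2000, 2000, 100))),
               c(FALSE, FALSE, TRUE))
  expect_false(any(low_intensity_flag(rep(1500, 6))))
  expect_equal(unname(low_intensity_flag(c(1000, 1000, 300), frac = 0.25)),
               c(FALSE, FALSE, FALSE))
  expect_error(low_intensity_flag(c(1, 2)), "at least 3")
  expect_warning(flags <- low_intensity_flag(rep(0, 5)), "all totals")
  expect_true(all(flags))
  # meth/unmeth pair interface
  expect_equal(unname(low_intensity_flag(c(1000, 1000, 50),
                                         c(1000, 1000, 50), frac = 0.25)),
               c(FALSE, FALSE, TRUE))
})

test_that("tight unimodal betas are called clean, with input validation", {
  set.seed(21)
  beta <- pmin(1, 0.9 + rnorm(40, 0, 0.01))
  call <- classify_beta_pattern(beta)
  expect_equal(call$label, "clean_unimodal")
  expect_equal(call$n_clusters, 1L)
  expect_error(classify_beta_pattern(beta[1:9]), "at least 10")
  expect_error(classify_beta_pattern(c(beta[-1], 1.4)), "\\[0, 1\\]")
})

test_that("each canonical scenario is recovered with its intended label", {
  labels <- vapply(c("trimodal", "bimodal", "flattened", "cloud"),
                   function(sc) classify_first_probe(
                     scenario_cohort(sc, n_per_pop = 200, seed = 31))$label,
                   "")
  expect_equal(unname(labels),
               c("trimodal", "bimodal", "flattened_high", "cloud"))
})

test_that("flattened calls put the non-extending genotypes among the low-intensity samples", {
  ch <- scenario_cohort("flattened", n_per_pop = 200, seed = 32)
  call <- classify_first_probe(ch)
  expect_equal(call$label, "flattened_high")
  g <- ch$truth$genotypes[1, ]
  expect_setequal(unname(call$low_intensity_samples), unname(which(g == 2)))
})

test_that("pattern labels are invariant under sample permutation", {
  ch <- scenario_cohort("trimodal", n_per_pop = 100, seed = 33)
  beta <- ch$beta[1, ]
  total <- ch$signal_meth[1, ] + ch$signal_unmeth[1, ]
  ref <- classify_beta_pattern(beta, total)
  set.seed(1)
  perm <- sample(length(beta))
  shuffled <- classify_beta_pattern(beta[perm], total[perm])
  expect_equal(shuffled$label, ref$label)
  expect_equal(shuffled$cluster_means, ref$cluster_means, tolerance = 1e-6)
})

test_that("genotype concordance scores cluster/genotype agreement", {
  # perfect genotype-driven trimodal split
  g <- rep(c(0L, 1L, 2L), times = c(30, 40, 30))
  assignment <- rep(c(3L, 2L, 1L), times = c(30, 40, 30))  # beta descending
  expect_equal(genotype_concordance(assignment, g), 1.0)
  # orientation-insensitive
  expect_equal(genotype_concordance(rep(c(1L, 2L, 3L),
                                        times = c(30, 40, 30)), g), 1.0)
  # two clusters against three genotype classes: best monotone matching
  g2 <- rep(c(0L, 1L, 2L), times = c(50, 30, 20))
  a2 <- rep(c(2L, 2L, 1L), times = c(50, 30, 20))
  expect_equal(genotype_concordance(a2, g2), 0.7)  # {hi->0, lo->2} matches 70
  # single cluster: undefined
  expect_message(val <- genotype_concordance(rep(1L, 10), rep(0:1, 5)),
                 "undefined")
  expect_true(is.na(val))
})

test_that("random betas cannot reach high genotype concordance", {
  set.seed(34)
  beta <- runif(200)
  g <- sample_genotypes(0.5, 200)
  call <- suppressMessages(classify_beta_pattern(beta, genotypes = g))
  if (call$n_clusters >= 2L)
    expect_lt(call$genotype_concordance, 0.7)
  # even a forced 3-way split of random data stays near the class frequencies
  forced <- cut(rank(beta), 3, labels = FALSE)
  expect_lt(genotype_concordance(forced, g), 0.7)
})

test_that("the tri-modal scenario reaches near-perfect genotype concordance", {
  call <- classify_first_probe(scenario_cohort("trimodal", n_per_pop = 200,
                                               seed = 35))
  expect_equal(call$label, "trimodal")
  expect_gte(call$genotype_concordance, 0.95)
})

test_that("signal noise degrades, never improves, genotype concordance", {
  conc <- vapply(c(0.05, 0.3, 0.6), function(sdlog) {
    mean(vapply(1:15, function(s) {
      ch <- scenario_cohort("trimodal", n_per_pop = 200, seed = 1000 + s,
                            params = chem_params(sdlog = sdlog))
      classify_first_probe(ch)$genotype_concordance
    }, 0))
  }, 0)
  expect_true(all(diff(conc) <= 0.005))  # non-increasing up to MC jitter
  expect_gt(conc[1], conc[3])
})

test_that("classify_cohort summarises per-probe calls of a cohort", {
  cfg <- cohort_config(list(scenario_locus("trimodal"),
                            scenario_locus("cloud")),
                       n_per_pop = 100, seed = 36)
  ch <- simulate_cohort(cfg)
  calls <- classify_cohort(ch)
  expect_equal(calls$probe_id, rownames(ch$beta))
  expect_equal(calls$label, c("trimodal", "cloud"))
  expect_gte(calls$genotype_concordance[1], 0.9)
})
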