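# Classification of per-probe distributions of individual beta values:
# genotype-driven multimodality, flattened low-signal inflation, clouds.

#' Parameters of the beta-distribution pattern classifier
#'
#' @param min_sep Minimum separation between adjacent cluster means for
#'   them to count as distinct modes (beta units).
#' @param merge_overlap Adjacent mixture components are also merged when
#'   their means are closer than `merge_overlap` times the sum of their
#'   SDs (heavily overlapping components describe one mode).
#' @param cloud_sd Within-cluster SD above which a unimodal distribution
#'   is labelled `cloud`.
#' @param flat_min For a two-mode pattern whose lower mode consists of
#'   low-intensity samples: lower-mode mean at or above which the pattern
#'   is labelled `flattened_high` (background-inflated betas sit in the
#'   mid/high range) rather than `bimodal`.
#' @param flat_mean Mean above which a tight unimodal pattern with
#'   low-intensity samples is labelled `flattened_high`.
#' @param low_frac A sample is low-intensity when its total signal is
#'   below `low_frac` times the cohort median total.
#' @param max_k Maximum number of mixture components considered.
#' @return A list of class `pattern_params`.
#' @export
pattern_params <- function(min_sep = 0.15, merge_overlap = 1.5,
                           cloud_sd = 0.12, flat_min = 0.35,
                           flat_mean = 0.6, low_frac = 0.25, max_k = 3) {
  stopifnot(min_sep > 0, merge_overlap >= 0, cloud_sd > 0,
            flat_min >= 0, flat_min <= 1, flat_mean >= 0, flat_mean <= 1,
            low_frac > 0, low_frac < 1, max_k %in% 2:5)
  structure(list(min_sep = min_sep, merge_overlap = merge_overlap,
                 cloud_sd = cloud_sd, flat_min = flat_min,
                 flat_mean = flat_mean, low_frac = low_frac,
                 max_k = as.integer(max_k)),
            class = "pattern_params")
}

#' Flag samples with abnormally low total fluorescence
#'
#' Flags samples whose total (meth + unmeth) intensity falls below
#' `frac` times the cohort median total — the signature of a probe that
#' fails to extend on both channels in that sample.
#'
#' @param signal_meth Per-sample methylated-channel intensities, or
#'   per-sample totals when `signal_unmeth` is NULL.
#' @param signal_unmeth Per-sample unmethylated-channel intensities.
#' @param frac Fraction of the median total below which a sample is
#'   flagged (default 0.25).
#' @return Named logical vector, TRUE for flagged samples.
#' @export
low_intensity_flag <- function(signal_meth, signal_unmeth = NULL,
                               frac = 0.25) {
  total <- if (is.null(signal_unmeth)) signal_meth
           else signal_meth + signal_unmeth
  if (length(total) < 3L)
    stop("at least 3 samples are required to flag low-intensity samples")
  med <- stats::median(total)
  if (med == 0) {
    warning("all totals are zero; every sample flagged as low-intensity")
    return(stats::setNames(rep(TRUE, length(total)), names(total)))
  }
  total < frac * med
}

# Fit 1..max_k component univariate Gaussian mixtures, select by BIC
# (ties broken toward fewer components), then merge adjacent components
# that do not form distinct modes.
fit_beta_mixture <- function(beta, params) {
  fit <- mclust::Mclust(beta, G = seq_len(params$max_k), modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit)) {  # degenerate data; treat as one tight cluster
    return(list(k = 1L, means = mean(beta), sds = stats::sd(beta) %||% 0,
                assignment = rep(1L, length(beta))))
  }
  ord <- order(fit$parameters$mean)
  means <- fit$parameters$mean[ord]
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1L) sds <- rep(sds, fit$G)
  sds <- sds[ord]
  props <- fit$parameters$pro[ord]
  assignment <- match(fit$classification, ord)
  # merge components that overlap too much to be separate modes
  repeat {
    k <- length(means)
    if (k == 1L) break
    gaps <- diff(means)
    thr <- pmax(params$min_sep,
                params$merge_overlap * (sds[-k] + sds[-1L]))
    mergeable <- which(gaps < thr)
    if (!length(mergeable)) break
    i <- mergeable[which.min(gaps[mergeable])]
    w <- props[i] + props[i + 1L]
    mu <- (props[i] * means[i] + props[i + 1L] * means[i + 1L]) / w
    va <- (props[i] * (sds[i]^2 + means[i]^2) +
             props[i + 1L] * (sds[i + 1L]^2 + means[i + 1L]^2)) / w - mu^2
    means <- c(means[seq_len(i - 1L)], mu, means[-seq_len(i + 1L)])
    sds <- c(sds[seq_len(i - 1L)], sqrt(max(va, 0)), sds[-seq_len(i + 1L)])
    props <- c(props[seq_len(i - 1L)], w, props[-seq_len(i + 1L)])
    assignment[assignment > i] <- assignment[assignment > i] - 1L
  }
  list(k = length(means), means = unname(means), sds = unname(sds),
       assignment = assignment)
}

#' Classify the distribution pattern of individual beta values at a probe
#'
#' Fits univariate Gaussian mixtures with 1 to `max_k` components to the
#' per-sample beta values, selects the number of components by BIC (ties
#' toward fewer), merges components that do not form distinct modes, and
#' labels the probe:
#'
#' * `trimodal` — three modes; the signature of a genotype-driven split
#'   (SNP in position 1 of a CpG interrogated by a type II probe, CpG
#'   allele methylated).
#' * `bimodal` — two modes; typical of a SNP in position 2, where
#'   heterozygotes merge with CpG homozygotes and non-CpG homozygotes
#'   collapse toward background.
#' * `flattened_high` — betas compressed into the mid/high range with
#'   low-intensity samples present: both channels collapse for non-CpG
#'   alleles and background inflates their betas (two-mode case with the
#'   lower mode made of low-intensity samples at mean >= `flat_min`, or a
#'   single high mode with low-intensity samples).
#' * `cloud` — one broad mode (within-SD > `cloud_sd`): variable,
#'   partial methylation.
#' * `clean_unimodal` — one tight mode.
#'
#' @param beta Per-sample beta values (>= 10 samples).
#' @param total_intensity Optional per-sample total (meth + unmeth)
#'   intensities used to flag low-intensity samples.
#' @param params A [pattern_params()].
#' @param genotypes Optional per-sample genotype codes (0/1/2 non-CpG
#'   allele copies); when given, genotype concordance is attached.
#' @return A list of class `pattern_call`: `label`, `n_clusters`,
#'   `cluster_means` (ascending), `cluster_sds`, `assignment` (per-sample
#'   cluster index, ascending by mean), `low_intensity_samples`,
#'   `genotype_concordance` (NA unless `genotypes` given and >= 2
#'   clusters).
#' @export
classify_beta_pattern <- function(beta, total_intensity = NULL,
                                  params = pattern_params(),
                                  genotypes = NULL) {
  beta <- as.numeric(beta)
  if (anyNA(beta)) stop("beta contains missing values")
  if (length(beta) < 10L)
    stop("at least 10 samples are required for a stable pattern call")
  if (any(beta < 0 | beta > 1)) stop("beta values must lie in [0, 1]")
  fit <- fit_beta_mixture(beta, params)
  low <- rep(FALSE, length(beta))
  if (!is.null(total_intensity)) {
    stopifnot(length(total_intensity) == length(beta))
    low <- low_intensity_flag(total_intensity, frac = params$low_frac)
  }
  label <- if (fit$k == 3L) {
    "trimodal"
  } else if (fit$k == 2L) {
    in_low_mode <- fit$assignment == 1L
    if (any(low) && mean(low[in_low_mode]) >= 0.8 &&
        fit$means[1L] >= params$flat_min) "flattened_high" else "bimodal"
  } else if (fit$sds[1L] > params$cloud_sd) {
    "cloud"
  } else if (fit$means[1L] > params$flat_mean && any(low)) {
    "flattened_high"
  } else {
    "clean_unimodal"
  }
  call <- structure(
    list(label = label, n_clusters = fit$k,
         cluster_means = fit$means, cluster_sds = fit$sds,
         assignment = fit$assignment,
         low_intensity_samples = which(low),
         genotype_concordance = NA_real_),
    class = "pattern_call")
  if (!is.null(genotypes))
    call$genotype_concordance <- genotype_concordance(call, genotypes)
  call
}

# All order-preserving injective matchings between cluster ranks and
# genotype-class ranks (both <= max_k, so brute force is exact).
monotone_matchings <- function(k, g) {
  s <- min(k, g)
  maps <- list()
  for (ci in utils::combn(k, s, simplify = FALSE))
    for (gi in utils::combn(g, s, simplify = FALSE))
      maps[[length(maps) + 1L]] <- cbind(cluster = ci, class = gi)
  maps
}

#' Concordance between beta clusters and SNP genotypes
#'
#' Scores how well the cluster structure of the beta values reproduces the
#' genotype classes: over all order-preserving one-to-one matchings of
#' beta-ordered clusters to genotype-ordered classes (in either
#' orientation, since the beta ordering of genotypes depends on the
#' methylation state), returns the largest fraction of samples whose
#' cluster is matched to their genotype class.
#'
#' @param call A [classify_beta_pattern()] result (or a per-sample cluster
#'   assignment vector ordered ascending by cluster mean).
#' @param genotypes Per-sample genotype codes (0/1/2 non-CpG allele
#'   copies), same length/order as the classified samples.
#' @return Fraction in \[0, 1\]; NA (with a message) when fewer than two
#'   clusters were found.
#' @export
genotype_concordance <- function(call, genotypes) {
  assignment <- if (inherits(call, "pattern_call")) call$assignment else call
  stopifnot(length(assignment) == length(genotypes))
  if (anyNA(genotypes)) stop("genotypes contain missing values")
  k <- max(assignment)
  if (k < 2L) {
    message("genotype concordance undefined for a single-cluster pattern")
    return(NA_real_)
  }
  classes <- sort(unique(genotypes))
  g <- length(classes)
  class_rank <- match(genotypes, classes)
  best <- 0
  for (orient in list(seq_len(k), rev(seq_len(k)))) {
    oriented <- orient[assignment]
    for (map in monotone_matchings(k, g)) {
      matched <- rep(FALSE, length(assignment))
      for (r in seq_len(nrow(map)))
        matched <- matched |
          (oriented == map[r, "cluster"] & class_rank == map[r, "class"])
      best <- max(best, mean(matched))
    }
  }
  best
}

#' @export
print.pattern_call <- function(x, ...) {
  cat("pattern:", x$label, "| clusters:", x$n_clusters,
      "| means:", paste(round(x$cluster_means, 3), collapse = ", "), "\n")
  if (length(x$low_intensity_samples))
    cat("  low-intensity samples:",
        paste(x$low_intensity_samples, collapse = ", "), "\n")
  if (!is.na(x$genotype_concordance))
    cat("  genotype concordance:", round(x$genotype_concordance, 3), "\n")
  invisible(x)
}

#' Classify every probe of a cohort or matrix set
#'
#' Convenience wrapper running [classify_beta_pattern()] per probe row.
#'
#' @param beta Loci x samples beta matrix (or an `snp_cohort`).
#' @param signal_meth,signal_unmeth Optional matching signal matrices for
#'   low-intensity flagging (taken from the cohort when `beta` is an
#'   `snp_cohort`).
#' @param params A [pattern_params()].
#' @param genotypes Optional loci x samples genotype matrix.
#' @return A data.frame with one row per probe: `probe_id`, `label`,
#'   `n_clusters`, `n_low_intensity`, `genotype_concordance`.
#' @export
classify_cohort <- function(beta, signal_meth = NULL, signal_unmeth = NULL,
                            params = pattern_params(), genotypes = NULL) {
  if (inherits(beta, "snp_cohort")) {
    cohort <- beta
    beta <- cohort$beta
    signal_meth <- cohort$signal_meth
    signal_unmeth <- cohort$signal_unmeth
    if (is.null(genotypes)) genotypes <- cohort$truth$genotypes
  }
  calls <- lapply(rownames(beta) %||% seq_len(nrow(beta)), function(id) {
    i <- if (is.character(id)) match(id, rownames(beta)) else id
    total <- if (!is.null(signal_meth))
      signal_meth[i, ] + signal_unmeth[i, ] else NULL
    g <- if (!is.null(genotypes)) genotypes[i, ] else NULL
    suppressMessages(
      classify_beta_pattern(beta[i, ], total_intensity = total,
                            params = params, genotypes = g))
  })
  data.frame(
    probe_id = rownames(beta) %||% as.character(seq_len(nrow(beta))),
    label = vapply(calls, `[[`, "", "label"),
    n_clusters = vapply(calls, `[[`, 0L, "n_clusters"),
    n_low_intensity = vapply(calls, function(x)
      length(x$low_intensity_samples), 0L),
    genotype_concordance = vapply(calls, `[[`, 0, "genotype_concordance"),
    row.names = NULL, stringsAsFactors = FALSE)
}
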