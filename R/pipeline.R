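# Beta/M computation, detection filtering, differential methylation,
# global methylation test, neighbor-probe scan.

#' Beta value from methylated/unmethylated signal intensities
#'
#' `beta = signal_meth / (signal_meth + signal_unmeth + offset)`. With the
#' default `offset = 0` and both signals zero the ratio is undefined and
#' reported as `NA`.
#'
#' @param signal_meth,signal_unmeth Non-negative numeric vectors or
#'   matrices of equal shape.
#' @param offset Denominator offset (the platform convention adds 100; the
#'   printed definition uses 0).
#' @return Beta values in \[0, 1\] (NA where undefined), same shape as the
#'   inputs.
#' @examples
#' compute_beta(1000, 0)   # 1
#' compute_beta(500, 500)  # 0.5
#' compute_beta(60, 55)    # background-level signals inflate beta: 0.522
#' @export
compute_beta <- function(signal_meth, signal_unmeth, offset = 0) {
  if (any(signal_meth < 0, na.rm = TRUE) ||
      any(signal_unmeth < 0, na.rm = TRUE))
    stop("signal intensities must be non-negative")
  stopifnot(offset >= 0)
  denom <- signal_meth + signal_unmeth + offset
  beta <- signal_meth / denom
  beta[!is.na(denom) & denom == 0] <- NA_real_
  beta
}

#' M value from beta
#'
#' `M = log2(beta / (1 - beta))` after clamping beta into
#' `[beta_min, beta_max]` (default \[0.001, 0.999\]), so `|M| <= log2(999)`.
#'
#' @param beta Beta values in \[0, 1\] (vector or matrix).
#' @param beta_min,beta_max Clamp interval.
#' @return M values, same shape as `beta`.
#' @examples
#' compute_m(0.5)  # 0
#' compute_m(1)    # log2(999)
#' @export
compute_m <- function(beta, beta_min = 0.001, beta_max = 0.999) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, beta_min), beta_max)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) {
    out <- matrix(out, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  }
  out
}

#' Background (negative-control) intensity model
#'
#' Normal model of the total (meth + unmeth) intensity expected from a
#' probe that does not extend, used to compute detection p-values.
#'
#' @param mean,sd Mean and SD of the background total intensity.
#' @return A list of class `background_model`.
#' @export
background_model <- function(mean, sd) {
  stopifnot(mean >= 0, sd > 0)
  structure(list(mean = mean, sd = sd), class = "background_model")
}

#' Background model implied by simulation parameters
#'
#' Under the signal model, a non-extending probe yields background `b` per
#' channel times mean-one lognormal noise, so the total intensity has mean
#' `2 b` and variance `2 b^2 (exp(sdlog^2) - 1)`.
#'
#' @param params A [chem_params()].
#' @return A [background_model()].
#' @export
background_from_params <- function(params = chem_params()) {
  b <- params$background
  v <- b^2 * (exp(params$sdlog^2) - 1)
  background_model(mean = 2 * b, sd = sqrt(max(2 * v, 1e-12)))
}

#' Detection filtering of probes against a background model
#'
#' The detection p-value of a measurement is the upper-tail probability of
#' its total (meth + unmeth) intensity under the background normal model.
#' A probe fails when its detection p-value exceeds `alpha` in at least
#' one sample.
#'
#' @param signal_meth,signal_unmeth Loci x samples signal matrices.
#' @param background A [background_model()].
#' @param alpha Detection p-value threshold (default 0.01).
#' @return A list with `failed` (character vector of failed probe ids),
#'   `retained`, and `detection_p` (loci x samples matrix).
#' @export
detection_filter <- function(signal_meth, signal_unmeth, background,
                             alpha = 0.01) {
  if (missing(background) || !inherits(background, "background_model"))
    stop("a background_model is required")
  total <- signal_meth + signal_unmeth
  p <- stats::pnorm(total, mean = background$mean, sd = background$sd,
                    lower.tail = FALSE)
  fail <- apply(p > alpha, 1L, any)
  list(failed = rownames(signal_meth)[fail],
       retained = rownames(signal_meth)[!fail],
       detection_p = p)
}

# Row-wise two-sample t statistics (equal-variance Student or Welch),
# vectorised over probes; cross-validated against stats::t.test in the
# test suite.
row_t_test <- function(x, g1, g2, var_equal = TRUE) {
  n1 <- length(g1); n2 <- length(g2)
  x1 <- x[, g1, drop = FALSE]; x2 <- x[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(x))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate probes: zero variance in both groups and equal means
  degen <- !is.finite(t)
  if (any(degen)) {
    t[degen] <- 0
    p[degen] <- 1
  }
  list(mean1 = m1, mean2 = m2, t = t, p = p, df = df,
       n_degenerate = sum(degen))
}

#' Per-probe differential methylation between two populations
#'
#' For each probe, computes the average M value per population, their
#' difference `m_av_diff`, a two-sided two-sample Student's t-test on M
#' values (equal-variance by default; Welch behind `var_equal = FALSE`),
#' and Benjamini-Hochberg FDR q-values. Probes are categorised as
#' `pop_diff` (q < `q_max` and `|m_av_diff| > m_strong`), `weak_diff`
#' (q < `q_max` and `m_weak < |m_av_diff| <= m_strong`) or `ns`.
#'
#' @param m Loci x samples matrix of M values.
#' @param groups Factor/character of population labels, one per column
#'   (exactly two levels, each with >= 2 samples).
#' @param beta Optional matching beta matrix; adds per-population average
#'   beta columns.
#' @param q_max FDR threshold (default 0.05).
#' @param m_strong `|m_av_diff|` threshold for the `pop_diff` category
#'   (default 1).
#' @param m_weak Lower `|m_av_diff|` screen for `weak_diff` (default 0; a
#'   common screen sets it to 0.3).
#' @param var_equal Equal-variance Student's t (TRUE) or Welch (FALSE).
#' @return A data.frame of class `diff_result` with one row per probe:
#'   `probe_id`, `m_av_1`, `m_av_2` (group order = factor level order),
#'   optional `beta_av_1`/`beta_av_2`, `m_av_diff`, `t`, `p`, `q`,
#'   `category`. Group labels are kept in `attr(, "populations")`.
#' @export
differential_methylation <- function(m, groups, beta = NULL, q_max = 0.05,
                                     m_strong = 1, m_weak = 0,
                                     var_equal = TRUE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two populations are required")
  if (length(groups) != ncol(m))
    stop("length(groups) must equal ncol(m)")
  if (min(table(groups)) < 2L)
    stop("each population needs at least 2 samples")
  if (anyNA(m))
    stop("M matrix contains missing values; filter or impute first")
  g1 <- which(groups == levels(groups)[1L])
  g2 <- which(groups == levels(groups)[2L])
  tt <- row_t_test(m, g1, g2, var_equal)
  if (tt$n_degenerate > 0)
    message(tt$n_degenerate,
            " probe(s) with zero variance and identical means: p set to 1")
  q <- stats::p.adjust(tt$p, method = "BH")
  d <- tt$mean1 - tt$mean2
  category <- ifelse(q < q_max & abs(d) > m_strong, "pop_diff",
                     ifelse(q < q_max & abs(d) > m_weak, "weak_diff", "ns"))
  out <- data.frame(probe_id = rownames(m) %||% seq_len(nrow(m)),
                    m_av_1 = tt$mean1, m_av_2 = tt$mean2,
                    m_av_diff = d, t = tt$t, p = tt$p, q = q,
                    category = factor(category,
                                      levels = c("pop_diff", "weak_diff", "ns")),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(beta)) {
    out$beta_av_1 <- rowMeans(beta[, g1, drop = FALSE], na.rm = TRUE)
    out$beta_av_2 <- rowMeans(beta[, g2, drop = FALSE], na.rm = TRUE)
  }
  attr(out, "populations") <- levels(groups)
  class(out) <- c("diff_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Global methylation comparison between two populations
#'
#' Global methylation of a sample is the mean beta value over all probes;
#' the two populations are compared with a two-sample Student's t-test.
#' Probes with missing beta are excluded from the per-sample means, with a
#' message reporting the count.
#'
#' @param beta Loci x samples beta matrix.
#' @param groups Population labels, one per column (two levels, >= 2 each).
#' @param var_equal Equal-variance Student's t (TRUE) or Welch (FALSE).
#' @return A list with `sample_means`, `t`, `p`, `df`.
#' @export
global_methylation_test <- function(beta, groups, var_equal = TRUE) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, length(groups) == ncol(beta))
  if (min(table(groups)) < 2L)
    stop("each population needs at least 2 samples")
  n_missing <- sum(apply(is.na(beta), 1L, any))
  if (n_missing > 0)
    message(n_missing, " probe(s) with missing beta excluded from global means")
  means <- colMeans(beta[!apply(is.na(beta), 1L, any), , drop = FALSE])
  res <- tryCatch(
    stats::t.test(means[groups == levels(groups)[1L]],
                  means[groups == levels(groups)[2L]],
                  var.equal = var_equal),
    error = function(e) NULL)  # essentially constant data
  if (is.null(res))
    return(list(sample_means = means, t = 0, p = 1,
                df = length(means) - 2L))
  list(sample_means = means, t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Probes neighboring a query probe on the array manifest
#'
#' Returns the ids of probes on the same chromosome whose interrogated
#' position lies within `window` bases (inclusive) of the query probe,
#' excluding the query itself.
#'
#' @param manifest Data.frame with columns `probe_id`, `chromosome`,
#'   `position` (1-based).
#' @param probe_id Query probe id (must be present in the manifest).
#' @param window Distance window in bases (default 500).
#' @return Character vector of neighboring probe ids.
#' @export
neighbor_probes <- function(manifest, probe_id, window = 500) {
  stopifnot(all(c("probe_id", "chromosome", "position") %in% names(manifest)))
  i <- match(probe_id, manifest$probe_id)
  if (is.na(i)) stop("unknown probe id: ", probe_id)
  same_chr <- manifest$chromosome == manifest$chromosome[i]
  close <- abs(manifest$position - manifest$position[i]) <= window
  manifest$probe_id[same_chr & close & manifest$probe_id != probe_id]
}
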