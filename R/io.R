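# TSV interchange: matrices, manifests, genotypes, run configuration.
# All writers embed provenance metadata ("#key<TAB>value" comment lines)
# so that re-running with identical inputs reproduces identical files.

#' Write a probes-x-samples matrix as TSV
#'
#' Probes as rows, samples as columns; first column `probe_id`, header row
#' of sample ids, missing values as `NA`. Metadata (for example the seed
#' and configuration hash) is embedded as leading `#key<TAB>value` comment
#' lines and recovered by [read_matrix()].
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output file path.
#' @param meta Named list of scalar metadata values.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, meta = list()) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta))
    writeLines(paste0("#", key, "\t", meta[[key]]), con)
  writeLines(paste(c("probe_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(r)
    paste(ifelse(is.na(r), "NA", format(r, digits = 15, trim = TRUE,
                                        scientific = FALSE)),
          collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a probes-x-samples TSV matrix
#'
#' Inverse of [write_matrix()]. Ragged rows and duplicate probe ids are
#' rejected with the offending line number.
#'
#' @param path File written by [write_matrix()] (or hand-built in the same
#'   layout).
#' @return Numeric matrix with embedded metadata in `attr(, "meta")`.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta_lines <- lines[is_meta]
  meta <- list()
  if (length(meta_lines)) {
    kv <- strsplit(sub("^#", "", meta_lines), "\t", fixed = TRUE)
    meta <- stats::setNames(lapply(kv, function(x) paste(x[-1L],
                                                         collapse = "\t")),
                            vapply(kv, `[[`, "", 1L))
  }
  body <- lines[!is_meta]
  if (length(body) < 1L) stop("no header row in ", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (header[1L] != "probe_id")
    stop("first header column must be probe_id in ", path)
  ncols <- length(header)
  line_no <- which(!is_meta)
  for (i in seq_along(fields)[-1L]) {
    if (length(fields[[i]]) != ncols)
      stop("ragged row at line ", line_no[i], " of ", path, ": expected ",
           ncols, " fields, found ", length(fields[[i]]))
  }
  ids <- vapply(fields[-1L], `[[`, "", 1L)
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("duplicate probe_id \"", ids[dup[1L]], "\" at line ",
         line_no[dup[1L] + 1L], " of ", path)
  vals <- t(vapply(fields[-1L],
                   function(f) suppressWarnings(as.numeric(f[-1L])),
                   numeric(ncols - 1L)))
  if (length(ids) == 1L) vals <- matrix(vals, nrow = 1L)
  dimnames(vals) <- list(ids, header[-1L])
  attr(vals, "meta") <- meta
  vals
}

#' Read a probe manifest TSV
#'
#' Expected columns: `probe_id`, `infinium_type` (I/II), `chromosome`,
#' `position` (1-based), `snp_in_cpg` (0/1), and optionally
#' `snp_position`, `alt_base` and per-population frequency columns
#' (`freq_<population>`).
#'
#' @param path Manifest TSV path.
#' @return A data.frame validated for unique probe ids, positive
#'   positions and valid probe types.
#' @export
read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  needed <- c("probe_id", "infinium_type", "chromosome", "position",
              "snp_in_cpg")
  missing_cols <- setdiff(needed, names(man))
  if (length(missing_cols))
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(man$probe_id))
    stop("manifest contains duplicate probe ids")
  if (any(man$position < 1)) stop("manifest positions must be >= 1")
  if (!all(man$infinium_type %in% c("I", "II")))
    stop("infinium_type must be \"I\" or \"II\"")
  man
}

#' Read/write a genotype matrix TSV
#'
#' Genotypes are coded as 0/1/2 copies of the non-CpG allele; layout as in
#' [write_matrix()].
#'
#' @param path Genotype TSV path.
#' @return Integer matrix (probes x samples).
#' @export
read_genotypes <- function(path) {
  g <- read_matrix(path)
  if (!all(is.na(g) | g %in% 0:2))
    stop("genotypes must be coded as 0, 1 or 2 copies of the non-CpG allele")
  storage.mode(g) <- "integer"
  g
}

#' @rdname read_genotypes
#' @param x Integer matrix of 0/1/2 genotype codes.
#' @param meta Named list of scalar metadata values.
#' @export
write_genotypes <- function(x, path, meta = list()) {
  stopifnot(all(is.na(x) | x %in% 0:2))
  write_matrix(x, path, meta = meta)
}

#' Analysis run configuration
#'
#' Bundles the thresholds of the analysis chain with the chemistry and
#' pattern parameters and the seed. The configuration (hash + seed) is
#' embedded in every output file header.
#'
#' @param q_max FDR threshold (default 0.05).
#' @param m_diff_popdiff `|m_av_diff|` threshold for the strongly
#'   differentiating (`pop_diff`) category (default 1).
#' @param m_diff_weak Lower `|m_av_diff|` screen for `weak_diff`
#'   (default 0.3).
#' @param detection_alpha Detection p-value threshold (default 0.01).
#' @param neighbor_window Neighbor-probe scan window in bases
#'   (default 500).
#' @param chem A [chem_params()].
#' @param pattern A [pattern_params()].
#' @param seed Integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(q_max = 0.05, m_diff_popdiff = 1, m_diff_weak = 0.3,
                       detection_alpha = 0.01, neighbor_window = 500,
                       chem = chem_params(), pattern = pattern_params(),
                       seed = 1L) {
  stopifnot(q_max > 0, m_diff_popdiff > 0, m_diff_weak > 0,
            detection_alpha > 0, neighbor_window > 0)
  structure(list(q_max = q_max, m_diff_popdiff = m_diff_popdiff,
                 m_diff_weak = m_diff_weak,
                 detection_alpha = detection_alpha,
                 neighbor_window = neighbor_window,
                 chem = chem, pattern = pattern, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / restore a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(q_max = raw$q_max %||% 0.05,
             m_diff_popdiff = raw$m_diff_popdiff %||% 1,
             m_diff_weak = raw$m_diff_weak %||% 0.3,
             detection_alpha = raw$detection_alpha %||% 0.01,
             neighbor_window = raw$neighbor_window %||% 500,
             chem = do.call(chem_params, raw$chem %||% list()),
             pattern = do.call(pattern_params, raw$pattern %||% list()),
             seed = raw$seed %||% 1L)
}

#' Deterministic hash of a configuration object
#'
#' MD5 of the canonical YAML serialization; embedded in output headers so
#' outputs can be traced to the configuration that produced them.
#'
#' @param config Any serializable list (for example a [run_config()] or
#'   [cohort_config()]).
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(rapply(list(unclass(config)), function(x)
    if (is.list(x)) unclass(x) else x, how = "replace"), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a cohort simulation configuration from YAML
#'
#' Schema: top-level `populations`, `n_per_pop`, `seed`, optional `params`
#' (fields of [chem_params()]) and a `loci` list whose entries give
#' `locus_id`, `infinium_type`, `meth_cpg_allele` (scalar or per-population
#' map), optional `meth_sd`, `under_probe_cpg_offsets`, `comethylation`,
#' and an optional `snp` map with `cpg_position`, `alt_base` and a
#' `freq_alt` population map.
#'
#' @param path YAML file path.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$loci) || !length(raw$loci))
    stop("cohort configuration must define at least one locus")
  loci <- lapply(raw$loci, function(l) {
    snp <- NULL
    if (!is.null(l$snp))
      snp <- snp_spec(l$snp$cpg_position, l$snp$alt_base,
                      unlist(l$snp$freq_alt))
    meth <- l$meth_cpg_allele %||% 1
    if (is.list(meth)) meth <- unlist(meth)
    locus_spec(locus_id = l$locus_id,
               snp = snp,
               under_probe_cpg_offsets =
                 as.integer(unlist(l$under_probe_cpg_offsets %||% integer())),
               meth_cpg_allele = meth,
               meth_sd = l$meth_sd %||% 0,
               comethylation = l$comethylation %||% TRUE,
               infinium_type = l$infinium_type %||% "II")
  })
  cohort_config(loci,
                n_per_pop = raw$n_per_pop %||% 18L,
                populations = unlist(raw$populations %||% c("EUR", "EAS")),
                params = do.call(chem_params, raw$params %||% list()),
                seed = raw$seed %||% 1L)
}
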