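# Infinium probe chemistry: bisulfite conversion, probe design,
# allele-specific hybridization and single-base extension.

BASES <- c("A", "C", "G", "T")

# Watson-Crick complement, plus the purine degeneracy code R (A/G) used at
# probe positions complementary to under-a-probe CpG cytosines (which read
# C when methylated, T after conversion when not).
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y")

seq_chars <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  toupper(strsplit(seq, "", fixed = TRUE)[[1L]])
}

#' Chemistry and signal-model parameters
#'
#' Parameters governing the simulated fluorescence signal model and the
#' mismatch penalty used for probe hybridization efficiency.
#'
#' The signal contributed by one fully extending allele copy is `scale`
#' arbitrary units; each channel additionally receives `background` units
#' before multiplicative lognormal noise with log-sd `sdlog` (mean-one
#' parameterisation, so noise does not bias expected signals).
#'
#' Hybridization efficiency of a probe/template duplex is the product over
#' mismatched positions of a per-mismatch penalty that depends on the
#' distance `d` (in bases) of the mismatch from the probe's 3' end:
#' a 3'-terminal mismatch (`d = 0`) essentially blocks single-base
#' extension (`eps_terminal`); mismatches within `prox_window` bases of the
#' 3' end are strongly destabilising (`prox_penalty`); beyond that the
#' penalty relaxes linearly toward 1 at rate `dist_slope` per base, so
#' 5'-distal mismatches are nearly harmless.
#'
#' @param scale Signal per extending allele copy (arbitrary units).
#' @param background Additive per-channel background signal.
#' @param sdlog Log-sd of the multiplicative lognormal signal noise.
#' @param eps_terminal Efficiency retained under a 3'-terminal mismatch.
#' @param prox_penalty Penalty for an internal mismatch within
#'   `prox_window` bases of the 3' end.
#' @param prox_window Width (bases) of the 3'-proximal region in which
#'   internal mismatches are maximally destabilising.
#' @param dist_slope Linear relaxation of the penalty per base beyond
#'   `prox_window`.
#' @param beta_offset Offset added to the denominator when computing beta
#'   values from these signals (the platform convention adds 100; the
#'   printed definition uses 0).
#' @return A list of class `chem_params`.
#' @export
chem_params <- function(scale = 1000, background = 50, sdlog = 0.15,
                        eps_terminal = 0.01, prox_penalty = 0.1,
                        prox_window = 9, dist_slope = 0.05,
                        beta_offset = 0) {
  stopifnot(scale > 0, background >= 0, sdlog >= 0,
            eps_terminal > 0, eps_terminal <= 1,
            prox_penalty > 0, prox_penalty <= 1,
            prox_window >= 0, dist_slope >= 0, beta_offset >= 0)
  structure(list(scale = scale, background = background, sdlog = sdlog,
                 eps_terminal = eps_terminal, prox_penalty = prox_penalty,
                 prox_window = prox_window, dist_slope = dist_slope,
                 beta_offset = beta_offset),
            class = "chem_params")
}

#' Mismatch penalty as a function of distance from the probe 3' end
#'
#' @param d Integer vector of distances (0 = the 3'-terminal base).
#' @param params A [chem_params()] object.
#' @return Numeric vector of multiplicative efficiency penalties in (0, 1].
#' @export
mismatch_penalty <- function(d, params = chem_params()) {
  stopifnot(all(d >= 0))
  ifelse(d == 0, params$eps_terminal,
         pmin(1, params$prox_penalty +
                params$dist_slope * pmax(0, d - params$prox_window)))
}

#' Bisulfite conversion of a nucleotide sequence
#'
#' Converts every unmethylated cytosine to thymine; cytosines at the
#' supplied methylated positions are protected and preserved. All other
#' bases are unchanged.
#'
#' @param seq Nucleotide string over A/C/G/T.
#' @param methylated_c_positions Integer set of 1-based positions holding a
#'   methylated C.
#' @return The converted sequence, same length as the input.
#' @examples
#' bisulfite_convert("ACGT", 2)  # "ACGT": methylated C preserved
#' bisulfite_convert("ACGT")     # "ATGT": unmethylated C converted
#' @export
bisulfite_convert <- function(seq, methylated_c_positions = integer()) {
  chars <- seq_chars(seq)
  bad <- setdiff(unique(chars), BASES)
  if (length(bad))
    stop("non-ACGT character(s) in sequence: ", paste(bad, collapse = ", "))
  pos <- as.integer(methylated_c_positions)
  if (length(pos)) {
    if (any(pos < 1L | pos > length(chars)))
      stop("methylated position index out of range [1, ", length(chars), "]")
    if (any(chars[pos] != "C"))
      stop("methylated position(s) ",
           paste(pos[chars[pos] != "C"], collapse = ", "),
           " do not hold a C")
  }
  convert <- chars == "C"
  convert[pos] <- FALSE
  chars[convert] <- "T"
  paste(chars, collapse = "")
}

#' Construct a synthetic genomic context for an interrogated CpG
#'
#' Builds a top-strand sequence of odd length with a CpG at the center and
#' additional CpG dinucleotides at the requested signed offsets (offset of
#' the under-a-probe C relative to the interrogated C). The filler
#' alphabet is A/T only, so the sequence contains no cytosines outside the
#' placed CpG sites and hence no unintended conversion or mismatch sites.
#'
#' @param under_probe_cpg_offsets Signed integer offsets of additional CpG
#'   Cs relative to the central C. Offsets must be at least 2 apart and
#'   not overlap the central CpG.
#' @param len Odd total length of the context (default 101).
#' @return A nucleotide string with `CG` at its center.
#' @export
synth_context <- function(under_probe_cpg_offsets = integer(), len = 101) {
  stopifnot(len >= 5, len %% 2 == 1)
  center <- (len + 1L) %/% 2L
  off <- sort(as.integer(under_probe_cpg_offsets))
  if (any(abs(off) < 2L))
    stop("under-probe CpG offsets must not overlap the interrogated CpG")
  if (length(off) > 1L && any(diff(off) < 2L))
    stop("under-probe CpG offsets must be at least 2 bases apart")
  pos <- center + off
  if (any(pos < 1L | pos + 1L > len))
    stop("under-probe CpG offset outside the context sequence")
  chars <- rep(c("A", "T"), length.out = len)
  for (p in c(center, pos)) {
    chars[p] <- "C"
    chars[p + 1L] <- "G"
  }
  paste(chars, collapse = "")
}

#' Specification of a SNP in the interrogated CpG dinucleotide
#'
#' Position 1 is the C and position 2 the G of the interrogated CpG on the
#' top strand. The reference base is therefore C (position 1) or G
#' (position 2), and the alternate allele destroys the CpG.
#'
#' @param cpg_position 1 or 2.
#' @param alt_base Alternate base, one of A/C/G/T, different from the
#'   reference base at that position.
#' @param freq_alt Named numeric vector of alternate (non-CpG) allele
#'   frequencies per population, each in \[0, 1\].
#' @return A list of class `snp_spec`.
#' @export
snp_spec <- function(cpg_position, alt_base, freq_alt = c(EUR = 0, EAS = 0)) {
  stopifnot(cpg_position %in% c(1L, 2L))
  alt_base <- toupper(alt_base)
  ref <- if (cpg_position == 1L) "C" else "G"
  if (!alt_base %in% BASES)
    stop("alt_base must be one of A, C, G, T")
  if (alt_base == ref)
    stop("alt_base must differ from the reference base (", ref,
         ") at CpG position ", cpg_position)
  freq_alt <- unlist(freq_alt)
  if (any(freq_alt < 0 | freq_alt > 1))
    stop("allele frequencies must lie in [0, 1]")
  structure(list(cpg_position = as.integer(cpg_position),
                 ref_base = ref, alt_base = alt_base, freq_alt = freq_alt),
            class = "snp_spec")
}

#' Genomic and epigenetic specification of one interrogated CpG locus
#'
#' Describes the top-strand context of a CpG interrogated by an Infinium
#' probe: the sequence, an optional SNP in the interrogated dinucleotide,
#' the positions of additional ("under-a-probe") CpG sites within the probe
#' footprint, and the methylation model of the CpG allele.
#'
#' `meth_cpg_allele` is the expected methylation fraction of the CpG allele
#' and may be a single number or a named per-population vector. When
#' `meth_sd > 0`, the realised per-sample methylation fraction is drawn
#' from a Beta distribution with that mean and standard deviation,
#' emulating inter-individual methylation variability (the "cloud"). Under
#' the co-methylation assumption (`comethylation = TRUE`) all under-a-probe
#' CpGs share the methylation state of the interrogated CpG.
#'
#' @param locus_id Probe/locus identifier.
#' @param context_seq Top-strand sequence of odd length with the
#'   interrogated C at the center; built with [synth_context()] when NULL.
#' @param snp Optional [snp_spec()].
#' @param under_probe_cpg_offsets Signed offsets of additional CpG Cs
#'   relative to the interrogated C.
#' @param meth_cpg_allele Methylation level of the CpG allele in \[0, 1\];
#'   scalar or named per-population vector.
#' @param meth_sd Between-sample SD of the methylation fraction (Beta
#'   model); 0 means every sample has exactly `meth_cpg_allele`.
#' @param comethylation Do under-a-probe CpGs share the interrogated CpG's
#'   methylation state?
#' @param infinium_type Probe chemistry interrogating this locus, "I" or
#'   "II".
#' @param probe_len Probe length in bases (default 50).
#' @return A list of class `locus_spec`.
#' @export
locus_spec <- function(locus_id, context_seq = NULL, snp = NULL,
                       under_probe_cpg_offsets = integer(),
                       meth_cpg_allele = 1, meth_sd = 0,
                       comethylation = TRUE,
                       infinium_type = c("II", "I"), probe_len = 50) {
  infinium_type <- match.arg(infinium_type)
  off <- sort(as.integer(under_probe_cpg_offsets))
  if (is.null(context_seq)) {
    len <- max(101L, 2L * (probe_len + max(0L, off, 2L)) + 3L)
    if (len %% 2L == 0L) len <- len + 1L
    context_seq <- synth_context(off, len = len)
  }
  chars <- seq_chars(context_seq)
  len <- length(chars)
  if (len %% 2L == 0L) stop("context_seq must have odd length")
  center <- (len + 1L) %/% 2L
  if (chars[center] != "C" || chars[center + 1L] != "G")
    stop("context_seq must contain the interrogated CG at its center")
  for (k in off) {
    p <- center + k
    if (p < 1L || p + 1L > len || chars[p] != "C" || chars[p + 1L] != "G")
      stop("under_probe_cpg_offset ", k,
           " does not point at a CG dinucleotide in context_seq")
  }
  if (any(meth_cpg_allele < 0 | meth_cpg_allele > 1))
    stop("meth_cpg_allele must lie in [0, 1]")
  stopifnot(meth_sd >= 0, probe_len >= 10)
  if (!is.null(snp) && !inherits(snp, "snp_spec"))
    stop("snp must be a snp_spec or NULL")
  structure(list(locus_id = locus_id,
                 context_seq = paste(chars, collapse = ""),
                 snp = snp,
                 under_probe_cpg_offsets = off,
                 meth_cpg_allele = meth_cpg_allele,
                 meth_sd = meth_sd,
                 comethylation = isTRUE(comethylation),
                 infinium_type = infinium_type,
                 probe_len = as.integer(probe_len)),
            class = "locus_spec")
}

locus_center <- function(locus) (nchar(locus$context_seq) + 1L) %/% 2L

# Template footprint (1-based positions in context_seq) covered by the
# probe body. The probe hybridizes antiparallel with its 3' end at the
# leftmost footprint position: type I probes cover the interrogated C and
# the downstream sequence; type II probes cover the G of the CpG and the
# downstream sequence, leaving the C to be read by single-base extension.
probe_footprint <- function(locus, infinium_type = locus$infinium_type) {
  center <- locus_center(locus)
  start <- if (infinium_type == "I") center else center + 1L
  end <- start + locus$probe_len - 1L
  if (end > nchar(locus$context_seq))
    stop("context_seq too short for a ", locus$probe_len,
         "-base probe downstream of the interrogated CpG")
  start:end
}

# Context sequence of one allele: the reference (CpG) allele, or the
# alternate allele with the SNP base substituted at CpG position 1 or 2.
allele_context <- function(locus, allele = c("cpg", "alt")) {
  allele <- match.arg(allele)
  chars <- seq_chars(locus$context_seq)
  if (allele == "alt") {
    if (is.null(locus$snp)) stop("locus has no SNP; only the CpG allele exists")
    center <- locus_center(locus)
    chars[center + locus$snp$cpg_position - 1L] <- locus$snp$alt_base
  }
  chars
}

# Positions of methylatable (CpG-context) cytosines on one allele, given
# the methylation state of the locus. A C can carry methylation only when
# followed by G; a SNP in position 2 therefore exposes the interrogated C
# to conversion regardless of the epigenetic state.
methylated_positions <- function(locus, chars, methylated) {
  if (!methylated) return(integer())
  center <- locus_center(locus)
  cand <- center + c(0L, locus$under_probe_cpg_offsets)
  if (!locus$comethylation) cand <- center
  cand[chars[cand] == "C" & chars[cand + 1L] == "G"]
}

#' Design Infinium I or II probe sequences for a locus
#'
#' Probes are built against the bisulfite-converted reference (CpG) allele.
#' Infinium I yields an M/U probe pair complementary to the fully
#' methylated / fully unmethylated converted template: the two differ at
#' the 3'-terminal base (reading the interrogated C/T) and at every
#' position complementary to an under-a-probe CpG C. Infinium II yields a
#' single probe whose 3'-most base is complementary to the second CpG
#' position and whose sequence carries the purine degeneracy code R at
#' positions complementary to under-a-probe CpG Cs.
#'
#' Probe sequences are reported 5' to 3'; the 3' end pairs with the
#' leftmost template position of the footprint.
#'
#' @param locus A [locus_spec()].
#' @param infinium_type "I" or "II" (defaults to the locus annotation).
#' @return A list of class `probe_design` with elements `probe_id`,
#'   `infinium_type`, `probe_len`, `footprint` (template positions),
#'   and `seq_m`/`seq_u` (type I) or `seq_deg` (type II).
#' @export
design_probes <- function(locus, infinium_type = locus$infinium_type) {
  stopifnot(inherits(locus, "locus_spec"))
  infinium_type <- match.arg(infinium_type, c("I", "II"))
  fp <- probe_footprint(locus, infinium_type)
  ref <- seq_chars(locus$context_seq)
  probe_from_template <- function(template_chars) {
    aligned <- unname(COMPLEMENT[template_chars[fp]])
    paste(rev(aligned), collapse = "")  # 5' -> 3'
  }
  out <- list(probe_id = locus$locus_id, infinium_type = infinium_type,
              probe_len = locus$probe_len, footprint = fp)
  if (infinium_type == "I") {
    meth_pos <- methylated_positions_all(locus)
    tmpl_m <- seq_chars(bisulfite_convert(locus$context_seq, meth_pos))
    tmpl_u <- seq_chars(bisulfite_convert(locus$context_seq))
    out$seq_m <- probe_from_template(tmpl_m)
    out$seq_u <- probe_from_template(tmpl_u)
  } else {
    tmpl <- seq_chars(bisulfite_convert(locus$context_seq,
                                        methylated_positions_all(locus)))
    aligned <- unname(COMPLEMENT[tmpl[fp]])
    # degenerate R wherever the template base is an under-a-probe CpG C
    under_c <- locus_center(locus) + locus$under_probe_cpg_offsets
    aligned[match(intersect(under_c, fp), fp)] <- "R"
    out$seq_deg <- paste(rev(aligned), collapse = "")
  }
  structure(out, class = "probe_design")
}

# All CpG-context C positions at the locus (interrogated + under-a-probe),
# used when designing probes against the fully methylated reference.
methylated_positions_all <- function(locus) {
  center <- locus_center(locus)
  center + c(0L, locus$under_probe_cpg_offsets)
}

probe_pairs_with <- function(probe_base) {
  switch(probe_base,
         A = "T", C = "G", G = "C", T = "A",
         R = c("C", "T"),  # purine probe base pairs pyrimidine template
         stop("invalid probe base: ", probe_base))
}

#' Hybridization efficiency of a probe/template duplex
#'
#' Aligns the probe (5' to 3') antiparallel to the template footprint
#' (given 5' to 3' on the top strand, so the probe's 3' end pairs the
#' template's first base) and multiplies the per-mismatch penalties of
#' [mismatch_penalty()]. The degenerate probe base R pairs both C and T
#' templates at full efficiency.
#'
#' @param probe_seq Probe sequence, 5' to 3', possibly containing R.
#' @param template_seq Template footprint sequence (top strand, 5' to 3'),
#'   same length as the probe.
#' @param params A [chem_params()].
#' @return Efficiency in (0, 1]; 1 for a perfect duplex.
#' @export
hybridization_efficiency <- function(probe_seq, template_seq,
                                     params = chem_params()) {
  probe <- seq_chars(probe_seq)
  template <- seq_chars(template_seq)
  if (length(probe) != length(template))
    stop("probe and template lengths differ (", length(probe), " vs ",
         length(template), ")")
  n <- length(probe)
  eff <- 1
  for (j in seq_len(n)) {
    probe_base <- probe[n - j + 1L]      # probe base pairing template pos j
    if (!template[j] %in% probe_pairs_with(probe_base))
      eff <- eff * mismatch_penalty(j - 1L, params)  # d = 0 at the 3' end
  }
  eff
}

#' Qualitative predicted readout for one allele (hand-coded oracle)
#'
#' Returns the predicted high/low level of the methylated and unmethylated
#' channel signals contributed by a single allele copy, for every
#' combination of probe type, SNP in the interrogated CpG, allele, and
#' methylation context. This is a direct transcription of the predicted
#' readout logic, independent of the sequence-level simulator, and serves
#' as its oracle:
#'
#' * Canonical CpG alleles read high in the channel matching their
#'   methylation state.
#' * Type II, SNP in position 1: C>T and C>A alleles template A/T
#'   incorporation (the red signals are not distinguishable) and mimic the
#'   unmethylated state; C>G templates C incorporation and mimics the
#'   methylated state.
#' * Type I, SNP in position 1, C>T: the allele mimics the unmethylated
#'   state unless the probes cover methylated under-a-probe CpGs, in which
#'   case both probes are mismatched (U in the body, M at its 3' end) and
#'   both signals collapse; C>A and C>G mismatch both probes at the 3'
#'   terminus and both signals collapse.
#' * Any SNP in position 2 (either probe type): the 3'-proximal mismatch
#'   blocks extension and both signals collapse ("flattened" readout).
#'
#' @param infinium_type "I" or "II".
#' @param snp A [snp_spec()] or NULL for a non-polymorphic CpG.
#' @param allele "cpg" or "alt" (the allele carried by this chromosome).
#' @param cpg_methylated Is the locus (CpG allele and, by co-methylation,
#'   any under-a-probe CpGs) methylated?
#' @param comethylated_context Are there under-a-probe CpGs that are
#'   methylated along with the interrogated CpG?
#' @return A list of class `expected_readout` with `signal_meth_level` and
#'   `signal_unmeth_level`, each "high" or "low" (low = background only).
#' @export
expected_readout <- function(infinium_type, snp = NULL,
                             allele = c("cpg", "alt"),
                             cpg_methylated = TRUE,
                             comethylated_context = FALSE) {
  infinium_type <- match.arg(infinium_type, c("I", "II"))
  allele <- match.arg(allele)
  if (allele == "alt" && is.null(snp))
    stop("allele \"alt\" requires a SNP specification")
  readout <- function(meth, unmeth)
    structure(list(signal_meth_level = meth, signal_unmeth_level = unmeth),
              class = "expected_readout")
  if (allele == "cpg") {
    return(if (cpg_methylated) readout("high", "low") else readout("low", "high"))
  }
  if (snp$cpg_position == 2L)           # 3'-proximal mismatch, no extension
    return(readout("low", "low"))
  # SNP in position 1
  if (infinium_type == "II") {
    return(switch(snp$alt_base,
                  T = readout("low", "high"),
                  A = readout("low", "high"),  # ddT, red like ddA
                  G = readout("high", "low"),  # ddC, green like ddG
                  stop("invalid alternate base for a position-1 SNP")))
  }
  # Type I, position 1
  if (snp$alt_base == "T") {
    if (comethylated_context) return(readout("low", "low"))
    return(readout("low", "high"))      # indistinguishable from converted TpG
  }
  readout("low", "low")                 # C>A or C>G: both probes 3'-mismatched
}

# Per-allele, per-methylation-state channel contributions of a single
# extending allele copy (in units of params$scale), computed from the
# sequence-level chemistry: bisulfite conversion of the allele template,
# hybridization of the designed probe(s), and single-base extension.
# Returns a 3-d array [allele, state, channel].
locus_channel_basis <- function(locus, params = chem_params(),
                                infinium_type = locus$infinium_type) {
  design <- design_probes(locus, infinium_type)
  fp <- design$footprint
  center <- locus_center(locus)
  alleles <- if (is.null(locus$snp)) "cpg" else c("cpg", "alt")
  basis <- array(0, dim = c(2L, 2L, 2L),
                 dimnames = list(allele = c("cpg", "alt"),
                                 state = c("meth", "unmeth"),
                                 channel = c("meth", "unmeth")))
  for (allele in alleles) {
    chars <- allele_context(locus, allele)
    for (state in c("meth", "unmeth")) {
      mpos <- methylated_positions(locus, chars, state == "meth")
      tmpl <- seq_chars(bisulfite_convert(paste(chars, collapse = ""), mpos))
      tmpl_fp <- paste(tmpl[fp], collapse = "")
      if (infinium_type == "I") {
        basis[allele, state, "meth"] <-
          hybridization_efficiency(design$seq_m, tmpl_fp, params)
        basis[allele, state, "unmeth"] <-
          hybridization_efficiency(design$seq_u, tmpl_fp, params)
      } else {
        eff <- hybridization_efficiency(design$seq_deg, tmpl_fp, params)
        ext_base <- tmpl[center]        # base read by single-base extension
        channel <- if (ext_base %in% c("C", "G")) "meth" else "unmeth"
        basis[allele, state, channel] <- eff
      }
    }
  }
  basis
}

# Vectorised signal synthesis from a channel basis: genotypes are counts
# of the non-CpG allele (0/1/2), meth_frac is the per-sample methylation
# fraction of the locus. Fractional mixing emulates the cell-population
# average measured on a bead.
signals_from_basis <- function(basis, genotypes, meth_frac, params,
                               noise = TRUE) {
  n_cpg <- 2 - genotypes
  n_alt <- genotypes
  f <- meth_frac
  out <- matrix(0, nrow = 2L, ncol = length(genotypes),
                dimnames = list(c("meth", "unmeth"), names(genotypes)))
  for (channel in c("meth", "unmeth")) {
    per_cpg <- f * basis["cpg", "meth", channel] +
      (1 - f) * basis["cpg", "unmeth", channel]
    per_alt <- f * basis["alt", "meth", channel] +
      (1 - f) * basis["alt", "unmeth", channel]
    sig <- params$scale * (n_cpg * per_cpg + n_alt * per_alt) +
      params$background
    if (noise && params$sdlog > 0)
      sig <- sig * stats::rlnorm(length(sig),
                                 meanlog = -params$sdlog^2 / 2,
                                 sdlog = params$sdlog)
    out[channel, ] <- sig
  }
  out
}

#' Simulate the fluorescence signal pair of one sample at one locus
#'
#' Runs the sequence-level chemistry (bisulfite conversion of each allele
#' copy, probe hybridization, single-base extension) and sums the channel
#' contributions of the two allele copies, adds per-channel background, and
#' optionally applies multiplicative lognormal noise.
#'
#' @param locus A [locus_spec()].
#' @param genotype Number of non-CpG allele copies (0, 1 or 2), or a
#'   character pair such as `c("cpg", "alt")`.
#' @param meth_frac Methylation fraction of the locus in this sample
#'   (cell-population average applied to the CpG allele and, under
#'   co-methylation, to under-a-probe CpGs on either allele). Defaults to
#'   the locus mean level.
#' @param params A [chem_params()].
#' @param noise Apply lognormal signal noise?
#' @param infinium_type Probe type; defaults to the locus annotation.
#' @return Named numeric vector `c(meth =, unmeth =)`.
#' @export
simulate_locus_signals <- function(locus, genotype,
                                   meth_frac = mean(locus$meth_cpg_allele),
                                   params = chem_params(), noise = TRUE,
                                   infinium_type = locus$infinium_type) {
  stopifnot(inherits(locus, "locus_spec"))
  if (is.character(genotype)) {
    if (length(genotype) != 2L || !all(genotype %in% c("cpg", "alt")))
      stop("character genotype must be a pair of \"cpg\"/\"alt\"")
    genotype <- sum(genotype == "alt")
  }
  if (!genotype %in% 0:2)
    stop("genotype must be 0, 1 or 2 copies of the non-CpG allele")
  if (genotype > 0 && is.null(locus$snp))
    stop("locus ", locus$locus_id,
         " has no SNP: only the CpG/CpG genotype is valid")
  stopifnot(meth_frac >= 0, meth_frac <= 1)
  basis <- locus_channel_basis(locus, params, infinium_type)
  sig <- signals_from_basis(basis, genotype, meth_frac, params, noise)
  c(meth = unname(sig["meth", 1L]), unmeth = unname(sig["unmeth", 1L]))
}

#' @export
print.expected_readout <- function(x, ...) {
  cat("expected readout: meth =", x$signal_meth_level,
      "| unmeth =", x$signal_unmeth_level, "\n")
  invisible(x)
}

#' @export
print.probe_design <- function(x, ...) {
  cat("Infinium", x$infinium_type, "probe design for", x$probe_id, "\n")
  if (x$infinium_type == "I") {
    cat("  M:", x$seq_m, "\n  U:", x$seq_u, "\n")
  } else {
    cat("  deg:", x$seq_deg, "\n")
  }
  invisible(x)
}
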