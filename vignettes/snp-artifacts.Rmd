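---
title: "How genomic SNPs distort Infinium methylation readouts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How genomic SNPs distort Infinium methylation readouts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpbeta)
```

## The problem

Infinium HM450K-style methylation arrays report, for each interrogated
CpG, a beta value
\[
\beta = \frac{\mathrm{signal}_{Meth}}{\mathrm{signal}_{Meth} + \mathrm{signal}_{Unmeth}},
\]
interpreted as the fraction of methylated DNA copies. That interpretation
assumes the interrogated dinucleotide actually is a CpG in every sample.
When a genomic SNP hits the C (position 1) or the G (position 2) of the
interrogated dinucleotide, the probe chemistry reacts to the *genotype*,
not the methylation state: non-CpG alleles can mimic unmethylated (C>T,
C>A) or methylated (C>G) states, or block probe extension altogether so
that both channels collapse to background and the ratio above is
dominated by noise. In a comparison of two populations whose allele
frequencies differ, these artifacts systematically masquerade as
differential methylation. `snpbeta` models the mechanism, generates
synthetic cohorts with known truth, and provides the diagnostics —
per-sample beta distribution patterns, low-intensity flags, genotype
concordance, allele-frequency differentiation — that separate genomic
from epigenetic signal.

## The chemistry model

A locus is a top-strand context sequence with the interrogated CpG at its
center (`locus_spec()`). Bisulfite conversion (`bisulfite_convert()`)
turns every cytosine into thymine unless it is methylated, and a C can
carry methylation only in CpG context — so a SNP in position 2 exposes
the neighbouring C to conversion no matter the epigenetic state.

Probes are designed against the converted reference allele
(`design_probes()`):

* **Infinium I** — an M/U probe pair covering the interrogated C and the
  downstream footprint. The pair differs at the 3'-terminal base (reading
  C vs converted T) and at every base complementary to an under-a-probe
  CpG C, because the design assumes co-methylation of neighbouring CpGs.
  The readout channel is the identity of the extending probe.
* **Infinium II** — a single probe covering the G of the CpG and the
  downstream footprint, degenerate (purine code R) at under-a-probe CpG
  positions. Single-base extension reads the converted first position of
  the CpG: incorporated C/G report methylated, A/T unmethylated — which
  is exactly why C>A looks unmethylated and C>G methylated.

Hybridization efficiency is a product of per-mismatch penalties
(`mismatch_penalty()`) that depend on the distance `d` of the mismatch
from the probe's 3' end: a terminal mismatch essentially blocks
single-base extension (`eps_terminal = 0.01`); internal mismatches within
`prox_window = 9` bases of the 3' end retain only `prox_penalty = 0.1` of
the signal; beyond that the penalty relaxes linearly (`dist_slope =
0.05` per base) toward harmless. Only the qualitative shape of this
family is constrained — extension chemistry punishes 3'-proximal
mismatches hardest — and the quantitative values are calibration choices,
exposed in `chem_params()`. They were fixed once so that the dichotomized
noise-free simulator (threshold: half the per-copy signal scale) agrees
with the hand-coded qualitative readout table `expected_readout()` over
the full enumeration of probe type × SNP × allele × methylation context;
the steeper-than-linear plateau near the 3' end is required for that
agreement (a mismatch one base in from the 3' terminus must not leave
more than half-scale signal).

A worked consequence of the penalty plateau: for a position-2 G>A locus
under a type I probe, the non-extending TpA homozygote keeps a small
residual in the U channel (one internal mismatch) and only background in
the M channel, so its beta settles in the low range — while a position-1
C>T locus with several methylated under-a-probe CpGs loses *both*
channels almost completely and its beta is inflated to the mid/high
range by background. This is what makes the two flavours of
"abnormally low fluorescence" distinguishable downstream.

Signals are synthesised per sample as
\[
\mathrm{signal}_c = \Big(\sum_{\text{allele copies}} S \cdot
\mathrm{eff} \cdot \mathbb{1}[\text{extension reports } c]\Big) + b,
\]
then multiplied by mean-one lognormal noise. Defaults `S = 1000`,
`b = 50` arbitrary units and `sdlog = 0.15` give clean probes a ~40:1
signal-to-background ratio and beta clusters a spread of a few
hundredths, comparable to normalised array intensities; all three are
`chem_params()` fields. Partial methylation is realised as *fractional
mixing*: a copy with methylation fraction `f` contributes `f` times its
methylated-template signal plus `1 - f` times its unmethylated-template
signal, emulating the cell-population average measured on a bead. (A
literal per-copy Bernoulli draw would make every intermediately
methylated clean locus look trimodal, which is not what arrays measure.)

## The cohort generator

`simulate_cohort()` draws, per locus and population, Hardy–Weinberg
genotypes (`sample_genotypes()`, two independent allele draws), a
per-sample methylation fraction (exactly `meth_cpg_allele`, or a Beta
draw with that mean and SD `meth_sd` to emulate inter-individual
variability), and mechanistic signals as above. Defaults mirror a
two-population cell-line panel: populations `EUR`/`EAS`, 18 samples
each, and strongly differentiated alternate-allele frequencies
(default 0.2 vs 0.7, `MAF_diff = 0.5`) for the canonical confounded
scenarios in `scenario_locus()`. Everything is deterministic given the
seed, and the genotype/methylation truth is returned alongside the
matrices.

What the generator deliberately does **not** emulate: batch and slide
effects (none were needed for the phenomena studied; the design leaves a
hook in the parameters rather than a model), under-a-probe SNPs and
indels, repeat/multi-mapping probes, linkage between loci, strand- and
orientation-resolved probe design, and the platform's within-array
normalisation (a pass-through; matrices are analysed as produced).
Passing the round-trip suite therefore shows that the *mechanism* of
SNP confounding is reproduced and detected, not that the classifier
thresholds transfer unchanged to any real data set.

## The analysis chain

`compute_beta()` implements the ratio above (offset 0 by default; the
platform's +100 convention is available), `compute_m()` the logit
transform after clamping beta into [0.001, 0.999], so
`|M| <= log2(999)`. Differential methylation
(`differential_methylation()`) is a per-probe two-sided Student's t-test
on M values (equal-variance by default, Welch behind a flag) with
Benjamini–Hochberg q-values; probes with `q < 0.05` are `pop_diff` when
`|M_av_diff| > 1` and `weak_diff` otherwise (an optional lower screen,
conventionally 0.3, demotes tiny differences to `ns`). Zero-variance
probes with equal means get `p = 1` by convention, with a message.
`global_methylation_test()` compares per-sample mean betas;
`detection_filter()` scores each measurement's total intensity against a
normal background model (upper-tail p, fail if `p > 0.01` in any
sample) — the background model is explicit because platform
implementations differ; `background_from_params()` derives one from the
simulation parameters. `neighbor_probes()` scans the manifest for probes
within an inclusive 500 bp window.

## The pattern classifier

`classify_beta_pattern()` fits univariate Gaussian mixtures with 1–3
components (mclust, model "V"), selecting by BIC with ties resolved
toward fewer components. mclust's model-based hierarchical
initialisation is deterministic, which replaces restart-based seeding
and makes calls reproducible. Components that do not form distinct
modes are merged: adjacent means closer than `min_sep = 0.15` beta
units, *or* closer than 1.5 times the sum of their SDs (heavily
overlapping components describing one broad mode — this keeps smooth
Beta-shaped clouds from being split in two). Labels:

* 3 modes → `trimodal`;
* 2 modes → `flattened_high` if the lower mode consists of low-intensity
  samples and sits at mean ≥ `flat_min = 0.35` (background-inflated
  betas), else `bimodal`;
* 1 mode → `cloud` if its SD exceeds `cloud_sd = 0.12`, else
  `flattened_high` when the mode is high (> 0.6) with low-intensity
  samples present, else `clean_unimodal`.

The extension of `flattened_high` to the two-mode case is a deliberate
design choice: under the mechanistic model the flattened scenario
(position-1 C>T under a type I probe with methylated under-a-probe CpGs)
still resolves its non-extending genotype as a second mode near 0.55–0.6,
so a one-mode-only rule could never fire; the position of the lower mode
(≥ 0.35 vs ≈ 0.2) plus the low-intensity flags is what separates the
flattened from the bimodal mechanism. All thresholds are calibrations
validated by the round-trip suite — the original pattern labels are
visual categories, not published numbers — and are exposed in
`pattern_params()`.

`low_intensity_flag()` marks samples whose total intensity falls below a
quarter of the cohort median — the practical test for "both channels
collapsed". `genotype_concordance()` scores the best order-preserving
one-to-one matching between beta-ordered clusters and genotype classes,
in either orientation (the beta order of genotypes flips with the
methylation state of the CpG allele).

When one genotype class is absent from a cohort, the classifier reports
the number of modes it actually sees (a tri-modal mechanism with no
alternate homozygotes sampled is reported as bimodal); interpretation
against genotype data is left to `confound_report()`.

## Population-genetic annotation

`fst_two_pop()` defaults to Hudson's two-population estimator — chosen
because it is unbiased-by-construction for two populations, stable at
the small, equal sample sizes of a cell-line panel, and assumes nothing
about a global ancestral population; the Weir–Cockerham theta (on allele
counts, with Hardy–Weinberg-implied heterozygosity) is available behind
`estimator = "wc"` for sensitivity analysis. Raw estimates are kept (they
can be negative under sampling noise); summaries truncate into [0, 1].
`maf_diff()` is the absolute alternate-allele frequency difference —
deliberately not folded minor-allele frequency, which is ambiguous when a
frequency crosses 0.5 between populations.

## Verdicts

`confound_report()` joins the differential categories, pattern labels
and SNP annotation into a per-probe verdict via a pure lookup table:
differential probes with multimodal or flattened patterns are
`snp_confounded` when a SNP is annotated in the interrogated CpG and
`suspected_snp` (genotyping recommended — the variant may be missing
from the annotation) when not; differential probes with cloudy or tight
unimodal patterns are `methylation_candidate` without an annotated SNP
and `ambiguous_snp_present` with one, since a SNP can mask a real
difference and discarding such probes outright would lose it.

## Numerical choices and degenerate inputs

* Beta with both signals zero (offset 0) is undefined and propagates as
  `NA`; such probes are dropped from global means with a logged count.
* The M clamp bounds test statistics; M is strictly increasing in beta
  on the clamped interval.
* Mixture fits need at least 10 samples; fewer is refused rather than
  classified unstably. Pattern labels are invariant under sample
  permutation.
* BH q-values are validated against a brute-force step-up; Fst
  denominators of zero (both populations fixed for the same allele)
  return 0 with a message.
* Beta-distribution moment matching for `meth_sd` caps the variance just
  below `m (1 - m)` so the shape parameters stay positive.

## Problem sizes

The validation suite runs, per canonical scenario, 100 replicate
cohorts of 200 samples per population for pattern recovery; 200 cohorts
at the study's 18 + 18 design for the confounding-reproduction rate;
10,000 clean probes for the type-I error of the differential test; and
100 samples per population for parameter recovery. These sizes hold the
Monte-Carlo error of each rate well below the margins being asserted
while keeping a full run in tens of seconds.

## Known limitations

Only the top strand and the downstream probe orientation are modelled;
real manifests mix strands and orientations. The mismatch penalty family
is qualitative calibration, not a thermodynamic model (no
nearest-neighbour duplex energies). Detection p-values use an explicit
normal background model rather than any platform's proprietary
definition. Under-a-probe SNPs — as opposed to under-a-probe CpGs — are
not simulated. Real-data preprocessing (IDAT parsing, within-array
normalisation, annotation lookups) is out of scope; the package consumes
and emits plain TSV matrices.
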