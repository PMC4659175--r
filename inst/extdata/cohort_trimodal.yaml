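# Example cohort: one SNP-confounded type II probe (C>T in CpG position 1,
# methylated CpG allele, strongly differentiated allele frequencies) and
# one clean partially methylated probe, 18 samples per population.
populations: [EUR, EAS]
n_per_pop: 18
seed: 1
params:
  scale: 1000
  background: 50
  sdlog: 0.15
loci:
  - locus_id: cg23556238
    infinium_type: II
    meth_cpg_allele: 1.0
    snp:
      cpg_position: 1
      alt_base: T
      freq_alt: {EUR: 0.20, EAS: 0.70}
  - locus_id: cgx_clean
    infinium_type: I
    meth_cpg_allele: {EUR: 0.15, EAS: 0.35}
    meth_sd: 0.10
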