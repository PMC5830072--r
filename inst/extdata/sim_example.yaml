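# Example configuration for `nonaddscan simulate` / run_simulate():
# 60 paternal half-sib families of 10 genotyped offspring, 1,000 markers,
# one planted dominance QTL, background heritability 0.3.
n_sires: 60
offspring_per_sire: 10
n_snps: 1000
maf_low: 0.05
maf_high: 0.5
sigma_u2: 0.3
sigma_e2: 0.7
mu: 0
seed: 11
qtls:
  - snp_index: 137
    model: dominance
    effect: 0.9
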