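# Packaged default run: the reference synthetic world.
# 8 species (2 focal, placed in distant lineages), 4 replicates each,
# 5,000 orthologous genes, 50 + 50 planted convergent genes shifted by
# 2 log2 units in the focal species, NB dispersion 0.1. All analysis
# parameters take the study defaults (E-value 1e-5, TMM trims 0.30/0.05,
# |log2FC| >= 1, BH FDR < 0.05, 1 kb promoters, >= 2 CpGs at depth > 5).
seed: 1
tissue: liver
outdir: convexpr_run
simulate: {}
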