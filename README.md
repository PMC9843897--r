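# convexpr — cross-species convergent gene expression analysis

When two distantly related lineages independently evolve the same
specialization — the textbook case being the giant panda and the red panda,
two carnivoran lineages that separately adopted an obligate bamboo diet —
the genes whose expression shifted **in the same direction in both
lineages, relative to every non-specialist species**, are candidates for
the molecular basis of the shared adaptation. `convexpr` is an R package
for exactly this comparison. It is aimed at comparative transcriptomics
practitioners who have per-species gene-level count matrices and pairwise
protein homology tables and want a tested, deterministic path to convergent
gene lists.

## What it computes

* **1:1 single-copy orthology** — longest isoform per gene, reciprocal best
  hits (lowest E-value, ties by bit score then subject ID; E ≤ 1e-5), and
  orthogroups as full RBH *cliques* across all species, guaranteeing
  single-copy 1:1 semantics.
* **GeTMM normalization** — reads per kilobase with species-specific gene
  lengths, then trimmed mean of M-values (double trim 30 % on M, 5 % on A,
  precision weights) computed jointly across all samples:
  `value[g,s] = RPK[g,s] / (Σ_g RPK[g,s] · f_s) · 10⁶`.
  A gene is kept only if its count exceeds 0 in every sample of every
  species.
* **Differential expression** — per focal–background species pair, a
  common-dispersion negative-binomial *exact* test (variance `μ + φμ²`,
  conditioning on per-gene totals after libraries are rescaled to the
  geometric mean), Benjamini–Hochberg adjustment, DEGs at
  `|log2FC| ≥ 1` and `FDR < 0.05`.
* **Convergence calling** — genes that are direction-consistent DEGs versus
  *every* background species in *both* focal species:
  `convergent_up = shared_up(focal₁) ∩ shared_up(focal₂)`, likewise down.
* **Descriptive layer** — log₂(x+1), sample PCA (`prcomp`, centred),
  Spearman correlation clustering (complete linkage, Newick export),
  2^-ΔΔCt qPCR quantification.
* **Enrichment** — hypergeometric upper-tail over-representation
  (`P[X ≥ k]`) against GMT-like term maps with BH correction.
* **Promoter methylation** — strand-aware 1 kb promoters upstream of the
  TSS; level `Σ mC / Σ(mC+C)` over CpGs with depth > 5, requiring ≥ 2
  passing CpGs; per-promoter two-sided Welch t-tests between groups.
* **Synthetic worlds with planted truth** — NB counts with species effects
  and planted convergent genes, matching hit tables, cytosine reports, and
  term maps, so the whole pipeline is validated by sensitivity/FDR against
  a known answer.

## Worked example

Run the packaged demonstration world (4 species, 2 focal, 400 genes,
10 + 10 planted convergent genes) end to end:

```sh
Rscript inst/cli/convexpr.R run-all --config inst/extdata/config_demo.yaml --outdir demo_out
#> convergent up: 10 down: 9
#> report: demo_out/report.json
```

The run report records every stage. For this config it contains:

| quantity | value | meaning |
|---|---|---|
| `orthology.n_orthogroups` | 400 | all 400 planted orthogroups recovered from the hit tables |
| `convergence.shared.sp01` | 21 up / 14 down | DEGs of focal species 1 shared across both backgrounds |
| `convergence.shared.sp02` | 14 up / 18 down | same for focal species 2 |
| `convergent_up` / `convergent_down` | 10 / 9 | direction-consistent intersection of the two focal species |
| `truth_score` | sensitivity 0.95, FDR 0 | 19 of 20 planted genes recovered, no false calls |
| `methylation` | 40 tested, 10 significant | exactly the 10 planted differential promoters at p < 0.05 |

The same call with `config_default.yaml` runs the reference world (8
species, 5,000 genes, 50 + 50 planted genes at |log2FC| = 2, φ = 0.1) in
about two minutes; across seeds it yields convergence sensitivity
0.93–0.97 at empirical FDR ≈ 0, with PCA replicates clustering by species.

Equivalent R session:

```r
library(convexpr)
report <- run_pipeline(system.file("extdata", "config_demo.yaml",
                                   package = "convexpr"))
report$stages$convergence$truth_score
```

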