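---
title: "Detecting convergent gene expression across species: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergent gene expression across species: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convexpr)
```

## The scientific problem

When two distantly related lineages independently adopt the same ecological
niche — the canonical example being the giant panda and the red panda, two
carnivorans that separately evolved an obligate bamboo diet — the genes whose
expression shifted *in the same direction in both lineages, relative to every
non-specialist relative*, are candidates for the molecular basis of the
shared adaptation. convexpr implements that comparison as a reusable,
fully tested pipeline, from per-species count matrices and pairwise protein
hit tables to convergent gene lists, enrichment, and promoter methylation
scores, with a synthetic-data generator that plants a known truth so every
stage can be validated end to end.

## The pipeline model, stage by stage

**1:1 orthology.** Within each species only the longest protein isoform per
gene is retained (ties broken by lexicographically smallest isoform ID, so
the choice is order-invariant). For every species pair, the best hit of each
protein in each direction is the hit with the lowest E-value, ties broken by
higher bit score and then lexicographic subject ID; pairs that are mutually
best are reciprocal best hits (RBH). Hits above the E-value cutoff
(default 1e-5) are discarded at read time. A tuple with one gene per species
becomes a 1:1 orthogroup only if *every* pairwise link inside the tuple is
an RBH pair (a clique). We deliberately use clique intersection rather than
transitive chaining or graph clustering: because best hits are unique within
a pair, cliques guarantee strict single-copy 1:1 semantics, and the planted
orthology in the synthetic world is recovered exactly. Graph-clustering
orthology tools reduce orthogroups to 1:1 sets in tool-specific ways; the
clique rule is this package's explicit, reproducible choice.

**GeTMM normalization.** Cross-species comparison must correct for both
gene length (orthologues differ in length between species) and library
size/composition. Counts are first converted to reads per kilobase (RPK)
using each species' own gene length; trimmed-mean-of-M (TMM) scaling
factors are then computed on the joint RPK matrix of all samples, and each
sample is put on a per-million scale using its factor-adjusted RPK library
size:

    value[g, s] = RPK[g, s] / (sum_g RPK[g, s] * f_s) * 1e6

TMM uses the canonical defaults: 30% two-sided trim on log-ratios, 5% trim
on average log-expression, inverse-asymptotic-variance precision weights,
and the reference sample whose 75th-percentile relative expression is
closest to the mean of 75th percentiles. Our implementation is checked in
three independent ways: a brute-force mean-of-M oracle (trims zero, weights
off), edgeR's `calcNormFactors` on random matrices, and invariance
properties (factors of 1 for identical or globally rescaled samples;
normalized values unchanged under any positive rescaling of one sample's
counts).

TMM factors could be computed per species group or jointly across all
samples of a tissue; we compute them jointly against one global reference,
the published usage of the gene-length-corrected TMM method (a per-species
route would leave cross-species composition bias uncorrected). Species
labels enter only the
expression filter and the test design. The filter retains a gene only if it
has a count above zero in every sample of every species, which also
guarantees finite M-values in all pairwise TMM comparisons.

**Differential expression.** Production analyses of this kind usually
delegate to edgeR's GLM machinery. We substitute a *common-dispersion NB
exact test*, a deliberate methodological choice: libraries are equalized by linear
rescaling to the geometric-mean size and rounding, and, conditional on each
gene's total, the two-sided p-value sums the probabilities of all group-A
sums at most as likely as the one observed (group sums of i.i.d. NB
variables with variance mu + phi mu^2). Everything is enumerable, so
p-values are verified against an independent convolution oracle, and
calibration is tested directly (null rejection rate, KS distance to
uniform). The common dispersion is estimated by a method-of-moments median
across genes. Fold changes use a 0.5 pseudocount per group mean so that
zero groups stay bounded. In the pipeline the tests run on count-scale
values with each gene's species-specific length bias divided out
(`count * gm_length / length`); an early design that tested on RPK values
was rejected because dividing counts by kilobases discards counting
information and visibly destroys power for low-expression genes.

**DEG and convergence calling.** A gene is a DEG when |log2FC| >= 1 and
BH-adjusted p < 0.05 (the `>=` reading is the only coherent one — a `<`
reading would declare most of the genome significant; both thresholds are
configurable). For each focal species, the *shared* up- (down-)
regulated set is the intersection of its DEG sets against every background
species with consistent direction; `min_support` can relax "every" to "at
least k". Convergent genes are the per-direction intersections of the two
focal species' shared sets. Each focal species is compared only against the
non-specialist background, not against the other focal species (a flag can
include it). Benjamini–Hochberg adjustment is implemented from scratch and
checked against a brute-force step-up oracle.

**Descriptive layer.** PCA (samples as observations, genes centred, not
scaled, via `prcomp`), Spearman correlation between samples with
average-rank ties, and complete-linkage clustering on 1 - rho, serialized
as Newick. qPCR support uses the standard 2^-ddCt relative quantification.
Pseudocount 1 before log2 keeps zeros at zero.

**Enrichment.** Hypergeometric upper-tail over-representation with the
focal species' full annotation as the default universe; terms without
overlap are not tested; BH across tested terms. Verified against exhaustive
enumeration of draws for all universes up to size 15.

**Promoter methylation.** Promoters are the 1,000 bp upstream of the TSS,
strand-aware ([TSS-1000, TSS) on +, [end, end+1000) on -, clipped at the
contig start). A CpG passes coverage when it has *strictly more than* five
reads ("more than five" read strictly: depth 5 fails, 6 passes,
configurable); a promoter is reported when at least two CpGs pass, and its
level is the pooled ratio sum(mC) / sum(mC + C) over passing CpGs.
Group comparisons use a two-sided Welch t-test on per-sample promoter
levels rather than pooled reads or per-CpG tests — per-sample levels match
a replicated WGBS design and keep biological replication as the unit of
inference (a pooled-variance flag exists) — with explicit degenerate
handling: equal constant groups give p = 1.

## The synthetic world: what it emulates, and its calibration

`sim_config()` describes the reference world: 8 species, the first two
focal, 4 replicates each, 5,000 orthologous genes, NB counts with
dispersion phi = 0.1 (between-replicate CV ~32%, typical for mammalian
tissue panels), expected counts proportional to library size x gene length
x relative expression, library sizes uniform on 2–5 million over the 5,000
gene panel (proportionally matching the 20–40 M reads over ~20,000 genes of
real libraries), and 50 + 50 planted convergent genes shifted up/down by
2 log2 units in both focal species.

Species effects have two components, and this structure is the package's
main design decision:

* a small i.i.d. wobble (sd 0.1 log2) on every gene — conserved orthologues
  drift a little in expression everywhere;
* strong lineage divergence (sd 1 log2) on a random 25% of *non-planted*
  genes, generated as 2-D loadings against species positions on a unit
  circle, with the focal species placed on opposite sides.

Two acceptance properties jointly constrain this choice, and i.i.d.
Gaussian species effects cannot satisfy both. Planted-truth recovery needs
small effects on planted genes: with per-species effect sd s, the true fold
change of a planted gene versus background b is 2 +/- (e_f - e_b), and the
call must clear |log2FC| >= 1 in all 12 focal-background comparisons, so
s >~ 0.4 collapses sensitivity. PCA separation of species needs large
between-species variance: with n = 32 samples and p ~ 5,000 genes the top
noise eigenvalue is ~ sigma_noise^2 p / n, and isotropic species effects
spread their variance over 7 dimensions, of which PC1/PC2 capture an
arbitrary 2 — two species can collide in the projection even when the
effects are large. The low-rank circle geometry resolves both tensions at
once: species means lie exactly in a plane (PC1/PC2 capture it fully; no
projection collisions), and placing the focal species at opposite positions
makes lineage-driven *false* convergence geometrically impossible, because
their lineage effects are equal and opposite for every gene. Exempting the
planted genes from the strong component is not a convenience: a planted
"convergent" gene carrying a large confounding lineage shift would not
actually be convergent in the generative model, so the truth labels would
be wrong, not merely hard.

The opposite placement also mirrors the real system — the two bamboo-eating
lineages are not sister taxa; their last common ancestor is shared with the
non-specialist background.

These parameters were fixed by design-time power analysis (summarized
above) plus a verification run, before the acceptance suite was frozen;
across four arbitrary seeds the world gives convergence sensitivity
0.93–0.97, empirical FDR 0, and species-pure PCA neighbourhoods.

What the generator does *not* emulate: read-level artifacts (mapping bias,
multi-mapping, 3' bias), phylogenetic covariance among background species,
isoform switching, and correlated gene modules. A green acceptance suite
therefore establishes that the statistical machinery recovers a planted
convergent signal under realistic count noise and strong lineage structure
— it does not certify performance on any real dataset, and published
convergent-gene counts from real data additionally depend on sequencing
depth, annotation quality, and GLM internals this package deliberately
replaces with an enumerable test.

The methylation generator draws per-CpG depth Poisson(30) over 10 CpGs per
1 kb promoter and methylated counts binomially around group-level truths
(0.8 vs 0.2 for differential promoters), which reproduces the coverage
regime in which the ">5 reads, >=2 CpGs" filter is meaningful; shallow
depth (mean 3) makes most promoters unreported, as expected.

## Numerical choices and degenerate inputs

* TMM returns factor 1 when no genes are shared or all M-values vanish;
  factors are rescaled to geometric mean 1 (tolerance 1e-9 in tests).
* The exact test uses log-space probabilities normalized per gene and a
  `(1 + 1e-10)` tie tolerance when summing outcomes "as extreme as
  observed"; all-zero genes give p = 1, log2FC = 0; phi = 0 falls back to
  the exact conditional binomial.
* BH is the step-up `min` over tail slopes, capped at 1, stable under
  permutation, monotone in every input.
* Spearman: average ranks; a constant sample is an error naming the sample
  rather than a silent NA.
* Welch df via Welch–Satterthwaite; zero pooled variance with equal means
  gives p = 1, with different means p = 0.
* Promoter clipping at the contig start can shorten a promoter below
  1,000 bp; length is never padded.
* All `simulate_*` functions derive independent RNG streams from
  `seed + {0,1,2,3}`, so each sub-generator is reproducible in isolation
  and the pipeline is bit-identical under reruns of one config.

## Known limitations

* The NB exact test uses one common dispersion per comparison; strongly
  gene-specific overdispersion would be under- or over-corrected (tagwise
  dispersion shrinkage is out of scope by design).
* Clique orthology is conservative: a single missing RBH link drops the
  orthogroup; with many fragmented annotations the joined matrix shrinks.
* Hit tables are gene-level in this artifact's interfaces; protein-to-gene
  mapping for real proteomes must happen upstream of the readers.
* The enrichment stage does no GO-graph propagation; terms are literal gene
  sets.
* Runtime of the exact test grows linearly in per-gene totals; very deep
  libraries (>100 M reads) would motivate a saddlepoint or asymptotic
  shortcut that the package intentionally omits in favour of enumerability.
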