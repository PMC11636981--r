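---
title: "Methods: co-expression networks and carbon fixation rates for a vent symbiont"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression networks and carbon fixation rates for a vent symbiont}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventnet)
```

## The scientific problem

The giant tubeworm *Riftia pachyptila* hosts a sulfur-oxidizing
chemoautotrophic endosymbiont that carries genes for two carbon fixation
pathways: the Calvin–Benson–Bassham (CBB) cycle, keyed by RuBisCO, and the
reductive tricarboxylic acid (rTCA) cycle, keyed by ATP citrate lyase.
High-pressure aquarium experiments expose worms to treatments where
sulfide, oxygen, nitrate and hydrogen are individually replete or
limiting, and ask two questions:

1. **How fast is inorganic carbon fixed** under each treatment, measured
   by ¹³C-bicarbonate labelling of the seawater DIC and isotope-ratio mass
   spectrometry of the symbiont-bearing trophosome tissue.
2. **How does symbiont gene expression reorganize** across treatments,
   analysed by pairwise differential expression and a weighted gene
   co-expression network whose modules are related to the substrate
   conditions, with hub genes and the first-neighbor "alliances" of the
   two carbon-fixation pathways as the structural readout.

`ventnet` implements both analysis arms as tested, composable functions,
and ships a synthetic-data generator with planted structure so every stage
can be verified against a known ground truth without any data download.

## Tracer arithmetic

Isotope measurements arrive as per-mille delta values against the VPDB
standard, \(\delta^{13}C = (R_{sample}/R_{standard} - 1)\times 1000\),
with \(R\) the atomic ¹³C/¹²C ratio.  Ratios convert to atom percent
\(A\% = R/(R+1)\times 100\).  The fraction of tissue carbon replaced by
label over an incubation is the excess of the labelled tissue over the
natural-abundance reference, scaled by the label strength of the water:

\[ \%^{13}C_{inc} = \frac{A\%_{lab} - A\%_{nat}}{A\%_{wat} - A\%_{nat}} \]

and the dry-weight rate is
\(\mathrm{Dry}C_{inc} = ((W^{13}C_{inc}/\mathrm{MW})\times 1000)/(\mathrm{DW}\times \mathrm{hours})\)
with \(W^{13}C_{inc} = \%^{13}C_{inc}\times \mathrm{DW}\) and MW = 13.
Two consequences of this definition are asserted as test properties: the
tissue dry weight cancels algebraically in the rate, and the rate is
linear in the label excess.  The formula is implemented exactly as the
protocol states it, including the \(\times 1000\) factor; the printed unit
(µM ¹³C g⁻¹ h⁻¹) is carried through to output metadata without
reinterpretation, and an optional tissue carbon-content fraction (default
1.0, i.e. off) can relax the implicit assumption that dry weight is all
carbon.  Wet-weight rates multiply by the dry-to-wet weight ratio.
`R_standard` defaults to the conventional VPDB ratio 0.0112372 and is an
explicit argument everywhere, since delta values are meaningless without
it.

Substrate uptake in the flow-through aquaria is
\((c_{in} - c_{out})\times \mathrm{flow}/\mathrm{biomass}\) per timepoint.
The flow term is explicit: concentrations alone cannot yield µmol h⁻¹, so
flow (of order 50 ml min⁻¹ in these systems) is a required input.
Negative rates (net production) are retained and flagged rather than
dropped.

The simulator inverts these equations exactly: given true wet-weight
rates, it computes the tissue delta a worm would show and adds per-mille
Gaussian measurement noise.  A noiseless round trip recovers rates to
relative error below 1e-9; with 0.2 per-mille noise over 100 simulated
worms the mean recovered/true ratio stays within 2% of 1.  Default true
rates span 1–24 µmol g⁻¹ h⁻¹ wet weight, the magnitude range these
incubations produce; the water label defaults to 2.64 atom percent ¹³C of
the DIC, and the natural-abundance tissue reference to −15‰, typical of
rTCA-influenced vent tissue.

## Differential expression

Counts are filtered to genes with CPM strictly above 1 in at least 3
samples, normalized with TMM (trims fixed at 30% on M-values and 5% on
A-values, reference column the library whose upper quartile is closest to
the mean upper quartile — the published defaults of the method), and
modelled on log2-CPM with a 0.5 prior count.  Precision weights are
computed at two levels: observation-level weights from the lowess mean–
variance trend of the log-counts, and per-sample quality weights that
down-weight noisy libraries, so outlying samples are kept rather than
discarded.  Both are returned and can be used separately or combined; the
combined product is the default, since the published description ("precision
weights for each sample") does not fully pin down the level.  Sample
weights are rescaled to mean 1, which leaves test statistics unchanged.

The linear model is a cell-means design over treatments; comparisons are
extracted as linear contrasts (the default layout yields five sulfide and
two oxygen replete-minus-limiting pairs), standard errors are moderated by
empirical Bayes (standard moments estimation; the robust variant is not
implemented and is recorded as a divergence in the run report), and
p-values are Benjamini–Hochberg adjusted within each contrast.  A gene is
flagged DE at adjusted p ≤ 0.05 and |log2FC| ≥ 1.

Calibration is checked on a two-group null design (two treatments × 6
worms, one contrast, 2,000 genes, no planted effects): the raw-p fraction
below 0.05 must sit in [0.035, 0.065] and no gene may pass the combined
flag.  The two-group layout is the canonical calibration experiment; a
many-contrast null multiplies the chance of a stray family-wise rejection
without saying anything more about calibration.  Power is checked the same
way with 50 genes carrying a planted 4-fold change at n = 6 vs 6, where at
least 90% recovery is required.

## The co-expression network

The network stage consumes normalized log-expression of the most variable
genes (the study-scale convention is the top 2,500; the synthetic default
uses all filtered genes since fewer are simulated).  The signed-hybrid
adjacency is \(a_{ij} = \max(\mathrm{cor}(i,j), 0)^\beta\): negative
correlations are zeroed, positive ones raised to the soft-thresholding
power.  β defaults to 8, the value at which the study data adhered best to
scale-free topology; `pick_soft_threshold()` reproduces that choice
procedure, returning the smallest candidate power whose signed fit index
reaches 0.8.  The fit index bins connectivity into 10 equal-width bins on
the log10 scale and regresses log-frequency on log mean connectivity —
equal-width binning is the cited methodology's construction, and the only
one for which a power-law degree sequence scores near +1 (equal-occupancy
bins would make the bin frequencies constant and the regression
degenerate).

Topological overlap is
\(\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij})/(\min(k_i,k_j) + 1 - a_{ij})\)
with \(\ell_{ij} = \sum_{u\neq i,j} a_{iu}a_{uj}\), diagonal 1; the matrix
implementation is checked against a literal triple-loop oracle to 1e-12.
Modules are detected by average-linkage hierarchical clustering on
1 − TOM with a **static** branch cut (default height 0.99) — the dynamic
tree-cut heuristic has unstated parameters, while the static cut is fully
specifiable and testable; both the height and the minimum module size
(default 30) are exposed.  Clusters below the minimum size become "grey"
(unassigned).  One behavior of the static cut worth knowing: genes with
near-zero TOM to everything can coalesce into a residual low-similarity
cluster rather than grey; on planted data this cluster is exactly the
noise-gene set and does not disturb recovery of the planted modules.
Module labels are colors assigned in decreasing size order from a fixed
palette so reruns are comparable.

Module eigengenes are the leading right singular vector of the gene-wise
z-scored module submatrix, sign-aligned to the module mean profile and
unit-normalized.  Modules whose eigengenes correlate at ≥ 0.75 (merge
height 0.25, the conventional default) are merged by single linkage —
chaining is intentional and covered by a dedicated test — and eigengenes
are recomputed.  Gene significance (GS) is the Pearson correlation of a
gene with a binary condition variable (1 = replete, 0 = limiting/absent),
module membership (MM) the correlation with a module eigengene; both use
asymptotic Student-t p-values with no multiplicity correction, as none is
stated for this statistic in the procedure being reproduced.  Network
correlations are computed on unweighted log-expression; a weighted variant
would be defensible but the unweighted reading is the default and the
choice is recorded in the run report.

## Hubs and first-neighbor alliances

The weighted network is thresholded into a simple graph: edges with TOM
strictly above 0.05, then an optional per-node top-k strongest-edge filter
(an edge survives if it is in either endpoint's top k; off by default,
matching the primary reading of the filter chain), then iterative removal
of nodes with degree ≤ 2 until a fixed point.  The degree comparator is
strict as printed, which means a bare triangle does not survive the
defaults; this is documented and pinned by a test.  TOM is the default
weight source because module structure in this methodology is TOM-based;
the source and filters are recorded as graph provenance.

Hubs are scored by maximal clique centrality:
\(\mathrm{MCC}(v) = \sum_{C \ni v} (|C|-1)!\) over maximal cliques,
enumerated exactly by Bron–Kerbosch with pivoting.  A node with an
edgeless neighborhood scores its degree (each incident edge is a maximal
2-clique), an isolated node 0.  Scores are verified against exhaustive
subset enumeration on small random graphs.  Ranking breaks ties by degree
then gene ID, so hub lists are deterministic.

First neighbors of the two pathway seed sets (the "CBB-like" and
"rTCA-like" gene sets) are the union of direct neighbors minus the seeds
themselves.  The alliance analysis builds the binary membership matrix
over neighbor sets, all exclusive intersection cardinalities (the UpSet
decomposition), pairwise shared counts and Jaccard indices, and
per-functional-category shared counts when an annotation table is given.

## Candidate genes for substrate limitation

For each condition the two modules with the highest mean |GS| are
searched; genes pass if |GS| > 0.2 with p ≤ 0.05 and own-module
|MM| > 0.8 (comparators strict as printed, pinned by boundary tests), and
are then filtered on the DE results: at least one of the condition's named
pairwise comparisons must be significant at adjusted p ≤ 0.05.  The mean
and SD of log2FC are taken over the comparisons that individually reached
significance.  MM is evaluated against the gene's own module eigengene,
the only reading under which the 0.8 threshold is meaningful inside the
top modules.  Contrasts are coded replete-minus-limiting, so candidates
with negative mean log2FC are labeled as increasing under limitation.

## What the synthetic generator emulates

`simulation_config()` defaults define the study conditions end to end:

| parameter | default | meaning |
|---|---|---|
| layout | 10 treatments × 3 worms | 30 samples, as in the sequenced cohort |
| module_sizes | 5 × 100 genes | planted co-expression modules |
| n_genes | 600 | 100 free genes are independent noise |
| effect_sizes | 2.0 (log scale) | module activity shift between replete and limiting |
| me_noise_sd | 1.0 | per-sample biological noise on module activity |
| loading_range | [0.7, 1] | gene-on-eigengene loadings |
| nb_dispersion | 0.1 | typical bulk RNA-seq biological dispersion |
| baseline_logmean_range | [2, 6] (natural log) | ~7–400 counts at 1e6 reads |
| libsize_range | [0.8, 1.2] × 1e6 | per-sample sequencing depth |
| n_seed_genes | 10 per pathway | highest-loading members of modules 1 and 2 |

Module activity is linear in the binary substrate states plus Gaussian
noise, which makes GS, MM and DE recovery analytically predictable: with
effect 2.0 and noise SD 1.0, member genes have expected GS ≈ 0.67 for a
balanced condition, MM ≈ 0.9, and expected |log2FC| ≈ 2.5 in the matched
treatment pairs — comfortably inside the triple-filter thresholds, which
is what makes ≥ 90% recovery a fair requirement rather than a tuned one.
Counts are negative-binomial with a shared dispersion, the noise model the
TMM/precision-weight pipeline assumes.  The ten treatments are arranged so
five pairs differ only in sulfide and two only in oxygen, reproducing the
five-sulfide/two-oxygen comparison structure; oxygen is deliberately
unbalanced (24 replete vs 6 limiting samples), so oxygen candidates have
less power than sulfide candidates — a realistic asymmetry worth keeping
in mind when interpreting a run with few or no oxygen candidates.

The two pathway seed sets are planted in two different modules with zero
cross-loading, so their true first-neighbor sets are disjoint; the
recovered sets sharing at most one gene is then a meaningful end-to-end
check of the whole network arm.

What the generator does **not** emulate: host/symbiont read competition
(counts are simulated post-mapping), time-course dynamics within a
treatment, gene-specific dispersions, batch effects, and annotation
structure.  Passing tests therefore demonstrate that the pipeline
recovers the structure it assumes, at realistic noise levels — not that
real trophosome libraries satisfy those assumptions.

## Numerical choices and degenerate inputs

* CPM columns sum to exactly 1e6; a zero-count sample is an error naming
  the sample.
* Zero-variance genes are an error in adjacency construction (correlation
  undefined) but are dropped with a warning inside the eigengene SVD.
* Correlation p-values clamp at the smallest positive double so the
  `p ∈ (0, 1]` invariant holds even for |r| = 1.
* All-equal connectivity makes the scale-free fit's binning degenerate and
  is an error, as is a module-size minimum below 2.
* Writers emit 10-significant-digit floats and stable orderings, so equal
  seeds give byte-identical outputs.
* All randomness flows from one master seed recorded in the run report;
  derived stage seeds are small fixed offsets.

## Problem sizes

The default configuration (600 genes × 30 samples) runs the full pipeline
in a few seconds; DE calibration and power checks use 2,000 genes × 12
samples; oracle equivalence checks use networks of up to 25 nodes (TOM)
and 12 nodes (MCC), where exhaustive enumeration is exact.  These sizes
were chosen so that the planted structure is recovered with comfortable
margins while every oracle remains literally brute-force.

## Known limitations

* The static branch cut can split one planted module across two labels
  when noise is high; the merge step usually repairs this, but the
  dynamic-tree-cut refinement used at study scale is not implemented.
* The robust empirical-Bayes hyperparameter variant is not implemented.
* Block-wise network decomposition is absent, so gene sets much beyond
  ~5,000 will be slow and memory-hungry.
* Oxygen-limitation candidates are under-powered at the default design,
  as discussed above.
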