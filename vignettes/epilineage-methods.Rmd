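---
title: "Models and methods in epilineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in epilineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`epilineage` analyzes multimodal single-cell maps of histone modifications
(H3K27ac, H3K27me3, H3K4me3 from scCUT&Tag) and transcriptomes along
branching neural differentiation. This vignette explains the models the
package implements, the choices made where the methodology was genuinely
open, and what the synthetic-data generator does and does not emulate.

## Detection, not quantification

Single-cell CUT&Tag yields a few hundred fragments per cell over thousands
of peaks, so per-cell counts are nearly binary. Every chromatin statistic
in the package therefore operates on *detection*: a peak is detected in a
cell when it carries at least one fragment, and a group's signal is its
detection rate. Differential enrichment between regional identities is a
binomial logit GLM on binarized counts,

```
Y ~ n_fragments + region      (full)
Y ~ n_fragments               (null)
```

compared by a likelihood-ratio chi-square with `levels − 1` degrees of
freedom and Benjamini–Hochberg correction across peaks. The per-cell
fragment total enters as a covariate because deeper cells detect more
peaks at any true occupancy. Group effects are reported as sum-to-zero
(deviation) coefficients so each region has a signed effect relative to
the grand mean, alongside the log2 fold change of detection rates with a
0.01 pseudocount. Peaks detected in no or in all cells are reported with
`p = 1` and a `degenerate` flag rather than dropped, so joins never lose
ids.

## QC and normalization

The filters use the field's standard thresholds, with strict inequalities:
RNA cells need more than 2,000 and fewer than 1.5×10^5 UMIs, more than
1,000 detected genes and a mitochondrial fraction below 0.2; chromatin
cells need at least 200 fragments (H3K27ac, H3K4me3) or 100 (H3K27me3) —
cells exactly at the boundary are kept, since the rule removes cells with
*fewer* fragments. Expression and gene activity are log-normalized with a
scale factor of 10,000. Chromatin embeddings use TF-IDF
(`tf = count / cell total`, `idf = log(1 + n_cells / (1 + occurrences))`)
followed by truncated SVD, keeping components 2–30: the first component
tracks depth and is dropped by convention. The exact TF-IDF variant is not
fixed by common usage; this one is frozen by a golden test. Note that
duplicating a peak column perturbs the cell totals and hence the
embedding slightly — exact invariance under column duplication is
impossible with this `tf`; the geometry is stable to high precision.

Gene activity sums fragment (or peak) counts over the gene body extended
2 kb upstream of the TSS on the strand-appropriate side, clamped at
coordinate 0, then log-normalizes. Peaks are labeled `promoter` within
2 kb of a TSS, `distal` farther than 3 kb from every gene body, `other`
between.

## Clustering

High-resolution clusters come from Louvain community detection on a
Jaccard-weighted shared-nearest-neighbor graph (Euclidean kNN, `k = 20` by
default — the common single-cell default; the source methodology does not
state one). Clusters smaller than `min_cells` (default 10) are merged into
the nearest cluster by centroid distance: detection rates over
near-singleton clusters are meaningless — a singleton cluster reports
rate 1.0 for every peak it happens to detect and would defeat every
percentage rule downstream. When a stage-restricted cluster set is needed
(e.g. neuroepithelium-stage detection), cells of that sampling timepoint
group are clustered separately, mirroring per-group clustering practice;
with a few hundred cells per group, a coarse resolution with a 50-cell
floor keeps the rate maxima statistically meaningful.

## Cross-modality matching

Chromatin clusters are matched to RNA clusters on the correlation of
cluster-mean gene activity with cluster-mean expression over the shared
variable genes (the 1,000 most variable RNA genes present in the activity
matrix; the choice of feature set is configurable). Activating marks use
the correlation distance `1 − r`; H3K27me3 uses the negative correlation
distance `1 + r`, because Polycomb repression anti-correlates with
expression. The assignment is an integral minimum-cost maximum-flow on a
bipartite graph keeping each node's 10 cheapest edges, with uniform
capacities `ceil(max(n_a, n_b)/min(n_a, n_b))` so the larger side can be
fully matched, and a null node priced at the 99th percentile of all costs.
Flow enters through one side only: each cluster either buys a real
counterpart or pays the null price — this construction is what makes
expensive matches drop out rather than being forced, and with a null cost
above all real costs it reduces exactly to the optimal assignment
(verified against exhaustive enumeration and the Hungarian algorithm in
the tests). Equal-cost optima are broken deterministically toward the
lexicographically smallest pair via an infinitesimal index bias.
Unmatched clusters are afterwards given their minimum-correlation-distance
counterpart as an explicit fallback, and label transfer prefers matched
over fallback pairs, then lowest cost.

## Fate probabilities and the trajectory graph

Pseudotime is the rank along the first nontrivial diffusion component of
an adaptive Gaussian kernel on the kNN graph (`k = 50` by default, large
enough to bridge the thin corridors of transitioning cells between dense
states), oriented by a root hint and normalized to `i/N`. The transition
kernel up-weights forward edges, `w(u→v) ∝ exp(β (t_v − t_u))` with
`β = 4`, row-normalized — a documented stand-in for velocity-based
kernels that preserves exactly the two properties downstream math needs:
row-stochasticity and forward bias. Absorption probabilities solve the
absorbing-chain system `(I − Q) F = R` directly (sparse LU), summing over
the terminal cells of each state; rows sum to 1 by construction and the
solution matches long-run power iteration to 1e-8 in the tests.

The coarse trajectory graph connects clusters by kNN in fate-vector space
(cluster fate = mean of member-cell fate rows), keeps only edges running
forward in mean pseudotime and drops edges whose endpoints carry different
region labels (the root/neuroepithelium label is a wildcard). Strict
pseudotime ordering makes the result a DAG. The circular projection
places terminal states at `α_t = 2π(t−1)/n_t` and each cell at the
fate-weighted average of the anchors; condition enrichment is
`log2((local treated fraction + ε)/(global + ε))` over `k = 100`
neighbors in fate space, `ε = 1e-9`.

## Bivalent and switching regions

Candidate pairs are peaks of the two marks overlapping after a ±2 kb
extension. A pair is *bivalent* when both marks are detected in more than
5% of cells of at least one neuroepithelium-stage cluster and the pair is
regionally differential with opposite effect signs (both FDR < 0.05 with
|log2 detection fold change| > 0.25); each branch is then classified as
resolving by activation (H3K4me3 up, H3K27me3 down), repression, or
staying bivalent. A pair is *switching* when exactly one of
H3K27me3/H3K27ac exceeds the 5% neuroepithelium threshold and the other
gains in a branch where the first is depleted; calls where repression
resolves to activation carry `direction = "activating"` — the converse
(an active region acquiring repression) is reported as `"deactivating"`
so both biological directions are visible. The same pair can never be
both bivalent and switching: the 5% rule is exclusive.

## Pseudotime dynamics and priming

Cells are stratified into equal-occupancy bins (50, or 20 for focused
neurogenesis trajectories) after per-timepoint even subsampling across
modalities (down to the smallest modality, but never below 100 cells).
Chromatin-state tracks restrict to regions where all three marks exceed
5% detection in some bin, threshold each mark at its median detection
over those regions and bins, and label each bin by the combination of
marks above threshold. The H3K27me3 + H3K27ac combination — mutually
exclusive on the same residue — is labeled `conflict` by default: in
droplet data it usually reflects two distinct elements inside one merged
region, and silently calling it an "active promoter" (as one could)
invites misreading; the label map is configurable for users who prefer
that convention.

Binned profiles are smoothed by a cubic regression spline GAM with
GCV-selected smoothing (`mgcv`); the `cr` basis leaves linear trends
unpenalized, so constant and linear profiles pass through unchanged.
Multimodal profiles (z-scaled per feature so no modality dominates) are
compared by dynamic time warping with the symmetric step pattern and no
window — the local cost is the Euclidean distance between stacked per-bin
modality vectors, and the alignment is the textbook recursion
`D[i,j] = c[i,j] + min(D[i−1,j], D[i,j−1], D[i−1,j−1])`, implemented in
C++ and verified against an independent full-table recomputation.
Clustering of the DTW matrix uses k-medoids (PAM): DTW distances do not
live in a vector space, so medoid-based partitioning is the faithful
distance-native analogue of k-means.

The *first divergent bin* of a feature tests each bin against the first
(baseline) bin with the binomial detection test, BH-corrected over all
(bin, feature) tests of the run, and returns the earliest bin with
FDR < 0.05 and log2 detection fold change > 0.25 (decrease for repressive
marks). The *pseudotime lag* is the RNA bin minus the chromatin bin;
positive lags are epigenetic priming. One calibration caveat is worth
knowing: with the run-wide BH family, a panel containing many strongly
divergent features raises the BH threshold for everything, so flat
features face a mildly inflated false-divergence rate (~5–10% rather than
the nominal ~2% in our simulations). Correcting within each feature
instead repairs that but degrades exact-onset detection of truly
divergent features, whose own signals then inflate their within-feature
thresholds. The run-wide family is kept as the default behavior; analyses
that need strict per-feature specificity should test candidate features
against an independently chosen background panel.

## Perturbation statistics

Composition shifts are tested per cluster by the Cochran–Mantel–Haenszel
test stratified by sampling timepoint: common odds ratio
`Σ(a_k d_k/n_k) / Σ(b_k c_k/n_k)` and the MH chi-square, with a 0.5
continuity correction applied only when some cell of the table is zero
(the uncorrected statistic is otherwise better calibrated); strata with an
empty margin are dropped from that cluster's test and counted in the
output. Significance is flagged at FDR < 1e-4. Differential expression
uses the logistic model `treatment ~ gene + covariates` with an LRT
against the covariate-only null (FDR < 0.01 and |log2FC| > 0.1); perfect
separation triggers a ridge-penalized IRLS refit, flagged in the output.
Motif enrichment is a two-sided Fisher exact test on occurrence counts
(foreground versus background peaks), with a Haldane-corrected odds ratio
so extreme tables stay finite; motif occurrence tables are an input — the
package does not scan position weight matrices. Regions for the
perturbation motif analysis are peaks depleted on treatment
(log2FC < −1) within 10 kb of genes passing FDR < 1e-4 and log2FC > 1.

## The synthetic-data generator

`simulate_dataset()` emits one independent cell population per modality
along a fixed lineage: pluripotent cells (PSC) → neuroepithelium (NE) →
four regional branches (telencephalon, diencephalon, mesencephalon,
rhombencephalon), each ending in neurons. Defaults are sized to the
study-like regime that still runs in minutes on one CPU: 2,400 cells per
modality, 3,000 peaks per mark, 2,000 genes, median depths of 600/400/600
fragments for H3K27ac/H3K27me3/H3K4me3 and 9,000 UMIs for RNA (log-normal
with sdlog 0.3).

**Emission model.** Chromatin sparsity is a detection process: a peak
with state probability `p` is detected in a cell with probability
`1 − (1 − p)^{d/median(d)}` (binomial thinning in depth; exactly `p` at
median depth), and a detected peak carries `1 + Poisson(λ)` fragments
with `λ` calibrated per cell so expected totals match the depth draw.
This satisfies simultaneously the two empirical anchors the model is held
to: per-state detection rates track the planted probabilities, and
per-cell totals match the depth distribution. RNA counts are negative
binomial (size 2) with per-state relative means scaled to the cell's UMI
draw.

**Biological structure.** Genes fall into housekeeping, pluripotency,
neuroepithelial, branch-specific, pan-neuronal, primed and silent
classes; each gene carries one promoter peak per mark whose detection
follows its class (active marks track expression; H3K27me3
anti-correlates — lineage genes are Polycomb-marked in pluripotency and
in the branches that do not adopt the identity, neuronal genes are
Polycomb-repressed in progenitors). Marker activation sits at detection
0.4 and absent marks at 0.01 — absent means absent; detection levels
near the 5% rule would make every threshold crossing a coin flip.
Planted features with known truth: 50 bivalent regions (both marks ~0.3
in NE, resolved per branch by activation or repression), 50 switching
regions (H3K27me3 0.4 in NE, H3K27ac 0.45 in one target branch; the two
planted sets occupy disjoint genomic slot ranges so they never pair after
the ±2 kb extension), and 40 primed genes whose H3K27ac detection steps
from 0.05 to 0.6 at a planted bin of the 20-bin telencephalic trajectory
with RNA following 1–5 bins later.

**Continuity.** Profiles are continuous in pseudotime: each state's
profile is fully realized outside narrow transition windows
(half-width 0.03 pseudotime units) around its boundaries, inside which a
cell blends linearly with the parent state's profile — or, past the exit
boundary, with the next state on the path to the cell's sampled terminal
*destiny* (so late neuroepithelial cells are already primed toward one
branch, which is what lets pseudotime and fate probabilities be
re-estimated from the data rather than read from the truth table).
Sampling timepoint groups follow developmental time (EB before
pseudotime 0.17, Mid to 0.30, Late after), so transition-corridor cells
are sampled outside the neuroepithelium stage — as in a real sampling
design, where a timepoint is when cells were collected, not what they
are.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: doublets and ambient contamination, batch
and line effects, peak-calling artifacts and blacklist regions, nucleosome
periodicity, genuine GC/mappability biases, cell-cycle structure, and the
paper-scale census quantities that require hundreds of thousands of
cells. Recovery rates measured here certify the pipeline's logic and
calibration, not its performance on any particular real dataset.

## Problem sizes and determinism

Every stochastic step takes an explicit seed (`withr::with_seed`
internally), and the same seed reproduces a dataset exactly. The test
suite and the acceptance script run the full pipeline at the default
generator scale (2,400 cells per modality, 3,000 peaks per mark), the
priming panel at 20 bins × 150 cells, and the numerical oracles at the
sizes stated in the tests; the whole suite completes in a few minutes on
one CPU.
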