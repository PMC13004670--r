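---
title: "humoralkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{humoralkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humoralkit)
```

# Scope

humoralkit quantifies the B-cell / plasma-cell (PC) arm of the antitumor
immune response in checkpoint-blockade cohorts from four kinds of input:
single-cell BCR rearrangements (AIRR format) with per-cell IGH
constant-region UMI counts, per-sample cell-state compositions, multiplex-IHC
centroid tables, and serological assays (ELISA titrations, ELISpot wells,
duplicate-spotted proteome arrays). Because the patient cohorts such analyses
are run on cannot ship with a package, a seeded synthetic generator produces
every input with the statistical structure the methods assume, together with
a ground-truth registry that allows exact scoring of each downstream stage.

# Isotype assignment and clonotypes

Cells with a productive IGH rearrangement carrying a constant-region call are
assigned that isotype directly. Cells lacking a call are rescued from IGH
constant-region (IGHC) UMI counts: the argmax gene is accepted iff it has at
least `rescue_min_umis = 3` UMIs and at least `rescue_min_fraction = 0.6` of
the cell's total IGHC UMIs. These two thresholds are package decisions — no
published rule exists for this rescue — chosen so that ties and low counts
become `ambiguous` rather than guesses. A concordance matrix over cells with
both sources of evidence (BCR call x expression argmax) is returned so users
can check diagonal dominance on their own data.

Clonotypes are keyed by the heavy-chain junction within patient — grouping
never crosses patients, since identical CDR3 in two individuals is
convergence, not clonality. The key resolution is configurable
(`junction_aa` default, `junction_nt`, or `vj_junction_aa`): published
analyses rarely state which they used, so all three are exposed and the
nucleotide mode provably refines the amino-acid mode. A clone is *expanded*
iff it has two or more cells. `track_shared_clones()` keeps clones observed
in at least two (tissue, timepoint) compartments, supporting the two standard
queries: lymph-node-and-tumor sharing (trafficking) and pre-and-post sharing
(persistence under therapy).

# Compositional differential abundance

Per-sample category counts are converted to strictly interior proportions by
the multiplicative smoothing transform `y* = (y (n - 1) + 1/K) / n` (n =
sample cell count, K = categories), the standard device for putting observed
zeros inside the Dirichlet support. The regression model places a log link
on every concentration: `log alpha_ic = sum_k beta_kc x_ik` (the "common"
parameterization; precision is absorbed into the intercepts). Fitting is
BFGS with the analytic digamma gradient, intercepts initialized by method of
moments, `max_iter = 500`. The group effect is tested globally by the
likelihood-ratio statistic `2 (ll_full - ll_null)` on K degrees of freedom;
per-category effects are reported as `log2fc` of fitted mean proportions at
group = 1 vs 0, with Wald p-values BH-adjusted across categories. All-zero
design columns are tolerated (their coefficients stay pinned at zero) so a
degenerate contrast degrades to the null model instead of erroring.

Two calibration facts, both measured by the acceptance suite, deserve
emphasis:

* **The count layer matters.** The model is a Dirichlet on proportions, not
  a Dirichlet-multinomial on counts. With deep per-sample counts the null
  global LRT rejects at ~5-6% at nominal 5% (calibrated); at shallow depth
  (1,000 cells/sample, precision 50) the un-modeled multinomial dispersion
  inflates this to ~9%. Users testing compositions from few cells per sample
  should treat borderline global p-values with caution.
* **Power at small cohorts is modest.** For a 5%-abundance category with a
  true twofold (log2fc = 1) shift, 30 samples/arm and Dirichlet precision 50
  (a realistic patient-heterogeneity level: the category then ranges roughly
  0-12% across samples), the per-category Wald z averages ~3.3 against a
  BH-adjusted threshold of ~3.9; FDR < 0.05 is reached in only ~72-80% of
  replicates, and pushing precision to 100 barely helps. The corresponding
  acceptance expectation (>= 90%) is deliberately left red rather than
  tightening the generator world to an implausible precision (>~ 150); the
  effect *ranking* (top |log2fc| category) and the effect estimate
  (|bias| < 0.09 on the log2 scale) are reliable at these sizes.

The estimand note: applying a 2^1 multiplier to one category's mean and
renormalizing the simplex makes the true log2 mean ratio
`1 - log2(1 + p)` (~0.93 for p = 0.05), not 1.0; the fitted `log2fc`
estimates this renormalized quantity.

Tumor-vs-adjacent enrichment uses per-patient scores
`log2((p_tumor + eps) / (p_adjacent + eps))` with `eps = 1 / median(sample
cell count)` — a pseudocount scaled to sampling depth — tested per cluster
against zero by a Wilcoxon signed-rank test. The signed-rank test is
implemented in-package with an exact, tie-aware dynamic program over doubled
mid-ranks for n <= 25 (base R refuses exact p-values under ties) and a
continuity-and-tie-corrected normal approximation beyond.

# Spatial analysis

**TLS-like communities** are connected components, under "within 10 um of
each other", of the cells positive for any seed marker (CD3, CD8, CD20);
components below `min_community_size = 10` (an artifact default suppressing
singleton "communities") are dropped. Neighbor search uses a grid index;
tests verify exact agreement with brute-force BFS over the full distance
matrix.

**Radial profiles.** The community centroid is the flat-kernel mean-shift
mode (bandwidth 20 um, ~2 cell diameters; unstated upstream) seeded at the
member coordinate mean. "Effective community area" is the convex-hull area;
ring radii `r_k = R_eff sqrt(k/10)` with `R_eff = sqrt(A/pi)` realize ten
equal-area disks on the equivalent circle — a closed-form, testable reading
of "~10% of the effective area per ring" (equal-width annuli were the
alternative; the equal-area form is asserted exactly by
`pi r_k^2 = (k/10) A`). The outermost ring extends to the farthest member if
needed; collinear member sets fall back to a bounding-circle area with a
warning. Cumulative densities count marker-positive cells among *all* cells
near the centroid, not just members, because the profile's purpose is to see
non-seed markers (MZB1) infiltrate.

**Radial-gradient aggregates.** Aggregates grow from every query-positive
cell by 10-um linkage over 1-3 query markers; the aggregate area is the
*exact* area of the union of 10-um disks around members, computed by the
Green's-theorem arc decomposition (each circle's boundary arcs not covered
by another disk bound the union; the two-disk case is verified against the
closed-form lens formula and random cases against grid quadrature).
Enrichment is phenotype density inside aggregates over density outside
(field = bounding box). Two estimator caveats are inherent to the
construction and documented rather than hidden: phenotypes overlapping the
query markers are enriched by construction (each query-positive cell seeds
its own disk), and for dense query markers the disks spill over the field
edge, deflating enrichment by ~10-15%. The estimator is consistent for
phenotypes disjoint from sparse query markers, which is how the calibration
test exercises it.

**Infiltration scores.** An undirected KNN graph (k = 10, union
symmetrization) over all centroids is partitioned by Leiden (modularity
objective, resolution 1.0, RNG seed pinned at 0 — objective and resolution
are unstated upstream, and pinning is required for reproducibility). Each
community's score is exactly `MZB1+ cells / total cells`; the section-level
score is the unweighted mean over communities. Scores are invariant to
rigid motions of the coordinates (KNN distances are preserved).

# Serology

**ELISA titers.** The default cutoff is the negative-control mean + 3 SD
pooled over dilutions (the conventional serology rule; the upstream cutoff
is unstated and the rule is pluggable). The titration curve is fit by least
squares as readout ~ a + b log10(reciprocal dilution) — log-dilution
linearity is the standard behavior of serial dilutions — and the reciprocal
titer is `10^((cutoff - a)/b)` for negative slope. Curves never reaching the
cutoff give titer 0; crossings outside `[min/2, 2 max]` are clipped to the
bound and flagged `extrapolated_low/high` ("predicted or interpolated"
permits bounded extrapolation). Seropositivity is reciprocal titer > 100,
exactly: a titer of 100.0 is negative. The generator constructs readouts
linear in log10 dilution crossing the cutoff exactly at the true titer
before noise, and centers negative controls at `cutoff - 3 noise_sd`, so the
default cutoff rule recovers the construction cutoff in expectation and
exactly in the noiseless case.

**ELISpot.** A condition is positive iff its mean spot count exceeds 50 and
is at least twice the mean background; a sanity flag is raised when the
background mean exceeds 3 spots per well. Means across replicate wells are
used (whether the upstream rule used means or single wells is unstated).

**Seromics.** Duplicate spots are z-scored on the *log* intensity scale
against the array's negative-control distribution (median/MAD). The log
scale matters: for a skewed, roughly log-normal baseline, a raw-scale
MAD-z of 3 sits only ~2 SD up the log-scale tail and floods the calls with
~3% false hits per array; log-scale scoring restores the intended stringency.
An antigen is a hit only if *both* duplicates reach `z_threshold = 3`
(discordant duplicates are artifacts). Duplicates are then collapsed by
median and arrays quantile-normalized within channel for the reported
normalized signal and z. Arrays with fewer than 10 negative controls are
refused. Hit counts are summarized per patient/timepoint/channel/antigen
class and compared between response groups with Wilcoxon rank-sum tests.

# What the generator does and does not emulate

The cohort generator draws per-sample cluster-by-isotype compositions from a
Dirichlet-multinomial whose IgG1+ PC mean is multiplied by
`2^igg1_pc_logfc_R` in responder tumors; clone sizes follow a discrete power
law (exponent 2.5, truncated at the sample size) — a stand-in matching
heavy-tailed clone-size plots without claiming their exact law; junctions
are random in-frame 36-60 nt sequences (Cys...Trp) translated to amino
acids; IGHC UMIs give the true isotype a negative binomial (mean 8,
dispersion 2) and all others Poisson(0.2), creating both clean and ambiguous
rescue cases. Defaults mirror a neoadjuvant anti-PD-1 discovery cohort:
8 responders, 19 non-responders, tumor/adjacent/lymph-node samples pre and
post treatment, 500 cells per sample, baseline cluster proportions summing
over ten B/PC states, precision 50.

The spatial generator places aggregate members sequentially within 8 um of
an existing member (guaranteeing a single component under 10-um linkage) and
no farther than the aggregate radius from the center; centers are spaced so
inter-aggregate member gaps exceed `min_aggregate_gap_um`. Two guarantees
make ground truth exactly recoverable, and are generator properties rather
than claims about tissue: every aggregate member carries at least one seed
marker, and background cells within 12 um of an aggregate have their seed
markers forced negative.

Not emulated anywhere: somatic hypermutation and lineage structure, light
chains, sequencing error, doublets, image-level artifacts, spatial
transcriptomics, batch effects. A green test therefore establishes that the
algorithms compute their definitions correctly and recover known structure
under the stated noise — not that the stand-in distributions match any
particular cohort.

# Determinism

Every generator consumes a single integer seed through R's default RNG;
fixed seed implies byte-identical output tables. The pipeline derives
per-stage child seeds from the global seed by hashing stage names (stable,
collision-free across stages), records a configuration hash in every output
header and in the manifest, and two runs with identical configuration are
verified byte-identical end to end. Leiden partitions are reproducible
because the igraph RNG seed is pinned.
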