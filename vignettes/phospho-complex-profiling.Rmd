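---
title: "Phosphorylation-linked complex profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphorylation-linked complex profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comigratr)
library(dplyr)
```

## The problem

Affinity purification coupled to mass spectrometry (AP-MS) lists the proteins
that co-purify with a tagged bait, but it pools every complex the bait
participates in: it cannot say *which* interactors assemble together, nor
which phosphorylated form of the bait each assembly carries. `comigratr`
implements the analysis chain that resolves this, built around three
experiment types:

1. **AP-MS differential interactomics** — replicated pull-downs under
   treatments or bait point mutants, quantified from peptide intensities and
   tested protein by protein.
2. **AP-BNPAGE correlation profiling** — the purified complex mixture is run
   on a blue-native gel, 64 consecutive slices are excised, and every
   interactor and bait phosphopeptide acquires a migration profile over the
   fraction axis. Proteins that co-migrate as sharp, coincident peaks form a
   *module*: a candidate physical assembly with an attached
   *phosphosignature* (the bait phosphosites whose peptide profiles
   co-cluster with it).
3. **Targeted PRM panels** — parallel reaction monitoring with heavy
   reference peptides, used to follow selected interactors and phosphosites
   across a knockout cell-line panel.

A synthetic-data module generates ground-truth-labeled inputs with the same
statistical structure, so every stage is testable without any external
download.

## AP-MS quantification model

Protein intensity in a run is the **sum of its top two unique peptide
intensities** (`top_n = 2`; the sum rather than the mean keeps the statistic
monotone in each peptide and consistent for one-peptide proteins). Tables are
then **bait-normalized**: each run is divided by its bait intensity and
rescaled by the mean bait level, which removes purification-yield variation
and leaves the bait with zero variance across runs.

Missing values are imputed in two tiers, per protein and condition, on the
log2 scale:

* exactly one missing replicate — the **median of the observed replicates**
  of that condition (we read "replicates" as the observed replicates within
  the condition, not across conditions);
* more missing — draws from a normal centered at a **low percentile of the
  run's observed log-intensity distribution** (5% for label-free AP-MS, 1%
  for DIA-style tables), with standard deviation equal to the median
  within-condition replicate SD. This is standard left-censored imputation:
  peptides missing in most replicates are usually below the detection limit,
  so replacements are drawn from the censored tail rather than from the
  center of the distribution. A run with no observations at all falls back
  to the global intensity distribution.

Differential statistics are a **two-sided Welch t test** on log2 intensities
(the unequal-variance form is the robust default for triplicate MS data; a
pooled-variance switch exists), with the log2 fold change as the difference
of group means and **Benjamini-Hochberg** adjustment applied within each
contrast, matching per-comparison reporting. Interactor lists are gated at a
SAINT-style confidence score **strictly above 0.90**.

## Kinetic clustering

Treatment time courses are expressed as `log2(mean(treated) /
mean(untreated))` per time point and clustered by **fuzzy c-means**, which we
implement directly (memberships `u_ij = 1 / sum_l (d_ij/d_il)^(2/(m-1))`,
centers as `u^m`-weighted means). Profiles are z-scored first so clusters
capture response *shape*, not magnitude. Defaults are `c = 3` clusters and
fuzzifier `m = 2` — three response classes is what the treatment panel
resolves, and `m = 2` is the conventional compromise between hard assignment
and uniform smearing; both are arguments. Initialization is seeded random
membership with 10 restarts keeping the lowest objective, which makes runs
reproducible and insulates against poor local minima. An independent
implementation (`e1071::cmeans`) serves as a cross-check in the test suite,
never as the implementation.

## Co-migration deconvolution

This is the core of the package. Preprocessing applies, in a fixed order:

1. per-fraction **iRT normalization** (divides out slice-to-slice recovery
   differences; a constant iRT vector only rescales and preserves every
   argmax);
2. bait phosphopeptides divided by the **bait protein profile**, so a
   phosphopeptide peak reflects site occupancy rather than local bait
   abundance;
3. the **two-level localization filter**: a phosphopeptide is kept only if
   its site-localization score exceeds 0.8 in at least one fraction, and
   individual fractions are masked below 0.5;
4. interior missing fractions imputed with the **mean of the two flanking
   fractions** (edge fractions use the single available neighbor);
5. scaling of every profile to **maximum 1**.

Peak detection smooths each profile with a Gaussian kernel of FWHM 2
fractions (`sigma = 2/2.355`; "width 2" is read as the FWHM of both the
kernel and the merge radius), finds local maxima of the smoothed trace, and
keeps those whose smoothed height reaches the kind-specific floor — **0.2
for proteins, 0.3 for phosphopeptides** (we follow the analysis-record
values; the alternative single 0.4 floor that appears in a figure legend is
reachable through `peak_params()`). Maxima closer than the width are merged
keeping the higher.

Profiles are then **split into single-peak traces**. Detected boundaries are
the nearest local minima, but for the split itself the outermost traces
extend to the range ends and adjacent peaks cut at the profile minimum
between their apexes (the valley fraction goes to the left trace). This
makes the split an exact partition: the traces of an entity sum to its
profile at every fraction, so no intensity is created or lost — a property
the test suite asserts exactly.

Traces are compared by **peak correlation distance**: one minus the Pearson
correlation over the union of the two supports. Disjoint peaks get distance
2 (maximally dissimilar) and a degenerate constant trace gets 1 by
convention. Average-linkage hierarchical clustering on this distance groups
traces into modules; the bait's own traces are excluded first, since the
bait migrates in every fraction and would bridge all groups. The number of
modules is chosen in `[k_min, k_max]` by **maximum mean silhouette width**,
ties toward fewer clusters. The silhouette is computed on the same
correlation-distance matrix by default; a Euclidean variant on the trace
vectors is provided because either reading of "distance" is defensible, and
on well-separated synthetic modules the two agree.

Each module reports its interactor members, its phosphosignature (possibly
empty — a module can carry no detectable bait phosphorylation), an
intensity-weighted apex fraction, and a **native molecular weight**
interpolated log-linearly between gel calibration points (extrapolation
beyond the calibrated range is flagged). Fractions are 1-based from the top
of the gel, so apex fraction decreases with native mass and the estimated
weight is monotone decreasing in apex.

## Module plausibility

Two orthogonal checks guard against coincidental co-migration:

* **Interaction-reference recall** — the fraction of within-module member
  pairs present in a curated protein-protein interaction edge list, compared
  with the recall over all pairs of the bait's interactor universe.
  Because a single pooled background number gives no dispersion, the
  background distribution is built by resampling module-sized random subsets
  of the universe (100 draws per module by default); module recalls are then
  compared by a two-sided unpaired t test, with a Shapiro-Wilk check on
  their normality.
* **Compartment enrichment** — an upper-tail hypergeometric test
  `P(X >= k)` of each module against cellular-component annotation sets,
  flagged at `p < 0.05`. No multiple-testing correction is applied by
  default with only a handful of curated terms; a Benjamini-Hochberg switch
  exists.

## Phosphosite-interactor association classes

An (interactor, phosphosite) pair is **associated** when any module contains
both (the any-module rule; requiring a specific module would discard
associations supported by a second assembly). Each association is classified
against the phospho-null mutant AP-MS of that site: `phospho_required` when
the interactor drops with `log2FC < -1` at `p < 0.05` in the alanine mutant,
`phospho_inhibitory` when it rises with `log2FC > 1` at `p < 0.05`,
`unaffected` otherwise, and `untested` when no single-site mutant exists.
All inequalities are strict, and raw p (not the BH q) gates the call,
following the thresholds' original definition; multi-site mutants are
reported but never classify single-site associations.

## Targeted PRM scoring

A peak group is accepted when its apex retention time is within **5% of the
gradient length** of the library value *and* its spectral **dot product**
(cosine between observed fragment areas and library relative intensities on
shared fragments) is **strictly above 0.75**. Quantification removes
fragments with signal-to-noise below 5 and **sums the top three remaining
areas**; fewer than three survivors are summed and flagged, zero yields a
missing value. Light/heavy ratios are `log2(light/heavy)`. Panel
normalization divides each run by the **geometric mean** of its reference
set (robust to a single outlier reference; the aggregator is not dictated by
the protocol text) — bait peptides, housekeeping-plus-iRT peptides, or a
shared affinity-tag peptide — and in bait mode additionally divides
phosphopeptides by the bait level, separating phosphorylation changes from
bait-abundance changes. Knockout-panel fold changes versus the parental line
feed a PCA on the centered (unscaled — log2 fold changes are already
comparable) entity-by-line matrix with the knockout targets removed, since
their own loss would trivially dominate.

## What the simulators emulate — and what they do not

`simulate_bnpage()` plants Gaussian co-migration peaks
(`sigma = FWHM/2.355`, matching the detection kernel) with stoichiometry
weights, multi-assembly proteins, module-linked phosphopeptides with
realistic localization-score structure, multiplicative log-normal intensity
noise (`noise_sd = 0.2`, about a 20% CV, typical of MS1 slice quantification)
and 5% dropout. `simulate_apms()` plants log2 fold changes on log-normal
peptide intensities with 2-5 peptides per protein. `simulate_prm()` builds
fragment areas proportional to abundance times library ratios, where
library entries have a dominant fragment and roughly geometric intensity
decay, as spectral libraries do; decoys are planted at retention-time
offsets beyond 5% of the gradient or with derangement-shuffled fragment
ratios (no fragment keeps its own intensity, the signature of a wrong peak
assignment). Noise magnitudes are not dictated by any protocol; they were
fixed once at values where the documented thresholds separate signal from
decoys, and are arguments throughout.

The simulators do **not** emulate: correlated noise between neighboring gel
fractions, peak tailing or other non-Gaussian peak shapes, shared peptides
between paralogs, interference in PRM transitions, or batch effects. Passing
tests therefore demonstrate correctness of the computation and recoverability
under the assumed noise model — not performance on any particular real
dataset.

## Numerical conventions and degenerate inputs

* Missing values are always explicit (`NA`/empty field); zero is a measured
  intensity. Zero observed peptides give a missing protein value, never 0.
* A profile that is entirely missing after filtering is dropped with a
  warning; an all-below-threshold profile yields no peaks and no traces.
* Correlation distance of a constant trace is 1; of disjoint traces, 2.
* Fuzzy c-means squared distances are floored at 1e-12 to avoid division by
  zero when a profile coincides with a center; convergence is the maximum
  center shift falling below `tol = 1e-6`.
* Degenerate zero-variance group comparisons report `p = 1`.
* Silhouette selection ties resolve toward the smaller number of modules;
  `k_max` beyond the trace count is clamped with a warning.

## Problem sizes used by the checks

The bundled verification uses the layout the fractionation study resolves:
nine planted modules of 3-8 members across 64 fractions (about 60 split
traces), 20 simulation seeds for recovery rates, 100 seeds for PRM
gatekeeping, 50 seeds of triplicate AP-MS for differential recovery, and
1,000 random small instances per statistical oracle. These sizes give stable
rate estimates while keeping a full run in the low minutes on a laptop.

## Worked example

```{r example, eval = FALSE}
truth <- default_complex_truth(seed = 1)
sim <- simulate_bnpage(truth, seed = 1)
prep <- preprocess_profiles(sim$profiles, sim$irt, bait = sim$bait)
traces <- split_profile(prep, detect_peaks(prep))
clusters <- cluster_modules(traces)
modules <- assemble_modules(clusters, traces,
                            calibration = tibble::tibble(
                              fraction = c(5, 60), kda = c(1200, 30)))
autoplot(clusters)          # silhouette model-selection curve
comigration_associations(modules)
```

## Known limitations

Overlapping peaks are split at valleys, not deconvolved by mixture fitting,
so two complexes closer than about one FWHM merge into one module. Module
membership is binary — stoichiometry within a module is reported only
through trace intensities. The association classes are threshold calls, not
causal estimates. Cross-condition differential migration (the same module
shifting size between conditions) is out of scope.
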