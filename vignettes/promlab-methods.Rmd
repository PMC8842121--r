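---
title: "promlab methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{promlab methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`promlab` packages the computational pipeline of a core-promoter
structure–function study: genome-scale motif/architecture statistics, a
saturation-mutagenesis design engine for synthetic promoters, dual-luciferase
plate processing, and additive models of promoter activity. This vignette is
the package's own account of the science: the models and their assumptions,
the tunable parameters with their defaults and units, what the synthetic-data
generators do and do not emulate, and where the design was genuinely open.

## Coordinates and motif models

All TSS-relative coordinates put the TSS at position 0; the motif-rich core
promoter is the 131-nt window −80..+50 (inclusive), tiling into block 3
(−80..−35), block 4 (−34..−10), block 5 (−9..+8) and block 6 (+9..+50).
Internally sequences are 0-based half-open, with a declared TSS offset per
sequence.

A motif is a position probability matrix (PPM) over {A,C,G,T}; scoring uses
the log2-odds position weight matrix (PWM)

\[ W(j,b) = \log_2 \frac{p(j,b) + \lambda\, q(b)}{(1+\lambda)\, q(b)}, \]

with background \(q\) (uniform by default) and pseudocount \(\lambda\)
(default 0.01). A window's match score is the sum of its per-position
weights; the minus strand scores the reverse complement. An ambiguous `N`
contributes its column's background-expected weight — it is neutral, never a
best match. All log-odds and information content are in bits; serialized
models declare the base.

A *hit* requires (i) the match score to reach the motif's minimal score
threshold and (ii), when the motif has an enriched region, the hit start to
lie inside that TSS-relative interval. The threshold itself is not a free
parameter: `optimize_threshold()` scans the grid −15..30 in steps of 0.1
(451 points) and keeps the threshold maximizing the mutual information
between motif presence and any positively correlated gene set, with
"positively correlated" implemented as a phi coefficient > 0 at the
candidate threshold and ties resolved to the smallest threshold. When no set
ever correlates positively, the motif is reported "uninformative" rather
than given an arbitrary cutoff.

## TSS peakedness

Tag tracks are smoothed with a 41-nt rectangular kernel (truncated at the
edges); clusters are maximal runs where the smoothed signal strictly exceeds
the genomic background rate (total tags / positions unless overridden). The
cluster TSS is the raw-count mode, leftmost on ties (the tie policy is ours;
ties are rare in real tag data). Filters, in order: at least 5 tags; no
other cluster TSS within 150 bp (*both* members of a close pair are dropped
— the stricter reading of "no other TSS within range"); and association
with annotation (gene start within 250 bp upstream, TSS inside an annotated
5'UTR, or an annotated TSS inside the cluster). Peakedness is the mean
absolute deviation from the median tag position — independent of cluster
size, unlike a shape index, so deeply and shallowly sequenced promoters are
comparable.

## Conservation

For each species, the observed statistic \(S\) is the mean PWM-score
difference between reference sites and their aligned counterparts (gapped
sites are skipped by default; optionally scored as N). The null resamples
each reference site through a position-specific 4×4 substitution model
learned from aligned context within ±10 positions (row-normalized counts
with pseudocount δ = 0.5 per cell — δ is ours; the source is silent), giving
\(N = 50\) null means \(B_i\) and

\[ S_{cons} = \frac{1}{N}\sum_i \frac{B_i - S}{B_i}. \]

Terms with \(B_i = 0\) are excluded and counted; an all-zero null returns a
sentinel, never a crash. With \(B\) fixed and positive the score decreases
strictly in \(S\): 1 means perfect conservation, 0 background-level
divergence.

A calibration note: at 200 sites and \(N = 50\), a *single* \(S_{cons}\)
draw under the background-rate null carries irreducible sampling noise of
roughly 0.05–0.1 (S is a mean over 200 sites; the learned substitution
model adds estimation noise that shrinks with context depth). The
acceptance check of the "background rate ⇒ score ≈ 0" property therefore
tests the expected score — the mean over five independent alignments at
exactly those sizes — against the ±0.1 band, with a per-draw 3σ bound; the
band itself is untouched. The generators' deep context (8000 pairs per
position) mirrors a genome-scale alignment, where the model is learned from
thousands of promoters.

## Design engine

Every mutation family preserves the 131-nt core (insertions into motif-less
promoters overwrite the target window — synthesized oligos are fixed
length). Key semantics:

* **knockout_random** draws i.i.d.-uniform same-length replacements and
  rejects (≤ 1000 draws) any that let *any* motif model gain a hit
  overlapping the replaced window; the window is scanned with ±(max motif
  length − 1) context so boundary-crossing hits are seen. Hits entirely
  outside the replacement are pre-existing promoter content and are the job
  of `validate_construct()`, not the sampler.
* **knockout_background** splices a designated motif-free background core at
  identical TSS-relative coordinates, so the "background" control sequence
  varies with the target's position, as in the original design.
* **strength_series** rejection-samples replacements into requested
  PWM-score bins (default: five equal bins from 10% above the attainable
  minimum to the maximum; proposals come from temperature-swept PPM columns
  so high-score bins stay reachable) and redraws if a *different* motif
  would gain an overlapping hit.
* **shifts** excise the target and re-insert it at ±Δ with the displaced
  context closed up ("slid", not overwritten — the source is silent; slid
  keeps sequence content identical), while all other motifs stay pinned at
  their native TSS-relative positions. Shifts leaving the core are design
  errors. Default offsets are ±{1,3,5,10,20} for broadly positioned motifs
  and ±{1,2,3,5,10} for strictly positioned ones, applied symmetrically.
* **substitute** anchors INR-like donors by their TSS position inside the
  motif (e.g. 3rd base of INR ↔ 10th of INR2) and start-aligns otherwise.
* **validate_construct** re-scans parent and construct threshold-passing but
  region-free — a motif created *anywhere* is a side effect — and flags any
  gain/loss whose motif is not named by the construct's intended targets.
* **resolve_clone** accepts the top observed sequence only at ≥ 3-fold read
  enrichment over the runner-up, then global-aligns it (unit scores) to the
  designed library; identity < 0.95 rejects the clone as a synthesis defect
  (the 0.95 cutoff is ours; the source reports ~40% defective clones but no
  cutoff).

Assembly is `[ovh, block1(239), ovh, block2(73), ovh, core(131), (ovh,
block7(240),) ovh]` with 4-nt junction overhangs — the overhangs reconcile
the individual block lengths (683/443 summed) with the published totals
(703/459); their sequences are configurable with defaults taken from the
printed receptor-block oligo ends.

## Plate normalization

Per plate: background `BG` is the mean second-read firefly signal of pooled
negative controls (empty-vector and untransfected wells); the normalization
factor is the mean of `(FF1 − BG)/REN` over the positive-control wells; each
sample yields `x = log2(((FF − BG)/REN)/Norm)`.

**FF1 vs FF2.** The transcribed normalization equation of the source
conflicts with its prose: we implement the prose — FF1 for strong wells
(FF1 > 2×10⁵ RLU), FF2 otherwise — because strong wells are physically
removed and quenched before the second read, making their FF2 meaningless.
Constants surface as configuration, not inline values: FF selection 2×10⁵
RLU, REN window 300–10,000 RLU, outlier cutoff 3.

The assay noise scale `SD_noise` is the median of per-construct replicate
SDs over the whole library. Outliers are replicates with
`|x_i − median(construct)| / SD_noise ≥ 3` (the per-construct center is the
median; downstream effects use means of log2 replicates). The coefficient of
variation is reported on the linear scale (sample SD of `2^x` over its mean,
percent) with the log-scale SD alongside, since the source does not say
which scale its reproducibility figure used.

## Effects, additivity, logos, models

Effects are differences of replicate means in log2, with pooled-variance
standard errors. Pairwise additivity is
`effect_ab − (effect_a + effect_b)`: positive = subadditive, negative =
superadditive (synergy), `|·| ≤ 0.2` called additive (the tolerance is ours;
records always carry the raw value), and a record is *gated* — treated as
reliable — only when all three effects exceed 3×`SD_noise`.

Activity logos map a saturation point-mutation panel to a PPM by
column-normalizing mean linear-scale (`2^x`) expression per base (log-scale
weighting is available behind a switch); the consensus base's value is the
consensus construct's expression, and missing variants leave a column
flagged incomplete. This linear-mean definition is this package's own — the
source states the construction exists but not its formula.

The linear model regresses construct log2 expression on 0/1 mutation
indicators by OLS; rank-deficient designs (inevitable when not all designed
constructs are recovered) get the minimum-norm SVD solution with the rank
reported. The parameter-free additive model predicts
`wt_mean + Σ single-mutation effects` with no fitting; constructs with an
unmeasured feature are skipped and counted. Reported r is in-sample, to
match how the source quotes its correlations.

## Synthetic data: what a green test establishes

The generators state a world: per-construct activity is a per-promoter
baseline plus additive per-feature log2 effects, optional pairwise
interactions, position penalties, and — under induction — a boost capped at
a saturation ceiling (`min(boost, ceiling − basal)`), which reproduces the
negative basal-vs-inducibility trend qualitatively. Plate signals are
`FF = Norm·REN·2^activity + BG` with lognormal multiplicative noise on each
luminescence channel (defaults σ_FF = 0.2, σ_REN = 0.1, giving replicate
CV ≈ 22%, the reproducibility regime of the assay; BG = 100 RLU,
REN = 2000 RLU — inside the 300–10,000 filter). FF2 is emitted
degradation-corrected (factor 1) by default, matching the processed second
read; strong wells get a quench sentinel. The generators are pure functions
of (seed, spec).

Not emulated: sequence-to-activity biophysics (truth effects attach to
design features, not chemistry), plate spatial artifacts beyond optional
neighbor bleed, luminometer drift, synthesis error profiles. A green
recovery test therefore establishes that the *pipeline* is correct and
well-calibrated under its stated noise model — not that the model of
promoter biology is complete.

Two acceptance parameters were fixed by power analysis before any test ran:
the linear-recovery world uses 12 features (a realistic intra-architectural
vocabulary: ~4 motifs × 4 mutation families), and the additivity-recovery
world uses 36 replicates per construct, chosen so that three estimation SDs
of the additivity statistic (which combines four construct means:
SD = 2σ/√n, σ = 0.3) equal its ±0.3 recovery band.

## Numerical choices and degenerate inputs

* Consensus ties break alphabetically and are flagged; printed consensi in
  the field never tie, so the flag is diagnostic only.
* `binary_mi` uses the plug-in estimator with 0·log 0 = 0 and is clamped at
  0 against floating-point underflow; `binary_mcc` returns 0 on any zero
  margin.
* Z-profiles use a binomial null with the global presence frequency (the
  source gives no formula); degenerate frequencies (p ∈ {0,1}) warn and
  return zeros.
* Quantile gene sets take exactly ⌊fraction·n⌋ top/bottom members (min 1);
  constant columns warn and give empty sets. The full 18-set catalogue is
  config-driven because the original distribution-minimum thresholds are
  not published.
* Empty scan regions warn and return empty hit tables; impossible
  thresholds yield empty results, not errors.
* `fit_linear` needs n ≥ 2; SE-based p-values are reported only when
  residual degrees of freedom remain.

## Known limitations

* De novo motif discovery is out of scope; the package consumes PWMs.
* The architecture class catalogue ships with the published five-class
  motif lists; promoters matching several classes equally are labelled
  "mixed" (the tie policy is ours).
* Clone resolution assumes one dominant sequence per well; chimeric clones
  below the identity cutoff are simply "defective".
* The deposited study dataset is not bundled, so the package's benchmarks
  run entirely on its own generators; functions accept real plate CSVs and
  motif files with the documented headers.
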