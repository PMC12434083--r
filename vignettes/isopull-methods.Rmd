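---
title: "Quantitative interactomics from two-channel pull-downs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative interactomics from two-channel pull-downs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The experimental design the package models

`isopull` analyzes affinity-purification mass-spectrometry (AP-MS)
interactome experiments in which a light (^14^N) and a uniformly
^15^N-labeled heavy culture are mixed *before* purification, so that every
peptide carries an internal two-channel ratio through all downstream steps.
A bait protein (e.g. a Twin-Strep-tagged transcription factor) is purified
together with its crosslinked partners, and each peptide ion is quantified
as a light/heavy (L/H) ratio within a single chromatogram.

Three mixes are measured per biological replicate:

* **WT/WT** — untagged light + untagged heavy. Nothing is specifically
  purified; whatever appears binds the resin nonspecifically and sits at
  L/H ≈ 1. This is the nonspecific-binding control.
* **Bait/WT** — tagged light + untagged heavy. The bait and everything
  crosslinked to it is enriched in the light channel (L/H ≫ 1); nonspecific
  binders stay at L/H ≈ 1. This is the experiment.
* **Bait/Bait** — tagged light + tagged heavy. Everything, including the
  bait, sits at L/H ≈ 1. This labeling/tag control catches artifacts tied to
  the tag or the capture chemistry (the classic example being a
  biotinylated carboxylase that binds the streptavidin-derived resin in
  every sample).

`enumerate_samples()` expands conditions × crosslinker levels × replicates
× the three mixes into the factorial sample sheet (2 × 2 × 4 replicates
gives the 48-run design this workflow was developed on). A label-swap flag
exists but is off by default: because both channels are mixed before
capture, purification artifacts hit both isotopologues equally and a
reciprocal layout would mainly double instrument time.

# Normalization

Search engines export H/L ratios; the pipeline inverts them
(`ratio_lh = 1 / ratio_hl`) to keep the light channel — the bait strain in
Bait/WT — in the numerator. Minor errors in the nominally 1:1 pellet mixing
shift all ratios of a run by a common factor, which is removed by dividing
every peptide of a run by the run's **normalization factor**: the median
L/H of its quality-passing peptides. After division the nonspecific
background is centered on 1 by construction (the package asserts the
QC-passing median equals 1 to 1e-9).

The QC set is formed in two passes:

1. ions pass the q-value cutoff (`q_value_max`, default 0.01);
2. a provisional per-run centering by the median L/H of the q-passing ions
   is applied, and the ion CV (sd/mean across the biological replicates of
   the condition, linear scale, n−1 denominator) is computed on these
   *centered* ratios; ions with CV below `ion_cv_max` form the final QC
   set, whose original-scale median is the run's factor.

The provisional centering is a deliberate design choice. Computing the ion
CV on raw ratios would confound it with the run-level mixing shifts the
factor is supposed to estimate: an ion would only look "stable across
replicates" if its noise happened to cancel the mixing differences, so the
surviving set would systematically pull the recovered factor toward 1. With
mixing errors of log2-sd 0.2 — the magnitude the simulator injects by
default — that bias reaches 5–18% of the factor, whereas the two-pass
scheme recovers injected factors to well under 2% with a few hundred
background peptides per run (this recovery is exercised directly by the
test suite and by `scripts/acceptance.R`).

# Stringent filtering

`filter_params()` carries the workflow's initial stringent thresholds:

| parameter | default | meaning |
|---|---|---|
| `q_value_max` | 0.01 | ion q-value cutoff (pass if ≤) |
| `ion_cv_max` | 0.2 | ion CV across replicates (pass if strictly <) |
| `data_completeness` | 1.0 | fraction of replicates a protein must be detected in |
| `seq_coverage_min` | 40 | sequence coverage %, pass if strictly > |
| `num_peptides_min` | 2 | distinct peptides per protein (pass if ≥) |
| `control_fc` | 2 | fold threshold of the control-consistency rule |

Boundary conventions are fixed constants of the implementation: CV and
coverage comparisons are strict ("CVs must be smaller", "coverage must be
greater"), q-value and peptide count are inclusive. Sequence coverage is
recomputed from the FASTA database as the union of all exact substring
occurrences of a protein's q-passing peptides (I/L are not collapsed;
coverage is an identification-quality metric, so it is deliberately not
conditioned on the CV filter). Completeness requires detection — at least
one fully passing peptide ion — in `ceiling(data_completeness × n)`
replicates, so designs with any replicate count work unchanged.

The `control_fc` threshold has two possible homes, selected by
`run_differential(control_fc_scope = ...)`:

* `"classifier"` (default): the threshold acts at the protein level, as the
  enrichment fold above which a *control* sample's significant enrichment
  excludes a protein from the candidate list. This is the semantics under
  which a biotinylated contaminant that is 3–4× enriched in both the
  experiment and the bait control is *seen* in both tables and excluded by
  the classifier.
* `"peptide"`: peptide ions whose normalized ratio deviates from 1 by more
  than `control_fc`-fold in any control replicate are excluded from
  aggregation in every sample type. This is stricter but self-defeating
  for control-based exclusion: it erases the control-enrichment signal the
  classifier needs, so genuinely contaminated proteins vanish instead of
  being flagged. It is retained as an option for datasets where control
  deviations indicate measurement failure rather than biology.

## Bait-inclusion tuning

A high-fold bait is exactly the protein most likely to fail the stringent
defaults: with only background peptides in the heavy channel its ion CVs
are inflated, and a large protein may sit below the coverage threshold.
`tune_filters()` walks an ordered grid of (coverage, CV) threshold pairs
from most to least stringent — coverage threshold descending first, CV
threshold ascending within — and returns the first pair under which the
bait passes every filter in all Bait/WT replicates, together with a full
trace of each tried pair and the bait's first failing filter. On the
canonical hard case (bait ion CV 0.28, coverage 35%) the walk lands on
(ion CV 0.3, coverage 30). The walk order prefers to keep coverage
stringency as long as possible and is overridable via the grid arguments.

# Protein-level statistics

Surviving peptides are aggregated per (protein, run) by the **median** of
their normalized ratios (robust to single outlier peptides; duplicate rows
of one peptide sequence all enter the median but count once toward
`n_peptides`), then log2-transformed.

For each protein *g* and sample-type group with *n* replicate log2 ratios,
the one-sample moderated t-test shrinks the sample variance
$s^2_g$ (df $d_g = n-1$) toward a prior variance $s_0^2$ with prior df
$d_0$:

$$s^2_{post} = \frac{d_0 s_0^2 + d_g s^2_g}{d_0 + d_g},\qquad
t = \frac{\bar y}{\sqrt{s^2_{post}/n}},\qquad
t \sim t_{d_0 + d_g} \text{ under } H_0.$$

The hyperparameters are fitted once per (condition, crosslinker) analysis
cell by the method of moments on the log scale, pooling the residual
variances of all three sample-type groups: with
$e_g = \log s^2_g - \psi(d_g/2) + \log(d_g/2)$, solve
$\psi'(d_0/2) = \mathrm{var}(e) - \overline{\psi'(d_g/2)}$ for $d_0$ by
monotone root-finding on the trigamma function, and
$s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$. When the observed
dispersion of log-variances does not exceed its expected sampling
dispersion, $d_0$ is set to a cap (default $10^6$), i.e. effectively
complete shrinkage. At $d_0 = 0$ the statistic reduces exactly to the
classical one-sample t-test; both limits are asserted by the test suite,
and the fit is cross-checked against an independent empirical-Bayes
implementation. A per-group prior fit is available behind
`per_group_prior = TRUE`.

P-values are two-sided; Benjamini–Hochberg correction is applied within
each sample type's p-value vector (each volcano panel is its own
multiplicity universe). A protein is **significant** when
`adj_p <= alpha` (default 0.001) *and* `enrichment_fold >= fc_threshold`
(default 2); directionality is thereby enforced on positive enrichment.
Enrichment is reported on both scales (`mean_log2` and
`enrichment_fold = 2^mean_log2`).

## Classification and condition contrasts

`classify_interactors()` assigns each protein of the union universe exactly
one status, in order: `bait` (the configured accession, regardless of
controls), `excluded_wt_control` (significantly enriched in WT/WT — "red"),
`excluded_bait_control` (significantly enriched in Bait/Bait — "yellow"),
`candidate` (significant in Bait/WT, clean controls), else
`not_significant`. "Enriched in a control" is determinized as the same
significance rule as in the experiment (`control_alpha`, `control_fc`), so
nonspecific binders that are merely *detected* at ratio 1 in a control are
never excluded. Absence from a control table counts as not enriched there;
removing control tables can therefore only promote excluded proteins to
candidates, never the reverse (property-tested).

`compare_conditions()` contrasts a protein's Bait/WT log2 enrichment
between two conditions with a moderated two-group statistic: the posterior
variances are pooled by residual df, and the degrees of freedom combine
both groups' residual df with the average of the two per-cell prior dfs
(entering once, symmetrically, so that swapping the conditions exactly
negates every contrast). BH correction is applied within the contrast
vector over proteins present in both conditions.

# ^15^N mass arithmetic

Uniform ^15^N labeling replaces every backbone and side-chain nitrogen, so
a peptide's heavy-channel mass shift is its total nitrogen count times the
exact isotopic mass difference 0.9970349 Da (the folk "1 Da per nitrogen"
is an approximation of this constant and is treated as a documented
property, not an implementation). Residue nitrogen counts follow the
residue composition (1 for most residues, 2 for K/Q/N/W, 3 for H, 4 for R);
heavy precursor m/z is `light_mz + shift / charge`. Fragment-ion channels
and partial (<100%) incorporation are out of scope.

# The synthetic-data generator

`simulate_experiment()` emits a peptide report, a FASTA database with every
simulated peptide embedded as a true substring at a recorded position, the
sample sheet, and full ground truth. The generative model: the observed
log2 L/H of ion *i* of protein *g* in run *r* is

$$y_{igr} = \mu_{g,\text{sampletype}(r),\text{condition}(r)}
  + \delta_r + \varepsilon_{igr},\qquad
\delta_r \sim N(0, \sigma_{mix}^2),\ \varepsilon \sim N(0, \sigma_{pep}^2),$$

stored as `ratio_hl = 2^{-y}`. Background proteins have $\mu = 0$
everywhere; the bait (default true fold 256, the order of magnitude a
well-enriched bait reaches) and interactors take their fold only in
Bait/WT and are *omitted entirely* from WT/WT runs, because the untagged
strain purifies no bait (in Bait/WT the heavy channel of the bait is a
background floor, so ratios are large but finite — the idealized
"infinite ratio" never enters the data, matching the ingest invariant).
Nonspecific binders sit at fold 1 in every sample type and are always
detected. Control decoys take their fold in their designated control *and*
in Bait/WT — the contaminant pattern the control-based exclusion exists to
catch. Interactors may carry a `condition` restriction to emulate
stress-specific partners.

Default magnitudes are fixed study conditions, not dials: peptide noise
log2-sd 0.3, replicate mixing log2-sd 0.2, 4 biological replicates, 5%
missingness, 2% of ions drawing a failing q-value, and per-protein
sequence coverage fractions of 0.55–0.75. One pseudo-random stream is
derived per run from (seed, sample id), so identical seeds give
byte-identical outputs and adding runs never perturbs existing ones.

A consequence worth stating plainly: at these defaults the *true* ion CV
of an enriched protein's normalized ratios is about 0.21 — just above the
stringent 0.2 threshold — so roughly half of all ions fail the CV filter
and a small fraction of planted interactors (of order 1%) can drop out of
the result set entirely. This is faithful to the phenomenon that motivates
the bait-inclusion tuning step, and it is why the recovery tests assert
tier-mean accuracy (±0.5 log2), zero misclassification, and ≥95%
detection, rather than per-protein perfection.

What the simulator does **not** emulate: spectra, chromatography,
interference, ratio compression, incomplete labeling (real incorporation
is ≥98%, idealized here to 100%), correlated peptide noise within a
protein, and intensity-dependent missingness (missingness is i.i.d.).
Passing tests therefore demonstrate the correctness of the statistical
machinery under the stated model, not robustness to every artifact of
instrument data.

# Numerical choices and degenerate inputs

* Medians of even-count sets are the mean of the central order statistics.
* Trigamma root-finding: bisection-based `uniroot` on $d_0 \in [10^{-3},
  10^7]$, tolerance 1e-10; dispersions below the bracket resolve to the
  cap.
* When *no* positive residual variance exists (exactly noiseless data),
  the prior fit cannot be computed and the pipeline falls back to maximal
  shrinkage toward a vanishing prior variance (1e-12), which makes exact
  nulls report t = 0, p = 1 and exact signals report extreme statistics.
* `s2_post = 0` (only possible at $d_0 = 0$ with zero sample variance)
  yields t = 0, p = 1 at mean zero and ±Inf, p = 0 otherwise.
* Ions with undefined CV (fewer than two replicate observations) fail the
  CV filter rather than erroring.
* Non-finite or non-positive ratios, bad q-values and sub-5-residue
  peptides are rejected at ingest with logged counts, never silently.
* Problem sizes in the test suite are chosen to keep sampling error well
  inside each asserted tolerance: e.g. mixing-factor recovery uses 1000
  background proteins × 8 peptides (median standard error ≈ 0.5% against
  a ±2% bound), hyperparameter recovery uses 5000 proteins, and the
  fold-tier recovery uses 200 planted interactors per tier against 800
  background proteins so that the background still dominates the run
  medians, as the normalization assumes.

# Known limitations

* Coverage computation is exact-substring based; peptides with
  modifications stripped inconsistently by the upstream search engine
  would need a custom `column_map` and pre-cleaning.
* The moderated model assumes independent proteins; co-regulated
  complexes violate this mildly, as in any empirical-Bayes proteomics
  analysis.
* BH is applied per sample type; joint correction across the three
  volcano panels would be slightly more conservative.
* The q-value is treated as ion-level; if an upstream engine exports
  protein-level q-values the cutoff semantics change accordingly.
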