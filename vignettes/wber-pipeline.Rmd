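---
title: "Decision-aligned evaluation of tumour-progression classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-aligned evaluation of tumour-progression classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmrelapse)
```

## The problem

After surgical resection of a glioblastoma (GBM), patients are followed with
monthly (later three-monthly) multiparametric MRI. At some follow-up session
— the *decision session*, written `L` — radiologists applying RANO criteria
commit to one of two clinical outcomes: *progressive* disease or a
*responsive* (complete-response) course. The question this package addresses
is whether a classifier trained on quantitative MRI features could have
called that outcome earlier than the radiological criteria did, and how to
measure "earlier and how reliably" in a single defensible number.

Each MRI session is summarised by a 27-feature vector:

* 3 region volumes — contrast enhancement (CE), perilesional oedema (ED),
  necrosis (N);
* 6 perfusion parameters — rrCBV, rrCBF, rDR over CE and ED, each normalised
  to contralateral normal-appearing white matter (NAWM), so healthy tissue
  sits near 1;
* 6 diffusion-kurtosis parameters — MK, MD, FA over CE and ED;
* 10 metabolite ratios from chemical shift imaging over CE (NAA/tCho,
  NAA/sum, tCho/sum, NAA/Cre, Lips/tCho, tCho/Cre, Myo/sum, Cre/sum,
  Lips/Cre, Glx/sum);
* a total-resection flag (0/1) and a treatment-protocol group code (0/1/2).

The three volumes and the two clinical codes are always observed; the three
advanced-MR modalities drop out per acquisition (quality control, motion,
missed acquisitions), and they drop out as whole blocks: a rejected
spectroscopy acquisition removes all ten ratios at once.

## Decision-aligned labeling

Every session is indexed by its signed ordinal offset from the decision
session: `L-3` is three sessions before the decision, `L+2` two after.
Offsets count sessions, not calendar days — the follow-up interval changes
from monthly to three-monthly during the study, and aggregation by session
index is what keeps per-offset patient counts meaningful.
`propagate_labels()` assigns the patient's decision class to every session
at or after the decision and `"unlabeled"` to every earlier session.

Training always uses labeled sessions only. Evaluation, however, scores
*every* session of the held-out patient — including the unlabeled,
pre-decision ones — against the patient's eventual decision class. That is
the point of the exercise: a correct prediction at `L-2` is a correct call
two sessions early.

## Volume-conditioned imputation

Missing modality values are filled by a rule keyed on the volume of the
tumour region the feature is measured over (CE for all spectroscopy and the
`_CE` parameters, ED for the `_ED` parameters):

* region volume exactly 0 — the tissue is absent, so the measurement is
  treated as coming from healthy tissue: perfusion ratios are filled with
  exactly 1 (the NAWM-normalised value of normal tissue), diffusion and
  spectroscopy with the mean over *responsive-labeled* sessions, the closest
  available surrogate for healthy tissue;
* region volume positive — filled with the mean over *all labeled*
  sessions.

The volume test is exact equality with zero, deliberately without a
tolerance: volumes are recorded as 0 when a region is absent, and small
positive volumes are real tissue. Inside cross-validation the imputation
model is refitted per fold on the training patients' labeled sessions only,
so the held-out patient never contributes to the means that fill their own
sessions. Whether a single, cohort-wide model would have been acceptable is
debatable (it leaks the test patient's labeled sessions into the fill
values); per-fold fitting is the conservative choice and is what
`evaluate(..., variant = "imputed")` does.

A structural consequence of mean filling worth knowing: when a whole
modality block is missing and the labeled training set is class-imbalanced,
the labeled mean sits closer to the majority class, so the filled block
nudges the session toward that class. This is why complete-feature
evaluation is the variant on which near-perfect early classification is
achievable, and the imputed variant is not expected to reach zero error even
on well-separated cohorts.

## The classifier bank

`default_classifier_bank()` holds ten supervised classifiers spanning the
families usually benchmarked on tabular biomedical data: 3-nearest-neighbour
with the correlation distance, linear discriminant scoring, SVMs with linear
and sigmoid (multilayer-perceptron) kernels, a classification tree, a
feed-forward neural net with 10 hidden units, a 100-tree random forest, and
three 100-round boosting variants over stumps (discrete AdaBoost, LogitBoost
— Newton boosting of the logistic likelihood over regression stumps — and a
subsampled LogitBoost standing in for robust boosting; the substitution is
recorded in every report that uses it).

Adapter choices worth noting:

* The linear discriminant uses the Moore–Penrose pseudoinverse of the
  pooled within-class covariance rather than its inverse, so it remains
  defined when folds are small and the covariance singular.
* Correlation-distance kNN is computed directly (1 − Pearson correlation
  between feature profiles); established kNN implementations only provide
  Euclidean-type metrics. Ties are broken by the nearest neighbour.
* Features are z-scored on the training fold for the scale-sensitive
  families (kNN, discriminant, SVM, neural net) and left untouched for the
  tree ensembles, which are invariant to monotone feature scaling.
* Class priors are left at each library's default; no rebalancing is
  applied. The balanced error rate corrects for imbalance at scoring time
  instead.

All stochastic learners draw per-fold, per-classifier sub-seeds derived
deterministically from the run seed, so every report is exactly
reproducible.

## Leave-one-patient-out evaluation and wBER

The cross-validation unit is the patient: sessions of one patient are never
split between training and test. For each of the `n` folds the classifier
trains on the labeled sessions of the other `n − 1` patients and predicts
each session of the held-out patient independently.

Predictions are pooled by offset. At offset `i` the balanced error rate is

$$\mathrm{BER}_i = \tfrac12\left(\mathrm{ERR}^{\mathrm{resp}}_i +
\mathrm{ERR}^{\mathrm{prog}}_i\right),$$

the mean of the two per-class misclassification rates. When only one class
is represented at an offset (common far from the decision, where few
patients have sessions), the error rate of the present class alone is used:
a single misclassified patient scores 1 and a single correct one scores 0,
rather than an artificial 0.5. This convention is what makes per-offset
tables with single-patient entries printable as 0/1.

Two weights aggregate the series into one number. A temporal weight

$$W^t_i = \begin{cases} 1 & i \ge 0\\ 1 - \frac{0.5}{11}\,|i| & i < 0
\end{cases}$$

gives full weight at and after the decision and decays linearly before it,
reaching 0.5 at eleven sessions out (the deepest offset in a typical
follow-up; the linear form is applied as-is beyond that). A population
weight proportional to the number of patients observed at the offset damps
the noisy single-patient entries. The weighted BER is

$$\mathrm{wBER} = \frac{\sum_i W^p_i W^t_i\,\mathrm{BER}_i}
{\sum_i W^p_i W^t_i},$$

summed over offsets that carry an estimate. The population normaliser
cancels in the ratio, so only relative counts matter — a property the test
suite asserts. Reported values are rounded to three decimals for table
rendering; full precision is kept internally.

The reference tables shipped under `inst/extdata/` — per-offset BER columns
for six classifiers on complete and on imputed data, with the matching
per-offset patient counts (45 complete sessions, 178 in total) — reproduce
the published summary rows of the study this package emulates to all three
printed decimals, with one exception: the linear-discriminant column of the
imputed table re-evaluates to 0.228 under the weighting formula, not the
0.216 its source prints. The recomputed value is the self-consistent one,
and the acceptance suite asserts it as such.

## The synthetic cohort generator

No per-patient feature data are deposited for the emulated study, so the
generator reproduces its *structure*, which is what the pipeline's
correctness depends on:

* 29 patients, with pre-/post-decision session-count distributions derived
  from the study's per-offset patient counts (expected total 178 sessions;
  up to 11 sessions before the decision, up to 5 after);
* a deterministic `round(n × fraction_progressive)` class split (default
  one half — the study does not report its split; a drawn split could leave
  a class empty, which no two-class design permits);
* block missingness at the study's per-modality rates — spectroscopy 0.66,
  diffusion 0.44, perfusion 0.30 — applied per session to whole modality
  blocks, mirroring per-acquisition quality rejection;
* protocol-group frequencies 16/29, 7/29, 6/29 matching the study's three
  treatment arms.

Modality features are class-conditional Gaussians: the responsive class
sits at a per-feature baseline (perfusion baselines are exactly 1, the NAWM
ratio of healthy tissue) and the progressive class is shifted by
`class_separation` (δ) within-class standard deviations, with a fixed
per-feature sign (perfusion ratios and MK rise with progression; MD, FA and
NAA ratios fall). The baselines and SDs are configured constants — the
study reports no distributional summaries, so only the direction and
magnitude *in SD units* of the separation is meaningful, and δ, not the
constants, is the knob experiments sweep.

Volumes follow per-patient lognormal baselines with a class trend applied
along the whole timeline — progressive regions grow per session, responsive
regions shrink — and responsive regions additionally collapse to exactly 0
with probability 0.5 per post-decision session (absorbing), which is what
exercises the zero-volume imputation branch. The trend spans the full
timeline because the evaluation scores pre-decision sessions against the
eventual class: a cohort whose pre-decision features carried no class
signal would make early prediction impossible by construction. At δ = 0 the
class trends are switched off entirely (both classes follow the responsive
trajectory), so "no separation" genuinely means identical class
distributions and chance-level wBER.

Missingness is completely at random given the modality, except for a
configurable coupling that tilts masking toward sessions whose CE region is
absent (default: a masked block has probability 0.25 of falling on a
zero-CE session, rates permitting) while preserving the marginal rate. The
true missingness mechanism of the study — motion, quality control — is not
recoverable from its description, so only the rates and the block structure
are emulated.

What passing tests on these cohorts does **not** show: that the package's
classifiers would reach the study's error rates on real data. Feature
correlations within and across modalities, non-Gaussian tails,
calendar-time effects and informative missingness are all absent from the
generator. The synthetic results validate the machinery — labeling,
imputation rules, fold hygiene, weighting — not the clinical effect size.

## Numerical choices and degenerate inputs

* Offsets with no eligible session contribute nothing to wBER; an
  all-empty series is an error, not NaN.
* `weighted_ber` matches a brute-force evaluation of the weighting formula
  to < 1e−12 over randomized series (asserted in the suite).
* Zero-variance features are centred but not scaled during z-scoring;
  correlation distances that are undefined (zero-variance profiles) are
  treated as maximal.
* A training fold containing a single class is a named error
  (`gbm_one_class_error`), not a silent constant prediction.
* One-session patients, decision at the first or last session, and
  patients with no complete session (skipped with a fold-log entry in the
  complete variant) are all exercised in the test suite.

## Problem sizes used by the test suite

The suite exercises the full 29-patient cohort size for the structural
checks (fold hygiene, separation, chance behaviour: 20 seeds each at δ = 3
and δ = 0, 10 seeds for the label-shuffle null) and 6–12-patient cohorts
for unit-level checks; the invariant suites use 1,000 randomized series /
masked sessions. These sizes keep the default run in the low minutes on one
core while leaving every scientific claim exercised at the cohort scale it
refers to.

## Known limitations

* The imputed variant inherits the majority-class pull of labeled-mean
  filling described above; imputation methods that model feature
  correlations (EM, MICE, kNN) are deliberately out of scope.
* Semi-supervised classifiers and least-squares SVMs from the emulated
  study's wider bank are not implemented; robust boosting is represented by
  a subsampled LogitBoost surrogate and flagged as such in reports.
* The kNN configuration (k = 3, correlation distance) is taken as given
  rather than re-derived by grid search.
* Confidence intervals on BER/wBER are not provided (the summary statistic
  is a weighted point estimate by design).
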