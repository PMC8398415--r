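---
title: "Classifying collar accelerometer bursts and detecting feeding events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying collar accelerometer bursts and detecting feeding events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(feedscan)
```

## The problem

Collars on free-ranging carnivores record short accelerometer (ACC)
bursts on a duty cycle — at the free-ranging settings, 3.6 s of the heave
(z) axis at 10 Hz every two minutes — alongside GPS fixes whose interval
adapts to activity (3 or 15 min when active, 6 h when the between-fix ACC
variance says the animal is inactive). The task is to recover *what* the
animal was doing from each burst, and to locate *feeding events*: the
intervals and places where prey was consumed, which for cheetahs are a
proxy for kills because scavenging is rare.

feedscan implements both stages and a simulator that makes them testable
without field data.

## Burst predictors

Each burst of n samples `z_1..z_n` is reduced to six predictors:

* `mnz`, `sdz` — sample mean and standard deviation. The standard
  deviation uses the population convention (divisor n); the `n-1`
  convention is available (`sd_divisor`), and at n = 36–40 the two differ
  by ~1%.
* `wmz` — the periodogram-weighted mean Fourier frequency. The
  periodogram of the mean-removed series is evaluated at the Fourier
  frequencies `w_j = 2*pi*j/n`, `j = 1..q`, `q = n/2` (n even) or
  `(n-1)/2` (n odd); then `wmz = sum(w_j I(w_j)) / sum(I(w_j))`, in
  radians per sample within (0, pi]. Two numerical choices matter here.
  First, the series mean is removed, otherwise the DC term dominates the
  weighting and erases the behavioural signal. Second, "weighted mean"
  admits another reading — the average ordinate itself — which is
  implemented behind `wmz_mode = "mean_ordinate"` but is not the default,
  because a mean ordinate makes no use of the frequency grid that the
  definition spells out. Note the odd-n rule must be `(n-1)/2` for the
  count to be an integer.
* `ICVz = mnz/sdz` — the inverse coefficient of variation.
* `kz`, `sz` — Pearson kurtosis (not excess) and the standardised third
  moment, both with divisor n. Under these conventions the invariances
  hold exactly: scaling all samples by c > 0 scales only `mnz` and `sdz`;
  adding a constant changes only `mnz` and `ICVz`.

A zero-variance burst leaves `sz`, `kz` and `ICVz` undefined; the package
returns `sz = kz = 0`, `wmz = 0` (all ordinates vanish) and a large
finite sentinel `ICVz = ±1e12`, with a `degenerate` flag, so downstream
classifiers always see finite inputs without losing the information that
the burst was flat.

## Resampling mixed collar firmware

Part of a deployment may record at 33.3 Hz (110 samples per 3.3-s burst)
instead of 10 Hz. 33.3 Hz is treated as exactly 100/3 Hz — the only
reading under which 3.3 s × 33.3 Hz = 110 samples comes out exact — so
33.3 → 10 Hz is the rational ratio 3/10 and a 110-sample burst becomes
`ceiling(110 * 3/10) = 33` samples. The resampler is a standard polyphase
design: upsample by p, FIR low-pass, downsample by q, with a
Kaiser-window (beta = 5) windowed-sinc filter of half-length
10·max(p, q) taps cut off at the narrower Nyquist frequency. Two details
depart from the bare textbook filter, both to honour contracts the
feature stage relies on: each polyphase branch is normalised to unit sum
so constants pass through exactly (a plain Kaiser design has passband
ripple well above 1e-6), and the burst is edge-replicated before
filtering so the first and last samples carry no startup transient.
Features then normalise by n, so 33-sample and 40-sample bursts mix
freely in one training table; the resampled bursts are not truncated to
the 40-sample firmware length.

## The classifier bank

Six algorithms are fitted on identical rows and identical predictors:
LDA, QDA (native posteriors), KNN (k = 5, neighbour-vote fractions), a
classification tree (leaf class frequencies), an RBF-kernel SVM
(Platt-style calibrated probabilities), and a random forest (500 trees,
tree-vote fractions). KNN and the SVM see z-scored predictors whose
centre and scale come from the training split only; the other methods use
the raw scale they are invariant to. Hyperparameters are fixed and
recorded in `classifier_config()` — there is no search. One deliberate
departure from the rpart default: the minimum node size for a split is 10
rather than 20, because training sets of tens of bursts per class
(typical at desk scale, and for rare behaviours in the field) otherwise
stop the tree before rare classes separate at all.

A burst is labelled by an algorithm only when its top class probability
reaches the threshold (default 0.5, the operating point at which
precision gain and abstention cost balance); otherwise it is
`NOT_CONCLUSIVE`. Two ensembles combine the bank: the mean vote averages
the six probability vectors and applies the same threshold; the majority
vote counts the six *thresholded* labels, excluding abstentions (an
abstention is a non-vote, not a seventh class; voting on raw argmax
labels is available via `majority_on = "argmax"`). Ties are deterministic
and seed-independent: an argmax tie goes to the alphabetically first
class; a majority tie defers to the mean-ensemble label when it is among
the tied classes, else to the alphabetically first tied class.

Abstention is monotone in the threshold for every per-algorithm label and
for the mean ensemble: raising the threshold can only turn concrete
labels into `NOT_CONCLUSIVE`. The majority vote is the one exception — as
members abstain, the recount can move between concrete labels — which is
why the invariant tests treat it separately.

## Cross-validation and reporting

`loocv()` refits the bank with each burst held out; `pacv()` holds out
one animal at a time, the transfer setting that matters for deploying a
captive-trained model on unknown individuals. Precision and recall per
behaviour come from confusion matrices with an abstention column:
`PR = TP/(TP+FP)` over conclusive predictions; `RE = TP/(TP+FN)` with
abstentions counted as misses, so `RE` never benefits from refusing to
answer. "Overall" figures are micro-averaged: overall PR is correct
conclusive predictions over all conclusive predictions, overall RE is
correct conclusive predictions over all bursts. This pair was chosen
because, under abstention, it makes overall precision exceed overall
recall for every method — the qualitative pattern such models show — and
because no other definition of "overall" is forced by the reporting
format; macro-averaging is available (`aggregate = "macro"`).

LOOCV probabilities are cached, and `threshold_sweep()` (default grid 0.3
to 0.8 in steps of 0.1) re-thresholds the cache rather than refitting:
the fits do not depend on the threshold, so a sweep that refits would
spend n × |grid| fits to compute the same numbers. Recall and the
abstention fraction are provably monotone in the threshold on a fixed
cache; precision is not a theorem (discarding a low-confidence *correct*
prediction lowers it), but rises monotonically on well-calibrated
prediction sets like the simulator's, where the property is asserted.

## Feeding-event fusion

All constants live in `detection_config()`, defaulting to the field
rules: a burst is **true feeding** when the SVM, the mean ensemble or the
majority ensemble says F (these are the predictors that carry feeding
most reliably); a time window of 30 min slides burst-by-burst, and a
window is feeding-dense when at least a third of *all* its bursts
(conclusive or not) are true feeding; bursts covered by any dense window
form candidates trimmed to their first and last true-feeding burst;
candidates separated by at most 120 min merge; merged candidates shorter
than 30 min are dropped. The window length is not dictated by the method
description, so it defaults to the one duration scale the rules state —
the 30-min minimum cluster length, i.e. 15 bursts at the 2-min
free-ranging spacing — and is configurable; windows are time-based, and
the gap allowance applies between candidate intervals, not between
individual bursts.

GPS clusters chain consecutive fixes at most 50 m apart (haversine on a
sphere of mean Earth radius 6,371,008.8 m) lasting at least 30 min, the
verbatim consecutive-pair rule rather than a distance-to-centroid
variant; centroids are arithmetic means of member coordinates. Each
feeding cluster is matched to the GPS clusters it overlaps in time:
several candidates merge when all pairwise centroids are under 50 m,
otherwise the largest time overlap wins, and a feeding cluster with no
candidate goes to an *unmatched report* — a batch pipeline must surface
what a field analyst would resolve by hand, never drop it. Matched event
boundaries are clamped to the GPS span plus one fix interval (3 or 15 min
taken from the animal's schedule metadata, not inferred from data gaps).
Finally the half-open hour before each event is scanned for
trotting/running bursts — identified by the same SVM-or-ensemble rule as
true feeding, for symmetry — flagging a likely chase.

Resting and walking clusters (`resting_walking_clusters()`) are a
re-designed, clearly-flagged extra — the original procedure for them is
not public — and stay off by default in the pipeline: a resting cluster
is a non-feeding GPS cluster whose overlapping bursts are majority R; a
walking cluster is a ≥ 15-min run of majority-W bursts with no GPS
cluster over it. Coalition handling is likewise deliberately minimal:
events are reported per animal, plus a suggestion when two animals'
events overlap in time with centroids under 50 m.

## The synthetic collar

The simulator exists to make the pipeline falsifiable, not to model
cheetah biomechanics. Each behaviour is a frequency-domain caricature —
offset + sinusoid + Gaussian noise, feeding adds Poisson head-jerk spikes
(rate 0.5/s, Exp(0.6) amplitudes) — with defaults (resting offset 1.0
noise 0.02; walking 1.5 Hz amp 0.3 noise 0.05; trotting 3.5 Hz amp 0.8
noise 0.1; grooming 0.5 Hz amp 0.15 noise 0.06; drinking 2 Hz amp 0.1
offset 0.8 noise 0.04; feeding noise 0.08) chosen once so that every
class pair separates by at least three pooled standard deviations in at
least one predictor, which the test suite asserts. GPS fixes jitter
uniformly within 10 m during stationary episodes — well under the 50-m
chain rule — move linearly during transits, and follow the ACC-informed
schedule (active interval during non-resting episodes, 6 h during rest).
All randomness descends from one master seed through per-animal derived
seeds, so streams are independent but exactly reproducible.

The canonical study scenario (`make_study_scenario()`) mirrors the
free-ranging deployment: two coalition males sharing one 21-day timeline
(bursts of 36 samples at 10 Hz every 120 s; GPS schedules 3 and 15 min),
nine feeding episodes of 60–150 min at distinct kill sites, six preceded
by a 10-min chase, with daily transits, grooming and drinking bouts, and
rest otherwise. Episode boundaries sit on the 2-min burst grid so
recovery can be scored to the burst. The captive scenario cycles the six
behaviours in 5-min episodes at the captive settings (40 samples at
10 Hz every 30 s) and can give one animal amplitude/noise-scaled signal
models (`shifted_animal`) to emulate an individual the trained model
transfers poorly to.

What passing tests on this simulator establishes: the plumbing,
definitions, and decision rules are implemented correctly, end to end.
What they do not establish: performance on real collars. Real bursts have
overlapping class signatures (grooming and drinking especially),
mixed-behaviour bursts, firmware drift, GPS error far above 10 m under
canopy, and behaviours absent from any training set — all the reasons the
field method reports abstentions and an unmatched-cluster queue instead
of forcing an answer.

## Problem sizes and runtime choices

The suites are sized for a single CPU: unit tests use 6–12 bursts per
class; the acceptance suite uses a two-animal captive set (144 bursts)
for the threshold sweep, 100 randomized streams of up to 200
bursts/fixes for the cluster oracles, 1,000 random bursts for the feature
oracle, and one full 21-day, two-animal study run (30,240 bursts) for
end-to-end recovery. `scripts/acceptance.R` uses three captive animals ×
20 bursts per class for the LOOCV figures. Larger sets change nothing
qualitatively; LOOCV cost grows linearly in bursts × fit time.

## Known limitations

* Single-axis by design; VeDBA/ODBA-style multi-axis features are out of
  scope.
* QDA needs more bursts per present class than the formal minimum of 5
  (its per-class covariance must be full-rank over six predictors, so
  at least 7 rows must remain after any hold-out); undersized classes
  surface as a QDA error rather than being silently dropped.
* The SVM's Platt-calibrated probabilities can contradict its own
  decision rule on degenerate training sets (exact duplicate points with
  conflicting labels) — a property of the calibration, handled by testing
  such cases against the label-symmetric methods.
* The boundary-correction rule only ever clamps feeding clusters toward
  the GPS span; events whose ACC evidence starts late are not extended.
* Coalition events are merged only as a suggestion; attributing a shared
  kill to one site remains an analyst decision.
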