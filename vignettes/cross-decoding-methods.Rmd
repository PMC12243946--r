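---
title: "Cross-decoding perception and visual working memory: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-decoding perception and visual working memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When an object is held in visual working memory (VWM), is the neural pattern
that stores it the same pattern evoked by seeing it?  The classic test is
cross-decoding: train a linear classifier on perceptual patterns, test it on
memory patterns.  Successful generalization argues for a shared code; a drop
relative to within-memory decoding argues that the memory code is
*transformed* away from the perceptual code.  The confound is that perceptual
and memory data are usually collected under different task conditions, so a
drop can reflect the task rather than the code.

The design implemented here removes that confound.  In every trial a target
object (one of four categories: bikes, couches, hangers, shoes) is encoded
and held across a 10 s delay; in 12 of the 16 trial conditions, exemplars of
a *different* object stream through the display during that same delay as
task-irrelevant distractors.  The same objects thus appear both as visible
distractors (perception) and as invisible memoranda (VWM) *within the same
delay periods of the same task*.  Training a classifier on a pair of objects
when they are distractors and testing on the same pair as memory targets —
with the irrelevant object held constant on both sides — probes perception/
memory overlap under matched conditions.

`vwmdecode` implements the full chain — task design, a synthetic data
generator with a controllable representational geometry, FIR beta-series
estimation, within/cross decoding, the cross-decoding ratio, and the group
statistics — so the whole analysis can be exercised end to end on data whose
right answer is known.

## Task design

Each 15 s trial is: fixation cue (0.5 s), target (0.5 s), early delay
(1.5 s), delay (10 s, blank or filled with 20 distractor images — 10
exemplars shown twice each, never back-to-back, at 0.3 s on / 0.2 s off),
and probe (2.5 s).  A run holds one trial of each of the 16 conditions
(4 targets x 3 distractor objects + 4 no-distractor trials), starts and ends
with an 8 s blank, and separates trials with 15 intertrial blanks (three 8 s,
twelve 2 s, randomly placed), for 304 s = 380 TRs at TR 0.8 s.  Two sessions
contribute 13 or 14 runs each; `c(13, 14)` is the canonical plan.

Condition order and blank placement are drawn uniformly per run from the
schedule seed (the source does not specify the randomization scheme beyond
randomness itself; no counterbalancing across runs is imposed).  Probe
identity is scheduled for completeness but plays no role downstream, since
decoding uses only pre-probe TRs.

## The synthetic generator

Every object has a *perceptual pattern* and a *memory pattern* over the
ROI's vertices, each a unit vector.  The memory pattern is the perceptual
pattern rotated by an angle `theta` within the plane spanned by the
perceptual pattern and a random orthogonal direction:

    memory = cos(theta) * perceptual + sin(theta) * q,   q ⟂ perceptual

so `theta = 0` is a fully shared code, `theta = pi/2` a fully transformed
(orthogonal) one, and `cos(theta)` is exactly the pattern correlation the
decoder must recover.  The neural signal of a trial is

* `gain_encoding * perceptual[target]` while the target is on screen,
* `gain_delay * memory[target]` as a sustained boxcar from target offset to
  probe onset (the simplest time course consistent with sustained delay
  activity; the source data do not constrain its shape), and
* `gain_distractor * perceptual[distractor]` during each distractor image,

convolved with a hemodynamic kernel and corrupted by i.i.d. Gaussian noise
per vertex and TR (an AR(1) option exists, but every reported property uses
the white-noise default).  The kernel is either the standard double-gamma
(peak 5 s, undershoot 15 s, peak:undershoot 6, unit peak, 24 s support) or
an identity tap (`fir_identity`) under which the simulated series equals the
FIR design times the true lag betas *exactly* — that is what makes
machine-precision GLM recovery testable.

### Default parameters and why

| parameter | default | meaning / rationale |
|---|---|---|
| `n_vertices` | 200 per ROI | large enough for stable linear decoding, small enough for seconds-scale runs |
| `theta` | 0 (`make_ground_truth`); pi/2 in the demo config | neutral geometry; the demo reproduces the transformed regime |
| `gain_distractor` | 1 | reference amplitude: one high-contrast distractor image |
| `gain_encoding` | 0.5 | a single, briefly attended target image; also limits the stimulus-transient carry-over into the late delay window (after convolution the encoding transient contributes 0.199·gain to the 9.6–12 s window, versus 6.44·gain for the sustained memory signal) |
| `gain_delay` | 0.5 | sustained memory amplitude an order of magnitude below the instantaneous perceptual drive; after convolution the delay window still carries more distractor than memory signal (3.62 vs 3.22) |
| `noise_sd` | 2 | puts distractor decoding at ceiling and within-target decoding high but below ceiling, so the ratio denominator is stable |
| `pattern_mean` | 1 | shared positive baseline so ROI-mean time courses are positive and BOLD-like; it is common to all objects, cancels in pairwise differences, and is removed by z-normalization |

The regime these defaults produce mirrors the qualitative facts of the real
experiment: distractor decoding saturates near 1, the delay-period response
is larger in with-distractor trials, and within-target decoding is robustly
above chance.  One deliberate departure: raw within-target accuracies here
(~0.9+) are higher than typical empirical values (~0.6), because the
cross-decoding *ratio* is only a stable estimator of the geometry when the
within-decoding denominator is far from chance.  Conclusions about the ratio
transfer; conclusions about absolute accuracy values do not.

What the generator does *not* emulate: anatomical cortical geometry,
physiological (cardiac/respiratory) noise, spatial noise correlations,
exemplar-level structure within object categories, probe- and
response-related signals, attentional fluctuations.  Passing tests therefore
show that the *analysis* recovers known geometry from data obeying its
assumptions — not that real cortex obeys them.

## FIR estimation and the split plan

Responses are estimated per vertex with a finite impulse response GLM: 30
lags x 16 conditions = 480 indicator regressors (lag `l` covers
`l * 0.8` s after trial onset, trial onsets rounded to the nearest TR, exact
half-TRs rounding up), plus one intercept per run; runs are detrended
(linear + quadratic) first; ordinary least squares, no prewhitening (no
autocorrelation correction is specified by the source analysis).

Because every condition occurs only once per run and intertrial gaps are
short, single-run estimates are unidentifiable — the package warns and then
fails on a rank-deficient design if you try.  Instead, runs are split into
odd and even halves within each session (odd run indices take the extra run)
and a GLM is fit to each leave-one-run-out combination within a half: seven
6-run combinations for a 7-run half, six 5-run combinations plus the all-6
combination for a 6-run half.  Either way each of the 4 splits yields 7
patterns — dependent within a split (they share runs), independent across
splits — for 28 patterns per condition and lag.  The leave-one-out rule
generalizes to other run counts with a warning.  (The source description of
this scheme contains an internal inconsistency about six versus seven
estimates per split; this implementation adopts seven, the reading under
which the totals add up.)

Condition-lag betas are averaged into an encoding period (4–6.4 s after
trial onset) and a delay period (9.6–12 s); with the closed-interval
convention each window covers exactly four lags ({5..8} and {12..15}).

## Decoding

Patterns are z-normalized (mean 0, population SD 1 across vertices — the
per-pattern reading of the normalization) and classified pairwise with a
linear SVM (LIBSVM via e1071, cost 1, no further scaling; hyperparameters
are the community defaults, as none are specified by the source).  A test
point exactly on the boundary goes to the first factor level, for
determinism.  Training uses all 21 patterns per condition from three splits;
testing uses the 7 patterns of the left-out split; the left-out split
rotates through all four positions and results are averaged.

All decoding is pairwise over the 6 object pairs.  Four-way decoding is
refused with an explanatory error: objects never distract themselves, so
distractor identity is unbalanced across target classes and a four-way
decoder would read out the (much stronger) distractor signal.

Two scheme families:

1. **Distractor → target.**  Train on a pair of objects as delay-period
   distractors, test on the same pair as targets — during the delay, during
   encoding, or in no-distractor trials — always in that direction only,
   because ceiling-level distractor decoding no longer tracks signal
   strength and the reverse direction would be uninterpretable.  The
   irrelevant object is matched between train and test by default
   (`irrelevant_match = "same"`, 12 pair instances); the `"different"`
   variant exists as a control.
2. **Encoding ↔ delay.**  Train on targets during encoding, test during
   delay, and vice versa; neither direction saturates, so both are run and
   averaged.  Available for with- and without-distractor trials.

Averaging order is fixed: rotations (and directions) → pair instances →
schemes → ROIs → sectors.  Sector values (posterior V1–V4, ventral LOT/VOT,
dorsal IPS2–IPS4) are unweighted means over each sector's ROI-level results,
never a decode of a merged ROI, so large ROIs cannot dominate.

**The cross-decoding ratio** `(cross - 0.5) / (within - 0.5)` is 1 under
full generalization and 0 under none.  Entries with `within <= 0.51`
(guard `eps = 0.01`) are flagged invalid, never dropped silently.  Because
the source does not say at which level the ratio was formed, both the
per-participant ratio and the group-level ratio (from participant-mean
accuracies) are emitted; the group-level one is the more stable and is what
the acceptance checks use.

## Group statistics

Per ROI and per sector: one-tailed one-sample t tests against chance (only
above-chance decoding is meaningful), one-tailed paired tests of the
within-minus-cross drop (the drop is expected null or positive), two-tailed
paired tests between sectors, and a two-way repeated-measures ANOVA with
trial type (with/without distractors) and decoding (within/cross) as
within-subject factors.  Benjamini–Hochberg correction is applied within
explicit families — the tests of one type within one ROI or sector, and the
three sector pairs — and the family identifier is carried in every output
row so the correction can be audited.  Test directions are fixed by the test
specification, never inferred from the data.  No sphericity correction is
applied (none is specified by the source); the ANOVA output says so.  For
the encoding↔delay comparison the "within" reference is the mean of
within-encoding and within-delay accuracy, mirroring the direction-averaged
cross measure.  Zero-variance inputs yield `t = 0, p = 0.5` at the null
value and an explicitly undefined (`NA`) p otherwise.

## Numerical and degenerate-input choices

* Half-TR onsets round *up*; any fixed rule would do, determinism is what
  matters.
* Distractor exemplar orders are rejection-sampled (≤ 1000 attempts).
* The GLM solves the normal equations by Cholesky; a failed factorization
  triggers a pivoted-QR diagnosis that names the collinear columns.
* Single-vertex ROIs decode but skip z-normalization with a warning;
  zero-variance patterns are an error.
* All randomness flows from explicit integer seeds through one child-seed
  derivation, so every stage is bit-reproducible.

## Problem sizes used by the automated checks

The package's own checks run the geometry-recovery study at the canonical
conditions — 200-vertex ROIs, 13 + 14 runs, 3-participant cohorts, 20 seeds
per rotation angle over `theta` in {0, pi/6, pi/3, pi/2}, plus a half-gain
sweep — and audit the statistics on 500 zero-signal cohorts.
`scripts/acceptance.R` reports the same quantities at a lighter scale (12
seeds, 2 participants per cohort, 300 null cohorts), which leaves the
group-level ratio estimates with a standard error of a few hundredths.

## Known limitations

* **Hemodynamic carry-over.**  Because the forward model convolves the
  encoding transient with a 24 s kernel and the delay window is fixed at
  9.6–12 s, a little target-perceptual signal genuinely sits in the
  delay-period betas whenever `gain_encoding > 0`.  A perception-trained
  classifier reads it: at `theta = pi/2`, where the memory code carries no
  perceptual information at all, cross-decoding therefore sits slightly
  *above* chance (~0.53 at the default gains rather than 0.50; setting
  `gain_encoding = 0` restores exact chance).  This is a property of fMRI's
  temporal blurring, not of the classifier, and real delay-period analyses
  face the same contamination.
* **Asymmetric classifier training.**  The distractor-trained classifier
  sees a stronger training signal than the memory-trained one (3.62 vs 3.22
  in delay-window beta units at the default gains).  Near saturation both
  recover the discriminant direction equally well and the shared-code ratio
  sits at ~1.02–1.04; at lower SNR (e.g., all gains halved) the
  better-trained cross classifier slightly outperforms, and the shared-code
  ratio rises to ~1.1 rather than staying at 1.  An SNR change alone thus
  never *mimics* a representational transformation (it cannot push the
  ratio below 1), but the ratio's symmetric interpretation around 1 holds
  only when within-decoding is strong.
* The forward model truncates each trial's response at the 24 s FIR window,
  so the tail of late-delay activity convolved with the undershoot is not
  simulated beyond lag 29.
* A lag that falls beyond the end of every run of a combination (possible
  when the same condition ends all of them) is unobservable; its beta is
  reported as `NA` and excluded from diagnostics — both decoding windows are
  unaffected.
* OLS without prewhitening is only exactly right under the white-noise
  default; with the AR(1) option the estimates stay unbiased but the
  downstream t tests inherit mild dependence.
* The ratio is undefined when within-decoding is at chance; in that regime
  only the raw accuracies are interpretable (the validity flag marks this).
* Accuracies near ceiling compress real geometry differences (a saturation
  the source analysis also acknowledges); the default regime keeps
  cross-decoding off the ceiling at nonzero `theta`, but very low-noise
  configurations will not.

## A minimal run

```{r, eval = FALSE}
library(vwmdecode)
cfg <- vwm_config(
  n_participants = 3,
  rois = data.frame(name = c("V1", "LOT", "IPS2"),
                    sector = c("posterior", "ventral", "dorsal"),
                    n_vertices = 200),
  theta = pi / 2,     # fully transformed memory code
  seed = 1)
res <- run_pipeline(cfg, out_dir = "vwm_out")
summary(res)
```
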