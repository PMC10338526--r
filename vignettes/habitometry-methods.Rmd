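---
title: "Methods: simulating and analysing pallidostriatal activity during goal-directed and habitual reward seeking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing pallidostriatal activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitometry)
```

# Scientific setting

Rodents trained under a **random-ratio (RR)** operant schedule (reward after
a random number of responses) develop goal-directed reward seeking, while
**random-interval (RI)** training (reward for the first response after a
random delay) promotes habitual seeking. The two strategies are dissociated
behaviourally by **reward devaluation**: pre-feeding the reward to satiety
suppresses responding in a subsequent nonreinforced extinction test only in
goal-directed animals. Fiber photometry of GCaMP-expressing pallidostriatal
(arkypallidal) neurons during terminal RR20 and RI120 sessions shows
condition-dependent peri-event calcium dynamics — larger RI responses around
nose pokes and rewarded magazine entry, larger RR responses at rewarded
magazine exit — and within-session drift of those responses. A linear
support-vector machine trained on peri-event activity can decode the
training schedule from single trials.

`habitometry` re-implements this analysis chain as a tested pipeline and
pairs it with a synthetic-data generator, so every stage can be exercised
and validated without animal recordings.

# The operant simulator

## Schedule engines

- **RR(v)** reinforces each active nose poke independently with probability
  $1/v$, so pokes-per-reward is geometric with mean $v$. This is the
  maximum-entropy reading of "one reward on average every $v$ responses";
  only the mean is prescribed.
- **RI(v)** arms a reward at a random delay after the previous reward
  delivery, and the first active poke at or after arming is reinforced.
  Delays are exponential with mean $v$ seconds by default (the memoryless
  reading of "random interval"); a uniform $(0, 2v)$ alternative is
  available via `ri_arming = "uniform"`. The arming clock restarts at
  reward delivery, not at magazine collection.
- **FR(v)** reinforces every $v$-th response; **EXTINCTION** never
  reinforces.

Sessions stop at whichever binds first of a 30-min time cap and a 60-reward
cap (both configurable, including `Inf` for calibration runs). Curricula
follow the staged progressions RI30 (2 d) / RI60 (2–3 d) / RI120 (4 d) and
RR2 (1–2 d) / RR5 (2–3 d) / RR10 (2–3 d) / RR20 (2–3 d), defaulting to the
minimum day counts.

## The behavioural agent

Responding is modelled as independent homogeneous Poisson processes per
event type (active pokes, inactive pokes, unrewarded magazine checks), with
an optional deterministic regular-grid responder for calibration. After a
reinforced poke the agent enters the magazine at a fixed 1-s latency and
dwells for an exponential time (mean 2 s). In devalued extinction the
active-poke rate is multiplied by a `devaluation_factor`: 0.3 for the
default goal-directed agent, 1.0 for the habitual agent. Default rates put
the RR agent (0.5 Hz) above the RI agent (0.25 Hz); the literature this
emulates reports only that ordering, not magnitudes, so magnitudes are
configurable and were fixed once at values producing realistic per-session
response and reward counts.

A zero-rate agent is permitted when a finite time cap guarantees
termination (it simply earns nothing); configurations that could never
terminate (no time cap and no reinforceable responding) are rejected as
degenerate.

## The fluorescence generator

Raw fluorescence is
$$F_\mathrm{RAW}(t) = F_0 + \sum_e a_e\,K(t - t_e) + \varepsilon(t),$$
with $K$ a double-exponential indicator kernel normalised to unit peak
(rise 0.2 s, decay 1.0 s — GCaMP6s-like; the kernel shape is a modelling
choice, not a measured quantity), $\varepsilon$ i.i.d. Gaussian per frame,
and the output clipped to a small positive floor. The amplitude of event
$e$ is the (condition × event class) base amplitude plus its decile block
index (0–9, by ordinal position within its class) times a per-block drift
slope. At the defaults ($F_0 = 100$, noise SD 0.5, amplitudes 2–6 units)
transients correspond to 2–6% dF/F. Default amplitudes encode the reported
orderings (RI > RR at nose pokes and rewarded magazine entry, RR > RI at
rewarded magazine exit, no difference for unrewarded entry/exit);
`default_event_amplitudes(separation = 0)` yields a null generator with
identical conditions.

What the generator does **not** emulate: photobleaching and slow drift,
motion and hemodynamic artefacts, indicator saturation and nonlinearity,
Poisson shot noise, and any biophysical neuron or dopamine-receptor model.
Passing tests therefore certify the analysis chain's correctness and
calibration on idealised recordings, not robustness to every artefact of
real photometry.

# dF/F preprocessing

Three causal stages at 30 frames/s:

1. $F_\mathrm{AVG}(t)$: sliding mean of $F_\mathrm{RAW}$ over a trailing
   0.75-s window (including the current frame; a centered variant is behind
   `centered_avg`).
2. $F_\mathrm{BASELINE}(t)$: minimum of $F_\mathrm{AVG}$ over the 3-s
   window **strictly preceding** the frame; then
   $\Delta F/F = (F_\mathrm{RAW} - F_\mathrm{BASELINE})/F_\mathrm{BASELINE}$.
3. Exponentially weighted smoothing over a trailing 1-s window with
   weights $\propto e^{-\Delta t/\tau}$, $\tau = 0.2$ s, normalised to sum
   to one over the defined frames.

The first 3 s of each trace have no complete baseline window and are `NA`,
not zero; they are excluded from event detection and peri-event extraction.
Whether the upstream acquisition software's windows are causal or centered
is not documented, so causal was chosen throughout for consistency and the
centered mean is available behind a flag. Calcium events are maximal runs
of frames with smoothed dF/F at or above a 2% threshold (the threshold is
applied to the smoothed trace; applying it unsmoothed is possible via
`dff_params(smooth = FALSE)`), summarised as events/min and mean duration.

Numerical notes: window lengths are `round(seconds * fps)` frames; the
sliding mean uses cumulative sums (error $\sim 10^{-11}$ relative on
hour-long traces, verified against a naive per-frame oracle at $10^{-10}$);
the rolling minimum is exact. dF/F is scale-invariant by construction,
which the suite asserts at $10^{-12}$.

# Peri-event analysis

Snippets cover the half-open window $[t_e - 2, t_e + 2)$ s: 60 pre-frames,
then the event frame (first frame at or after $t_e$) at 0-based index 60,
for 120 frames total. Events whose window touches undefined frames are
dropped and counted. Six classes are used: rewarded/unrewarded nose poke
(NP R+/R−), magazine entry (M_entry R+/R−) and magazine exit
(M_exit R+/R−).

The trial-progression analysis orders a class's events by time, partitions
them into 10 contiguous blocks — block $b$ (0-based) holding ordinals
$\lfloor bn/10\rfloor$ to $\lfloor (b+1)n/10\rfloor - 1$, a disjoint cover —
and regresses the block-mean change metric on block index by OLS. The
default per-event metric is mean post-window dF/F minus mean pre-window
dF/F; "degree of change" is not pinned down by the source analysis, so peak
and baseline-subtracted AUC are selectable alternatives. Ordinal position,
not wall-clock time, defines the deciles.

`pointwise_group_compare()` runs a Welch t test per frame with
Benjamini–Hochberg correction across the 120 frames and reports maximal
significant runs. This deliberately lightweight plumbing approximates a
repeated-measures ANOVA + posthoc time-range readout without reimplementing
that machinery (which is out of scope).

# Decoding protocol

Features per trial default to two scalars: mean dF/F over the 2 s before
and the 2 s after the event (the event frame belongs to the post half);
the input range is configurable. Each of 400 repeats undersamples the
majority class without replacement to the minority count, draws a fresh
stratified 4-fold split, standardises features with training-fold
statistics only, fits a linear SVM (`e1071`, cost 1 — kernel and
regularisation are unstated in the protocol being modelled, so the
simplest choice is fixed and configurable), and pools the held-out decision
values into one ROC/AUC and one confusion matrix at the zero-decision
threshold. Accuracy, sensitivity and specificity use the standard
confusion-count formulas; with balanced evaluation sets accuracy equals
(sensitivity + specificity)/2 exactly, which the suite asserts. ROC curves
are vertically averaged on a 101-point false-positive-rate grid.

**Chance calibration.** With balanced classes, undersampling leaves the
dataset unchanged, so 400 repeats on a single label-permuted dataset all
inherit that dataset's chance-level separation (SD ≈ 0.03 at 200
trials/class) rather than averaging it away. `permute_labels = TRUE`
therefore permutes labels afresh in every repeat — a standard
permutation-null control — and its 400-repeat mean estimates the empirical
chance level (measured: AUC 0.500, accuracy 50.0%) that one-sample t tests
compare against. Per-event-class models are trained separately, and
`compare_to_chance()` provides the two-tailed one-sample t test.

# Behavioural statistics

`devaluation_test()` runs a two-sided Wilcoxon signed-rank test on paired
valued/devalued counts. For up to 25 informative pairs the p-value is
exact over all $2^n$ sign patterns, computed by a rank-polynomial
convolution (doubled ranks keep tie-averaged ranks integral) that is
mathematically identical to full enumeration; the suite verifies it against
brute-force enumeration for $n \le 10$ and against the classical
implementation on tie-free data. Zero differences are dropped (classical
convention rather than Pratt's); all-tied data yield p = 1 with a flag.
Above 25 pairs the tie- and continuity-corrected normal approximation is
used. Six uniformly decreasing pairs give $p = 2/2^6 = 0.03125$, the
familiar floor for a cohort of six.

`group_compare()` pairs the tie-corrected Kruskal–Wallis omnibus test with
Dunn's pairwise z tests on mean ranks, Bonferroni-adjusted over all
unordered pairs (the adjustment is unnamed in the source analyses;
Bonferroni is the conservative default and any `p.adjust` method can be
substituted). `normalize_evaporation()` subtracts the mean control-cage
evaporation loss from raw two-bottle volumes, clamping at zero with a flag.

# Reproducibility and problem sizes

Every stochastic function takes a `seed` and restores the ambient RNG
state; `run_pipeline()` derives per-stage sub-seeds from one master seed,
so a configuration reproduces byte-identical summary JSON. The test suite
runs at deliberately desk-scale sizes chosen for tight Monte-Carlo error at
interactive runtimes: schedule calibration uses 1 000–10 000
reinforcements (3-SEM bands of a few percent), the decoding null uses the
protocol's full 400 repeats at 200 trials/class, type-I error control uses
1 000 simulated cohorts, and parameter-recovery checks use 100 seeded
runs. The default `pipeline_config()` similarly trims session length and
resample counts; production analyses should raise `n_resamples` to 400.

# Known limitations

- The generator's amplitudes and rates encode orderings, not fitted
  magnitudes; absolute dF/F effect sizes are not calibrated to tissue.
- The pointwise comparison is not a repeated-measures ANOVA and ignores
  within-subject correlation across frames beyond the BH correction.
- The devaluation agent scales a single Poisson rate; it does not model
  satiety dynamics within the extinction session.
- Real-data headline quantities (condition AUCs, trace statistics) depend
  on recordings that are not bundled, so the package validates calibration
  and protocol properties rather than reproducing those numbers.
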