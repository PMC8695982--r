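---
title: "Models and methods behind alphasurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind alphasurf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphasurf)
```

## The scientific problem

`alphasurf` studies how the *type of task instruction* given during motor
training shapes (a) motor performance and (b) the attentional brain networks
visible in alpha-band (7–15 Hz) EEG. The motor task is a virtual surfing
game: a participant steers a boat with a joystick and gains speed by
aligning the boat with incoming waves. Three instruction conditions are
compared: implicit training without instructions (IMP), explicit written
instructions disclosing the task rule (E), and explicit-implicit visual
cueing with go/no-go buoys (E-IMP). Performance and epoched EEG are
compared between a Baseline and a Retention phase.

Because the corresponding human dataset cannot be regenerated, the package
ships *generators* for both data modalities: a closed-loop kinematic
simulator of the surfing task with parameterized agent skill, and a
synthetic epoched-EEG generator with planted topographic effects. Every
downstream method — kinematic metrics, the behavioural test battery, the
temporal-spectral-evolution (TSE) transform, and the randomization-based
topographic ANOVA (TANOVA) — is exercised end to end against these
generators, so all statistical claims in the test suite are claims about
the implementation, not about human data.

## The task simulator

### Acceleration law

The boat's forward acceleration $a_w$ (in maritime units per second
squared, m.u./s²) is updated once per simulation step as a four-branch
function of the boat pitch $\varphi$ (deg):

$$
a_w(i) = \begin{cases}
a_w(i-1) + c_s\,\varphi + 0.1 & \varphi \in [15°, 90°],\; a_w(i-1) < 20\\
20 & \varphi \in [15°, 90°],\; a_w(i-1) \ge 20\\
a_w(i-1) - 5\,c_s\,\varphi + 2 & \varphi \notin [15°, 90°],\; a_w(i-1) > 0\\
0 & \varphi \notin [15°, 90°],\; a_w(i-1) \le 0
\end{cases}
$$

with $c_s = 0.17$ m.u./(s²·deg) and a hard cap of 20 m.u./s². The printed
third branch, evaluated literally, *gains* up to $+2$ per step when
$\varphi$ is near zero and is unbounded below for large out-of-range
pitch, so all outputs are clamped to $[0, 20]$. The package keeps the
literal reading as the default (`decel_mode = "literal"`) and offers a
strictly decelerating reading $a_w - (5 c_s \varphi + 2)$ as
`decel_mode = "monotone"`. The two modes differ only in the out-of-range
branch; `accel_update()` is property-tested against an independent
brute-force branch evaluator in both modes.

One consequence of the literal branch is worth spelling out: once a boat
has accelerated and the wave passes ($\varphi \to 0$), the $+2$ gain holds
the clamped acceleration at the cap, so trial speed keeps rising to the
end of the trial. The qualitative "speed bump" shape — peak speed after
wave onset and before the envelope ends — therefore holds in the
`monotone` mode, and that is the mode under which the package tests this
shape property.

### Steering, pitch, and drag

The joystick angle $\gamma_z$ (mechanically limited to ±15°) maps to a
yaw torque $|\tau_s| = \gamma_z \cdot c_R$ with $c_R = 0.27$ N·m.u./deg.
Yaw rate and forward speed integrate with first-order linear drags
(defaults: rotational 2 s⁻¹, translational 0.35 s⁻¹), replacing the
rendered ocean physics of the original environment with an explicit,
testable model.

The boat pitch is only stated to be proportional to the wave slope and
inversely related to the absolute alignment error
$\beta = |\omega - \alpha|$ (wave direction minus heading, folded to
$[0°, 180°]$). The package fixes the functional form as

$$\varphi(t) = \varphi_{peak}\, E(t)\, \max(0,\, 1 - \beta(t)/90°),$$

with $E(t)$ a raised-cosine envelope (8 s default) and
$\varphi_{peak} = 60°$. These two constants were chosen once so that the
closed-loop time to peak speed of a competent agent falls inside the
analysis window used for the free-surfing task (see below); they are not
fitted to data. The *incoming wave onset* — the epoching and ToI anchor —
is the first sample where $\varphi$ crosses 15° upward. Trials in which a
badly misaligned boat never reaches 15° receive a nominal onset at the
time a perfectly aligned boat would have crossed it, so every trial stays
analyzable.

### The agent and the cohort generator

The simulated participant is a proportional controller: joystick command
$\gamma = k_p \cdot \mathrm{err} + \eta$, saturated at ±15°, with white
command noise $\eta \sim N(0, \sigma^2)$, a systematic alignment bias,
and a reaction delay (0.3 s) that only governs obstacle avoidance.
`simulate_cohort()` draws 3 × 12 agents (the study-scale design) and
plants learning as additive Retention changes to bias and noise SD.

Two generator choices deserve explanation:

* **Noise calibration.** The joystick limit truncates the command noise,
  so the *measured* joystick variability is smaller than the generator
  SD. The default Baseline noise SD (12°) and per-group Retention deltas
  (−4.15, −10.75, −11.05° for IMP, E, E-IMP) were calibrated once against
  this truncation so that the measured per-group median
  joystick-variability changes land near the study-scale values
  (−2.27, −8.4, −8.69°). Per-subject learning deltas are jittered with
  SD 4° so the spread of change scores is of the same order as the
  study's interquartile ranges; the resulting pairwise effect sizes are
  d ≈ 1.5–2.
* **Attentional lapses.** On a configurable fraction of trials (default
  15 %) the agent steers 90° off the wave. Without lapses every simulated
  trial is a Hit; with them both Hit and Missed waves occur at realistic
  rates (~15 %).

What the generator does *not* emulate: continuous drift of heading
between waves, speed-accuracy trade-offs, fatigue, or any within-trial
adaptation. Passing recovery tests therefore shows that the pipeline
recovers effects of this planted form at study-scale sizes — not that the
original human effects must take this form.

## Behavioural metrics

Raw logs are linearly interpolated to a uniform 50 Hz grid
(`resample_log()`). Metrics are computed over a fixed post-onset *time of
interest* (ToI): 0.15–6.4 s for the free-surfing Horizon task (HT), 0–7 s
for the Obstacle task (OT). Sample inclusion is half-open
`[lower, upper)`; the ToI clock starts at the 15°-crossing sample itself.
`compute_toi()` reports the per-trial time of maximum smoothed speed
(zero-phase 2nd-order Butterworth, 5 Hz cut-off) with its median and
2.5/97.5 percentile interval as diagnostics for the fixed window.

Per trial: mean horizontal speed, distance surfed toward the finish line
(|Δ pos_y| between the exact window edges, linearly interpolated),
mean |β|, and the sample (n−1) standard deviation of the joystick angle.
A trial is a *Hit* when mean ToI speed ≥ 0.98 × the speed at the window
start (the 2 % decay allowance for drag); at v₀ = 0 the rule degenerates
to "any speed gained". OT trials are *misaligned* when max |β| over the
OT window reaches 20°, giving the TP/TN/FP/FN taxonomy, success rate
(TP+TN)/N and obstacle-avoidance inability FN/N.

Participant summaries average HT metrics over all trials (Hits and
Misses pooled), OT kinematic metrics over Obstacle trials only, and OT
rates over all trials; empty subsets yield missing values, never zeros.

## Behavioural test battery

Change scores (Retention − Baseline) are tested with the study's battery:
Wilcoxon signed-rank within groups (exact null up to n = 25 without ties,
normal approximation with tie correction otherwise); between groups, a
normality gate (Lilliefors/KS with estimated parameters, per group,
p ≥ 0.05) and a homogeneity gate (Levene, p > 0.05) select one-way ANOVA
with Tukey-Kramer post-hocs, else Kruskal-Wallis with Holm-corrected
pairwise Mann-Whitney U tests ("Bonferroni-Holmes" is read as the Holm
step-down). Zero-variance groups force the nonparametric branch. Pairwise
effect sizes are pooled-SD Cohen's d with $r = d/\sqrt{d^2+4}$.

## Synthetic EEG

Electrodes lie on a Fibonacci lattice over the upper unit hemisphere,
with scalp regions (frontal, central, temporal left/right, parietal,
occipital) assigned by angular sector; a CSV loader accepts real layouts.
Per epoch and electrode,

$$x(e,t) = \Big[A_0 + u_{subj} + \sum_k \delta_k(\text{cell})\,
G_k(e)\, W_k(t)\Big] \sin(2\pi f_\alpha t + \phi_{trial})
+ \text{pink} + \text{white},$$

with a 10 Hz carrier (mid alpha band) and uniform trial-random phase
shared across electrodes, spherical Gaussian patches $G_k$, smooth
cosine-ramped time windows $W_k$, subject random offsets, and per-electrode
1/f (spectrally shaped) plus white noise. Defaults are desk-scale (250 Hz,
32 electrodes, 4 subjects/group); study-scale sizes are configuration
values. There is no volume-conduction mixing and no artifact model.

`plant_alpha_pattern()` encodes the expected instruction-dependent
learning pattern as planted deltas on the Hit−Missed contrast at
Retention: E-IMP gains contrast over frontal, occipital and
right-parietal patches; E loses contrast over bilateral fronto-temporal
patches; IMP is untouched. The active window is −130 to +170 ms around
the incoming wave onset.

## TSE transform

Per trial and electrode: zero-phase band-pass to 7–15 Hz, full-wave
rectification, zero-phase low-pass at half the band's low-cut (3.5 Hz),
then averaging over trials within subject × phase × trial-type cells.
Filters are linear-phase Hamming windowed-sinc FIRs (2 Hz transition)
applied by FFT convolution with exact group-delay compensation and
mirror padding of one filter length; the contract is spectral (a unit
10 Hz sinusoid settles at 2/π of its amplitude, out-of-band leakage
< 5 %), not sample-exact equivalence with any particular toolbox
implementation. Small negative values left by the smoothing filter are
clamped to zero and counted. Trials are smoothed first and averaged
second; the difference from the reverse order is second-order.

## TANOVA

The mixed design is 3 (group, between) × 2 (phase, within) × 2
(trial type, within). Effect components come from the classical
unweighted marginal-means decomposition of the subject × cell maps (cell
means per group, grand mean removed, interactions as residuals from the
additive reconstruction — the components reconstruct the cell means to
machine precision). The statistic at each time point is the
root-mean-square of the effect component across electrodes and effect
levels, a generalized global field power of the effect. TSE amplitude
maps enter as-is: no average re-reference and no GFP normalization,
because TSE maps are non-negative amplitude fields, not potentials.

Randomization schemes per effect role:

* within-subject effects — independently shuffle the four condition
  labels inside each subject;
* the between-subject effect — shuffle the group assignment across
  subjects;
* interactions involving group — remove each subject's mean map, then
  shuffle condition labels within subjects. (The subject-centering step
  is this package's choice for the mixed design.)

$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{perm})$, so p is
never 0 and can reach 1; 5000 permutations per time point is the default.
One permutation sequence is reused across time points, so the smoothness
of the p series reflects the data rather than permutation noise.

**Duration correction.** To control multiple testing across time, each
permutation in the pool is itself scored against the pool (rank at each
time point, pool size n+1 to mirror the add-one rule), its longest run of
sub-α p values is recorded, and the 95th percentile of those maximal runs
becomes the *critical duration*; only observed runs longer than that are
reported. On tiny designs an `exhaustive` mode enumerates all assignments
and the suite verifies it against brute-force oracles.

Window tests average maps over a window before a single randomization
test. Post-hoc contrasts are per-subject map subtractions (e.g.
Hit − Missed), optionally baseline-normalized (Retention contrast minus
Baseline contrast); two-sample pairwise TANOVAs shuffle group labels on
those contrasts. Electrode t-maps (threshold |t| > 2.36, a configurable
constant) are descriptive only — hypothesis decisions rest on the
TANOVAs.

## Numerical and interface choices

* Angles in degrees throughout; β folded to [0°, 180°]; time series are
  0-based in seconds with half-open intervals `[start, end)`.
* The joystick variability metric is a standard deviation (n−1); tables
  elsewhere may label the same quantity "variance".
* The time-to-peak interval is a percentile (2.5/97.5) interval; OT
  misalignment is operationalized as max |β| within the OT window.
* The epoch container is a plain-text directory (`meta.json` +
  long-format `data.csv`) so datasets remain portable and diffable;
  configs round-trip through YAML/JSON; TANOVA results through JSON.
* Every stochastic stage derives its seed from one master seed
  (`derive_seed()`), making full pipeline runs bit-identical.

## Problem sizes used by the test suite

The acceptance-style properties run at sizes chosen to make the suite a
routine check rather than a compute job, and those sizes are fixed:
the acceleration oracle uses 10⁵ random inputs; TANOVA null calibration
uses 200 replicates of a 2-subjects-per-group, 16-electrode, 100 Hz
generator with 99 permutations; the planted-interaction power regression
uses 25 replicates at 3 subjects per group and 6 trials per cell with
contrast scale 3.4 µV (≈1.5× the combined noise SD), a configuration
calibrated once to near-complete detection and then frozen; behavioural
recovery uses 15 full 36-subject cohorts. Under the null generator the
pointwise p values are uniform and the duration-corrected family-wise
false-positive rate stays inside the binomial 95 % band around 5 %.

## Known limitations

* The simulator's 2-D kinematics with linear drag are a deliberate
  simplification of the rendered ocean environment; constants of the
  pitch law are design choices, not estimates.
* The literal acceleration branch keeps boats accelerating after the
  wave passes (see above); use `monotone` mode when a physically decaying
  profile matters.
* The EEG generator has no volume conduction, no artifacts and a single
  fixed alpha carrier; TANOVA calibration under this generator does not
  certify behaviour under real EEG preprocessing chains.
* The critical durations reported on real data by the original study
  (279 ms HT, 316 ms OT) depend on that data and are not reproducible
  from synthetic inputs; the package validates the *procedure* (its
  calibration and power), not those constants.
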