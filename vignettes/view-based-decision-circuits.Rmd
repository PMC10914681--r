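---
title: "View-based decision circuits: models, synthetic data, and population analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{View-based decision circuits: models, synthetic data, and population analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viewchoice)
```

# The problem

In primate value-based choice tasks with *sequentially* presented options,
the decision can be represented in two reference frames: relative to object
identity (choose object A vs object B) or relative to the current view
(choose the currently viewed vs the previously viewed option). A view-based
code is abstract — it generalizes over objects — but it poses a readout
problem: the motor system ultimately needs the chosen object. This package
implements, end to end, the computational apparatus for studying this
question: behavioral models of sequential economic choice, a three-stage
firing-rate circuit that makes view-based decisions and re-expands them
into object choices, a synthetic-session generator, and the single-neuron,
decoding, and representational-similarity analyses used to characterize
the resulting codes.

All inputs are synthetic: the generator emulates recording sessions of a
two-object choice task with block-wise reward probabilities drawn from
{0, 0.15, 0.35, 0.5, 0.65, 0.75, 0.85, 1.0} in blocks of 15–40 trials and
trial-wise cued reward magnitudes from {0.25, 0.4, 0.65} mL, with a small
0.05 mL consolation reward on non-rewarded trials. Control variants cover a
four-object task (probability only, 0.85/0.15 reversing between objects)
and a two-juice task (reward type × magnitude, association switching twice
per session).

# Behavioral models

## Reinforcement-learning family

The core model is *reversal* reinforcement learning with a softmax policy:
after a choice of A with binary outcome $R_t$,

$$V_{A,t+1} = V_{A,t} + \alpha (R_t - V_{A,t}), \qquad
  V_{B,t+1} = V_{B,t} + \alpha (-R_t - V_{B,t}),$$

so the unchosen option is updated in the opposite direction — appropriate
for a task whose probabilities reverse in blocks — and

$$P(A) = \bigl(1 + e^{-\beta (V_A - V_B)}\bigr)^{-1}.$$

Variants: `basic` (no unchosen update), `*_2lr` (separate learning rates
for rewarded and unrewarded trials), and Pearce–Hall variants whose
learning rate tracks the unsigned prediction error,
$\alpha_t = \gamma\,|\delta_{t-1}| + (1-\gamma)\,\alpha_{t-1}$, with
$\gamma$ a fitted decay. This associability form is the standard
Pearce–Hall choice; it is isolated in one place (`rl_step`) and swappable.
Values start at 0 with no free initial-value parameter. Fitting is maximum
likelihood with Nelder–Mead from random restarts (20 by default,
tolerance 1e-6), with learning rates mapped through a logistic and the
inverse temperature through an exponential so the search is unconstrained.
Choice probabilities are floored at 1e-12 before logs; a fitted $\beta$
near zero flags an uninformative likelihood (e.g., deterministic
alternation). AIC $= 2k + 2\,\mathrm{negLL}$ and
BIC $= k \ln n + 2\,\mathrm{negLL}$ hold by construction and
`compare_rl_models()` tabulates summed criteria and per-session winners.

The `simulate_agent()` utility adds an optional magnitude weight
(`w_mag`): the decision utility is $U_X = V_X + w_{mag} M_X$ with $M_X$
the cued magnitude in mL. The pure probability-tracking agent
(`w_mag = 0`) is the generative model matched by the likelihood; the
magnitude-sensitive agent produces sessions whose choices trade
probability against magnitude, which the session-level logistic then
quantifies.

## Session values and the optimality grid

Within a session, `session_value_model()` fits
$\mathrm{logit}\,P(A\ \text{chosen}) = \beta_0 + \beta_1\,\mathrm{AFirst} +
\beta_2\,\Delta RM + \beta_3\,\Delta Prob$, and the session-specific
object value is $\beta_2 RM + \beta_3 Prob$ — the animal's own
magnitude-versus-probability exchange rate. Complete separation triggers a
ridge-stabilized IRLS refit (penalty 0.01 on slopes), flagged in the
result. `attach_values()` rescales the session values affinely to [0, 1]
by the session minimum/maximum, the scale the circuit and the tuning
curves require.

`optimality_grid()` replays the reversal learner over
$\alpha \in [0,1]$ (step 0.01) × $\beta \in [0,5]$ (step 0.05) — 101 × 101
cells — on the block structure of given schedules and records mean
obtained volume. All cells advance in lock-step through each trial
(vectorized over the grid), so the full grid at 5 repetitions × 5
schedules runs in seconds. In the equal-weighting mode the decision
variable adds the cued magnitude rescaled by its largest level to the
probability estimate; a probability-only mode ignores magnitudes.

# The circuit model

`simulate_circuit_trial()` integrates a three-stage firing-rate network
(Euler–Maruyama, dt = 0.5 ms; additive Gaussian noise of amplitude
$\eta$ = 0.025 scaled by $\sqrt{dt}$ in every rate equation; synaptic
variables noise-free; deterministic at $\eta = 0$):

1. **Value comparison with integral feedback.** Two populations $V_1,
   V_2$ receive complementary value inputs $1 - V_X$ and $V_X$ while an
   object is on screen; memory populations $M_i$ integrate $[V_i]_+$ and
   feed back inhibition $-w_{VM} [M_i]_+$. After the first cue, the memory
   holds $M_2 \approx V_{first}/w_{VM}$, so the response to the second cue
   is the *difference* $V_{second} - V_{first}$: the comparison is
   implemented by history-dependent suppression, and $V_2$'s value tuning
   reverses sign between the first cue and the delay — the signature of
   integral feedback control.
2. **A bistable switch gating a winner-take-all decision.** An E–I pair
   with a low- and a high-activity state receives the facilitating
   object-selective drive; facilitation builds during the first cue so the
   drive crosses the saddle-node of the low branch only during the second
   cue, switching the background input $I_0 = r_E$ of the choice
   populations $C_1/C_2$ (self-excitation $w_+$ = 2.5, mutual inhibition
   $w_-$ = 2) from the stable low regime into the winner-take-all band.
   The value inputs then bias which attractor wins: $C_1$ codes choice of
   the first-viewed, $C_2$ of the currently viewed option — a view-based
   choice, independent of object identity.
3. **Expansion recoding to object choice.** Object-sequence units (A1 =
   "A viewed first", A2 = "A viewed second", etc.) arise from short-term
   synaptic depression of object-selective drive; combination units
   threshold the sum of a sequence unit and a choice unit
   ($f(u) = [u - 1.35]_+$), so each fires only for one conjunction of
   sequence and view-choice; their sums route to an object
   winner-take-all $C_A/C_B$. This expansion is exactly what a linear
   readout needs to recover object choice from a view-based code.

## Parameter choices the reference set leaves implicit

The reference parameter set fixes all coupling constants, time constants,
transfer functions, and $\eta$. Implementing the equations verbatim,
however, exposes four places where unit scales are implicit, and taking
the reference numbers at face value there contradicts the circuit's
described function. The package resolves them as explicit parameters with
documented defaults:

- **Memory self-coupling.** The memory population is a perfect integrator
  ($w_{MM} = 1$ under the $k = 1$ convention, else $1/k$): with the
  transfer slope $k$ = 0.2, the reference $w_{MM} = 1$ is read as the *effective*
  self-coupling of $[M]_+$ (i.e., the $k = 1$ normalization). A literal
  product $w_{MM} k = 0.2$ would leak the memory away with a ~12 ms time
  constant and destroy the comparison.
- **Switch drive (`b_gain` = 1.5)** and **presynaptic facilitation.** The
  low-activity branch of the E–I switch is annihilated only at an input
  near 2.05, while $w_b (r_A + r_B) \le 0.2$; `b_gain` is the firing-rate
  scale of the object-selective input populations, and facilitation is
  driven by the presynaptic object drive ($k_2 (r_A + r_B) w_F$, the
  standard use-dependent form) so that the facilitated second-cue drive
  crosses the saddle-node while the first-cue drive stays safely below it
  (noise-induced premature switching under the default $\eta$ remains at
  the few-percent level).
- **Decision background (`I_bg` = −1.6).** With $\sigma(0) = 0.5$ and no
  resting bias, the choice stage would sit near 0.57 and be
  winner-take-all unstable *before* any stimulus, while the switched-on
  state $I_0 = 1$ would be stable-symmetric. A constant background equal
  to the $I_1$ of the structurally identical object
  winner-take-all places the off state at ~0.18 (stable) and the on state
  in the winner-take-all band.
- **Value drive (`v_gain` = 6)** and **combination drive (`s_gain` = 4).**
  The rate scales of the V-population output onto the choice stage and of
  the combination units onto the object winner-take-all; with raw
  unit-scale inputs the value bias would be an order of magnitude below
  the integrated decision noise (flat psychometric function) and the
  object stage would never separate.

## Readout and tie handling

The view-based choice is read as the larger of $C_1/C_2$ at the end of
the second cue. With the value-scaled bipolar V feed, both V populations
are strongly negative during the post-cue delay (memory inhibition), which
pushes the choice stage out of its winner-take-all band after the second
cue: the view-based choice signal is *transient*, consistent with the
transient view-based signals the recordings describe, and with choice
signals reverting to an object-referenced code before the action. A trial
is labeled *decided* when the winner exceeds 0.5 with a margin above 0.2
(full attractor separation); exact ties at $\eta = 0$ are labeled
undecided, never arbitrarily resolved. The object choice is read from
$C_A/C_B$ over the last 100 ms of the second cue, while the combination
drive is present. Under the default noise amplitude, decision accuracy grows with
the value difference (from near chance at $|\Delta V| = 0.1$ to above 95%
at 0.8), and commitment is incomplete at the readout on a minority of
trials (decided fraction ~80–90%).

`switch_bifurcation()` and `decision_regime()` expose the fixed-point
structure directly (dense-start damped Newton, stability from Jacobian
eigenvalues, threshold 1e-8 on eigenvalue real parts; non-converged grid
cells are flagged, never fabricated). `run_ablation()` implements the
alternative architectures: the classical simultaneous attractor circuit,
the no-switch variant (never decides at low background), the
object-specific view stage (always selects the second option — removing
the cross-connections removes the integral feedback, so the second
stimulus always out-competes the decayed first), and the positively tuned
variant with memory weight 0.8 (correct for two objects, not extensible).
The last variant has no canonical equations; it is realized here as
object-specific channels whose drive is the larger of the stimulus input
and the stored memory trace, both at gain 0.8, which reproduces the
described behavior stably. `simulate_many_objects()` extends the
sequence/combination stages to arbitrary object sets with the view stage
untouched — the point of the abstract code.

The integrator is validated against a 10× finer step at $\eta = 0$:
choices and margins agree, and state trajectories match to a few
hundredths in rate units; first-order Euler cannot do better than a few
percent on 10-ms transients, and the switch-flip time is intrinsically
step-sensitive near the saddle-node, so agreement is asserted at that
realistic precision.

# Synthetic recordings

`generate_population()` draws functional types (object-value A/B,
view-value ±, view-choice current/last, object-choice, object-sequence,
combination, untuned) from configurable proportions, log-normal baselines
across neurons (default median 8 impulses/s — baseline distributions are
unreported for the recorded sample, so this is a module parameter, not a
claim), Gaussian gains, uniform response latencies (40–120 ms), and
amygdala nucleus labels (dLA, vLA, BL, BM, CE; object-value cells enriched
in dLA, combination cells in BL).

`generate_spike_counts()` emits Poisson counts in 20-ms bins from −500 ms
(pre-cue fixation, the normalization baseline) to +2500 ms, with 500-ms
epochs (fixation, cue1, delay1, cue2, delay2, targets; half-open windows).
Two rate sources:

- **Parametric**: each type's rate follows its defining contrast. Value
  tunings are centered on the mid value ($g (v - 1/2)$), i.e., gain
  modulation around the operating point — responses fall below baseline
  for below-average values, which is also what gives value codes their
  product-form representational similarity structure.
- **Circuit**: rates follow the population traces of a
  `simulate_circuit_session()` run (V1/V2, C1/C2, sequence, combination
  and object winner-take-all units; object-value cells follow the
  value-scaled object drive). Because the network is then the decision
  maker, `align_behavior_to_circuit()` replaces the agent's choice labels
  by the circuit readout.

Negative tuned rates are clipped at zero and counted. What the generator
does *not* emulate: trial-to-trial co-fluctuations between neurons (all
emission is conditionally independent Poisson — decoding from trial-matched pseudo-populations is a lower bound for the
same reason), non-Poisson spiking
statistics, slow drifts, or latency variability across trials. Passing
tests on this corpus therefore validate the *analysis machinery* and the
circuit's coding claims, not distributional details of real recordings.

Eye traces are uniformly sampled 2-D positions with tracker-style
quantization (fixational jitter below the resolution quantizes away);
`detect_fixations()` applies the rule that a fixation is a maximal run
with speed below 25% of the trace's speed SD for more than 60 ms (central
differences, per-trace SD), flagging fixations that begin within 100 ms of
a stimulus onset as anticipatory. The 25%-of-SD rule presupposes that
saccades dominate the speed SD; on a constant-position trace the SD
degenerates to zero, which is handled as "everything slow".

# Single-neuron statistics

`neuron_glm()` is ordinary least squares with two-sided t tests,
standardized coefficients $x_i s_i / s_y$, an overall F test, and the
coefficient of partial determination
$(SSE_{reduced} - SSE_{full}) / SSE_{reduced}$ per regressor;
rank-deficient designs error with the offending columns named. The design
builders use the documented codings (ViewChoice 1 = first-viewed chosen;
ObjectChoice 1 = A; ObjectView 1 = A-then-B; 1/−1/0 block contrasts for
the four-object variant; juice terms for the two-juice variant; cue
position/side terms omitted in the four-object model).

The angle classifier regresses the first-cue response jointly on both
object values and classifies by the polar angle of the two standardized
coefficients in eight half-open 45° segments (exact boundaries go to the
counter-clockwise segment; the classification is invariant to common
positive rescaling; responses failing the overall-fit gate at p ≥ 0.05
are unclassified). Segments toward 0°/180° are object-A value, 90°/270°
object-B value, 45° positive and 225° negative view-based value; the
remaining diagonal segments (135°/315°, opposite-signed coefficients) are
labeled `view_value_mixed` — a view-based pattern not produced by the
generator's pure types but possible in principle.

Sliding-window regression (200-ms windows, 20-ms steps) is fit for all
windows at once through a single QR decomposition (the design is fixed
across windows). Significance uses the run-length criterion: more than
`min_run` consecutive windows at p < 0.05, default 9. On this window
geometry the ">9" criterion's empirical false-positive rate on
trial-shuffled data is slightly above 5% (~6%), so
`shuffle_run_calibration()` re-derives the threshold from shuffled data —
">10" holds the rate below 5% here — exactly the calibration procedure
the criterion comes from; the acceptance checks derive the threshold on an
independent shuffled corpus before evaluating it.

`value_choice_transition()` declares a transition when a neuron's graded
value run begins before its view-choice run, with the choice run in or
after the second-cue epoch. On circuit-generated spikes the per-neuron
verdict rarely fires: the V-stage value transient decays with the ~130-ms
slow mode of the integral-feedback loop, shorter than the >180-ms run
criterion, and circuit choices are near-deterministic functions of value,
entangling the two regressors. The verdict logic is therefore validated
on constructed two-phase responses, and the circuit corpus is checked for
the presence of both signal types.

`tuning_reversal_test()` compares first-cue versus second-cue value
coefficients (magnitude-only value components, which are uncorrelated
across options by design) and tests the consistent-sign-flip proportion
against 0.5 with a one-proportion z (48/60 gives z = 4.65).
`value_anticorrelation()` correlates, across neurons, the first- and
second-option value coefficients in the second-cue response — the
comparison signature is an anti-correlation, abolished by shuffling the
neuron pairing.

# Decoding

Pseudo-populations aggregate separately generated neurons: neurons lacking
5 (or 10/15) trials per group are excluded and listed, group sizes equal
the per-group minimum across included neurons, and every repetition
randomly re-matches trials within groups. The linear maximum-margin
classifier uses cost 1 (multi-class by its native one-vs-one voting); the
nearest-neighbor decoder is exact brute force on Euclidean distances with
ties broken by the lowest trial index (arbitrary but deterministic).
Leave-one-out is the default cross-validation, with an 80/20 split mode
available; accuracy is the mean over matching repetitions with SD
dispersion, and significance is a two-sided rank-sum against label
shuffles (1000 unless configured down — the examples and tests use far
fewer repetitions than the 150/500-repetition standard configuration to
keep runtimes in seconds; the defaults carry the standard values).

Cross-condition schemes train on one viewing sequence and test on the
other; `invert_by_sequence` recodes the test labels, which restores
object-choice decoding from a view-based code. Difficulty terciles split
trials by the unsigned value difference (exact thirds limited by ties in
the discrete value levels). The nucleus-level variant selects the 20
strongest value coders per nucleus and classifies against leave-one-out
group-mean vectors.

# Representational similarity analysis

Condition-mean population vectors (value RSA: object × value quartile,
pooled over both viewing periods; choice RSA: sequence × view-choice,
optionally × side) are normalized per neuron and correlated across neurons
(Pearson). Templates: identity; shared object; view-based value as
pairwise products of the mean-centered level codes −2.25, −0.75, 0.75,
2.25 (entry −5.0625 for the extreme pair); object value as the elementwise
product of the object and value templates; an ordinal value variant
(adjacent levels equally similar); object-choice, view-choice, and
left-choice templates. The vectorized matrix (full matrix by default; the
unique-upper-triangle mode is the robustness check) is regressed on all
templates jointly — the object-value and view-based value templates
compete for variance. Significance is non-parametric: condition rows of
the condition-by-neuron matrix are shuffled jointly (preserving neuron
marginals), the correlation matrix and regression recomputed (10,000
permutations at p < 0.001 in the standard configuration; tests use
hundreds at p < 0.05), and the critical |t| and critical t-differences
are read from the permuted distributions. With eight conditions this null
is coarse and conservative; the planted-structure recoveries therefore
pool both viewing periods, which is also the standard configuration.
Sliding-window RSA returns per-template partial-R² time courses; on
circuit corpora the first-object structure peaks during the first cue,
view-choice structure around the decision, and object-choice structure
last.

# Orchestration and reproducibility

`run_experiment()` executes schedule → agent → session values →
population → spike counts → classification/decoding/RSA from one nested
configuration (R list or YAML), with all stage seeds derived
deterministically from the global seed; identical configurations
reproduce identical reports, and stage outputs (trial log, epoch counts,
summary JSON) can be exported. Percentages are reported with
nearest-integer rounding by default and a one-decimal truncation mode for
compatibility with one-decimal figures.

Problem sizes used by the test-suite and the acceptance script are the
package's own choices: sessions of 150–300 trials, populations of 50–233
neurons, 100 recovery sessions, 200 shuffled neurons and 200 null corpora
for the calibration checks, and the full 101 × 101 optimality grid at 5
repetitions × 5 schedules.

# Known limitations

- The circuit's unit-scale resolutions (`b_gain`, `v_gain`, `s_gain`,
  `I_bg`, presynaptic facilitation, memory self-coupling convention) are
  this package's choices; other resolutions of the reference set are
  conceivable and would change quantitative (not qualitative) behavior.
- Premature switch escapes under noise occur on a few percent of trials
  and commit the decision on first-cue information; they are part of the
  model's behavior here, not filtered out.
- The per-neuron value-to-choice transition verdict is validated by
  construction, not on circuit spikes (see above).
- Synthetic corpora are conditionally independent Poisson; no
  noise-correlation structure, drift, or cross-trial latency variability.
- The mixed-effects session-level logistic (random effects across
  sessions) is intentionally out of scope; the session-wise fixed-effects
  logistic covers the value-definition role.
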