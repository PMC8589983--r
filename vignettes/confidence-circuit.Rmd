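---
title: "An attractor decision circuit with adaptive confidence neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An attractor decision circuit with adaptive confidence neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confcircuit)
```

## The model

`confcircuit` simulates a two-module firing-rate circuit for perceptual
decisions and decision confidence.

**Decision module.** Two competing excitatory populations A and B follow
the reduced mean-field attractor model of two-alternative choice. Each
pool is described by one slow NMDA gating variable,

$$\frac{dS_i}{dt} = -\frac{S_i}{\tau_{NMDA}} + (1 - S_i)\,\gamma\, r_i,
\qquad r_i = \phi(I_{syn,i}),$$

with the instantaneous rate given by the population transfer function
$\phi(I) = (c_E I - I_{th}) / \left(1 - e^{-g_E (c_E I - I_{th})}\right)$
(the value at the removable singularity $c_E I = I_{th}$ is $1/g_E$).
The synaptic current collects recurrent self-excitation, cross-inhibition,
background input, the stimulus, feedback from the confidence pool and a
noise current:

$$I_{syn,i} = J_{ii} S_i - J_{ij} S_j + I_0 + I_{ext,i} + J_{fc} r_C +
I_{noise,i}.$$

A stimulus of coherence $c$ (percent) biases the two pools,
$I_{ext,\pm} = J_{ext}\,\mu_0 (1 \pm c/100)$, so the summed drive is
independent of difficulty. A choice is made when either pool's rate first
reaches $\theta = 25$ Hz.

**Confidence module.** One population receives the summed decision rates
$r_{in} = r_A + r_B$ and monitors how *fast* they ramp. Its rate relaxes
to a threshold-linear transfer $\phi_C(I) = \max(c_E I - I_{th,C}, 0.5)$
with time constant $\tau_r = 2$ ms, has its own NMDA gating variable, and
-- crucially -- carries spike-frequency adaptation:

$$\frac{da}{dt} = -\frac{a}{\tau_a} + A_1 r_C + A_0,
\qquad I_{syn,C} = J_C S_C + J_{dc} r_{in} + I_{0c} - J_a a + I_{noise,C}.$$

Because $\tau_a = 250$ ms is slow, a steep ramp (easy stimulus, short
trial) reaches threshold before the adaptation current catches up, so the
confidence pool fires strongly at the decision moment; a shallow ramp
(hard stimulus, long trial) gives adaptation time to accumulate and the
pool is suppressed. The confidence report `rc` is the mean confidence
rate over the 10 ms preceding the decision. An alternative mechanism,
short-term synaptic depression of the decision-to-confidence synapses
(variant `"std"`: the feedforward term becomes $J_{dc} r_{in} x$ with
$dx/dt = (1-x)/\tau_d - U_0 x\, r_{in}$), implements the same
high-pass/slope-detection computation presynaptically and produces the
same qualitative behaviour.

## What the simulator emulates

A reaction-time random-dot-motion session: each trial runs from
$-200$ ms (background only) through stimulus onset at $t = 0$ and offset
at 1 s, to 1.5 s; crossings are accepted until the end of the trial
because the NMDA dynamics can carry a ramp past stimulus offset. The
default experiment is 10 sessions of 500 trials, cycling through the
canonical coherence ladder $\{0, 3.2, 6.4, 12.8, 25.6, 51.2\}\%$ with the
rewarded side alternating. Sessions differ only by their noise streams
and serve as the resampling unit for standard errors. Every per-trial
seed derives deterministically from the master seed, so any table or
sweep replays bit-exactly.

What it does **not** emulate: non-decision (sensory/motor) latencies,
reward and bias effects, sequential dependencies between trials,
change-of-mind or any post-decisional processing, and spiking
variability. Passing tests therefore show that the circuit mechanism
produces the behavioural signatures of confidence under this idealised
protocol, not that it fits any particular data set.

## Parameter choices that required judgement

The published constant set for this circuit is not dimensionally
self-consistent, and three quantities had to be fixed by analysis before
the model behaves at all. These are deliberate design choices of this
package, with the literal printed magnitudes always available.

* **Stimulus coupling `j_ext`.** The printed value (0.15 nA) would make
  the stimulus current $J_{ext}\mu_0 = 4.5$ nA -- fourteen times the
  background current -- which saturates the transfer function at
  stimulus onset, producing instant four-digit firing rates and no
  evidence accumulation. The default is the coupling of the underlying
  reduced decision model, $5.2\times10^{-4}$ nA/Hz, which restores the
  documented regime: ~2 Hz spontaneous rates, ramping to a ~40 Hz
  attractor, reaction times of hundreds of milliseconds.
* **Adaptation strength `j_a_scale`.** With the printed magnitudes the
  adaptation current $J_a a$ is below $10^{-3}$ nA -- about 0.1 Hz
  through the transfer slope -- while the feedforward drive it must
  modulate varies by tens of Hz. The scale factor (default 1500,
  an effective $J_a = 1.5$) makes the adaptation current a few tens of
  Hz at the operating point ($r_C \approx 30$ Hz), the magnitude needed
  for slope detection; `j_a_scale = 1` recovers the printed text.
* **Depression strength and site.** The printed release fraction
  $U_0 = 10^{-4}$ depletes resources by under 0.5% at 40 Hz. The default
  `u0_scale = 1000` gives an effective release fraction of 0.1, a
  standard value for depressing cortical synapses, at which the
  depression time constant at the operating point
  ($\tau_d / (1 + U r_{in}) \approx 200$ ms) is commensurate with
  decision times. Depression acts by default on the
  decision-to-confidence synapses (`std_site = "feedforward"`, driven by
  the presynaptic rate $r_{in}$); placing it on the confidence
  recurrent synapses (`"recurrent"`, as an alternative reading of the
  model) leaves the dominant feedforward confound untouched and cannot
  produce confidence coding at any strength we tested.

**Noise model.** The noise currents are exact discrete
Ornstein--Uhlenbeck processes, one per population, updated outside the
deterministic integrator so their stationary statistics are independent
of `dt`. The defaults are a correlation time of 50 ms and a stationary
SD of 0.005 nA. This is a considered departure from the fast-noise
convention (2 ms, 0.02 nA) of reduced decision models: with
millisecond noise at that amplitude, rate fluctuations of ±5 Hz trigger
the 25 Hz threshold long before the underlying ramp reaches it, which
compresses the chronometric range and -- because hard trials then end as
early as easy ones -- *inverts* the confidence--coherence relation
regardless of adaptation strength. Slow, evidence-like fluctuations
instead produce errors through the integration itself (a trial whose
effective drive is tilted against the true stimulus is decided wrongly),
leaving threshold crossings ramp-determined. Under the defaults the
psychometric ladder spans 0.5 to 1.0 with errors through 25.6%
coherence, decision times fall from ~0.69 s to ~0.32 s across the
ladder, and about 6% of zero-coherence trials reach no decision within
1.5 s (they are recorded and excluded from confidence analyses).

**Rate equation.** As printed, the confidence rate equation has fixed
point $\tau_r \phi_C$ (~0.05 Hz) -- dimensionally inconsistent with the
tens-of-Hz confidence rates it is meant to produce. The default
`rate_eq_mode = "relaxation"` uses the standard firing-rate form
$dr_C/dt = (\phi_C - r_C)/\tau_r$; the literal form is retained behind
the flag for comparison.

**Other numerical choices.** Midpoint second-order Runge--Kutta at
`dt = 0.05` ms, with noise frozen within a step; gating variables
clamped to $[0,1]$, resources to $(0,1]$, rates non-negative (the
continuous dynamics respect these bounds; clamping guards finite-step
overshoot). The adaptation variable starts at its zero-rate fixed point
$\tau_a A_0$, resources full, gating at zero; the 200 ms pre-stimulus
epoch then settles the network at its spontaneous equilibrium.
Decision ties at a sample (both pools at threshold) go to the larger
rate, then to pool A. Within-cell median splits put the median trial in
the low-confidence half. Quantile bins for the accuracy-by-confidence
summary are pooled across coherences (5 bins by default); the
high/low-confidence split is taken within coherence so it is not
confounded by the confidence--coherence correlation.

## The behavioural signatures

```{r signatures, eval = FALSE}
plan <- experiment_plan(master_seed = 1)      # 10 sessions x 500 trials
tab <- run_experiment(plan, model_parameters(), trial_protocol())

mean_rc_by_coherence(tab)        # confidence rises with coherence
accuracy_by_confidence(tab)      # accuracy rises across rc quintiles
folded_x(tab)                    # correct branch up, error branch down
psychometric_by_confidence(tab)  # high-confidence curve dominates
```

The trend tests use trial-level Spearman correlations within each
correctness branch, with permutation nulls obtained by shuffling the
readout against coherence inside the branch. (Shuffling correct/error
labels instead would leave the permuted branch means equal to the cell
means, whose trend is the very signal being tested, so that null cannot
detect the correct branch's rise.)

Among the four candidate readouts, the confidence-pool rate `rc` and the
absolute decision-rate difference `rc_absdiff` carry the folded-X
signature, while the summed decision rates `rc_sum` and the total
decision-module input `rc_totalinput` do not (both are dominated by the
loser pool's rate, which is *higher* on hard trials):
`readout_contrast(tab)` computes this comparison. This contrast is a
property of the default parameter regime, and the corresponding test is
reported at warning level rather than enforced.

The sensitivity of confidence coding to the adaptation parameters is
mapped by `run_sweep()` over an $(A_0, A_1)$ grid; each cell reports the
coding slope -- the least-squares slope of mean relative confidence
($rc - rc(c{=}0)$) against coherence. Spike-driven adaptation $A_1$ is
the operative knob; $A_0$ enters as a nearly constant offset (the
adaptation variable is initialised at its $A_0$-determined fixed point)
which the relative-confidence baseline subtraction removes, so slopes
vary smoothly and stay positive across the default grid.

## Problem sizes and runtime

The compiled integrator advances a 1.7 s trial (34,000 steps) in about
15 ms, so the package uses the full study sizes throughout: the
behavioural statistics and their tests run on 10 x 500-trial experiments
per variant (~75 s each), and the parameter sweep uses a 3 x 3 grid at
100 trials per cell. The fixed-point checks integrate 5--12 s of
noise-free dynamics and compare endpoints against roots found
independently by a quasi-Newton solver applied to the derivative field;
convergence order is estimated from endpoint differences at
`dt`, `dt/2`, `dt/4` on a trajectory kept away from the transfer
function's floor kink (where the right-hand side is non-smooth and
formal second order degrades locally).

## Known limitations

* Under a *sustained* stimulus (several seconds, no decision boundary)
  the strong adaptation loop can settle into a slow relaxation limit
  cycle through the floor of $\phi_C$ rather than a fixed point. This
  does not occur within the reaction-time protocol, but it is why the
  sustained-stimulus fixed-point checks use the non-adaptive variants.
* The confidence--coherence effect at low coherence (0 vs 3.2%) is a
  fraction of a hertz against a ~9 Hz trial-to-trial SD; resolving it
  reliably needs several hundred trials per level, as in the default
  plan.
* Error trials vanish above ~25% coherence, so error-branch statistics
  there rest on few trials and the corresponding cells are flagged by
  `folded_x()` rather than silently averaged.
* The literal printed parameter magnitudes (`j_a_scale = 1`,
  `u0_scale = 1`, `j_ext = 0.15`) are preserved as overrides for
  fidelity experiments, but they do not produce decision making or
  confidence coding, for the reasons documented above.
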