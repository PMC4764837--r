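---
title: "A consensus model of decision confidence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A consensus model of decision confidence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(consensusconf)
```

## The model

`consensusconf` simulates two-alternative perceptual decisions taken
collectively by `N` loosely coupled *modules*. Each module is a reduced
two-variable attractor circuit: two option-selective populations (A and B)
whose slow NMDA gating variables `s` integrate input through an effective
f-I transfer curve,

    ds_i/dt = -s_i / tau + gamma * (1 - s_i) * r_i
    r_i     = phi( sum_j W_ij s_j + I0 + I_ext,i + eta_i )
    phi(I)  = (aI - b) / (1 - exp(-d (aI - b)))

Recurrent excitation (`w_same` = 0.2609 nA) and cross-population inhibition
(`w_diff` = -0.0497 nA) make each module winner-take-all. Modules share the
sensory current `I_ext` but receive independent Ornstein-Uhlenbeck
background currents `eta` (correlation time 10 ms, stationary SD 0.02 nA).
The coupling fraction `IC` interpolates the weight tensor between
block-diagonal independence (`IC = 0`) and uniform all-to-all coupling
(`IC = 1`), normalized as `W = w_ij ((1-IC) delta_kl + IC/N)` so the total
recurrent drive per population is the same at every `IC`. That conservation
is why first-order behavior (accuracy, RT) is unchanged by coupling while
the *information content* of the inter-module dispersion changes
drastically.

A module *votes* for the option whose population rate first reaches the
threshold `lambda` = 15 Hz; votes are irrevocable ("commitment"). The
network decides when one option holds a strict majority (> N/2 votes); the
decision time is the RT. At that moment two dispersion statistics are read
from the chosen option's rates across modules:

* `sigma_dv` — the population SD across modules (the latent confidence
  signal: small dispersion = reliable evidence = high confidence);
* `FMC` — the fraction of modules whose chosen-option rate lies in
  `[lambda, lambda + delta_lambda)` with `delta_lambda` = 5 Hz. Because the
  median chosen-option rate sits at `lambda` at the moment of the majority,
  this counts a fixed percentile band and is inversely related to
  `sigma_dv`; it is the quantity a neural circuit could plausibly read out
  with threshold-crossing counters.

Binary confidence is sampled in a separate stage from a sigmoid of the
dispersion estimate, `P(high) = 1 / (1 + exp(-(x - c) / a))` for FMC input
(sign flipped for `sigma_dv` input).

## Numerical scheme

Integration is Euler-Maruyama with `dt` = 0.5 ms; the O-U noise uses its
exact discretization (`eta' = eta e^(-dt/tau) + sd * xi`, with the exact
stationary increment SD), so the noise statistics are correct at any `dt`.
The batch integrator is compiled (Rcpp) and consumes ~10^6 normal draws per
trial from a dedicated xoshiro256++ stream; per-trial stream seeds are drawn
from R's RNG, so `set.seed()` reproduces whole experiments bit-for-bit.
Halving `dt` does not change any of the summary statistics beyond sampling
error; the plain-R reference stepper (`step_network()`) is tested
step-for-step against the compiled core in the noiseless case.

The transfer curve's removable singularity at `aI = b` is evaluated by its
series limit `1/d`; the far-negative branch underflows cleanly to 0. Gating
variables are clamped to [0, 1] (an inactive constraint at `dt` <= 1 ms;
it exists to keep pathological parameter sets finite).

Tie conventions, all tested: if both populations cross `lambda` within one
step the higher rate wins, then option A; forced (fixed-delay) decisions
take the option with more latched votes, ties to the higher mean rate;
rates "at decision" are those of the integration step on which the majority
completed.

## Stimuli and the luminance transform

The flicker task redraws each patch's luminance every 40 ms from a Gaussian.
Two modes mirror the two uses in the study:

* *protocol mode* — one luminance trace per patch, frame SD 5 cd/m^2, used
  for the coupling sweep and the pulse experiments (0.2 s pre-stimulus);
* *behavioral mode* — 4 bars per patch, frame SD 10 cd/m^2; the network
  integrates the patch mean (whose SD is then 5 cd/m^2), kernels are
  computed per bar; 1 s pre-stimulus wait and a 1 s forced-decision window,
  as in the fitting protocol.

Luminance maps to current as `I = g (L + b)`. The affine form with the bias
inside the parentheses keeps `b` in cd/m^2. Pre-onset input current is
exactly zero; background `I0` and noise are always on, and the background
current enters once per population, independent of `IC`.

### Choosing the default g and b

The printed gain and bias are not recoverable from the source, so the
package's defaults are its own calibration, fixed once from the study's
qualitative constraints and not revisited:

* the task is designed so that *external* luminance noise, not internal
  noise, limits performance — the flicker-induced current SD
  (`g * 5` cd/m^2 per patch) must be comparable to the O-U current SD
  (0.02 nA), which requires `g` of order 10^-3 rather than 10^-4;
* accuracy should run from chance at zero discriminability to ~1 by
  ~16 cd/m^2 (the psychometric range of the sweep experiments);
* the trial-averaged median chosen-option rate at decision must sit within
  `delta_lambda / 2` of `lambda` (the percentile argument behind FMC);
* the pulse-protocol asymmetries must point the right way.

The defaults `g = 3e-3` nA m^2/cd and `b = -30` cd/m^2 satisfy these
(baseline stimulus current 0.06 nA per population, flicker current SD
0.015 nA). The confidence-sigmoid defaults (`center_c = 0.24`,
`slope_a = 0.03`) put the midpoint at the median FMC observed under
behavioral-mode conditions, with a slope of about half the FMC SD (0.054),
so both confidence levels occur at realistic rates.

## What the synthetic subject emulates — and what it does not

`generate_synthetic_subject()` plays the behavioral task through the model
itself: per-trial target means from a truncated Gaussian (mean 55, SD 5,
truncated to [51, 70] cd/m^2 — the subject-specific distribution is not
available, so this is a stand-in), randomized target side, 4-bar flicker,
forced decision within 1 s, binary confidence from the FMC sigmoid. It is
the fitting pipeline's test bed: since the generating (g, b, a, c) are
known, parameter recovery can be checked end-to-end.

It does not emulate: sequential effects, lapses, motor noise, confidence
criteria that drift over a session, or a speed-accuracy policy that varies
with feedback. Passing recovery tests therefore shows the pipeline is
consistent, not that it would capture every feature of human data.

A known limitation of the calibrated regime: with the reduced-model
constants, the attractor transition after stimulus onset is fast, so most
behavioral-mode responses land 10-100 ms after onset and the psychophysical
kernels concentrate on the first one or two frames. The kernel *asymmetry*
(selected-patch fluctuations drive confidence far more than
non-selected-patch ones) survives, but the kernels' temporal extent is much
shorter than in slow-integration regimes.

## Kernels

Fluctuations are measured against the nominal generating mean of each patch
(a documented switch uses the empirical trial mean instead: with it, kernel
baselines shift by the luminance the subject actually saw). A frame enters
a trial's trace if the frame has *started* before the response
(`rule = "frame_end"` instead requires the frame to have ended; the choice
is a convention left open by the construction, and both are implemented and
tested). The permissive rule is the default because responses concentrate
shortly after onset in the calibrated regime: requiring completed frames
would discard the majority of trials and leave the kernel estimate to a
slow-response tail. Decision kernels
are choice-conditioned means over trials and bars; confidence kernels are
high-minus-low differences per patch. Bootstrap errors resample trials
(bars move with their trial). Kernel units are raw cd/m^2; any linear
transform of the stimulus rescales them, so only shapes and ratios are
meaningful.

## Fitting

Stage 1 recovers (g, b) by CMA-ES on
`w_lsq * sum_t [(Dhat_S - D_S)^2 + (Dhat_N - D_N)^2] + w_chi2 * chi2(hits,
misses, undecided) + pen_early * N_e + pen_undecided * N_d`. With unit
weights the two fitted terms sit at the same order of magnitude at the
self-fit point (kernel term: ~frames x 2 kernels x squared-SE;
chi-squared: ~df), so the defaults are 1, 1, 1, 1. Penalties are linear in
the counts. Three estimator details matter and are deliberate:

* the kernel difference is evaluated on the *target's* frame grid, with
  frames the candidate model never reaches scored as zero influence —
  restricting the sum to the overlap would let fast-deciding candidates
  win by emptying it;
* frames are weighted by the target's contributing-trial counts (mean
  weight 1), because late frames are estimated from the few slow responses
  and would otherwise drown the informative early frames in noise;
* the Pearson term is the *two-sample* statistic that the subject's and the
  simulation's (hit, miss, undecided) counts come from one multinomial.
  Two details matter: including the undecided category means the subject's
  non-decision rate is treated as behavioral data (an absolute undecided
  penalty alone would reward candidates for driving that rate to zero),
  and the two-sample form keeps the statistic's sampling noise bounded
  when a category is rare — a one-sample test against model-estimated
  proportions explodes when the model's rare-category estimate approaches
  zero. Along the near-equivalence manifold `g (L + b) ~ const` (where
  signal-to-external-noise is invariant in `g`), matching the non-decision
  rate and the accuracy is what separates the true gain from over-driven
  look-alikes whose dispersion statistics — and hence metacognitive
  signature — differ.

Stage 1 can optionally run in two passes (`refine`): a coarse CMA-ES at
small `n_sim` localizes the merit basin, then a second pass with several
times more simulated trials per evaluation, inside a shrunken box around
the first optimum, buys the merit precision that separates nearby manifold
points. The parameter-recovery checks use this scheme.

Stage 2
freezes (g, b), simulates one pool of trials, and recovers (a, c) by
minimizing the Pearson statistic of the 4-way confidence-by-correctness
table; because the pool's FMC values do not depend on (a, c), each stage-2
evaluation only resamples confidences, which makes stage 2 cheap. Both
stages fix a common-random-numbers seed per evaluation so the merit is a
deterministic function of the parameters and CMA-ES is not chasing
simulation noise. The optimizer is the package's own
(mu/mu_w, lambda)-CMA-ES (no external implementation is available in this
stack), unit-tested on quadratic objectives; box constraints are handled by
repair.

Desk-scale choices (all configurable): 1000 simulated trials per stage-1
evaluation (the original protocol used 10000), population 6, ~20
generations. The recovery checks run a 2000-trial synthetic subject with a
0.4 s wait and `dt` = 1 ms, stage 1 at `n_sim` = 800 with a refinement
pass at 2000 — problem sizes chosen so the whole recovery exercise stays
in the minutes range. Note the identifiability caveat below.

A caveat this package can quantify because the generating parameters are
known: in the calibrated fast-transition regime, the statistics stage 1
observes — accuracy, the non-decision rate, and kernels that extend over
only one or two frames — do not uniquely determine (g, b). A family of
over-driven parameter sets reproduces all of them while carrying a
*different inter-module dispersion structure* (in the extreme, the
FMC-correctness coupling inverts), and stage 2, which only reweights the
already-simulated dispersion through the sigmoid, cannot repair that.
When stage 1 lands near the generating manifold point, the recovered
model's 4-way confidence table is statistically indistinguishable from
the subject's; when it drifts to an over-driven look-alike, the table
check fails even though kernels and accuracy match. With slow-integration
dynamics (kernels spanning many frames) the kernel time course itself
pins the transform and this degeneracy closes — it is a property of the
regime, not of the estimator.

## Experiment drivers

* `run_ic_sweep()` — accuracy/RT/sigma_dv/FMC per (IC, discriminability)
  cell with trial-bootstrap CIs; the error/correct RT split is always
  reported because this task yields slow errors.
* `run_sp_asymmetry()` — the two 40 ms, 1 cd/m^2 pulse protocols at zero
  nominal discriminability, with one-sided Welch tests of the four
  asymmetry contrasts.
* `run_fixed_delay()` — forced choice at stimulus offset over a duration
  grid, with a Cochran-Armitage trend test of the high-confidence rate
  (longer stimulus, tighter dispersion, higher confidence).

Every driver is reproducible from its `write_run()` sidecar (parameters,
seed, test tables).

## Design choices that were genuinely open

* **Coupling normalization** `IC/N`: required for the sweep's invariance of
  first-order behavior; any non-conserving normalization changes total
  drive with `IC` and breaks it.
* **Population vs sample SD** for `sigma_dv`: population SD; the choice
  only rescales the confidence sigmoid.
* **Half-open FMC window** `[lambda, lambda + delta)`: boundary convention,
  tested explicitly.
* **Irrevocable votes**: modules "commit"; a module whose rate later falls
  below threshold keeps its vote. This is why the trial-averaged median at
  decision sits slightly *below* `lambda` — some voters have dipped back —
  and the gap grows with dispersion.
* **i0 enters once per population**, not scaled by coupling: the source is
  silent; uniform entry keeps the spontaneous state IC-independent.
* **Merit weights**: unit weights after checking the two fitted terms'
  magnitudes at self-fit; nothing was tuned per-dataset.

## Known limitations

* The network constants are the standard reduced-model values, not the
  original study's (those are unrecoverable from the source); quantitative
  RT distributions and kernel time courses therefore differ even where the
  qualitative phenomena agree.
* At full coupling the dispersion is not perfectly uninformative: a small
  positive dispersion-discriminability coupling remains through the rate
  slope at threshold crossing, a regime effect of the fast attractor
  transition (see the acceptance notes).
* The vote-counting stage is implemented as an exact count over module
  rates, not as the disinhibition/bursting microcircuit; the source states
  the two give qualitatively identical results, and only the count enters
  any analysis here.
* Single subject, single session; no hierarchical fitting.
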