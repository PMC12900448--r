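---
title: "Models and numerical methods in plastnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in plastnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plastnet simulates spike-driven synaptic plasticity across three scales:
single synapses under prescribed spike trains, multiple synapses coupled by
particle diffusion along a dendritic branch, and recurrent networks of
spiking neurons whose excitatory synapses carry a two-phase consolidation
rule. This vignette describes the models, the numerical methods behind
them, the parameters that matter (with units and defaults), and the design
choices we made where the design was genuinely open.

## Random numbers and stochastic integration

Every random variate in the package is produced by a counter-based
generator (Threefry-4x64 with 12 rounds): a stateless bijection from a
4 x 64-bit key and a 64-bit counter to four uniform variates. Keys encode
`(global seed, cell, mechanism, variable)`, counters encode the timestep,
so any variate can be regenerated in isolation and an entire simulation is
a pure function of its configuration and seed — reruns are bit-identical,
and no stream ever needs to be "advanced past" another. Normal variates
come from the Box-Muller transform; both outputs of each transform are
consumed, so cached uniforms deplete uniformly across noise sources. The
guard for a zero uniform substitutes the smallest positive double.

Stochastic differential equations `dX = f dt + sum_i g_i dB_i` are
integrated by the Euler-Maruyama scheme with independent Wiener increments
`dW_i ~ N(0, dt)` (identity noise-correlation matrix; correlated noise is
out of scope). With all diffusion terms zero the step is exactly
deterministic forward Euler, which the tests exploit as an oracle.

The plasticity noise terms below are printed in the source material as
`xi = tau (H_p + H_d) sigma_pl Gamma(t)` with white noise `Gamma` of
variance `1/dt`. Dimensional analysis of the corresponding
Ornstein-Uhlenbeck-type equations shows a radical is missing from that
rendering; we implement `xi = sigma_pl sqrt(tau (H_p + H_d)) Gamma(t)`,
which reproduces the stationary statistics of the upstream model family.
`Gamma` is realized as `dW/dt`, so `g Gamma dt = g dW` inside the
Euler-Maruyama step.

## Cable equation and particle diffusion

Morphologies are trees of tapered cylinders; `discretize()` splits every
segment into `ceiling(L/dl)` equal compartments with frustum geometry, so
compartment volumes sum exactly to the segment volumes. Both the cable
equation for the membrane potential and the diffusion equation for
dissolved species have the same one-dimensional second-order spatial
operator, and both are advanced by the same implicit (backward-Euler)
update, solved in one pass by Hines-ordered Gaussian elimination on the
compartment tree. The scheme is unconditionally stable (millisecond steps
on stiff geometries remain bounded) and, for diffusion, is written in
finite-volume (flux) form with sealed ends, so the total dissolved amount
is conserved to rounding — the tests require 1e-10 over a thousand steps.

Units: lengths in micrometres, times in milliseconds, potentials in mV,
concentrations in umol/l. Diffusivities are accepted in m^2/s and
converted once at construction (1 m^2/s = 1e9 um^2/ms); we deliberately do
not adopt the historical 1e-7-scaled diffusion units that some upstream
tooling used.

Species carry no charge: diffusion is fully decoupled from the membrane
potential, and the optional feedback of particle fluxes on reversal
potentials is intentionally not implemented.

Active membranes use the classical squid-axon sodium/potassium channel
set (120 and 36 mS/cm^2, reversals +50/-77 mV, standard rate functions
shifted to a resting potential near -65 mV); the source material names the
channel family but prints no rates, so the constants are documented
configuration. Gating variables advance by exponential integration at the
pre-step potential; their conductances then enter the implicit voltage
solve.

## The five plasticity rules

**Pair-based STDP.** Eligibility traces `a_pre`, `a_post` decay
exponentially (`tau_pre`, `tau_post`) and are updated analytically at
event times, so the event-driven implementation equals dense ODE
integration exactly; the isolated-pair window is
`A_pre exp(-dt/tau_pre)` for positive timing differences and
`A_post exp(dt/tau_post)` for negative ones. On coincident spikes the
convention is: decay traces, apply presynaptic effects, then postsynaptic
ones. The weight's contribution to the postsynaptic cell is clipped at
`w_max`; the weight itself clips at zero by default (configurable), since
the source material prescribes only the upper clip.

**Spike-driven homeostasis.** The plastic weight moves by `+dw` on every
presynaptic and `-dw` on every postsynaptic spike, clipped to
`[0, w_max]`. With symmetric amplitudes the stationary output rate equals
the plastic input's rate by a balance argument. The LIF neuron behind the
bundled experiment (threshold 4 mV above rest, reset at rest, 1 mV/nA
delta-synapse depolarization) was chosen so that this set point is
attainable across the whole input schedule: the static input alone stays
below 50 Hz at its maximal scheduled rate while the plastic input can
exceed it with its weight well inside the clip range. The experiment is
simulated event-drivenly (delta synapses; the membrane decays in closed
form between events), which is exact for this model.

**Calcium-based bistable plasticity.** Postsynaptic calcium decays with
`tau_c` and jumps by `c_pre` (delayed by `tc_delay`, implemented by an
internal scheduled event) and `c_post` at spikes. The weight carries a
cubic bistability plus threshold-gated potentiation/depression and
threshold-gated noise; the full drift is integrated jointly in one
Euler-Maruyama step. The pairing-protocol observable is the mean of
`w_end - w_start` over trials with the initial weight drawn uniformly
from {0, 1}. We run the protocol at its published 4000 trials: the
compiled kernel needs only seconds, and at a few hundred trials the
depression-side sign is within one standard error of zero.

**Heterosynaptic calcium-diffusion plasticity.** Four one-compartment
spines sit on an 80-um branch; driven spines inject a monoexponential
calcium-carrying current, converted to a concentration flux by the
calcium fraction, the double ion charge (2F), and the head volume. The
injected amount per step is the analytic integral of the current, which
makes the discrete mass balance (injection and decay accounted) exact to
solver rounding. Weights follow threshold rules on the local
concentration. One calibration deserves emphasis: the upstream
implementations of this model used *different* injection amplitudes for
the same physics (4.0 vs 5.5 pA) because their spine-dendrite coupling
models differ, and with our full-diffusion coupling the printed amplitudes
put the whole branch far above both thresholds (the diffusion length
`sqrt(D tau_C)` is 4.7 um, larger than the spine separations, so no
spatial contrast survives at that scale). Our calibrated default of
0.65 pA places the quasi-steady profile across the two thresholds, which
is the regime in which stimulated spines and their near neighbour
potentiate while the remote spine depresses. The unit-conversion contract
(`gamma I0 tau_I / 2F` moles per spike) is independent of this choice and
is tested at the printed amplitude. The initial spine weight (0.5) is
configuration; it starts the spines between their depressed and
potentiated states.

**Synaptic tagging and capture.** The total weight is `w = h + h0 z`.
The early phase `h` follows the calcium-based rule (potentiation towards
10 mV, depression towards 0, relaxation towards `h0` at rate `0.1/tau_h`)
with threshold-gated noise; under noise `h` is clipped to `[0, 10]` mV
(the noise-off drift keeps it there by itself). A synapse is tagged while
`|h - h0|` exceeds `theta_tag`; the neuron synthesizes plasticity-related
products while the *summed* `|h - h0|` of its synapses exceeds
`theta_pro`; the late phase `z` integrates towards +1 (or -0.5 for
depression) while the synapse is tagged and products are available. The
parameter identities `h0 = 0.5 gamma_p/(gamma_p+gamma_d) * 10 mV`,
`theta_pro = 0.5 h0`, `theta_tag = 0.2 h0` hold at the printed precision.

The four induction protocols (STET: three 1-s 100-Hz bursts 10 min apart;
WTET: one 0.2-s burst; SLFS: 900 three-spike 20-Hz bursts at 1 Hz; WLFS:
900 single pulses at 1 Hz) are configuration presets whose pulse
parameters come from the upstream protocol literature, not from printed
constants. Stimulation phases run at a 0.5-ms step; the remaining hours to
the 8-h readout are fast-forwarded: only the early-phase relaxation (exact
exponential), the product pool (exact exponential towards its target), and
the late phase (coarse Euler, 1-s steps against 60-min time constants) are
advanced — spiking and calcium are frozen, which is exact once calcium has
decayed and no cell fires.

## Networks and memory recall

Networks are Bernoulli-connected (no self-loops), with plastic
tagging-and-capture synapses within the excitatory population (calcium
amplitudes corrected by the in vivo factor 0.6) and static synapses
elsewhere. Neurons are LIF with exponential synaptic currents
(`tau_syn = 5 ms`), axonal delay 3 ms (1 ms for inhibitory connections),
and a white-noise background current (mean 0.15 nA, 0.05 nA sqrt(s)); the
compiled engine carries all state — including delivery ring buffers and
the noise-stream step counter — across phase boundaries, so a run split
into consecutive phases is bit-identical to the unsplit run.

The reduced 500-neuron network (400 excitatory, p = 0.1) needed three
documented design choices, all in quantities the source material leaves as
configuration:

* *No weight upscaling.* Scaling synaptic weights by N_full/N_reduced to
  preserve mean input makes single EPSPs near-threshold and tips the
  network into seizure-like runaway; reduced networks therefore run at
  the native full-size couplings.
* *Normalized inhibition.* At this size the Bernoulli inhibitory
  in-degree varies by about 30% between neurons; scaling each neuron's
  inhibitory in-weights to a fixed summed total (a synaptic-scaling
  assumption) removes quenched rate differences that otherwise dominate
  the assembly response.
* *A strong refractory cap.* The network neuron uses an 8-ms absolute
  refractory period — a strong after-hyperpolarization limiting sustained
  firing to roughly 110 Hz. Without it, feedback inhibition plus recurrent
  potentiation produce a winner-take-all assembly response; with it, the
  stimulated assembly fires homogeneously (about 90 Hz under the default
  learning drive), *below* the rate at which presynaptic calcium alone
  crosses the potentiation threshold. Potentiation then requires
  coincident pre- and postsynaptic firing: synapses within the stimulated
  assembly potentiate strongly, assembly-to-outside synapses depress, and
  incoming/control synapses stay at baseline. This synapse specificity is
  what carries pattern completion.

Learning applies three 0.5-s pulses (0.2-s gaps) of 3600 Poisson arrivals
per second at unit weight `h0` to the assembly; recall applies 0.1 s of
the same drive to half the assembly; the pattern-completion coefficient
`Q = (rate_ans - rate_ctrl)/rate_as` is read from a 0.5-s window centred
200 ms after recall onset. Static couplings are `w_ei = 2 h0`,
`w_ie = 6 h0`, `w_ii = 2 h0`. These stimulus parameters stand in for
protocol details the source material delegates to external references.

Morphological cells reduce to the same somatic dynamics with a
morphology correction factor `c_morpho` multiplying recurrent excitatory
couplings (smaller for longer dendrites), following the source's own
treatment of the electrical side; the intracellular side is explicit: a
signalling species deposited at synapse sites in proportion to the change
of `|h - h0|` diffuses to the soma (its total amount equals the summed
deviation under instantaneous mixing), the somatic concentration is
compared against the volume-renormalized threshold
`theta_pro* = theta_pro / V_total`, and the product field is synthesized
in the dedicated mid-soma compartment and diffuses outwards with its own
diffusivity while decaying with `tau_p`. For a single-compartment cell the
whole loop reduces exactly to the scalar pool equation.

## What the bundled experiments emulate — and what they do not

The experiment generator produces the study conditions at desk scale:
single synapses under deterministic protocols, a four-spine branch, and
reduced 500-neuron networks read out 10 s after learning, averaged over
network realizations. Real cortical data differ in ways these conditions
deliberately ignore: neurons are not homogeneous LIF units, connectivity
is structured rather than Bernoulli, inhibition is not a single
population, and full-size (2000-neuron) 8-hour consolidation runs are out
of desk scope. Passing tests therefore demonstrate that the implemented
rules reproduce the model family's fixed points, protocol outcomes, and
the *sign and trends* of pattern completion in the reduced condition —
not quantitative recall magnitudes of the full-size condition, which are
substantially larger than the reduced network's (our mean Q is of order
a few hundredths).

## Numerical choices and degenerate inputs

* Fixed-step integration with spike times aligned to the step grid
  (threshold crossings register at step end); network step 0.5 ms,
  cable/diffusion steps 0.1-1 ms, benchmark ring 0.025 ms.
* Within a timestep: deliver due events, integrate membranes, detect
  spikes, dispatch the postsynaptic-spike hook, update plasticity.
* Coincident pre/post events: decay traces, apply pre, then post.
* Delayed presynaptic calcium is an internal scheduled event applied at
  its exact time inside the step; calcium decays analytically between
  events.
* Degenerate inputs error loudly: empty morphologies, dangling SWC
  parents (with line numbers), non-positive radii or step sizes, counter
  overflow, time regressions at synapses, silent recall subpopulations,
  ring sizes that do not divide the cell count.
* Problem sizes in the tests are chosen for a single-CPU desk run:
  1e5-draw generator statistics, 256-chain Ornstein-Uhlenbeck ensembles,
  3-s dendrite experiments at 0.1-ms steps, ten-seed network batches.

## Known limitations

Correlated noise sources, higher-order stochastic solvers, ion-specific
reversal feedback, structural plasticity, and short-term plasticity are
out of scope. The spike-propagation ring uses the stated delay as the
nominal period; the measured period additionally contains the (small)
synaptic-to-threshold latency of the Hodgkin-Huxley soma, so rates match
`1/(k t_delay)` to within one spike per 200-ms run rather than exactly.
The morphological network variant treats the electrical effect of
dendrites through the correction factor only; voltage is not resolved
along the tree during network runs.
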