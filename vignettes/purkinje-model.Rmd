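---
title: "A 41-compartment Purkinje neuron model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 41-compartment Purkinje neuron model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`purksim` simulates a cerebellar Purkinje neuron reduced to a 41-compartment
unbranched cable: a 22 x 22 um cylindrical soma, 20 "smooth" (proximal) and
20 "spiny" (distal) dendritic compartments. Because the reduction that
produced this compartment count does not conserve membrane area, dendritic
membrane capacitance carries a correction factor C_d = 3.80
(C_m = 0.8 C_d uF/cm2 smooth, 1.5 C_d spiny — the higher spiny value stands
in for spine membrane); the dendritic maximal-conductance table is already
expressed on the corrected scale and is used as printed.

The soma carries three voltage-gated K+ currents (fast, intermediate and
slow TEA sensitivity), a Ca- and voltage-gated BK current, a P-type Ca2+
current through a GHK flux with fixed internal (100 nM) and external (2 mM)
calcium, a hyperpolarisation-activated cation current I_h, a leak, a
resurgent Na+ current, and an electrogenic 3:2 Na+/K+ pump. The dendrites
carry T-, E- and P-type Ca2+ currents (ohmic, E_Ca fixed at +135 mV), A-,
D-, M-type and delayed-rectifier K+ currents, Ca-gated BK and K2 currents,
I_h and a leak; smooth compartments additionally carry an SK-type
Ca2+-activated K+ conductance whose maximal value is switch-controlled (see
below). Somatic gate kinetics are (inf, tau) pairs with time constants
printed in seconds (converted to ms internally); dendritic kinetics are
alpha/beta pairs per ms, combined with the temperature factor
mt = 3^((T-37)/10) at T = 36 C.

### Resurgent sodium

The somatic Na+ current is a 13-state Markov scheme: five closed states
with statistical activation factors {4a, 3a, 2a, a, g}, an open state, six
inactivated states mirroring the closed chain (scaled by
a = (Oon/Con)^(1/4) forward and b = (Ooff/Coff)^(1/4) backward), and an
open-blocked state. Unbinding from the blocked state on repolarisation
re-opens channels and produces the resurgent current that supports rapid
firing. The connectivity ships as an edge list (`markov_edges()`), so the
scheme is auditable, and the occupancy is advanced by a backward-Euler
linear solve each step: at the 150/ms-scale rates an explicit update is
unstable at dt = 25 us, while the implicit solve conserves probability to
round-off and preserves positivity (M-matrix structure).

### Layered calcium dynamics

Each dendritic compartment has a 0.1 um sub-membrane shell. Spiny
compartments follow
d[Ca]/dt = chan - kt [Ca]/([Ca]+kd) + (y - [Ca])/tau_r with the influx
term clamped at zero for outward current and a fixed set point
y = 4e-5 mM. Smooth compartments use the same fast shell (kt = kd = 1e-4)
but let the set point float: y itself integrates the clamped Ca influx —
divided by a large factor g and the compartment diameter — and relaxes to
z = 2.4e-4 mM with time constant tau_m. This layering separates
milliseconds-scale Ca spiking from seconds-scale accumulation.

Two switches couple this system to the climbing fiber (CF):

* `w`: a summed Ca-current magnitude above 0.06 mA/cm2 (a CF-scale influx)
  sets w = 1; w decays as exp(-t/f), f = 100 ms. While w > 0.1 the set
  point uses the fast-creep pair (g = 1e4, tau_m = 1000 ms) instead of the
  default (1e5, 100 ms). The lifespan of one trigger is f ln 10 = 230 ms;
  a re-trigger restarts it.
* `r`: a CF synaptic current above 3 nA sets r = 1; r decays with
  s = 1000 ms, lifespan s ln 10 = 2.30 s, so 1 Hz CF input holds r above
  0.1 continuously. While r > 0.1 the SK maximal conductance is the
  protocol value (0.72 S/cm2 in the toggle protocol); otherwise it is
  1e-7 S/cm2. Both switches are evaluated per smooth compartment on the
  instantaneous values each step.

The SK gate reads the compartment's bulk shell calcium; the selective
CF-to-SK coupling is realised abstractly through the r switch.

### Pump-driven quiescence

The somatic pump current is d_pump/(1 + exp(40 - [Na]i)) with
d_pump = 0.04 mA/cm2, 3 Na+ out / 2 K+ in. Internal sodium integrates the
net outward Na+ current (resurgent influx plus pump efflux) with the
printed 4e4/(d F) scaling — about 1.9 mM/s per 0.1 mA/cm2 of sustained
influx for the 22 um soma — but lagged by tau = 5 s through a FIFO buffer
of exactly tau/dt entries, representing slow diffusion from channels to
pumps. The lag is what ends firing epochs: sodium keeps rising for ~5 s
after spiking stops, holding the pump on, and the resulting hyperpolarised
quiescence lasts until the buffered influx drains. [Na]i floors at 10 mM;
E_Na floors at +70 mV (with [Na]i floored, the Nernst value never rises
above it, so E_Na is effectively constant). The buffer is primed with the
first pushed value (quasi-stationary start) to avoid a spurious 5 s
transient; the optional longitudinal Na+ diffusion term vanishes
identically in a build whose only Na+ compartment is the soma, and the
config flag is accepted as a no-op.

### Synapses

CF input makes 17 contacts of 1 uS on the 17 most proximal smooth
compartments, firing synchronously (1 Hz in all presets). PF input makes
one 0.0005 uS contact per spiny compartment, firing as independent
homogeneous Poisson trains (100 Hz mean), one seeded stream per synapse
derived from the master seed. Both use a dual-exponential conductance
(tau1 = 0.5 ms, tau2 = 1.2 ms) normalised so a lone event peaks at exactly
g_syn (the Exp2Syn convention; peak at 0.750 ms). Events snap to the next
integration grid point.

## Integration

One global step at dt = 25 us: (1) synaptic conductances (two decaying
state variables per synapse); (2) exponential-Euler gate updates at frozen
voltage, carrying the printed per-channel rate factors (E-type m: 4, h:
10; D-type m: 10, h: k = 0.1); (3) implicit Markov solve; (4)
backward-Euler cable solve — ohmic currents (including the resurgent
current at fixed open fraction and the live SK) enter implicitly, the GHK
flux and pump current enter as constants evaluated at the current step —
by the Thomas algorithm on the chain's tridiagonal system; (5) explicit
updates of the three calcium systems, the w/r switches and the lagged
sodium state at the new voltage. Initial conditions: v = -65 mV
everywhere, gates at steady state, Markov mass in C1, [Na]i = 10 mM; every
protocol is preceded by a 2 s settle window without synaptic input.
Somatic spikes are detected at full rate as upward -20 mV crossings,
dendritic Ca spikes as -30 mV crossings on a monitored smooth compartment.

On small cables the tridiagonal solve is checked against a dense solve to
1e-10, the passive soma against the analytic RC relaxation to 0.1%, and
the Markov step against matrix-exponential propagation at the stationary
distribution to 1e-6. Refining dt from 25 to 12.5 us changes the tonic
firing rate by under 3%; note that pointwise voltage traces decohere over
a second regardless, because a 3% rate change shifts spike phases — a
property of any fixed-step scheme on a limit-cycle spiker, and the reason
trace-level comparisons are made on rates and mode structure rather than
on voltage RMS.

## Dendritic geometry as the calibration surface

The published description fixes the soma (22 x 22 um), the compartment
counts, C_d and every channel density, but not the dendritic compartment
dimensions, which descend from an unpublished equivalent-cable reduction.
Geometry is therefore an explicit configuration field. The shipped default
— smooth 20 x 1.3 um, spiny 10 x 0.35 um, uniform — was calibrated once
against the intrinsic protocol: it yields the repeating
tonic -> burst -> quiescent pattern with a pooled tonic rate of ~99 Hz and
a repeat length of ~19.5 s, and PF input at 100 Hz raises the tonic rate
to ~125 Hz. Scalar entries describe uniform segments; vectors describe
tapered dendrites.

Geometry is the model's stiffest axis. The intrinsic pattern needs enough
smooth-dendrite membrane to regenerate Ca2+ spikes (smooth diameters below
~1.2 um lose the burst mode), while the CF response regimes want a weaker
SK-to-soma balance (thinner smooth dendrites). A broad search over uniform
and tapered geometries found no configuration satisfying both at the
printed SK conductances, for the reason below.

## Known limitations

* **Standing dendritic calcium.** The T/E/P-type window conductances
  (products m_inf h_inf ~ 2e-3 across -95..-55 mV against E_Ca = +135 mV)
  drive a resting shell influx that the saturable extrusion
  (kt = 1e-4 mM/ms) cannot match, so basal smooth-compartment [Ca]i sits
  at ~5-7 uM rather than near the set point z = 0.24 uM. The floating set
  point y then modulates [Ca]i by only a few percent, and the SK
  conductance needed to silence the soma is reached well below the
  protocol values g_sk = 0.62/0.72 S/cm2: under 1 Hz CF input at those
  values the model rests in the down state rather than alternating. The
  CF toggle phenomenology is present in the model — at this geometry the
  sustained-firing/silenced boundary lies at g_sk ~ 0.1-0.3 S/cm2, where
  CF input produces sustained ~33 Hz tonic firing with complex spikes at
  lower SK and up/down switching near the boundary — but not at the
  printed conductances. The acceptance script reports the CF-protocol
  measurements as computed.
* The analysis constants (spike threshold -20 mV, refractory 2 ms,
  quiescence gap 500 ms, burst window 50 ms, complex-spike onset/extent
  5/15 ms, cf-pause ceiling 100 ms) are fixed from the model's waveform
  scales and are all overridable arguments; the model's complex spike
  expresses a single somatic spikelet, so the complex-spike detector
  requires one spikelet plus CF gating and a coincident dendritic Ca
  spike.
* The k parameter (D-type K+ inactivation) shortens the tonic mode when
  raised, but the effect is modest in this realisation because the
  recovered D-type availability after a quiescent period is itself small
  at the realised dendritic resting potentials.
* Tonic-mode frequency is reported as the pooled mean (total tonic spikes
  over total tonic time, complex spikes and their pauses excluded), one of
  several defensible conventions.

## What the simulations do and do not show

The synthetic protocols reproduce deafferented-cell conditions: no
background inhibition, no synaptic noise beyond the PF Poisson trains, and
a single CF firing metronomically. Passing tests therefore demonstrate the
internal consistency of the mechanisms (trimodal cycling driven by D-type
inactivation and lagged pump sodium; PF rate gain; CF-gated SK control),
not quantitative agreement with any particular in vitro recording.

## Reproducing the headline numbers

```{r, eval = FALSE}
library(purksim)
tr <- simulate_protocol("trimodal", seed = 1)
analyze_trace(tr)$summary
```

`scripts/acceptance.R` reruns every protocol from scratch (intrinsic,
PF x 3 seeds, CF at g_sk = 0.62, CF+PF x 3 seeds, CF toggle at 0.72) and
writes the measured quantities as JSON; see the README.
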