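---
title: "Pulse decoding in GnRH signalling to ERK: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse decoding in GnRH signalling to ERK: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnrhpulse)
```

Gonadotropin-releasing hormone (GnRH) reaches the pituitary as discrete
secretory pulses, and gonadotrope cells decode pulse frequency, width and
amplitude into graded transcriptional responses through the ERK MAP kinase
cascade. `gnrhpulse` implements a reduced kinetic model of this pathway —
from receptor occupancy through ERK activation and nucleocytoplasmic
shuttling to an ERK-dependent transcript — together with the in-silico
pulse-protocol experiments, integrated-response metrics, genetic-algorithm
parameter fitting and a synthetic-data generator that stands in for
live-cell imaging data. This vignette is the package's own account of the
model, its assumptions, the numerical choices, and what the tests do and do
not establish.

## The model

The GnRH input is a square wave: concentration $p$ (µM) while
$t \bmod \Pi < t_p$ and 0 otherwise, where $\Pi$ is the pulse period and
$t_p$ the pulse width; pulses occupy half-open intervals
$[k\Pi, k\Pi + t_p)$. Two discrete interventions can modify a protocol:
*washout* (the input is identically zero from the event time on) and *MEK
inhibition* (the ERK-phosphorylating fluxes are zero from the event time
on, while the ligand and everything upstream keep evolving — the model
counterpart of adding a MEK inhibitor such as PD184352 without removing
hormone).

Ten states evolve (concentrations in µM, per compartment; rates per
minute). With $G(t)$ the input and $C_{cn}$ the cytoplasm:nucleus volume
ratio:

$$
\begin{aligned}
\dot{HR} &= k_1 G (R_0 - HR) - k_{-1} HR\\
\dot{GQ} &= -k_2\, HR \cdot GQ + k_{-2}(GQ_{tot} - GQ)\\
\dot{E} &= k_2\, HR \cdot GQ - k_{-3} E - k_3\, ppE_{fb}\, E\\
\dot{E}_c &= -v_1 + v_4 - k_{imp} E_c + (k_{exp}/C_{cn}) E_n\\
\dot{pE}_c &= v_1 - v_2 + v_3 - v_4\\
\dot{ppE}_c &= v_2 - v_3 - k_{imp,act}\, ppE_c + (k_{exp,act}/C_{cn})\, ppE_n\\
\dot{E}_n &= C_{cn} k_{imp} E_c - k_{exp} E_n + v_5\\
\dot{ppE}_n &= C_{cn} k_{imp,act}\, ppE_c - k_{exp,act}\, ppE_n - v_5\\
\dot{TF1} &= k_{TF1}\, \frac{ppE_n}{K_{MM,TF1} + ppE_n} - d_{TF1}\, TF1\\
\dot{TF1DT} &= k_{TF1DT}\, \frac{TF1}{K_{MM,TF1DT} + TF1} - d_{TF1DT}\, TF1DT
\end{aligned}
$$

MEK activation is fast relative to the rest of the cascade and is treated
algebraically (quasi-steady state in the effector $E$):
$ppMEK = MEK_{tot}\,(k_{MEK,basal} + k_{mek}E) / (k_{MEK,basal} +
k_{mek}(K_{MM,MEK}+E))$, which at the default $k_{MEK,basal}=0$ is the
Michaelis–Menten form $MEK_{tot}E/(K_{MM,MEK}+E)$. Note that at this
default $k_{mek}$ cancels exactly — it is retained in the parameter set
(and in the fitted subset) for provenance, but it has no numerical effect,
with consequences for identifiability discussed below.

ERK is phosphorylated distributively at two sites in the cytoplasm only
($v_1, v_2$, catalysed by ppMEK with competitive inhibition between the
unphosphorylated and mono-phosphorylated forms) and dephosphorylated in
both compartments ($v_3, v_4$ by the cytosolic phosphatase, $v_5$ by the
nuclear phosphatase, which removes both phosphates in one step — the only
nuclear Michaelis constant in the parameter set is the one for $v_5$).
Mono-phosphorylated ERK exists only in the cytoplasm: no transport rates
are defined for it. Transport terms carry the $C_{cn}$ and $1/C_{cn}$
factors so that ERK *amount* is conserved:
$(E_c + pE_c + ppE_c) + (E_n + ppE_n)/C_{cn} = ERK_{tot}$ exactly along
any trajectory; this invariant is checked to $10^{-6}$ in the tests and is
a sensitive probe of implementation errors.

The derived observables are the ones measurements see: whole-cell ppERK as
the volume-weighted mean $(C_{cn}\,ppE_c + ppE_n)/(C_{cn}+1)$, the
nuclear:cytoplasmic ratio of total ERK
$(E_n + ppE_n)/(E_c + pE_c + ppE_c)$ (the ERK2-GFP translocation readout,
0.8 at rest under the default shuttling rates), and ppMEK.

## Design choices where the design was open

The equation system is a reconstruction: the model is defined here by the
code, and several structural choices deserve an explicit record.

* **Feedback target.** The negative feedback $k_3 \cdot ppE_{fb} \cdot E$
  can plausibly act through cytosolic or nuclear active ERK. The package
  default is the **nuclear** pool ($ppE_{fb} = ppE_n$): that is the wiring
  the parameter description for $k_3$ names, and it is the one that
  reproduces the published upstream-effector frequency response (integrated
  $E$ at 45-min pulse intervals ≈ 23% of the constant-stimulation value,
  against ≈ 11% for the cytosolic wiring). The cytosolic variant remains
  one keyword away: `gnrh_parameters(feedback = "cytosolic")`.
* **Units of $k_{-2}$.** The published table prints $k_{-2}$ in s⁻¹ amid
  otherwise minute-based units; it is read here as 1 min⁻¹ (a unit typo),
  and it is assigned to recovery of the free G-protein pool rather than to
  decay of $E$, so that effector decay after washout is governed by
  $k_{-3} + k_3\,ppE_{fb}$ and MEK activity can outlast short pulses.
* **$GQ_{tot}$** is not part of the published constants; the default is
  1 µM. Its magnitude trades off against $k_2$, so only the product is
  meaningfully constrained.
* **Volume convention.** $C_{cn} = 3$ is interpreted as the
  cytoplasm:nucleus volume ratio $V_c/V_n$; concentrations are
  per-compartment and transport conserves amounts, not concentrations.
* **Transcription tier.** TF1 activation by $ppE_n$ and transcript
  production by TF1 use saturating Michaelis–Menten kinetics with
  first-order degradation — the minimal forms that house the two published
  Michaelis constants.

## Numerics

The square wave and the interventions make the right-hand side
discontinuous at known times, so `simulate_protocol()` integrates
piecewise: the horizon is split at every pulse edge and event time, the
input is constant within each segment, and the stiff-capable adaptive
solver (`deSolve::lsoda`, compiled right-hand side) is restarted at each
boundary with relative tolerance $10^{-8}$ and absolute tolerance
$10^{-10}$ — tight enough that the ERK conservation residual stays below
$10^{-6}$ over 24-hour horizons. Segment inputs are classified at segment
*midpoints* because floating-point modulo is unreliable exactly at the
edges (e.g. `60.9 %% 60 < 0.9`). Output grids always contain every
segment boundary. Small negative solver undershoots are clipped to zero in
the observables only, never in the propagated state; undershoot beyond
$-10^{-8}$ is treated as an error. Everything is deterministic: identical
inputs give bit-identical trajectories.

`oracle_simulate()` is a deliberately independent check: a plain-R
classical fixed-step RK4 over the same segments. The tests require
agreement with the adaptive path to $10^{-4}$ relative and verify the
fourth-order convergence of the oracle itself. Because the receptor
binding step is fast ($k_1 G \approx 500\,\mathrm{min^{-1}}$ at
$10^{-7}$ M), the oracle needs steps ≲ 0.002 min during pulses at that
dose; the convergence-order test uses a low-amplitude protocol to stay in
the asymptotic regime.

Integrated responses are trapezoidal areas above the pre-stimulus resting
baseline of each measure, on a 0.5-min output grid by default. The
deviation is signed, not clipped: model trajectories do not undershoot
their baseline, and clipping would mask bugs if they ever did. The one
exception is the GnRH input itself, whose integral is computed in closed
form — sampling a discontinuous signal onto the grid biases its area. The
frequency axis is reported as pulses/h and the constant-stimulation limit
(interval = width) is included as the maximal-frequency normalization
reference. Gradients in `sensitivity_gradient_ratio()` are central
differences with ±10% perturbations of the interval or width.

## Protocols and problem sizes

The standard analyses (and `run_battery()`) use: 1- and 10-min pulses of
$10^{-7}$ M GnRH; intervals {width, 15, 30, 45, 60, 90, 120, 240} min over
a 480-min horizon for frequency responses; widths {1, 2.5, 5, 10, 20, 30,
60} min at 60-min intervals for width responses; 30-min horizons for
single-pulse ppERK time courses; and a 360-min endpoint for the
termination-ratio analysis over widths {1, 5, 15, 30, 60} min. These sizes
make each full response surface a sub-minute computation while keeping
every pulse edge resolved exactly.

## Fitting

`fit_parameters()` implements a genetic algorithm over the flagged
(historically fitted) subset {$R_0$, $k_2$, $k_{-2}$, $k_{exp,act}$,
$k_{exp}$, $k_{imp,act}$, $k_{imp}$, $k_{mek}$, $K_{MM,MEK}$,
$MEK_{tot}$}: each generation every candidate's flagged parameters are
multiplied by $(1 + 0.1\,\varepsilon)$ with standard-normal
$\varepsilon$ (the update is read as multiplicative; a positivity floor of
$10^{-12}$ applies), candidates are scored by weighted mean squared error
against the pseudo-observations, and a new population is drawn with
replacement with probability proportional to fitness rank (best of $N$
gets weight $N$). One elite — the best vector found so far — is carried
through unmutated each generation; without it rank sampling can lose the
best candidate, and with it the best-so-far fitness is provably
non-increasing. There is no annealing of the mutation scale and no
stopping rule beyond the generation budget, both deliberate: the algorithm
is kept exactly as simple as described.

Two identifiability caveats matter when interpreting recovered parameters.
First, $k_{mek}$ has no effect at the default $k_{MEK,basal}=0$ and
therefore performs an unconstrained multiplicative random walk. Second,
the observables see the effector only through saturating MEK kinetics, so
scaling $E \to \alpha E$ while scaling $K_{MM,MEK} \to \alpha K_{MM,MEK}$
(with the production scale absorbed into $R_0$, $k_2$, $k_{-2}$) leaves
every observable nearly invariant. The fitness landscape is
correspondingly sloppy: on noiseless synthetic objectives generated at the
default parameters (`recovery_objectives()`: 1-min, 10-min and constant
stimulation N:C traces plus a 5-point integrated-N:C dose–response), a
population of 50 evolved for 150 generations from a 2× perturbed start
reliably drives the MSE down by about two orders of magnitude, but the
recovered vector lands on the sloppy manifold near — not at — the
generating truth: the shuttling rates and MEK abundance return within
roughly 20% (median over seeds), while the members of the scaling family
($R_0$, $k_{-2}$, $K_{MM,MEK}$) and $k_{mek}$ drift much further. The
acceptance test prints the per-parameter medians over five seeds so this
behaviour is visible rather than hidden.

## Synthetic data

`generate_nc_traces()` emulates ratio-imaging time courses: the
deterministic N:C signal, i.i.d. additive Gaussian noise per cell (default
s.d. 0.05 in ratio units, roughly the magnitude seen in single-cell
ratio imaging), each trace normalized to its own t = 0 value as imaging
analyses do. All cells share the model signal — the generator emulates
measurement noise, not cell-to-cell kinetic variability, matching the
model's single-cell-average scope. `generate_dose_response()` produces
integrated-N:C or transcript-endpoint responses across doses, normalized
to the maximal dose. What passing tests on these data show is that the
pipeline is self-consistent (generator → objectives → fitness → fitting);
they cannot show that the model describes real imaging data, and the
normalization step means absolute concentrations are only constrained
through the model's own scale.

## Known limitations

* The equation system is a reconstruction from a prose description and a
  parameter table; the original renderings were unavailable. The upstream
  tier (receptor, effector, ppERK timing, post-pulse behaviour,
  termination-ratio shape) reproduces the published predictions well. The
  transcriptional tier does not: with the printed constants, integrated
  TF1DT for 1-min pulses at 45-min intervals is ≈ 18% of the
  constant-stimulation value, a much weaker frequency nonlinearity than
  the ≈ 90% reported for the original model. The ppE$_n$ transient after a
  1-min pulse (peak ≈ 0.2–0.3 µM, gone within ~10 min) is simply too small
  and too brief to saturate a TF1 tier with $K_{MM,TF1} = 0.4$ µM. No
  wiring variant documented above closes this gap; a dynamic (slowly
  inactivating) MEK species — excluded here by the algebraic MEK
  assumption — is one mechanism that would.
* Receptor internalization/desensitization, stochastic single-cell
  variability, graded secretory pulse shapes and partial inhibitor
  efficacy are out of scope.
* The washout and inhibitor interventions are instantaneous and complete.

## A worked frequency-decoding run

```{r freq, eval = FALSE}
params <- gnrh_parameters()
fr <- frequency_response(params, width = 1,
                         intervals = c(1, 15, 30, 45, 60, 90, 120, 240),
                         amplitude_molar = 1e-7, horizon = 480)
subset(fr, interval_min == 45, c(measure, auc, auc_normalized))
```

The normalized column divides each measure by its value under constant
stimulation; upstream measures fall roughly in proportion to the input
duty cycle while downstream measures are progressively less reducible —
the quantitative statement of frequency decoding this package exists to
compute.
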