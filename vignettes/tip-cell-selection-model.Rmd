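---
title: "An agent-based model of filopodia-driven tip cell selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of filopodia-driven tip cell selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiomsm)
```

## The biological problem

During angiogenesis, endothelial cells in a pre-existing vessel collectively
select which of them become migratory "tip" cells, producing an alternating
(salt-and-pepper) pattern of tip and stalk cells. The canonical mechanism is
Notch-Dll4 lateral inhibition: VEGF activates VEGFR-2; activated receptors
up-regulate the ligand Dll4; Dll4 binds Notch on the neighbouring cell, and
cleaved Notch represses that neighbour's VEGFR expression. Gene-regulatory
cycles are slow, however, and on their own struggle to explain how quickly
tip cells emerge in vivo. This package implements a constrained
membrane-agent model in which the missing speed comes from *filopodia*: thin
actin-driven protrusions that carry VEGF receptors up the gradient, creating
a fast positive feedback between movement and sensing that biases and
accelerates the slow Notch competition.

## Model structure

**Lattice and VEGF field.** Space is a 3-D lattice of 0.5 µm cubic sites.
The VEGF field is static: either a linear gradient anchored at zero
concentration at the bottom of the volume (`I = V * y`) or a uniform level.
Whether `y` in that formula is the lattice index or the physical coordinate
in micrometres is a genuine unit ambiguity of this model family (the two
differ by the 0.5 µm site size). We use micrometres (`vegf_y_units = "um"`):
with index units the vessel body itself collects so much activation that the
fast body-mediated inhibition loop dominates and destabilises into a
synchronised oscillation of the whole vessel, while the micrometre convention
leaves the body weakly stimulated and puts the bulk of the signal on
filopodia — which is the regime this model is about. The op-level
`vegf_field()` still defaults to index units for bare-lattice arithmetic.

**Vessel mesh.** Each cell is a 10 µm wide full cross-section of a 6 µm
diameter cylinder, meshed as a quad ring-lattice of ~1200 membrane agents
(memAgents) joined by Hookean springs; cells form a ring with periodic ends.
Agents whose lattice site has a Moore (26-connected) neighbour occupied by
another cell are *junction* agents. In this constrained configuration all
body agents are pinned ("cells fixed in place") and filopodia chain agents
are anchored to the lattice between adhesions, so the spring relaxation pass
(`relax_springs()`, exposed and tested on its own) has no free vertices to
move during a run; mechanics would matter only in the migratory extensions
that are deliberately switched off here.

**Per-step update order** (fixed, documented in `msm_step()`):

1. the cell's VEGFR pool is split equally over all its current agents
   (integer split; the remainder is assigned round-robin with a rotating
   offset — deterministic yet unbiased over time), and Dll4 is split equally
   over junction agents only;
2. each agent activates `Vegfr* = min(Vegfr, Vegfr * I)` where `I` is its
   local VEGF input (for a linear field the Moore-neighbourhood mean equals
   the site's own value). Activation is kept continuous; quantising it to
   integers creates dead zones in which weakly inhibited cells emit exactly
   zero signal and every partially inhibited state becomes absorbing;
3. Notch-Dll4 binding with consumption: on each directed cell-cell
   interface the binder takes `min(presented Dll4 share, binder Notch
   capacity)` and that amount is debited from the presenter's pool. Notch
   capacity is the cell's Notch pool divided by its *current* agent count —
   a cell with many filopodium agents dilutes Notch at its junctions;
4. filopodia: tips extend stochastically with
   `P = min(1, F * Vegfr*_tip / p_cap)`, stepping into a free Moore
   neighbour (the maximal-VEGF one with probability `G`, else uniformly at
   random); each 0.5 µm step costs actin; an adhesion anchors the chain
   every 2 µm; a tip idle for 15 steps triggers burst retraction to the most
   distal adhesion, which is then released, until the filopodium is gone and
   its actin returned. New filopodia initiate from body agents under the
   same probability law, subject to a minimum base spacing of 2 agents;
5. spring relaxation (no free vertices here, see above);
6. delayed gene regulation:
   `Vegfr_cell = max(0, Vegfr_max - sigma * N*(t - 28))` and
   `D_cell = min(d_max, D_cell + delta * Vegfr*(t - 28))`, with the 28-step
   delay implemented as zero-primed ring buffers. Dll4 accumulation is
   bounded by the ceiling `d_max` and drained by the neighbours' consumptive
   binding, which provides its only sink (a "replace" mode is available via
   `dll4_mode`).

All stochastic draws come from R's global RNG in a fixed documented order,
so every run is exactly reproducible from its seed.

## Parameters

Printed, fixed values: `F` in (0, 3) with control 2; gradient `V` in
(0.01, 0.04) with control 0.04 (uniform: control 0.8); `G` in (0, 1) with
control 0.9; `filtipmax` 15; `token_strength` 1 per µm; `filspacing` 2;
gene-regulatory delay 28 steps; pattern criteria of 600 Dll4 ligands held
for 100 steps (two-cell runs), 4-5 non-adjacent tip cells stable for 100
steps (ring runs), and run windows of 2000 steps (gradient) / 5000
(uniform). The Dll4 ceiling follows from the printed relation that the
600-ligand criterion is 6 percent of the maximum: `d_max = 10000`.

Unprinted values (they live in prior calibrations of this model family)
were fixed once by a calibration sweep whose goals were: a control two-cell
run reaches the 600-ligand criterion within the run window; the 10-cell
ring patterns within 2000 steps with 4-5 non-adjacent tips; a clamped
external Dll4 of about 950 fully silences an undefended cell while 500
leaves it active. The frozen values are `vegfr_max = 12000` (10 receptors
per agent at rest), `notch_pool = 13200` (11 per agent at rest),
`sigma = 13`, `delta = 0.55`, actin budget 360 µm-tokens per cell, and
`p_cap` resolved at initialisation to 1.5 x the per-agent receptor count of
the resting mesh (15 at the default density; the factor keeps control
extension probabilities below saturation so that the F = 2 vs F = 3
distinction survives). These are model constants, not experiment dials: the
experiment dials are `F`, `V`, `G` and the VEGF mode.

## Why the model patterns, in brief

Write the per-cell activation as `A = Vegfr_cell * Phi`, where `Phi` is the
activation fraction set by where the cell's receptors sit in the field. The
body contributes a small, fast `Phi`; filopodia contribute a larger, *slow*
component because chains take tens of steps to build and their tips sit at
high VEGF. Lateral inhibition transfers `sigma * delta * A` between the
cells with a 2 x 28 step loop delay. The fast body loop alone is kept
subcritical (no synchronised oscillation); the filopodia component pushes
the *differential* loop gain above one, so any fluctuation-induced
asymmetry in filopodia mass grows exponentially until one cell silences the
other. That is exactly the claimed mechanism — selection speed lives in the
movement-sensing feedback, not in the gene circuit — and it explains the
conditions: reducing `F` or `V`, randomising guidance (`G` low), or making
the field uniform (movement no longer changes what is sensed) all remove
the filopodia gain and slow or abolish patterning.

## Hysteresis testbed

`run_hysteresis()` rebuilds the bistability protocol: a centre cell flanked
by two pseudo-cells that present a clamped external Dll4 total (`d_ext`,
split equally) and consume the centre's junction Dll4 without responding.
The ramp rises from zero in increments of 50 until the centre has been
inhibited for two consecutive levels (capped at `d_max`), then reverses. A
level advances only when two adjacent 250-step windows (after a 250-step
transient) agree in mean and standard deviation to within the normalised
tolerance 0.5, or after 60000 steps (recorded as a timeout). Branches are
classified on the smoothed VEGFR pool against `vegfr_max / 6` rather than
on Dll4: the active branch's Dll4 equilibrium varies strongly with `d_ext`
(production balances the flanks' consumption), so a Dll4 midpoint between
the level-0 equilibrium — which sits at the `d_max` ceiling — and the
silenced state misclassifies live, filopodia-bearing cells. The VEGFR pool
separates the branches cleanly at every level.

`step_response()` probes metastability: equilibrate with `d_ext = 0`, jump
to a target, and classify the long post-jump trace as `active`, `inhibited`
(one-way transition) or `flip_flop` (two or more branch crossings).

## Sensory map and active-perception measures

Every step, each agent's activation count is projected radially onto the
fixed cylindrical vessel surface (axial coordinate and azimuth preserved),
accumulating a sensory map on 0.5 µm x 0.5 µm patches; activations on a
filopodium that leans over the neighbour's territory are credited to the
patch beneath it, because the map represents what the *vessel* senses.
Two measures summarise the map: intensity `I` (the total activation, equal
by conservation to the summed `Vegfr*`) and Shannon entropy `H` in bits,
computed after Laplace smoothing `p_i = (v_i + alpha) / (sum v + N alpha)`
with `alpha = 1` activation count (the smoothing constant is a convention;
we use the unit pseudo-count). A two-cell run that resolves the competition
concentrates activation on the winner's half of the map, so `H` falls by
around one bit (the shipped calibration measures a drop of roughly 0.7 bits
averaged over replicates) — the package's quantitative patterning signature
— while `I`
saturates under the actin constraint, giving the logistic-like late shape.

## Spatial periodicity

`lomb_scargle()` implements the classical Scargle least-squares spectrum
directly (it is validated in the tests against per-frequency sinusoid fits
and against the FFT periodogram on even grids). Frequencies are *angular*
(radians per length unit) so that the dominant period is `P = 2 pi / f`;
the near-DC band (periods longer than 80 percent of the profile span) is
excluded from dominance because such modes are indistinguishable from a
constant offset. `synth_profile()` generates staining-like test profiles:
Gaussian bumps at a stated spacing (~90 length units for the control-like
preset) with amplitude noise, positional jitter and optional bump dropout;
the "latb" preset (high jitter, 50 percent dropout) mimics the diffuse
patterning of filopodia-disrupted embryos. These synthetic profiles emulate
only the first-order structure of quantified images — periodic intensity
with noise — not imaging artefacts, background gradients or inter-embryo
averaging, so tests on them validate the spectral machinery, not the
biology of any particular dataset.

## Problem sizes used in the tests

The packaged tests run the full-resolution mesh (1200 agents per cell)
throughout, since coarser meshes change the body-to-filopodia signal ratio
and with it the dynamical regime. Replicate counts are kept modest (a
handful of seeds per condition for orderings; a dozen or two for the
entropy-drop average; single seeds per hysteresis ramp), chosen so the
whole suite completes comfortably on one CPU while each assertion still
tests the stated property; the experiment drivers accept arbitrary
replicate counts for heavier reproduction runs.

## Known limitations

* The model inherits the constrained scope of its source: no migration,
  veil advance, junction remodelling or cell rearrangement; the VEGF field
  neither diffuses nor depletes.
* Notch binding in the engine is aggregated per interface (the per-agent
  greedy rule is exposed as `bind_notch()` and is equivalent on the dense
  default mesh); per-agent Notch state is therefore not tracked during runs.
* Unprinted constants were calibrated to the anchors above; other
  calibrations satisfying the same anchors may differ quantitatively, so
  downstream numbers (e.g. exact patterning times) should be read as
  model-relative, not absolute.
* Because the VEGFR pool is a memoryless assignment from delayed Notch
  activation, a cell silenced by an intermediate external Dll4 clamp cannot
  nucleate the filopodium mass whose Notch dilution would relieve it: the
  silenced state is absorbing, so the intermediate clamp produces a delayed
  one-way transition rather than a two-sided stochastic flip-flop, and under
  the long quasi-static ramp residencies the branch memory equilibrates away
  entirely (bistability here is finite-horizon metastability, and
  Dll4-level ramp gaps are sensitive to where the stationarity test halts
  relative to slow Dll4 relaxation). Reproducing a true two-sided flip-flop
  would need additional state, such as graded receptor turnover or
  per-agent Notch dynamics.

## A minimal session

```{r example, eval = FALSE}
p <- msm_params()                      # control parameters
tr <- msm_run(p, n_cells = 2, seed = 1, record_ap = TRUE)
dll4_advantage_time(tr)                # when one cell won
res <- entropy_drop_experiment(p, reps = 12, base_seed = 1)
res$mean_drop                          # ~1 bit entropy drop after patterning

sp <- lomb_scargle(synth_profile(preset = "control", seed = 1)$position,
                   synth_profile(preset = "control", seed = 1)$value)
dominant_period(sp)$period             # ~90 length units
```
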