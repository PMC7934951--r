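# angiomsm

An agent-based simulation of endothelial **tip cell selection** during
angiogenesis, for researchers studying Notch-mediated collective cell
decisions and the role of filopodia in them.

When a blood vessel is activated by VEGF, its endothelial cells compete
through Dll4-Notch lateral inhibition until an alternating ("salt and
pepper") pattern of migratory tip cells and inhibited stalk cells emerges.
Gene-regulatory cycles are slow; this model implements the hypothesis that
*filopodia* — actin-driven protrusions that carry VEGF receptors up the
gradient — add a fast sensorimotor feedback that biases and accelerates the
competition.

## The model in brief

Cells are cylindrical surfaces of ~1200 membrane agents (memAgents) on a
0.5 µm lattice, joined by Hookean springs and pinned in place (only
filopodia move). Per time step:

* each cell's receptor pool is spread equally over its current agents, and
  Dll4 over its junction agents;
* local activation: `Vegfr*_m = min(Vegfr_m, Vegfr_m · I)` with `I` the
  local VEGF input (`I = V·y` in the gradient);
* junction Notch binds and consumes apposed Dll4:
  `N* = min(Dll4 available, Notch capacity)`;
* filopodia extend with `P = min(1, F · Vegfr*_tip / p_cap)`, step
  up-gradient with probability `G` (else randomly), cost actin, anchor
  adhesions every 2 µm, and burst-retract adhesion-by-adhesion after 15
  idle steps;
* delayed gene regulation (28 steps):
  `Vegfr_cell = max(0, Vegfr_max − σ·N*′)` and
  `D_cell = min(d_max, D_cell + δ·Vegfr*′)`.

On top of the core model the package provides the three analysis testbeds
used to characterise it: time-to-pattern scoring on the 10-cell ring and the
two-cell testbed (600-ligand Dll4 advantage held for 100 steps), a
quasi-static hysteresis protocol driving a single cell with clamped external
Dll4 (`run_hysteresis()`, `step_response()`), and active-perception measures
on the cylindrical sensory map (intensity, and Shannon entropy with Laplace
smoothing). A Lomb-Scargle spatial periodogram module quantifies
salt-and-pepper periodicity in 1-D intensity profiles, with a synthetic
profile generator for controlled tests.

## Worked example

```r
library(angiomsm)

p <- msm_params()                       # control: F = 2, V = 0.04, G = 0.9
tr <- msm_run(p, n_cells = 2, seed = 1, record_ap = TRUE)
dll4_advantage_time(tr)
#> patterned at t = 704 (tips: 1), seed 1
```

Cell 1 established a 600-ligand Dll4 lead at step 704 and held it for 100
steps: the selection decision is made. With filopodia reduced
(`msm_params(F = 0.5)`) the same seeds do not pattern within the 2000-step
window. The sensory-map entropy drops once the competition resolves:

```r
ed <- entropy_drop_experiment(p, reps = 10, base_seed = 1)
ed$mean_drop
#> [1] 0.7234
```

about 0.7 bits lower after patterning than before — the winning cell now
receives nearly all of the VEGF input. The spatial-periodicity module
recovers the spacing of a periodic staining profile:

```r
pr <- synth_profile(preset = "control", seed = 1)   # bumps every 90 units
dominant_period(lomb_scargle(pr$position, pr$value))$period
#> [1] 90.956
```

A thin command-line wrapper over these functions ships in
`inst/cli/msm.R` (subcommands `run`, `sweep`, `hyst`, `step`, `ap`,
`periodogram`, `synth-profile`).

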