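---
title: "Methods: an agent-based model of gap-junction transport in differentiating stem-cell colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an agent-based model of gap-junction transport in differentiating stem-cell colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gjcolony)
```

## Scope

`gjcolony` implements an agent-based model of a growing embryonic stem-cell
colony in which a small diffusible molecule (a cAMP-like second messenger)
moves between adjacent cells through gap junctions, accumulates through
autoinhibited production, and drives an irreversible pluripotent-to-
differentiated fate switch. The package also provides the two analysis
pipelines built on top of the model: a pattern-classification latent space
(seven network metrics reduced by PCA) and GAP-FRAP recovery-constant
fitting for calibrating intercellular transport.

This vignette documents the model equations, the numerical scheme, every
default constant, and the places where the package's working constants
deviate deliberately from commonly printed values — with the arithmetic
that motivates each choice.

## Cells, geometry and the contact network

Cells are rigid disks of fixed radius $r = 6.5\ \mu m$ confined to a 2D
plane. Two cells are in gap-junction contact when their membranes are within
a $2\ \mu m$ gap, i.e. when their center distance is at most
$2r + 2 = 15\ \mu m$. The contact network is rebuilt whenever positions
change; it is undirected, with no self-edges.

Division places two daughters at the mother's position $\pm r$ along a
uniformly random direction; both inherit the mother's phenotype,
concentration (treated as intensive) and threshold count, and restart their
division clock at zero. Overlaps created by division are resolved by
iterative pairwise relaxation: each overlapping pair is pushed apart along
its center line until the maximum overlap is below $0.05\ \mu m$ (at most
500 sweeps), with the displacement share weighted towards the cell farther
from the colony centroid so colonies expand outward. On radially symmetric
configurations the weighting introduces no net centroid drift.

The division clock `t_div` advances 1 h per simulated hour; a cell divides
when the clock reaches its phenotype's cell-cycle length (CCL): 18 h
pluripotent, 51 h differentiated.

## Transport

Each simulated hour comprises 1200 synchronous explicit substeps of 3 s.
Per substep, cell $i$ updates as

$$\Delta C_i = \sum_{j \in N(i)} PM_{eff}(i,j)\,(C_j - C_i)
  \;+\; \frac{v_p}{1 + C_i / K_{50}} \;-\; k_d\, C_i$$

with all terms evaluated from the pre-substep state (Jacobi update), so
pairwise fluxes are antisymmetric and transport alone conserves total
concentration exactly.

The effective pairwise permeability is
$PM_{eff} = PM_{max} \cdot (CCE_1\, PM_{n,1}) \cdot (CCE_2\, PM_{n,2})$,
the product of the two cells' cycle-modulated nascent permeabilities.
The cell-cycle effect is

$$CCE(t_{div}) = \frac{1}{1 + (DT_{norm}/CCL)^2}
  \;-\; \frac{0.69\, t_{div}^6}{t_{div}^6 + CCL^6},
  \qquad DT_{norm} = |t_{div} - CCL/4|$$

which peaks at $\approx 1$ (100% of nascent permeability) in G1
($t_{div} = CCL/4$) and falls to $\approx 0.295$ (~30%) at mitosis
($t_{div} = CCL$).

### Sign of the oscillatory CCE term

This expression is sometimes printed with the sixth-order term *added*.
Addition gives $CCE(CCL) = 1/(1+0.75^2) + 0.345 \approx 0.985$ — no mitotic
minimum at all — while subtraction gives $0.64 - 0.345 = 0.295$, matching
the ~30%-at-mitosis behaviour the modulation is meant to encode.
`gjcolony` therefore subtracts by default; the added form remains available
via `gj_params(eq2_sign = "printed")`.

### Stability and the default `PM_max`

The explicit 3-s update is stable only while every cell's summed effective
permeability over its neighbours stays below 1 (the package errors
otherwise rather than integrating garbage). With rigid disks and a 15 µm
contact threshold the attainable contact degree is at most 7, and the
largest per-edge factor is $PM_{n,D}^2 = 0.85^2 = 0.7225$ at peak CCE. A
`PM_max` of 1 therefore guarantees a guard trip (worst row sum ≈ 5.06) in
any colony with adjacent differentiated cells. The default is
`pm_max = 0.1`, for a worst-case row sum of
$7 \times 0.1 \times 0.7225 \approx 0.51$, comfortably stable while keeping
pair equilibration fast relative to the 1-h fate cadence.

### Production constants and the `K50` scale

Per-substep constants (`gj_params()` defaults):

| constant | pluripotent | differentiated | units |
|---|---|---|---|
| nascent permeability $PM_n$ | 0.45 | 0.85 | fraction |
| production $v_p$ | 4.89e-6 | 6.0e-6 | conc / 3 s |
| half-inhibition $K_{50}$ | 3.0 | 4.0 | conc |
| degradation $k_d$ | 1.3e-7 | 1.3e-7 | 1 / 3 s |
| cell-cycle length | 18 | 51 | h |

$K_{50}$ is sometimes printed as 0.03 / 0.04. Those values are inconsistent
with the rest of the parameterization: the operating concentration range
(initialization 0.6–0.65, differentiation threshold $C_{th} = 0.74$) sits
20–35× *above* them, so production is ~96% inhibited everywhere. Net
accumulation near $C = 0.65$ is then
$1200 \times (4.89\times10^{-6}/(1 + 0.65/0.03) - 1.3\times10^{-7}\times 0.65)
\approx 1.6\times10^{-4}$ per hour, and the threshold is first crossed after
roughly 600 h — no concentration-driven differentiation can occur inside a
72-h experiment, and production/permeability perturbations become inert.
Rescaling by 100 to $K_{50} = 3.0/4.0$ (ratio preserved) puts the
half-inhibition point above the operating range, giving a net accumulation
of ~0.005–0.01 per hour and a colony-wide threshold crossing at ≈ 19–30 h —
the fast differentiation event near one day that the model is built to
produce. The printed scale remains available via
`gj_params(table_constants = "printed")`. Note the production at zero
concentration equals $v_p$ under either choice.

## Differentiation

At the end of each hour every cell updates its threshold count `tC`: +1 if
its concentration strictly exceeds $C_{th} = 0.74$, otherwise −1 with a
floor at 0 (the floor keeps the even-exponent Hill probability monotone).
Each pluripotent cell then draws two independent Bernoulli trials:

* threshold channel: $P = tC^4 / (tC^4 + 2^4)$ (half-maximal after 2 h
  above threshold);
* stochastic channel: $P = 0.002 + |0.001 \sin(t_{sim}/8)|$, bounded in
  [0.002, 0.003], evaluated at the colony time at the start of the hour.

If either succeeds the cell differentiates irreversibly, switching to the
differentiated CCL, $PM_n$, $v_p$ and $K_{50}$ immediately; the division
clock carries over. Cells are visited in ascending id order from a single
seeded RNG stream, so runs are exactly reproducible from
`(structure, params, seed)`.

Each simulated hour is: 1200 transport substeps → fate step → divisions →
overlap relaxation → network rebuild → clocks and time +1 h.

## Perturbation modes

`perturb_params()` / `run_perturbation()` implement the two in-silico
interventions: `"SQ"` (adenylyl-cyclase inhibition; the differentiated
production constant is scaled, default ×0.5) and `"BGA"`
(β-glycyrrhetinic-acid gap-junction block; `pm_max` is scaled globally,
default ×0.5), run seed-matched against an unmodified control.

A caveat worth knowing: under the default (corrected-$K_{50}$) dynamics the
colony saturates to ~100% differentiated by ~30–35 h, so differentiated
fractions compared *at 48 h* tie between control and perturbed arms; the
perturbation effects are visible mid-transition (~20–30 h), not at
saturation. The acceptance test encoding the 48-h comparison is left
failing rather than moved.

## Pattern classes and the latent space

`make_structures()` grows synthetic colony geometries by sequential random
peripheral attachment of touching disks (each new cell touches a random
parent; among a few valid candidates the one nearest the centroid is kept,
keeping packings compact and the contact network connected). The default
training set (`make_training_set()`) labels 120 structures of 100–400 cells
with all eight pattern classes — `random`, `outside_in`, `inside_out`,
`snaked`, `half`, `spotted`, `ring`, `gradient` — for 960 labelings, with
the target differentiated fraction cycling through
{0.1, 0.3, 0.5, 0.7, 0.9} across structures. Every labeling receives one
pass of neighbour smoothing: cells whose differentiated-neighbour fraction
exceeds the population mean are additionally labelled (existing labels are
kept, making all-0/all-1 fixed points).

Seven scalar metrics (`metric_names()`) summarize extent
(`frac_diff`), organization (`n_diff_clusters`, `largest_cluster_share`,
`diff_neighbor_frac`) and locale (`radial_locale`, `degree_excess`,
`assortativity_excess`); all are invariant to rigid motion and id
permutation. `train_pca()` centers, scales and rotates them
(`stats::prcomp`), orienting each component so its largest-magnitude
loading is positive; `project_latent()` applies the frozen transform to new
colonies and `latent_trajectory()` averages repeated runs per time point.
On default training sets the first three components carry ~85–90% of the
variance with PC1 dominant. Because several organization metrics co-vary
with extent, the extent signal splits between PC1 and PC2 rather than
loading PC1 alone (jointly, PC1–PC3 recover the differentiated fraction
with $R^2 \approx 0.8$).

## GAP-FRAP fitting

`normalize_frap()` shifts the time origin to the post-bleach intensity
minimum and rescales by the post-bleach maximum; `fit_frap()` fits
$I(t) = 1 - e^{-t/R_c}$ by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`), initializing $R_c$ at the time of 63.2% recovery.
The recovery constant is inversely related to the summed permeability into
the bleached cell; when a pre-bleach maximum is supplied the
pre-bleach-normalized constant is reported too. At the 3.8-s sampling used
experimentally, noiseless recovery constants across 5–200 s are recovered
with < 1% bias (the small bias comes from normalizing by the finite-window
post-bleach maximum).

## Numerical scale and limitations

* A 48-h run starting from 100 cells (~265 cells at the end) takes a few
  seconds on one CPU; a 72-h run stays well inside 10 minutes. The inner
  substep loop and the overlap relaxation are implemented in C++ (Rcpp).
* Growth: with the 51-h differentiated cell cycle, a 72-h run from 100
  cells reaches ~400–600 cells (pure 18-h cycling would give ~1600; the
  ~26-h commitment event slows division).
* The model has no cell death, no cell motility beyond overlap relaxation,
  and a binary phenotype; concentration is a single scalar species.
* The explicit integrator requires per-cell summed permeability < 1; the
  package enforces this rather than silently losing accuracy.

## Reproducibility

All stochastic entry points take explicit seeds (`simulate_colony()`,
`make_training_set()`) or consume the caller's RNG state
(`label_pattern()`, `init_colony()`). `write_manifest()` records the
package version, full parameter set, seed and md5 hashes of inputs next to
every CLI run, and `read_config()` rejects unknown keys so configuration
typos fail loudly.
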