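---
title: "Methods: models, Monte Carlo protocol and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, Monte Carlo protocol and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hardwater` simulates two minimal water-like fluids whose structure is
dominated by hard cores and short-range association, with an optional
dipole-dipole interaction on top.  This vignette records the models and
parameters exactly as implemented, the Monte Carlo protocol, the analysis
definitions, and the known limitations.  All lengths are in units of the
hard-core diameter $\sigma = 1$ and all energies are reduced
($\beta u$, dimensionless).

## The primitive model (`model = "pm"`)

A molecule is a hard sphere of diameter $\sigma$ carrying three interaction
sites in the body frame:

* two positive "proton" sites **P** on the sphere surface (distance
  $0.5\,\sigma$ from the center), separated by the tetrahedral angle
  ($\cos\theta = -1/3$);
* one negative site **N** on the bisector of the P-P angle at distance
  `n_offset` $= 0.25\,\sigma$ from the center, on the opposite side.

The pair interaction is:

* **O-O hard core** at $\sigma$ between molecular centers;
* **P-N square well**: $-\epsilon_{HB}$ whenever an intermolecular P-N
  distance is below `r_sw` $= 0.55\,\sigma$ (each of the four P-N pairs
  counts independently) -- this is the hydrogen bond;
* **like-site hard cores**: P-P pairs below `d_pp` and N-N pairs below
  `d_nn` are forbidden.  These block doubly-donated bonds.

The published description of this model family leaves the numerical values
of `d_pp`, `d_nn` and `r_sw` to earlier work and does not print them, so
they are package choices, set once on geometric grounds and overridable in
every configuration: `r_sw = 0.55` (a bonding shell of width
$\sim 0.1\,\sigma$ outside the P site, mimicking the narrow hydrogen-bond
shell of the parent atomistic geometry) and `d_pp = d_nn = 0.45`
(like-site avoidance at the bonding-shell scale).

The like-site core size deserves a note.  Steric blocking of double bonds
would ideally use cores comparable to the site spacing
($\sim 0.8\,\sigma$), but a systematic packability scan (documented in the
tests and reproducible with `build_initial_config`) shows that at the
liquid packing fraction $\eta = 0.35$ cores of $0.55\,\sigma$ and larger
cannot be constructed at all with this package's packing protocol -- the
orientational excluded volume jams compression near $\eta \approx 0.24$
well below the target -- while $0.45$--$0.50$ pack in seconds.  The default
is therefore $0.45$.  A consequence worth knowing: with these small cores
the first coordination shell of the center-center correlation function
contains, beside the $\approx 3.5$ hydrogen-bonded neighbors, several
non-bonded neighbors, so the first-shell coordination number comes out
near $6$--$7$ rather than the $\approx 4$ of a fully tetrahedral network.
The square-well (bonding) energy itself is insensitive to this choice.

## Dipolar hard tetrahedra (`model = "ht"`)

A regular hard tetrahedron inscribed in the $\sigma$ sphere (circumsphere
diameter $\sigma$; insphere diameter $\sigma/3$).  Overlap of two
tetrahedra is decided by a separating-axis test over the 8 face normals
and 36 edge-edge cross products, short-circuited by the two exact bounds:
centers closer than $\sigma/3$ always overlap, centers farther than
$\sigma$ never do.  A point-containment sampling oracle cross-checks the
separating-axis implementation in the test suite.

## Dipoles

Both models can carry a point dipole of reduced strength
$\lambda = \mu^2 / (4\pi\varepsilon_0 k_B T \sigma^3)$ along the symmetry
axis.  `lambda_from_physical()` converts physical parameters; e.g.
$\mu = 1.85$ D, $T = 298$ K, $\sigma = 3$ &#8491; gives $\lambda \approx 3$,
and the liquid-phase moment $2.9$ D gives $\lambda \approx 7.6$.

The dipole is realised as **two opposite unit charges** displaced by `l0`
along the axis (default $0.01\,\sigma$; the two-charge energy differs from
the point-dipole limit at $O(l_0^2)$).  The pair energy sums the four
charge-charge terms with a **reaction field**,

$$\beta u_{qq}(r) = \lambda\, \frac{q_i q_j}{l_0^2}
  \left( \frac{1}{r} + \frac{\varepsilon_r - 1}{2\varepsilon_r + 1}
  \frac{r^2}{r_c^3} \right), \qquad r_{\mathrm{centers}} \le r_c,$$

with conducting boundary ($\varepsilon_r = \infty$, coefficient $1/2$) by
default and the cutoff $r_c = L/2$ at the half box.  Pairs are included or
excluded as whole molecules by their center-center distance.

Three modes:

* `none` -- hard/square-well reference system;
* `full` -- the dipolar energy as written above;
* `screened` -- the dipolar pair energy multiplied by the cubic smoothstep
  switch $S(r)$ rising from 0 to 1 between `r_lo` $= 4/2.653$ and `r_hi`
  $= 6/2.653$ (in $\sigma$ units), i.e. short-range dipolar contributions
  are removed while the long-range part is kept.  $S$ has exact endpoint
  values and zero endpoint slopes and is monotone.

## Monte Carlo protocol

* **Ensemble**: canonical (NVT), cubic box, periodic boundaries, minimum
  image.
* **Moves**: single-particle joint translation (uniform in a cube of side
  $2 d_{\mathrm{trans}}$) plus rotation (random axis, angle uniform in
  $[0, d_{\mathrm{rot}}]$, applied as a quaternion product).  Acceptance by
  the Metropolis rule on the reduced energy difference; hard overlaps
  reject immediately.
* **Incremental bookkeeping**: per-pair square-well and dipolar energies
  are cached, so a trial move only computes the changed row.  Every
  `revalidate_every` sweeps the total is recomputed from scratch and the
  run aborts if the incremental total has drifted by more than $10^{-8}$.
  The $O(N^2)$ audit `config_audit()` is the reference implementation.
* **Amplitude tuning**: during equilibration only, every 100 sweeps the
  amplitudes are scaled by the clamped ratio of the observed acceptance
  rate to the 30--50% target window; production runs with frozen
  amplitudes so detailed balance is exact.  At the dense bonded state
  points the tuned translation amplitude is small
  ($d_{\mathrm{trans}} \approx 0.015$).
* **Equilibration monitoring**: the energy trace is split into windows and
  half-window means are compared against their standard errors
  (`monitor_equilibration()`); non-stationarity produces a warning, never
  a silent pass.
* **Reproducibility**: all randomness (including the C++ kernels, via
  R's `unif_rand`) flows from the single `seed` of the configuration, so
  runs are bit-reproducible.
* **Initial configurations**: an FCC (or, where the site count fits
  better, simple-cubic) lattice directly at the target box whenever the
  orientation-independent core allows it, with random orientations and a
  short overlap-relaxation phase; otherwise (tetrahedra, extreme site
  geometries) a dilute lattice beyond the full interaction range is
  compressed stepwise with moves that never increase a particle's overlap
  count.  The construction fails loudly with the reached packing fraction
  if the target is not attainable.

**Cell lists are deliberately not implemented.**  With the reaction-field
cutoff at $r_c = L/2$, a cell decomposition admits only two cells per
dimension, so neighbor enumeration degenerates to the all-pairs loop
anyway; the $O(N)$ per-move scan in C++ is the production path.

## Analysis

* **Site-site correlation functions**: distance histograms between any
  site pairs (`"O-O"`, `"O-P"`, `"P-N"`, ... for the primitive model;
  `"C-C"` centers otherwise) up to $L/2$, normalised by the ideal-gas
  shell count with partner density $(N-1)/V$ for like pairs; per-bin
  standard errors from block averages.
* **First minimum**: `find_first_minimum()` locates the first local
  minimum after the first maximum of a lightly smoothed $g(r)$.
* **Coordination number**: $N_C = 4\pi\rho\int_0^{R_{\min}} g(r)\, r^2 dr$
  by trapezoidal quadrature, closing the integral exactly at $R_{\min}$.
  A direct neighbor-counting oracle agrees to within 2% in the tests.
* **Energy table**: `energy_table()` reports per-particle reduced energies
  split into square-well and dipolar parts with block-average errors, both
  in thermal units ($\beta E/N$) and -- for square-well models -- in units
  of the well depth ($\beta E / N \beta\epsilon_{HB}$), the scaling in
  which the published liquid-state values of this model family are quoted.

## Problem sizes and limitations

* Desk scale is $N = 216$ at $\eta = 0.35$.  A sweep costs about 1.5 ms
  (no dipole) to 2.8 ms (dipolar) on one core; the published primitive
  model state point ($\beta\epsilon_{HB} = 8$) equilibrates slowly --
  $5\times 10^4$ sweeps leave a slight residual drift, which the monitor
  reports honestly.
* Dipolar runs at $\lambda = 7$ equilibrate more slowly still; energies
  from desk-scale runs are upper bounds that keep drifting downward.
  Treat any run that warns about non-stationarity accordingly.
* Dense hard-tetrahedron state points ($\eta \ge 0.35$) are SAT-dominated
  and far beyond desk scale with this all-pairs implementation; they ship
  as presets (`ht-eta035`, `ht-eta0425`, `ht-eta0425-l1-screened`) for a
  long suite.  Desk-scale tetrahedron runs up to $\eta \approx 0.20$
  construct in seconds.
* The first-shell coordination number of the primitive model depends
  strongly on the like-site core size (see above); with the packable
  default it overestimates the tetrahedral-network value.
* At $\lambda = 3$ the screened dipole leaves $g_{OO}$ *almost* unchanged:
  in a 40k-sweep desk-scale comparison ($N = 125$, $\eta = 0.35$,
  $\beta\epsilon = 8$) about 97% of bins agree within combined errors,
  but a small systematic shift ($\Delta g \approx 0.05$, several standard
  errors, sign-consistent over adjacent bins) survives just outside the
  bonding shell near $r \approx 1.8$.  With this package's site
  parameters the "indistinguishable" idealisation is therefore close but
  not exact.

## Reproducing the headline numbers

```{r}
library(hardwater)

# the published primitive-model state point, no dipole
cfg <- run_config(model = "pm", eta = 0.35, n = 216, beta_eps = 8,
                  dipole_mode = "none", n_equil = 50000, n_prod = 50000,
                  sample_every = 25, pairs = "O-O", seed = 1)
run <- run_simulation(cfg, verbose = TRUE)
print(run)                         # beta E/N, well-depth units, N_C
energy_table(list(pm_none = run))

# screened dipole at lambda = 7, continuing from the equilibrated state
cfg7 <- run_config(model = "pm", eta = 0.35, n = 216, beta_eps = 8,
                   lambda = 7, dipole_mode = "screened",
                   n_equil = 40000, n_prod = 40000, sample_every = 25,
                   pairs = "O-O", seed = 2)
run7 <- run_simulation(cfg7, init = run$final, verbose = TRUE)
```

The same protocol, with one run per target, is what
`scripts/acceptance.R` executes.
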