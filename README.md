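# hardwater

NVT Metropolis Monte Carlo for simple dipolar water-like fluids built from
hard cores and short-range association:

* the **primitive model** of water: a hard sphere of diameter σ carrying
  two surface "proton" sites and one off-center acceptor site; hydrogen
  bonds are square wells between unlike sites, doubly-donated bonds are
  blocked by small like-site hard cores;
* **dipolar hard regular tetrahedra** inscribed in the σ sphere, with
  exact separating-axis overlap tests.

Either model can carry a point dipole (realised as two opposite charges a
distance `l0` apart) in one of three modes — `none`, `full`, or
`screened`, where a cubic smoothstep switch removes the short-range part
of the dipole–dipole energy while keeping the long-range part — with
reaction-field electrostatics beyond a half-box cutoff.  The scientific
question this setup probes: how much of the structure of a water-like
liquid is fixed by hard-core shape plus short-range bonding alone, and how
little the long-range dipolar tail adds to it.

Everything is driven by R with C++ (Rcpp) kernels; a single integer seed
makes entire trajectories bit-reproducible.

## Worked example

A hard-sphere fluid at liquid packing, N = 216, η = 0.35 — equilibrate,
sample g(r), locate the first minimum and integrate the coordination
number:

```r
library(hardwater)

cfg <- run_config(model = "hs", eta = 0.35, n = 216,
                  n_equil = 2000, n_prod = 10000, sample_every = 10,
                  pairs = "C-C", seed = 7)
run <- run_simulation(cfg, verbose = TRUE)
print(run)
```

Real output (this exact script, seed 7):

```
[hs] N=216 eta=0.350 box=6.862 lambda=0 mode=none
  equilibration: 2000 sweeps, acc 0.41, d_trans 0.153, d_rot 0.447
  production: 10000 sweeps, acc 0.41, beta E/N = 0.0000 +- 0.0000, N_C = 11.519
<mc_run> hs N=216 eta=0.350 mode=none lambda=0
  beta E/N = 0.0000 +- 0.0000 (sw 0.0000, dd 0.0000)
  R_min = 1.630, N_C = 11.519
  acceptance 0.409, 11.0 s elapsed
```

About 12 neighbors in the first shell — the close-packed-like shell of a
dense simple liquid.  The same machinery on the hydrogen-bonding primitive
model at the same packing (βε = 8, no dipole):

```r
cfg <- run_config(model = "pm", eta = 0.35, n = 216, beta_eps = 8,
                  dipole_mode = "none", n_equil = 50000, n_prod = 50000,
                  sample_every = 25, pairs = "O-O", seed = 1)
run <- run_simulation(cfg, verbose = TRUE)
```

```
[pm] N=216 eta=0.350 box=6.862 lambda=0 mode=none
  equilibration: 50000 sweeps, acc 0.35, d_trans 0.017, d_rot 0.049
  production: 50000 sweeps, acc 0.32, beta E/N = -13.1329 +- 0.0664, N_C = 6.056
```

βE/N = −13.13 thermal units is −1.64 in well-depth units, i.e. about 3.3
hydrogen bonds per molecule: association restructures the liquid
completely even though both systems are at the same packing fraction.

Dipolar runs continue from the equilibrated association structure:

```r
cfg7 <- run_config(model = "pm", eta = 0.35, n = 216, beta_eps = 8,
                   lambda = 7, dipole_mode = "screened",
                   n_equil = 40000, n_prod = 40000, sample_every = 25,
                   pairs = "O-O", seed = 2)
run7 <- run_simulation(cfg7, init = run$final, verbose = TRUE)
```

The command-line layer wraps the same calls
(`inst/cli/hardwater run --config <file> --out-dir <dir>`, plus `audit`,
`analyze`, `resume` and `fixtures` subcommands), and shipped presets
(`preset_names()`) encode the standard state points.

## Desk-scale results and honest caveats

`scripts/acceptance.R --seed 1 --out acceptance.json` reproduces the
headline numbers at desk scale (N = 216; ~7 minutes on one core).
Closed-form values — the tetrahedron shape factor 2.2346 and the reduced
dipole strengths λ ≈ 3 (gas-phase moment) and λ ≈ 7.6 (liquid moment) —
are exact.  Stochastic values from the run above: the non-dipolar
primitive-model energy lands within a few percent of the published
−1.727 (well-depth units) and the hard-sphere coordination number within
5% of 12.

Two documented discrepancies remain (see `vignettes/hardwater-methods.Rmd`
for the full analysis):

* the package's like-site cores must be small (0.45 σ) for the liquid to
  be constructible at η = 0.35 at all; the bonding energy is insensitive
  to this, but the first shell then contains non-bonded neighbors beside
  the ~3.5 bonded ones, so the primitive-model coordination number comes
  out near 6 instead of ≈ 4;
* dipolar energies at λ = 7 equilibrate very slowly at desk scale and the
  reported values are still drifting downward (the equilibration monitor
  warns about this rather than hiding it).

## Testing

```r
testthat::test_dir("tests/testthat", package = "hardwater",
                   load_package = "installed")
```

The suite checks the geometry kernels against independent oracles
(point-containment sampling for the separating-axis test, quadrature and
weighted-sampling oracles for energies and occupation ratios), the
incremental energy bookkeeping against full O(N²) audits, estimator
normalisations against closed forms, and the acceptance criteria above.

The acceptance tests (`test-acceptance.R`) deliberately keep the
published targets even where this implementation is known to differ, so
a handful of expectations **fail by design**: the λ = 7 dipolar energies
(still drifting at desk scale), the primitive-model coordination number
(≈ 6 with the packable like-site cores, see above), and the strict 99%
bin-agreement criterion for the λ = 3 g_OO comparison (97% observed).
All module tests pass.
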