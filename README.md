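# ramadyn

Conformational-state and relaxation analysis of polypeptide backbone-dihedral
trajectories, built for anionic homo-polypeptides (poly-aspartic and
poly-glutamic acid) but applicable to any per-residue (Φ, Ψ) time series.

Molecular-dynamics studies of these polyelectrolytes keep asking the same
four questions: what fraction of residue-frames sits in each Ramachandran
basin (α_R, α_L, 3₁₀, PPII, β); do same-state residues cluster into
contiguous *equiconformational sequences* long enough to count as secondary
structure; how do chain size and counterion bridging co-vary with
conformational content; and on what time scales do the chain and its
torsions decorrelate. `ramadyn` answers them as a composable, tested
pipeline, with a synthetic-trajectory generator so every stage can be
validated without running MD.

## What it computes

* **Classification** — validated region sets (axis-aligned boxes on the
  (Φ, Ψ) torus, partition checked on a 1° grid), per-residue-frame state
  labels, 2-D dihedral densities, and population fractions with
  block-averaged errors. Fractions via direct classification and via density
  integration agree exactly when box bounds lie on bin edges.
* **Sequence statistics** — counts R_ij of maximal same-state runs of length
  i in frame j, and the fraction of monomers in runs of at least one helical
  turn,

  F = (1/t) Σ_j Σ_{i≥4} i·R_ij / n,

  with n = 30 analysed monomers for a 32-residue chain (termini excluded).
* **Chain geometry** — radius of gyration, end-to-end distance, and
  counterion bridges (an ion within a species cutoff — Na⁺ 0.32 nm,
  K⁺ 0.36 nm — of carboxylate oxygens of two residues at least 3 apart),
  with the time-averaged bridged-carboxyl fraction.
* **Relaxation** — FFT-based autocorrelation functions (mean-subtracted for
  scalars; unit-vector embedding for angles, exactly circular) and bounded
  Levenberg–Marquardt fits of the stretched exponential
  f(t) = A·exp(−(t/τ)^β), reporting τ, β, A and the mean relaxation time
  (τ/β)·Γ(1/β).
* **Synthetic data** — residue-wise Markov state dynamics with prescribed
  lifetimes (exact stationary law attached), truncated-Gaussian dihedral
  emission closed under classification, state-dependent bead chains, exact
  bridge fixtures, and noisy KWW series.
* **Reporting** — comparison against packaged experimental reference
  fractions, per-monomer conformation timelines, and a deterministic
  `run_pipeline()` that writes JSON + TSV artifacts.

## Worked example

Simulate a 32-residue chain with PGA-like conformational content (stretched
states dominant, minor α_R), then run the full analysis:

```r
library(ramadyn)
regions <- builtin_region_set("standard_literature")

states_def <- data.frame(
  label       = c("alphaR", "PPII", "beta"),
  pi          = c(0.12, 0.44, 0.44),
  lifetime_ns = c(1, 2, 2)
)
st   <- markov_state_trajectory(5000, states_def, n_residues = 30,
                                dt = 0.1, seed = 42)
traj <- emit_dihedrals(st, regions, jitter = 12, seed = 43)

report <- run_pipeline(traj, analysis_config(seed = 42), molecule = "PGA")
report
#> <ramadyn_report>
#>   state fractions:
#>     alphaR       0.0991 (sd 0.0075)
#>     alphaL       0.0000 (sd 0.0000)
#>     beta         0.4594 (sd 0.0121)
#>     PPII         0.4415 (sd 0.0119)
#>     other        0.0000 (sd 0.0000)
#>   alphaR sequences (runs >= 4): fraction 0.0003
```

The fractions recover the generator's exact stationary law (attached as
`attr(st, "stationary")`) within the block errors. The α_R-sequence fraction
is near zero: with ~10% α_R occupancy and 1 ns lifetimes, four contiguous
helical residues are rare — exactly the behaviour the F statistic is built
to expose, since a plain 10% basin fraction says nothing about helicity.
The report also carries the comparison against packaged experimental
fractions, e.g. computed PPII 0.441 vs the PGA reference 0.40 (deviation
0.042), and the α_R bound (< 0.20) evaluates as satisfied.

Individual stages compose with the pipe as well:

```r
traj |>
  discard_equilibration(0.1) |>
  classify_trajectory(regions) |>
  state_fractions(n_blocks = 5)

acf <- synthetic_acf(A = 0.9, tau = 5, beta = 0.6, noise_sd = 0.01,
                     n_lags = 300, seed = 1)
fit_stretched_exponential(acf) |> glance()
```

Plots: `plot_ramachandran()`, `plot_timeline()`, `autoplot()` on ACF series,
fits and fraction tables.

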