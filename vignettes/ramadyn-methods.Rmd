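---
title: "Conformational-state and relaxation analysis of polypeptide trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational-state and relaxation analysis of polypeptide trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramadyn)
```

## The problem

Anionic homo-polypeptides such as poly(aspartic acid) and poly(glutamic acid)
are standard model polyelectrolytes. Their local structure is summarised by
the backbone torsions $(\phi, \psi)$ of each residue: the Ramachandran plane
partitions into conformational basins (right- and left-handed $\alpha$-helix,
$3_{10}$-helix, polyproline-II helix, $\beta$-sheet), and the questions a
trajectory analysis answers are (i) what fraction of residue-frames falls in
each basin, (ii) whether same-state residues cluster into contiguous
*equiconformational sequences* (a precondition for genuine secondary
structure), (iii) how chain size relates to conformational content and to
counterion bridging, and (iv) on what time scales the chain and its torsions
decorrelate. `ramadyn` implements this pipeline for per-residue dihedral
time series, with a synthetic-trajectory generator that makes every stage
testable without molecular dynamics.

## Region sets and classification

A region set is a list of angular boxes on the $(\phi,\psi)$ torus, each
owned by a state label; everything outside every box is `other`. The shipped
`standard_literature` set encodes the published basin bounds for Asp/Glu
residues:

| state | $\phi$ (deg) | $\psi$ (deg) |
|---|---|---|
| $\alpha_R$ | $[-90, -30]$ | $[-90, 0]$ |
| $\alpha_L$ | $[30, 90]$ | $[0, 90]$ |
| $\beta$ | $[-180, -104)$ | $[104, 180]$ |
| PPII | $[-104, -46]$ | $[116, 174]$ |

All printed bounds are closed except the $\beta$ upper $\phi$ bound. The
$\beta$ $\psi$ clause is printed in inverted order in the source literature
("$180 \le \Psi \le 104$"); we read it as $[104, 180]$, the only
self-consistent interpretation.

Three further sets (`charmm_integration`, `amber99_integration`,
`opls_integration`) reproduce the integration-area topology used when
populations are read off force-field Ramachandran maps: area 0 ($\alpha_R$),
area 1 (the surrounding screw region, labelled $3_{10}$ for CHARMM-like maps
where that basin separates, `add_screw` otherwise), area 2 (PPII), area 3
($\beta$), area 4 (the positive-$\phi$ half, mostly $\alpha_L$). Area-1
bounds are not published numerically anywhere; we ship them as the
complement of the $\alpha_R$ box inside an enclosing screw box
$\phi \in [-160, -30]$, $\psi \in [-90, 50]$, flag them `approximate`, and
let any bound be overridden through the YAML serialisation
(`write_region_set()` / `read_region_set()`).

Numerical conventions that matter:

* all comparisons happen after wrapping angles to $(-180, 180]$;
  classification is invariant under $\pm 360^\circ k$;
* boxes are lower-closed/upper-open unless the printed bound is closed;
  every constructed set is validated on a $1^\circ$ torus grid (129,600
  points) — exactly one label per point, counting `other`;
* the torus seam: $\phi = 180 \equiv -180$ belongs to the printed closed
  $\beta$ box, so the positive-$\phi$ integration area is open at
  $\phi = 180$;
* the sparsely populated $\zeta$ and $\gamma'$ basins (near $(-135, 60)$ and
  $(-80, 80)$) are available via `include_intermediate = TRUE`, clipped so
  the partition stays overlap-free; they are off by default because
  populations there are usually folded into the neighbouring areas.

Terminal residues have no $\phi$ (first) or $\psi$ (last); both termini are
excluded from all statistics, so a 32-residue chain contributes 30 analysed
monomers.

Fractions come with block errors: the frames are cut into `n_blocks`
(default 5) contiguous equal-length blocks and the error is the standard
deviation of per-block fractions. Five blocks is a compromise between bias
(few blocks) and block-length shortness relative to the slowest relaxation
times; it is configurable.

Two routes to the same populations are provided and tested against each
other: direct per-sample classification (`state_fractions()`), and
integration of a normalised 2-D histogram over the region boxes
(`ramachandran_density()` + `integrate_regions()`). Bins are assigned by
bin-centre membership; when every box bound lies on a bin edge (all printed
bounds are even, so 2-degree bins suffice) the two routes agree exactly.

## Equiconformational sequences

Within one frame, a maximal run of $i$ contiguous residues sharing the
target state contributes one count $R_{ij}$ at length $i$. The fraction of
monomers in runs of at least $m$ residues, averaged over $t$ frames, is

$$F = \frac{1}{t} \sum_j \sum_{i \ge m} \frac{i\, R_{ij}}{n},$$

with $n$ the number of analysed monomers (30 here). The default threshold
$m = 4$ encodes "at least one helical turn": an $\alpha$-helix has 3.6
residues per turn, so a genuine helical stretch needs more than three
monomers. The same machinery serves $\beta$-sequence analysis (same $m$).
Runs are frame-wise and non-wrapping (the chain is linear); no temporal
persistence is required for a run to count. With $m = 1$, $F$ reduces
exactly to the plain state fraction — a useful invariant that the tests
assert, together with conservation ($\sum_i i R_{ij}$ equals the per-frame
state count) and equality with a brute-force re-scan of the label matrix.

## Chain geometry and counterion bridges

`radius_of_gyration()` is the mass-weighted RMS distance from the centre of
mass, per frame; `end_to_end_distance()` is the Euclidean distance between
the first and last alpha-carbon (no minimum image — the chain is whole).

An ion *bridges* residues $a$ and $b$ when it lies within a species-specific
cutoff of at least one carboxylate oxygen of each, with $|a-b| \ge 3$. The
cutoffs (Na$^+$–O 0.32 nm, K$^+$–O 0.36 nm) are typical first minima of
ion–oxygen radial distribution functions; the separation rule
operationalises "distant" groups as opposed to nearest-neighbour contacts.
Both are configurable in `bridge_spec()`, and any result that depends on
them should be reported with the values attached (the pipeline stamps its
config fingerprint into every report). Minimum-image distances are used when
an orthorhombic box is present; triclinic boxes are rejected. The bridge
fraction is the time-averaged share of carboxyl-bearing residues in at least
one bridge, with a block-SD error.

## Autocorrelation and stretched-exponential relaxation

Two estimators, both averaged over all time origins and limited to half the
series length:

* **scalar (distance) ACF** — mean-subtracted and variance-normalised,
  $C(k) = \frac{(N)\sum_t \delta d_t \delta d_{t+k}}{(N-k)\sum_t \delta d_t^2}$;
* **dihedral ACF** — each angle embedded as the unit vector
  $u = (\cos\theta, \sin\theta)$, $C(k) = \langle u(t)\cdot u(t+k)\rangle$,
  averaged over origins first, then residues with equal weight. The
  embedding makes the estimator exactly invariant to $\pm 360^\circ$ jumps,
  and $C(0) = 1$ holds identically.

Both use an FFT fast path; an $O(N^2)$ lag-sum oracle in the test suite
pins them to $10^{-10}$.

Relaxation times come from a bounded Levenberg–Marquardt fit of the
Kohlrausch–Williams–Watts form

$$f(t) = A \exp\!\big(-(t/\tau)^\beta\big),$$

where $\beta$ is the stretching exponent (width of the relaxation-time
distribution; $\beta = 1$ is simple-exponential), $\tau$ the relaxation
time, and $A$ the amplitude of the decaying contribution. The derived mean
relaxation time is $\tau_{\mathrm{mean}} = (\tau/\beta)\,\Gamma(1/\beta)$;
both $\tau$ (the fit parameter) and $\tau_{\mathrm{mean}}$ are reported,
with $\tau$ the headline value. Fitting choices:

* window: from the first positive lag (lags below the sampling step carry no
  information) to the first crossing of $C = 0.02$ or half the series,
  whichever comes first, extended so the window holds at least 8 points;
* bounds $\tau > 0$, $\beta \in (0.05, 2]$, $A \in (0.05, 1.5]$; two starts,
  $(A, \tau, \beta) = (1, t_{\mathrm{mid}}, 1)$ and
  $(1, t_{\mathrm{mid}}, 0.5)$, keeping the lower residual sum of squares;
* `baseline = "tail"` (used for dihedral ACFs in the pipeline): a
  basin-pinned chain's orientational ACF decays to $|\langle u\rangle|^2 > 0$
  rather than to zero; this mode estimates the plateau as the mean of the
  last quarter of lags, fits the renormalised decaying component
  $(C - c_\infty)/(1 - c_\infty)$, and records $c_\infty$. The default is
  `"none"`.

A caution the recovery experiments make quantitative: relaxation times at or
below the sampling step are poorly determined. Over a grid
$\tau \in \{1, 10, 100\}$ lag units $\times$ $\beta \in \{0.5, 0.8, 1.0\}$
at noise $\sigma = 0.01$, the grid-wide median relative error of $\tau$ and
$\beta$ is a few percent, but the $\tau = 1$ cells alone sit near 35% — with
three free parameters and only $\sim$4 informative points above the noise
floor, that error is a statistical (Cramér–Rao) limit, not an optimiser
failure; extra starting points do not change it. Fitted times of the order
of the sampling step should therefore be read as upper-bound statements, the
same reason dynamics studies only report relaxation times longer than their
sampling step.

## The synthetic-trajectory generator

The generator targets the *statistical structure* the analyses assume, with
no physical realism (no excluded volume, no electrostatics):

* **states** (`markov_state_trajectory()`): each residue is an independent
  discrete-time Markov chain. The stay probability of state $s$ is
  $q_s = e^{-\Delta t / \lambda_s}$ (lifetime $\lambda_s$), and the leaving
  mass is split over the other states proportionally to their target
  weights. This proportional-attraction construction approximates the
  requested stationary law; the matrix's *exact* eigen-solved law is
  attached to every generated trajectory, and all recovery tests compare
  against that, not the targets;
* **dihedrals** (`emit_dihedrals()`): truncated-Gaussian emission about the
  state's box centroid guarantees classification closure —
  `classify(emit(s)) = s` for every shipped region set;
* **coordinates** (`synthetic_chain()`): a virtual-bond bead chain whose
  bond length and bend angle depend on the state (stretched states give
  straighter, longer chains), providing a test bed for the correlation
  between chain size and conformational content;
* **bridges** (`bridge_fixture()`): exact programmed bridge sets — one ion
  0.1 nm from one oxygen of each member of a requested pair, every other ion
  at least 0.6 nm from every oxygen, with optional per-frame on/off
  modulation;
* **ACFs** (`synthetic_acf()`): the KWW form plus Gaussian noise.

All generators are seed-deterministic and restore the caller's RNG state.

What passing tests on these inputs do **not** show: real trajectories have
correlated residues (cooperative helix formation), emission distributions
that are not box-truncated Gaussians, basin populations that drift with slow
chain-scale dynamics, and bridge geometries far messier than two displaced
oxygens. The generator validates the *estimators*, not force fields.

## Default parameters

| parameter | default | unit | why |
|---|---|---|---|
| equilibration fraction | 0.1 | — | common discard for microsecond-scale runs (first tenth) |
| analysed monomers | chain − 2 | — | termini lack one torsion each |
| min run length | 4 | residues | one helical turn (3.6 residues/turn) |
| blocks for SD | 5 | — | bias/variance compromise, configurable |
| Na$^+$–O cutoff | 0.32 | nm | first RDF minimum, typical |
| K$^+$–O cutoff | 0.36 | nm | first RDF minimum, typical |
| min bridge separation | 3 | residues | excludes nearest-neighbour contacts |
| ACF noise floor | 0.02 | — | window end for the KWW fit |
| generator dt | 0.1 | ns | typical trajectory sampling step |

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline on
synthetic studies of $10^4$–$10^5$ frames $\times$ 30 monomers (a
$10^4$-frame run at 0.1 ns sampling emulates a 1 μs trajectory), with
PGA-like stationary fractions (stretched states $\approx 0.44$ each,
$\alpha_R \approx 0.12$) and 1–2 ns lifetimes; chain geometry uses 4,000
frames and the KWW recovery grid 450 fits of 500-lag series. These sizes
give block-SD errors well below the effect sizes being checked.

## Known limitations

* Coordinate input is PDB (single- or multi-model) only; dihedral tables
  (CSV/TSV) are the primary input format.
* No kernel-density smoothing or automatic basin detection on Ramachandran
  maps; regions are axis-aligned boxes.
* No hydrogen-bond (DSSP-style) secondary-structure assignment — state
  identity is purely dihedral-region membership.
* No multi-exponential or inverse-Laplace decomposition of ACFs, and no
  bootstrap errors on fitted parameters beyond the residual RMS.
* Bridge analysis reports contact-defined bridges; no residence-time
  kinetics or condensation analysis.
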