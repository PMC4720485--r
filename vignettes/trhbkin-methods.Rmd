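---
title: "Predicting O2 kinetics of truncated hemoglobins: model and methods"
author: "trhbkin"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The kinetic model

`trhbkin` predicts the O₂ association rate (k_on), dissociation rate
(k_off) and affinity (p50) of truncated hemoglobins from three
structure-derived quantities: the free-energy landscape of ligand
migration through the protein's tunnel/cavity system, the hydrogen-bond
network holding the distal water in place, and the stabilization of the
bound O₂ by the distal residues.

## Association

Association is modelled as a two-step mechanism. First, the distal water
blocking the sixth iron coordination site must leave; we treat this as a
fast pre-equilibrium with constant

$$K_{H_2O} = \exp(-n_{HB}\,\Delta G_{HB}/RT), \qquad
  \Delta G_{HB} = 2.95\ \mathrm{kcal/mol\ per\ bond},$$

where $n_{HB}$ is the number of hydrogen bonds the protein donates to
that water. Second, the ligand migrates from bulk solvent through one of
three topological tunnels (LT, STG8, E7G). Each tunnel's 1D free-energy
profile — an alternating sequence of docking wells and barriers referenced
to bulk — defines a linear chain of states with Eyring hop rates
$k = (k_BT/h)\,e^{-\Delta G^\ddagger/RT}$, the activation energy measured
from the originating well to the intervening barrier. A well adjacent to
bulk with no explicit barrier gets a diffusion-limited entry
($\Delta G^\ddagger = 0$); a profile ending in a well gets a barrierless
final bond-formation hop, reflecting the very small spin-transition
barrier of Fe–O₂ bond formation, which is essentially constant across the
family (all members share the proximal histidine) and is therefore left
out of the per-protein comparison.

The tunnel's migration probability is the splitting probability of this
birth–death chain — the chance that a ligand in the outermost well reaches
the heme before escaping to solvent:

$$k_t = \left[\sum_{i=0}^{n}\ \prod_{j=1}^{i} \frac{k_{b,j}}{k_{f,j}}\right]^{-1},$$

computed in log space for stability. With a single interior well this is
exactly $k_f/(k_f+k_b)$. The closed form is checked in the test suite
against an independent master-equation linear solve. Deep wells enter the
physics through the slowed back-escape: a 3 kcal/mol well concentrates
the ligand by $e^{3/RT}\approx 153$ at 300 K (`well_enhancement()`
exposes this factor as a diagnostic). Parallel tunnels add,
$k_{tunnels} = k_{LT}+k_{STG8}+k_{E7G}$; since each term is a probability
bounded by 1, a second open tunnel at most doubles the rate — extra
tunnels are largely redundant, which matches the observed insensitivity
of k_on to single tunnel closures.

The association rate is
$k_{on} = (k_BT/h)\cdot k_{tunnels}\cdot K_{H_2O}\cdot c^{-1}$.
The Eyring product alone carries units of s⁻¹; the conversion to a
bimolecular constant requires a concentration scale. We close the
dimension with an explicit configurable factor (`conc_factor`, default
1 M⁻¹, i.e. a 1 M standard state); the default reproduces the worked
cyanobacterial example at its reported precision with physically
plausible tunnel and water inputs, and the factor is reported in all
outputs so any recalibration is transparent.

For hexacoordinated proteins (His or Lys at position E10 can occupy the
sixth coordination site) the model assumes the 5c state; the prediction
is flagged as an upper bound rather than corrected, because the 5c/6c
equilibrium constant is not available from sequence alone.

## Dissociation and affinity

Dissociation is controlled by breaking the distal stabilization of the
bound O₂. We express a protein's stabilization as the excess
$\Delta\Delta E_{O_2}$ over an isolated imidazole-bound heme
(22 kcal/mol), whose dissociation rate anchors the scale at
$k_{off}^{free} = 10^4\ \mathrm{s^{-1}}$:

$$k_{off} = k_{off}^{free}\, e^{-\Delta\Delta E_{O_2}/RT}.$$

The relative (excess) form cancels the large systematic errors of
DFT-level binding energies (spin-gap overestimation, 0 K optimization,
functional dependence) that make absolute binding energies unusable as
activation energies. Raw binding energies (negative = favourable) are
converted by `ddE_from_binding_energy()`: $|\Delta E_{O_2}| - 22$.
Affinity follows as $p50 = k_{off}/(k_{on}\cdot s)$ with
$s = 1.82\times10^{-6}$ M/mmHg; at p = p50 the fractional saturation is
exactly ½.

## Classification thresholds

All thresholds live in `kinetic_constants()` and are configurable:

| parameter | default | meaning |
|---|---|---|
| `T` | 300 K | temperature of all Boltzmann factors |
| `dG_per_hbond` | 2.95 kcal/mol | water stabilization per protein H-bond |
| `dE_heme` | 22 kcal/mol | free-heme O₂ binding reference |
| `koff_freeheme` | 10⁴ s⁻¹ | dissociation of the free-heme reference |
| `conc_factor` | 1 M⁻¹ | standard-state closure of k_on |
| `o2_solubility` | 1.82·10⁻⁶ M/mmHg | converts k_off/k_on to p50 |
| `open_max` / `closed_min` | 3 / 10 kcal/mol | tunnel class bounds on the max barrier |
| `p50_low` / `p50_high` | 1 / 5 mmHg | affinity class bounds |
| `koff_fast` / `koff_low` | 100 / 1 s⁻¹ | dissociation class bounds |

Barriers of a few kcal/mol are crossed readily at room temperature
(open); barriers ≥ 10 kcal/mol block migration on binding-relevant
timescales (closed). The k_off bands separate proteins whose oxy complex
lives for milliseconds (fast), seconds (moderate) or much longer (low) —
the low band combined with tunnel openness drives the rough functional
typing (`functional_type()`): an open polar E7 gate plus a tight oxy
complex suggests catalase/peroxidase-like chemistry and takes precedence
over the multi-tunnel NO/O₂ type, because the E7 route is the natural
entry for polar or charged substrates.

# Grid analysis

Grids are OpenDX scalar fields (value order on disk: z fastest, the
OpenDX convention); energies above a cap (default 30 kcal/mol) may be
mapped to +Inf as steric exclusion. Bulk referencing subtracts a constant
so the mean over the finite voxels of the outer shell (default width 2
voxels) is exactly zero; the operation is idempotent and all profile
values are therefore invariant to constant grid shifts.

Path extraction is exact minimax over 26-connected voxel paths: the
returned path minimizes the maximum node energy (a bottleneck Dijkstra),
which is the discrete lowest saddle a ligand must cross. Ties are broken
deterministically inside the bottleneck-feasible subgraph by the smallest
energy path-integral — computed with node energies shifted to be
non-negative there, since Dijkstra requires non-negative weights and
wells are negative — then by shortest arc length, then by smallest voxel
index. Diagonal moves carry their Euclidean length.

Profiles are read off the energy-vs-arc-length curve after a centered
moving average over a 1 Å window; interior extrema are kept if their
topographic prominence reaches 0.25 kcal/mol, and strict well/barrier
alternation is enforced by merging the weaker of two same-kind
neighbours. A monotonic curve yields an empty profile. The prominence
default suppresses thermal-noise ripples (≈0.1 kcal/mol) while keeping
every physically meaningful docking site; both knobs are exposed.

Portal voxels (tunnel entry/exit) are explicit inputs: there is no
robust structure-free rule for where a tunnel meets the solvent, so the
caller (or the fixture generator, which knows its own geometry) supplies
them.

# Synthetic fixtures: what they emulate and what they do not

`make_grid()` plants tunnels of specified well/barrier sequences into a
high-energy background (25 kcal/mol — above the closed-tunnel band,
below the steric cap) with a zero-energy bulk shell, then adds Gaussian
noise and re-references the shell mean to zero. Each stationary point is
held on a flat plateau (default 2 Å) wider than the smoothing window, so
detection is unbiased; channels in the bundled multi-tunnel fixture are
kept ≥ 2 voxels apart, because 26-adjacent channels would let the minimax
path hop between tunnels and bypass a planted barrier (the same physics
that makes real tunnels converging at the distal pocket share a single
entry bottleneck). At the test noise level (σ = 0.1 kcal/mol) recovered
stationary values are max-statistics over ~3 smoothed voxels, giving a
small outward bias (worst observed error ≈ 0.19 kcal/mol over hundreds
of seeds, inside the ±0.2 acceptance band).

`make_rate_table()` emulates experimental-vs-calculated validation
tables. Inputs are drawn independently: hydrogen-bond counts from
probabilities (0.25, 0.5, 0.25) for 0–2 bonds, and the dominant tunnel's
net forward barrier from a normal distribution (mean 4.25 kcal/mol). The
"calculated" columns follow the package's own model exactly;
"experimental" columns add Gaussian noise in log10 space. Noise and
spread are derived analytically from the target coefficients of
determination: for $y = x + \varepsilon$,
$E[R^2] = \mathrm{Var}(x)/(\mathrm{Var}(x)+\sigma^2)$, and with
independent tunnel (variance $a$) and water (variance $b$) contributions
the tunnel-only predictor satisfies $R^2_{tun}/R^2_{kon} = a/(a+b)$.
The defaults target $R^2 = 0.78$ (k_on), $0.79$ (k_off) and $0.47$
(tunnel-only) — the benchmark correlations the full model and its
water-free ablation are expected to reach — so an end-to-end refit of
the generated tables is a genuine two-sided check of the model's
algebra, not of the generator alone. What these fixtures do **not**
emulate: correlated errors between proteins sharing a scaffold,
heteroscedastic measurement noise, hexacoordination biases, or any
systematic model error — so passing validation shows internal
consistency at realistic noise, not accuracy on new laboratory data.

The worked cyanobacterial example ships as a labelled synthetic
reconstruction (`inst/extdata/synthetic_validation_*.tsv`): the model's
published operating point (k_on = 2.0·10⁷ M⁻¹ s⁻¹ for a
hexacoordinated trHb) back-propagated to plausible inputs — two water
hydrogen bonds and a single open short tunnel with a −2.0 kcal/mol well
behind a +1.6 kcal/mol exit barrier.

# Numerical choices and problem sizes

* Splitting probabilities accumulate rate-ratio products as log-sums
  (log-sum-exp), exact to machine precision on arbitrarily steep
  landscapes. The master-equation cross-check draws hop-rate ratios up to
  10³ (barrier asymmetries to ≈4 kcal/mol) because beyond that the
  double-precision linear solve — not the closed form — loses the 10⁻¹⁰
  comparison; the closed form has no such limit.
* Minimax optimality is verified against an exhaustive
  threshold-connectivity search on 100 random 5×5×5 grids and full
  path enumeration on 2×2×3 grids; test grids are kept ≤ 26×9×9 so the
  pure-R Dijkstra stays in milliseconds per grid.
* Validation refits use n = 400 synthetic proteins, where the sampling
  standard deviation of R² (≈ $2R(1-R^2)/\sqrt n$) is ~0.02–0.04; test
  tolerances (±0.08 on 0.78/0.79, ±0.12 on 0.47) were fixed from that
  formula in advance.
* All generators take an explicit seed and restore the caller's RNG
  state, so fixtures are bitwise-reproducible.

# Known limitations

* The model assigns identical kinetics to every sequence sharing the same
  key-position residues; real rates are modulated by second-shell effects
  the model ignores — predictions are order-of-magnitude tools for
  family-scale comparison, not replacements for measurement.
* k_on for hexacoordinated proteins is an upper bound only; the 5c/6c
  equilibrium is not modelled quantitatively.
* The standard-state closure of k_on is a single global constant; any
  genuinely diffusion-limited protein would need a different treatment.
* Functional typing is a rough rule table over predicted classes; it
  partitions proteins but does not assert function.
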