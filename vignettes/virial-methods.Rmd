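---
title: "Methods: second virial coefficients of rigid biomolecules from FFT energy scans"
author: "virialscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: second virial coefficients of rigid biomolecules from FFT energy scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virialscan)
```

## The physical model

Weak, nonspecific protein–protein interactions are summarized by the
second osmotic virial coefficient $A_2$: the first-order correction to
solution ideality, negative when pairwise self-association is favorable
and positive when net repulsion dominates. For two different species (for
example a folded domain and a short interaction-motif peptide) the
analogous cross coefficient $A_{23}$ captures all pairwise contacts
between them, including low-affinity, multi-configuration modes that
affinity assays do not see.

For two rigid bodies the virial coefficient is a configurational integral
of the Mayer function over all relative placements — translations
$\mathbf{R}$ and orientations $\Omega$:

$$
B \;=\; -\tfrac12 \int \big\langle e^{-U(\mathbf{R},\Omega)/k_BT} - 1
\big\rangle_\Omega \, d\mathbf{R},
$$

reported in mass units as $A = N_A B \times 10^{-24} / (M_A M_B)$ in
mol·mL·g$^{-2}$ (for $A_2$, $M_A = M_B$). The same $-\tfrac12$ prefactor
is used for both the self and the cross coefficient; cross-coefficient
conventions differ across the literature, so this choice is part of the
package contract and is validated against the hard-sphere closed form
$B = \tfrac{2\pi}{3}\sigma^3$ rather than against any printed formula.

The pair energy $U$ is a sum over all cross pairs of atoms of three
terms:

* **steric** — infinite when two atoms approach closer than
  $\eta\,(r_a + r_b)$, zero otherwise;
* **nonpolar** — a 12-6 Lennard-Jones well,
  $\varepsilon\big[(\sigma/d)^{12} - 2(\sigma/d)^6\big]$ with
  $\sigma = r_a + r_b$, minimum $-\varepsilon$ at contact;
* **electrostatic** — the Debye–Hückel screened Coulomb interaction
  $q_a q_b \, l_B \, e^{-\kappa d}/d$ (in $k_BT$), with Bjerrum length
  $l_B$ and inverse screening length $\kappa$ fixed by temperature,
  dielectric constant and ionic strength.

All energies are carried internally in $k_BT$; unit conversions happen
only at reporting time.

### Parameters

| parameter | default | units | notes |
|---|---|---|---|
| temperature | 298 | K | with ionic strength 0.175 M these give $1/\kappa \approx 7.3$ Å |
| ionic_strength | 0.175 | mol/L | 1:1 electrolyte convention |
| relative_permittivity | 78.5 | — | water at 25 °C |
| clash_factor $\eta$ | 0.8 | — | hard-core scaling; 1.0 for strict hard spheres |
| lj_well_depth $\varepsilon$ | 0.3 | $k_BT$ | per atom pair; deliberately weak |
| energy_cap | 20 | $k_BT$ | numerical guard where Boltzmann factors are formed |
| grid spacing | 0.6 | Å | virial default; coarser grids are fine for toys |
| n_orientations | 600 | — | default orientation sample; convergence trace reported |
| r_cut | max(3/$\kappa$, 16) | Å | pair-interaction truncation in grid scans |

The steric scaling factor and the Lennard-Jones depth are declared
package defaults, configurable per run: the underlying energy model
family only fixes the functional forms, not these numbers, so they are
explicit parameters rather than inferred constants.

## Protonation microstates

Solution pH enters through histidine protonation. Each titratable site
(pKa 6.3 by default, appropriate for a solvent-exposed imidazole with no
ion-pair partner) is protonated with Henderson–Hasselbalch probability
$f = 1/(1 + 10^{\,\mathrm{pH} - \mathrm{p}K_a})$. All $2^n$ combinations
over $n$ sites are enumerated; the weight of a combination is the product
of its per-site probabilities, so weights sum to one. A protonated site
adds +1 elementary charge spread over the residue's imidazole-ring atoms
(or uniformly when no ring atoms exist, as in single-atom toys); only the
residue charge sums — +1 protonated, 0 deprotonated — are contractual,
the per-atom split is a template choice. $A_2$ (or $A_{23}$) is computed
per microstate and Boltzmann-averaged with these weights.

Two conventions deserve note:

* For $A_2$ the two interacting copies of the molecule share a single
  microstate, so three histidines give 8 combinations with
  product-of-probabilities weights. This matches the averaging convention
  of per-state virial calculations driven by one charge set per run.
* For $A_{23}$ the titratable sites of both bodies are enumerated
  jointly (weights multiply across bodies). As a consequence
  `compute_A23(A, copy_of_A)` equals `compute_A2(A)` exactly only for
  bodies without titratable sites; with sites, the shared-state and
  joint-state averages genuinely differ.

## Numerical machinery

**Lattice snapping and FFT correlation.** The translational scan snaps
atom centers to a cubic lattice and evaluates, by FFT cross-correlation,
the exact pair-energy sum at *every* lattice displacement of body B
(rotated) relative to body A. Snapping is the only discretization: given
the snapped coordinates, the FFT result equals the direct double-loop
sum to machine precision, which is the module's core oracle (asserted to
1e-6 $k_BT$, observed ~1e-8). Clash detection uses one indicator-kernel
correlation per distinct radius pair; the Lennard-Jones sum one kernel
per radius pair; electrostatics a single charge-weighted correlation,
whose kernel FFT is reused across protonation microstates.

**Box padding.** The cyclic box is sized to the two bodies' spans plus
twice the truncation radius, so the cyclic correlation equals the linear
one everywhere within interaction range; cells beyond the range
contribute exactly zero to the Mayer sum.

**Truncation.** Pair interactions in grid scans are truncated beyond
`r_cut` (default three Debye lengths, at least 16 Å). The scalar
`pair_potential()`/`pose_energy()` functions are exact (untruncated);
the per-residue decomposition replays the scan's truncated rules so that
residue contributions conserve pose totals to round-off.

**Infinite cells and the energy cap.** Clashing cells contribute a Mayer
factor of exactly −1, never NaN. Finite energies are capped at
`energy_cap` only where Boltzmann factors are formed
(`mayer_integral()`). Capping there, rather than per atom pair, keeps
the component bookkeeping additive (total = nonpolar + electrostatic)
and preserves the FFT ≡ direct-sum identity, while being numerically
indistinguishable from a per-pair cap: at 20 $k_BT$ the capped Mayer
factor differs from the steric limit by ~2e-9.

**Orientations.** Rotations are uniform random quaternions (Shoemake)
from a dedicated seeded stream: reproducible for fixed `(n, seed)`, with
`n = 1` yielding the identity. The orientation seed is recorded in every
result, and a per-orientation convergence trace of the averaged
coefficient is attached.

**Degenerate inputs.** Pairs at exactly zero lattice separation are
always inside the clash core (radii are positive) and contribute zero to
the finite terms in both the FFT and direct paths; a grid spacing larger
than the smallest atomic radius triggers a warning rather than an error.

## Pose analysis

The lowest-energy lattice configurations (default 1000) are mined from
the scan fields in ascending energy with deterministic tie-breaking. The
total energy of each pose is decomposed into residue contributions by
crediting each atom-pair energy half to the residue on either side
(default), so the grand total over both partners equals the pose energy
identically; a per-partner full-attribution mode is also provided, since
reported decompositions are often drawn per partner and the attribution
convention is a genuine free choice.

Poses are clustered by ligand RMSD — the RMSD of the smaller partner's
exact transformed coordinates between two poses, with the larger partner
superposed — using greedy single linkage: seed at the lowest-energy
unassigned pose, absorb everything within the cutoff of any member until
closure, repeat. Defaults follow the field's practice for weak-complex
ensembles: 9 Å cutoff, clusters below 10 members discarded, the
lowest-energy member as representative. Seeding order (ascending energy)
is a tie-break choice made for determinism.

## Titration and phase statistics

**Hill fits.** Chemical-shift titrations are fit to the two-plateau
base-10 logistic
$\delta_{obs} = \delta_{H^0} + (\delta_{H^+} - \delta_{H^0}) / (1 +
10^{\,n(\mathrm{pH} - \mathrm{p}K_a)})$ by Levenberg–Marquardt least
squares, initialized from the series extremes and midpoint crossing.
The Hill coefficient is fitted by default with a `fix_n` option; at
realistic noise (0.01 ppm over eight pH points) the matched fixed-$n$
estimator recovers pKa with median absolute error well under 0.02 units,
while the free-$n$ fit roughly doubles that spread — both are
characterized in the test suite. Confidence intervals are Wald-type from
the fit covariance, with a parametric Monte Carlo option.

**Turbidity thresholds.** The phase-separation threshold is the
x-intercept of the least-squares line through the three points at
concentrations strictly above the first concentration whose absorbance
exceeds the 0.1 onset. Series with no onset, or fewer than three points
beyond it, yield no threshold (treated as "did not phase-separate up to
the maximum tested"); a negative intercept on pathological input is
reported as-is with a warning.

**PCA + MLR.** The four virial features (A2/A23 × open/closed) are
correlated by construction, so thresholds are regressed on principal
components instead: features are column-centered (unscaled by default —
they share units; a standardize flag exists), decomposed by SVD, and the
thresholds regressed by OLS on a selected component subset (default PC1
and PC4; single-component trial fits for all components are always
reported so the selection is auditable). Component signs follow a fixed
convention (largest-magnitude loading positive) so results are
deterministic. Censored conditions are imputed at 400 µM and flagged;
imputed rows carry equal weight in the regression, a deliberate
simplification. Calibration against an experimental anchor adds one
constant to all values of a feature — absorbing, e.g., the putatively
constant contribution of flexible termini absent from the rigid model —
and preserves every pairwise difference.

## Synthetic data: what it emulates, and what it does not

The generators produce every input class the pipeline consumes, with
known ground truth:

* **toy bodies** (≤ ~200 atoms, ≤ ~30 Å) with patterned surface
  charges: near-isotropic shells, two-patch "surface dipoles" whose
  positive cap can titrate on at low pH, and extended acidic peptides.
  These reproduce the physics being modeled — oppositely charged surface
  patches pairing, pH switching through histidine-like sites — at a size
  where full virial runs take seconds.
* **titration curves** on the Hill model over pH 5.5–8.0 with Gaussian
  noise;
* **turbidity hinges** with a known x-intercept;
* **feature tables** built from planted orthogonal score directions
  with strictly decreasing variances (SDs 20, 8, 3, 0.12, chosen so the
  default coefficients 6.1/413.4/182.5 give thresholds spanning roughly
  50–350 µM) and thresholds linear in PC1 and PC4.

Every generator is pure given its seed. What passing tests demonstrate:
the integrator agrees with closed forms and brute force, protonation
averaging and the statistical procedures recover planted truths, and the
orchestration is deterministic. What they do not demonstrate: force-field
fidelity for real proteins, the adequacy of the rigid-body assumption,
or the accuracy of any particular clash/LJ parameter choice — on real
structures those must be assessed against experimental virial data, and
an additive calibration against at least one measured condition is
expected.

## Problem sizes

The shipped tests and the acceptance script run, by choice, at toy
scale: bodies of 24–48 atoms, grids of 32³–54³ cells at 0.5–1.75 Å
spacing, 3–16 orientations, 100–200 mined poses, 200 simulated
titrations, and 30-row feature tables. The full-scale defaults (0.6 Å,
600 orientations, 1000 poses) are the recommended settings for real
structures.

## Known limitations

* Rigid bodies only: no flexible linkers, no conformational averaging
  beyond the discrete open/closed alternatives supplied as inputs.
* The dielectric is uniform and implicit; no polarizability.
* Mutations applied in-package use a reduced side-chain representation
  (backbone + Cβ + centroid pseudo-atom carrying the target's net
  side-chain charge); faithful mutants of real proteins should be
  prepared with an external parametrizer and supplied as PQR.
* Molar masses are estimated from residue composition (average residue
  masses) unless overridden; only mass ratios affect relative virial
  comparisons for a fixed structure.
* Third and higher virial coefficients are out of scope.
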