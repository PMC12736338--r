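---
title: "Polarizable embedding and solvatochromism with fqembed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarizable embedding and solvatochromism with fqembed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqembed)
library(dplyr)
```

## The problem

The UV-Vis absorption band of a dye in water is shaped by its solvent shell.
Each instantaneous arrangement of water molecules produces a slightly
different transition energy and intensity, and the measured band is the
ensemble average of these "stick" spectra — its width is largely
*inhomogeneous*, i.e. it comes from solvent disorder rather than from any
intrinsic lineshape. A workflow that wants to reproduce this needs three
ingredients: configurations of the solvent shell, a polarizable description
of how that shell responds to the solute's electric field, and machinery to
turn per-configuration transitions into an averaged spectrum and a
solvatochromic shift. `fqembed` implements that workflow end to end at desk
scale, replacing the two expensive engines (a molecular-dynamics sampler and
an excited-state code) with a controlled synthetic generator and a mock
excitation model so that every stage can be tested quantitatively.

## The embedding model

Water sites carry *fluctuating charges*: each atomic site $i$ has an
electronegativity $\chi_i$ and a chemical hardness $\eta_i$ (both in atomic
units), and the site charges $q$ minimize the quadratic energy

$$E(q) = \sum_i (\chi_i + V_i)\,q_i + \tfrac12 \sum_{ij} q_i\,T^{qq}_{ij}\,q_j$$

subject to a fixed total charge per molecule, where $V_i$ is an external
potential (here, that of a point-charge solute). The FQFμ extension adds an
induced point dipole $\mu_i$ with isotropic polarizability $\alpha_i$ on
every site, coupled to the external field $E_i$; the FQFμCT variant replaces
the per-molecule charge constraints with a single total-system constraint,
so charge may flow between solvent molecules. Introducing one Lagrange
multiplier per constraint gives a symmetric saddle-point linear system in
$(q, \lambda, \mu)$, with $-(\chi + V)$ on the charge rows, the target
charges on the constraint rows and $+E$ on the dipole rows; the charge-only
model is recovered by deleting the dipole rows and columns. `fqembed`
assembles this system (`build_kernels()`, `assemble_system()`) and solves it
by direct factorization (`solve_embedding()`); at the sizes a droplet
produces (up to a few thousand sites) a dense solve is a second-scale
operation. The interaction energy with the external source is
$\sum_i q_i V_i - \sum_j \boldsymbol\mu_j \cdot \mathbf{E}_j$
(`interaction_energy()`), the dipole term entering with a minus sign.

### Kernel form

Published fluctuating-charge parameterizations differ in the exact form of
the interaction kernels, so the package ships two selectable families:

* `"ohno"` (default): the screened Coulomb form
  $s(r) = (r^2 + d_{ij}^2)^{-1/2}$ with $d_{ij} = 2/(\eta_i + \eta_j)$, so
  that $s(0)$ joins the diagonal hardness self-term and $s(r) \to 1/r$ at
  large separation. Charge–dipole and dipole–dipole blocks are the first and
  second derivatives of the same screened potential, keeping the energy
  functional consistent across blocks.
* `"coulomb"`: bare $1/r$ multipole interactions off the diagonal.

Two further conventions are fixed by limiting cases rather than taken from
any particular parameterization. The dipole self-term is $1/\alpha_i$ on the
diagonal $3\times3$ blocks, which is exactly what makes an isolated site
with frozen charge obey $\boldsymbol\mu = \alpha \mathbf{E}$. And
*intramolecular* charge–dipole and dipole–dipole couplings are excluded, the
1-2/1-3 polarization exclusion conventional in induced-dipole force fields:
with bare intramolecular coupling the induced dipoles are dominated by their
own molecule's large site charges and anti-align with the solute-induced
response, which screens the probe field and inverts the qualitative
coupling-ordering the model exists to express. Charge–charge coupling keeps
its intramolecular terms — electronegativity equalization across a molecule
requires them.

Coincident sites (closer than 0.1 Å) are rejected with an error rather than
regularized; a silently regularized singular system would hide generator
bugs behind plausible-looking numbers.

### Parameters

The `"toy"` parameter set (`fq_parameters()`) used throughout the tests is
$\chi_O = 0.18$, $\chi_H = 0$, $\eta_O = 0.60$, $\eta_H = 0.70$,
$\alpha_O = 6.0$, $\alpha_H = 1.0$ a.u. It is deliberately *not* a
literature water model: it is chosen to be numerically well-conditioned,
to give water-like charge magnitudes (a few tenths of an elementary charge)
and a stable dipole response at hydrogen-bonding distances. Named templates
for published parameterizations are shipped with `NA` placeholders; the
actual values live in the original papers and must be supplied by the user —
inventing them here would be worse than refusing to.

## The synthetic-data generator

`generate_snapshots()` emulates what an equilibrated MD trajectory of a
carbonyl dye in water delivers to the spectroscopy stages:

* a rigid point-charge solute (default: a four-site carbonyl probe,
  `carbonyl_solute()`) fixed at the droplet centre;
* a hydrogen-bonded shell: a Poisson-distributed number of waters (mean 2 by
  default, capped at 5 for steric sanity) whose donor hydrogen points at the
  carbonyl oxygen at a distance drawn from
  $\mathcal{N}(1.8\,\text{Å}, 0.1\,\text{Å})$ — the canonical acceptor–H
  distance of a carbonyl–water hydrogen bond;
* bulk waters placed uniformly in a sphere (default radius 17 Å, number
  density 0.0334 Å$^{-3}$, liquid water) with random orientations, rejected
  below a 2.4 Å heavy-atom contact and kept out of the acceptor's first
  shell (3.4 Å) so that shell occupancy is controlled solely by the
  hydrogen-bond parameters.

Waters are rigid three-site molecules (O–H 0.9572 Å, H–O–H 104.52°). One
seed drives everything; each snapshot gets an independent substream, so
ensembles are reproducible and order-independent.

What the generator does *not* emulate matters for interpreting green tests:
there are no forces, no thermal correlations between snapshots, no
exchange between shell and bulk, and the orientational statistics of bulk
water are isotropic rather than hydrogen-bonded. Passing tests therefore
demonstrate that the analysis pipeline recovers what the generator put in
(shell distance, occupancy, field-driven dispersion), not that any force
field reproduces real water structure.

## The mock excitation model

`mock_excitations()` stands in for a per-snapshot excited-state calculation
with the simplest model that reproduces the physical mechanism — the
carbonyl-centred hydrogen-bond shell modulates the first transition — while
admitting exact parameter-recovery tests:

$$E_1 = e_0 - m\,F + \varepsilon, \qquad \varepsilon \sim \mathcal{N}(0, \sigma)$$

where $F$ is the electric field of the *solved* solvent charges and dipoles
at a probe point (default: the carbonyl oxygen), projected on the
oxygen-to-carbon axis. Defaults: $e_0 = 3.10$ eV (a visible-band push-pull
dye), Stark slope $m = 25$ eV per a.u. of field — equivalent to an
excited-state dipole change of about 1 a.u. (≈ 2.4 D) — and
$\sigma = 0.02$ eV of residual noise. Measured droplet fields at the probe
are of order 0.02 a.u., so typical shifts come out at a few tenths of an eV,
the magnitude familiar from aqueous solvatochromic dyes. Higher states sit
at fixed offsets with independent noise and no field coupling; oscillator
strengths are drawn from a truncated normal law. Because hydrogen-bond
donors put positive charge density just outside the carbonyl oxygen, the
projected field is positive on average and the model red-shifts in
solution; because the field scales linearly with the solvent charges, any
increase in coupling strength (doubled charges, enabled dipoles) widens the
$E_1$ distribution — the inhomogeneous-broadening mechanism in miniature.

## Spectra and shifts

`convolve_gaussian()` broadens each snapshot's sticks with a unit-height
Gaussian per stick, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, on a uniform
grid (default 1.5–8.0 eV, step 0.01 eV; default FWHM 0.3 eV). Intensities
are in arbitrary units with the stated area convention
($\int I = \sum_k f_k\,\sigma\sqrt{2\pi}$); only relative intensities are
ever compared, so no absolute extinction scale is imposed, and normalization
before plotting is left to the caller. `ensemble_average()` is a pointwise
mean over identical grids; `band_maximum()` reads the band position off the
*averaged* curve (the way an experimental $\lambda_\text{max}$ is read, as
opposed to averaging per-snapshot maxima) with three-point parabolic
refinement; and `solvatochromic_shift()` applies
$\Delta E = E_\text{vac} - E_\text{solv}$, positive for a red shift. A grid
that clips more than 0.1 % of the analytic broadened area triggers a
truncation warning with the clipped mass.

## Structural analysis

`spherical_cut()` implements droplet extraction with a whole-molecule rule
keyed on the water oxygen — a broken water would violate the per-molecule
charge constraints downstream, so molecules are kept or dropped atomically.
`radial_distribution()` histograms site–site distances and normalizes by the
ideal-gas expectation with the partner density *measured inside the analysis
sphere*: snapshots here are finite droplets, not periodic boxes, so a
periodic bulk density is not available, and this normalization makes the
running coordination number
$n(r) = 4\pi\rho_B \int_0^r g(s)\,s^2\,ds$ (trapezoidal accumulation,
`running_coordination_number()`) equal the direct average neighbour count —
a property the tests exploit as a cross-check. Defaults: bin width 0.05 Å,
range 8 Å. Peak positions are read by `rdf_peak()` (5-point smoothing plus
parabolic refinement, to suppress single-bin counting noise), and the first
shell is delimited by the first local minimum of the smoothed curve after
its first maximum (`first_shell_minimum()`), where the coordination number
is conventionally read. No angular hydrogen-bond criterion is applied;
shells are characterized by distance only.

## The pipeline

`run_pipeline()` chains generate → cut → solve → excite → broaden → average
→ shift, writes each stage's artifacts (multi-frame XYZ plus a molecule map,
per-snapshot solution CSVs, a stick table, the averaged curve and a JSON
report with md5 checksums) into a workspace directory, and is bit-identical
under a fixed master seed — the generator and the excitation model receive
seeds derived from it. `compare_variants()` reruns the identical ensemble
under different force-field variants and tabulates the shift, band maximum
and stick dispersion per variant.

```{r pipeline-demo, eval = FALSE}
cfg <- pipeline_config(
  generator = generator_config(n_snapshots = 100, droplet_radius = 8),
  variant = "FQ", seed = 1)
report <- run_pipeline(cfg)
tidy(report)
compare_variants(cfg, c("FQ", "FQFMU", "FQFMU_CT"))
```

## Numerical choices and problem sizes

* Direct LU factorization of the saddle-point matrix; residuals above
  $10^{-8}\,\max(1, \lVert b\rVert_\infty)$ or a singular factorization
  raise a classed error rather than returning garbage.
* Unit conversions are pinned in one place (`fq_constants`):
  1 Å = 1/0.529177210903 bohr, $hc$ = 1239.841984 eV·nm,
  1 kcal/mol = 0.04336 eV.
* The test suite runs its statistical checks at deliberately modest sizes —
  droplets of radius 7–10 Å (≈ 50–140 waters), ensembles of 100–200
  snapshots — chosen so that the whole suite completes in a few minutes
  while keeping every stated tolerance: shell-distance recovery to
  ±0.05 Å, shell occupancy to ±0.2 waters, solver-versus-oracle agreement
  to $10^{-8}$ a.u., constraints to $10^{-10}$ a.u. The solver oracle is an
  independent conjugate-gradient minimizer of the loop-built energy
  functional in constraint-eliminated coordinates.

## Known limitations

* The solvent never polarizes back onto the source: the solute is frozen
  point charges, so the mutual self-consistency of a real embedding (where
  the quantum density and the solvent response iterate to convergence) is
  emulated, not implemented.
* No analytic forces, no periodic electrostatics: droplets are solved as
  finite clusters.
* The charge-transfer variant changes only the constraint structure; whether
  a published CT parameterization also modifies the interaction kernels is
  left open, and the variant should be read as "constraint-structure CT".
* The mock excitation model is linear in the field by construction; real
  transitions saturate and mix states. It is a test harness for the
  ensemble machinery, not a spectroscopic predictor.
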