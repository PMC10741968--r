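---
title: "Elastic modelling of bilayer thickness perturbation by membrane inclusions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic modelling of bilayer thickness perturbation by membrane inclusions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
elastic model and its assumptions, the boundary conditions for each
inclusion type, the meaning and accounting of the thickness disturbance,
the numerical method and its tunable controls, the design choices made
where the modelling was genuinely open, and the known limitations. Every
number quoted here is computed by the package's own test suite or
acceptance script.

## The model

A lipid bilayer near its flat state is described by five fields on the
membrane plane: the heights $H_u(x,y)$ and $H_l(x,y)$ of the neutral
surfaces of the upper and lower monolayers (the surfaces where bending and
stretching decouple), the height $M(x,y)$ of the interface where the two
monolayers' chains meet, and the in-plane components of the two director
fields $\mathbf n_u, \mathbf n_l$ describing average chain orientation. In
the linearized (small-deformation) theory the director's vertical component
is fixed at $\mp 1$ and all differential operators act in the plane.

Each monolayer carries a quadratic energy density: splay
$\tfrac B2(\operatorname{div}\mathbf n + J_0)^2 - \tfrac B2 J_0^2$ (the
subtraction makes the flat state the energy zero), tilt
$\tfrac{K_t}2(\mathbf n \mp \nabla H)^2$, lateral tension
$\tfrac\sigma2(\nabla H)^2$, lateral compression
$\tfrac{K_a}{2h^2}\bigl(h - \tfrac{h^2}2\operatorname{div}\mathbf n \pm (M - H)\bigr)^2$
— the form that results from eliminating the area strain under local
volumetric incompressibility of the hydrophobic chains — plus Gaussian
splay $K_G\,K$ and twist $\tfrac{K_{rot}}2(\operatorname{rot}\mathbf n)^2$.
Far from any inclusion the fields take the ground-state values $H_u = h$,
$H_l = -h$, $M = 0$, $\mathbf n = 0$.

Assumptions inherited from this functional: deformations are small
(quadratic expansion), the membrane is a one-component symmetric bilayer
(apart from an explicit lipid patch), each monolayer is volumetrically
incompressible, and inclusions are rigid objects that act only through
boundary conditions. There is no electrostatics, no thermal fluctuation
spectrum, and no lateral interaction between inclusions — the model is
strictly a single-inclusion, dilute-limit one.

### Parameters

All internal quantities are in thermal units and nanometres. The packaged
presets (`preset_parameters()`) are, per monolayer:

| parameter | DOPC | POPC:POPS 3:1 | units | meaning |
|---|---|---|---|---|
| B | 10 | 11 | kBT | splay modulus |
| K_t | 40 | 40 | mN/m | tilt modulus |
| K_a | 133 | 117 | mN/m | lateral compression modulus |
| σ | 0.1 | 0.1 | mN/m | lateral tension |
| K_rot | B/2 | B/2 | kBT | twist modulus |
| K_G | −B/2 | −B/2 | kBT | Gaussian splay modulus |
| J_0 | −0.091 | 0 | 1/nm | monolayer spontaneous curvature |
| h | 1.45 | 1.46 | nm | monolayer hydrophobic thickness |

Quantities quoted in mN/m are converted to kBT/nm² with
`convert_to_internal()`; the temperature of that bridge is a user
parameter defaulting to 300 K (the parameter sets themselves do not fix a
temperature, so the conversion of K_t, K_a and σ is approximate at the
percent level over the physiological range). The conversion factor in use
is recorded in every task log.

The lipid-inclusion presets (`inclusion_common`, `inclusion_thin`) carry
DOPC-like tilt/compression/tension moduli with twist and Gaussian moduli
fixed at +5/−5 kBT; the patch splay modulus `B`, spontaneous curvature
`J0` and thickness `h_inc` are the quantities a user varies. Geometry
defaults: patch radius 0.5 nm ("common") or 0.662 nm with
h_inc = 0.7 nm ("thin", modelling photoswitchable lipids in their bent
configuration).

## The observable: thickness disturbance

A single inclusion perturbs the local thickness $H_u - H_l$ over a few
nanometres around itself. The integral of the deviation,
$\Delta = \int (H_u - H_l - 2h)\,dS$ (nm³), is exactly what dilute
thickness measurements see: with $N$ non-interacting inclusions on area
$S$, the average thickness is $\langle d\rangle = 2h + C\Delta$ at surface
concentration $C = N/S$. Because the energy is quadratic, $\Delta$ is
linear in each inclusion's boundary data; the package extracts these
response coefficients by solving at several probe values and fitting
(`extract_eta()`, `extract_beta_gamma()`, `extract_k_b()`), with the
residuals and free intercept reported as diagnostics — for a correctly
configured solver they vanish to rounding (observed: residuals below
1e-13 of the response scale).

Two accounting choices deserve explicit statement:

* **Transmembrane peptides.** The integration domain is the total
  membrane area, including the peptide's own disk, where the rigid
  peptide pins the local thickness to its hydrophobic length $h_p$. The
  disk adds $\pi r_p^2\,(h_p - 2h)$ to $\Delta$ — at $r_p = 0.65$ nm this
  is $1.33\,(h_p-2h)$, a material part of the mismatch response: with it
  the DOPC coefficients are $\beta = 10.67$ nm³ and $\gamma = 3.90$ nm²;
  the lipid-annulus-only integral would give $\gamma = 2.58$ nm².
* **Amphipathic peptides.** There is no upper neutral surface beneath the
  footprint, so the local thickness is undefined there and $\Delta$
  integrates over the footprint exterior only. Users comparing with
  measurements that average over total area (including the
  peptide-covered fraction) can add a footprint correction of their own
  choosing.

For lipid patches $\Delta$ integrates over the whole plane including the
patch disk — the patch is real bilayer. A patch whose monolayer thickness
matches the host ($h_{inc} = h$) produces exactly zero $\Delta$ for any
patch splay modulus and spontaneous curvature, even though the local
thickness deviates when $J_{0,inc} \ne J_0$; the acceptance suite verifies
this null to below $10^{-9}$ nm³ across the parameter grid.

## Boundary conditions per inclusion type

**Transmembrane peptide** (axisymmetric): on the circle $r = r_p$ the
radial director projections are fixed on both neutral surfaces
($n_{0u}, n_{0l}$; positive = splayed outward, barrel-like) and the local
thickness is constrained, $H_u(r_p) - H_l(r_p) = h_p$. The peptide's
vertical position is *not* fixed: only the difference is constrained and
the mean height at the boundary is determined variationally (implemented
as a single linear constraint in a KKT system). For mirror-symmetric
peptides this yields $H_u(r_p) = h_p/2$, and the full solve agrees with
the half-problem reduction (`reduce_symmetric()`, upper monolayer with
$M = 0$, energy doubled) to 1e-9 relative.

**Lipid patch** (axisymmetric): no essential conditions at the patch edge.
The patch region uses its own moduli and its own reference thickness in
the compression term, $\tfrac{K_a}{2h_{inc}^2}\bigl(h_{inc} -
\tfrac{h_{inc}^2}2\operatorname{div}\mathbf n_u + M - H_u\bigr)^2$;
assembling one energy with piecewise coefficients makes the neutral
surface and director continuous and enforces the natural (flux) matching
variationally. At the origin the radial director components vanish by
regularity ($n_r(0) = 0$, enforced).

**Amphipathic peptide** (planar 2D): the upper monolayer is excluded from
the footprint (the helix occupies the polar-head region; its energy is
not modelled), while the lower monolayer and the interface height remain
defined beneath it. On the footprint outline the upper director is fully
prescribed: outward-normal projection $n_0$, zero tangential projection;
the upper height is free there. $|n_0|$ can be estimated geometrically
from the helix radius as $r_p/\sqrt{r_p^2 + h^2}$
(`estimate_boundary_director()`; 0.409 for $r_p = 0.65$, $h = 1.45$),
with the negative, beneath-the-peptide sign for surface-bound helices.

### The footprint outline

The outline shape of an in-plane helix is not sharply defined physically;
it is the one genuinely open geometric choice in the planar problem, and
the response coefficient is sensitive to it at the several-percent level.
The package's default is an **ellipse** with semi-axes $(l_p/2, r_p)$; a
**stadium** (rectangle of length $l_p - 2r_p$ capped by semicircles) is
available via `solve_amphipathic(outline = "stadium")`. With the DOPC
preset and $l_p = 5$, $r_p = 0.65$ nm the measured coefficients are
$\eta = 9.98$ nm³ (ellipse) and $\eta = 10.45$ nm³ (stadium), a 4.7%
spread; both outlines give response curves that are exactly linear in
$n_0$ with zero intercept. Variants that relax the director condition on
parts of the outline were examined and rejected: leaving the high-
curvature ends free re-activates the spontaneous-curvature source term
$B J_0 \operatorname{div}\mathbf n$ (its integral is then no longer fixed
by boundary data), which deforms the membrane even at $n_0 = 0$ and
destroys the zero-intercept linearity that the quadratic model should
have. With the director fixed on the whole outline that term is constant
on the constraint space — discretely as well, by the element-wise
divergence theorem — so the spontaneous curvature affects the energy but
not the fields, and $\Delta(n_0 = 0) = 0$ exactly.

## Numerical method

The energy is discretized with first-order (P1) elements — it contains
only first derivatives of every field — and minimized as a sparse
quadratic program: Dirichlet data are eliminated, the one non-trivial
linear constraint (the transmembrane thickness difference) is handled by a
KKT system, and the reduced Hessian is factorized sparsely. An LDL'
factorization checks positive definiteness of the quadratic form first;
an indefinite form (possible for unphysical moduli) raises a stability
warning rather than failing silently.

Because $M$ enters the energy without derivatives, it is eliminated
pointwise in closed form before discretization (exact at the continuum
level) and reconstructed after solving; beneath an amphipathic footprint,
where only the lower compression term involves $M$, the elimination
annihilates that term — equivalent to leaving $M$ free there.

*Axisymmetric problems* use a graded 1D mesh from the inclusion boundary
(first element 0.005 nm, geometric growth 1.05) to a truncation radius
$R_{max} = 50$ nm where the ground state is imposed — deformations decay
within a few nanometres, so the truncation error is negligible (doubling
$R_{max}$ and halving the element size moves $\Delta$ by well under 1%,
and `refine_check = TRUE` automates that diagnostic). Two-point Gauss
quadrature is exact for the integrands except the $1/r$ metric factors,
whose error is absorbed by the grading. In axisymmetric configurations
the twist term vanishes identically and the Gaussian term telescopes to
boundary data; both facts are asserted numerically in the tests.

*The planar problem* uses a boundary-fitted structured mesh built from
offset curves of the footprint outline (offsets of a convex outline are
meshed ring by ring; the footprint interior is meshed by shrinking rings
that collapse onto the centre). Defaults: 80 outline points, first ring
offset 0.05 nm, growth 1.18, far boundary at offset $L = 30$ nm. The two
mirror symmetries can be exploited (`quadrant = TRUE`, with
odd-component director conditions on the axes); the quarter-domain result
matches the full plane to 0.04%, and refinement plus domain doubling
moves $\Delta$ by under 2%.

*Independent oracle.* A dense-grid finite-difference minimizer
(`fd_transmembrane()`) rebuilds the axisymmetric energy from scratch on a
uniform grid (spacing 0.01 nm) with midpoint-rule difference and
averaging operators assembled as sparse matrices — no code shared with
the finite-element assembly. Its $\Delta$ agrees with the FEM within
0.5% (observed: ≤ 0.12%) across sign-varying parameter points.

Solver tasks are fully deterministic: no iteration-order dependence, no
randomness; repeated runs are byte-identical (asserted in the CLI tests).

## Inverse analysis and the synthetic generator

`fit_n0()` is the inverse step: weighted least squares of
$\langle d\rangle$ on $C$ (intercept free; its agreement with $2h$ is a
diagnostic), slope divided by $\eta$, confidence interval from the
linear-fit covariance with the t distribution. Mole-fraction series are
converted by $C = 2x/A_L$, counting lipids in both leaflets ($S = N_L
A_L/2$); whether a published series counts one or both leaflets changes
the conversion by a factor of two, so the counting convention is an
explicit argument (`leaflets`), never a silent default, and the area per
lipid $A_L$ must be supplied by the user.

`generate_series()` emulates the measurement this inversion targets:
thickness values on the affine law $2h + C\eta n_0$ with i.i.d. Gaussian
noise, reproducible per seed. Default study conditions used in the tests:
8 concentrations spanning 0.002–0.016 nm⁻² (within the linear regime —
`forward_thickness()` warns above a mole fraction of about 1/65, where
deformation zones overlap and additivity fails) and 0.01 nm thickness
noise, a typical scattering-measurement precision. Under these
conditions the zero-noise inversion is exact to rounding, and over 200
noisy replicates with the director drawn in (−0.6, −0.2) the 95% interval
covers the truth in 96% of replicates. What the generator deliberately
does *not* emulate: concentration-dependent (non-ideal) mixing at high
coverage, correlated or multiplicative measurement error, uncertainty in
$C$ itself, and any systematic offset in absolute thickness calibration —
passing tests therefore demonstrate correctness of the model and the
inversion under ideal dilute-regime statistics, not robustness to real
experimental systematics.

## Energies, signs and degenerate inputs

The reported $W$ is the functional value relative to the flat unperturbed
membrane. For peptide inclusions with fixed boundary data it is
non-negative up to the (constant) spontaneous-curvature boundary term;
for lipid patches it can legitimately be negative — a patch with mismatched
spontaneous curvature *prefers* a deformed state. Energies of
boundary-driven solves scale exactly quadratically, $W(\lambda\,bc) =
\lambda^2 W(bc)$, whenever the linear boundary source vanishes (zero
spontaneous curvature, or pure thickness mismatch); the tests assert this
to 1e-9.

Degenerate inputs are rejected with messages rather than propagated:
non-positive moduli or thicknesses, $|n_0| \ge 1$, footprints shorter
than their width, concentration series with fewer than three points or
zero span, mole fractions without $A_L$. A pointwise
`energy_density()` evaluator is exported for inspection; it warns when
the local density is negative (possible where the local splay approaches
a nonzero spontaneous curvature — the integrated energy is still bounded
below).

## Problem sizes

The default discretizations — roughly 130–250 nodes (4 fields) for
axisymmetric solves, about 2 600 nodes (6 fields) for full-plane planar
solves and a quarter of that with `quadrant = TRUE`, and a 5 000-node
uniform grid for the finite-difference oracle — were chosen so that every
reported coefficient sits within a fraction of a percent of its
mesh-converged value while a full coefficient extraction (including the
planar probes for two lipid systems) completes in seconds on one core.

## Known limitations

* Small-deformation theory: boundary directors approaching 1 or
  mismatches of order $h$ leave its validity range even though the solver
  still returns numbers.
* Single inclusion only; no membrane-mediated inclusion–inclusion
  interaction, hence no validity above the linear concentration regime.
* The bulk bilayer is symmetric; leaflet asymmetry enters only through
  the explicit patch construct.
* The amphipathic footprint outline is a modelling choice with a
  several-percent effect on $\eta$ (quantified above); derived boundary
  directors inherit that uncertainty.
* The temperature of the mN/m → kBT bridge is nominal (300 K).
* Helix flexibility and tilted or partially inserted orientations are
  absorbed into the effective $n_0$, not resolved.
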