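---
title: "Modeling meniscal tensile failure with continuum damage mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling meniscal tensile failure with continuum damage mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meniscusCDM)
```

## The problem

The meniscus is a fibrocartilage whose type-I collagen fibers run
predominantly circumferentially. Tensile failure is therefore anisotropic:
coupons pulled along the fiber direction (*longitudinal*) are stiff and
strong and fail by fiber rupture, while coupons pulled normal to the fibers
(*transverse*) are soft and extremely extensible and fail through the ground
substance. `meniscusCDM` implements a continuum damage mechanics (CDM)
description of this behavior: a transversely isotropic hyperelastic solid
whose effective stress is degraded by a scalar damage variable, together
with the drivers (homogeneous material point and 3-D finite elements), the
calibration procedure, and the tear-region validation metrics needed to use
it as a complete analysis pipeline.

All quantities are in MPa, mm and N; stretches and strains are
dimensionless.

## Constitutive model

The strain energy density is uncoupled into deviatoric and volumetric
parts,

$$\Psi = F_1(\tilde I_1, \tilde I_2) + F_2(\tilde\lambda)
       + \tfrac{K}{2}\,(\ln J)^2,$$

where $\tilde I_1,\tilde I_2$ are invariants of the deviatoric right
Cauchy–Green tensor, $\tilde\lambda$ is the deviatoric fiber stretch, $J =
\det F$ and $K$ is a bulk modulus used as an incompressibility penalty
(default 1000 MPa, two to four orders above the tissue shear moduli). The
ground substance is Veronda–Westmann,

$$F_1 = C_1\left(e^{C_2(\tilde I_1 - 3)} - 1\right)
      - \tfrac{C_1 C_2}{2}(\tilde I_2 - 3),$$

and the fiber network is defined through its stress,

$$\tilde\lambda \frac{\partial F_2}{\partial \tilde\lambda} =
\begin{cases}
0 & \tilde\lambda \le 1\\
C_3\left(e^{C_4(\tilde\lambda - 1)} - 1\right) & 1 < \tilde\lambda < \lambda_m\\
C_5\tilde\lambda + C_6 & \tilde\lambda \ge \lambda_m,
\end{cases}$$

an exponential toe (fiber uncrimping) that transitions to a linear response
with fiber modulus $C_5$ at the transition stretch $\lambda_m$. $C_6$ is
never a free parameter: [compute_C6()] equates the two branches at
$\lambda_m$ so the fiber stress is continuous. Because only the derivative
form is given, the energy $F_2$ is fixed by the conventions $F_2(1)=0$ and
$C^1$ continuity at $\lambda_m$; the toe branch has no elementary
antiderivative and is integrated numerically (composite Simpson, error far
below any tolerance used here). Fibers carry no load in compression.

The undamaged Cauchy stress is the standard deviatoric push-forward of the
isochoric terms plus the pressure $K\ln(J)/J$; the implementation is
verified against central-difference differentiation of the energy (relative
error below $10^{-3}$ on random states, typically $10^{-9}$) and against
objectivity under random rotations.

### Damage

Damage evolves through a quintic smoothstep of the criterion $\Xi$:

$$D(\Xi) = \begin{cases}
0 & \Xi \le \mu_{min}\\
D_{max}\, x^3(6x^2 - 15x + 10), \quad x = \frac{\Xi-\mu_{min}}{\mu_{max}-\mu_{min}}
  & \mu_{min} < \Xi < \mu_{max}\\
D_{max} & \Xi \ge \mu_{max}.
\end{cases}$$

The middle branch is scaled by $D_{max}$: without that factor the function
would jump from 1 to $D_{max}$ at $\mu_{max}$, contradicting the stated role
of $D_{max}$ as the saturation damage. The criterion is either the von
Mises stress of the undamaged stress deviator or the maximum normal
Lagrange strain. Damage is irreversible; the package uses the standard CDM
history rule $D = D(\max_t \Xi)$, so $D$ is constant during unloading. The
damaged stress is $\sigma = (1-D)\,\sigma_0$, applied to the full stress
tensor including the volumetric term — the equation is taken literally,
although restricting damage to the deviatoric part would be an equally
defensible reading; at near-incompressibility the practical difference is
small because $\ln J \approx 0$ on the loading paths used here. $D_{max}$
is kept below 1: elements never lose all load carrying capacity, which both
stabilizes the solver and, notably, reproduces the bounded-damage plateaus
(re-stiffening after local saturation) seen in transverse experiments.

## Material-point driver

`simulate_uniaxial()` drives a homogeneous uniaxial-stress state: the axial
stretch is prescribed and the two lateral stretches are solved by Newton
iteration so both lateral Cauchy stresses vanish (residual tolerance
$10^{-8}$ MPa). The lateral stretches are independent unknowns because an
active fiber family off the load axis breaks axisymmetry (under transverse
loading the fibers are slack and the response is in fact laterally
symmetric). Damage is updated once per converged step from the criterion
history maximum, with internal sub-stepping whenever a step would increase
damage by more than 0.05. This driver maps grip-to-grip stretch 1:1 to
material stretch — an approximation to the full coupon (shoulders deform
less) that is used inside calibration loops for speed; the finite element
model is the reference.

## Finite element model

The coupon is modeled as its 1/8-symmetry octant (symmetry planes x = 0,
y = 0, z = 0; y is the loading axis). The exact dogbone dimensions are a
package default chosen once to represent punch-cut meniscus micro-coupons.
Longitudinal coupons are long and narrow (octant: gauge half-width 0.6 mm,
grip half-width 1.2 mm, half-thickness 0.5 mm, half grip-to-grip length
3.2 mm); transverse coupons are short and wide (gauge half-width 1.2 mm,
half length 1.25 mm) because the tissue's transverse dimension limits how
long such strips can be punched. Both use a long cosine-blend shoulder —
the generous shoulder matters, since a sharp re-entrant fillet concentrates
strain at the free edge and draws the damage band to the shoulder edge
rather than the midsubstance.

The mesh is a structured grid of hexahedral cells, each split into 6
tetrahedra with a fixed template (deterministic element counts). A band
(default 2.5 mm of full-coupon height, centered on the coupon mid-plane) is
refined by an integer factor: width and thickness axes are subdivided
globally (the band spans the full cross-section) and the length axis only
inside the band, which refines the band isotropically while keeping the
mesh conforming — no hanging nodes. The base resolution is 10 x 8 x 2 cells
(960 tetrahedra); factor 4 yields ~34k elements, the same order as the
~16k-element reference configuration (the exact count depends on the
hex-to-tet convention).

The solver is total-Lagrangian Newton with a displacement predictor
(previous field scaled to the new stretch), a backtracking line search, and
numeric element tangents (central difference on the 12 element dofs) —
robust against the piecewise fiber law and the damage nonsmoothness.
Convergence requires the free-dof residual below $10^{-6}$ of the reaction
norm. The grip is the rigid kinematic limit of a frictionless sliding
contact: grip-face nodes carry the prescribed axial displacement with free
lateral translations. Damage is explicit per load step (frozen during
Newton, updated from the converged fields); steps are halved on divergence
or when any element damage increment exceeds 0.1, and exhaustion returns a
partial solution flagged `"terminated"` — the same premature-termination
behavior damage localization causes in coarse-mesh simulations generally.

Pure displacement formulation with penalty incompressibility on linear
tetrahedra accepts mild volumetric locking; that is the deliberate element
choice being reproduced, not an accident.

## Tear metrics

The DIC-comparable surface is the z-max face of the octant. `locate_roi()`
finds the y-layer with the greatest volume-averaged damage and takes one
element layer above and below — at refinement factor 4 the ROI height is
~0.24 mm, matching the reported experimental analysis bands.
`roi_strains()` area-averages the surface Lagrange components ($E_{yy},
E_{xx}, E_{xy}$) and the per-face in-plane principal values; the maximum
shear strain is defined as $\gamma_{max} = E_1 - E_2$, the diameter of the
in-plane Mohr circle, matching planar-DIC convention (the source analyses
do not define it explicitly). `tear_angle()` thresholds the surface damage
at 80% of its maximum and fits the principal axis of the thresholded
face centroids, aggregated per parent grid cell (the tet template's
diagonal face lattice would otherwise bias the axis); 0 deg is a tear
straight across the coupon, 90 deg is parallel to loading. The band is
additionally split at its median width coordinate into outer (free-edge)
and inner halves, a convention for detecting tears that change direction
toward the coupon midline; how the experimental bimodal angles were
segmented is not recorded, so this split is this package's own rule.
Because thresholded bands are clipped by the narrow coupon, the principal
axis measures the band direction only when the band is thin relative to
its traverse; the synthetic fixtures used in tests respect that.

`mesh_convergence_report()` repeats a solve over refinement levels and
flags the expected monotone-increase-then-plateau of the ROI-averaged
$E_{yy}$ (plateau: last increment < 25% of the first).

## Calibration

The sequential fit mirrors experimental practice:

1. **Yield point**: the sample of maximum slope of the locally
   quadratic-smoothed force–stretch curve (earliest on ties; straight
   lines are flagged degenerate). Default smoothing window: 15% of the
   samples.
2. **Ground substance**: $C_1, C_2$ fit to transverse curves up to yield,
   bounded Levenberg–Marquardt (`minpack.lm`) on force residuals, damage
   off. $C_2$'s initial guess is 1.
3. **Fibers**: $C_3, C_4, C_5, \lambda_m$ fit to longitudinal curves up to
   yield with the ground substance frozen. Whenever a parameter lands on a
   bound, that bound is expanded by 30% and the fit re-run (up to 10
   times). Failed forward runs contribute a large finite penalty residual
   instead of aborting the optimizer.
4. **Damage**: $(\mu_{min}, \mu_{max}, D_{max})$ per orientation by
   deterministic search against explicit success criteria: model ultimate
   stress within 0.2 MPa (longitudinal) / 0.03 MPa (transverse), ultimate
   grip-to-grip strain within 3% strain, and a post-UTS stress drop of at
   least 1% / 0.5%. "3% strain" is interpreted as engineering strain
   (stretch − 1), the scale on which grip-to-grip ultimate strain is
   reported. The search is seeded at the criterion values at the yield and
   ultimate points with $D_{max} = 0.6$, runs coordinate descent in
   $(\mu_{min}, \mu_{max}-\mu_{min}, D_{max})$ with multiplicative steps
   (x1.3, shrinking 50% on no improvement), restarts from an
   elastic-departure-based seed (the criterion value where the data first
   drop 3% below the elastic prediction — what a careful manual fit would
   try next), and polishes the winner with a Nelder–Mead simplex under a
   logistic cap $D_{max} < 0.96$; total budget 300 objective evaluations.
   Automated gradient optimization of these parameters is avoided by
   design: damage parameter combinations that terminate the forward model
   early would halt it, whereas the search just scores them.

The driver inside all fitting loops is the material point (speed); an
accepted fit can be re-verified with the FE model. `cdm_fit()` packages the
whole sequence and returns an object with the usual `coef`, `predict`,
`plot`, `residuals`, `simulate` methods. When several curves per
orientation are supplied the elastic stages pool them (noise averages out
of the shared constants, which materially improves fiber-parameter
identifiability); damage parameters remain per-specimen, so pooled means of
those can still be reported.

Quality of fit is NRMSE (RMSE of force over the mean target force, in
percent, on a common resampled grid — equivalent to normalizing stress by
mean stress) and $R^2$.

## Synthetic data

No public tensile data exist for this protocol, so the package generates
its own with known ground truth. The study conditions are fixed once in
`synthetic_truth()` / `generator_spec()`:

* ultimate targets ~2.25 N at grip-to-grip stretch ~1.155 (longitudinal)
  and ~0.100 N at ~1.493 (transverse), the experimental group means being
  emulated;
* homoscedastic Gaussian force noise, sd = 1% of the ultimate force (no
  noise model is reported; 1% is a typical load-cell scale);
* curves sampled to 15% of the ultimate strain past the UTS so the
  softening tail is observed;
* n = 5 specimens per orientation in the recovery studies, matching the
  per-group scale of the emulated experiments.

The ground-truth constants were calibrated once, at design time, so the
material-point forward model places its UTS at those targets, and are
frozen in code. Two structural choices deserve note. First, the fiber toe
is slope-continuous at $\lambda_m$ ($C_3 C_4 e^{C_4(\lambda_m-1)} = C_5$),
as fitted soft-tissue parameter sets tend to be — a slope discontinuity
would pin the yield point artificially at $\lambda_m$. Second, the damage
law is arranged to be ~90% saturated at the end of the sampled curve:
otherwise $(\mu_{max}, D_{max})$ are only weakly identifiable from the
sampled range and no fitting procedure could recover them reliably. These
ground-truth constants differ from the printed fitted averages for real
tissue (e.g. $C_5 \approx 16$ vs ~120 MPa) deliberately: the printed
averages were calibrated through full FE models, where gauge stretch
exceeds grip-to-grip stretch, so driving a homogeneous material point with
them cannot place the UTS at the grip-to-grip targets.

`generate_curve_phenomenological()` provides a model-independent surrogate
(exponential toe, linear region, smooth softening with its peak exactly at
the targets; transverse curves superpose seeded localized pre-UTS peaks
emulating sporadic tie-fiber failures). `generate_damage_field_fixture()`
paints oriented damage bands on a mesh for exercising the tear metrics
with known ground truth. Everything embeds its seed; regeneration is
bit-reproducible.

What the generators do **not** emulate: inter-specimen biological variance
(dispersion across seeds is noise-driven and well inside the experimental
SDs), preconditioning history, strain-rate effects, heteroscedastic load
noise, DIC speckle/correlation error, and grip slippage. Passing the
recovery tests therefore shows the pipeline is correct and well-identified
under the stated conditions — not that real cadaveric data would be this
benign.

## Numerical choices and degenerate inputs

* Lateral-stress Newton: residual tolerance $10^{-8}$ MPa, forward-difference
  Jacobian, step guard against non-positive stretches.
* FE tolerances: free-residual $\le \max(10^{-8}, 10^{-6}\times$ reaction
  norm$)$; numeric element tangents with $h = 10^{-6}$ mm; up to 8 step
  halvings.
* Ties: yield and UTS resolve to the earliest sample; the ROI layer
  resolves to the lowest y and is flagged ambiguous when tied (e.g.
  uniform damage).
* Degenerate inputs error early with specific messages: non-monotone
  stretch columns name the offending row; zero damage fields direct the
  caller to the damage parameters; inverted elements terminate the
  solve rather than returning garbage.
* Problem sizes in the shipped tests and acceptance study: material-point
  grids of 100–400 points; FE meshes of 960 (factor 1) to ~17k (factor 3)
  tetrahedra; tear-pattern runs at factor 1–2; 5 specimens per orientation
  in recovery studies. These sizes were chosen so the full study runs on a
  single CPU in minutes while staying within the regimes where the
  qualitative conclusions are mesh-stable.

## Known limitations

* Linear tetrahedra with penalty incompressibility lock mildly; absolute
  strain levels in the tear region are under-predicted relative to DIC
  observations, and further refinement plateaus rather than closing that
  gap — a genuine limitation of this class of model, not of the mesh.
* No viscoelasticity, rate dependence, plasticity/permanent set, or
  compression-specific behavior; the loading-rate metadata of emulated
  experiments is not used.
* No nonlocal or gradient damage regularization, by design: localization
  (and the resulting mesh sensitivity and occasional premature
  termination) is part of the modeled behavior.
* The rigid frictionless grip is the limiting case of the elastic sliding
  contact it replaces; compliance of a real clamp would shift grip-to-grip
  curves slightly.
* The tear-angle half-split convention (median width coordinate) is this
  package's rule; other segmentations of bimodal tears are possible.
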