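---
title: "Modeling left atrial appendage morphology and blood stasis with atriflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling left atrial appendage morphology and blood stasis with atriflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The left atrial appendage (LAA) is a blind-ended pouch off the left atrium
and the dominant site of intracardiac thrombus formation in atrial
fibrillation (AF): blood that stagnates in the appendage clots, and the clot
embolizes. Whether an appendage washes out well or poorly depends on its
shape — volume, orifice size, length, tortuosity — and on the hemodynamic
environment at its mouth. `atriflow` implements a complete in-silico
workflow for studying how LAA *morphology alone* shapes atrial hemodynamics
and appendage blood stasis: donor appendages are grafted onto one fixed
template atrium so every simulation shares the same chamber, and only the
appendage differs.

The pipeline has five stages, each usable on its own:

1. **Segmentation** — the shape diameter function (SDF) is computed on the
   atrial surface and clustered into semantic regions; the appendage region
   is isolated automatically (`computeSDF`, `clusterRegions`,
   `identifyLAA`, `extractSubmesh`).
2. **Grafting** — a donor appendage rim is registered onto the template
   ostium by iterative closest point (ICP) and stitched on
   (`icpAlign`, `graftLAA`, `buildModelSet`).
3. **Geometric quantification** — volume V, lateral surface area A_s,
   orifice area A_o and perimeter P_o, centerline length L and tortuosity
   chi = L/D - 1 (`geometryReport`).
4. **Flow simulation** — incompressible Navier-Stokes in the composite
   atrium under AF boundary conditions (`solveFlow`).
5. **Stasis quantification** — Q-criterion vortex structures, the ostium
   velocity trace, and Lagrangian particle residence (`qCriterion`,
   `ostiumVelocity`, `seedParticles`, `advectParticles`,
   `residenceCounts`, `residualFraction`).

`runPipeline` chains all stages and writes per-model reports plus a
comparative summary ranked by fifth-cycle residual fraction.

Patient meshes are not distributed with the package. A parametric
synthetic-anatomy generator (`makeTemplateLA`, `makeParametricLAA`,
`makeStudySet`) supplies template atria and appendage variants with
analytically known ground truth; all tests and the bundled experiments are
built on it.

## The synthetic anatomy and what it does (not) emulate

The template atrium is an ellipsoidal chamber (semi-axes 3.5 x 2.8 x 2.4 cm,
enclosed volume about 100 ml — a physiologic, mildly dilated AF atrium)
carrying four pulmonary-vein (PV) tubes, a mitral-valve (MV) port, and an
appendage ostium port. Port positions follow the real topology: PVs
posterior-superior, MV inferior, and the LAA ostium left-lateral adjacent
to the mitral annulus, so the ostium borders the transmitral stream — the
placement that gives the appendage mouth a realistic shear environment. PV
radius is 0.8 cm (within the physiologic 0.45–1.25 cm range), chosen so PV
sections stay resolved on the coarse lattices used here.

Appendages are circular tubes swept along cubic splines with
rotation-minimizing frames (no twist), distally capped, proximally open
(the ostium rim). Ground truth refers to the swept spline: L is its
arclength, D the endpoint distance, chi = L/D - 1; so a straight segment
has chi = 0 exactly and a semicircular arc chi = pi/2 - 1. The computed
centerline additionally runs to the cap apex, extending L by roughly the
tip radius; centerline-recovery checks therefore use tapered tips, where
the extension is within the stated tolerances. A `taper` parameter mimics
appendages that shrink toward the distal part.

`makeStudySet` generates variants whose tortuosity spans at least
[0.03, 0.46] and length at least [2.3, 3.5] cm — the ranges observed across
the five patient appendages the workflow was designed around. Volume is
paired *inversely* with tortuosity (about 2.6 cm^3 for the straightest,
2.05 cm^3 for the most tortuous), mirroring the patient set where the most
tortuous appendage was the narrow small-volume one and the straightest had
the widest orifice. Donor sweep resolution is chosen so the donor's
face density matches the template's; the chamber then remains the modal
region after clustering, which the appendage-identification rule relies on.

What the generator does *not* emulate: trabeculations and pectinate
muscles, lobes, non-circular cross-sections, real PV branching, and the
anatomical variability of the chamber itself. Passing tests on synthetic
anatomies demonstrate correctness of the algorithms and directionally
meaningful physics, not patient-level prediction.

## Segmentation choices

The SDF at a face is the weighted average of interior cone-ray lengths
(cone half-angle 60 degrees, 30 rays by default; the original SDF
formulation leaves both free). Hits whose surface normal points the same
way as the source normal are discarded; only ray lengths within one
standard deviation of the median survive; weights are inverse to the
ray-to-axis angle (clamped at 1/30 of the cone angle to keep the axial ray
finite). The cone frame is built from the face's own edges, which makes the
field exactly pose-invariant for a fixed seed.

Clustering is 1-D k-means on log-SDF (k = 4 by default: chamber, PVs,
appendage, transition), seeded deterministically from value quantiles,
followed by an iterated neighborhood vote (weight `spatialWeight`) and
splitting into edge-connected components. Because a near-uniform field
splits arbitrarily, adjacent regions whose mean log-SDF differs by less
than `mergeTol` (0.3 log units) are merged back — a uniform sphere ends up
a single region, while chamber/appendage contrasts (typically > 1 log
unit) survive. The chamber is the modal region; regions touching PV or MV
port rims are absorbed into it; the appendage is the largest remaining
connected complement component adjacent to the chamber (or the one holding
a user hint point — the explicit stand-in for the anatomical-position rule,
which cannot be operationalized without an atlas). Candidates below
`minAreaFrac` (2%) of the surface are ignored so transition slivers are
never mistaken for an appendage.

## Grafting choices

ICP alternates nearest-neighbor matching with the closed-form Kabsch fit
(optionally the Umeyama uniform scale), initialized by centroids and
principal axes. Rim-only registration cannot see which side of the ostium
plane the appendage should occupy; if the apex lands inside the chamber the
donor is rotated by pi about an in-plane rim axis and re-refined. Donors
are *not* scaled by default: the donor's geometry report stays intact and
the ostium-size mismatch is absorbed by the seam strip. The seam is a
greedy zipper triangulation between the two rims (advancing whichever side
yields the shorter new edge), validated by a twist check — if the median
angular mismatch of seam spokes about the rim axis exceeds 60 degrees the
seam would bow-tie and the graft aborts. A 2-ring band around the seam is
relaxed by Laplacian smoothing (3 sweeps, relaxation 0.4); everything
outside the band is bitwise identical across all composites built from one
template.

## Volume meshing

No tetrahedral meshing library is available in this R stack, so
`tetrahedralize` is self-contained: a background lattice is classified
against the watertight surface (parity ray casting; outside points within
half a cell of the wall are annexed), interior cubes are split into six
Kuhn tetrahedra (conforming across cubes), the outer vertex layer is
snapped onto the surface, and snapping is rolled back locally where a
tetrahedron would drop below 2% of the cube volume (slivers would poison
the lumped-mass projection). Boundary faces inherit the patch of the
nearest input face, except that faces nearly tangential to a port cap
(normal alignment below 0.6) are reassigned to the wall so port areas stay
faithful. Disconnected pockets (possible behind thin necks) are dropped.
The unit cube meshes exactly; smooth shapes converge as O(h^2) in volume.

## The flow model

Blood is incompressible and Newtonian: density 1.06 g/cm^3, dynamic
viscosity 0.035 poise (CGS throughout; velocities in cm/s, flowrates in
ml/s). The AF boundary-condition system is:

- **Mitral outflow** Q^O(t): a periodic waveform with a zero systolic
  plateau (valve closed) and a half-sinusoid E wave; the A wave is absent,
  as in AF. Defaults: period T = 0.8 s (75 bpm), peak 160 ml/s, valve open
  from 0.35T to 0.95T, giving a stroke volume of about 49 ml. The source
  waveform's numeric parameters are not published, so all four numbers are
  configurable assumptions.
- **PV inflows** from mass balance: Qtot = -Q^O - dV/dt is split across the
  four PVs proportionally to their sectional areas, minus each section's
  wall flux (`pvFlowSplit`); the lab-frame balance closes exactly by
  construction. Inlet profiles are flux-exact plugs (parabolic optional).
- **Wall motion**: every wall vertex oscillates along its outward normal as
  a 4 Hz sinusoid times an independent uniform(0,1) factor, amplitude
  0.1 mm — the irregular, strongly reduced AF contraction. The amplitude is
  far below the cell size, so the ALE treatment is quasi-static: operators
  are assembled once on the reference mesh; the harmonic extension of the
  boundary displacement is separable (sin(2 pi f t) times a static mode),
  and the mesh velocity enters only the advective transport and the flux
  bookkeeping.
- **Backflow penalization** at the MV: the explicit boundary term
  beta * min(u.n, 0) * u (beta = 0.2) damps energy influx when flow locally
  re-enters the open outlet.

The solver is a Chorin-style incremental pressure projection on P1
tetrahedra with lumped mass: advection is semi-Lagrangian with BFECC
(back-and-forth error compensation — three interpolation sweeps, clamped to
the pre-step range), which is unconditionally stable at dt = 0.005 s and
far less diffusive than a single first-order sweep; viscosity is implicit
(one Cholesky factorization reused across all steps); the pressure Poisson
solve (factorized once) is applied twice per step because the lumped-mass
velocity correction removes only part of the weak divergence per pass. The
residual global mass defect is then closed exactly by a uniform
normal-velocity adjustment on the free outlet nodes — the flow-rate
correction customary at natural outlets; both the raw and the closed defect
are recorded per step in the flowrates history. Runs cover five cardiac
cycles (800 steps) by default so the unphysiological initial condition has
washed out by the reported fifth cycle.

Verification: steady tube flow reproduces the analytic parabolic profile
(centerline velocity within 5% at about 2 x 10^4 tetrahedra); zero forcing
stays exactly at rest; kinetic energy decays in the unforced limit;
halving dt changes the section-velocity trace of a pulsed tube benchmark
by about 1% in L2. Known limitation: at desk lattices (h ~ 0.24 cm), plug
inlets entering 3–4-cell-wide tubes produce locally exaggerated velocities
in the first cells off the PV caps; these artifacts are confined to the
inlet necks, far from the appendage.

## Stasis metrics

The Q-criterion is computed from the cell-constant P1 velocity gradient.
Two conventions are offered: the *printed* one, S_ij = g_ij + g_ji and
W_ij = g_ij - g_ji with Q = (W:W - S:S)/2 (so solid-body rotation at rate w
gives Q = 4 w^2), and the *standard* one with the 1/2 inside S and W, which
is exactly a quarter of it. The sign pattern — hence the set of Q > 0
vortex regions — is identical, so the choice is cosmetic and the printed
form is the default.

The ostium velocity trace is the area-averaged normal velocity on a
triangulated disc spanning the grafted rim, oriented so emptying is
positive; the trace flags a peak emptying velocity below the 20 cm/s
washout threshold used clinically. For a nearly rigid blind pouch the
*net* ostium flux is tiny (it equals the appendage volume rate), so
area-averaged traces sit in the 0–2 cm/s range at this scale; exchange is
recirculatory.

Residence: 500 passive tracers are seeded uniformly in a sphere about the
centerline midpoint (radius 0.8x the local wall clearance — no seeding
radius is prescribed anywhere) and advected through the stored velocity
series by RK4 (linear interpolation in space and time). Wall exits are
projected back inside (a tangential slide); MV exits freeze the particle as
departed. Counts at cycle ends use instantaneous membership in the closed
appendage by default — re-entry is allowed; a `first-exit` mode drops a
particle permanently at its first exit. Counting at the ends of cycles 3,
4 and 5 mirrors the published reporting; `residualFraction` reports
100 * count / n0 to one decimal.

## Numerical and design notes

- Coordinates are cm everywhere; the geometry report is invariant under
  rigid transforms exactly for V, A_s, A_o, P_o, and to lattice accuracy
  (a few %) for L and chi, because the centerline lives on an axis-aligned
  interior lattice (edge weight length/clearance, endpoints at the ostium
  barycenter and the geodesically farthest surface point).
- Orifice area is the shoelace area of the rim projected onto its
  least-squares plane (the minimal-surface alternative is not used); a
  self-intersecting projection falls back to the barycentric cross-product
  sum, with a message.
- Tube self-intersection is rejected via centerline clearance (non-adjacent
  stations must be separated by more than the sum of local radii, and the
  tube radius must stay below the local curvature radius) — a sufficient
  embedding condition for swept tubes that avoids all-pairs triangle tests.
- Cluster count k, cone parameters, smoothing iterations (10, relaxation
  0.5) and the solver's beta are exposed configuration with the defaults
  above; none of them is prescribed by the application domain.
- Resolution tiers: `test` (lattice 0.34 cm, ~1.5 x 10^4 tets, 2 cycles)
  for fast checks; `desk` (0.24 cm, ~4.5 x 10^4 tets, 5 cycles) for
  results — the directional washout experiment runs two models at the desk
  tier with 500 tracers over three seeds. The clinical-resolution regime
  (10^6+ elements) is documented but out of scope on a desktop.

## What the directional experiment shows

Two synthetic models sharing one template — a short, straight, wide-mouthed
appendage (chi < 0.1) versus a long, tortuous, narrow one (chi > 0.3) — are
simulated for five cycles and their fifth-cycle residual fractions
compared. The tortuous appendage retains more tracers in every seed: deep
particles in a narrow curved lumen are beyond the reach of the
ostium-driven recirculation, while the wide straight pouch exchanges
freely. This reproduces the *direction* of the published patient contrast
(the long tortuous appendage retained 33.6% versus 11.6% for the short
straight one); the absolute fractions at desk resolution are higher than
the published ones because coarse lattices under-resolve the ostium shear
layer that drives washout. That bias is expected and documented — the claim
tested is ordinal, not quantitative.
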