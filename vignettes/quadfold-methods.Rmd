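---
title: "Methods: path collective variables, biased sampling and free-energy analysis in quadfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: path collective variables, biased sampling and free-energy analysis in quadfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadfold)
```

quadfold is a desk-scale implementation of the computational protocol used in
enhanced-sampling studies of parallel DNA G-quadruplex (GQ) folding. The
production version of this protocol runs on explicit-solvent MD engines over
microseconds and many replicas; quadfold reproduces the *algorithms* — the
metrics, the collective variables, the band optimizer, the biasing and
reweighting machinery, and the path analysis — and exercises them on toy
landscapes and synthetic structures where every answer can be checked against
an analytic or brute-force reference. This vignette records the models, the
parameters that matter, and the design decisions taken where the protocol
leaves freedom.

## Structural metrics

**Kabsch RMSD.** `kabsch_rmsd()` computes the minimum mass-unweighted RMSD
over proper rotations and translations via SVD of the covariance matrix with
the usual determinant correction. The default atom mask is all non-hydrogen
solute atoms, the same mask used for NEB neighbor fitting. Two-point
selections are handled by exact segment alignment; one point has no defined
superposition and errors.

**eRMSD.** Cartesian RMSD is insensitive to the local rearrangements —
stacking and pairing — that dominate nucleic-acid folding intermediates.
`ermsd()` implements the base-arrangement metric: each base gets a local
frame from the C2/C4/C6 triangle of its six-membered ring (origin at the
centroid; in-plane axes toward C2/C4 with the traversal sense swapped between
purines and pyrimidines so paired bases produce consistent relative
geometry); inter-base displacement vectors are expressed in the first base's
frame and rescaled anisotropically by (5, 5, 3) Å, reflecting the ellipsoidal
reach of base-base interactions; each rescaled vector maps to a 4-component
G-vector that vanishes smoothly at the rescaled cutoff 2.4; the metric is the
root-mean-square G-vector difference over ordered base pairs, normalized by
the number of bases. These constants are exposed in `metric_spec()`.

**Combined metric.** The pathCV milestone distance is
$d(A,B) = \sqrt{a\,\mathrm{RMSD}^2 + b\,C\,\varepsilon\mathrm{RMSD}^2}$ with
$a = 0.5$, $b = 2$ and $C = 1\,\mathrm{Å}^2$ bridging the units. The
prefactors make the conventional similarity cutoffs of the two metrics —
1 Å RMSD and 0.5 a.u. eRMSD — contribute equally ($0.5 \cdot 1^2 = 2 \cdot 1
\cdot 0.5^2$). The protocol's inline form can be read as the sum or its
square root; we return the square root so the combined metric carries
distance units and can serve directly as a milestone distance. The
equal-contribution property is invariant to this choice.

## Path collective variables

A transition is described by an ordered milestone set $X_1 \dots X_N$ with a
distance metric. The progress coordinate and orthogonal distance are

$$s(X) = \frac{\sum_i i\, e^{-\lambda d_i^2}}{\sum_i e^{-\lambda d_i^2}},
\qquad
z(X) = -\tfrac{1}{\lambda}\ln \sum_i e^{-\lambda d_i^2},$$

with $d_i = d(X, X_i)$. Distances enter squared, so for structural metrics
$z$ is in Å² — the units of the restraint wall below. Both sums are
evaluated with a log-sum-exp shift; if even the nearest milestone's weight
would underflow the naive sum, the evaluation errors with advice to reduce
$\lambda$ (the value would be numerically meaningless there).

Decisions:

* **Padding** (`pad_path()`): one linearly extrapolated milestone before the
  first and after the last ($2X_1 - X_2$, $2X_N - X_{N-1}$), so the physical
  endpoints sit in the interior of the index range and are sampled with the
  same weight as any other milestone. A 40-milestone path becomes 42, a
  73-milestone path 75.
* **λ selection** (`select_lambda()`): the protocol never states its λ, so
  we adopt $\lambda = \ln 2 / \overline{d^2}$ over consecutive squared
  milestone spacings — a probe halfway between neighbors retains half weight,
  keeping milestones distinguishable but overlapping. This is a package
  decision, not a protocol value; no numeric claim about s/z on real
  milestone sets is reproducible from the protocol's description, and tests
  pin s/z to the defining sums instead.
* **Normalization**: with `normalize = TRUE` the progress is rescaled so
  evaluation *at the terminal milestones* gives exactly 0 and 1 (not an
  index-range rescale, which would leave endpoint evaluations offset by the
  soft-min tails). Property-map components use this convention.
* **Abstract points**: milestones may be plain numeric vectors with
  Euclidean distance, so 2D toy landscapes exercise the same code paths as
  structural milestones.

## Nudged elastic band

`optimize_band()` converges a chain of images to a minimum-energy path over
a pluggable `energy_provider()`. The tangent at each interior image is the
improved (Henkelman–Jónsson) estimate — forward/backward difference on
monotone stretches, energy-weighted mix at extrema — which prevents the
kinks of the naive bisector tangent. The NEB force combines the
perpendicular component of the true force with a parallel spring force
(default 5 kcal mol⁻¹ Å⁻², the production value). Structural bands support
partial-NEB masks: NEB forces act on the moving mask, and
`rms_fit_neighbors()` sequentially superposes each image onto its
predecessor over the fit mask to remove rigid-body drift.

The production protocol optimizes bands by thermostatted MD; at desk scale
we use deterministic damped descent (quick-min velocity projection, or plain
steepest descent via `step_rule`), which shares the same stationary points
and makes tests bit-reproducible. The climbing-image variant is available as
a flag and off by default; it is used when the saddle energy itself is the
quantity of interest (e.g. the Müller–Brown benchmark, where the highest
image converges onto the saddle at −40.665). Default force tolerance is
10⁻³ kcal mol⁻¹ Å⁻¹ on toy landscapes; endpoints are held fixed.

## Biased sampling

`langevin_step()` is a reference BAOAB integrator at unit mass; with zero
friction it reduces to velocity Verlet. Long runs use the same scheme
compiled (`run_biased_sampling()`), drawing noise from R's RNG so
`set.seed()` governs every trajectory. Replica streams derive their seeds as
`seed + offset`; since the sampler is single-threaded there is no scheduling
nondeterminism to protect against.

**Well-tempered metadynamics.** Hills of initial height $h_0$ are deposited
every `stride` steps with the damped height
$h = h_0\, e^{-V(s)/((\gamma-1)kT)}$ and accumulated on a grid (resolution
σ/5 by default at the R level). The production parameters are the defaults
of `wt_metad_params()`: $h_0 = 0.956$ kcal/mol, widths 0.4 (pathCV) and
0.4 Å² (z), bias factor γ = 35. Time is abstract: the production 50-ps
deposition stride maps onto a configurable step stride.

**Walls and restraints.** The orthogonal distance z is restrained by a
one-sided harmonic wall, zero below the onset 0.81 Å² and
$(k/2)(z-z_0)^2$ above with $k = 17.2$ kcal mol⁻¹ Å⁻⁴. The protocol states
only a "force constant"; we adopt the half-k convention $E = (k/2)\Delta^2$
(the dominant MD-engine convention) and document it prominently because the
alternative $k\Delta^2$ differs by a factor of two. The same convention
applies to the glycosidic flat-bottom restraint `dihedral_wall()`, which
penalizes the 0°…180° (syn-facing) arc harmonically from the nearer
boundary with periodic wrapping. kT at 298 K is taken as 0.5926 kcal/mol
throughout.

**REST2 utilities.** `rest2_lambda()` is $T_{ref}/T_{eff}$ and
`build_ladder()` produces a geometric effective-temperature ladder; the
298→491 K ladder ends at λ = 0.607. (The protocol's printed endpoint 0.586
for 298–509 K is inconsistent with $T_{ref}/T_{eff}$ rounding, which gives
0.5855; we implement the definition and pin tests to the 0.607 case.)
`exchange_accept()` is the Metropolis rule on cross-evaluated energies.

## Free-energy estimation

**Reweighting.** `metad_reweight()` assigns frames weights
$\propto e^{+V/kT}$. The well-tempered time-dependent offset $c(t)$ is
handled by the *final-bias convention*: each retained frame is weighted by
the final accumulated bias at its CV location, after discarding an initial
transient (default 25%). This is the simplest consistent estimator; the
instantaneous-bias column can be used instead via the default arguments.

**Binless WHAM.** `binless_wham()` pools K biased runs without
histogramming, iterating
$e^{-f_k/kT} = \sum_i w_i e^{-b_k(x_i)/kT}$,
$w_i \propto 1/\sum_k N_k e^{(f_k-b_k(x_i))/kT}$ to tolerance 10⁻⁷ kcal/mol
(cap 10⁵ iterations). K = 1 reduces exactly to reweighting. Frames with zero
density under every run are dropped with a warning (they cannot be tied into
a common scale), and runs with no overlap against any other run are flagged.

**FES grids.** `build_fes()` bins weighted samples (defaults: 50 bins/axis
in 1–2D, 40 in 3D) and sets $F = -kT\ln\sum w$, min-shifted; unsampled nodes
are masked, never zero-filled, and are impassable to the MEP search unless
an explicit energy cap is supplied. Per-node SEM comes from re-estimating
node weights on 5 contiguous frame blocks (the protocol reports SEM error
bars but no block count; 5 is the package default) and propagating
$kT\,\mathrm{sem}(w)/w$.

**Property map.** The full three-hairpin analysis projects frames onto a
three-component CV. The cited property-map formalism is not restated in the
protocol; we read each component as the *normalized pathCV progress along
that hairpin's milestone path* (`property_map_spec()` +
`project_property_map()`), which reproduces the endpoint anchoring the
folding cube requires. This reading is a documented decision.

**Restraint correction.** The z-wall biases minima whose unrestrained
ensembles extend beyond the onset. From restrained-ensemble samples,
`restraint_correction()` returns
$\Delta\Delta G = -kT \ln \langle e^{+U_{wall}(z)/kT}\rangle_r$, the
free-energy change of releasing the wall, to be *added* to the restrained
minimum's free energy. It is ≤ 0 — relaxation can only open configuration
space — which stabilizes broad off-path states (e.g. cross-strand
ensembles) relative to the walled estimate; the sign convention is
configurable in the caller's bookkeeping if the opposite convention is
preferred.

**gHBfix accounting.** The folded GQ is supported by native H-bonds that an
external per-bond stabilization term strengthens by a fixed increment.
`ghbfix_shift()` performs the bookkeeping
$\Delta G_{without} = \Delta G_{with} + n \cdot \delta$: with
ΔG = −9 kcal/mol, 24 native bonds and δ = 0.5 kcal/mol the unfixed estimate
is +3 kcal/mol. Only this arithmetic is in scope; the potential itself is an
MD force-field term.

## Folding cube and minimum-energy paths

Sequential folding of n hairpin coordinates spans an n-cube: $2^n$ states,
$n\,2^{n-1}$ single-coordinate folding steps, $n!$ monotone pathways (8/12/6
for the full GQ, 4/4/2 for the triplex). Vertex labels render unfolded
coordinates as "s" and folded ones by a caller-supplied character, because
folded coordinates may carry cross (C) or Hoogsteen-hairpin (H) character
that the binary tuple cannot distinguish.

`dijkstra_mep()` searches the FES lattice over face neighbors (no
diagonals — standard lattice-MEP practice). The protocol does not state its
edge-weight construction, so both natural modes are implemented:
**minimax** (default), minimizing the highest free energy touched — the
physically meaningful "lowest highest point" — with ties broken by the
smaller path sum and then node order; and **integrated**, minimizing the sum
of node free energies. Both are verified against exhaustive enumeration and
an independent threshold-connectivity characterization on small grids; the
acceptance surfaces are built so the two modes agree on the barrier.
`sector_mep()` chains per-edge searches, confining each folding step to the
grid sector spanned by its cube edge, and returns one concatenated path that
visits the pathway's vertices in order.

## The synthetic-data generators, and what passing tests show

`generate_strand()` builds idealized planar-base strands (B-form-like
stacked helix: 3.4 Å rise, 30° twist; or an extended chain), with the ring
atoms, glycosidic quadruples and guanine O6/N7 acceptors the metrics and
observables need, plus a 0.02 Å seeded jitter to avoid exact degeneracies.
`perturb()` adds seeded Gaussian noise. The two-channel toy surface
(`ep_two_channel()`: mean channel barrier A = 5 kcal/mol, channel split
δ = 1, inter-basin tilt ε = 0.75, channel separation C = 1) emulates the
kinetic-partitioning motif of GQ folding — two basins connected by
competing channels of unequal barrier — at a size where the exact FES is
computable by quadrature.

These generators emulate the *geometry and topology* the algorithms must
handle: they do not emulate force-field energetics, solvent, ions, backbone
substates, or the timescale separation of real GQ folding. A passing test
shows the estimator or search is correct on a landscape where the truth is
known; it says nothing about force-field accuracy or sampling convergence of
microsecond MD.

## Numerical choices and toy-run calibrations

* Workflow problem sizes (chosen as desk-scale defaults): 21 NEB images per
  channel, 61×61 pathCV lookup tables, 4×10⁵ Langevin steps per
  metadynamics run, 42×42 FES bins. The toy metadynamics runs use
  h₀ = 0.15 kcal/mol, σ_s = 0.6 (in milestone-index units), γ = 8,
  stride 250 — scaled to the toy landscape's barrier heights and diffusion
  time, since the production values (h₀ = 0.956, γ = 35) are calibrated for
  a solvated biomolecule sampled for microseconds and would leave a
  hill-sized ripple on a desk-scale run. The double-well recovery exercise
  uses h₀ = 0.1, σ = 0.15, γ = 8, stride 200 for the same reason.
* Well-tempered FES estimates average the bias over snapshots spanning the
  final half of the deposition history, the standard remedy for
  hill-by-hill ripple.
* WHAM tolerance 10⁻⁷ kcal/mol on run free energies; weight normalization
  asserted to 10⁻¹⁰ after every estimator.
* Degenerate inputs: amplitude-0 perturbation returns its input; empty
  H-bond pair lists count 0; structures without ion records coordinate 0
  ions (not an error); empty FES bins are masked; single-node MEP profiles
  have barrier 0.
* Tie-breaks in the MEP search are deterministic (path sum, then node
  order), so repeated runs give identical paths on degenerate surfaces.

## Known limitations

* No explicit-solvent MD, no force-field energetics, no actual REST2
  Hamiltonian scaling of a solute — the ladder and acceptance utilities
  handle the bookkeeping only.
* The absolute folding free energies and barriers of the production study
  (−9 kcal/mol; 10–13 kcal/mol third-hairpin barriers; 0.3/3.1 kcal/mol
  restraint corrections) require cluster-scale ensembles and are out of
  scope as numeric targets.
* eRMSD assumes identical base-annotated residue lists; there is no
  sequence alignment or symmetry-corrected RMSD.
* The compiled sampler supports 1D metadynamics on one CV with a wall on z;
  the R-level `deposit_hill()` supports 2D hill grids for algorithmic tests,
  but the long-run engine does not deposit 2D hills.
* Hydrogens are not placed; geometric H-bond checks fall back to the
  distance criterion when a pair names no hydrogen.
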