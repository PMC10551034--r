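---
title: "Free-energy profiles along path collective variables: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy profiles along path collective variables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathFE)
```

pathFE turns a rough "guess" trajectory of a ligand leaving its receptor
into a quantitative free-energy profile, and then improves the guess. The
pipeline has four stages: (1) project snapshots into a six-dimensional
anchor-based descriptor space, (2) build a path there and measure progress
along it with a metric-corrected path collective variable, (3) sample the
path with harmonic umbrella windows and integrate the profile with WHAM,
and (4) relax the path toward the minimum free energy path (MFEP) with an
adaptive string method. This vignette explains the models behind each
stage, the tunable parameters, and what the built-in toy systems do and
do not establish.

## The six anchor-based collective variables

The relative position and orientation of two rigid-ish bodies is fully
described by six coordinates. pathFE builds them from three anchor points
per species -- geometric centers of user-chosen atom groups
$P_1,P_2,P_3$ on the receptor and $L_1,L_2,L_3$ on the ligand:

* $d = |P_1 - L_1|$ (Å), the separation;
* $\theta_A = \angle(P_2,P_1,L_1)$ and $\theta_B = \angle(P_1,L_1,L_2)$
  (rad), the two polar angles;
* $\varphi_A = \varphi(P_3,P_2,P_1,L_1)$,
  $\varphi_B = \varphi(P_2,P_1,L_1,L_2)$,
  $\varphi_C = \varphi(P_1,L_1,L_2,L_3)$ (rad), three dihedrals with the
  IUPAC sign convention, computed in the numerically stable atan2 form.

This is the standard six-degree-of-freedom construction used for
restrained binding free-energy calculations; its configuration measure in
the rigid limit is $d^2 \sin\theta_A \sin\theta_B$, which the brute-force
oracle below uses. Anchor groups should be chosen so the two triangles
are roughly equilateral and insensitive to thermal noise;
`anchorFrame()` rejects nearly collinear triples (minimum angle 10° by
default) and warns when a triangle's side ratio exceeds 1.5. All
derivatives are analytic: `cvJacobian()` distributes each anchor-point
gradient uniformly over its group members, and the CV-space metric
tensor is $M = J W J^\top$ with unit weights by default (inverse-mass
weighting is available but not the default, since the anchor definition
already makes the CVs geometric rather than inertial quantities).

## The metric-corrected path collective variable

A path is an ordered set of $N$ nodes in CV space. Distances mix a
length with angles, so raw Euclidean distance is meaningless; pathFE
measures displacements with the quadratic form
$\|\Delta\|^2 = \Delta^\top M^{-1} \Delta$ (dihedral components wrapped
into $(-\pi,\pi]$), where $M^{-1}$ is the pseudo-inverse of the metric
frozen into the path at construction. Per segment the inverse metric is
taken from the mean of the two endpoint metrics rather than switching at
the segment midpoint: this keeps the bias force continuous within a
segment and conservative, at the cost of a slightly coarser metric
interpolation. One internal distance helper isolates this choice.

Progress and off-path distance are defined by clamped per-segment
projection blended with softmin weights: each segment $i$ yields a
clamped projection fraction $t_i$ and squared distance $D_i^2$, and

$$ w_i \propto e^{-\lambda D_i^2 / D^2_\mathrm{min}}, \qquad
   s = \sum_i w_i \frac{i - 1 + t_i}{N-1}, \qquad
   z = \Big(\sum_i w_i D_i^2\Big)^{1/2}. $$

The construction is exact at the nodes, smooth between segments, and
reduces to plain Euclidean projection when $M$ is the identity and the
point is within a fraction of a node spacing of the path -- the regime
umbrella confinement keeps the system in. $\lambda$ defaults to 4.6, so
a segment one node-spacing farther than the best one receives weight
0.01. Points metrically beyond the terminal nodes saturate at exactly
$s = 0$ or $s = 1$. Gradients of $s$ and $z$ are analytic, including the
softmin and clamping terms, so bias forces follow by the chain rule
through the CV Jacobian.

Building a path from a human-generated guess trajectory uses three
steps: a backtracking filter that greedily keeps frames advancing by at
least (total length)/(4 N) and drops frames revisiting the neighbourhood
of earlier kept frames (human trajectories pause and wobble); cubic
smoothing-spline regression of each CV component against cumulative
metric arc length; and resampling to $N$ nodes equally spaced in arc
length. The series endpoints become the first and last nodes, except
that a trailing backtrack is dropped in favour of the farthest point
reached. Reparameterization -- used every string iteration -- moves
nodes along the current polyline to equal arc-length fractions, leaving
endpoints fixed; equality is exact along the parent polyline, while
chord-measured gaps agree to within about a percent for smooth paths.

## Umbrella sampling

Windows are centered uniformly on $s \in [0,1]$ and biased by
$\tfrac12 k_s (s - s_0)^2 + \tfrac12 k_z z^2$. The $z$ term is identical
in all windows and is treated as part of the system: the profile WHAM
recovers is that of the tube-confined ensemble, and the brute-force
oracles integrate exactly the same ensemble. Defaults and their
rationale:

* `kS = kT / spacing^2`, so the unbiased width of a window roughly
  equals the window spacing and neighbouring histograms overlap.
* `kZ` has no universal default; the toy studies use
  20 kcal/mol per metric-unit$^2$, giving a transverse tube of width
  $\sqrt{kT/k_z} \approx 0.17$ metric units. Tighter tubes equilibrate
  faster and suppress the transverse entropy the profile would otherwise
  have to sample; the oracle uses the same value, so the comparison is
  exact either way.
* The bias ramps linearly from zero over `rampSteps` (the analog of the
  paper-style 1-ps equilibration); the ramp period is the burn-in and is
  discarded. Production samples of $(s, z)$ and the bias energy are
  recorded every `stride` steps.

The integrator is BAOAB Langevin dynamics; with zero friction it reduces
to velocity Verlet (energy-conservation tests run in that limit). Toy
systems use natural units: unit masses, energies in kcal/mol, lengths in
Å, $k_B T = 0.59616$ kcal/mol at the 300 K convention, friction
$\gamma = 1$ per time unit and $\mathrm{d}t = 0.012$ (the stiff guest
bond network, $k = 300$ kcal/mol/Å$^2$, sets the stability limit).
Per-window seeds derive deterministically from a master seed; a window
rerun from its seed is bitwise identical, and campaigns persist each
window to CSV so an interrupted campaign resumes where it stopped.

The host-guest sampling runs through a compiled kernel (BAOAB, CV
geometry, pathCV bias in C++) that draws from the same RNG stream as the
plain-R engine; the two are cross-checked per seed in the test suite,
and the R engine remains the reference for all CV-space toys and the
restrained-host variant.

## WHAM

The profile is integrated by the standard self-consistent weighted
histogram iteration over uniform bins on $s$, converging on the window
offsets $f_i$ to $10^{-8}$ kcal/mol. Bins never visited remain `NA` --
deliberately not interpolated, since silent interpolation hides exactly
the overlap failures the workflow is meant to expose; windows whose
histograms share no bin raise a connectivity error naming the gap. The
profile is reported with min $F = 0$. Uncertainties come from a
moving-block bootstrap (blocks preserve autocorrelation) with a full
WHAM re-solve per replicate, warm-started from the full-data solution;
`bootstrapProfileStats()` propagates the replicates through
`profileStatistics()` to give $\sigma$ for the unbinding free energy
$\Delta F$ (mean over the unbound region minus the bound minimum) and
the barrier height.

Two practical notes. First, the end windows of any campaign straddle the
path termini, so their saturated samples pile into the first and last
bins; comparisons against analytic references exclude those bins and
align profiles by their mean offset (free energies are defined up to a
constant). Second, profile comparisons across campaigns use the bin
count as the resolution unit -- positions are "within $k$ bins".

## Adaptive string method

Mean forces are estimated by restrained sampling: holding the CVs at a
node with harmonic restraints $k_\mathrm{node}$ and invoking linear
response, $-\nabla F \approx k_\mathrm{node}(\langle \mathrm{cv}\rangle -
\mathrm{node})$, with standard errors from ten block averages. Each
iteration moves interior nodes by `stepSize` times the metric-
preconditioned force $M^{-1}f$ projected perpendicular to the local
tangent (in the $M^{-1}$ inner product), lets the endpoints relax along
the full force so they find the free-energy minima, and
reparameterizes. Convergence is declared when the mean RMS node
displacement over a trailing window falls below a tolerance. The
per-node metrics stay frozen at their construction values -- the
standard simplification that keeps the preconditioner cheap and the
dynamics of the string well-defined; for large node excursions the
metric becomes stale, which is a known limitation. The step size is
fixed (no line search); on the four-Gaussian 2-D benchmark a straight
string between the two deepest minima converges in roughly 60
iterations to a path through the saddle.

## Toy systems and their oracles

* **1-D double well** $V = \Delta E\,((x/h)^2-1)^2$: in one dimension
  the free energy *is* the potential, so WHAM output can be compared to
  a closed form.
* **2-D four-Gaussian benchmark** (the classic string-method test
  surface): minima and saddles are located at construction by BFGS plus
  Newton polishing on the analytic gradient/Hessian, giving
  machine-precision stationary points without hard-coding them.
* **Cartesian host-guest complex**: a frozen equilateral three-atom host
  and a rigid hexagonal six-atom guest (stiff bond network; ligand
  anchor groups are genuinely multi-atom). The interaction is a function
  of the CVs alone: a Morse well in $d$ ($D_e = 8$ kcal/mol, $d_0 = 3$
  Å, $a = 1.5$ Å$^{-1}$), a Gaussian exit bump in $d$ (3 kcal/mol at 5
  Å, width 0.4 Å) so an unbinding barrier exists, and harmonic terms in
  $\theta_A$ and $\varphi_B$ (5 kcal/mol/rad$^2$). Because the guest is
  rigid and the interaction separable in the CVs, the profile along any
  path can be computed independently by direct Boltzmann integration
  over the six rigid-body coordinates with the exact measure
  $d^2\sin\theta_A\sin\theta_B$: a seeded importance sampler with a
  Gaussian tube proposal around the path, with proposal widths matched
  per CV to the curvature-plus-confinement precision. 1-D and 2-D
  oracles use dense grid quadrature instead.

Synthetic guess trajectories script three pulling styles -- `direct`
(straight out, favourable orientation), `detour` (angular excursion,
same endpoints), and `bad_orientation` (an unfavourable $\varphi_B$
rotation held through the exit) -- plus seeded Gaussian CV jitter
imitating human pauses and wobble. By construction the bad-orientation
barrier exceeds the direct one, and string refinement should recover
most of that difference; both orderings are asserted by the tests.

## Study conditions used by the tests and the acceptance script

All end-to-end numbers are computed at desk scale with fixed conditions:
56 umbrella windows (dense coverage of the steep Morse wall), default
`kS`, `kZ = 20`, a 500-step ramp, 20000 production steps per window for
full campaigns and exactly 1% of that for the short-sampling
comparison, 50 bins, guess-trajectory jitter $\sigma = 0.03$; the 1-D
harmonic WHAM validation uses 12 windows of 8000 steps, and the
refinement comparison uses 32-window, 5000-step campaigns on 12-node
paths. The short campaign must still span several correlation times of
the window dynamics ($\tau \approx 30$ steps here), which is what sets
the full-campaign length.

## What the toys do and do not show

The fixtures exercise every contract the real workflow relies on --
geometric consistency of CVs and Jacobians, path projection against
brute-force oracles, WHAM against analytic surfaces, refinement against
independently located stationary points -- under exactly known
energetics. They do not emulate solvent, receptor flexibility beyond
harmonic restraints, rugged landscapes with many competing basins, or
anchor-group choices that deform under thermal motion. Passing tests
therefore validates the machinery, not the convergence of any particular
real protein-ligand campaign; for real systems the same diagnostics
(window overlap, bootstrap uncertainty, short-vs-long consistency,
path-to-path spread of $\Delta F$) are the intended convergence checks.

## Numerical choices

Degenerate geometry (three collinear dihedral points, $\sin <
10^{-6}$) raises errors naming the CV and frame. Pseudo-inverses of
metric tensors floor eigenvalues at $10^{-12}$ (string preconditioning:
$10^{-8}$) of the largest. The softmin guards the on-path limit
($D_\mathrm{min}^2 \to 0$) by zeroing the weight derivatives of
negligible-weight segments. WHAM fixes the gauge $f_1 = 0$; profile
normalization subtracts the minimum over defined bins. Window
initialization resolves ties toward the lower frame index. All file
formats are plain text (PDB/DCD via bio3d, JSON paths, CSV samples and
profiles, YAML anchors and configs) with 0-based atom indices in every
artifact file.
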