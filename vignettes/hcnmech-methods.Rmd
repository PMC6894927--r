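---
title: "Models and methods in hcnmech"
author: "hcnmech authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hcnmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcnmech)
```

`hcnmech` analyses the mechanical coupling between the C-linker gating
ring, the HCN domain (HCND) and the voltage-sensor domain (VSD) of HCN
channels. This vignette explains the models the package implements, the
parameters that matter and their defaults, what the synthetic generators
do and do not emulate, and the numerical and design choices a maintainer
would want spelled out.

## The anisotropic network model and linear response

A structure is reduced to one bead per residue at the C-alpha position
(`readStructure()`), preserving author chain labels and residue numbers so
that selections can be written in the numbering the literature uses. Beads
closer than a distance cutoff are joined by Hookean springs. For a
contacting pair $(i, j)$ at distance $d_{ij}$ with spring constant
$\gamma_{ij}$, the off-diagonal $3 \times 3$ block of the Hessian is

$$ H_{ij} = -\frac{\gamma_{ij}}{d_{ij}^2}\, \mathbf{r}_{ij}
   \mathbf{r}_{ij}^\mathsf{T}, $$

and diagonal blocks are minus the sum of the row's off-diagonal blocks, so
every super-row sums to zero (translation invariance). The full symmetric
eigendecomposition is stored. For a connected network exactly six
eigenvalues are numerically zero (rigid translations and rotations); a
mode counts as rigid when its eigenvalue is below $10^{-8}$ of the largest,
and a structure whose contact graph has more than one component triggers a
disconnection warning with the component count.

The static displacement response to an external force $\mathbf{f}$ is the
mode sum over non-rigid modes,

$$ \mathbf{u} = \sum_{m:\ \lambda_m > 0}
   \frac{\mathbf{v}_m^\mathsf{T} \mathbf{f}}{\lambda_m}\, \mathbf{v}_m, $$

i.e. the Moore–Penrose pseudo-inverse of the Hessian applied to the force.
Excluding the rigid modes makes the response free of net translation and
rotation by construction. The response is exactly linear in the force
magnitude, and the test suite verifies reciprocity
($\mathbf{f}_j \cdot \mathbf{u}_{i \to j} = \mathbf{f}_i \cdot
\mathbf{u}_{j \to i}$), translation invariance and rotational equivariance
against a dense pseudo-inverse oracle.

Key parameters:

* **cutoff** (Å, default 13): contact distance. The default is the value
  used for channel-scale C-alpha networks.
* **spring model**: uniform $\gamma = 1$ by default. A pairwise
  residue-name table (`pairSprings()`) is accepted as a stand-in for
  heterogeneous parameterizations; every quantitative default in the
  package (cutoff, force count, magnitude, clustering) is independent of
  the spring table, and the directional read-outs are robust to it.
  Response amplitudes are therefore reported in arbitrary units and no
  thermal ($k_BT$) scaling is applied.
* **force magnitude** (a.u., default 1600) and **ensemble size** (default
  1000 directions): by linearity the direction results are invariant to
  the magnitude; it only scales amplitudes.
* **symmetry**: the z axis of the input frame is taken as the channel's
  four-fold axis; there is no axis auto-detection. `makeC4Perturbation()`
  places one force per chain at the same residue, with directions that are
  successive 90° z-rotations of the base direction, chains ordered by the
  azimuth of the target bead.
* **eigensolver**: dense symmetric decomposition; practical up to a few
  thousand beads, which covers channel-sized C-alpha models.

## Clustering force ensembles

Random force directions are drawn uniformly on the sphere (normalized
Gaussians) from an explicit seed. Each force's response is summarized by
the concatenated displacement of a "shoulder" selection (in the channel,
C'/D' helices, residues 446–465, over all four chains) — the clustering
variable is the displacement this force causes, not the force direction
itself. k-means uses k-means++ seeding and Lloyd iterations (via
`stats::kmeans`), keeping the best of 10 restarts; the representative of
a cluster is the sample nearest its centroid, an automated stand-in for
picking a force from the cluster centre by hand.

**Elbow criterion.** The model-size diagnostic is the natural log of the
maximal per-cluster within-cluster sum of squares as a function of $k$.
A rule based on when successive drops fall below a fraction of the first
drop fails on exactly the cases it must separate: for well-separated blobs
the drop from $k$ to $k+1$ is already near zero before the true $k$
(splitting one multi-blob cluster leaves another multi-blob cluster as the
maximum), and for a single blob the drops decay smoothly without ever
satisfying it at $k = 1$. The package therefore takes the candidate
immediately after the *largest* drop, and requires that drop to be
pronounced — at least one natural-log unit (max withinss falls by a factor
$e$), configurable via `minLogDrop` — otherwise $k = 1$. On labelled
four-blob data this selects $k = 4$ with adjusted Rand index 1, on a
single blob it selects $k = 1$, and on degenerate (zero-scatter) data it
returns $k = 1$ with the log guarded. The production protocol for channel
perturbations nevertheless fixes $k = 4$ clusters, which is the
experiment's standard; `k = "auto"` switches to the elbow.

**Domain motions and matching.** For a domain selection the package
reports the mean displacement vector, its angle to the z axis
($\arccos(u_z/\lVert \mathbf{u} \rVert)$, in $[0°, 180°]$), and the mean
in-plane rotation: the signed angle, positive counter-clockwise viewed
from the extracellular side (looking down +z), between each bead's radial
position projected to the xy plane (about the structure's centre of mass)
and that position plus its displacement. Experiments at different
perturbation sites are compared by the cosine similarity of their stacked
per-domain mean displacements; given a reference motion, the best-matching
cluster is the one maximizing that cosine. For four-fold symmetric force
patterns the per-domain mean displacement is dominated by its axial
component (in-plane components cancel over the four subunits), so the
comparison effectively asks whether the same pattern of upward/downward
domain motion is elicited regardless of where the force is applied.

## Trajectory observables

`minDistanceSeries()` reports, per frame and subunit, the minimum over all
atom-pair distances between two selections — the shortest distance between
two side chains — with the across-subunit mean and an SEM band (SD
optionally). `rdf()` histograms, per target atom, the distance to the
*nearest* atom of the reference group and normalizes each bin by the
ideal-gas expectation (shell volume times bulk target density), averaged
over frames. The group-minimum convention is a choice: "distance from the
side chain" could also be read per-atom-averaged; the group minimum is
used because the first-solvation-shell read-out asks how close water gets
to any part of the side chain. Distances are plain Euclidean without a
box and minimum-image on an orthorhombic box when box lengths are present;
box-free trajectories require an explicit bulk-density override for
normalization. Binary MD trajectory formats are not parsed natively — the
package reads multi-model PDB and a whitespace frames table
(`readFramesTable()`), and coordinates can be passed directly to
`trajectoryEnsemble()` from any reader.

## Electrophysiology fits and energetics

Tail-current amplitude versus step voltage is fitted per cell with

$$ I(V) = \frac{A}{1 + \exp((V - V_{1/2})/k)} $$

by Levenberg–Marquardt least squares on the raw amplitudes with free $A$
(normalized curves are derived output, not the fitting target). Starting
values: $V_{1/2}$ from the voltage of half-maximal observed amplitude, $k$
from the 25–75% amplitude voltage span divided by 2.2, $A$ from the
maximum; $|k|$ is bounded to (0.5, 50) mV. $V_{1/2}$ is stored *signed*
(negative for hyperpolarization-activated channels) because the sign of
$\Delta G_\mathrm{app}$ depends on it; printed tables in the literature
often show magnitudes, so check the convention before comparing. Data
whose amplitudes span less than 5% of their maximum are flagged saturated
with a warning and not fitted; a fitted midpoint outside the measured
voltage range also sets the saturated flag. Mean activation parameters
average per-cell fits (not a fit to the mean curve). Kinetics are fitted
as $I = I_0 e^{-t/\tau}$ on a window, with time relative to the window
start.

Energetics: $\Delta G_\mathrm{app} = (RT/k) V_{1/2}$ with
$R = 1.987 \times 10^{-3}$ kcal/(mol·K) and $T$ defaulting to 298 K (room
temperature); $V_{1/2}$ and $k$ share units so their ratio is
dimensionless. The double-mutant cycle reports per-edge perturbation
energies $\Delta G_p$ and the non-additivity

$$ \Delta\Delta G = \Delta G_\mathrm{app}^{wt} +
   \Delta G_\mathrm{app}^{double} - \Delta G_\mathrm{app}^{s1} -
   \Delta G_\mathrm{app}^{s2}, $$

flagging $|\Delta\Delta G| > 1$ kcal/mol (configurable) as coupled. Per
construct, the default aggregation is the mean of per-cell
$\Delta G_\mathrm{app}$ values; since the cycle takes
`constructEnergetics()` objects, a fit to the mean curve can be
substituted by the caller. Group comparisons use Student's t-test for two
groups and one-way ANOVA followed — only when the ANOVA is significant at
$\alpha = 0.05$ — by Fisher's LSD pairwise tests on the pooled residual
variance, with no further multiple-testing correction; that mirrors common
practice in the field and is a documented limitation.

## What the synthetic generators emulate

Every generator is a pure function of its parameters and an explicit seed.

* `makeC4Structure()`: four exact 90°-rotation copies of a jittered
  helical bead trace — the symmetry and connectivity of a channel
  tetramer, not its fold.
* `makeCoupledAssembly()`: a sliding-crank toy. A double-layered gating
  ring (the clustering shoulder, 32 beads) is contacted by four zigzag
  arms whose azimuth advances with height (50° over the arm), so the
  assembly's softest four-fold symmetric mode converts planar ring
  rotation into vertical arm displacement. That slant is the design's
  load-bearing feature: with straight vertical arms the collective twist
  produces almost no net domain displacement and near-degenerate local
  arm-bending modes dominate the linear response, making cross-site
  concordance an accident of the jitter seed. The severed variant removes
  the arm beads in contact with the ring (residues 104–107), splitting
  the network into ring + four arms; perturbation sites survive severing.
* Activation datasets, current traces, blobs, energy tables and solvent
  trajectories add Gaussian noise (or Poisson counts) around closed-form
  truths; the truth rides along as an attribute so tests never re-derive
  it.

What passing tests on these generators shows: the mechanics, clustering,
fitting and normalization code is correct on inputs whose answers are
known. What it does not show: that a real channel structure behaves like
the toy (real structures have heterogeneous contact topology, missing
residues, and no exact symmetry), that real recordings have Gaussian
noise (they have rundown, leak and seal artefacts the package does not
model), or that MD water obeys the ideal-gas reference outside the bulk.
The energy-table defaults place all four constructs' activation midpoints
inside the standard step-protocol range so that each synthetic activation
curve is resolvable by per-cell fitting — mirroring the experimental
requirement that a construct's midpoint be measurable with the protocol
at hand.

## Numerical choices and degenerate inputs

* Rigid-mode threshold $10^{-8} \times \lambda_\mathrm{max}$; disconnected
  networks warn (component count) and linear response then simply excludes
  every near-zero mode.
* Levenberg–Marquardt is run to tight tolerances (`ftol`, `ptol`, `gtol`
  $10^{-14}$, 500 iterations max) so the first-order condition at the
  optimum holds to numerical precision; the tests check that the residual
  vector is orthogonal to every Jacobian column to $10^{-6}$.
* k-means++ with duplicated seed points perturbs the duplicate centres by
  $10^{-9}$ to keep Lloyd iterations defined; restarts that lose a cluster
  are discarded.
* Zero mean displacement of a domain yields an undefined angle, reported
  as `NA` rather than an arbitrary value.
* `log(max withinss)` is guarded against zero scatter; the degenerate
  all-identical-points case short-circuits to $k = 1$.
* Alternate locations in PDB input resolve to the first listed atom;
  residues without a C-alpha are dropped with a warning; missing residues
  are simply absent and selections resolve over what exists.
* Multi-model PDB is the morph output format (universally viewable); the
  interpolation is linear because the morph illustrates relative
  directional movement, not physical amplitudes.

## Problem sizes

The shipped tests and the acceptance script run on toy scales chosen as
the package's standard validation sizes: bead clouds of 15–60 beads for
the Hessian/response oracles, a 116-bead coupled assembly with 1000-force
ensembles per site, 100-cell activation recovery, 150-frame solvent
trajectories at water-like density (0.0334 Å⁻³), and 20-seed clustering
replicates. The whole suite runs in well under a minute.

## Known limitations

* The heterogeneous spring table of published channel ANMs is not
  reproduced; the uniform default is a documented stand-in.
* No Gaussian (isotropic) network variant, thermal amplitudes or all-atom
  Hessians.
* Non-orthorhombic boxes and per-atom-averaged g(r) conventions are not
  implemented.
* No leak subtraction, capacitance compensation or liquid-junction
  correction on electrophysiology input; Fisher's LSD is uncorrected by
  design.
* Cluster separation is not tested for statistical significance; domain
  definitions beyond the shoulder default are user input.
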