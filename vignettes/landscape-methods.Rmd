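---
title: "Geometric landscape models of cell-fate decisions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric landscape models of cell-fate decisions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatescapes)
```

## The model

A differentiating cell is represented as a point $x = (x_1, x_2)$ in an
abstract phase space, moving under a *Riemannian-metric gradient system*

$$\dot x = -G(x)^{-1}\,\nabla F(x;\theta),$$

where $F$ is a scalar landscape potential from a small catalogue of
catastrophe-theory unfoldings, $G$ a symmetric positive definite matrix
field, and $\theta = (a, b)$ the unfolding parameters through which
extrinsic signals reshape the landscape. Attractors (local minima of $F$)
are cell states; index-1 saddles sit on the ridges between them, and their
one-dimensional unstable manifolds are the *escape routes* along which
state transitions happen. Two facts organise everything the package does:

1. **The potential alone does not fix the dynamics.** Changing $G$ leaves
   every rest point and its Morse index in place (Sylvester's law of
   inertia applied to $-G^{-1}H$), but it can reroute the unstable
   manifolds, i.e. change which attractor a transitioning cell reaches.
   The `box2_example` landscape with constant metrics having off-diagonal
   $\mp 0.6$ demonstrates this: identical rest points, different escape
   routes.
2. **Generic one-parameter decision events come in exactly two kinds**:
   a *fold* (saddle-node), where an attractor and a saddle collide and
   annihilate, and a *flip*, a global bifurcation in which a saddle's
   unstable manifold forms a momentary heteroclinic connection to another
   saddle and switches destination attractor. In a two-parameter family
   these events trace *fold curves* and *flip curves* that partition the
   parameter plane into regions of qualitatively equivalent landscapes.

Noise enters as additive isotropic Gaussian forcing of amplitude
$\sigma$ (Euler–Maruyama, fixed step). The noise is deliberately not
metric-transformed: no particular noise structure is implied by the
deterministic geometry, so the simplest dimensionless choice is exposed
as a single model field. Quantities such as a system-size parameter or a
quasi-potential are outside the package's scope.

## The potential catalogue

All built-in families are polynomial with quartic-or-higher confining
terms, so every landscape is compact (no trajectory escapes to infinity)
and derivatives are exact:

* `elliptic_umbilic`: $F = x^3 - 2xy^2 - 0.4x^2 + ax + by +
  (x^4 + y^4)/4$. The workhorse family: up to three attractors, a small
  three-cusped fold loop (deltoid) near the origin enclosing an extra
  saddle–repellor pair, and flip curves, one of which is pinned to the
  symmetry axis $b = 0$ by the $y \mapsto -y$, $b \mapsto -b$ symmetry.
* `box2_example`: the same polynomial frozen at $(a, b) = (-3, -1)$; a
  fixed tristable landscape used for metric-dependence demonstrations.
* `cusp1d`: the classical cusp unfolding $x^4/4 + a x^2/2 + bx$,
  embedded in 2D by $+\,y^2/2$. Its fold locus is the cubic discriminant
  $4a^3 + 27b^2 = 0$, which provides a closed-form accuracy check for
  the continuation code.
* `dual_cusp1d`: a sextic normal form $x^6/6 - x^4/4 + a x^2/2 + bx +
  y^2/2$. No closed form is printed for this family in the catastrophe
  literature tailored to this use, so the package fixes one whose
  bifurcation set contains a dual cusp at the origin: for
  $0 < a < 1/4$ and small $|b|$ three attractors coexist (the
  binary-choice arrangement A–P–B), and the two fold curves that destroy
  the central attractor meet at $(0,0)$, where the new attractor–saddle
  pair attaches to an existing *saddle* (the defining property of a dual
  cusp). Quantitative details of the region boundaries (for example the
  narrow bistable sliver between central and outer folds) are properties
  of this normal form, not claims about any particular figure in the
  literature.
* `flip_with_cusp`: the elliptic umbilic restricted to the parameter
  sub-box $[-0.6, 0.25] \times [-0.25, 0.25]$, which contains one fold
  curve, a cusp and a flip-curve termination.

Essentially one-dimensional families are embedded in 2D so that every
module operates on a single phase-space dimensionality.

## Numerical methods and the parameters that matter

**Rest points** are found by damped multistart Newton iteration on
$\nabla F = 0$ from a lattice over the family's domain box (default
12×12), deduplicated at $10^{-5}$ and classified by Hessian inertia.
Because a confining planar potential must satisfy the Poincaré–Hopf
relation (#attractors − #saddles + #repellors = 1), the search doubles
its lattice and retries whenever the relation fails — this reliably
recovers the small-basin repellors inside the elliptic-umbilic deltoid.
The relation check can be disabled (`strict = FALSE`) where only
attractors matter, e.g. population fate calling.

**Flow.** Deterministic trajectories use adaptive `lsodar` (tolerance
$10^{-10}$) with root functions for convergence (speed below $10^{-8}$)
and domain escape (twice the domain box). Unstable manifolds are seeded
at $\pm\,10^{-4}$ along the unit unstable eigenvector of $-G^{-1}H$ and
integrated to an attractor-proximity radius of $10^{-3}$; a branch that
stalls within $10^{-3}$ of another saddle is reported `near_saddle`,
the signature of a flip. Basin calls for single points use the same
machinery; population fate calls use a fixed-step relaxation (compiled
for the catalogue families) with a wider attractor radius of 0.02.
Cells already within a per-attractor safe radius — a fraction of that
attractor's distance to the nearest saddle, capped at 0.12 — are
assigned without relaxing; the saddle-aware cap ensures a flattening
near-fold basin never causes misassignment. The rest-point search
behind each fate call keeps the Poincaré–Hopf retry enabled: attractors
with small Newton basins (the dual-cusp centre) are otherwise easy to
miss.

**Fold curves** are continued in $(x, y, a, b)$ by pseudo-arclength
prediction with a Newton corrector on $\{\nabla F = 0,\ \det H = 0\}$
(default step 0.02, adapted on corrector failure; corrector tolerance
$10^{-11}$). **Cusps** are located at tangent reversals of the traced
curve, refined by Newton on the augmented system that appends the third
directional derivative of $F$ along the Hessian kernel, and classified
by probing rest-point censuses across a single fold branch near the
cusp: the persisting rest point closest to the newly created pair is an
attractor for a standard cusp and a saddle for a dual cusp. Probe
offsets follow the $s^{3/2}$ scaling of the cusp wedge's width with
arclength $s$, over a ladder of scales, because the wedge (and, in the
sextic family, a bistable sliver between near-parallel folds) can be
very thin.

**Flips** are located by bisection (to $10^{-6}$ in parameter space by
default) on the destination attractor of a tracked saddle branch, with
attractor identity matched by position against a fixed reference set so
that relabelling caused by potential-order changes cannot mask a
connection change. Flip curves are continued by repeated bisection on
short transverse sweeps; an endpoint is labelled `source_end` or
`sink_end` when the respective saddle's Hessian determinant falls below
a threshold (a fold is destroying it), `box_boundary` at the box edge,
and `lost` otherwise. Near strongly degenerate organising centres (the
deltoid) tracking can end `lost` a short distance from the true
termination; the curves' existence and mechanism classification are
unaffected. Whether a flip end meets its fold transversally or
tangentially is recorded only through these labels; the order of
tangency is not verified numerically.

**The atlas** scans a parameter lattice (default 22 per axis — an even
count, so lattice lines avoid symmetry axes where branch destinations
are degenerate), seeds folds where the lattice rest-point count changes,
seeds flips between equal-count neighbours whose saddle-branch
destination patterns differ, and partitions the box into lattice
components not separated by any traced curve. Regions are labelled by
attractor count, with three-attractor regions refined to `binary_choice`
(dual cusp on the boundary) or `binary_flip` (flip curve on the
boundary). Structures narrower than the lattice spacing — the
elliptic-umbilic deltoid, or the dual-cusp family's tristable wedge over
a $[-3,3]^2$ box — are not resolved as separate regions at the default
resolution; they are recovered by zooming the box, and the package's
tests do exactly that for the binary-choice label.

## Population simulation and the synthetic-data generator

`simulate_population()` evolves `n_cells` independent Euler–Maruyama
trajectories per condition (default step $10^{-2}$) under a
piecewise-linear signal path $\theta(t)$, and at each observation time
scores each cell's fate as the basin of attraction of its instantaneous
position under the frozen landscape — the alternative (proximity to an
attractor) was rejected because transitioning cells would be
unclassifiable. Cells that fail to relax onto an attractor are reported
`undecided`, never dropped. Reproducibility comes from per-condition RNG
streams derived from the master seed by a fixed affine hash; within a
condition the population is advanced as one vectorised stream rather
than per-cell streams, trading per-cell parallel reproducibility for an
order-of-magnitude faster simulator while remaining exactly reproducible
for a given seed.

`synth_dataset()` adds the finite-sampling layer of a real experiment:
multinomial resampling of each (condition, time) proportion vector at
assay size `multinomial_n`, with the generating parameters stored in the
metadata. The generator's default study conditions mirror the package's
binary-flip scenario: a progenitor population (Gaussian ball of s.d.
0.05 around the progenitor attractor) under a signal ramp that destroys
the progenitor through a fold, noise $\sigma = 0.2$, several hundred
cells, and proportions read on a grid of times straddling the fold
crossing. For fitting studies the grid is chosen so that the implied
crossing-time thresholds are spaced about 0.2 apart in the ramp target
over the prior range — the identifiability of a ramp parameter through
a basin-based fate call is limited by this threshold spacing, because
the fate table is piecewise constant in the crossing time between
observations. What the
generator does *not* emulate: cell division and death, cell–cell
signalling, measurement noise on expression levels (fates are scored
exactly), and temporal correlation of the assay. Passing recovery tests
therefore show that the inference machinery is consistent with its own
forward model, not that real fate data are this clean.

The French-flag scenario is realised in the dual-cusp family: cells
start in the central attractor and see a pulse whose amplitude ramps
monotonically (negative to positive) across the *two* fold curves that
meet at the dual cusp, destroying the centre towards the right for one
sign and towards the left for the other. Cells indexed by signal level
form three bands (R–C–L), and because the baseline landscape is
tristable the bands persist after the pulse returns to baseline. Cells
whose pulse barely crosses a fold may fail to pass the saddle before
the signal is withdrawn and fall back — the band boundaries are
therefore set by commitment dynamics, not only by the fold positions.

## Fitting by ABC-SMC

Landscape parameters are fitted to fate-proportion tables by sequential
Monte Carlo approximate Bayesian computation: generation 1 samples the
independent uniform priors with tolerance $\infty$; each later
generation resamples the previous weighted particles, perturbs with a
Gaussian kernel of per-parameter variance twice the weighted sample
variance, and accepts candidates whose distance falls below the 0.3
quantile of the previous generation's accepted distances, with standard
importance weights. The distance is the mean absolute difference of
proportions over matched (condition, time, fate) keys; tables built with
reference fate labels emit explicit zero rows so keys always align. Each
particle is evaluated with a single stochastic replicate under a seed
derived deterministically from the particle counter, which makes the
whole fit reproducible from one master seed. ABC-MCMC is deliberately
not implemented: one fully specified, seed-deterministic algorithm
covers the fitting contract. Model selection between families is also
out of scope; per-family fit distances can be compared manually.

The recovery study used in the tests fits the ramp target `a_end` and
the path offset `b_off` of the elliptic-umbilic flip scenario
(priors $[-7.5, -5.7]$ and $[-0.4, 0.4]$). `a_end` is identified through
the time at which the progenitor fate vanishes from the observation
grid, `b_off` through the committed-fate split; 200 particles and 4
generations with candidate populations of 80 cells (step 0.04) recover
both to well within a tenth of the prior width. Problem sizes
throughout the test-suite (lattice resolutions, cell counts, particle
counts) are chosen as the smallest that leave comfortable margins on
the assertions; they are stated in each test.

## Correlation signatures

For an expression matrix $g_{ij}$ (cell $i$, gene $j$) the package
reports the two Pearson statistics used to flag transitions: gene–gene
correlations $\gamma_{jj'}$ across cells (summarised by the mean
absolute off-diagonal value) and the mean cell–cell correlation between
cell vectors across genes. Cells in transit along a one-dimensional
escape route are near-collinear in gene space, which drives all defined
$|\gamma_{jj'}|$ towards 1; the accompanying claim that collinear cells
have *zero* cell–cell correlation holds only under a particular
centering convention that is not standard, so the package computes
plain Pearson correlations between raw cell vectors, offers per-gene
standardisation as an explicit option, and asserts nothing about the
raw cell–cell value for collinear data. Zero-variance genes or cells
give undefined correlations; they are flagged and excluded from
averages, never imputed.

## Degenerate inputs, tie-breaks, tolerances

* Rest-point searches at bifurcation parameters can legitimately find
  degenerate points; classification near-degeneracy is resolved by an
  eigenvalue tolerance of $10^{-9}$.
* Basin calls within $10^{-6}$ of a saddle report `undecidable` rather
  than guessing a side; saddles whose two branches reach the same
  attractor are kept in the saddle map but contribute no decision-graph
  edge (self-loops are deleted, repeats collapsed).
* The decision-topology census is enumerated by edge subsets with
  canonical-form deduplication (BLISS canonical permutations) up to five
  nodes; for six and seven nodes every graph is generated by
  single-vertex augmentation of the (n−1)-node census — every n-node
  graph arises this way — followed by the same deduplication. The test
  suite re-derives the counts with an independent minimum-bitmask
  canonicalization.
* All user-facing randomness flows from one integer seed; internal
  derived seeds use fixed affine hashes and stay below $2^{31}$.

## Known limitations

* Phase space is two-dimensional throughout. The decision-structure
  theory is dimension-agnostic, but this implementation is not.
* Flip-curve endpoint labelling is heuristic near organising centres
  (see above); `lost` endpoints are reported, not resolved.
* Atlas regions are lattice components; structures below the lattice
  scale require a zoomed box.
* The ABC layer assumes the observed table's key set is reachable by
  the simulator (use reference fate labels); it does not weight keys by
  assay size.
* Near-symmetric landscapes in which an unstable manifold passes close
  to a higher-index saddle can give integrator-sensitive branch
  destinations; the package reports what the integrator finds.
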