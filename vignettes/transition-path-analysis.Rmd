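---
title: "Transition-path shooting analysis: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition-path shooting analysis: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transpath)
```

## What the package computes

`transpath` analyses barrier crossings of elevator-type transporters — and
of toy surrogates — through four connected layers: unbiased two-segment
shooting, rigid-body structural order parameters, water-access analysis,
and committor-based reaction-coordinate optimization. This vignette is the
package's account of the underlying models, the defaults, and the
numerical decisions; everything quantitative said here is recomputed by the
test suite, not asserted from memory.

## Two-segment shooting and stitching

From a candidate transition state with positions $r$, initial velocities
$v$ are drawn from the Maxwell–Boltzmann distribution (independent
Gaussians of variance $k_BT/m$) and two trajectory segments are run, one
with $v$ and one with $-v$. Commitment is **first passage**: a segment
ends the first time the order-parameter state satisfies the A (inward-open)
or B (outward-open) predicate; segments exhausting `max_steps` are
*uncommitted* and are excluded from committor estimates. When the two
conjugate segments commit to opposite states, the A-segment is reversed in
time and prepended, giving a continuous A→B path in which the shooting
point appears exactly once; a forward segment of $n$ steps and a backward
segment of $m$ steps stitch into $m+n+1$ frames, and every inter-frame gap
— including the seam — is a single integration step.

Assumptions worth stating:

- The dynamics is stochastic (Langevin), so the conjugate segments share
  only their initial velocities; each consumes an independent thermostat
  noise stream. Exact time-reversal symmetry of realized noise is *not*
  required for the stitched path to be a genuine unbiased transition path.
- Basin predicates must be mutually exclusive; `toy_states(x_A, x_B)`
  enforces `x_A < x_B`.
- Random draws are consumed in a documented fixed order (velocities, then
  forward noise, then backward noise), so every result is a pure function
  of its seed.

The committor estimate is $\hat\phi_B = n_B/(n_A+n_B)$ with binomial
standard error. Detailed-balance path weights for the recursive scheme are
the exact rational $p_\text{new}/p_\text{old} = n_\text{old}/n_\text{new}$,
the ratio of shooting-range configuration counts; paths are stored
unweighted with the ratios recorded alongside. The shooting range is the
union of the occluded and connected access states (every transition path
must traverse it); shooting-point selection is uniform over in-range frames
when no reaction-coordinate model exists, and argmin $|Q|$ (predicted
committor closest to ½) when one does, with exact ties resolved by frame
order. Orchestration of successive shooting *rounds* (alternating
access-state and committor-targeted selection) is deliberately left to
user scripts and the CLI config rather than hard-coded: the round
structure is an experimental-design choice, not part of the method's
contract.

## The toy engine

The integrator is BAOAB: velocity Verlet with the Ornstein–Uhlenbeck
friction/noise step applied symmetrically mid-step. With friction and
temperature zero it reduces exactly to velocity Verlet; at small
$\omega\,dt$ its configurational sampling bias is $O(dt^2)$ and far below
the statistical resolution of the tests. The default toy landscape is the
symmetric 2D double well $V(x, y) = h(x^2-1)^2 + \tfrac12 k y^2$ with
$h = 5\,k_BT$ and $k = 5\,k_BT/\text{Å}^2$: the saddle at $x = 0$ is an
analytic committor-½ surface by symmetry, which anchors the acceptance
statistics without needing a reference simulation. Default engine
parameters (`dt = 0.01`, `friction = 1`, `temperature = 1`,
`max_steps = 10^4`, unit masses, engine time units) keep saddle shots
committing within a few hundred steps while leaving recrossings visible.
The blow-up guard raises an error naming the first step with non-finite
coordinates.

## Rigid-body order parameters

Frames are superposed by Kabsch least squares (SVD of the coordinate
covariance with reflection correction, determinant +1 enforced) on the
static dimerization scaffold; the transporter-domain translation is then
the difference of domain geometric centres (unweighted means — no mass
weighting) and the rotation comes from an optimal domain-on-domain fit.
The angle is $\Delta\phi = \cos^{-1}[(\mathrm{tr}\,R - 1)/2]$, defined
positive; the axis is the normalized antisymmetric part,
$(R_{32}-R_{23},\, R_{13}-R_{31},\, R_{21}-R_{12})/(2\sin\Delta\phi)$,
undefined at 0° and 180° (an error the caller may treat as "axis absent").
Relative to the inward- and outward-open references the conventions are
$\Delta\phi = (\Delta\phi_\text{in} - \Delta\phi_\text{out})/2$ and
$\Delta z = (\Delta z_\text{in} + \Delta z_\text{out})/2$, with $z$ the
membrane normal (box z-axis).

Numerical choices:

- The trace argument is clamped to $[-1, 1]$, and the arccos is evaluated
  through `atan2` with $\sin\Delta\phi$ taken from the antisymmetric part
  of $R$. The two forms are mathematically identical on $[0°, 180°]$, but
  the plain arccos of a clamped trace loses ~$10^{-6}$ degrees of accuracy
  near 0° (where $d\cos^{-1}/dx$ diverges), which would drown the
  $10^{-8}$-degree identity round-trips the tests demand.
- Collinear fit selections make the rotation non-unique; the second
  singular value is checked and a degeneracy error raised.
- Whether the domain rotation should come from a domain-on-domain fit
  *after* the scaffold alignment or from a direct domain-on-domain fit is
  genuinely open; both are implemented
  (`rotation_route = "domain_on_domain"` (default) vs `"direct"`), the
  choice is recorded in the result, and for rigid synthetic fixtures the
  two agree exactly. Angles are reported in degrees throughout.

`average_structure` superposes a trajectory window onto its first frame
before averaging, so slow drift does not smear the mean structure.

## Hydration order parameter and access states

Water access to the binding site is quantified as
$n_\text{access} = \sum_{i \in \text{water}} \sigma_r(|r_i - r_0|)\,
\sigma_z(z_i - z_0)$ with $\sigma_r(x) = 1/(1+e^{\beta(x-\alpha)})$
($\alpha = 10$ Å, $\beta = 5$ Å$^{-1}$) and
$\sigma_z(x) = (x/\gamma)\,e^{1/2 - x^2/2\gamma^2}$ ($\gamma = 5$ Å).
$\sigma_z$ is antisymmetric with extrema $\pm 1$ at $x = \pm\gamma$, so
outward-side waters count positively and inward-side negatively; a
z-mirror-symmetric water arrangement gives exactly zero. $r_0$ is the 3D
geometric centre of the configured "inside" and "gate" residues (in
fixtures, the probe atom), and $z_0$ is its z-coordinate.

The discrete access state clusters water oxygens by single linkage at a
3.0 Å cutoff under the minimum-image convention (orthorhombic boxes only),
after removing a slab that cuts the periodic bulk solvent into an inward
and an outward layer. The slab's existence is part of the method; its
width is not specified anywhere authoritative, so it is configurable with
a 10 Å default centred on the bulk mid-plane (the periodic z boundary in
the fixtures). A cluster is *inward (outward) bulk* if any member lies
within 3.0 Å in z of the retained region's lower (upper) face — a
deterministic operationalization of "bulk water". The probe atom (the
proton-carrying aspartate's carboxyl oxygen in the real system) is then
classified by the bulk character of the clusters within its 3.0 Å contact
cutoff: `inward`, `outward`, `connected` (both sides, including one
membrane-spanning cluster), or `occluded` (no bulk contact — including
contact with only non-bulk pore water). The qualitative notion of sites
connected "only by fragile water interactions" has no quantitative
definition and deliberately gets no extra rule beyond the 3.0 Å criterion.

## Reaction-coordinate optimization

Shooting outcomes enter the binomial likelihood
$\mathcal{L} = \prod_{r \to B} \phi_B[Q(r)] \prod_{r \to A}
\{1 - \phi_B[Q(r)]\}$ with $\phi_B(Q) = [1+\tanh Q]/2$ and
$Q = a_0 + \sum_i a_i q_i$. Uncommitted shots are excluded; per-point
outcome counts expand multiplicities, so each committed shot contributes
exactly one factor.

Design decisions, and why:

- **Standardization.** Descriptors are centred and scaled (empirical mean
  and s.d.) before fitting, and the constants are stored in the model.
  Coefficient magnitudes are read as descriptor significance, which is
  only meaningful on a common scale; it also makes the maximized
  likelihood invariant under affine re-parametrization of raw descriptors
  (a tested property). Zero-variance descriptors are flagged and given
  unit scale.
- **Optimizer.** Restarted greedy Monte Carlo with adaptive isotropic
  Gaussian proposals (accept iff the log-likelihood does not decrease;
  step size grows ×1.1 on acceptance, shrinks ×0.98 on rejection), five
  restarts by default, optional Metropolis phase. The accepted-move
  likelihood sequence is non-decreasing within each greedy phase by
  construction. Note $\phi_B(Q) = \mathrm{logit}^{-1}(2Q)$: the model is
  exactly a binomial logistic regression in $2Q$, which provides the
  independent generic-optimizer oracle (`glm`, coefficients halved) used
  by the acceptance tests — the Monte Carlo search is retained as the
  package's own route.
- **Uncertainties.** Standard deviations over bootstrap resamples of the
  shooting records (200 by default, warm-started refits). Among the
  candidate recipes (bootstrap, Monte Carlo spread, Hessian
  approximation), bootstrap was chosen as the sole implementation because
  it is assumption-light at the small point counts typical of shooting
  campaigns; the others would add surface without changing any tested
  behaviour.
- **Separation.** Probabilities are clipped at $10^{-12}$ inside logs and
  coefficients capped at $|a| \le 20$ (configurable); hitting the cap
  raises a separation warning rather than silently diverging.

Calibration compares predicted committors with observed fractions on
validation points and counts points whose observed outcome count lies in
the central 95% mass of the predicted binomial — the criterion used on
held-out synthetic shooting points (expected coverage 19/20; the fixed-seed
acceptance bound is ≥ 14/20 to absorb binomial discreteness).

## Synthetic systems: what they emulate, and what they do not

The fixture generator builds frames whose ground truth is exact by
construction: a rigid scaffold, a rigid transporter template rotated by
`delta_phi_true` about an in-plane axis through its geometric centre and
translated by `delta_z_true` along z (so the centre displacement *is* the
requested translation), a probe atom, and water chains spaced 2.9 Å —
just under the 3.0 Å cutoff — anchored at the retained-region faces, with
a bridge through the probe only in the connected state and deliberate
≥ 3.9 Å gaps otherwise. Default water counts (13/13 per side) and the
canonical displacement (3.5 Å, 10°) match the magnitudes of the real
elevator motion; requests that cannot be realized (connected without pore
water, inward access with too few inward waters, pore waters in
non-connected states) raise infeasibility errors instead of producing
ambiguous geometry. The synthetic shooting-record generator draws
descriptors from independent Gaussians and outcomes from the true tanh
committor; shots fail to commit with a descriptor-independent probability
`uncommitted_rate`, the least-structured choice given that no mechanistic
model of non-commitment is available.

A green test on these systems establishes that the *analysis operators*
are correct on inputs whose truth is known exactly: superposition recovers
constructed transforms, clustering matches a brute-force transitive
closure, the classifier returns the constructed access state, the fit
recovers generating coefficients within its own error bars. It does **not**
establish anything about force fields, membrane physics, flexible domains,
hydrogen-bond-mediated water wires, or sampling convergence of real
trajectories — fixtures are rigid, waters are points, and descriptor
distributions are Gaussian by fiat.

## Degenerate inputs and tie-breaks

- Rotation axis at 0°/180°: error ("axis undefined"); `domain_motion`
  stores `NULL` for the axis and keeps the angle.
- Empty water selection: `n_access` returns 0 with a warning; zero
  retained waters give an empty clustering and an `occluded`
  classification.
- Zero committed shots: committor estimation errors rather than returning
  NaN.
- Path weights with a zero count: error — a valid transition path always
  contains at least one shooting-range configuration.
- Uniform shooting-point draws use the seeded RNG; model-based selection
  is deterministic given the model.

## Seeds and reproducibility

Every stochastic operation takes an explicit seed and restores the
caller's RNG state (`withr::with_seed`). The CLI derives one sub-seed per
stage from the master seed (`derive_seed`, always below $2^{31}$), so any
stage can be re-run in isolation from its logged seed; re-running the full
toy pipeline with a fixed seed reproduces every output table byte for
byte (a tested property). Indices are 1-based throughout, the R
convention; PDB serials are metadata only.

## Known limitations

- Orthorhombic boxes only; minimum image is applied per axis.
- The hand-rolled PDB layer covers ATOM/HETATM/MODEL/CRYST1 — enough for
  fixtures and stitched-path export, not a general structure parser.
- The linear-Q/tanh committor family is assumed, not tested against
  nonlinear alternatives; descriptor-set search is out of scope.
- Single-linkage clustering is $O(N^2)$ in memory and time — fine for
  fixture-scale water counts, not for full solvation boxes.
- The toy engine is not a molecular force field and makes no claim about
  real transition mechanisms; it exists to give the shooting and
  inference machinery a ground truth.
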