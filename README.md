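# transpath

Transition-path shooting analysis for elevator-type membrane transporters,
with a self-contained toy dynamics engine and synthetic fixtures so the
whole pipeline is testable on a laptop — no MD cluster or trajectory data
required.

## The problem

Secondary-active transporters of the cation/proton-antiporter family move
ions by an elevator mechanism: a six-helix transporter domain slides
(Δz ≈ 3–4 Å) and tilts (Δϕ ≈ 10°) against a static dimerization scaffold,
alternately exposing the ion-binding site to the two sides of the membrane.
The actual barrier crossings are rare (seconds) but fast (~10 ns), so they
are studied by *transition-path shooting*: from a candidate transition
state, pairs of unbiased trajectory segments are launched with
Maxwell–Boltzmann velocities **v** and −**v**; when the two conjugate
segments commit to opposite metastable states they are stitched (one
segment time-reversed) into a continuous transition path.

`transpath` implements the analysis stack around that idea:

- **Toy engine** — underdamped Langevin dynamics (BAOAB splitting) on
  analytic potentials; the default symmetric 2D double well
  `V(x,y) = h(x²−1)² + ½ky²` (h = 5 kT, k = 5 kT/Å²) has an analytic
  committor-½ surface at the saddle.
- **Shooting** (`shoot_pair`, `stitch`, `run_until_committed`) —
  first-passage commitment to states A (inward-open) and B (outward-open),
  conjugate-pair stitching, committor estimation
  `ϕ̂_B = n_B/(n_A+n_B)` with binomial errors, shooting-range selection,
  and exact detailed-balance path weights `p_new/p_old = n_old/n_new`.
- **Rigid-body order parameters** (`superpose`, `domain_motion`) — Kabsch
  least-squares superposition on the scaffold, then domain translation and
  rotation relative to inward- and outward-open references; angle from
  `Δϕ = cos⁻¹[(tr R − 1)/2]` (reported positive), axis from the
  antisymmetric part of R, averaged as `Δϕ = (Δϕ_in − Δϕ_out)/2`,
  `Δz = (Δz_in + Δz_out)/2`.
- **Hydration** (`n_access`, `cluster_waters`, `classify_access`) — the
  continuous order parameter
  `n_access = Σ_i σ_r(|r_i − r_0|) σ_z(z_i − z_0)` with
  `σ_r(x) = 1/(1+e^{β(x−α)})` (α = 10 Å, β = 5 Å⁻¹) and
  `σ_z(x) = (x/γ)e^{1/2 − x²/2γ²}` (γ = 5 Å); single-linkage water
  clustering at a 3.0 Å O–O cutoff with a bulk-slab exclusion, and the
  four discrete access states (inward / outward / occluded / connected)
  of the probe (binding-site) atom.
- **Reaction-coordinate optimization** (`rc_fit`) — maximum-likelihood fit
  of the linear coordinate `Q = a₀ + Σ aᵢqᵢ` under the committor model
  `ϕ_B(Q) = [1 + tanh Q]/2` by restarted Monte Carlo search on shooting
  outcomes, bootstrap coefficient uncertainties, and
  predicted-vs-observed committor calibration.
- **Synthetic systems** (`gen_fixture`, `gen_shooting_records`) —
  protein-like frames with exactly known Δz, Δϕ and access state, and
  shooting ledgers drawn from a known committor model, used as ground
  truth throughout the tests.

## Worked example

```r
library(transpath)

# a synthetic frame whose transporter domain sits 3.5 A up and 10 deg
# rotated from the inward-open reference, with a water wire spanning the
# membrane through the binding site
fx <- gen_fixture(fixture_spec(3.5, 10, "connected", 13, 13, 2L))
dm <- domain_motion(fx$frame, fx$ref_in, fx$ref_out,
                    fx$selections$dimer, fx$selections$transporter)
cl <- cluster_waters(fx$frame, fx$selections$water)
classify_access(fx$frame, fx$selections$probe, cl, fx$selections$water)
n_access(fx$frame, fx$selections$water, fx$params)
```

prints

```
dz_in = 3.500 A, dphi_in = 10.000 deg, dz = 1.750 A, dphi = 5.000 deg
access state: connected
n_access = 0.482
```

i.e. the rigid-body module recovers the constructed domain motion exactly
(`dz`/`dphi` are halved because the outward reference itself sits at
+3.5 Å/+10°), the water wire is classified as connected, and `n_access`
is near zero — connected and occluded sites are balanced between the two
sides, inward/outward sites give clearly signed values.

```r
# shooting from the toy saddle and fitting a reaction coordinate
pot <- potential_spec("double_well_2d"); st <- toy_states()
res <- shoot_pair(engine_state(c(0, 0)), pot, st, max_steps = 5000,
                  dt = 0.01, friction = 1, temperature = 1, seed = 3)
res$path
# stitched path: 109 frames, endpoints A -> B, shooting index 60

truth <- rc_model(c(0, 2, 0, 0), c("q1", "q2", "q3"))
rec <- gen_shooting_records(truth, 200, 10, uncommitted_rate = 0.1, seed = 108)
fit <- rc_fit(rec, c("q1", "q2", "q3"), seed = 109)
fit$model
#   (intercept)    a0  =  -0.1083  (s.d. 0.0374)
#   q1             a1  =   1.7569  (s.d. 0.0925)
#   q2             a2  =  -0.0195  (s.d. 0.0357)
#   q3             a3  =  -0.0393  (s.d. 0.0401)
```

The fit recovers the informative descriptor (true a₁ = 2) and flags q2,
q3 as insignificant (|aᵢ| < 2 s.d.), reproducing in kind the
4-descriptor → 2-descriptor reduction used to isolate domain translation
and gate distance as the mechanistically relevant coordinates. On 20
held-out points × 30 shots, `rc_calibrate` reports RMSE 0.030 with 20/20
points inside the 95% binomial interval.

## Command line

An installed `exec/transpath` script dispatches the pipeline stages
(`gen-toy`, `gen-fixture`, `gen-records`, `orderparams`, `hydration`,
`shoot`, `committor`, `fit-rc`, `predict-rc`, `calibrate-rc`,
`stitch-audit`) from a JSON config; `--seed` overrides the config master
seed and every stage seed is derived from it deterministically.

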