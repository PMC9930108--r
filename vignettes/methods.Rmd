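---
title: "Surrogate-based conformer search with steric-clash handling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-based conformer search with steric-clash handling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boconf)
```

## The problem

Finding the low-energy conformers of a flexible molecule bound to a rigid
environment (an adsorbed amino acid on a metal cluster, a ligand at a fixed
binding site) is a global optimization problem over the molecule's rotatable
bonds. Each energy evaluation is expensive when it comes from an electronic
structure code, so the search must be sample-efficient — and it must survive
the *steric clash* problem: many torsion combinations drive the molecule into
its environment, where the energy either diverges to unphysically high values
or the calculation fails outright and returns nothing. Left untreated, both
outcomes poison an active-learning loop: a missing observation stalls the
iteration, and a huge one wrecks the surrogate fit; an acquisition function
that never learns the region is bad keeps returning to it.

`boconf` implements the full workflow: a Gaussian-process (GP) surrogate of
the potential-energy surface (PES) over dihedral angles, refined by
lower-confidence-bound active learning, with three selectable strategies for
steric clashes, followed by surrogate-minima extraction, local refinement,
duplicate purging, and conformer analysis (similarity fingerprints,
hydrogen-bond typing).

## The building-block convention

The searched system is an `atomic_structure`: elements, Cartesian
coordinates, a covalent bond graph, and a mobile mask. Environment atoms
never move. Within the molecule, bond lengths and angles are frozen at their
input values; only the declared torsions vary. A torsion is four atoms
(a, b, c, d) about the rotatable bond b–c; the set of atoms that rotates is
derived by cutting the bond graph at b–c and taking the component containing
d. Torsions are applied in their listed order, so a dihedral vector
reconstructs coordinates deterministically. Angles are measured with the
signed IUPAC convention (cross-checked against `bio3d::torsion.xyz`) and
reported canonically in [0°, 360°), which keeps printed restriction windows
like [70°, 210°] contiguous.

The steric-clash diagnostic is `min_pair_distance()`: the minimum Euclidean
distance over all (mobile, environment) atom pairs, called D_min below.
Covalently anchored pairs are included; since bond lengths are frozen they
contribute a constant and cannot trigger false clashes.

## The surrogate model

The surrogate PES is a zero-mean GP (targets are centered) with a product
kernel over torsion dimensions and a fixed noise nugget of 1e-4 eV²
(backend evaluations are deterministic; the nugget is purely numerical).
Nonperiodic dimensions — those produced by a domain restriction — use the
squared-exponential kernel. Periodic dimensions use the standard-periodic
kernel, which we parameterize through the chordal distance

  s(Δ) = (360°/π) · sin(π Δ / 360°),   k(Δ) = σ² exp(−s²/(2ℓ²)).

This is the usual sin²-form periodic kernel with one deliberate twist: the
lengthscale ℓ is in *degrees* and the kernel reduces exactly to the squared
exponential with the same ℓ for separations small against the period. The
naive form exp(−2 sin²(πΔ/360)/ℓ²) makes ℓ a dimensionless number of order
0.1: plugging in a "lengthscale in degrees" there silently produces a
near-constant kernel (at ℓ = 40 every pair of angles correlates above 99.8%),
which we found makes simulated-data lengthscale recovery impossible. With the
chordal form, refitting data simulated at ℓ = 40° recovers ℓ within a factor
of two in 20 of 20 replicates (this is one of the acceptance checks).

Hyperparameters (log signal variance, log per-dimension lengthscales,
bounded in [5°, 720°]) maximize the log marginal likelihood by multi-start
L-BFGS-B with analytic gradients; the fit is never allowed to be worse than
the heuristic start (σ² = var(y), ℓ = 60°). Degenerate data (all targets
identical) fall back to prior lengthscales with a warning. Posterior queries
use a Cholesky factorization with escalating jitter; the reported predictive
standard deviation is that of the latent function (no noise added).

## Acquisition and the active-learning loop

The next configuration minimizes the exploratory lower confidence bound,
eLCB(x) = μ(x) − κ_n σ(x), with the standard GP-UCB schedule

  κ_n = sqrt(2 log(n^(d/2+2) π² / (3δ))),  δ = 0.1,

which is nondecreasing in the iteration index n. The acquisition is
optimized by screening 300 uniform random candidates in the (possibly
restricted) torsion box, then polishing the best 3 with bounded L-BFGS-B.
For fully periodic dimensions the box is [0°, 360°]; an acquisition optimum
sitting exactly on that seam is reachable through the candidate screen, so
no explicit wrapping is needed during polishing.

A run starts from a uniform random initial design of 5 + d points, then
iterates: propose → evaluate through the active clash policy → append the
training target → refit. Hyperparameters are refit every iteration while the
training set holds at most 50 points and every 5th iteration afterwards — a
fidelity/cost trade-off; between refits the Cholesky factor is rebuilt with
the cached hyperparameters. Every stochastic step draws from one RNG stream
seeded once per run, so a run is exactly reproducible from its seed. The
per-iteration trace records the proposal, raw and transformed energy,
provenance, incumbent, hyperparameters, and (optionally) the predicted
global minimum — the quantities used for convergence diagnostics
(hyperparameter stabilization, predicted-minimum settling).

## The three clash strategies

All three convert a proposal into a finite GP training target; parameters
default to the study values.

**Strategy i — restricted domain.** `strategy_i_domain()` narrows chosen
torsions to a clash-free window (found beforehand with the phase-space scan,
below); restricted dimensions lose their periodicity and switch to the
squared-exponential kernel. The search can never propose a clash, but it can
never see minima outside the window either.

**Strategy ii — safe-distance substitution.** If D_min < D₀ (default 1.4 Å,
around a typical covalent bond length) the backend is *not* called and the
constant E₀ (default 6.0 eV) becomes the target; otherwise the backend's
energy passes through unchanged. The boundary case D_min = D₀ evaluates
(the condition for substitution is strict). A backend failure on a
supposedly safe structure also falls back to E₀, with a warning — the loop
must never lose an iteration.

**Strategy iii — energy transform.** Every proposal is evaluated. Energies
below E_cut (default 2.0 eV) pass through bit-identically; energies at or
above it are attenuated as

  E_new = E_cut (1 + ln(E / E_cut)),

which is continuous with slope 1 at the junction and strictly increasing, so
the energy order of successful evaluations is preserved exactly. Outright
failures receive the penalty E_p (default 4.5 eV ≥ E_cut).

A fourth mode, `none`, is the experimental baseline: a failed evaluation
contributes nothing, so the surrogate never learns the failing region —
which is precisely the pathology the strategies exist to cure.

## Postprocessing

After the budget is spent, `extract_minima()` collects the surrogate's local
minima by multi-start bounded minimization of the posterior mean, keeps
endpoints that pass a stationarity check (numerical gradient below
1e-3 eV/°; endpoints pinned to a restriction boundary are kept as boundary
minima), and merges endpoints closer than 2°. A flat surrogate collapses to
a single representative. `refine_minima()` then relaxes each candidate on
the true backend surface and `purge_duplicates()` removes duplicates with
the study thresholds: a record is dropped only when *both* its maximum
per-torsion periodic difference (≤ 10°) *and* its energy difference
(≤ 0.0057 eV) match an already-kept record, scanning greedily from the
lowest energy. Requiring both is the conservative reading: distinct basins
can coincide in energy, and identical geometry implies identical energy.
The greedy scan is idempotent and its output never contains a pair that
would merge with an earlier kept record.

Two refinement details matter. First, on synthetic landscapes (below),
refinement runs in dihedral space with analytic gradients; Gaussian wells
have exponentially flat tails on which quasi-Newton steps crawl, so a
normalized-gradient descent walks into the attracting basin before BFGS
polishes. Refinement never increases the energy. Second, a refined record
whose dihedrals leave the searched domain is excluded from the ranked
output: a restricted-domain search reports only conformers inside its own
window. Without this rule a candidate pinned to the window boundary can
slide downhill out of the window during refinement and "find" minima the
strategy never sampled — which would misrepresent what the restricted
search knows. Ranked tables can additionally be cut to an energy window
above the global minimum, mirroring how conformer sets are reported in
practice.

## The synthetic landscape generator

Real electronic-structure backends are out of scope, so validation runs on
`make_synthetic_landscape()`: a flat baseline (0 eV, the reference-energy
convention) minus Gaussian wells on the wrapped angular metric,

  E(x) = E₀ − Σ_k D_k exp(−Δ_k²/(2 w_k²)),  Δ_k = wrapped distance to
  center k,

exactly 360°-periodic in every dimension. Gaussian wells (rather than, say,
von Mises profiles) keep every test oracle in closed form; for widths well
under 360° the two are indistinguishable. Defaults, chosen once as
chemically plausible scales: depths uniform in [0.5, 1.0] eV (the spread of
conformer energies and the barrier scale of torsional PESs), widths uniform
in [25°, 40°] (basins tens of degrees wide), centers rejection-sampled to
pairwise separations of at least three maximum widths so wells do not
coalesce and the deepest center is the global minimum (stored after a local
refinement, and verified against a 1° grid scan in the tests).

Two kinds of boxes decorate the landscape. *Failure boxes* return an
evaluation failure — the crashed-calculation pathway. *Clash boxes* drop the
reported D_min from 3.0 Å to 1.0 Å — the geometric pathway that strategy ii
screens. The two are independent controls because the two real-world
mechanisms are distinct. Boxes are rejection-sampled away from every well
center (one-width margin) so that planted minima stay evaluable.

What the generator does *not* emulate: correlated anharmonic well shapes,
minima inside clash zones, the strong energy/distance coupling of real
adsorption (here d_min is a step function of position), or evaluation noise.
Passing tests therefore demonstrate the machinery — surrogate fidelity,
clash-policy behavior, pipeline correctness — not chemical accuracy on any
real system.

The packaged molecular fixture (`make_fixture_system()`) is a synthetic
cysteine-like molecule (13 atoms: thiolate anchor, CH₂, backbone CH, NH₂,
COOH) built from idealized internal coordinates and anchored to a 10-atom
rigid cluster, with three torsions and one cluster atom placed so that
anchor-torsion values near 300–340° collide. It exists so that geometry,
scans and hydrogen-bond analysis run on something molecule-shaped without
any external data.

## Conformer analysis

`similarity_index()` compares two conformers by the cosine of the angle
between their dihedral-cosine fingerprints [cos d_i]; it is symmetric and
lies in [−1, 1]. The anchor torsion is excluded by default: its reference
frame involves the environment, so it has no meaning for isolated-molecule
references; the included subset is configurable.

`detect_hbonds()` uses the heavy-atom criterion alone — donor(N,O)-to-
acceptor(N,O) distance at most r_HB = 3.5 Å, donor carrying at least one H,
donor and acceptor not covalently bonded — because that is the criterion the
workflow defines; an optional donor–H···acceptor angle filter exists but
defaults to off. Types are a lookup table (data, not code): amino N–H to
carbonyl O is type I with a cis carboxyl and type IV with a trans carboxyl;
carboxyl O–H to amino N is type II; amino N–H to the hydroxyl O is type III;
everything else is "other". The carboxyl isomer comes from the H–O–C=O
dihedral with a ±90° split: (−90°, 90°] is cis.

`phase_space_scan()` draws uniform random dihedral vectors, poses the
structure, tabulates D_min against each torsion, and reports safe fractions
overall and inside candidate restriction windows — the evidence on which a
strategy-i window is chosen.

## Numerical choices and degenerate inputs

* Noise nugget 1e-4 eV²; Cholesky jitter escalates from 1e-8 of the mean
  diagonal by factors of 10, at most 6 times, then errors.
* Lengthscale bounds [5°, 720°]; signal variance bounds [1e-6, 1e4] eV².
* Ties in acquisition screening resolve to the first minimal candidate
  (deterministic under the run seed).
* D_min = D₀ exactly evaluates (strategy ii); E = E_cut exactly transforms
  (the two branches agree there, so the choice is invisible).
* Empty environment, all-identical targets, zero-norm similarity vectors,
  collinear dihedral atoms, non-cut ring bonds: explicit errors or flagged
  fallbacks, never silent wrong answers.
* A 360°-wide restriction leaves a dimension periodic; bounds wider than the
  original domain are rejected.

## Validation experiment sizes

The shipped experiments (also re-run by `scripts/acceptance.R`) use 2-D
landscapes: 20 replicate seeds × 150 iterations for the three-strategy
comparison, 20 × 100 iterations for the clash-avoidance contrast (proposal
rate inside a 20%-coverage failure region after iteration 50, paired sign
test), 20 refits of n = 60 simulated points for lengthscale recovery, one
200-iteration run for the four-well recovery pipeline, and 2,000–20,000
samples for the fixture phase-space scans. These sizes make each claim
statistically decidable while keeping a full validation run in the
minutes range; larger runs only tighten the same estimates.

## Known limitations

* The acquisition optimizer is stochastic-multistart, not global: in
  pathological surrogates (very short lengthscales) it can miss the exact
  acquisition minimum; this costs sample efficiency, not correctness.
* Hyperparameter refits reuse the previous optimum as a warm start; a
  drastically multimodal likelihood could retain a stale mode between the
  periodic full restarts.
* The strategy-ii surrogate is intentionally wrong inside the substituted
  region (a constant plateau at E₀) and exhibits edge undershoot next to
  the substitution cliff; the refinement-and-rank pipeline is what makes
  its final conformer list reliable, and the comparison experiment measures
  exactly that.
* Backend refinement for real molecules must be supplied by the caller
  (`structure_backend(..., refine_fn)`); only dihedral-space refinement of
  synthetic landscapes ships with the package.
* No batch acquisition, no gradient observations, no multi-fidelity
  modelling, and no free-energy or dispersion corrections.
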