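---
title: "Models and methods behind emtnfatc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emtnfatc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The circuit

`emtnfatc` analyses the regulatory circuit controlling epithelial to
mesenchymal transitions (EMT) and its coupling to the transcription factor
NFATc.  The core of the circuit is the mutual-inhibition loop between the
miR-200 microRNA family and the EMT transcription factor ZEB, driven by
SNAIL (which stands in for any exogenous EMT-inducing signal such as
TGF-beta): SNAIL activates ZEB transcription and represses miR-200, ZEB
represses miR-200 and activates itself, and miR-200 silences ZEB
post-transcriptionally.  This loop is the canonical three-way switch whose
stable states are epithelial (E: high miR-200, low ZEB), mesenchymal
(M: low miR-200, high ZEB) and a hybrid E/M state (H) with intermediate
levels of both.

NFATc couples to this core in four places: it activates ZEB, miR-200,
E-cadherin and SNAIL.  E-cadherin is itself repressed by ZEB and restrains
ZEB indirectly (through sequestration of beta-catenin), closing a second
mutual-inhibition loop.  The wild-type coupled topology therefore has five
nodes and eleven edges, six activating and five inhibiting.  Because the
main text of the literature this circuit comes from does not pin down the
NFATc-SNAIL arm unambiguously, the shipped topology is the unique reading
of the described interactions that satisfies the 6/5 edge-sign constraint;
it is data, not hard-coded, and any other topology can be supplied as a
`.topo` file.

# The mechanistic model

The mechanistic model tracks five species in molecules and hours: miR-200
(`mu`), ZEB mRNA (`mz`), ZEB protein (`Z`), E-cadherin (`E`) and NFATc
(`N`), with SNAIL (`S`) a clamped input.  Transcriptional and indirect
edges use the shifted Hill function
`H(x) = (1 + lambda (x/A0)^n) / (1 + (x/A0)^n)`,
which equals 1 at zero regulator and `lambda` at saturation.  The
miR-200 to ZEB-mRNA edge uses the binding-site formalism: with six sites
and occupancy probabilities `M_i(mu)`, miR-200 scales translation by
`L(mu)`, adds mRNA degradation `Ym(mu)`, and is itself consumed through
duplex formation at rate `mz * Ymu(mu)`.  ZEB mRNA and protein are
tracked separately because the stochastic reduction (below) relies on
their separated time scales.  NFATc has constitutive production, so its
only steady state is `gN/kN`; all NFATc regulation therefore acts through
constant fold-changes, and the E-cadherin loop is the only dynamic element
the coupling adds.

Setting the four coupling fold-changes (`lNu`, `lNm`, `lNE`, `lEm`) to 1
makes the (`mu`, `mz`, `Z`) subsystem exactly the three-species core
model; `core_reduction()` implements this and the test suite asserts the
equivalence at machine precision.

## Parameters and calibration

The core kinetic values (`gu = 2100`, `ku = 0.05`, `gm = 11`, `km = 0.5`,
`gz = 100`, `kz = 0.1`, the Hill blocks and the binding-site vectors) are
the published values of the miR-200/ZEB binding-site literature.  Two core
values were calibrated: both SNAIL Hill cooperativities were lowered from
2 to 1.  This flattens the SNAIL dependence so that the coupled circuit's
multistable window spans SNAIL around 310-395 thousand molecules — the
range in which the landscape analyses are reported — instead of collapsing
into a narrow band near 200 thousand.  The NFATc fold-changes
(`lNu = 1.6`, `lNm = 1.15`, `lNE = 4`) and the E-cadherin arm
(`lEm = 0.85`, `Z0E = 150000`, `lZE = 0.05`) were then calibrated against
three conditions: coexisting H and M states at SNAIL 323k and 330k with M
dominant at 380k; a hybrid window strictly wider than the core's; and a
delayed complete EMT at SNAIL 330k.  None of these numbers is a measured
constant and all are flagged as calibrated in `default_parameters()`.

Calibration has one consequence worth stating plainly: at SNAIL = 330k
the coupled circuit still has a stable epithelial state, so an epithelial
cell never completes EMT deterministically at that stimulus — the
delayed-transition comparison reports a censored (horizon) time for the
coupled circuit against a finite core time.  This is the strong form of
the claim that NFATc raises the SNAIL level needed to leave the
epithelial state.

## Steady states, branches and phases

`find_steady_states()` runs damped Newton iteration (numerical Jacobian,
non-negativity clipping) from log-uniform multi-starts, deduplicates
roots at 1% relative tolerance (levels floored at one molecule) and
classifies stability by the Jacobian's leading eigenvalue against
`eps_eig = 1e-6` per hour.  `sweep_bifurcation()` scans a SNAIL grid
twice (upward and downward) with warm starts so that hysteretic branches
are picked up from whichever side reaches them, links stable states into
branches by nearest-neighbour continuation in log ZEB mRNA (ties broken
towards the smaller jump), and labels branches by identity: the low-SNAIL
branch is E, the branch persisting at the high end with the highest ZEB
mRNA is M, everything else is H.  Phenotype bands for trajectory
classification are derived from the model's own hybrid branch rather than
absolute thresholds, so core and coupled trajectories are classified by
their own diagrams.

The calibrated phase sequences are `{E} -> {E,M} -> {E,H,M} -> {H,M} ->
{M}` for both circuits.  The appearance of a direct E/M bistable region
before the hybrid state emerges is a feature of this parameter family
(direct epithelial-mesenchymal transitions at lower SNAIL, the hybrid
state appearing at intermediate SNAIL); there is no monostable hybrid
regime in the coupled circuit.

`hybrid_interval()` measures the SNAIL range supporting a stable H state,
refining both endpoints by bisection on the stable-state count to 0.1% of
the grid span.  `sensitivity_analysis()` perturbs every continuous scalar
parameter by +/-10% (integer Hill cooperativities are deliberately
excluded: a 10% change of an integer exponent is not a defined operation
in this model class) and reports the percent change of the window length,
against the reference change obtained by removing NFATc altogether.

# Stochastic reduction and landscapes

Because ZEB mRNA, E-cadherin and NFATc relax much faster than ZEB protein
and miR-200, their equations are closed at quasi-steady state, leaving a
two-variable system in (`Z`, `mu`) whose fixed points coincide with the
full model's (asserted to 1e-6 relative in the tests).  The reduced
system is simulated with Euler-Maruyama at `dt = 0.01` h with additive
Gaussian noise, per-variable amplitude 5% of that variable's span across
the coexisting attractors, and a reflecting boundary at zero.  The noise
model is a modelling choice (the source analyses state only "external
noise"); a multiplicative mode is available and gives the same orderings
in all cases examined.

Each sample is coarse-grained to the basin of the attractor a
deterministic relaxation from it converges to; assignments are cached on
a 100x100 log-spaced grid (relaxation horizon 800 h; cells that do not
resolve are excluded from the labelled statistics).  Mean residence time
is the mean length of contiguous stays times `dt`; occupancy fractions
are renormalised over labelled steps and sum to one exactly.  The
quasi-potential is `U = -ln P` of the Gaussian-smoothed (bandwidth 1.5
cells) visit histogram pooled over seeds and starts; minima are matched
to attractors by steepest descent, saddles are found by flooding (cells
added in order of increasing `U`; the level at which two minima's
components merge is their saddle), and a state's barrier is its lowest
adjacent saddle level minus its minimum.

Default problem sizes (5 seeds of 15,000 h per attractor at each SNAIL
level) keep the analyses reproducible on a laptop while separating the
tested orderings, which differ by one to two orders of magnitude; the
figures they produce are Monte-Carlo estimates, not converged rate
constants, and absolute residence times are not comparable across noise
models.

## A calibration limit on the barrier ordering

At SNAIL 380k the mesenchymal basin is the deeper one, as in the source
landscapes.  At 323k and 330k, however, this calibration gives the
mesenchymal state the larger barrier, whereas the published landscapes
report the hybrid state's barrier as larger there.  The reversal is
structural in this parameter family: the mesenchymal branch appears near
SNAIL 220k, so by 323k its basin has grown log-deep on the ZEB axis,
while the hybrid state's saddle sits close to it in log space.  An
extensive calibration search did not find a parameter set that makes H
the deeper state at 323k/330k while simultaneously keeping the wider
hybrid window, the monostable-E low-SNAIL regime, the core circuit's
mesenchymal monostability at 330k (needed for the delayed-EMT
comparison), and the residence-time trends.  The corresponding acceptance
check is left failing rather than weakened; residence-time and barrier
orderings remain mutually consistent at every SNAIL level examined.

# Ensemble analysis

The ensemble engine reimplements random-circuit-perturbation analysis:
for a fixed topology, each model draws production `g ~ U[1,100]`,
degradation `k ~ U[0.1,1]`, per-edge cooperativity `n ~ U{1..6}` and
fold-change `lambda ~ U[1,100]` (reciprocal for inhibitions), and
per-edge thresholds by the half-functional rule — uniform in
`[0.02, 1.98]` times the source's median operating level.  That median is
estimated by Monte-Carlo with a fixed sub-seed, modulating `g/k` draws by
a half-activation factor `(1 + lambda)/2` for *every* incoming edge.
Modulating by inhibitory inputs only was tried first and yields
essentially no tristable models at all (0 of 3000 for the core), which
would make the ensemble figures unreproducible in principle; symmetric
modulation restores a realistic ~1% tristability rate and is the shipped
rule.  Ensemble dynamics use shifted-Hill products only (no binding-site
formalism), are relaxed by adaptive forward Euler from 100 log-uniform
initial conditions per model, deduplicated in log levels, and verified
stable by the Jacobian.

Phenotypes are called on z-scores of log2 levels pooled over all stable
states of the ensemble: `z_ZEB > 0 > z_miR200` is M, both positive is H,
`z_miR200 > 0 > z_ZEB` is E, and both negative falls in an explicit
unlabeled bin (the source method defines only the three quadrants; the
fourth is reported, not silently dropped).  A model's phase is the set of
its states' labels; phase counts partition the ensemble exactly.

## What this reimplementation does and does not reproduce

With 1,000 models and 3 replicates: the wild-type coupled topology's
{E,H,M} fraction sits near the 90th percentile of its degree-preserving
sign randomizations (the enrichment result), and in {H,M}-phase models
the hybrid state captures the majority of random initial conditions in
roughly nine out of ten models (the relative-stability result).  Two directional
results of the original ensemble tool are *not* reproduced: the coupled
topology here shows slightly fewer {E,H} and {E,H,M} models and more
{H,M} models than the core, and in tristable models the epithelial basin
is the largest rather than the smallest.  These directions were stable
across seeds, threshold-rule variants and initial-condition boxes, so
they are reported as genuine disagreements of this reimplementation —
most plausibly traceable to unpublished internals of the original tool's
threshold estimation and initial-condition ranges — and the corresponding
acceptance checks are left failing rather than tuned.

# Randomization

Sign randomization enumerates all `C(11,6) = 462` assignments of six
activations to the eleven fixed source-target pairs and removes the
wild-type, leaving 461 networks; every member preserves all in/out
degrees exactly, and per-node sign counts are deliberately *not*
conserved (that is the null model's point).  Desk-scale comparisons run a
seeded subsample (default 25 networks at 600-1000 models each); the
percentile of the wild-type within the randomized fractions is reported
with ties split.

# Synthetic fixtures

`generate_fixtures()` writes every input the analyses consume — the two
shipped topologies, the calibrated parameter files, toy oracle circuits
(a single unregulated node whose steady state is `g/k`; a strong toggle
switch whose two states are verified against a brute-force grid
relaxation in the tests), and a seeded example trajectory — plus a
manifest with sub-seeds and md5 checksums.  All randomness derives from
one master seed by fixed offsets, and regeneration is byte-identical.
What the generator emulates is the *computational* input space of the
analyses (topologies, kinetic parameters, noisy trajectories); it does
not emulate any experimental readout, so passing tests say nothing about
biological measurements — they validate the mathematics and the code.

# Known limitations

* All quantitative results are properties of a calibrated parameter set,
  not fits to data; only orderings and trends are meaningful.
* SNAIL is an input: there is no TGF-beta/miR-34 module, no delay, no
  spatial or population structure.
* The quasi-potential is estimated from finite noisy runs on a log grid;
  barrier values depend on the noise amplitude and grid, and only their
  ordering is used.
* The ensemble reimplementation matches the cited method's published
  description, not its code; two of its directional results disagree, as
  detailed above.
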