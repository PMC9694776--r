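---
title: "Stereochemical assignment from force-field ensembles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereochemical assignment from force-field ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixjdp4)
```

## The problem

Assigning the relative configuration of a small organic molecule from NMR
data means deciding which of up to $2^{n-1}$ diastereomers ($n$
stereocenters, enantiomers being indistinguishable by chemical shifts) best
explains the observed $^1$H and $^{13}$C shifts and $^3J_{\mathrm{HH}}$
couplings. The workflow this package implements predicts those observables
for every candidate from a molecular-mechanics conformer ensemble, compares
them with experiment through a Bayesian error model, and reports a posterior
probability per candidate. Because the geometries come straight from a force
field, the result depends visibly on which force field generated them; the
package therefore treats the (molecule, candidate, force field) triple as
its unit of computation and offers a consensus step that averages the
probabilities obtained from several independent force fields.

## Models and assumptions

**Boltzmann averaging.** Per-nucleus shieldings are averaged as
$\sigma_x=\sum_i \sigma_i^x e^{-E_i/RT}/\sum_j e^{-E_j/RT}$ with
$R=8.3145$ J K$^{-1}$ mol$^{-1}$ and $T=298$ K by default. Relative energies
are in kJ/mol, always re-referenced so the ensemble minimum is exactly 0.
Weights are evaluated with the max-shift trick, so a 50 kJ/mol gap yields a
weight below $2\times10^{-9}$ without underflow.

**Referencing and scaling.** Unscaled shifts are
$\delta_u=\sigma_0-\sigma_x$ with the reference standard's shielding
$\sigma_0$ supplied per element — never defaulted, since it depends on the
level of theory. Scaled shifts are $\delta_s=(\delta_u-b)/m$ from the OLS
regression of $\delta_u$ (ordinate) on $\delta_{exp}$ (abscissa), performed
per candidate and per element channel. This orientation is deliberate and
the inverse is not offered: it is the form under which $\delta_s$ is exactly
invariant to any affine distortion of the predictions, which is what makes
scaled errors comparable across force fields. Computed shifts of equivalent
nuclei are averaged within experimentally declared groups *before*
regression, because experimental signals, not nuclei, are the unit of
comparison. Channels with fewer than three signals are left unscaled and
flagged.

**Error model.** Scaled errors $e_j=\delta_{s,j}-\delta_{exp,j}$ are modeled
per channel by a Student-t distribution $t_\nu((e-\mu)/\sigma)$; with a
uniform prior, normalized likelihood products over candidates give the
posterior. The likelihood is accumulated in log space and normalized by
log-sum-exp, so results are independent of signal ordering and a
200-signal, 10-sigma case cannot underflow to an all-zero vector. The
shipped profile `"dp4-2010"` carries the canonical H/C parameters
($^1$H: $\sigma=0.185$ ppm, $\nu=14.18$; $^{13}$C: $\sigma=2.306$ ppm,
$\nu=11.38$). The `"jdp4-2019"` profile adds a coupling channel whose
parameters ($\sigma=1$ Hz, $\nu=8$) are package defaults, flagged as such in
the provenance string: the calibrated values belong to the coupling-error
literature and should be supplied by the user when available. No statistical
parameter is hardcoded in the probability logic; custom models are ordinary
lists.

**Couplings.** Computed couplings are Fermi-contact values rescaled by a
named linear profile; `"fc-b3lyp"` ($a=0.9117$, $c=0$) is the widely used
rescale for B3LYP-quality Fermi-contact terms, `"identity"` is available,
and any `c(a=, c=)` pair is accepted. The direct channel (dJ) feeds
Boltzmann-averaged scaled couplings into the same t machinery. The indirect
filter (iJ) maps each filtering-grade experimental coupling through a
Karplus curve, $^3J(\phi)=A\cos^2\phi+B\cos\phi+C$ (`"classical"` profile:
$A=7.76$, $B=-1.10$, $C=1.40$ Hz), to its admissible dihedral angles and
keeps only conformers whose dihedrals lie within a tolerance of one of them.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| energy window | 12 | kJ/mol | recommended trade-off between coverage and cost; inclusive, so boundary conformers are never trimmed |
| dedup criterion | MAD | — | maximum atom deviation discards less structural diversity than RMSD at equal threshold (since RMSD $\le$ MAD per pair) |
| dedup threshold | 0.5 | Å | recommended duplicate threshold |
| alignment subset | heavy atoms | — | avoids methyl-rotor false distinctions; configurable to all atoms |
| temperature | 298 | K | room-temperature populations |
| iJ mode | dihedral window | — | follows the standard description of coupling-constrained searches |
| iJ dihedral tolerance | ±30 | degrees | half the 120° separation of staggered rotamers: wide enough for force-field dihedral error, narrow enough to separate rotamer states. A package decision, echoed loudly in result metadata |
| iJ J-match tolerance | 2 | Hz | alternative mode; roughly twice a typical coupling-error scale |
| channels | H + C + J | — | the combined method is the strongest single-force-field variant |

Deduplication is greedy in ascending energy order (ties broken by input
order, for determinism): a conformer is discarded iff its distance to an
already-retained conformer is below threshold. The algorithm is a
convention — common conformational-search practice — chosen because it
guarantees the global minimum survives and is idempotent. Energy units must
be declared (`kJ/mol` or `hartree`, 1 hartree = 2625.499 kJ/mol); guessing
units from magnitude is deliberately refused, as silent unit errors are the
worst failure mode of this kind of plumbing.

## Degenerate inputs and numerical choices

* Superposition uses the Kabsch SVD construction restricted to proper
  rotations; fewer than three non-collinear subset atoms is an error.
* Karplus inversion clamps an experimental coupling into the curve's
  attainable range before solving: a trans coupling of 11 Hz under a curve
  that tops out at 10.26 Hz still means "trans", not "no admissible angle".
  The strict inverse is available via `clamp = FALSE`.
* If the iJ filter removes *every* conformer of a candidate, the filter is
  released for that candidate with a warning rather than returning an empty
  ensemble: an emptied filter signals misconfiguration (wrong Karplus
  profile, mis-assigned coupling), not impossible stereochemistry. Released
  filters are recorded in result metadata.
* Saturated probabilities are clamped to `<0.1%` / `>99.9%` only by the
  report formatter; all internal values and serialized JSON stay exact.
* Dihedrals follow the signed IUPAC convention on $(-180, 180]$.
* The consensus (mix) step is the plain arithmetic mean of the per-force-field
  *combined* probabilities — not a geometric mean, not a renormalized
  likelihood product — so the mean of valid probability vectors is itself
  one. Per-channel means are emitted as supplementary columns only. Two
  force fields are accepted with a warning; three independent force fields
  are the recommended practice.
* Diastereotopic proton pairs may be flagged swappable (`swap_group` column
  in the experimental table); the error-minimizing pairing is then used per
  candidate. This is an opt-in convenience and slightly optimistic by
  construction, so it is off unless requested.

## What the synthetic generator emulates

`fixture_spec()`/`make_fixture()` produce complete, ground-truthed inputs.
The generator is a *statistical* stand-in for the workflow's real inputs,
emulating:

* conformer ensembles as a self-avoiding carbon/hydrogen chain with rotamer
  states at $-60/60/180°$ on the coupling-bearing bonds (combinations
  sampled without replacement, as a systematic search would enumerate them),
  torsion jitter, and Cartesian noise at 0.02 Å — the scale of typical
  inter-force-field geometry differences;
* relative energies drawn uniformly on $[0, 8]$ kJ/mol *independently of
  rotamer state*, standing in for force-field energy error — this is what
  gives the iJ filter something real to fix;
* per-conformer shieldings that encode, through a stored affine map
  (slope/intercept recovered by the scaling step), a per-signal base shift
  plus a rotamer-linked offset (0.2 ppm $^1$H, 2 ppm $^{13}$C amplitude), so
  Boltzmann averaging genuinely matters;
* experimental values generated at the "solution" rotamer with Student-t
  noise from the configured error model, and wrong candidates inflated by a
  per-signal location shift of 2 channel-sigmas with random signs (a
  *constant* shift would be absorbed by the regression intercept) and an
  optional scale multiplier;
* couplings tied to true dihedrals through the Karplus curve, emitted in
  Fermi-contact encoding so the pipeline's rescale recovers them.

Candidates share one set of conformer geometries per force field and differ
only through their error structure. What passing tests on these fixtures
shows is that the *statistical engine and plumbing* behave exactly as
specified under the model's own assumptions; what they cannot show is
anything about real force-field energetics, real Karplus chemistry, solvent
effects, or the accuracy of DFT shieldings — the fixtures have none of
those. Headline benchmark performance on real compound sets requires DFT
data for thousands of conformers and is out of scope at desk scale.

All generator randomness is Mersenne-Twister with inversion normals, seeded
explicitly (no wall-clock seeding); seeds are recorded in every output.

## Problem sizes used by the test and acceptance suites

The suites were sized to run comfortably on one CPU: parameter recovery
uses 200 replicate systems with 20 signals and 2 couplings; normalization
checks span 1000+ randomized assignment runs; the deduplication oracle
comparison uses 200 random 10-conformer ensembles. The method-ordering check
(DP4 $\le$ dJ $\le$ iJ/dJ in top-rank rate) allows two binomial standard
errors at $n=200$ ($\approx 0.035$) of simulation slack, fixed in advance.
The goodness-of-fit check of the generator's error law runs on $10^4$ direct
sampler draws; full-pipeline scaled errors are checked on calibrated moments
instead, because regressing on noisy experimental abscissae perturbs the
exact t shape at finite signal counts (an attenuation effect inherent to
the scaling step, not a defect of the sampler).

## Known limitations

* Atom correspondence between conformers is by input ordering only; there is
  no symmetry/automorphism-aware matching, so topologically symmetric
  molecules can over-count distinct conformers.
* Only $^1$H and $^{13}$C channels are supported; no solvent models; no
  ab initio computation of any observable.
* The J-channel t parameters ship as package defaults and should be
  overridden with calibrated values for quantitative work.
* Whether published MAD/RMSD duplicate criteria align structures before
  measuring deviations, or include hydrogens, varies by software and is
  often unstated; this package always aligns first (heavy atoms by default)
  and documents that as its own convention.
* DP4 variants that require DFT-optimized geometries, and trained
  machine-learning shift predictors, are intentionally out of scope.
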