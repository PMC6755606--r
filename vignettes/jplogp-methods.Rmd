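---
title: "Atom-type holograms for logP: model, typer and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-type holograms for logP: model, typer and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jplogp)
```

## The model

The octanol-water partition coefficient is modelled as a sum of atomic
contributions: every atom of a molecule, hydrogens included, is mapped
to a discrete *atom-type code*, the molecule is represented by the
counts of those codes (its **hologram**), and the prediction is

$$\widehat{\log P} \;=\; \sum_{t} \alpha_t \, n_t ,$$

where $n_t$ is the count of type $t$ and $\alpha_t$ a coefficient fit by
linear least squares. There is deliberately no intercept: the baseline
is absorbed by the carbon and hydrogen types present in every organic
molecule.

A second prediction mode exploits compounds with *measured* logP. If a
reference compound is sufficiently similar to the query, the signed
**difference hologram** $d = n^{\text{query}} - n^{\text{ref}}$ converts
its experimental value:

$$\widehat{\log P}_{\text{lib}} \;=\;
  \log P^{\text{ref}}_{\text{exp}} + \sum_t \alpha_t d_t .$$

Because the correction involves only the atom types that *differ*, the
shared part of the least-squares imprecision cancels. Algebraically the
corrected value always equals
`anchor + predict_coeff(query) - predict_coeff(ref)`; the package
asserts this identity to machine precision, which pins down the
implementation of the difference hologram and of both predictors at
once. When several references pass the similarity threshold the
corrected values are averaged unweighted; nothing in the model suggests
a particular weighting, and the unweighted mean keeps the estimator
transparent.

## The atom code

Each atom receives a six-digit integer `A BB C DD`:

| field | width | content |
|-------|-------|---------|
| `A`   | 1     | formal charge + 1 (so an anion has `A = 0`; charges below −1 are rejected, above +8 impossible to encode) |
| `BB`  | 2     | atomic number (elements beyond Z = 99 are rejected) |
| `C`   | 1     | number of heavy-atom neighbours |
| `DD`  | 2     | element-specific environment class |

The `DD` vocabulary is what makes the typer hierarchical. A *polar
atom* here is S, O, N or P; the halogens are not polar under this
definition (their inductive pull is handled separately where it
matters, i.e. for fluorine).

**Carbon** splits first on the maximum incident bond order, with the
ordering single < aromatic < double < triple (aromatic bonds count
1.5, so the grouping falls out of a numeric maximum). sp3 carbons form
only two classes — polar neighbour present or not. For the aromatic,
double and triple groups the *location* of the polar atoms matters: a
polar atom attached through the multiple/aromatic bond perturbs the
carbon differently from one attached through a single bond, so the
class is `base + 3·min(n_multi, 2) + min(n_single, 2)` with base
10/20/30. This is what separates the carbon alpha to a pyridine
nitrogen (polar through the aromatic bond) from the C1 of aniline
(polar through a single bond).

**Nitrogen** prioritises electronics over hybridisation. Nitrogen bound
directly to another polar atom (hydrazines, nitro, sulfonamide N) is
classed by that fact first; next, nitrogens whose lone pair is
delocalised — bound by a single bond to an aromatic atom
(aniline-like) or to a carbon double-bonded to O or S (amide-like,
thioamides included) — share one class; the remainder split by
bond-order group. When a nitrogen is both polar-bound and
aniline-like, the direct polar bond wins: it is the stronger
perturbation of the lone pair.

**Oxygen** is treated more specifically than a monolithic polar-bound
rule: O bound to N and O bound to S are their own classes, the sp2
oxygens of amides, carboxylic acids, esters, thioesters and plain
ketones/aldehydes are all distinct, as are the sp3 oxygens sitting on a
carbonyl or thiocarbonyl carbon (acid −OH vs ester −O−). Then
aromatic O (furan), hydroxyl, ether and terminal oxide. Carbamate-like
carbons bearing both N and O are resolved in the order
amide > acid > ester > thioester; the more electron-donating
substituent dominates the sp2 oxygen's character.

**Fluorine** is keyed on its carrier: non-carbon carriers form one
class, and on carbon the class combines the carbon's bond-order group
with the number of *additional* electron-withdrawing substituents
(halogens plus polar atoms) on that carbon, the F being typed excluded.
Fluorine's own withdrawing strength damps the effect of further
withdrawing groups, and counting them recovers that saturation: the F
of CH3F, CF4 and PhCF3 are three different types.

**Hydrogen** classes look only at the attached heavy atom (element
family and, for carbon, its bond-order group) — no beta-position
lookups. **Everything else** (Cl, Br, I, S, P, metals, …) is classed
aromatic vs `10 + polar-neighbour count`.

The concrete `DD` integers are this package's own stable enumeration of
those semantics; they are documented by the tables in
`R/atom-typer.R` and frozen by the typer version tag
(`jplogp-r/1`) stored in every saved coefficient bundle. A bundle
trained under a different vocabulary refuses to load — coefficients are
meaningless across typer versions, so the failure must be loud.
Consequently, coefficient tables produced by other implementations of
this family of typers are not interchangeable with this one.

## Similarity

Counts demand a generalisation of Tanimoto similarity:
$s(h_1, h_2) = \sum_t \min(h_{1t}, h_{2t}) \big/ \sum_t \max(h_{1t},
h_{2t})$ over the union of codes. It degenerates to the classic
Tanimoto coefficient on 0/1 vectors, is symmetric, lives in $[0,1]$,
equals 1 exactly on identical holograms and 0 exactly on disjoint code
sets. An alternative reading — averaging per-position min/max ratios —
is available behind `per_position = TRUE` but is not the default: it
weights a rare type as heavily as a type occurring twenty times.
Hydrogens participate in the similarity like every other code; they
carry real signal (an alcohol and its methyl ether differ in H types).

Library defaults are a minimum similarity of 0.75 and at most 5
matches, the optimum of the similarity/match-count grid search that
`grid_search()` reproduces on any user-supplied labelled set. Ties at
equal similarity break by library id so results are identical across
platforms and orderings.

## Training

`fit_coefficients()` solves the over-determined count system by QR
decomposition. Codes whose *atom-level* total occurrence across the
training set is below `min_occurrence = 3` are removed before fitting:
one or two sightings of a type cannot support a coefficient and invite
overfitting. (The cut is on atom totals, not compound presence — a
single compound with three such atoms is accepted.)

Count columns can be exactly collinear — on small sets, aromatic C-H
hydrogens and unsubstituted aromatic carbons co-occur in fixed ratio,
for example. A rank-deficient system has infinitely many least-squares
solutions with identical fitted values; the package returns the
minimum-norm solution via SVD, with a warning, because it is the one
reproducible choice. Fit quality is reported as
$R^2 = 1 - SS_{res}/SS_{tot}$ and the training RMSE; standard errors
come from the SVD factors of the design and are reported only for
full-rank fits, where individual coefficients are identifiable.

Consensus targets: when a training file carries several per-method
predicted logP columns instead of one target, the target is their
arithmetic mean. Averaging several imperfect teachers reduces the
variance of the label; the model then distils them into one additive
predictor.

## Targeted sampling

Random subsampling of a large structure collection starves rare atom
types. `targeted_sample()` walks the occurrence table from rarest to
most common code and tops up the selection with random compounds
containing each code until `level` selected compounds carry it;
compounds chosen for earlier (rarer) codes count toward later quotas,
so the common codes are usually already saturated when their turn
comes. Codes below `min_occurrence` are not targeted — but the
compounds containing them are not excluded, so such codes may still
ride along. The guarantee, asserted in the tests, is that every code
with dataset occurrence ≥ `min_occurrence` ends up in at least
`min(level, pool size)` selected compounds. All draws run under a
caller-supplied seed recorded in the output manifest.

## Perception layer and its limits

SMILES and SDF input is normalised through OpenBabel (explicit
hydrogens, formal charges, kekulised bonds) and parsed with ChemmineR;
ring perception and the aromatic flags come from ChemmineR's ring
analysis. Multi-fragment records are reduced to the largest covalent
fragment with a warning — counter-ion dominated species are outside
the model's domain. Bond-less records (bare ions, single atoms) bypass
ChemmineR, which refuses them, and are read directly from the V2000
atom lines.

This perception model has known edges: no 3D, no tautomer enumeration,
no pKa-driven charge-state adjustment — the input structure is typed
as drawn. Borderline aromatic systems follow ChemmineR's perception
(2-pyridone, for instance, is treated as a non-aromatic ring), so a
library and a query should always be typed by the same package version,
which the typer version tag enforces.

## The fixture generator

`make_fixtures()` is the package's synthetic study system: a fixed
panel of 89 small organic molecules spanning every classifier family
(sp3/aromatic/carbonyl carbons; amine, aniline, amide, heteroaromatic
and charged nitrogens; the full oxygen spectrum; F/Cl/Br/I; S and P;
anions and cations), typed into 66 distinct codes, with targets
generated as `hologram · alpha_toy + N(0, 0.35)` from seeded toy
coefficients of realistic magnitude (sd 0.4). The noise default of
0.35 log units matches the scale of residual a consensus-target fit
leaves. What the panel does *not* emulate: the size and chemical
breadth of a real training collection, real experimental error
structure, or conformer/tautomer ambiguity — so green tests on
fixtures demonstrate the algebra and the classifier logic, not
field accuracy.

On so small a panel the count matrix is rank deficient, so individual
toy coefficients are not recoverable; the estimable quantity is the
fitted surface, and the tests require the fitted values to sit within
twice the injected noise of the noise-free truth. Identifiable
parameter recovery is checked where it is well-posed:
`simulate_training_matrix()` draws Poisson count holograms
(per-code rates from U(0.5, 3)) at n = 1000 with noise sd 0.3, where
every recovered coefficient must fall within three standard errors of
truth. These problem sizes — 89 molecules end-to-end, 1000×20 for
recovery, 1000 compounds with a 5-compound planted rare code for the
sampler guarantee — were chosen as the smallest sizes at which each
property is cleanly testable.

## Reproducibility choices

* All randomness (toy coefficients, noise, sampler draws, simulated
  counts) flows from explicit integer seeds; sampling restores the
  caller's RNG state afterwards.
* Coefficient bundles serialise at full precision (17 significant
  digits) and round-trip bit-exactly.
* Library ranking ties break by id; refitting a model on its own
  fitted values reproduces the coefficients; row and column order of
  the design matrix do not affect the solution.
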