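---
title: "Methods: the algapept in silico peptide-screening cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the algapept in silico peptide-screening cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algapept)
```

`algapept` re-implements, as offline and tested code, the computational arm
of a bioactive-peptide discovery workflow: starting from short peptides
identified by LC-MS/MS in a macroalgal protein hydrolysate, it predicts
their bitterness, simulates their gastrointestinal (GI) digestion, matches
the released fragments against known bioactives, and provides the
allergenicity- and toxicity-screening machinery applied downstream. This
vignette records the models, the tunable parameters, the numerical and
design choices, and the known limitations. It states no result that the
package's test suite or `scripts/acceptance.R` does not itself compute.

## The bundled study data

The package ships, as human-diffable TSV files under `inst/extdata/`:

* the 48 identified peptides (lengths 6–23) with their printed masses, m/z,
  charge states and Q-values, one of them carrying a deamidation
  annotation;
* the 16-entry di/tri-peptide bioactive reference (ACE-I, DPP IV, HMG-CoA
  reductase inhibitors), with duplicated sequences merged on load;
* the 70 digestion fragments with their external SVM toxicity scores and
  allergenicity labels (28 allergenic, 42 non-allergenic);
* the 7 digestion-resistant peptides;
* the 20-row residue property table (Δf, monoisotopic and average masses,
  E-descriptors) and the cleavage-rule dialect.

`load_fixtures()` re-checks all cardinalities (48 / 16 / 70 = 28 + 42 / 7)
and sequence validity at load time and refuses to return a malformed set.

## Masses and m/z

Monoisotopic mass is the residue-mass sum plus one water (18.010565 Da)
plus modification deltas; deamidation contributes +0.984016 Da per site and
is modelled as a **mass delta, not a sequence edit** — the digestion engine
and the Q rule see the unmodified residue letter, which is how the
identified deamidated peptide is handled throughout. Average mass uses the
average-residue scale and average water (18.01528 Da). m/z uses the proton
mass 1.007276 Da, which reproduces the printed two-decimal m/z values;
using the hydrogen atomic weight instead would not. Masses are additive
under concatenation minus one water, which the suite property-tests on
random peptide pairs, and the m/z ↔ mass relation is tested as an exact
round trip for z = 1…5.

All 48 printed calculated MW and theoretical m/z values reproduce to
±0.01 Da (the printed precision). The fragment-table MW column is on the
average scale for 63 of 70 rows; the 7 remaining rows are the
digestion-resistant parents, whose printed values were carried over
verbatim from the identified-peptide table (5 monoisotopic masses, 2
theoretical m/z values). The mass checks therefore run on the 63
average-scale cells and treat the 7 carry-overs as what they are.

## Bitterness: the Ney Q rule

`Q = (Σ Δf)/n` (cal/mol) over the residue composition; a peptide is
predicted bitter iff `Q > 1400` **and** `MW < 6000 Da`. Choices:

* **Strict inequality** at 1400, matching the rule's "exceeds" phrasing; a
  dipeptide scoring exactly 1400 (e.g. KM) is not bitter.
* **MW on the average scale.** The 6 kDa bound is coarse enough that the
  scale is immaterial; average is used for consistency with the fragment
  tables.
* **Δf constants.** The shipped table is not taken on faith: a unit test
  reconstructs all 20 values by solving the over-determined linear system
  contributed by the bundled peptide rows (`Σ Δf = Q·n` per row) and
  requires the exact solve to land on the shipped constants.

Three printed Q-values are internally inconsistent with *any* Δf table that
satisfies the remaining 45 rows, each of which pins its residues through
several other exactly-matching rows: HSAVFAAS (printed 883.75, computed
888.75), VVPKAAPPPN (1343 vs 1681) and KFKGMNHINDIEKFK (1304 vs 1340.67).
These are treated as errata of the source table; the fixtures store the
printed values verbatim and the tests document the three rows as the only
mismatches. The VVPKAAPPPN erratum has a visible consequence: its correct
Q (1681) exceeds the bitterness threshold, so `bitter_subset()` flags 9 of
the 48 peptides where the original report, using its mis-printed value,
listed 8. The package deliberately reports the computation, not the typo.

## Simulated GI digestion

### Rule model

A cleavage rule constrains a window of up to eight positions
(P4…P1 ↓ P1′…P4′) around a candidate site between residues *i* and *i*+1;
each position may carry a required residue set or a forbidden set. Window
positions beyond the termini carry no residue: they **satisfy forbidden
sets and fail required sets**. Every enzyme owns `cleave` rules and `block`
(exception) rules; an enzyme cuts a site iff at least one of its cleave
rules matches and none of its block rules does. The four enzymes act
**simultaneously**: sites are unioned in one pass over the parent, which is
required to reproduce fragments whose flanking cuts come from different
enzymes. Rule sets live in editable TSV files (cells: `.` unconstrained,
`KR` required, `^P` forbidden), round-trip through
`read_cleavage_rules()`/`write_cleavage_rules()`, and alternative dialects
can be swapped in by path.

### The shipped dialect

* **Trypsin** — cleave after K/R; blocked before proline (with the
  classical two positive exceptions W‑K|P and M‑R|P) and at the classical
  small-motif exceptions (C/D‑K|D, C‑K|H/Y, C‑R|K, R‑R|H/R).
* **Chymotrypsin, low specificity** — cleave after F/Y/W/L/M/H; blocked
  before proline, plus W|M, M|Y and H|D/M/W. Low specificity (including M
  and H) is required by the fragment evidence: H-side cuts release
  documented fragments.
* **Pepsin** — at pH 1.3 the target set is {F, L}; at pH > 2 it widens to
  {F, L, W, Y}. Two rules per pH: a P1-side rule (cut after a target
  residue) with forbidden P2 = P and P3 ∈ {H, K, R}, and a P1′-side rule
  (cut before a target residue) with forbidden P2 = P, P2′ = P and
  P3 ∈ {H, K, R}.

The pepsin context vetoes beyond P2 are **fixture-derived calibrations**:
the bundled fragment tables are the arbiter of the dialect, and the
P2′/P3 constraints (and the *absence* of a P1′≠P veto on the P1-side rule)
are each forced by specific parent/fragment pairs — e.g. cuts into a
following proline must be allowed for the fragments ending in L before P,
while a P2′ proline or a P3 basic residue must veto the P1′-side rule to
keep other documented fragments whole. With this dialect the 48 parents
yield exactly the 86 documented unique fragments (length ≥ 2), the 7
documented intact peptides, and the 16 bioactive matches.

### Semantics and invariants

* Fragments partition the parent (tested on every digestion); number of
  fragments = number of cut sites + 1; zero sites ⇔ intact.
* The vectorised engine is checked against an independently written naive
  per-site oracle (`brute_force_digest()`) on the fixtures and on 1000
  seeded random peptides.
* Monotonicity: removing a cleave rule never adds sites (tested per rule).
* Digestion is **single-pass, not idempotent**: a context veto can
  disappear when the protecting residue ends up across a cut. The released
  fragment GTF illustrates this — shielded in its parent by a P3 basic
  residue, it would be re-cut in isolation. The source data itself (GTF is
  a final fragment) shows the original workflow was also single-pass, so
  re-digestion of fragments is intentionally not performed; the test suite
  pins the counterexample, and asserts idempotence only for the
  context-free trypsin subset, where it genuinely holds.
* `min_length` defaults to 2: no single residues occur in the documented
  fragment tables, and single residues are uninformative for
  dipeptide-level matching.

## Bioactive matching

Matching is exact, case-normalised, **whole-sequence** equality against the
loaded reference — a reference dipeptide never matches inside a longer
fragment, because the workflow compares released fragments, not motifs.
"Novel" therefore means only "absent from the loaded reference" (16
sequences by default); substituting a larger reference export will shrink
the novel set accordingly. Matched and novel always partition the pool,
which is property-tested on random pools.

## Allergenicity machinery: ACC + 1-NN

Variable-length sequences are mapped to fixed-length vectors by auto- and
cross-covariance over a d = 5 E-descriptor profile:
`A_jk(l) = Σ_{i=1}^{n−l} E_j(aa_i) · E_k(aa_{i+l}) / (n − l)`,
for lags `l = 1…L`, giving `d²·L` components regardless of peptide length
(for peptides longer than `L`). Classification is k-nearest-neighbour
(k = 1 by default) under Euclidean distance against any labelled reference
set, with a deterministic tie-break (lowest reference id
lexicographically), so predictions are invariant to reference ordering.

Choices and limitations:

* `l_max` defaults to 8, the standard ACC lag of the method family, and is
  configurable.
* Sequences of length ≤ `l_max` cannot be transformed; `classify_pool()`
  reports them as `"not_classifiable"` rather than dropping them. Many
  real digestion fragments (length 2–5) fall in this class at the default
  lag, so the published per-fragment allergen labels — which also depend
  on an external ~2400+2400-protein training database that is out of
  scope — are **not** a reproduction surface. The bundled labels are data,
  used for bookkeeping, never as a training set.
* Validation is by parameter recovery instead: seeded synthetic two-cluster
  reference sets (below) must be recovered by held-out 1-NN, the same
  machinery is cross-checked against an independent kNN implementation
  (`class::knn`), and identical sequences must classify at distance zero.

## Screening scores

The two assay formulas are implemented exactly, with their algebraic limits
(0% when the sample equals the uninhibited control, 100% at full
inhibition) tested as identities; out-of-range percentages from
pathological absorbances are returned as-is with a warning, and a zero
denominator (blank1 = blank2) or non-positive initial activity is a domain
error. Toxicity is a threshold rule on **externally supplied** SVM scores
(`toxic ⇔ score > 0`, boundary non-toxic); no toxicity model is trained or
shipped, and over the bundled score column the rule yields zero toxic
calls.

## Synthetic data

`generate_peptides()` draws lengths uniformly from a configured range
(default 2–23, the fixture's span) and residues independently from a
composition that defaults to the empirical frequencies of the 48 bundled
peptides — chosen over a uniform composition so that rare residues (W, C)
are exercised at realistic rates. `generate_reference_sets()` produces two
labelled populations by tilting the composition in opposite directions
along the first E-descriptor (a hydrophobicity axis): class weights
∝ `exp(∓s·e1)` with `s = cluster_separation`. At `s = 0` the populations
are identical and held-out 1-NN recovery sits at chance; at the default
`s = 10` the ACC clusters are well separated and recovery at the tested
seeds reaches ≥ 0.95. Generation stays in sequence space (like real
inputs) and separation is verified post hoc by the recovery experiments.

All generators take an integer seed through `generator_config()` and use
R's default Mersenne-Twister stream under a local RNG scope, so identical
seeds give identical outputs without disturbing the caller's RNG state.
What the generators do **not** emulate: residue autocorrelation within real
peptides, hydrolysis kinetics, mass-spectral noise, and any property of
real allergen databases — passing the recovery tests shows the machinery
is correct, not that real allergens are separable.

## Problem sizes and tolerances

Numeric comparisons against printed values use ±0.01 (half a printed least
significant digit, doubled) for masses, m/z and Q-values. Property tests
run on a few dozen seeded random peptides per property; the engine/oracle
equivalence runs on 1000; the recovery experiments use 120–200 entries per
class. These sizes were chosen to exercise every code path (including rare
residues and termini) while keeping the default suite fast; all synthetic
inputs are regenerated from seeds at test time, never stored.

## Known limitations

* The cleavage dialect is calibrated to one study's fragment tables; it is
  a faithful single-pass Keil-style model, not a general claim about
  enzyme kinetics, partial digestion or missed cleavages.
* Whole-sequence bioactive matching will not find motifs embedded in
  longer fragments, by design.
* The allergenicity module provides the transformation/classification
  machinery only; absolute allergenicity calls require a curated labelled
  reference the user must supply.
* Bitterness is composition-only (the Q rule); sequence-order effects on
  taste are outside the model.
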