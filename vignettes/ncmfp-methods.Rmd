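---
title: "Scaffold-based hierarchical fingerprints: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold-based hierarchical fingerprints: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmfp)
```

## The model

Natural compounds are poorly served by general-purpose structural keys:
their chemistry is dominated by large fused ring systems with oxygen-rich
decoration, and the handful of keys such systems trip in a 166- or 881-bit
keyset carries little discriminating information. This package encodes a
compound against a *hierarchy of molecular scaffolds* instead. Three feature
classes make up the fingerprint:

* **Scaffolds.** The Bemis–Murcko (BM) framework of a molecule keeps every
  ring atom, every linker atom between rings, and any atom double-bonded to a
  retained atom (exocyclic and terminal double bonds are part of the
  scaffold); all other side-chain atoms are removed. Ring systems are then
  pruned one peripheral ring at a time until a single ring remains. A
  scaffold with $r$ rings (smallest set of smallest rings) sits at **level**
  $r-1$ of the hierarchy, so level-0 scaffolds are single rings. For a
  class-labelled compound collection, the *scaffold library* of class $i$ is
  the union of the hierarchies of its compounds, deduplicated within each
  (class, level) cell and ordered lexicographically by canonical SMILES, so
  the $k$-th scaffold at level $j$ of class $i$ is reproducible across runs.
  Duplicates across classes are retained: per-class counts are meaningful on
  their own and totals are row sums.

* **Scaffold–fragment connection points (SFCPs).** The atom positions on a
  scaffold at which substituents are attached. Positions are 0-based indices
  into the scaffold's *own* canonical atom ordering, reduced over the
  scaffold's automorphism group to the minimal index tuple. Without this
  reduction a symmetric scaffold (all six benzene atoms are equivalent) would
  report arbitrary positions depending on the query's atom numbering; with
  it, a methyl on toluene is always position 0 and the two methyls of
  *m*-xylene are always positions {0, 2}.

* **Fragments.** Deleting the atoms of a matched scaffold from a query cuts
  the remainder into connected components; each component becomes a fragment
  carrying a `*` marker at every cut bond, identified by canonical SMILES and
  indexed by ascending molecular weight (ties broken lexicographically). The
  marker weighs nothing but is part of the identity, so a methoxy substituent
  (`*OC`) never collides with an ethanol-like fragment.

Fingerprint generation follows six steps: (I) preprocessing — hydrogens are
made explicit, atom indices fixed, molecular weight and Hill formula
computed; (II) scaffold matching — every dictionary scaffold that is a
subgraph of the query is found by exact substructure matching; (III)
fragment generation; (IV) SFCP assignment; (V) fragment identification by
canonical-form lookup; (VI) bit-string representation. The bit layout is
`scaffold block ∥ SFCP block ∥ fragment block`, fixed by a *feature
dictionary* built once from a scaffold library plus a reference compound
set. Queries never change the layout: unknown fragments or connection points
are dropped and counted in per-fingerprint flags. A query that matches no
scaffold yields the all-zero string and a `no_scaffold_match` flag.

One reading ambiguity is worth recording: the generation procedure speaks of
*a* scaffold being selected, but a fixed multi-thousand-bit layout only makes
sense if several scaffold bits can fire. We therefore set bits for **all**
matched scaffolds and derive SFCP/fragment features from each match;
`compute_ncmfp(mode = "single")` restricts to the largest matched scaffold
for comparison. Similarly, "exact matching" is read as substructure
containment (fragments could not exist otherwise), not whole-graph equality.

## Library diagnostics

Two diagnostics guide the choice of scaffold levels.

**Database coverage.** For a compound database $Y$ and level $m$, the
coverage is $X_Y^m = \sum_i X_Y^{m,i}$ with $X_Y^{m,i} =
n^{m,i}_{\mathrm{matched},Y} / n_Y$, the fraction of compounds containing at
least one level-$m$ scaffold of class $i$. A compound matching several
classes is counted once: it goes to the class whose matched scaffold has the
largest ring count, ties broken by library class order (the source procedure
states the one-class rule but not the tie-break; this choice is
deterministic and favours the most specific match). Coverage is monotone
non-increasing in level, since every level-$(m{+}1)$ scaffold contains a
level-$m$ descendant.

**Class-assignment heat map.** For class-labelled compounds,
$P^m_{i,i} = n^m_i / n^o_i$ and $P^m_{i,j} = n^m_{i\to j} / n^o_i$ count how
often compounds of true class $i$ are assigned to class $j$ by level-$m$
scaffold matching. An ideal library gives the identity matrix. Here each
compound contributes to *every* matching class by default (the matrix is
described as asymmetric with per-cell proportions, which requires
multi-assignment); `multi_assign = FALSE` switches to the coverage dedup
rule since the source is silent about which counting the figure used.

## Benchmark protocol

Fingerprint quality is measured with a 1-nearest-neighbour classifier under
Tanimoto similarity $|a \wedge b| / |a \vee b|$ — deliberately the simplest
model, so performance reflects the representation rather than the learner.
The protocol: ten repeats of a seeded random 80/20 train/external split,
tenfold cross-validation within the training portion, 1-NN prediction of the
external set, and the average of the ten external metric sets as the
headline result. A 1-NN model has no hyperparameters, so the CV metrics are
reported for protocol fidelity only. Activity labels derive from IC50 with a
strict cut: active iff IC50 < 10 µmol.

Metrics are accuracy, sensitivity, specificity, precision, F1 (harmonic mean
of precision and sensitivity) and the Matthews correlation coefficient;
0/0 ratios are reported as 0 with a `degenerate` flag.

**Y-randomization** guards against chance separation: labels are reshuffled
(default 100 rounds, configurable), the full protocol is rerun per round,
and the original model is summarised as
$Z = (M_{\mathrm{ori}} - \bar M_{\mathrm{rand}}) / \sigma_{\mathrm{rand}}$
for both MCC and accuracy; $Z > 3$ is read as significant. A zero spread
across rounds is flagged rather than divided by.

Numerical and procedural choices:

* Tanimoto of two all-zero fingerprints is 0 (possible under
  `no_scaffold_match`).
* 1-NN ties are broken by stable input order and logged.
* Splits are stratified by class so small datasets cannot produce
  single-class test sets (can be disabled).
* Before any seeded draw the rows are put into a canonical order (label,
  then bit string), making results invariant to how the input happened to be
  sorted.
* All randomness flows from the protocol seed; reruns are bit-identical.

## What the synthetic generator emulates

Real inputs (class-annotated natural-product dictionaries, activity-screened
compound sets) are licensed databases, so the package ships a seeded
generator instead. Each class owns a distinct parent ring system from a
built-in catalog (single heteroaromatic and saturated rings first, fused
bicyclics after, echoing class-specific core structures at toy scale);
compounds are built by attaching marked fragments at free-valence scaffold
positions; a planted rule — presence of one designated fragment, optionally
at a fixed position — defines activity, optionally flipped with probability
`noise_rate`; IC50 values are drawn consistently with the activity
threshold. Classes are balanced to within one compound and every structure
contains a ring.

Two generator conditions are deliberate and fixed. First, each compound
carries at most one incidental decoration beside the (possible) rule
fragment, from a four-fragment vocabulary (methyl, hydroxy, amino, methoxy).
The parameter-recovery property this generator must support — external 1-NN
accuracy ≥ 0.95 on a noiseless planted rule at n = 200 — requires the
training split to cover the decoration combinatorics; with a larger
vocabulary or more decorations per compound, rare undecorated or
singleton inactives sit closest to active supersets under Tanimoto
similarity and external accuracy plateaus around 0.9 regardless of how
clean the labels are. Second, all randomness flows from the single spec
seed; there is no global RNG state.

What passing these tests shows — and does not. The fixtures have shallow
hierarchies (one or two rings), small fragment sets, clean class structure
and a single-fragment activity rule, so green tests demonstrate the
correctness of the machinery (pruning, symmetry reduction, bit accounting,
protocol plumbing), not performance on real natural-product collections,
whose deep fused systems, charged species and tautomers are outside what the
generator produces.

## Degenerate inputs and edge handling

* Acyclic molecules are rejected wherever a scaffold is required (the
  fingerprint is defined only for ring-containing compounds) and filtered
  out, with counts, when reading compound sets.
* Multi-component records (salts) keep the largest covalent component
  before the ring filter; standard practice, as the sources are silent.
* Pruning candidates that disconnect the scaffold, fail to reduce the ring
  count by exactly one, or cannot be re-perceived as a valid structure
  (for example an unkekulizable aromatic remainder) are discarded with a
  logged note.
* Fragments produced by cutting through fused aromatic systems can fail
  canonicalization; they are counted as unknown rather than guessed at.
* Stereochemistry is parsed and ignored: the fingerprint is 2-D.
* Formal charges are carried on atoms but do not participate in matching;
  elements and aromatic state must agree exactly, so aromatic rings never
  match their saturated analogues.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `levels` (`build_library`) | 1, 2 | scaffold levels kept in a library; levels 1+2 balance coverage against class discrimination, which level-0 single rings lack and level-3 scaffolds buy at too low coverage |
| `train_fraction` | 0.8 | split protocol training share |
| `repeats` | 10 | random splits averaged for the headline metrics |
| `cv_folds` | 10 | cross-validation folds on the training portion |
| `rounds` (`y_randomization`) | 100 | label shuffles behind the null distribution (the source does not state its count) |
| `threshold` (`label_activity`) | 10 µmol | strict activity cut-off |
| `noise_rate` (`make_toy_spec`) | 0 | label-flip probability in synthetic data |

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run entirely on generated data:
libraries from a few dozen compounds, dictionaries of ~20 bits, a benchmark
of 200 compounds across 3 classes with 20 Y-randomization rounds (50 for the
shuffled-label null). These sizes exercise every code path while keeping the
whole suite in the minutes range; the same functions ingest arbitrarily
large SMILES/SDF collections through `read_compound_set()`, where
substructure matching cost grows with both library size and compound size.

## Known limitations

* Aromaticity follows Open Babel's perception; toolkits differ on borderline
  systems (fused quinones, mesoionics), so scaffold counts on real databases
  may shift slightly relative to implementations built on other toolkits.
* The published fingerprint instance (676 scaffolds, 10,016 bits) is tied to
  a licensed reference compound set; this package reproduces the *procedure*
  (the dictionary builder makes the layout derivable from any library +
  reference set) rather than those constants.
* Bridged and spiro polycyclics follow SSSR counting; a spiro ring is a
  prunable peripheral, and bridged systems may reach level 0 through more
  than one single-ring scaffold.
* Fragments attached to a scaffold at two or more points carry one marker
  per cut; dictionary entries observed in practice have a single marker.
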