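---
title: "Ontology-guided rule learning: model, tuning and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-guided rule learning: model, tuning and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontorules)
```

## The model

`ontorules` learns IF-THEN rules whose antecedents are conjunctions of
ontology terms and whose (implicit) consequent is the positive class of a
two-dimensional binary matrix. The ingredients are:

* **Examples.** Every cell of a genes × samples matrix is one example,
  identified by its (row id, column id) pair. In *matrix mode* cells valued
  1 are positive and cells valued 0 negative; numeric matrices are first
  binarized with a strict cutoff (`value > threshold`, default 0.5, the
  usual "expressed above 0.5 TPM" rule — a value exactly at the cutoff is
  *not* expressed). In *treatment/control mode* a set of pre-selected rows
  is crossed with a treatment column group (positives) and a control group
  (negatives), and the matrix values are ignored.
* **Ontologies.** One or more OBO DAGs; `is_a` edges define the
  "more general than" partial order ≽ (reflexive and transitive; `part_of`
  can be opted in at parse time, obsolete terms are dropped). Terms of
  different ontologies are never comparable — in particular a rule may
  freely mix gene-ontology and anatomy-ontology terms.
* **Annotation propagation.** Direct row/column annotations are propagated
  along ≽ into semantic covers `S(t)`: the examples annotated by `t` or any
  term below it. A rule `R` covers `Θ(R)`, the intersection of its terms'
  covers; the empty rule covers everything.

A separate-and-conquer covering loop induces up to `max_rules` rules; after
each accepted rule the covered examples are removed (all of them by
default, or only the covered positives with
`covering_removal = "positives-only"`, the classical unordered-CN2 choice)
and the next rule is induced on the remainder.

## Quality, potential quality, significance

Covered examples are classified positive, which yields confusion counts
TP/FP/FN/TN and three evaluators: accuracy, F1, and a single-point AUC
(the area under the one-point ROC polygon, computed exactly as the sum of
two triangles and a rectangle; note this construction yields 1 when
TPR = FPR = 1, unlike the trapezoidal one-point AUC — it is kept in this
form deliberately). Each evaluator has a *potential quality* `Q_p`, the
quality reached if refinement removed every covered negative while keeping
every covered positive. `Q_p` is an admissible bound: refinements only
shrink covers, so no specialization can exceed it — the test suite verifies
this by exhaustively enumerating all sub-covers of 12-example worlds.

Rules must also be significant under a likelihood-ratio statistic compared
against the χ² distribution with 1 df (99% level by default, critical value
6.635). Two LRS conventions are provided:

* `lrs_variant = "printed"` (default) uses TP+TN as the "covered set" size:
  `2(TP·log2((TP/(TP+TN))/((TP+FN)/|E|)) + TN·log2((TN/(TP+TN))/((FP+TN)/|E|)))`.
* `lrs_variant = "cn2"` is the classical rule-learning form with the
  covered set TP+FP (FP in place of TN throughout).

Both are nonnegative (each is 2·n·KL between a cover distribution and the
class prior). They behave very differently at the extremes: under the
`"printed"` convention a *perfect* rule (FP = FN = 0) has LRS exactly 0 and
can therefore never pass the significance gate, while an all-covering rule
scores highly; the `"cn2"` convention does the opposite. The package keeps
`"printed"` as the documented default form of the statistic, but any
workflow that expects perfect rules to be accepted — planted-rule recovery
in particular — must run with `lrs_variant = "cn2"`; the recovery tests and
examples do exactly that, and we recommend `"cn2"` for real analyses.

## The refinement operator and its two reductions

Search starts from the empty rule; each level appends one feature (ontology
term) to each beam rule. Two reductions prune candidates:

* **Redundant Generalization.** If the appended term is comparable with a
  term already in the rule (either direction; duplicates count via
  reflexivity), the candidate's cover equals its parent's, so it is skipped
  *before* evaluation. All emitted rules are therefore antichains of ≽.
* **Redundant Non-potential.** An evaluated candidate with
  `Q_p < best quality so far` is dropped along with its whole
  specialization subtree. The comparison is strict: a candidate tying the
  bound survives, so an equal-quality rule can never be lost. The bound is
  the best *significant* quality found, held fixed for the duration of one
  refinement call and refreshed between calls; it resets to 0 in every
  single-rule induction.

The beam (`filter_rules`) keeps the `beam_width` best candidates by
quality; ties break deterministically by larger cover, then by the
lexicographically smallest sorted term tuple, so runs are bit-reproducible
without any RNG. The best-rule update also requires *strictly* greater
quality, so the earliest-found rule wins ties. Disabling pruning
(`pruning = FALSE`, or `run_exhaustive_baseline()`) recovers the
traditional CN2 refinement operator; with an infinite beam it degenerates
to brute-force enumeration, which the tests use as an oracle.

## Feature selection

Three nested pre-filters over the term set:

* `atLeastOne`: terms covering at least one example in scope. A term with
  an empty cover can only produce empty-cover rules, so nothing useful is
  lost.
* `onlySig`: covering terms whose singleton rule passes the LRS gate. The
  non-empty-cover requirement is part of this method here: significance of
  a term that covers nothing is vacuous (and under the `"printed"` LRS such
  terms can otherwise score arbitrarily high), and requiring coverage keeps
  the three selections nested.
* `sigAtLeastOne`: covering terms that are significant or generalize a
  significant term.

Because ≽ is reflexive, `onlySig ⊆ sigAtLeastOne ⊆ atLeastOne` holds
structurally, and the acceptance tests confirm the size ordering on random
instances under both LRS conventions.

## Tunables

| parameter | default | meaning |
|---|---|---|
| `evaluator` | `"acc"` | rule quality: `acc` for balanced classes, `f1` to emphasize positives, `auc` for imbalance |
| `feature_selection` | `"atLeastOne"` | term pre-filter (above) |
| `beam_width` | 100 | candidates kept per refinement level; `Inf` = exhaustive breadth |
| `max_rule_length` | 10 | maximum terms per rule (longer rules are hard to interpret) |
| `max_rules` | 10 | covering budget |
| `significance` | 0.99 | χ²(1) confidence level of the LRS gate |
| `covering_removal` | `"all-covered"` | which covered examples leave the working set |
| `pruning` | `TRUE` | apply the two reductions |
| `lrs_variant` | `"printed"` | LRS convention (see above; use `"cn2"` when perfect rules must pass the gate) |
| binarization threshold | 0.5 | strict cutoff for numeric matrices (TPM scale) |

## Synthetic data: what it does and does not emulate

`build_toy_fixture()` is a fully hand-checkable seven-term, three-example
world; every cover, confusion count and quality in it is verifiable on
paper, and the edge set is one reconstruction among the several consistent
with the required propagated covers — tests assert the covers, not the
edges. `random_ontology()` grows single-rooted DAGs (each non-root term
draws 1..`max_parents` earlier terms as parents); `planted_rule_dataset()`
annotates rows (and optionally columns) with random terms, plants a
pairwise-incomparable conjunction with a non-trivial cover (at least 4
cells and not the whole matrix), writes its cover as the 1-cells and
optionally flips cells with independent probability `noise_rate`.

These generators exercise the algorithmic claims — planted-rule recovery,
pruning soundness and economy, feature-selection nesting — but they do not
emulate real expression data: no TPM-scale marginal distributions, no
correlated noise between samples, no annotation bias toward well-studied
genes, and ontologies that are orders of magnitude smaller than GO. Passing
tests therefore certify the search machinery, not biological performance on
real datasets.

## Numerical and degenerate-input choices

* Quality equality between pruned and unpruned runs is asserted to 1e-12
  (pure floating-point determinism; exact equality holds in practice).
* F1 with a zero denominator is 0; accuracy on zero examples and AUC with
  an empty class raise errors.
* `0·log2(·) = 0` and degenerate ratios contribute 0 to the LRS.
* Single-rule induction requires at least one positive and one negative
  example; the covering loop stops when either class empties, when no
  significant rule exists, or when an accepted rule covers no positives.
* Example identity is the (row id, column id) pair; integer indices are an
  internal detail and all reported output uses the original string ids.
* Annotation terms absent from every loaded ontology are dropped with a
  warning and counted, mirroring how retired IDs occur in real annotation
  files.

## Problem sizes used by the test suite

The shipped tests run on desk-scale worlds chosen to keep the full suite
within a couple of minutes while still exercising every code path: random
DAGs of 10–50 terms, matrices up to 8×5 (30–40 cells), 50 planted
instances per evaluator × feature-selection combination for the pruning
equivalence property, exhaustive sub-cover enumeration on 12 examples, and
full specialization-subtree enumeration over 8-feature worlds. The
algorithms themselves have no such limits; the original use case of this
method class is matrices of thousands of genes against GO-sized
ontologies, where the explored-rule savings of the two reductions are
orders of magnitude.

## Known limitations

* Only positive conjunctive antecedents: no negated terms, disjunctions or
  numeric conditions.
* Binary class only; one rule set describes the positive class.
* `S` is materialized per term as example-id sets; for GO-scale ontologies
  against large matrices a bitset representation would be the natural
  optimization.
* The `"printed"`/`"cn2"` LRS duality means significance-gated results are
  convention-dependent; both are exposed so the choice is explicit.
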