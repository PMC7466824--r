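# ontorules

Ontology-guided conjunctive rule learning for binary omics matrices.

Gene set enrichment tools report single ontology terms enriched in a gene
list. `ontorules` addresses the richer question asked in semantic
biclustering: *which conjunctions of ontology terms — possibly mixing a gene
ontology with a sample/anatomy ontology — describe the over-expressed cells
of a genes × samples matrix?* Each matrix cell is one example, positive if
its (binarized) value is 1; a rule is a set of terms `t1 AND t2 AND ...`
predicting the positive class; the learner returns a small set of such rules
covering the positives. It is aimed at transcriptomics users (bulk or
single-cell) who have an expression matrix plus OBO annotations of its rows
and/or columns, and at anyone studying ontology-aware rule search.

## The method

Let `E+`/`E-` be the positive/negative cells, `T` the terms of one or more
OBO ontologies with the "more general than" partial order ≽, and `M` the
direct annotation of rows/columns by terms. Annotations propagate upward
into per-term **semantic covers**

```
S(t) = ∪ { M'(t') : t ≽ t' }          (all examples at or below t)
Θ(R) = ∩ { S(t) : t ∈ R }             (cover of rule R; Θ(∅) = E)
```

Rules are induced CN2-style: a beam search refines rules by appending terms,
inside a separate-and-conquer covering loop that removes covered examples
after each accepted rule. Rule quality is accuracy, F1 or single-point AUC
of the confusion counts `TP = |Θ(R) ∩ E+|`, `FP = |Θ(R) ∩ E-|`, etc., and a
rule must pass a likelihood-ratio (χ², 1 df) significance gate. Two sound
reductions prune the search drastically without changing the best rule
quality:

* **Redundant Generalization** — a rule containing comparable terms
  (`t1 ≽ t2`) covers exactly what the reduced rule covers; never generate it.
* **Redundant Non-potential** — each quality `Q` has an admissible upper
  bound `Q_p` (all covered negatives become uncovered, e.g.
  `Q_p_ACC = (TP+TN+FP)/(TP+TN+FP+FN)`); a candidate with `Q_p` below the
  best quality found so far is discarded together with its entire
  specialization subtree.

## Worked example

```r
library(ontorules)

onto <- random_ontology(n_terms = 12, max_parents = 2, seed = 7, id = "GO")
inst <- planted_rule_dataset(onto, n_rows = 8, n_cols = 5,
                             rule_length = 2, noise_rate = 0, seed = 11)
inst
#> <planted_instance: 8x5 matrix, planted rule {GO:003, GO:004} covering 15 cells>

ctl <- sem1r_control(evaluator = "acc", lrs_variant = "cn2",
                     max_rule_length = 4)
fit <- sem1r(inst$examples, inst$ontologies, inst$cover, ctl)
fit
#> Ontology-guided rule set (acc evaluator, pruned refinement)
#> Rule 1: GO:010 [GO:010]
#>   TP=15 FP=0 FN=0 TN=25  quality=1.0000  LRS=42.451
#> Uncovered positives: 0 | explored rules: 38 | 0.02s
```

The learner found a rule covering exactly the 15 planted positive cells
(TP=15, FP=0, FN=0: quality 1) — here a single term whose propagated cover
coincides with the planted two-term conjunction, which is an equally valid
description of the same bicluster. The LRS of 42.5 is far above the 99%
critical value 6.635, so the rule is significant. Results are tidyverse
friendly:

```r
tidy(fit)[, c("rule", "label", "tp", "fp", "quality", "lrs")]
#> # A tibble: 1 × 6
#>    rule label     tp    fp quality   lrs
#>   <int> <chr>  <int> <int>   <dbl> <dbl>
#> 1     1 GO:010    15     0       1  42.5
glance(fit)$explored_rules
#> [1] 38
run_exhaustive_baseline(inst$examples, inst$ontologies, inst$cover,
                        ctl)$stats$explored_rules
#> [1] 688
```

The pruned search evaluated 38 candidate rules where the exhaustive
CN2-style operator needed 688 — same answer, ~18× less work. `autoplot(fit)`
plots per-rule quality or coverage; `write_rules_json(fit, "rules.json")`
emits a machine-readable report. A thin command-line wrapper with the same
options lives at `exec/sem1r` (see `Rscript exec/sem1r --help` from a source
checkout, or `system.file("exec", "sem1r", package = "ontorules")` once
installed).

## Learn more

The methods vignette (`vignettes/ontology-rule-learning.Rmd`) documents the
model, the two reduction theorems, the two likelihood-ratio conventions and
when each matters, every tunable with its default, and the limits of what
the synthetic generators emulate.
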