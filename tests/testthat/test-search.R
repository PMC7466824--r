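toy <- build_toy_fixture()

test_that("feature selection implements its three definitions", {
  # every toy term covers something, so atLeastOne keeps all seven
  expect_equal(select_features("atLeastOne", toy$cover, toy$examples,
                               toy$ontology),
               paste0("t", 0:6))

  # a term annotated to no entity is excluded
  ont2 <- ontology("toy2", c(toy$ontology$terms$term, "t7"),
                   parents = c(
                     lapply(toy$ontology$parents[
                       lengths(toy$ontology$parents) > 0], identity),
                     list(t7 = "t0")))
  s2 <- suppressWarnings(build_semantic_cover(ont2, toy$annotations,
                                              toy$examples))
  expect_false("t7" %in% select_features("atLeastOne", s2, toy$examples, ont2))

  # literal re-derivation of onlySig and sigAtLeastOne on random instances
  for (seed in c(81, 82)) {
    inst <- make_instance(seed)
    ont <- inst$ontologies[[1]]
    alpha <- 0.05
    for (v in c("printed", "cn2")) {
      al <- select_features("atLeastOne", inst$cover, inst$examples, ont,
                            alpha, v)
      os <- select_features("onlySig", inst$cover, inst$examples, ont,
                            alpha, v)
      sa <- select_features("sigAtLeastOne", inst$cover, inst$examples, ont,
                            alpha, v)
      sig_lit <- al[vapply(al, function(t) {
        cc <- confusion_counts(inst$cover$cover[[t]], inst$examples)
        oracle_lrs(cc[["tp"]], cc[["fp"]], cc[["fn"]], cc[["tn"]], v) >
          qchisq(1 - alpha, 1)
      }, TRUE)]
      expect_setequal(os, sig_lit)
      sa_lit <- al[vapply(al, function(t) {
        t %in% sig_lit || any(sig_lit %in% descendants(ont, t))
      }, TRUE)]
      expect_setequal(sa, sa_lit)
    }
  }
})

test_that("the beam filter keeps the top candidates under deterministic ties", {
  mk <- function(terms, q, csize) {
    r <- ontorules:::new_rule(terms)
    r$quality <- q
    r$cover <- seq_len(csize)
    r
  }
  few <- list(mk("a", 0.5, 1), mk("b", 0.9, 1), mk("c", 0.1, 1),
              mk("d", 0.7, 1), mk("e", 0.7, 2))
  expect_length(filter_rules(few, 100), 5L)
  top <- filter_rules(few, 3)
  expect_equal(vapply(top, `[[`, "", "key"), c("b", "e", "d"))  # cover breaks tie

  ties <- lapply(sprintf("t%03d", 1:200), mk, q = 0.5, csize = 1)
  kept <- filter_rules(ties, 100)
  expect_equal(vapply(kept, `[[`, "", "key"), sprintf("t%03d", 1:100))

  distinct <- withr::with_seed(91, {
    qs <- runif(30)
    list(rules = lapply(seq_along(qs), function(i) mk(sprintf("x%02d", i), qs[i], 1)),
         qs = qs)
  })
  top10 <- filter_rules(distinct$rules, 10)
  expect_equal(vapply(top10, `[[`, 0, "quality"),
               sort(distinct$qs, decreasing = TRUE)[1:10])
})

test_that("single-rule induction solves the toy world at a loose gate", {
  ctl <- sem1r_control(significance = 0.5, max_rule_length = 3)
  res <- induce_single_rule(toy$examples, toy$ontology, toy$cover, ctl)
  expect_equal(res$rule$quality, 2 / 3)
  expect_equal(res$rule$counts, c(tp = 2L, fp = 1L, fn = 0L, tn = 0L))
  expect_gt(res$stats$explored_rules, 0)
})

test_that("at the default 99% gate the toy world has no significant rule", {
  res <- induce_single_rule(toy$examples, toy$ontology, toy$cover,
                            sem1r_control())
  expect_null(res$rule)
})

test_that("a uniquely annotated positive is found as a perfect singleton rule", {
  ont <- ontology("tiny", c("root", "leafA", "leafB"),
                  parents = list(leafA = "root", leafB = "root"))
  m <- matrix(c(1L, 0L, 0L, 0L), 4, 1,
              dimnames = list(paste0("g", 1:4), "s1"))
  ann <- annotation_map(
    data.frame(id = c("g1", "g2", "g3", "g4"),
               term = c("leafA", "leafB", "leafB", "leafB")), "rows")
  e <- cells_to_examples(m)
  s <- build_semantic_cover(ont, ann, e)
  res <- induce_single_rule(e, ont, s, sem1r_control(significance = 0.5,
                                                     lrs_variant = "cn2"))
  expect_equal(res$rule$terms, "leafA")
  expect_equal(res$rule$quality, 1)
})

test_that("pruned and unpruned searches find the same quality, pruned explores less", {
  for (seed in c(101, 102, 103, 104, 105)) {
    inst <- make_instance(seed)
    for (ev in c("acc", "f1")) {
      ctl <- sem1r_control(evaluator = ev, max_rule_length = 3, max_rules = 1,
                           lrs_variant = "cn2")
      a <- sem1r(inst$examples, inst$ontologies, inst$cover, ctl)
      b <- run_exhaustive_baseline(inst$examples, inst$ontologies, inst$cover, ctl)
      expect_equal(vapply(a$rules, `[[`, 0, "quality"),
                   vapply(b$rules, `[[`, 0, "quality"), tolerance = 1e-12)
      expect_lte(a$stats$explored_rules, b$stats$explored_rules)
    }
  }
})

test_that("covering splits two disjoint planted clusters into two rules", {
  ont <- ontology("cl", c("root", "a", "b", "pad"),
                  parents = list(a = "root", b = "root", pad = "root"))
  m <- matrix(0L, 10, 2, dimnames = list(paste0("g", 1:10), c("s1", "s2")))
  m[1:3, ] <- 1L    # cluster A rows
  m[8:10, ] <- 1L   # cluster B rows
  ann <- annotation_map(
    data.frame(id = paste0("g", 1:10),
               term = c("a", "a", "a", rep("pad", 4), "b", "b", "b")), "rows")
  e <- cells_to_examples(m)
  s <- build_semantic_cover(ont, ann, e)
  ctl <- sem1r_control(lrs_variant = "cn2", significance = 0.95,
                       max_rule_length = 2)
  fit <- sem1r(e, ont, s, ctl)
  expect_equal(length(fit$rules), 2L)
  expect_setequal(unlist(lapply(fit$rules, `[[`, "terms")), c("a", "b"))
  expect_equal(nrow(fit$uncovered_positives), 0L)

  capped <- sem1r(e, ont, s, sem1r_control(lrs_variant = "cn2",
                                           significance = 0.95,
                                           max_rule_length = 2, max_rules = 1))
  expect_equal(length(capped$rules), 1L)
  expect_gt(nrow(capped$uncovered_positives), 0L)

  # all-negative example set induces nothing
  allneg <- cells_to_examples(matrix(0L, 2, 2,
                                     dimnames = list(c("g1", "g2"),
                                                     c("s1", "s2"))))
  s0 <- build_semantic_cover(ont, annotation_map(
    data.frame(id = c("g1", "g2"), term = c("a", "b")), "rows"), allneg)
  expect_length(sem1r(allneg, ont, s0, ctl)$rules, 0L)
})

test_that("an infinite beam without pruning equals brute-force enumeration", {
  for (seed in c(111, 112, 113)) {
    inst <- make_instance(seed, n_terms = 10)
    alpha <- 0.05
    ctl <- sem1r_control(beam_width = Inf, max_rule_length = 3, max_rules = 1,
                         pruning = FALSE, significance = 1 - alpha,
                         lrs_variant = "cn2")
    res <- induce_single_rule(inst$examples, inst$ontologies, inst$cover, ctl)
    want <- oracle_best_quality(inst, "acc", 3, alpha, "cn2")
    got <- if (is.null(res$rule)) 0 else res$rule$quality
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("search respects its iteration budgets", {
  inst <- make_instance(121)
  ctl <- sem1r_control(max_rule_length = 2, max_rules = 3, lrs_variant = "cn2")
  fit <- sem1r(inst$examples, inst$ontologies, inst$cover, ctl)
  expect_lte(length(fit$rules), 3L)
  for (r in fit$rules) expect_lte(length(r$terms), 2L)
  expect_equal(length(fit$stats$per_rule_breakdown) >= length(fit$rules), TRUE)
})

test_that("feature-set sizes are nested across the three selection methods", {
  for (seed in c(131, 132, 133, 134)) {
    inst <- make_instance(seed)
    ont <- inst$ontologies[[1]]
    for (v in c("printed", "cn2")) {
      al <- select_features("atLeastOne", inst$cover, inst$examples, ont, 0.05, v)
      sa <- select_features("sigAtLeastOne", inst$cover, inst$examples, ont, 0.05, v)
      os <- select_features("onlySig", inst$cover, inst$examples, ont, 0.05, v)
      expect_true(all(os %in% sa))
      expect_true(all(sa %in% al))
    }
  }
})
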