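toy <- build_toy_fixture()

test_that("binarization is strict: only values above the cutoff become 1", {
  m <- matrix(c(0.6, 0.0, 0.5, 2.0), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  b <- binarize(m, 0.5)
  expect_identical(as.vector(b), c(1L, 0L, 0L, 1L))  # boundary 0.5 -> 0

  z <- matrix(0, 3, 2, dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
  expect_true(all(binarize(z, 0.1) == 0L))

  r <- withr::with_seed(4, matrix(rnorm(200), 20, 10,
                                  dimnames = list(paste0("g", 1:20),
                                                  paste0("s", 1:10))))
  expect_equal(sum(binarize(r, 0.3)), sum(r > 0.3))

  mm <- m; mm[1, 1] <- NA
  expect_error(binarize(mm, 0.5), "row 1, column 1")
  expect_error(binarize(m, Inf), "finite")
})

test_that("matrix cells become labelled examples with conserved counts", {
  eye <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  e <- cells_to_examples(eye)
  expect_equal(length(e$positives), 2L)
  expect_equal(length(e$negatives), 2L)

  ones <- matrix(1L, 3, 2, dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
  expect_equal(length(cells_to_examples(ones)$positives), 6L)
  expect_equal(length(cells_to_examples(ones)$negatives), 0L)

  r <- withr::with_seed(5, matrix(rbinom(60, 1, 0.4), 6, 10,
                                  dimnames = list(paste0("g", 1:6),
                                                  paste0("s", 1:10))))
  e <- cells_to_examples(r)
  expect_equal(length(e$positives), sum(r == 1))
  expect_equal(length(e$positives) + length(e$negatives), length(r))
})

test_that("treatment/control designs cross rows with column groups", {
  m <- matrix(0L, 5, 7, dimnames = list(paste0("g", 1:5), paste0("s", 1:7)))
  e <- treatment_control_examples(m, paste0("g", 1:3), paste0("s", 1:4),
                                  paste0("s", 5:6))
  expect_equal(length(e$positives), 3L * 4L)
  expect_equal(length(e$negatives), 3L * 2L)
  expect_equal(e$n, 18L)

  empty <- treatment_control_examples(m, character(0), "s1", "s2")
  expect_equal(empty$n, 0L)

  expect_error(treatment_control_examples(m, "g9", "s1", "s2"), "unknown")
  expect_error(treatment_control_examples(m, "g1", c("s1", "s2"), "s2"),
               "overlap")

  for (seed in 1:5) {
    pick <- withr::with_seed(seed, list(
      rows = sample(rownames(m), sample(5, 1)),
      tr = sample(colnames(m), 3),
      ct = character(0)
    ))
    pick$ct <- setdiff(colnames(m), pick$tr)[1:2]
    e <- treatment_control_examples(m, pick$rows, pick$tr, pick$ct)
    expect_equal(length(e$positives), length(pick$rows) * length(pick$tr))
  }
})

test_that("annotation propagation reproduces the toy covers", {
  ids_of <- function(idx) toy$examples$ids$row_id[match(idx, toy$examples$ids$example)]
  expected <- list(t0 = c("e1", "e2", "e3"), t1 = "e1",
                   t2 = c("e1", "e2", "e3"), t3 = "e2",
                   t4 = "e1", t5 = "e2", t6 = "e2")
  for (t in names(expected)) {
    expect_setequal(ids_of(toy$cover$cover[[t]]), expected[[t]])
  }
})

test_that("covers equal the brute-force union over descendants on random data", {
  for (seed in c(11, 12)) {
    inst <- make_instance(seed)
    ont <- inst$ontologies[[1]]
    map <- inst$maps[[1]]
    for (t in ont$terms$term) {
      expect_identical(inst$cover$cover[[t]],
                       oracle_semantic_cover(ont, map, inst$examples, t))
    }
  }
})

test_that("unknown annotation terms are dropped with a warning", {
  ann <- annotation_map(data.frame(id = c("e1", "e1"),
                                   term = c("t4", "NOT:A:TERM")), "rows")
  expect_warning(
    s <- build_semantic_cover(toy$ontology, ann, toy$examples),
    "dropped"
  )
  expect_equal(s$dropped_terms, "NOT:A:TERM")
  expect_equal(s$cover$t4, 1L)
})

test_that("rule covers are conjunctions of term covers", {
  expect_equal(rule_cover(c("t0", "t2"), toy$cover), 1:3)
  expect_equal(rule_cover(character(0), toy$cover), 1:3)  # empty conjunction
  expect_equal(rule_cover(c("t4", "t5"), toy$cover), integer(0))
  expect_equal(rule_cover("unseen-term", toy$cover), integer(0))

  for (seed in c(21, 22)) {
    inst <- make_instance(seed)
    terms <- names(inst$cover$cover)
    scope <- example_scope(inst$examples)
    rules <- withr::with_seed(seed, replicate(10, sample(terms, 3), simplify = FALSE))
    for (r in rules) {
      expect_identical(rule_cover(r, inst$cover),
                       oracle_rule_cover(r, inst$cover, scope))
    }
  }
})

test_that("cover structure is monotone and downward closed", {
  for (seed in c(31, 32)) {
    inst <- make_instance(seed)
    ont <- inst$ontologies[[1]]
    # downward closure of S along every edge
    for (child in names(ont$parents)) {
      for (p in ont$parents[[child]]) {
        expect_true(all(inst$cover$cover[[child]] %in% inst$cover$cover[[p]]))
      }
    }
    # monotonicity of the cover function under rule extension
    terms <- names(inst$cover$cover)
    sets <- withr::with_seed(seed, replicate(8, sample(terms, 2), simplify = FALSE))
    for (r in sets) {
      bigger <- rule_cover(r[1], inst$cover)
      smaller <- rule_cover(r, inst$cover)
      expect_true(all(smaller %in% bigger))
    }
  }
})

test_that("rule generality mirrors cover inclusion", {
  expect_true(is_more_general_rule("t2", c("t0", "t2"), toy$cover))
  expect_true(is_more_general_rule(c("t0", "t2"), c("t0", "t2"), toy$cover))
  expect_false(is_more_general_rule("t3", "t2", toy$cover))
  inst <- make_instance(41)
  terms <- names(inst$cover$cover)
  prs <- withr::with_seed(41, replicate(10, list(sample(terms, 2), sample(terms, 2)),
                                        simplify = FALSE))
  for (p in prs) {
    c1 <- rule_cover(p[[1]], inst$cover)
    c2 <- rule_cover(p[[2]], inst$cover)
    expect_identical(is_more_general_rule(p[[1]], p[[2]], inst$cover),
                     all(c2 %in% c1))
  }
})

test_that("file fixtures round-trip to the in-code toy world", {
  ext <- system.file("extdata", package = "ontorules")
  ont <- parse_obo(file.path(ext, "toy.obo"))
  m <- binarize(read_matrix(file.path(ext, "toy_matrix.tsv")), 0.5)
  ann <- read_annotations(file.path(ext, "toy_annotations.tsv"), "rows")
  e <- cells_to_examples(m)
  s <- build_semantic_cover(ont, ann, e)
  expect_identical(s$cover, toy$cover$cover)
  expect_identical(e$positives, toy$examples$positives)
})
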