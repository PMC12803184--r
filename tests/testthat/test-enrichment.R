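test_that("ancestor closure handles chains, roots and diamonds", {
  dag <- ontology_dag(data.frame(child = c("c", "b"), parent = c("b", "a")))
  closed <- ancestor_closure(dag, list(p1 = "c", p2 = "a"))
  expect_setequal(closed$p1, c("a", "b", "c"))
  expect_setequal(closed$p2, "a")   # root: closed = direct
  diamond <- data.frame(child = c("d", "d", "b", "c"),
                        parent = c("b", "c", "a", "a"))
  dd <- ontology_dag(diamond)
  expect_setequal(ancestor_closure(dd, list(p = "d"))$p, c("a", "b", "c", "d"))
  # matches the brute-force reachability oracle on every term
  anc <- term_ancestors(dd)
  for (t in dd$terms)
    expect_setequal(anc[[t]], bf_ancestors(diamond, t))
})

test_that("closure is idempotent and cycles are rejected", {
  set.seed(12)
  terms <- sprintf("T%02d", 1:20)
  edges <- data.frame(child = terms[-1],
                      parent = sapply(2:20, function(i)
                        terms[sample(i - 1, 1)]))
  dag <- ontology_dag(edges)
  direct <- list(p1 = sample(terms, 3), p2 = sample(terms, 2))
  once <- ancestor_closure(dag, direct)
  twice <- ancestor_closure(dag, once)
  expect_equal(twice, once)
  expect_true(all(mapply(function(d, c) all(d %in% c), direct, once)))
  expect_error(ontology_dag(data.frame(child = c("a", "b"),
                                       parent = c("b", "a"))), "cycle")
})

test_that("Fisher 2x2 equals enumeration on the worked tables", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2, byrow = TRUE)), 0.5)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)),
               1 / 6, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 2), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 1), 2)), "nonnegative")
})

test_that("Fisher 2x2 equals exhaustive fixed-margin enumeration for all N <= 30", {
  for (N in c(5, 12, 21, 30)) {
    tabs <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    tabs$d <- N - tabs$a - tabs$b - tabs$c
    tabs <- tabs[tabs$d >= 0, ]
    p_pkg <- acetylatlas:::fisher_exact_2x2_vec(tabs$a, tabs$b, tabs$c, tabs$d)
    p_or <- mapply(enum_fisher_greater, tabs$a, tabs$b, tabs$c, tabs$d)
    expect_equal(p_pkg, pmin(p_or, 1), tolerance = 1e-9)
  }
  # and the two-sided variant agrees with stats::fisher.test
  set.seed(13)
  for (i in 1:20) {
    tb <- matrix(rpois(4, 5), 2)
    expect_equal(fisher_exact_2x2(tb, "two.sided"),
                 fisher.test(tb)$p.value, tolerance = 1e-8)
    expect_equal(fisher_exact_2x2(tb, "greater"),
                 fisher.test(tb, alternative = "greater")$p.value,
                 tolerance = 1e-8)
  }
})

test_that("tissue enrichment flags planted terms and sets p = 1 where not computable", {
  universe <- sprintf("P%02d", 1:40)
  ann <- setNames(lapply(universe, function(p) character()), universe)
  for (p in universe[1:8]) ann[[p]] <- "Tliver"
  tp <- list(liver = universe[1:10], brain = universe[11:20],
             empty = character())
  em <- tissue_enrichment(tp, ann, universe)
  expect_lt(em$p["Tliver", "liver"], 1e-3)
  expect_gte(em$p["Tliver", "brain"], 0.05)
  expect_equal(unname(em$p[, "empty"]), rep(1, nrow(em$p)))
  expect_equal(unname(em$neglog[, "empty"]), rep(0, nrow(em$p)))
  # term annotating the whole universe is never enriched
  ann2 <- setNames(lapply(universe, function(p) "Tall"), universe)
  em2 <- tissue_enrichment(tp, ann2, universe)
  expect_equal(unname(em2$p["Tall", ]), rep(1, 3))
  expect_error(tissue_enrichment(tp, ann, character()), "empty")
})

test_that("variance-based term selection applies all three strict criteria", {
  nl <- rbind(spike = c(rep(0, 14), 4),
              const5 = rep(5, 15),
              const0 = rep(0, 15))
  em <- structure(list(p = 10^-nl, neglog = nl), class = "enrichment_matrix")
  expect_equal(select_variable_terms(em), "spike")
  expect_equal(select_variable_terms(em, atlas_config(sd_convention = "population")),
               "spike")
  # the spike vector clears the sd threshold under both conventions
  expect_gt(sd(nl["spike", ]), 0.6)
  expect_gt(sqrt(mean((nl["spike", ] - mean(nl["spike", ]))^2)), 0.6)
})

test_that("overlap pruning removes only strictly-over-threshold pairs, keeping the stronger term", {
  nl <- rbind(T1 = c(5, 0), T2 = c(4, 0), T3 = c(3, 0))
  em <- structure(list(p = 10^-nl, neglog = nl), class = "enrichment_matrix")
  tps <- list(T1 = sprintf("P%d", 1:10), T2 = sprintf("P%d", 1:10),
              T3 = sprintf("P%d", 11:20))
  got <- prune_overlapping_terms(c("T1", "T2", "T3"), tps, em)
  expect_setequal(got, c("T1", "T3"))   # identical sets: stronger T1 kept
  # overlap exactly at the threshold (9/10 = 0.9) keeps both
  tps2 <- list(T1 = sprintf("P%d", 1:10), T2 = sprintf("P%d", c(1:9, 30)))
  got2 <- prune_overlapping_terms(c("T1", "T2"), tps2, em)
  expect_setequal(got2, c("T1", "T2"))
})

test_that("parent-child pruning keeps the most specific terms", {
  edges <- data.frame(child = c("c", "b", "e"), parent = c("b", "a", "a"))
  dag <- ontology_dag(edges)
  expect_equal(prune_parent_child(c("b", "c"), dag), "c")
  expect_setequal(prune_parent_child(c("c", "e"), dag), c("c", "e"))
  expect_equal(prune_parent_child(c("a", "b", "c"), dag), "c")
})

test_that("uniqueness ranking scores tissue-specific terms first and is affine-invariant", {
  nl <- rbind(brainy = c(6, 0, 0, 0, 0),
              everywhere = c(5, 5, 5, 5, 5),
              liverish = c(0, 4, 0, 0, 0))
  colnames(nl) <- c("brain", "liver", "kidney", "lung", "heart")
  em <- structure(list(p = 10^-nl, neglog = nl), class = "enrichment_matrix")
  rk <- rank_unique_terms(em, "brain")
  expect_equal(rk$term[1], "brainy")
  expect_equal(rk$score[rk$term == "everywhere"], 0)
  # affine rescaling of a term's profile leaves the ranking unchanged
  nl2 <- nl
  nl2["brainy", ] <- 3 * nl["brainy", ] + 2
  em2 <- structure(list(p = 10^-nl2, neglog = nl2),
                   class = "enrichment_matrix")
  expect_equal(rank_unique_terms(em2, "brain")$score,
               rk$score, tolerance = 1e-12)
})

test_that("select-then-prune output is a subset of input and permutation-stable", {
  set.seed(14)
  nl <- matrix(rexp(30 * 6), 30, dimnames = list(sprintf("T%02d", 1:30),
                                                 sprintf("t%d", 1:6)))
  nl[1:5, 1] <- 6   # a few strong terms
  em <- structure(list(p = 10^-nl, neglog = nl), class = "enrichment_matrix")
  sel <- select_variable_terms(em)
  expect_true(all(sel %in% rownames(nl)))
  tps <- setNames(lapply(sel, function(t) sample(sprintf("P%d", 1:40), 15)),
                  sel)
  kept <- prune_overlapping_terms(sel, tps, em)
  expect_true(all(kept %in% sel))
  perm <- sample(length(sel))
  kept2 <- prune_overlapping_terms(sel[perm], tps, em)
  expect_setequal(kept2, kept)
})
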