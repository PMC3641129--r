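# symmetric closeness matrix from a list of pair values, default 0 elsewhere
sym_from_pairs <- function(prots, pairs) {
  S <- matrix(0, length(prots), length(prots),
              dimnames = list(prots, prots))
  for (p in pairs) S[p[[1L]], p[[2L]]] <- S[p[[2L]], p[[1L]]] <- p[[3L]]
  S
}

test_that("clique density is the mean pairwise symmetrized closeness", {
  S <- sym_from_pairs(c("a", "b", "c"),
                      list(list("a", "b", 0.5), list("a", "c", 0.5),
                           list("b", "c", 0.5)))
  expect_equal(clique_density(c("a", "b", "c"), S), 0.5)

  S2 <- sym_from_pairs(c("a", "b", "c"),
                       list(list("a", "b", 0.2), list("a", "c", 0.4),
                            list("b", "c", 0.6)))
  expect_equal(clique_density(c("a", "b", "c"), S2), 0.4)

  S0 <- sym_from_pairs(c("a", "b", "c"), list())
  expect_equal(clique_density(c("a", "b", "c"), S0), 0)
  expect_error(clique_density("a", S0), "at least 2")
  expect_error(clique_density(c("a", "zz"), S0), "absent")
})

test_that("seed selection removes cliques pruned below the minimum size", {
  prots <- letters[1:6]
  pairs <- c(
    lapply(combn(c("a", "b", "c", "d"), 2L, simplify = FALSE),
           function(p) list(p[1L], p[2L], 0.8)),
    lapply(combn(c("e", "f"), 1L, simplify = FALSE), function(p) NULL))
  S <- sym_from_pairs(prots, Filter(Negate(is.null), pairs))
  # second clique {c,d,e,f}: give its non-{a..d} pairs value 0.56 so its
  # density is 0.6 while cd stays 0.8
  for (p in list(c("c", "e"), c("c", "f"), c("d", "e"), c("d", "f"),
                 c("e", "f"))) {
    S[p[1L], p[2L]] <- S[p[2L], p[1L]] <- 0.56
  }
  cands <- list(c("a", "b", "c", "d"), c("c", "d", "e", "f"))
  expect_equal(clique_density(cands[[1L]], S), 0.8)
  expect_equal(clique_density(cands[[2L]], S), 0.6)
  seeds <- select_seed_cliques(cands, S)
  expect_identical(seeds$seeds, list(c("a", "b", "c", "d")))
  expect_equal(seeds$densities, 0.8)
})

test_that("seed selection keeps pruned remainders meeting the minimum size", {
  prots <- letters[1:7]
  S <- sym_from_pairs(prots, c(
    lapply(combn(c("a", "b", "c", "d"), 2L, simplify = FALSE),
           function(p) list(p[1L], p[2L], 0.8)),
    lapply(combn(c("e", "f", "g"), 2L, simplify = FALSE),
           function(p) list(p[1L], p[2L], 0.5))))
  S["d", "e"] <- S["e", "d"] <- 0.9  # boosts {d,e,f,g} density
  cands <- list(c("a", "b", "c", "d"), c("d", "e", "f", "g"))
  seeds <- select_seed_cliques(cands, S)
  expect_identical(seeds$seeds,
                   list(c("a", "b", "c", "d"), c("e", "f", "g")))
  expect_equal(seeds$densities, c(0.8, 0.5))
})

test_that("two disjoint triangles both become seeds, ordered by density", {
  S <- sym_from_pairs(letters[1:6], c(
    lapply(combn(c("a", "b", "c"), 2L, simplify = FALSE),
           function(p) list(p[1L], p[2L], 0.3)),
    lapply(combn(c("d", "e", "f"), 2L, simplify = FALSE),
           function(p) list(p[1L], p[2L], 0.7))))
  seeds <- select_seed_cliques(list(c("a", "b", "c"), c("d", "e", "f")), S)
  expect_identical(seeds$seeds, list(c("d", "e", "f"), c("a", "b", "c")))
  expect_equal(seeds$densities, c(0.7, 0.3))
})

test_that("selected seeds are always pairwise disjoint", {
  inst <- random_augmented_instance(20L, 0.45, 4L, 0.4, seed = 60L)
  P <- transition_matrix(build_augmented_graph(inst$net, inst$ann))
  S <- symmetrized_distance(unified_distance(P))
  cands <- maximal_cliques(inst$net)
  seeds <- select_seed_cliques(cands, S)
  all_members <- unlist(seeds$seeds)
  expect_identical(anyDuplicated(all_members), 0L)
  expect_true(all(vapply(seeds$seeds, length, 1L) >= 3L))
})

test_that("connectivity score is the seed-normalized mean closeness", {
  S <- sym_from_pairs(c("p", "x", "y", "z"), list(
    list("x", "y", 0.4), list("x", "z", 0.4), list("y", "z", 0.4),
    list("p", "x", 0.4), list("p", "y", 0.4), list("p", "z", 0.4)))
  expect_equal(connectivity_score("p", c("x", "y", "z"), S), 1)

  S["p", c("x", "y", "z")] <- S[c("x", "y", "z"), "p"] <- 0.2
  expect_equal(connectivity_score("p", c("x", "y", "z"), S), 0.5)

  S["p", c("x", "y", "z")] <- S[c("x", "y", "z"), "p"] <- 0
  expect_equal(connectivity_score("p", c("x", "y", "z"), S), 0)

  S0 <- sym_from_pairs(c("p", "x", "y", "z"), list())
  expect_equal(connectivity_score("p", c("x", "y", "z"), S0), 0)
  expect_error(connectivity_score("x", c("x", "y", "z"), S), "member")
})

test_that("expansion is single-pass and monotone in the threshold", {
  inst <- toy_instances()$triangle_pendant
  P <- transition_matrix(build_augmented_graph(inst$net, inst$ann))
  S <- symmetrized_distance(unified_distance(P))
  seed <- c("a", "b", "c")
  # a vacuous threshold absorbs every PPI neighbour of the seed
  expect_setequal(expand_seed(seed, inst$net, S, extend_thres = 1e-9),
                  c(seed, "d"))
  # an unreachable threshold returns the seed unchanged
  expect_identical(expand_seed(seed, inst$net, S, extend_thres = 50),
                   sort(seed))
  # nesting across a threshold grid, on a denser random instance
  inst <- random_augmented_instance(18L, 0.4, 4L, 0.4, seed = 31L)
  P <- transition_matrix(build_augmented_graph(inst$net, inst$ann))
  S <- symmetrized_distance(unified_distance(P))
  seeds <- select_seed_cliques(maximal_cliques(inst$net), S)
  for (s in seeds$seeds) {
    lo <- expand_seed(s, inst$net, S, extend_thres = 0.3)
    hi <- expand_seed(s, inst$net, S, extend_thres = 0.7)
    expect_true(all(hi %in% lo))
    expect_true(all(s %in% hi))
  }
})

test_that("parameters are validated", {
  expect_error(coan_params(c = 1.2), "between 0 and 1")
  expect_error(coan_params(extend_thres = 0), "positive")
  expect_error(coan_params(min_clique = 2L), "at least 3")
})

test_that("an empty network predicts no complexes", {
  expect_length(predict_complexes(ppi_network(), annotation_map()), 0L)
})

test_that("two slim-coherent 4-cliques joined by a bridge come out exactly", {
  inst <- toy_instances()$two_cliques_bridge
  pred <- predict_complexes(inst$net, inst$ann)
  expect_identical(
    complex_keys(pred),
    complex_keys(complex_set(list(sprintf("q%d", 1:4), sprintf("p%d", 1:4)))))
})

test_that("prediction is deterministic and every complex contains its seed", {
  inst <- toy_instances()$random8
  a <- predict_complexes(inst$net, inst$ann)
  b <- predict_complexes(inst$net, inst$ann)
  expect_identical(a, b)
  P <- transition_matrix(build_augmented_graph(inst$net, inst$ann))
  S <- symmetrized_distance(unified_distance(P))
  seeds <- select_seed_cliques(maximal_cliques(inst$net), S)
  for (s in seeds$seeds) {
    expect_true(any(vapply(a$complexes, function(m) all(s %in% m), TRUE)))
  }
})

test_that("the pipeline matches a straight-line re-implementation on toys", {
  for (inst in toy_instances()) {
    pred <- predict_complexes(inst$net, inst$ann)
    oracle <- naive_predict(inst$net, inst$ann)
    expect_identical(complex_keys(pred),
                     complex_keys(complex_set(oracle)))
  }
})
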