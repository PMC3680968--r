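test_that("compatibility enforces one-to-one mappings and chain ownership", {
  p <- fake_pair(c(a = "x"), c(c1 = "d1"), "r1", "s1")
  q_conflict <- fake_pair(c(a = "y"), c(c1 = "d1"), "r2", "s2")
  expect_false(compatible(p, q_conflict))

  q_disjoint <- fake_pair(c(b = "y"), c(c2 = "d2"), "r2", "s2")
  expect_true(compatible(p, q_disjoint))

  # two keys mapping to one value breaks injectivity in the other direction
  q_surject <- fake_pair(c(b = "x"), c(c2 = "d2"), "r2", "s2")
  expect_false(compatible(p, q_surject))

  # r2 claimed by two distinct chains
  p2 <- fake_pair(c(a = "x"), c(c1 = "d1"), c("r1", "r2"), c("s1", "s2"))
  q2 <- fake_pair(c(b = "y"), c(c1 = "d1"), c("r2", "r3"), c("s3", "s4"))
  expect_false(compatible(p2, q2))

  # the same chain matched twice to the same partner is consistent
  p3 <- fake_pair(c(a = "x"), c(c1 = "d1"), c("r1", "r2"), c("s1", "s2"))
  q3 <- fake_pair(c(b = "y"), c(c1 = "d1"), c("r1", "r2"), c("s1", "s2"))
  expect_true(compatible(p3, q3))

  # a chain and its reversed chain count as the same pathway
  p4 <- fake_pair(c(a = "x"), c(c1 = "d1"), c("r1", "r2"), c("s1", "s2"))
  q4 <- fake_pair(c(b = "y"), c(c1 = "d1"), c("r2", "r1"), c("s2", "s1"))
  expect_true(compatible(p4, q4))
})

test_that("the compatibility graph mirrors pairwise compatibility", {
  expect_length(build_compatibility_graph(list())$pairs, 0)

  disjoint <- list(
    fake_pair(c(a = "x"), c(c1 = "d1"), "r1", "s1"),
    fake_pair(c(b = "y"), c(c2 = "d2"), "r2", "s2"),
    fake_pair(c(c = "z"), c(c3 = "d3"), "r3", "s3")
  )
  cg <- build_compatibility_graph(disjoint)
  expect_true(all(cg$adj[upper.tri(cg$adj)]))
  expect_false(any(diag(cg$adj)))

  # p and q conflict on species a; r is compatible with both
  pqr <- list(
    fake_pair(c(a = "x"), c(c1 = "d1"), "r1", "s1"),
    fake_pair(c(a = "y"), c(c1 = "d1"), "r2", "s2"),
    fake_pair(c(b = "z"), c(c2 = "d2"), "r3", "s3")
  )
  cg <- build_compatibility_graph(pqr)
  expect_equal(cg$adj[1, 2], FALSE)
  expect_equal(cg$adj[1, 3], TRUE)
  expect_equal(cg$adj[2, 3], TRUE)
})

adj_from_edges <- function(n, edges) {
  adj <- matrix(FALSE, n, n)
  for (e in edges) adj[e[1], e[2]] <- adj[e[2], e[1]] <- TRUE
  adj
}

test_that("Bron-Kerbosch finds the expected cliques on tiny graphs", {
  triangle <- adj_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(clique_keys(bron_kerbosch_v2(triangle)), "1,2,3")

  path <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(clique_keys(bron_kerbosch_v2(path)), c("1,2", "2,3"))

  empty <- matrix(FALSE, 0, 0)
  expect_length(bron_kerbosch_v2(empty), 0)

  isolated <- matrix(FALSE, 3, 3)
  expect_equal(clique_keys(bron_kerbosch_v2(isolated)), c("1", "2", "3"))
})

test_that("Bron-Kerbosch equals exhaustive subset enumeration", {
  for (seed in 1:40) {
    n <- 4 + (seed %% 9)
    adj <- random_adjacency(n, p = 0.2 + 0.06 * (seed %% 10), seed = seed)
    got <- bron_kerbosch_v2(adj)
    expect_false(attr(got, "truncated"))
    expect_identical(clique_keys(got), oracle_max_cliques(adj),
                     info = paste("seed", seed))
  }
})

test_that("limits truncate the enumeration to a maximal-clique prefix", {
  adj <- random_adjacency(10, p = 0.5, seed = 99)
  full <- bron_kerbosch_v2(adj)
  capped <- bron_kerbosch_v2(adj, solver_limits(max_solutions = 2))
  expect_length(capped, 2)
  expect_true(attr(capped, "truncated"))
  expect_identical(clique_keys(capped),
                   sort(clique_keys(full)[clique_keys(full) %in%
                                            clique_keys(capped)]))
  # every truncated clique is still maximal
  expect_true(all(clique_keys(capped) %in% oracle_max_cliques(adj)))

  timed <- bron_kerbosch_v2(adj, solver_limits(max_time = 0))
  expect_true(attr(timed, "truncated"))
})

test_that("identical maps are recovered with identity mapping and score 1", {
  g <- toy_graph(
    rbind(tsp("a", "A"), tsp("b", "B"), tsp("c", "C"), tsp("d", "D")),
    list(trx("r1", "a", "b"), trx("r2", "b", "c"), trx("r3", "c", "d")),
    model_id = "m1"
  )
  sol <- iterative_overlap(g, g, N = 3)
  expect_equal(unname(sol$scores), c(1, 1))
  expect_identical(validate_solution(sol), TRUE)
  # identity on names: every species maps to the species with its own name
  expect_identical(sol$species_map[sort(names(sol$species_map))],
                   stats::setNames(sort(g$vertices), sort(g$vertices)))
})

test_that("an extra unmatched reaction forces asymmetric scores", {
  g1 <- linear_graph(3, "a", "S")
  g2big <- toy_graph(
    rbind(linear_graph(3, "b", "S", comp = "c2")$species,
          tsp("z1", "Z1", "c2"), tsp("z2", "Z2", "c2")),
    c(linear_graph(3, "b", "S", comp = "c2")$reactions,
      list(trx("b_extra", "z1", "z2")))
  )
  sol <- iterative_overlap(g1, g2big, N = 3)
  expect_equal(sol$scores[["s1"]], 1)
  expect_lt(sol$scores[["s2"]], 1)
  expect_equal(sol$scores[["s2"]], 3 / 4)
})

test_that("disjoint name spaces give an empty solution with zero scores", {
  g1 <- linear_graph(2, "a", "LEFT")
  g2 <- linear_graph(2, "b", "RIGHT")
  sol <- iterative_overlap(g1, g2, N = 3)
  expect_length(sol$pairs, 0)
  expect_equal(unname(sol$scores), c(0, 0))
})

test_that("solutions satisfy clique and injectivity invariants", {
  for (seed in c(1, 4, 7, 10)) {
    fx <- generate_toy_pair(fixture_params(
      topology = c("linear", "branched", "cyclic", "random")[1 + seed %% 4],
      n_reactions = 5, planted_fraction = 0.6, reversible_fraction = 0.4,
      modifier_rate = 0.5, seed = seed
    ))
    res <- compare_sbml(fx$doc1, fx$doc2)
    expect_identical(validate_solution(res$solution), TRUE)
    smap <- res$solution$species_map
    expect_false(anyDuplicated(names(smap)) > 0)
    expect_false(anyDuplicated(smap) > 0)
  }
})

test_that("repeated runs are identical under fixed limits", {
  fx <- generate_toy_pair(fixture_params(topology = "random", seed = 21,
                                         planted_fraction = 0.5))
  a <- compare_sbml(fx$doc1, fx$doc2)$solution
  b <- compare_sbml(fx$doc1, fx$doc2)$solution
  expect_identical(a$species_map, b$species_map)
  expect_identical(a$chain_map, b$chain_map)
  expect_identical(a$scores, b$scores)
})

test_that("the staged heuristic never beats, and often meets, the optimum", {
  for (seed in c(2, 6, 14)) {
    g1 <- random_pathway_graph(5, 4, seed = seed, prefix = "s")
    g2 <- random_pathway_graph(5, 4, seed = seed + 50, prefix = "s")
    pairs <- match_paths(enumerate_simple_paths(g1, 2),
                         enumerate_simple_paths(g2, 2), g1, g2)
    if (!length(pairs) || length(pairs) > 12) next
    opt <- oracle_best_total_score(pairs, g1, g2)
    sol <- iterative_overlap(g1, g2, N = 2)
    expect_lte(sum(sol$scores), opt + 1e-12)
  }
  # planted case where the optimum uses only the shortest lengths: staged
  # search attains it exactly
  g1 <- linear_graph(3, "a", "S")
  g2 <- linear_graph(3, "b", "S", comp = "c2")
  pairs <- match_paths(enumerate_simple_paths(g1, 3),
                       enumerate_simple_paths(g2, 3), g1, g2)
  opt <- oracle_best_total_score(pairs, g1, g2)
  sol <- iterative_overlap(g1, g2, N = 3)
  expect_equal(sum(sol$scores), opt)
  expect_equal(opt, 2)
})
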