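test_that("default species equivalence compares names, user lists override", {
  atp1 <- list(id = "a1", name = "ATP")
  atp2 <- list(id = "b1", name = "ATP")
  gene <- list(id = "a2", name = "GeneX")
  prot <- list(id = "b2", name = "ProtX")

  expect_true(species_equivalent(atp1, atp2))
  expect_false(species_equivalent(gene, prot))
  expect_true(species_equivalent(
    gene, prot, equivalence_spec(allowed_species = cbind("a2", "b2"))
  ))
  expect_false(species_equivalent(
    atp1, atp2, equivalence_spec(forbidden_species = cbind("a1", "b1"))
  ))
  # nameless species are equivalent only through the allowed list
  anon1 <- list(id = "a3", name = NA_character_)
  anon2 <- list(id = "b3", name = NA_character_)
  expect_false(species_equivalent(anon1, anon2))
  expect_true(species_equivalent(
    anon1, anon2, equivalence_spec(allowed_species = cbind("a3", "b3"))
  ))
  # surrounding whitespace is trimmed before comparison
  expect_true(species_equivalent(list(id = "x", name = " ATP "), atp2))
})

test_that("equivalence is symmetric when the lists are symmetric", {
  set.seed(4)
  names_pool <- c("A", "B", "C", NA)
  for (i in 1:20) {
    s1 <- list(id = "i1", name = sample(names_pool, 1))
    s2 <- list(id = "i2", name = sample(names_pool, 1))
    expect_identical(species_equivalent(s1, s2), species_equivalent(s2, s1))
  }
})

test_that("a rejected pair in both allowed and forbidden lists errors", {
  expect_error(
    equivalence_spec(allowed_species = cbind("a", "b"),
                     forbidden_species = cbind("a", "b")),
    "both allowed and forbidden"
  )
})

test_that("the rules file round-trips through the TSV reader", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment",
    "species allow GeneX ProtX",
    "species forbid a1 b1",
    "chain forbid r1,r2 s9"
  ), path)
  spec <- read_equivalence_spec(path)
  expect_equal(unname(spec$allowed_species[1, ]), c("GeneX", "ProtX"))
  expect_equal(unname(spec$forbidden_species[1, ]), c("a1", "b1"))
  expect_equal(unname(spec$forbidden_chains[1, ]), c("r1,r2", "s9"))

  writeLines("species allow onlythree", path)
  expect_error(read_equivalence_spec(path), "4 fields")
})

# Gap-match geometry: doc1 a->c direct-ish (2 steps), doc2 a'->c' in 3 steps.
gap_graphs <- function(interior2_names = c("XX", "YY")) {
  g1 <- toy_graph(
    rbind(tsp("a1", "A"), tsp("b1", "B"), tsp("c1", "C")),
    list(trx("r1", "a1", "b1"), trx("r2", "b1", "c1"))
  )
  g2 <- toy_graph(
    rbind(tsp("a2", "A", "c2"), tsp("x2", interior2_names[1], "c2"),
          tsp("y2", interior2_names[2], "c2"), tsp("c2s", "C", "c2")),
    list(trx("s1", "a2", "x2"), trx("s2", "x2", "y2"),
         trx("s3", "y2", "c2s"))
  )
  list(g1 = g1, g2 = g2)
}

match_between <- function(g1, g2, N = 3, spec = equivalence_spec()) {
  match_paths(enumerate_simple_paths(g1, N), enumerate_simple_paths(g2, N),
              g1, g2, spec)
}

pair_sig <- function(pr) {
  paste(paste(pr$path1$chain, collapse = ","),
        paste(pr$path2$chain, collapse = ","), sep = " ~ ")
}

test_that("paths of different lengths match when interiors stay unpaired", {
  gg <- gap_graphs()
  pairs <- match_between(gg$g1, gg$g2)
  expect_true("r1,r2 ~ s1,s2,s3" %in% vapply(pairs, pair_sig, ""))
})

test_that("an equivalent interior pair blocks the long match (rule b)", {
  gg <- gap_graphs(interior2_names = c("B", "YY"))
  pairs <- match_between(gg$g1, gg$g2)
  sigs <- vapply(pairs, pair_sig, "")
  expect_false("r1,r2 ~ s1,s2,s3" %in% sigs)
  # the shorter subpath pairs are matched at their own lengths instead
  expect_true("r1 ~ s1" %in% sigs)
  expect_true("r2 ~ s2,s3" %in% sigs)
})

test_that("cycle paths only match cycle paths (rule c, species side)", {
  g1 <- toy_graph(tsp("a1", "A"), list(trx("r1", "a1", "a1")))
  g2 <- toy_graph(
    rbind(tsp("a2", "A", "c2"), tsp("c2s", "C", "c2")),
    list(trx("s1", "a2", "c2s"))
  )
  expect_length(match_between(g1, g2), 0)

  g3 <- toy_graph(tsp("a3", "A", "c3"), list(trx("t1", "a3", "a3")))
  pairs <- match_between(g1, g3)
  expect_length(pairs, 1)
  expect_equal(pairs[[1]]$path2$start, "a3")
})

test_that("same-compartment paths only match same-compartment paths (rule c)", {
  g1 <- toy_graph(
    rbind(tsp("a1", "A", "cytosol"), tsp("b1", "B", "nucleus")),
    list(trx("r1", "a1", "b1"))
  )
  g2_cross <- toy_graph(
    rbind(tsp("a2", "A", "cy2"), tsp("b2", "B", "nu2")),
    list(trx("s1", "a2", "b2"))
  )
  g2_same <- toy_graph(
    rbind(tsp("a3", "A", "only"), tsp("b3", "B", "only")),
    list(trx("t1", "a3", "b3"))
  )
  expect_length(match_between(g1, g2_cross), 1)
  expect_length(match_between(g1, g2_same), 0)
})

test_that("user-forbidden species and chain pairs suppress matches (rule a)", {
  g1 <- linear_graph(1, "a", "S")
  g2 <- linear_graph(1, "b", "S", comp = "c2")
  expect_length(match_between(g1, g2), 1)

  spec <- equivalence_spec(forbidden_species = cbind("a1", "b1"))
  expect_length(match_between(g1, g2, spec = spec), 0)

  spec <- equivalence_spec(forbidden_chains = cbind("a_r1", "b_r1"))
  expect_length(match_between(g1, g2, spec = spec), 0)
})

test_that("matching is invariant to the ordering of the path collections", {
  gg <- gap_graphs()
  p1 <- enumerate_simple_paths(gg$g1, 3)
  p2 <- enumerate_simple_paths(gg$g2, 3)
  a <- match_paths(p1, p2, gg$g1, gg$g2)
  b <- match_paths(rev(p1), rev(p2), gg$g1, gg$g2)
  expect_identical(vapply(a, `[[`, "", "key"), vapply(b, `[[`, "", "key"))
})

test_that("matching equals a direct Cartesian filter of the written rules", {
  # independent restatement of the endpoint/a/b/c rules, forward orientation
  oracle_match <- function(p1, p2, g1, g2, spec) {
    out <- character(0)
    name1 <- function(id) g1$species$name[match(id, g1$species$id)]
    name2 <- function(id) g2$species$name[match(id, g2$species$id)]
    comp1 <- function(id) g1$species$compartment[match(id, g1$species$id)]
    comp2 <- function(id) g2$species$compartment[match(id, g2$species$id)]
    eq <- function(id1, id2) {
      !is.na(name1(id1)) && !is.na(name2(id2)) && name1(id1) == name2(id2)
    }
    for (p in p1) for (q in p2) {
      if (!eq(p$start, q$start) || !eq(p$end, q$end)) next
      if ((p$start == p$end) != (q$start == q$end)) next
      if ((comp1(p$start) == comp1(p$end)) !=
          (comp2(q$start) == comp2(q$end))) next
      blocked <- FALSE
      for (a in p$interior) for (b in q$interior) {
        if (eq(a, b)) blocked <- TRUE
      }
      if (blocked) next
      out <- c(out, paste(mapoverlap:::path_key(p),
                          mapoverlap:::path_key(q), "forward",
                          sep = " :: "))
    }
    sort(out)
  }
  for (seed in c(1, 5, 8, 12)) {
    g1 <- random_pathway_graph(5, 5, seed = seed, reversible_prob = 0,
                               prefix = "s")
    g2 <- random_pathway_graph(5, 5, seed = seed + 100, reversible_prob = 0,
                               prefix = "s")
    p1 <- enumerate_simple_paths(g1, 3)
    p2 <- enumerate_simple_paths(g2, 3)
    got <- match_paths(p1, p2, g1, g2)
    expect_identical(sort(vapply(got, `[[`, "", "key")),
                     oracle_match(p1, p2, g1, g2, equivalence_spec()),
                     info = paste("seed", seed))
  }
})
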