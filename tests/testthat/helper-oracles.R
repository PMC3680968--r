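# Independent brute-force oracles. These deliberately share no code with the
# package internals they check.

# All reaction-id-distinct walks of length <= N, then per-(start, end)
# minimal-length filter. Plain recursive DFS over the edge table.
oracle_simple_paths <- function(graph, N) {
  edges <- graph$edges
  out <- list()
  walk <- function(at, chain, interior, start) {
    if (length(chain) > 0) {
      out[[length(out) + 1L]] <<- list(start = start, end = at,
                                       chain = chain, interior = interior)
    }
    if (length(chain) == N) return()
    for (e in seq_len(nrow(edges))) {
      if (edges$from[e] != at) next
      if (edges$reaction[e] %in% chain) next
      walk(edges$to[e], c(chain, edges$reaction[e]),
           if (length(chain) > 0) c(interior, at) else interior, start)
    }
  }
  for (src in graph$vertices) walk(src, character(0), character(0), src)
  if (!length(out)) return(character(0))
  lens <- vapply(out, function(p) length(p$chain), integer(1))
  pair <- vapply(out, function(p) paste(p$start, p$end, sep = "\r"), "")
  minlen <- tapply(lens, pair, min)
  keep <- lens == unname(minlen[pair])
  keys <- vapply(out[keep], function(p) {
    paste(p$start, p$end, paste(p$chain, collapse = ","),
          paste(p$interior, collapse = ","), sep = "|")
  }, "")
  sort(unique(keys))
}

# Key for comparing enumerate_simple_paths() output against the oracle
# (orientation flags dropped: the oracle does not model them).
impl_path_keys <- function(paths) {
  sort(unique(vapply(paths, function(p) {
    paste(p$start, p$end, paste(p$chain, collapse = ","),
          paste(p$interior, collapse = ","), sep = "|")
  }, "")))
}

# Exhaustive maximal-clique enumeration over all vertex subsets, bitmask
# based. Returns sorted "i,j,k" strings.
oracle_max_cliques <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(character(0))
  stopifnot(n <= 16)
  nbr <- vapply(seq_len(n), function(i) {
    sum(2^(which(adj[i, ]) - 1))
  }, numeric(1))
  bits <- 2^(seq_len(n) - 1)
  res <- character(0)
  for (s in seq_len(2^n - 1)) {
    members <- which(bitwAnd(s, bits) != 0)
    is_clique <- all(vapply(members, function(v) {
      bitwAnd(s, bitwOr(nbr[v], bits[v])) == s
    }, logical(1)))
    if (!is_clique) next
    outside <- setdiff(seq_len(n), members)
    is_maximal <- !any(vapply(outside, function(w) {
      bitwAnd(nbr[w], s) == s
    }, logical(1)))
    if (is_maximal) res <- c(res, paste(members, collapse = ","))
  }
  sort(res)
}

clique_keys <- function(cliques) {
  sort(vapply(cliques, function(cl) paste(sort(cl), collapse = ","), ""))
}

# Brute-force best consistent solution: every pairwise-compatible subset of
# the matched pairs, scored; returns the maximum of S(G1)+S(G2).
oracle_best_total_score <- function(pairs, g1, g2,
                                    spec = equivalence_spec()) {
  n <- length(pairs)
  stopifnot(n <= 16)
  best <- 0
  comp <- matrix(TRUE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) comp[i, j] <- comp[j, i] <- compatible(pairs[[i]], pairs[[j]])
  }
  subsets <- if (n) 0:(2^n - 1) else 0
  bits <- 2^(seq_len(n) - 1)
  for (s in subsets) {
    members <- which(bitwAnd(s, bits) != 0)
    if (length(members) > 1) {
      ok <- all(comp[members, members][upper.tri(diag(length(members)))])
      if (!ok) next
    }
    sol <- mapoverlap:::solution_from_pairs(pairs[members], g1, g2)
    sol <- map_modifiers(sol, g1, g2, spec)
    s1 <- overlap_score(g1, sol, 1)
    s2 <- overlap_score(g2, sol, 2)
    best <- max(best, s1 + s2)
  }
  best
}

# Random undirected adjacency matrix for clique tests.
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    ut <- stats::runif(n * (n - 1) / 2) < p
    adj[upper.tri(adj)] <- ut
    adj <- adj | t(adj)
  }
  adj
}
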