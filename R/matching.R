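#' Match simple paths between two maps
#'
#' Two simple paths are candidate matches when their endpoint species are
#' equivalent (start with start, end with end). A candidate is nevertheless
#' rejected when (a) the species pair or the chain pair is explicitly
#' forbidden by the user, (b) the paths contain a pair of equivalent
#' intermediate species — the shorter subpaths are then matchable on their
#' own and are preferred — or (c) the match would break one-to-one species
#' or compartment mapping at the pair level: a cycle path (start == end)
#' only matches a cycle path, and a path that stays within one compartment
#' only matches a path that stays within one compartment.
#'
#' When every reaction in both chains is reversible and the forward
#' orientation fails, a reversed-orientation match (start1 with end2) is
#' attempted and recorded.
#'
#' @param paths1,paths2 Output of [enumerate_simple_paths()] for each graph.
#' @param g1,g2 The two `pathway_graph` objects the paths came from.
#' @param spec An [equivalence_spec()].
#' @return A list of `path_pair` records, sorted deterministically. Each has
#'   `path1`, `path2`, `orientation` (`"forward"` or `"reversed"`),
#'   `species_map`, `comp_map` (named character vectors, doc1 to doc2),
#'   `chain_key1`, `chain_key2` (orientation-canonical chain identifiers),
#'   `rids1`, `rids2` (reaction-id sets) and `len` (the larger chain length,
#'   used for staging).
#' @export
match_paths <- function(paths1, paths2, g1, g2, spec = equivalence_spec()) {
  pairs <- list()
  for (p in paths1) {
    for (q in paths2) {
      pair <- match_one(p, q, g1, g2, spec, orientation = "forward")
      if (is.null(pair) && all_reversible(p, g1) && all_reversible(q, g2)) {
        pair <- match_one(p, q, g1, g2, spec, orientation = "reversed")
      }
      if (!is.null(pair)) pairs[[length(pairs) + 1L]] <- pair
    }
  }
  if (!length(pairs)) return(pairs)
  keys <- vapply(pairs, function(x) x$key, "")
  pairs[order(keys)]
}

all_reversible <- function(p, graph) {
  all(vapply(graph$reactions[p$chain], `[[`, logical(1), "reversible"))
}

match_one <- function(p, q, g1, g2, spec, orientation) {
  s2 <- if (orientation == "forward") q$start else q$end
  e2 <- if (orientation == "forward") q$end else q$start

  # rule (c), species side: cycle paths only match cycle paths
  if ((p$start == p$end) != (q$start == q$end)) return(NULL)

  if (!species_equivalent(species_row(g1, p$start), species_row(g2, s2), spec))
    return(NULL)
  if (!species_equivalent(species_row(g1, p$end), species_row(g2, e2), spec))
    return(NULL)

  # rule (c), compartment side
  c1s <- species_compartment(g1, p$start)
  c1e <- species_compartment(g1, p$end)
  c2s <- species_compartment(g2, s2)
  c2e <- species_compartment(g2, e2)
  if ((c1s == c1e) != (c2s == c2e)) return(NULL)

  # rule (a), chain lists
  if (chain_pair_listed(spec$forbidden_chains, p$chain, q$chain)) return(NULL)
  chain_allowed <- chain_pair_listed(spec$allowed_chains, p$chain, q$chain)

  # rule (b): equivalent intermediate species mean the shorter subpaths
  # should be matched instead (an explicitly allowed chain pair overrides)
  if (!chain_allowed && length(p$interior) && length(q$interior)) {
    for (a in unique(p$interior)) {
      ra <- species_row(g1, a)
      for (b in unique(q$interior)) {
        if (species_equivalent(ra, species_row(g2, b), spec)) return(NULL)
      }
    }
  }

  species_map <- stats::setNames(c(s2, e2), c(p$start, p$end))
  species_map <- species_map[!duplicated(names(species_map))]
  comp_map <- stats::setNames(c(c2s, c2e), c(c1s, c1e))
  comp_map <- comp_map[!duplicated(names(comp_map))]

  structure(
    list(
      path1 = p, path2 = q, orientation = orientation,
      species_map = species_map, comp_map = comp_map,
      chain_key1 = canonical_chain(p$chain),
      chain_key2 = canonical_chain(q$chain),
      rids1 = unique(p$chain), rids2 = unique(q$chain),
      len = max(length(p$chain), length(q$chain)),
      key = paste(path_key(p), path_key(q), orientation, sep = " :: ")
    ),
    class = "path_pair"
  )
}

# A chain and its reversed chain denote the same reaction pathway.
canonical_chain <- function(chain) {
  a <- paste(chain, collapse = ",")
  b <- paste(rev(chain), collapse = ",")
  if (b < a) b else a
}

chain_pair_listed <- function(m, chain1, chain2) {
  if (!nrow(m)) return(FALSE)
  k1 <- c(paste(chain1, collapse = ","), paste(rev(chain1), collapse = ","))
  k2 <- c(paste(chain2, collapse = ","), paste(rev(chain2), collapse = ","))
  any(m[, 1] %in% k1 & m[, 2] %in% k2)
}

#' @export
print.path_pair <- function(x, ...) {
  cat(x$path1$start, "..", x$path1$end, " ~ ",
      x$path2$start, "..", x$path2$end,
      " [", x$orientation, "]\n", sep = "")
  invisible(x)
}
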