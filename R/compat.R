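#' Pairwise compatibility of two matched path pairs
#'
#' Two matched path pairs are compatible when the union of their induced
#' mappings is still one-to-one on species, on compartments and on reaction
#' chains, and no reaction id is claimed by two distinct matched chains (a
#' chain and its reversed chain count as the same pathway).
#'
#' @param p,q `path_pair` records from the same [match_paths()] output.
#' @return Logical scalar.
#' @export
compatible <- function(p, q) {
  if (!maps_consistent(p$species_map, q$species_map)) return(FALSE)
  if (!maps_consistent(p$comp_map, q$comp_map)) return(FALSE)

  # chain-level one-to-one: same doc1 chain cannot match two doc2 chains
  chain_map_p <- stats::setNames(p$chain_key2, p$chain_key1)
  chain_map_q <- stats::setNames(q$chain_key2, q$chain_key1)
  if (!maps_consistent(chain_map_p, chain_map_q)) return(FALSE)

  # a reaction id may belong to at most one matched chain per side
  if (p$chain_key1 != q$chain_key1 && length(intersect(p$rids1, q$rids1)))
    return(FALSE)
  if (p$chain_key2 != q$chain_key2 && length(intersect(p$rids2, q$rids2)))
    return(FALSE)
  TRUE
}

# Union of two named maps stays a well-defined injective mapping: no key with
# two values, no value with two keys.
maps_consistent <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) && any(a[shared] != b[shared])) return(FALSE)
  only_a <- setdiff(names(a), shared)
  only_b <- setdiff(names(b), shared)
  !length(intersect(a[only_a], b[only_b]))
}

#' Build the compatibility graph over matched path pairs
#'
#' @param pairs A list of `path_pair` records ([match_paths()] output).
#' @return An object of class `compatibility_graph`: list with `pairs` (the
#'   vertices, in deterministic order) and `adj` (logical adjacency matrix,
#'   no self-loops).
#' @export
build_compatibility_graph <- function(pairs) {
  n <- length(pairs)
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- compatible(pairs[[i]], pairs[[j]])
        adj[i, j] <- ok
        adj[j, i] <- ok
      }
    }
  }
  structure(list(pairs = pairs, adj = adj), class = "compatibility_graph")
}

#' @export
print.compatibility_graph <- function(x, ...) {
  cat("compatibility_graph: ", length(x$pairs), " vertices, ",
      sum(x$adj) / 2, " edges\n", sep = "")
  invisible(x)
}
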