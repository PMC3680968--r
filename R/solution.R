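#' @name match_solution
#' @title Consistent overlap solutions
#'
#' @description A `match_solution` is a pairwise-compatible (clique) set of
#' matched path pairs together with the one-to-one mappings it induces:
#' `species_map`, `comp_map` and `chain_map` (doc1 to doc2), plus a
#' `modifier_map` filled in by [map_modifiers()]. The induced maps are
#' injective in both directions by construction.
NULL

solution_from_pairs <- function(pairs, g1, g2) {
  species_map <- character(0)
  comp_map <- character(0)
  chain1 <- character(0)
  chain2 <- character(0)
  for (p in pairs) {
    species_map <- merge_map(species_map, p$species_map)
    comp_map <- merge_map(comp_map, p$comp_map)
    if (!p$chain_key1 %in% chain1) {
      chain1 <- c(chain1, p$chain_key1)
      chain2 <- c(chain2, p$chain_key2)
    }
  }
  chain_map <- data.frame(chain1 = chain1, chain2 = chain2,
                          stringsAsFactors = FALSE)
  if (nrow(chain_map)) {
    chain_map <- chain_map[order(chain_map$chain1), , drop = FALSE]
    rownames(chain_map) <- NULL
  }
  structure(
    list(
      pairs = pairs,
      species_map = species_map,
      comp_map = comp_map,
      chain_map = chain_map,
      modifier_map = character(0),
      truncated = FALSE,
      scores = NULL
    ),
    class = "match_solution"
  )
}

merge_map <- function(a, b) {
  new <- b[!(names(b) %in% names(a))]
  c(a, new)
}

# Reaction ids covered by the matched chains, per side.
matched_reaction_ids <- function(solution, side) {
  keys <- if (side == 1) solution$chain_map$chain1 else solution$chain_map$chain2
  unique(unlist(strsplit(keys, ",", fixed = TRUE), use.names = FALSE))
}

#' @export
print.match_solution <- function(x, ...) {
  cat("match_solution: ", length(x$pairs), " path pairs, ",
      nrow(x$chain_map), " matched chains, ",
      length(x$species_map), " mapped species\n", sep = "")
  if (!is.null(x$scores)) {
    cat(sprintf("scores: S(G1,E) = %.4f, S(G2,E) = %.4f\n",
                x$scores[["s1"]], x$scores[["s2"]]))
  }
  if (isTRUE(x$truncated)) cat("note: clique enumeration was truncated\n")
  invisible(x)
}

#' Verify the consistency invariants of a solution
#'
#' Checks that the pair set is a clique of the compatibility relation and
#' that the species, compartment and chain maps are injective in both
#' directions. Used by tests and available to users as a sanity check.
#'
#' @param solution A `match_solution`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_solution <- function(solution) {
  pairs <- solution$pairs
  n <- length(pairs)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (!compatible(pairs[[i]], pairs[[j]])) {
          stop("solution pairs ", i, " and ", j, " are incompatible")
        }
      }
    }
  }
  check_injective <- function(m, label) {
    if (anyDuplicated(names(m))) stop(label, " maps a key twice")
    if (anyDuplicated(m)) stop(label, " maps two keys to one value")
  }
  check_injective(solution$species_map, "species_map")
  check_injective(solution$comp_map, "comp_map")
  check_injective(stats::setNames(solution$chain_map$chain2,
                                  solution$chain_map$chain1), "chain_map")
  # no reaction id in two distinct matched chains
  for (side in 1:2) {
    keys <- if (side == 1) solution$chain_map$chain1 else solution$chain_map$chain2
    rids <- unlist(strsplit(keys, ",", fixed = TRUE), use.names = FALSE)
    if (anyDuplicated(rids)) {
      stop("reaction id claimed by two matched chains on side ", side)
    }
  }
  invisible(TRUE)
}
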