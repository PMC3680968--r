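#' Map modifiers over the matched chains
#'
#' After the clique search has fixed the matched chains, modifiers carried
#' by the reactions of each matched chain pair are mapped one-to-one:
#' a modifier on the doc1 side is paired with the first equivalent,
#' still-unmapped modifier on the doc2 side, in deterministic (sorted)
#' order. The species map is augmented accordingly, preserving injectivity.
#'
#' @param solution A `match_solution`.
#' @param g1,g2 The two `pathway_graph` objects.
#' @param spec An [equivalence_spec()].
#' @return The solution with `modifier_map` and `species_map` extended.
#' @export
map_modifiers <- function(solution, g1, g2, spec = equivalence_spec()) {
  smap <- solution$species_map
  mmap <- solution$modifier_map
  cm <- solution$chain_map
  if (!nrow(cm)) return(solution)
  for (k in seq_len(nrow(cm))) {
    rids1 <- strsplit(cm$chain1[k], ",", fixed = TRUE)[[1]]
    rids2 <- strsplit(cm$chain2[k], ",", fixed = TRUE)[[1]]
    mods1 <- sort(unique(unlist(lapply(g1$reactions[rids1], `[[`, "modifiers"),
                                use.names = FALSE)))
    mods2 <- sort(unique(unlist(lapply(g2$reactions[rids2], `[[`, "modifiers"),
                                use.names = FALSE)))
    for (m1 in mods1) {
      if (m1 %in% names(smap)) next
      r1 <- species_row(g1, m1)
      for (m2 in mods2) {
        if (m2 %in% smap) next
        if (species_equivalent(r1, species_row(g2, m2), spec)) {
          smap[m1] <- m2
          mmap[m1] <- m2
          break
        }
      }
    }
  }
  solution$species_map <- smap
  solution$modifier_map <- mmap
  solution
}

#' Per-reaction overlap weight
#'
#' The weight of a reaction is 0 when its id belongs to no matched chain.
#' Otherwise it is the fraction of the reaction's reactants, products and
#' modifiers whose species are mapped by the solution:
#' `(|R_E| + |P_E| + |M_E|) / (|R| + |P| + |M|)` with set semantics per
#' category. Incomplete reactions never reach the graph, so the denominator
#' is at least 2.
#'
#' @param r A reaction record from a `pathway_graph`.
#' @param solution A `match_solution` (after [map_modifiers()]).
#' @param side 1 when `r` belongs to the first document, 2 for the second.
#' @return A number in `[0, 1]`.
#' @export
reaction_weight <- function(r, solution, side = 1) {
  if (!(r$id %in% matched_reaction_ids(solution, side))) return(0)
  mapped <- if (side == 1) names(solution$species_map) else
    unname(solution$species_map)
  num <- sum(r$reactants %in% mapped) + sum(r$products %in% mapped) +
    sum(r$modifiers %in% mapped)
  den <- length(r$reactants) + length(r$products) + length(r$modifiers)
  num / den
}

#' Overlap score of a map under a solution
#'
#' Mean of [reaction_weight()] over all reaction ids of the graph; unmatched
#' reactions contribute 0, so the score roughly measures how much of this
#' map is contained in the other according to the solution. The score is
#' normalised by this map's own reaction count, so the two directions need
#' not be equal.
#'
#' @param graph A `pathway_graph`.
#' @param solution A `match_solution` computed against this graph (as side
#'   `side`) and its partner.
#' @param side 1 when `graph` is the first document of the comparison, 2 for
#'   the second.
#' @return A number in `[0, 1]`.
#' @export
overlap_score <- function(graph, solution, side = 1) {
  if (!length(graph$reactions)) {
    stop("degenerate input: graph '", graph$model_id,
         "' has no retained reactions; overlap score is undefined",
         call. = FALSE)
  }
  w <- vapply(graph$reactions, reaction_weight, numeric(1),
              solution = solution, side = side)
  mean(w)
}

score_solution <- function(solution, g1, g2) {
  solution$scores <- c(s1 = overlap_score(g1, solution, side = 1),
                       s2 = overlap_score(g2, solution, side = 2))
  solution
}
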