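#' Build the labelled multidigraph of an SBML map
#'
#' Each reaction is spliced into directed edges connecting every reactant to
#' every product, all labelled with the reaction id. Reversible reactions
#' additionally contribute the reversed edges, carrying a reversed-orientation
#' flag. Modifiers are not traversed: they stay attached to the reaction
#' record. Incomplete reactions (empty reactant or product set) and species
#' that participate in no retained reaction as reactant or product are
#' dropped.
#'
#' @param parsed A list with `species` and `reactions` as returned by
#'   [parse_sbml()] (extra components such as `compartments` are carried
#'   through when present).
#' @return An object of class `pathway_graph`: a list with
#'   \describe{
#'     \item{species}{all declared species (modifier-only species included,
#'       so reaction records stay resolvable).}
#'     \item{vertices}{character vector of retained species ids.}
#'     \item{reactions}{named list of retained (complete) reactions.}
#'     \item{edges}{data.frame `from`, `to`, `reaction`, `reversed`; one row
#'       per distinct (from, to, reaction, reversed) combination.}
#'     \item{compartments, model_id}{carried through from the parse.}
#'   }
#' @export
build_graph <- function(parsed) {
  species <- parsed$species
  reactions <- parsed$reactions

  declared <- species$id
  for (r in reactions) {
    refs <- c(r$reactants, r$products, r$modifiers)
    missing <- setdiff(refs, declared)
    if (length(missing)) {
      stop("consistency error: reaction '", r$id,
           "' references undeclared species '", missing[1], "'",
           call. = FALSE)
    }
  }

  complete <- vapply(reactions, function(r) {
    length(r$reactants) > 0 && length(r$products) > 0
  }, logical(1))
  retained <- reactions[complete]

  if (length(retained)) {
    edge_list <- lapply(retained, function(r) {
      fwd <- expand.grid(from = r$reactants, to = r$products,
                         stringsAsFactors = FALSE)
      fwd$reaction <- r$id
      fwd$reversed <- FALSE
      if (r$reversible) {
        rev <- data.frame(from = fwd$to, to = fwd$from,
                          reaction = r$id, reversed = TRUE,
                          stringsAsFactors = FALSE)
        fwd <- rbind(fwd, rev)
      }
      fwd
    })
    edges <- do.call(rbind, c(edge_list, list(make.row.names = FALSE)))
    edges <- unique(edges)
    ord <- order(edges$reaction, edges$reversed, edges$from, edges$to)
    edges <- edges[ord, , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        reaction = character(), reversed = logical(),
                        stringsAsFactors = FALSE)
  }

  vertices <- intersect(declared, unique(c(edges$from, edges$to)))

  structure(
    list(
      species = species,
      vertices = vertices,
      reactions = retained,
      edges = edges,
      compartments = parsed$compartments,
      model_id = if (is.null(parsed$model_id)) "model" else parsed$model_id
    ),
    class = "pathway_graph"
  )
}

#' Read and build a pathway graph in one step
#'
#' @param path Path to an SBML file.
#' @return A `pathway_graph`; see [build_graph()].
#' @export
read_pathway <- function(path) {
  build_graph(parse_sbml(path))
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph '", x$model_id, "': ",
      length(x$vertices), " species, ",
      length(x$reactions), " reactions, ",
      nrow(x$edges), " spliced edges\n", sep = "")
  invisible(x)
}

# Lookup helpers used across modules -----------------------------------------

species_row <- function(graph, id) {
  graph$species[match(id, graph$species$id), , drop = FALSE]
}

species_name <- function(graph, id) {
  graph$species$name[match(id, graph$species$id)]
}

species_compartment <- function(graph, id) {
  graph$species$compartment[match(id, graph$species$id)]
}
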