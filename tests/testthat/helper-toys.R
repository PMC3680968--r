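# Small in-code builders for toy documents and graphs.

tsp <- function(id, name = toupper(id), comp = "c1") {
  data.frame(id = id, name = name, compartment = comp,
             stringsAsFactors = FALSE)
}

trx <- function(id, reactants, products, modifiers = character(0),
                reversible = FALSE) {
  list(id = id, name = NA_character_, reactants = sort(unique(reactants)),
       products = sort(unique(products)),
       modifiers = sort(unique(modifiers)), reversible = reversible)
}

toy_doc <- function(species, reactions, model_id = "toy") {
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  comps <- data.frame(id = unique(species$compartment), name = NA_character_,
                      stringsAsFactors = FALSE)
  list(species = species, reactions = reactions, compartments = comps,
       model_id = model_id)
}

toy_graph <- function(species, reactions, model_id = "toy") {
  build_graph(toy_doc(species, reactions, model_id))
}

# Linear chain with distinct names: s1 -r1-> s2 -r2-> ... Species names get
# a prefix so two documents can share (or not share) names.
linear_graph <- function(n_rxn, id_prefix = "a", name_prefix = "X",
                         comp = "c1", reversible = FALSE) {
  ids <- paste0(id_prefix, seq_len(n_rxn + 1))
  species <- do.call(rbind, lapply(seq_along(ids), function(i) {
    tsp(ids[i], paste0(name_prefix, i), comp)
  }))
  reactions <- lapply(seq_len(n_rxn), function(i) {
    trx(paste0(id_prefix, "_r", i), ids[i], ids[i + 1],
        reversible = reversible)
  })
  toy_graph(species, reactions, model_id = paste0("linear_", id_prefix))
}

# A hand-built path_pair for compatibility-rule tests (bypasses matching).
fake_pair <- function(species_map, comp_map, chain1, chain2,
                      orientation = "forward") {
  structure(
    list(path1 = NULL, path2 = NULL, orientation = orientation,
         species_map = species_map, comp_map = comp_map,
         chain_key1 = mapoverlap:::canonical_chain(chain1),
         chain_key2 = mapoverlap:::canonical_chain(chain2),
         rids1 = unique(chain1), rids2 = unique(chain2),
         len = max(length(chain1), length(chain2)),
         key = paste(paste(chain1, collapse = ","),
                     paste(chain2, collapse = ","), sep = " :: ")),
    class = "path_pair"
  )
}

# Subgraph pair: doc1 is a linear chain, doc2 the same chain (shared names,
# distinct ids) plus a disjoint extra chain. Written to disk as SBML.
subgraph_pair <- function(n_core = 3, n_extra = 2, dir = tempfile("sub")) {
  dir.create(dir, recursive = TRUE)
  g1 <- linear_graph(n_core, "a", "S")
  core2 <- linear_graph(n_core, "b", "S", comp = "c2")
  extra <- linear_graph(n_extra, "e", "EXTRA", comp = "c2")
  doc2 <- list(
    species = rbind(core2$species, extra$species),
    reactions = c(core2$reactions, extra$reactions),
    compartments = data.frame(id = "c2", name = NA_character_,
                              stringsAsFactors = FALSE),
    model_id = "doc2"
  )
  doc1 <- list(species = g1$species, reactions = g1$reactions,
               compartments = g1$compartments, model_id = "doc1")
  p1 <- file.path(dir, "doc1.xml")
  p2 <- file.path(dir, "doc2.xml")
  write_sbml(doc1, p1)
  write_sbml(doc2, p2)
  list(doc1 = p1, doc2 = p2, n_core = n_core, n_extra = n_extra)
}
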