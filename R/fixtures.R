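#' Parameters for the synthetic fixture generator
#'
#' @param n_species Number of species per document (the generator may use
#'   fewer when the topology needs fewer; it never uses more).
#' @param n_reactions Number of reactions per document.
#' @param planted_fraction Fraction of each document's reactions that belong
#'   to the planted shared core (name-equivalent participants, distinct
#'   ids). The remainder is a document-unique component with disjoint names.
#' @param topology Shape of each component: `"linear"`, `"branched"`,
#'   `"cyclic"` or `"random"`.
#' @param reversible_fraction Fraction of core reactions flagged reversible.
#' @param modifier_rate Probability that a core reaction carries a (shared,
#'   name-equivalent) modifier species.
#' @param gap_species Number of core reactions of document 2 that are split
#'   by inserting a document-2-only gap species mid-chain (linear topology
#'   only); the planted match then becomes a gap match.
#' @param seed RNG seed; identical parameters and seed give byte-identical
#'   documents.
#' @return An object of class `fixture_params`.
#' @export
fixture_params <- function(n_species = 8, n_reactions = 6,
                           planted_fraction = 1,
                           topology = c("linear", "branched", "cyclic",
                                        "random"),
                           reversible_fraction = 0, modifier_rate = 0,
                           gap_species = 0, seed = 1) {
  topology <- match.arg(topology)
  stopifnot(n_species >= 1, n_reactions >= 1,
            planted_fraction >= 0, planted_fraction <= 1,
            reversible_fraction >= 0, reversible_fraction <= 1,
            modifier_rate >= 0, modifier_rate <= 1, gap_species >= 0)
  k <- round(planted_fraction * n_reactions)
  if (planted_fraction > 0 && k < 1) {
    stop("infeasible fixture parameters: planted_fraction * n_reactions < 1",
         call. = FALSE)
  }
  if (gap_species > 0 && topology != "linear") {
    stop("gap_species is only supported for the linear topology",
         call. = FALSE)
  }
  if (gap_species > k) {
    stop("gap_species cannot exceed the planted core size", call. = FALSE)
  }
  structure(list(n_species = n_species, n_reactions = n_reactions,
                 planted_fraction = planted_fraction, topology = topology,
                 reversible_fraction = reversible_fraction,
                 modifier_rate = modifier_rate, gap_species = gap_species,
                 seed = seed, n_core = k),
            class = "fixture_params")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# One standalone component: returns list(species = df(base, ...),
# reactions = list of (base reaction records using base species labels)).
# Labels are later instantiated per document with id/name prefixes.
component_skeleton <- function(n_rxn, topology, n_species_cap) {
  edges <- switch(
    topology,
    linear = {
      lapply(seq_len(n_rxn), function(i) {
        list(reactants = paste0("x", i), products = paste0("x", i + 1))
      })
    },
    cyclic = {
      m <- max(n_rxn, 2)
      lapply(seq_len(n_rxn), function(i) {
        list(reactants = paste0("x", i),
             products = paste0("x", (i %% m) + 1))
      })
    },
    branched = {
      lapply(seq_len(n_rxn), function(i) {
        list(reactants = paste0("x", ceiling(i / 2)),
             products = paste0("x", i + 1))
      })
    },
    random = {
      m <- min(max(3, n_species_cap), n_rxn + 2)
      lapply(seq_len(n_rxn), function(i) {
        nr <- sample(1:2, 1)
        np <- sample(1:2, 1)
        list(reactants = sort(sample(paste0("x", 1:m), nr)),
             products = sort(sample(paste0("x", 1:m), np)))
      })
    }
  )
  labels <- sort(unique(unlist(lapply(edges, function(e) {
    c(e$reactants, e$products)
  }), use.names = FALSE)))
  list(edges = edges, labels = labels)
}

#' Generate a synthetic SBML pair with a planted overlap
#'
#' Builds two SBML documents that share a planted core component: identical
#' topology and name attributes, distinct ids and compartments. The rest of
#' each document is a component with document-unique names, so the planted
#' mapping is the only overlap. The expected outcome of a comparison —
#' the planted species mapping, the matched reaction ids and the
#' closed-form overlap scores of the planted solution — is returned for
#' assertions.
#'
#' @param params A [fixture_params()].
#' @param dir Directory for the two files (created if needed).
#' @return A list with `doc1`, `doc2` (file paths) and `expected`, a list
#'   with `species_map` (doc1 id to doc2 id over the planted core),
#'   `matched_rids1`, `matched_rids2` and scores `s1`, `s2`.
#' @export
generate_toy_pair <- function(params, dir = tempfile("fixtures")) {
  stopifnot(inherits(params, "fixture_params"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  with_seed(params$seed, {
    k <- params$n_core
    u <- params$n_reactions - k
    core <- if (k) component_skeleton(k, params$topology, params$n_species)
    n_rev <- round(params$reversible_fraction * k)
    core_rev <- if (k) seq_len(k) <= n_rev else logical(0)
    core_mod <- if (k && params$modifier_rate > 0) {
      stats::runif(k) < params$modifier_rate
    } else rep(FALSE, k)
    uniq1 <- if (u) component_skeleton(u, params$topology, params$n_species)
    uniq2 <- if (u) component_skeleton(u, params$topology, params$n_species)

    doc1 <- instantiate_doc(core, core_rev, core_mod, uniq1,
                            id_prefix = "a", name_prefix_core = "CORE",
                            name_prefix_uniq = "U1", compartment = "c1",
                            model_id = "fixture_doc1", gaps = integer(0))
    gaps <- if (params$gap_species) seq_len(params$gap_species) else integer(0)
    doc2 <- instantiate_doc(core, core_rev, core_mod, uniq2,
                            id_prefix = "b", name_prefix_core = "CORE",
                            name_prefix_uniq = "U2", compartment = "c2",
                            model_id = "fixture_doc2", gaps = gaps)

    p1 <- file.path(dir, "doc1.xml")
    p2 <- file.path(dir, "doc2.xml")
    write_sbml(doc1, p1)
    write_sbml(doc2, p2)

    expected <- planted_expectation(doc1, doc2)
    list(doc1 = p1, doc2 = p2, expected = expected)
  })
}

# Turn skeletons into a parsed-document structure. Core species get names
# shared across documents ("CORE_x1"); unique-component names carry the
# per-document prefix. `gaps` lists core reaction indices to split with a
# document-local gap species.
instantiate_doc <- function(core, core_rev, core_mod, uniq, id_prefix,
                            name_prefix_core, name_prefix_uniq, compartment,
                            model_id, gaps) {
  species <- data.frame(id = character(0), name = character(0),
                        compartment = character(0), stringsAsFactors = FALSE)
  reactions <- list()

  add_species <- function(species, labels, prefix_id, prefix_name) {
    rbind(species, data.frame(
      id = paste0(prefix_id, "_", labels),
      name = paste0(prefix_name, "_", labels),
      compartment = compartment, stringsAsFactors = FALSE
    ))
  }

  if (!is.null(core)) {
    species <- add_species(species, core$labels, paste0(id_prefix, "c"),
                           name_prefix_core)
    for (i in seq_along(core$edges)) {
      e <- core$edges[[i]]
      rid <- paste0(id_prefix, "_r", i)
      mods <- character(0)
      if (core_mod[i]) {
        mid <- paste0(id_prefix, "c_m", i)
        species <- rbind(species, data.frame(
          id = mid, name = paste0(name_prefix_core, "_m", i),
          compartment = compartment, stringsAsFactors = FALSE
        ))
        mods <- mid
      }
      r_ids <- paste0(id_prefix, "c_", e$reactants)
      p_ids <- paste0(id_prefix, "c_", e$products)
      if (i %in% gaps) {
        gid <- paste0(id_prefix, "c_gap", i)
        species <- rbind(species, data.frame(
          id = gid, name = paste0(name_prefix_uniq, "_gap", i),
          compartment = compartment, stringsAsFactors = FALSE
        ))
        reactions[[paste0(rid, "a")]] <- list(
          id = paste0(rid, "a"), name = NA_character_, reactants = r_ids,
          products = gid, modifiers = mods, reversible = core_rev[i]
        )
        reactions[[paste0(rid, "b")]] <- list(
          id = paste0(rid, "b"), name = NA_character_, reactants = gid,
          products = p_ids, modifiers = character(0),
          reversible = core_rev[i]
        )
      } else {
        reactions[[rid]] <- list(
          id = rid, name = NA_character_, reactants = r_ids,
          products = p_ids, modifiers = mods, reversible = core_rev[i]
        )
      }
    }
  }
  if (!is.null(uniq)) {
    species <- add_species(species, uniq$labels, paste0(id_prefix, "u"),
                           name_prefix_uniq)
    for (i in seq_along(uniq$edges)) {
      e <- uniq$edges[[i]]
      rid <- paste0(id_prefix, "_u", i)
      reactions[[rid]] <- list(
        id = rid, name = NA_character_,
        reactants = paste0(id_prefix, "u_", e$reactants),
        products = paste0(id_prefix, "u_", e$products),
        modifiers = character(0), reversible = FALSE
      )
    }
  }

  list(species = species, reactions = reactions,
       compartments = data.frame(id = compartment, name = NA_character_,
                                 stringsAsFactors = FALSE),
       model_id = model_id)
}

# Closed-form expectation for the planted solution, from the construction's
# own bookkeeping: shared names identify the mapped species; matched
# reactions are exactly the core reactions of each side; each reaction's
# weight is the fraction of its participants whose names are shared.
planted_expectation <- function(doc1, doc2) {
  shared <- intersect(doc1$species$name, doc2$species$name)
  map1 <- doc1$species$id[doc1$species$name %in% shared]
  names_of <- function(doc, ids) doc$species$name[match(ids, doc$species$id)]
  map2 <- doc2$species$id[match(names_of(doc1, map1), doc2$species$name)]
  species_map <- stats::setNames(map2, map1)

  side_expect <- function(doc, mapped_ids) {
    weights <- vapply(doc$reactions, function(r) {
      parts <- c(r$reactants, r$products, r$modifiers)
      matched <- any(c(r$reactants, r$products) %in% mapped_ids)
      # a core reaction always has all reactants and products shared or is a
      # gap split; unique-component reactions share nothing
      if (!all(c(r$reactants, r$products) %in% mapped_ids) &&
          !any(c(r$reactants, r$products) %in% mapped_ids)) {
        return(0)
      }
      sum(parts %in% mapped_ids) / length(parts)
    }, numeric(1))
    list(weights = weights,
         matched = names(doc$reactions)[weights > 0],
         score = mean(weights))
  }
  e1 <- side_expect(doc1, map1)
  e2 <- side_expect(doc2, map2)
  list(species_map = species_map,
       matched_rids1 = e1$matched, matched_rids2 = e2$matched,
       s1 = e1$score, s2 = e2$score)
}

#' Random pathway graph for property tests
#'
#' Draws a random labelled multidigraph directly (no SBML round trip):
#' species `s1..n` with names equal to their ids, a single compartment, and
#' reactions with 1-2 reactants and 1-2 products drawn uniformly, each
#' reversible with probability `reversible_prob`.
#'
#' @param n_species,n_reactions Sizes.
#' @param reversible_prob Probability a reaction is reversible.
#' @param seed RNG seed.
#' @param compartment Compartment id.
#' @param prefix Prefix for species/reaction ids (and species names).
#' @return A `pathway_graph`.
#' @export
random_pathway_graph <- function(n_species = 6, n_reactions = 6,
                                 reversible_prob = 0.2, seed = 1,
                                 compartment = "c", prefix = "s") {
  with_seed(seed, {
    ids <- paste0(prefix, seq_len(n_species))
    species <- data.frame(id = ids, name = ids, compartment = compartment,
                          stringsAsFactors = FALSE)
    reactions <- lapply(seq_len(n_reactions), function(i) {
      list(id = paste0(prefix, "_r", i), name = NA_character_,
           reactants = sort(sample(ids, sample(1:2, 1))),
           products = sort(sample(ids, sample(1:2, 1))),
           modifiers = character(0),
           reversible = stats::runif(1) < reversible_prob)
    })
    names(reactions) <- vapply(reactions, `[[`, "", "id")
    build_graph(list(species = species, reactions = reactions,
                     compartments = data.frame(id = compartment,
                                               name = NA_character_,
                                               stringsAsFactors = FALSE),
                     model_id = paste0("random_", seed)))
  })
}

#' Write the degenerate-edge-case fixture set
#'
#' One small SBML document per stated edge case: an incomplete reaction
#' (empty reactant set), an isolated species, a nameless species, a
#' self-loop reaction and a fully reversible chain.
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_degenerate_fixtures <- function(dir = tempfile("degenerate")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  comp <- data.frame(id = "c1", name = NA_character_,
                     stringsAsFactors = FALSE)
  sp <- function(id, name = toupper(id)) {
    data.frame(id = id, name = name, compartment = "c1",
               stringsAsFactors = FALSE)
  }
  rx <- function(id, reactants, products, modifiers = character(0),
                 reversible = FALSE) {
    stats::setNames(list(list(id = id, name = NA_character_,
                              reactants = reactants, products = products,
                              modifiers = modifiers,
                              reversible = reversible)), id)
  }
  docs <- list(
    incomplete_reaction = list(
      species = rbind(sp("a"), sp("b")),
      reactions = c(rx("r1", "a", "b"),
                    rx("r_incomplete", character(0), "b"))
    ),
    isolated_species = list(
      species = rbind(sp("a"), sp("b"), sp("lonely")),
      reactions = rx("r1", "a", "b")
    ),
    nameless_species = list(
      species = rbind(sp("a"), sp("noname", NA_character_)),
      reactions = rx("r1", "a", "noname")
    ),
    self_loop = list(
      species = sp("a"),
      reactions = rx("r1", "a", "a")
    ),
    reversible_chain = list(
      species = rbind(sp("a"), sp("b"), sp("c")),
      reactions = c(rx("r1", "a", "b", reversible = TRUE),
                    rx("r2", "b", "c", reversible = TRUE))
    )
  )
  paths <- vapply(names(docs), function(nm) {
    doc <- docs[[nm]]
    doc$compartments <- comp
    doc$model_id <- nm
    write_sbml(doc, file.path(dir, paste0(nm, ".xml")))
    file.path(dir, paste0(nm, ".xml"))
  }, "")
  paths
}
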