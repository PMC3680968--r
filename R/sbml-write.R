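#' Write a parsed SBML model back to disk
#'
#' Emits an SBML Level 2 Version 4 document containing the compartments,
#' species and reactions of a parsed model (the subset this package reads).
#'
#' @param parsed A list with `species`, `reactions`, `compartments`,
#'   `model_id` in the shape produced by [parse_sbml()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(parsed, path) {
  root <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level2/version4",
    level = "2", version = "4"
  )
  model <- xml2::xml_add_child(root, "model", id = parsed$model_id)

  comps <- parsed$compartments
  if (is.null(comps) || !nrow(comps)) {
    comps <- data.frame(id = unique(parsed$species$compartment),
                        name = NA_character_, stringsAsFactors = FALSE)
  }
  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (i in seq_len(nrow(comps))) {
    attrs <- c(id = comps$id[i])
    if (!is.na(comps$name[i])) attrs <- c(attrs, name = comps$name[i])
    do.call(xml2::xml_add_child, c(list(loc, "compartment"), as.list(attrs)))
  }

  los <- xml2::xml_add_child(model, "listOfSpecies")
  sp <- parsed$species
  for (i in seq_len(nrow(sp))) {
    attrs <- c(id = sp$id[i])
    if (!is.na(sp$name[i])) attrs <- c(attrs, name = sp$name[i])
    attrs <- c(attrs, compartment = sp$compartment[i])
    do.call(xml2::xml_add_child, c(list(los, "species"), as.list(attrs)))
  }

  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (r in parsed$reactions) {
    attrs <- c(id = r$id)
    if (!is.null(r$name) && !is.na(r$name)) attrs <- c(attrs, name = r$name)
    attrs <- c(attrs, reversible = if (r$reversible) "true" else "false")
    rx <- do.call(xml2::xml_add_child, c(list(lor, "reaction"),
                                         as.list(attrs)))
    add_refs <- function(tag, ref_tag, ids) {
      if (!length(ids)) return()
      lst <- xml2::xml_add_child(rx, tag)
      for (s in ids) xml2::xml_add_child(lst, ref_tag, species = s)
    }
    add_refs("listOfReactants", "speciesReference", r$reactants)
    add_refs("listOfProducts", "speciesReference", r$products)
    add_refs("listOfModifiers", "modifierSpeciesReference", r$modifiers)
  }

  xml2::write_xml(root, path)
  invisible(path)
}

#' Write the comparison outputs
#'
#' Produces the four result files for a comparison: the two input documents
#' pruned to their matched reactions (matched reactions are kept in full
#' definition, including unmatched participants), the merged overlap
#' document in which every matched chain pair becomes a single reaction
#' holding only the matched reactants, products and modifiers (doc1-side
#' ids), and a TSV report of the species, compartment, chain and modifier
#' mappings together with both scores.
#'
#' @param g1,g2 The compared `pathway_graph` objects.
#' @param solution A scored `match_solution`.
#' @param output_prefix Path stem; files are written as
#'   `<prefix>_doc1_pruned.xml`, `<prefix>_doc2_pruned.xml`,
#'   `<prefix>_overlap.xml` and `<prefix>_mapping.tsv`.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_outputs <- function(g1, g2, solution, output_prefix) {
  dir <- dirname(output_prefix)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  paths <- c(
    doc1 = paste0(output_prefix, "_doc1_pruned.xml"),
    doc2 = paste0(output_prefix, "_doc2_pruned.xml"),
    overlap = paste0(output_prefix, "_overlap.xml"),
    report = paste0(output_prefix, "_mapping.tsv")
  )

  write_pruned(g1, matched_reaction_ids(solution, 1), paths[["doc1"]])
  write_pruned(g2, matched_reaction_ids(solution, 2), paths[["doc2"]])
  write_overlap_doc(g1, g2, solution, paths[["overlap"]])
  write_report(solution, paths[["report"]])
  invisible(paths)
}

write_pruned <- function(graph, keep_rids, path) {
  reactions <- graph$reactions[names(graph$reactions) %in% keep_rids]
  used <- unique(unlist(lapply(reactions, function(r) {
    c(r$reactants, r$products, r$modifiers)
  }), use.names = FALSE))
  sp <- graph$species[graph$species$id %in% used, , drop = FALSE]
  comps <- graph$compartments
  if (!is.null(comps) && nrow(comps)) {
    keep_c <- comps$id %in% unique(sp$compartment)
    if (any(keep_c)) comps <- comps[keep_c, , drop = FALSE]
  }
  write_sbml(list(species = sp, reactions = reactions, compartments = comps,
                  model_id = paste0(graph$model_id, "_pruned")), path)
}

write_overlap_doc <- function(g1, g2, solution, path) {
  cm <- solution$chain_map
  mapped1 <- names(solution$species_map)
  reactions <- list()
  for (k in seq_len(nrow(cm))) {
    rids1 <- strsplit(cm$chain1[k], ",", fixed = TRUE)[[1]]
    part <- function(field) {
      ids <- unique(unlist(lapply(g1$reactions[rids1], `[[`, field),
                           use.names = FALSE))
      sort(intersect(ids, mapped1))
    }
    id <- paste0("m", k, "_", paste(gsub("[^A-Za-z0-9_]", "_", rids1),
                                    collapse = "_"))
    reactions[[id]] <- list(
      id = id,
      name = paste0(cm$chain1[k], " ~ ", cm$chain2[k]),
      reactants = part("reactants"),
      products = part("products"),
      modifiers = part("modifiers"),
      reversible = FALSE
    )
  }
  used <- unique(unlist(lapply(reactions, function(r) {
    c(r$reactants, r$products, r$modifiers)
  }), use.names = FALSE))
  sp <- g1$species[g1$species$id %in% used, , drop = FALSE]
  comps <- g1$compartments
  if (!is.null(comps) && nrow(comps) && nrow(sp)) {
    keep_c <- comps$id %in% unique(sp$compartment)
    if (any(keep_c)) comps <- comps[keep_c, , drop = FALSE]
  }
  write_sbml(list(species = sp, reactions = reactions, compartments = comps,
                  model_id = paste0(g1$model_id, "_overlap")), path)
}

write_report <- function(solution, path) {
  lines <- character(0)
  section <- function(title, keys, values) {
    c(paste0("# ", title),
      if (length(keys)) paste(keys, values, sep = "\t") else "# (empty)")
  }
  lines <- c(lines, section("SPECIES", names(solution$species_map),
                            unname(solution$species_map)))
  lines <- c(lines, section("COMPARTMENTS", names(solution$comp_map),
                            unname(solution$comp_map)))
  lines <- c(lines, section("CHAINS", solution$chain_map$chain1,
                            solution$chain_map$chain2))
  lines <- c(lines, section("MODIFIERS", names(solution$modifier_map),
                            unname(solution$modifier_map)))
  s <- solution$scores
  lines <- c(lines, "# SCORES",
             paste("S_G1", format(s[["s1"]], digits = 10), sep = "\t"),
             paste("S_G2", format(s[["s2"]], digits = 10), sep = "\t"))
  if (!nrow(solution$chain_map)) {
    lines <- c(lines, "# NOTE", "empty overlap: no matched path pairs")
  }
  writeLines(lines, path)
  invisible(path)
}
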