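#' Parse an SBML document
#'
#' Reads the subset of SBML (Level 2 or Level 3) needed for map comparison:
#' compartments, species (id, optional name, compartment) and reactions
#' (reactants, products, modifiers, reversibility flag). Kinetic laws, rules,
#' events and SBML extension packages are ignored. No filtering is applied
#' here; incomplete reactions and isolated species are removed later by
#' [build_graph()].
#'
#' @param path Path to an SBML (XML) file.
#' @return A list with components:
#'   \describe{
#'     \item{species}{data.frame with columns `id`, `name` (`NA` when the
#'       optional attribute is absent) and `compartment`.}
#'     \item{reactions}{named list of reaction records, each a list with
#'       `id`, `name`, `reactants`, `products`, `modifiers` (character
#'       vectors of species ids, set semantics) and `reversible` (logical).}
#'     \item{compartments}{data.frame with columns `id`, `name`.}
#'     \item{model_id}{the model's id attribute (or the file stem).}
#'   }
#' @export
parse_sbml <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read SBML document: file not found: ", path, call. = FALSE)
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("not well-formed XML: ", path, " (", conditionMessage(e), ")",
         call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "sbml") {
    stop("format error: root element is <", xml2::xml_name(doc),
         ">, expected <sbml>", call. = FALSE)
  }
  model <- xml2::xml_find_first(doc, "./model")
  if (inherits(model, "xml_missing")) {
    stop("format error: no <model> element in ", path, call. = FALSE)
  }

  comp_nodes <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
  compartments <- data.frame(
    id = vapply(comp_nodes, xml2::xml_attr, "", attr = "id"),
    name = vapply(comp_nodes, xml2::xml_attr, "", attr = "name"),
    stringsAsFactors = FALSE
  )
  if (nrow(compartments) && anyNA(compartments$id)) {
    stop("format error: <compartment> without id attribute", call. = FALSE)
  }

  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  species <- data.frame(
    id = vapply(sp_nodes, xml2::xml_attr, "", attr = "id"),
    name = vapply(sp_nodes, xml2::xml_attr, "", attr = "name"),
    compartment = vapply(sp_nodes, xml2::xml_attr, "", attr = "compartment"),
    stringsAsFactors = FALSE
  )
  if (nrow(species)) {
    if (anyNA(species$id)) {
      stop("format error: <species> without id attribute", call. = FALSE)
    }
    if (anyDuplicated(species$id)) {
      stop("format error: duplicated species id: ",
           species$id[duplicated(species$id)][1], call. = FALSE)
    }
    if (anyNA(species$compartment) || any(!nzchar(species$compartment))) {
      bad <- species$id[is.na(species$compartment) | !nzchar(species$compartment)][1]
      stop("format error: species '", bad, "' lacks the mandatory ",
           "compartment attribute", call. = FALSE)
    }
  }

  rx_nodes <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    if (is.na(id)) {
      stop("format error: <reaction> without id attribute", call. = FALSE)
    }
    refs <- function(xp, attr = "species") {
      nodes <- xml2::xml_find_all(node, xp)
      out <- vapply(nodes, xml2::xml_attr, "", attr = attr)
      if (anyNA(out)) {
        stop("format error: species reference without species attribute in ",
             "reaction '", id, "'", call. = FALSE)
      }
      sort(unique(out))
    }
    rev_attr <- xml2::xml_attr(node, "reversible")
    list(
      id = id,
      name = xml2::xml_attr(node, "name"),
      reactants = refs("./listOfReactants/speciesReference"),
      products = refs("./listOfProducts/speciesReference"),
      modifiers = refs("./listOfModifiers/modifierSpeciesReference"),
      # SBML Level 2 defaults reversible to true when the attribute is absent
      reversible = if (is.na(rev_attr)) TRUE else identical(rev_attr, "true")
    )
  })
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("format error: duplicated reaction id: ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  names(reactions) <- ids

  model_id <- xml2::xml_attr(model, "id")
  if (is.na(model_id)) model_id <- tools::file_path_sans_ext(basename(path))
  list(species = species, reactions = reactions,
       compartments = compartments, model_id = model_id)
}
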