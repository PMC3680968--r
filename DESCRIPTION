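Package: mapoverlap
Title: Overlap Between SBML Molecular Interaction Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the overlap between two molecular interaction maps
    encoded in the Systems Biology Markup Language (SBML). Each map is
    modelled as a labelled multidigraph in which every reaction is spliced
    into reactant-to-product edges, with modifiers as edge attributes and
    compartments as vertex attributes. Bounded-length shortest reaction
    chains ("simple paths") are enumerated in both maps, matched at their
    endpoint species under default name equivalence or user-supplied
    allowed/forbidden lists, and a consistent one-to-one set of matched
    path pairs is selected by iterative maximal-clique search on a
    compatibility graph (Bron-Kerbosch with pivoting). The overlap is
    scored per reaction by the fraction of matched reactants, products and
    modifiers, normalised by map size. Includes SBML output of the pruned
    maps and the merged overlap, a synthetic fixture generator with planted
    overlaps, and a leave-one-out benchmark harness with ROC/AUC reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
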