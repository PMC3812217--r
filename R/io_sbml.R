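# SBML (level 2/3) import. Read-only, core constructs: species with
# boundaryCondition/compartment, reactions with reversibility and
# reactant/product stoichiometry. Rules and events are reported as
# unsupported rather than silently ignored.

#' Import a network from an SBML document
#'
#' External status follows the union of the two conventions seen in
#' practice: `boundaryCondition="true"` or membership in a compartment
#' named `"external"`. Reversibility comes from the reaction attribute
#' (SBML level 2 defaults to reversible when absent).
#'
#' @param source path to an SBML file or the document text.
#' @param id network identifier.
#' @return an `efm_network`.
#' @export
read_sbml <- function(source, id = "sbml") {
  if (length(source) == 1L && !grepl("<", source) && file.exists(source)) {
    doc <- xml2::read_xml(source)
    if (id == "sbml") id <- sub("\\.(xml|sbml)$", "", basename(source))
  } else {
    doc <- xml2::read_xml(paste(source, collapse = "\n"))
  }
  # namespace-agnostic lookup
  find_all <- function(node, name) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  }
  unsupported <- character(0)
  for (construct in c("listOfRules", "listOfEvents", "listOfConstraints")) {
    if (length(find_all(doc, construct)) > 0L) {
      unsupported <- c(unsupported, construct)
    }
  }
  if (length(unsupported) > 0L) {
    stop("unsupported SBML construct(s): ",
         paste(unsupported, collapse = ", "), call. = FALSE)
  }
  species <- find_all(doc, "species")
  if (length(species) == 0L) stop("SBML document declares no species",
                                  call. = FALSE)
  mets <- lapply(species, function(sp) {
    sid <- xml2::xml_attr(sp, "id")
    nm <- xml2::xml_attr(sp, "name")
    bc <- identical(tolower(xml2::xml_attr(sp, "boundaryCondition")), "true")
    comp <- xml2::xml_attr(sp, "compartment")
    ext <- bc || identical(tolower(comp), "external")
    metabolite(sid, if (is.na(nm)) sid else nm, external = ext)
  })
  rxn_nodes <- find_all(doc, "reaction")
  rxns <- lapply(rxn_nodes, function(rx) {
    rid <- xml2::xml_attr(rx, "id")
    rev_attr <- xml2::xml_attr(rx, "reversible")
    reversible <- is.na(rev_attr) || identical(tolower(rev_attr), "true")
    stoich <- numeric(0)
    add <- function(node_list, sign) {
      for (ref in node_list) {
        sid <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(st)) 1 else as.numeric(st)
        stoich[sid] <<- (if (sid %in% names(stoich)) stoich[[sid]] else 0) +
          sign * coef
      }
    }
    for (lst in xml2::xml_find_all(rx, "./*[local-name()='listOfReactants']")) {
      add(xml2::xml_find_all(lst, "./*[local-name()='speciesReference']"), -1)
    }
    for (lst in xml2::xml_find_all(rx, "./*[local-name()='listOfProducts']")) {
      add(xml2::xml_find_all(lst, "./*[local-name()='speciesReference']"), 1)
    }
    stoich <- stoich[stoich != 0]
    reaction(rid, stoich, reversible = reversible)
  })
  build_network(mets, rxns, id = id)
}
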