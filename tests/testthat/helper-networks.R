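# Small networks used across the suite; built in code, never stored.

chain_network <- function() {
  build_network(
    list(metabolite("Aext", external = TRUE), metabolite("B"),
         metabolite("Cext", external = TRUE)),
    list(reaction("R1", c(Aext = -1, B = 1)),
         reaction("R2", c(B = -1, Cext = 1))),
    id = "chain")
}

two_route_network <- function() {
  build_network(
    list(metabolite("Aext", external = TRUE), metabolite("B"),
         metabolite("B2"), metabolite("Cext", external = TRUE)),
    list(reaction("Ra1", c(Aext = -1, B = 1)),
         reaction("Ra2", c(B = -1, Cext = 1)),
         reaction("Rb1", c(Aext = -1, B2 = 1)),
         reaction("Rb2", c(B2 = -1, Cext = 1))),
    id = "two-route")
}

rev_pair_network <- function() {
  # isolated reversible A <-> B with both internal: no steady-state mode
  build_network(
    list(metabolite("A"), metabolite("B")),
    list(reaction("R1", c(A = -1, B = 1), reversible = TRUE)),
    id = "rev-pair")
}

# split every reversible reaction of `net` into irreversible forward and
# backward copies (used by the split/merge invariance test)
split_reversibles <- function(net) {
  mets <- lapply(seq_len(nrow(net$metabolites)), function(i) {
    metabolite(net$metabolites$id[i], net$metabolites$name[i],
               net$metabolites$external[i])
  })
  rxns <- list()
  for (r in net$reactions) {
    if (r$reversible) {
      rxns <- c(rxns,
                list(reaction(paste0(r$id, "_f"), r$stoich),
                     reaction(paste0(r$id, "_b"), -r$stoich)))
    } else {
      rxns <- c(rxns, list(r))
    }
  }
  build_network(mets, rxns, id = paste0(net$id, "-split"))
}

# merge a mode vector of a split network back onto the original reactions
merge_split_mode <- function(v, net) {
  out <- stats::setNames(numeric(length(net$reactions)), names(net$reactions))
  for (id in names(v)) {
    if (grepl("_f$", id)) {
      out[sub("_f$", "", id)] <- out[sub("_f$", "", id)] + v[[id]]
    } else if (grepl("_b$", id)) {
      out[sub("_b$", "", id)] <- out[sub("_b$", "", id)] - v[[id]]
    } else {
      out[id] <- v[[id]]
    }
  }
  out
}

random_case <- function(s) {
  nr <- 3 + (s %% 6)                       # 3..8 reactions
  ni <- max(1, min(2 * nr - 2, 1 + (s %% 5)))
  random_network(ni, nr, p_reversible = 0.3, seed = s)
}

sbml_chain_text <- function(boundary = TRUE) {
  ext_a <- if (boundary) 'compartment="cell" boundaryCondition="true"' else
    'compartment="external"'
  paste0('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="chain">
  <listOfCompartments>
   <compartment id="cell"/><compartment id="external"/>
  </listOfCompartments>
  <listOfSpecies>
   <species id="Aext" ', ext_a, '/>
   <species id="B" compartment="cell"/>
   <species id="Cext" compartment="cell" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R1" reversible="false">
    <listOfReactants><speciesReference species="Aext" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>
   </reaction>
   <reaction id="R2" reversible="false">
    <listOfReactants><speciesReference species="B"/></listOfReactants>
    <listOfProducts><speciesReference species="Cext"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>')
}
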