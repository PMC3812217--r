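#' Declare a metabolite
#'
#' A chemical species or enzyme-bound moiety. Internal metabolites are
#' mass-balanced at steady state; external ones are free sources/sinks.
#'
#' @param id short unique token, e.g. `"Pyr"`, `"HE-TPP"`.
#' @param name free-text name; defaults to the id.
#' @param external logical; `TRUE` exempts the species from steady-state
#'   balancing.
#' @return an object of class `metabolite`.
#' @examples
#' metabolite("Pyr", "pyruvate")
#' metabolite("CO2", external = TRUE)
#' @export
metabolite <- function(id, name = id, external = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("metabolite id must be a non-empty string", call. = FALSE)
  }
  structure(list(id = id, name = name, external = isTRUE(external)),
            class = "metabolite")
}

#' Declare a reaction
#'
#' Stoichiometry is a named numeric vector over metabolite ids: negative
#' coefficients are consumed, positive produced. Coefficients must be exact
#' small rationals (integers in practice). `catalysts` are annotation-only
#' domain/enzyme labels with no stoichiometric effect.
#'
#' @param id short unique token, e.g. `"citA"`, `"R5"`.
#' @param stoich named numeric vector, no zero entries.
#' @param reversible logical.
#' @param catalysts character vector of catalytic domain labels.
#' @return an object of class `reaction`.
#' @examples
#' reaction("citA", c(AcCoA = -1, OAA = -1, Cit = 1, CoA = 1))
#' @export
reaction <- function(id, stoich, reversible = FALSE, catalysts = character()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("reaction id must be a non-empty string", call. = FALSE)
  }
  if (length(stoich) == 0L) {
    stop("reaction '", id, "' has empty stoichiometry", call. = FALSE)
  }
  if (is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop("reaction '", id, "' stoichiometry must be fully named", call. = FALSE)
  }
  if (anyDuplicated(names(stoich))) {
    stop("reaction '", id, "' repeats a metabolite in its stoichiometry",
         call. = FALSE)
  }
  if (any(stoich == 0)) {
    stop("reaction '", id, "' stores a zero coefficient", call. = FALSE)
  }
  structure(list(id = id, stoich = stoich, reversible = isTRUE(reversible),
                 catalysts = as.character(catalysts)),
            class = "reaction")
}

#' Build a validated metabolic network
#'
#' Declaration order of metabolites and reactions is preserved exactly; it
#' fixes row/column order of the stoichiometric matrix and the rendering
#' order of mode supports.
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param id optional network identifier used in provenance fields.
#' @return an object of class `efm_network` with fields `metabolites`
#'   (data frame), `reactions` (named list) and `id`.
#' @examples
#' net <- build_network(
#'   list(metabolite("Aext", external = TRUE), metabolite("B"),
#'        metabolite("Cext", external = TRUE)),
#'   list(reaction("R1", c(Aext = -1, B = 1)),
#'        reaction("R2", c(B = -1, Cext = 1))))
#' net
#' @export
build_network <- function(metabolites, reactions, id = "network") {
  if (inherits(metabolites, "metabolite")) metabolites <- list(metabolites)
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  stopifnot(is.list(metabolites), is.list(reactions))
  for (m in metabolites) {
    if (!inherits(m, "metabolite")) stop("expected metabolite objects",
                                         call. = FALSE)
  }
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite id: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "),
         call. = FALSE)
  }
  rxn_ids <- character(length(reactions))
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    if (!inherits(r, "reaction")) stop("expected reaction objects",
                                       call. = FALSE)
    rxn_ids[i] <- r$id
    missing <- setdiff(names(r$stoich), met_ids)
    if (length(missing) > 0L) {
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction id: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "),
         call. = FALSE)
  }
  external <- vapply(metabolites, `[[`, logical(1), "external")
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich)),
                        use.names = FALSE))
  isolated <- met_ids[!external & !(met_ids %in% used)]
  if (length(isolated) > 0L) {
    stop("internal metabolite(s) participate in no reaction: ",
         paste(isolated, collapse = ", "), call. = FALSE)
  }
  mets <- data.frame(
    id = met_ids,
    name = vapply(metabolites, `[[`, character(1), "name"),
    external = external,
    stringsAsFactors = FALSE
  )
  names(reactions) <- rxn_ids
  structure(list(id = id, metabolites = mets, reactions = reactions),
            class = "efm_network")
}

#' @export
print.efm_network <- function(x, ...) {
  n_int <- sum(!x$metabolites$external)
  n_rev <- sum(vapply(x$reactions, `[[`, logical(1), "reversible"))
  cat(sprintf("<efm_network '%s': %d reactions (%d reversible), %d metabolites (%d internal)>\n",
              x$id, length(x$reactions), n_rev, nrow(x$metabolites), n_int))
  invisible(x)
}

reaction_ids <- function(net) names(net$reactions)

internal_ids <- function(net) net$metabolites$id[!net$metabolites$external]

external_ids <- function(net) net$metabolites$id[net$metabolites$external]

reversibility <- function(net) {
  vapply(net$reactions, `[[`, logical(1), "reversible")
}

#' Stoichiometric matrix over internal metabolites
#'
#' Rows are internal metabolites (declaration order), columns reactions
#' (declaration order). Entries are exact; rational inputs are preserved
#' as given (the enumerator clears denominators row-wise, which leaves the
#' nullspace unchanged).
#'
#' @param net an `efm_network`.
#' @param internal_only logical; if `FALSE`, include external metabolite rows
#'   (used for overall-reaction accounting).
#' @return numeric matrix with dimnames (metabolite ids x reaction ids).
#' @examples
#' net <- build_network(
#'   list(metabolite("Aext", external = TRUE), metabolite("B"),
#'        metabolite("Cext", external = TRUE)),
#'   list(reaction("R1", c(Aext = -1, B = 1)),
#'        reaction("R2", c(B = -1, Cext = 1))))
#' stoichiometric_matrix(net)
#' @export
stoichiometric_matrix <- function(net, internal_only = TRUE) {
  stopifnot(inherits(net, "efm_network"))
  rows <- if (internal_only) internal_ids(net) else net$metabolites$id
  S <- matrix(0, nrow = length(rows), ncol = length(net$reactions),
              dimnames = list(rows, reaction_ids(net)))
  for (r in net$reactions) {
    keep <- names(r$stoich) %in% rows
    if (any(keep)) S[names(r$stoich)[keep], r$id] <- r$stoich[keep]
  }
  S
}

# Coerce a flux vector to the network's reaction order; names optional.
align_flux <- function(v, net) {
  ids <- reaction_ids(net)
  if (!is.null(names(v))) {
    unknown <- setdiff(names(v), ids)
    if (length(unknown) > 0L) {
      stop("flux vector names not in network: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    full <- stats::setNames(numeric(length(ids)), ids)
    full[names(v)] <- v
    full
  } else {
    if (length(v) != length(ids)) {
      stop("flux vector length ", length(v), " does not match ",
           length(ids), " reactions", call. = FALSE)
    }
    stats::setNames(as.numeric(v), ids)
  }
}

#' Net overall reaction of a flux vector on external metabolites
#'
#' For each external metabolite the net production `sum_r v_r * s_mr` is
#' returned; zero entries are omitted. For an elementary mode this is the
#' mode's overall reaction, invariant under positive scaling.
#'
#' @param v flux vector, named by reaction id or in network reaction order.
#' @param net an `efm_network`.
#' @return named numeric vector over external metabolite ids (negative =
#'   consumed, positive = produced); empty if the mode touches no external.
#' @export
overall_reaction <- function(v, net) {
  v <- align_flux(v, net)
  ext <- external_ids(net)
  if (length(ext) == 0L) return(stats::setNames(numeric(0), character(0)))
  S <- stoichiometric_matrix(net, internal_only = FALSE)
  tot <- as.vector(S[ext, , drop = FALSE] %*% v)
  names(tot) <- ext
  tot[tot != 0]
}

#' Remove reactions from a network
#'
#' Deletes the given reactions; metabolites that are no longer referenced by
#' any remaining reaction are dropped as well (an unreferenced internal row
#' would impose no constraint but fail network validation). Used for
#' knockout-by-re-enumeration analyses.
#'
#' @param net an `efm_network`.
#' @param ids reaction ids to remove.
#' @return a new `efm_network`.
#' @export
drop_reactions <- function(net, ids) {
  stopifnot(inherits(net, "efm_network"))
  unknown <- setdiff(ids, reaction_ids(net))
  if (length(unknown) > 0L) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- net$reactions[!(reaction_ids(net) %in% ids)]
  used <- unique(unlist(lapply(keep, function(r) names(r$stoich)),
                        use.names = FALSE))
  mets <- net$metabolites[net$metabolites$id %in% used, , drop = FALSE]
  met_objs <- lapply(seq_len(nrow(mets)), function(i) {
    metabolite(mets$id[i], mets$name[i], mets$external[i])
  })
  out <- build_network(met_objs, unname(keep),
                       id = paste0(net$id, "-ko"))
  # carry domain metadata through knockouts
  for (field in c("domain_table", "species_domains", "enzyme_map")) {
    if (!is.null(net[[field]])) out[[field]] <- net[[field]]
  }
  class(out) <- class(net)
  out
}

#' Flip a metabolite between internal and external status
#'
#' @param net an `efm_network`.
#' @param id metabolite id.
#' @param external new status.
#' @return a new `efm_network`.
#' @export
set_external <- function(net, id, external = TRUE) {
  stopifnot(inherits(net, "efm_network"))
  i <- match(id, net$metabolites$id)
  if (is.na(i)) stop("unknown metabolite '", id, "'", call. = FALSE)
  net$metabolites$external[i] <- isTRUE(external)
  net
}
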