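# Functional-domain networks: enzymes decomposed into catalytic and binding
# domains. Catalytic domains are annotations on reaction steps; binding
# domains are species that form enzyme-bound complexes and therefore enter
# the stoichiometry. Regulatory domains are annotation-only.

#' Annotate a functional protein domain
#'
#' @param label unique token used in the network, e.g. `"PdhD2"`.
#' @param gene gene name, e.g. `"pdhD"`.
#' @param scop_fold SCOP fold identifier, e.g. `"c.4.1"`.
#' @param fun free-text description of the elementary activity.
#' @param role one of `"catalytic"`, `"binding"`, `"regulatory"`.
#' @return an object of class `domain_annotation`.
#' @export
domain_annotation <- function(label, gene, scop_fold, fun,
                              role = c("catalytic", "binding", "regulatory")) {
  role <- match.arg(role)
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("domain label must be a non-empty string", call. = FALSE)
  }
  structure(list(label = label, gene = gene, scop_fold = scop_fold,
                 fun = fun, role = role),
            class = "domain_annotation")
}

#' Specify a functional-domain network
#'
#' A curated decomposition of enzymes into elementary steps. `species` may
#' include enzyme-bound intermediates (e.g. `HE-TPP`) and domain-ligand
#' complexes; `species_domains` records which domain labels each complex
#' species involves, so that domain inhibition can locate the reactions a
#' binding domain participates in.
#'
#' @param domains list of [domain_annotation()] objects.
#' @param species list of [metabolite()] objects.
#' @param steps list of [reaction()] objects whose `catalysts` reference
#'   declared domain labels.
#' @param enzyme_map named list: enzyme-level reaction id -> character vector
#'   of step ids realizing it.
#' @param species_domains named list: species id -> character vector of
#'   domain labels the species involves (free domains and complexes).
#' @param id network identifier.
#' @return an object of class `domain_network_spec`.
#' @export
domain_network_spec <- function(domains, species, steps, enzyme_map = list(),
                                species_domains = list(), id = "domain-network") {
  for (d in domains) {
    if (!inherits(d, "domain_annotation")) {
      stop("domains must be domain_annotation objects", call. = FALSE)
    }
  }
  labels <- vapply(domains, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate domain label: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  step_ids <- vapply(steps, `[[`, character(1), "id")
  if (anyDuplicated(step_ids)) {
    stop("duplicate step id: ",
         paste(unique(step_ids[duplicated(step_ids)]), collapse = ", "),
         call. = FALSE)
  }
  for (s in steps) {
    dangling <- setdiff(s$catalysts, labels)
    if (length(dangling) > 0L) {
      stop("step '", s$id, "' cites undeclared domain(s): ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
  }
  for (sp in names(species_domains)) {
    dangling <- setdiff(species_domains[[sp]], labels)
    if (length(dangling) > 0L) {
      stop("species '", sp, "' tagged with undeclared domain(s): ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
  }
  for (enz in names(enzyme_map)) {
    missing <- setdiff(enzyme_map[[enz]], step_ids)
    if (length(missing) > 0L) {
      stop("enzyme '", enz, "' maps to unknown step(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (length(enzyme_map[[enz]]) == 0L) {
      stop("enzyme '", enz, "' maps to no step", call. = FALSE)
    }
  }
  structure(list(domains = domains, species = species, steps = steps,
                 enzyme_map = enzyme_map, species_domains = species_domains,
                 id = id),
            class = "domain_network_spec")
}

#' Build a network from a functional-domain specification
#'
#' @param spec a [domain_network_spec()].
#' @return an `efm_network` (additionally classed `domain_network`) whose
#'   reactions are the elementary steps; domain annotations are attached as
#'   `domain_table`, `species_domains` and `enzyme_map` fields.
#' @export
build_domain_network <- function(spec) {
  stopifnot(inherits(spec, "domain_network_spec"))
  net <- build_network(spec$species, spec$steps, id = spec$id)
  net$domain_table <- data.frame(
    label = vapply(spec$domains, `[[`, character(1), "label"),
    gene = vapply(spec$domains, `[[`, character(1), "gene"),
    scop_fold = vapply(spec$domains, `[[`, character(1), "scop_fold"),
    fun = vapply(spec$domains, `[[`, character(1), "fun"),
    role = vapply(spec$domains, `[[`, character(1), "role"),
    stringsAsFactors = FALSE
  )
  net$species_domains <- spec$species_domains
  net$enzyme_map <- spec$enzyme_map
  class(net) <- c("domain_network", class(net))
  net
}

#' Reactions linked to a functional domain
#'
#' A catalytic domain is linked to the steps it annotates; a binding domain
#' is linked to every reaction whose stoichiometry involves a species
#' carrying that domain (the free domain or one of its complexes).
#'
#' @param net a network built by [build_domain_network()].
#' @param label domain label.
#' @return character vector of reaction ids (possibly empty, e.g. for a
#'   regulatory domain attached to no step).
#' @export
reactions_of_domain <- function(net, label) {
  stopifnot(inherits(net, "efm_network"))
  if (is.null(net$domain_table) || !(label %in% net$domain_table$label)) {
    stop("unknown domain label '", label, "'", call. = FALSE)
  }
  tagged <- names(net$species_domains)[vapply(net$species_domains,
                                              function(d) label %in% d,
                                              logical(1))]
  hit <- vapply(net$reactions, function(r) {
    label %in% r$catalysts || any(names(r$stoich) %in% tagged)
  }, logical(1))
  reaction_ids(net)[hit]
}

resolve_targets <- function(net, targets) {
  rids <- reaction_ids(net)
  if (length(targets) == 1L && !is.null(net$domain_table) &&
      targets %in% net$domain_table$label && !(targets %in% rids)) {
    out <- reactions_of_domain(net, targets)
  } else {
    unknown <- setdiff(targets, rids)
    if (length(unknown) > 0L) {
      stop("target(s) resolve to no reaction or domain: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out <- targets
  }
  if (length(out) == 0L) {
    stop("target '", paste(targets, collapse = ", "),
         "' resolves to no reaction", call. = FALSE)
  }
  out
}

#' Impact of inhibiting reactions or a domain on an EFM set
#'
#' Partitions the mode set into modes whose support intersects the target
#' reactions (removed) and the rest (surviving), and lists the external
#' metabolites that some removed mode produced but no surviving mode can
#' (lost production capabilities). Blocking a domain removes every reaction
#' linked to it (see [reactions_of_domain()]).
#'
#' @param net the network the modes were enumerated on.
#' @param efms an `efm_set`.
#' @param targets character vector of reaction ids, or a single domain label.
#' @return an object of class `inhibition_report` with fields `target`,
#'   `target_reactions`, `removed_modes`, `surviving_modes` (indices into
#'   `efms$modes`) and `lost_capabilities`.
#' @export
inhibit <- function(net, efms, targets) {
  stopifnot(inherits(net, "efm_network"), inherits(efms, "efm_set"))
  rxns <- resolve_targets(net, targets)
  unsigned <- lapply(efms$modes, function(m) sub("^-", "", m$support))
  removed <- which(vapply(unsigned, function(s) any(rxns %in% s), logical(1)))
  surviving <- setdiff(seq_along(efms$modes), removed)
  producible <- function(idx) {
    prods <- unlist(lapply(efms$modes[idx], function(m) {
      names(m$overall)[m$overall > 0]
    }), use.names = FALSE)
    unique(prods)
  }
  lost <- setdiff(producible(removed), producible(surviving))
  structure(list(target = targets,
                 target_reactions = rxns,
                 removed_modes = removed,
                 surviving_modes = surviving,
                 lost_capabilities = lost),
            class = "inhibition_report")
}

#' @export
print.inhibition_report <- function(x, ...) {
  cat(sprintf("<inhibition_report: target %s -> reactions {%s}>\n",
              paste(x$target, collapse = ","),
              paste(x$target_reactions, collapse = ", ")))
  cat(sprintf("  removed modes:   %s\n",
              if (length(x$removed_modes)) paste(x$removed_modes, collapse = ", ") else "none"))
  cat(sprintf("  surviving modes: %s\n",
              if (length(x$surviving_modes)) paste(x$surviving_modes, collapse = ", ") else "none"))
  cat(sprintf("  lost production capabilities: %s\n",
              if (length(x$lost_capabilities)) paste(x$lost_capabilities, collapse = ", ") else "none"))
  invisible(x)
}

#' JSON-ready rendering of an inhibition report
#' @param report an `inhibition_report`.
#' @return a plain list suitable for `jsonlite::toJSON`.
#' @export
inhibition_report_json <- function(report) {
  stopifnot(inherits(report, "inhibition_report"))
  list(target = report$target,
       target_reactions = report$target_reactions,
       removed_modes = report$removed_modes,
       surviving_modes = report$surviving_modes,
       lost_capabilities = report$lost_capabilities)
}

#' Modes producing or consuming an external metabolite
#'
#' @param efms an `efm_set`.
#' @param metabolite_id external metabolite id.
#' @param direction `"produce"` (strictly positive overall coefficient) or
#'   `"consume"` (strictly negative).
#' @return integer vector of mode indices.
#' @export
producing_modes <- function(efms, metabolite_id,
                            direction = c("produce", "consume")) {
  stopifnot(inherits(efms, "efm_set"))
  direction <- match.arg(direction)
  net <- efms$network
  i <- match(metabolite_id, net$metabolites$id)
  if (is.na(i)) stop("unknown metabolite '", metabolite_id, "'", call. = FALSE)
  if (!net$metabolites$external[i]) {
    stop("metabolite '", metabolite_id,
         "' is internal; overall reactions are defined on externals only",
         call. = FALSE)
  }
  hit <- vapply(efms$modes, function(m) {
    cf <- m$overall[metabolite_id]
    !is.na(cf) && if (direction == "produce") cf > 0 else cf < 0
  }, logical(1))
  which(hit)
}

# normalize an overall-reaction map through an alias table and return a
# canonical string key
overall_key <- function(ov, aliases = NULL) {
  if (length(ov) == 0L) return("")
  ids <- names(ov)
  if (!is.null(aliases) && length(aliases) > 0L) {
    hit <- ids %in% names(aliases)
    ids[hit] <- unname(aliases[ids[hit]])
  }
  o <- order(ids)
  paste(sprintf("%s:%s", ids[o], format(unname(ov[o]))), collapse = " ")
}

#' Match two EFM sets by overall reaction
#'
#' Two mode sets over the same external-metabolite vocabulary (after alias
#' normalization) are matched when their overall reactions are equal as
#' maps. Unmatched modes on either side are reported, not raised.
#'
#' @param classical,domain `efm_set` objects.
#' @param aliases named character vector mapping external metabolite ids of
#'   either set onto a shared vocabulary (applied to both sides).
#' @return an object of class `efm_comparison`: a data frame `matches` with
#'   columns `classical` and `domain` (mode indices), plus
#'   `unmatched_classical` and `unmatched_domain` index vectors.
#' @export
compare_representations <- function(classical, domain, aliases = NULL) {
  stopifnot(inherits(classical, "efm_set"), inherits(domain, "efm_set"))
  kc <- vapply(classical$modes, function(m) overall_key(m$overall, aliases),
               character(1))
  kd <- vapply(domain$modes, function(m) overall_key(m$overall, aliases),
               character(1))
  used <- logical(length(kd))
  ci <- integer(0); di <- integer(0)
  for (i in seq_along(kc)) {
    j <- which(kd == kc[i] & !used)
    if (length(j) > 0L) {
      used[j[1]] <- TRUE
      ci <- c(ci, i); di <- c(di, j[1])
    }
  }
  structure(list(
    matches = data.frame(classical = ci, domain = di),
    unmatched_classical = setdiff(seq_along(kc), ci),
    unmatched_domain = which(!used)
  ), class = "efm_comparison")
}

#' @export
print.efm_comparison <- function(x, ...) {
  cat(sprintf("<efm_comparison: %d matched, %d unmatched left, %d unmatched right>\n",
              nrow(x$matches), length(x$unmatched_classical),
              length(x$unmatched_domain)))
  if (nrow(x$matches) > 0L) {
    for (i in seq_len(nrow(x$matches))) {
      cat(sprintf("  EFM %d <-> EFM %d\n", x$matches$classical[i],
                  x$matches$domain[i]))
    }
  }
  invisible(x)
}
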