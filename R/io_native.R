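# Native JSON network-definition schema. A human-editable structured
# format that, unlike the metatool dialect, preserves catalyst annotations.
#
# {
#   "id": "...",
#   "metabolites": [{"id": "...", "name": "...", "external": false}, ...],
#   "reactions":   [{"id": "...", "stoich": {"A": -1, "B": 1},
#                    "reversible": false, "catalysts": ["PdhA"]}, ...]
# }

#' Serialize a network to the native JSON schema
#'
#' @param net an `efm_network`.
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @return JSON string (invisibly when writing to a file).
#' @export
write_network_json <- function(net, path = NULL) {
  stopifnot(inherits(net, "efm_network"))
  obj <- list(
    id = net$id,
    metabolites = lapply(seq_len(nrow(net$metabolites)), function(i) {
      list(id = net$metabolites$id[i],
           name = net$metabolites$name[i],
           external = net$metabolites$external[i])
    }),
    reactions = lapply(net$reactions, function(r) {
      list(id = r$id, stoich = as.list(r$stoich),
           reversible = r$reversible,
           catalysts = as.list(r$catalysts))
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a network from the native JSON schema
#'
#' @param source path to a JSON file or the JSON text.
#' @return an `efm_network`.
#' @export
read_network_json <- function(source) {
  obj <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  mets <- lapply(obj$metabolites, function(m) {
    metabolite(m$id, if (is.null(m$name)) m$id else m$name,
               external = isTRUE(m$external))
  })
  rxns <- lapply(obj$reactions, function(r) {
    reaction(r$id, vapply(r$stoich, as.numeric, numeric(1)),
             reversible = isTRUE(r$reversible),
             catalysts = unlist(r$catalysts) %||% character(0))
  })
  build_network(mets, rxns,
                id = if (is.null(obj$id)) "network" else obj$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
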