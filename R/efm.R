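# Elementary flux mode enumeration in exact integer arithmetic.
#
# enumerate_efms(): double description on the split cone {v >= 0, S v = 0}
# (every reversible reaction split into a forward and a backward column),
# followed by recombination, exclusion of the futile forward+backward
# two-cycles, and canonicalization. For pointed cones the classical
# combinatorial adjacency test (no third ray's support inside the union of
# the pair's supports) is exact, so no tolerances exist anywhere.
#
# brute_force_efms(): independent oracle — enumerate signed supports
# directly via exact rank tests. Kept deliberately free of any code shared
# with the double-description path beyond the integer primitives.

signed_support <- function(v) {
  nz <- which(v != 0)
  ids <- names(v)[nz]
  unname(ifelse(v[nz] > 0, ids, paste0("-", ids)))
}

support_key <- function(ss) paste(ss, collapse = " ")

#' Canonicalize a flux vector
#'
#' Scales to coprime integer entries. If every support reaction is
#' reversible the orientation is chosen so that the first support entry in
#' network reaction order is positive (a reversible-only mode is reported
#' once, in one orientation).
#'
#' @param v flux vector (named by reaction id, or in network reaction order).
#' @param net the `efm_network` the vector belongs to.
#' @return named numeric vector of coprime integers over all reactions.
#' @examples
#' net <- build_network(
#'   list(metabolite("A", external = TRUE), metabolite("B"),
#'        metabolite("C", external = TRUE)),
#'   list(reaction("R1", c(A = -1, B = 1)),
#'        reaction("R2", c(B = -1, C = 1))))
#' canonicalize(c(R1 = 0.5, R2 = 0.5), net)
#' @export
canonicalize <- function(v, net) {
  v <- align_flux(v, net)
  if (all(v == 0)) stop("cannot canonicalize the zero vector", call. = FALSE)
  v <- to_coprime_integers(v)
  rev <- reversibility(net)
  nz <- which(v != 0)
  if (all(rev[nz]) && v[nz[1]] < 0) v <- -v
  v
}

new_flux_mode <- function(v, net) {
  structure(list(coeffs = v,
                 support = signed_support(v),
                 overall = overall_reaction(v, net)),
            class = "flux_mode")
}

#' @export
print.flux_mode <- function(x, ...) {
  cat("<flux_mode>", render_support(x$coeffs), "\n")
  if (length(x$overall) > 0L) {
    cat("  overall:", render_overall(x$overall), "\n")
  }
  invisible(x)
}

# "R1 (2 R5) -R25" rendering in the style of the metatool mode listings.
render_support <- function(v) {
  nz <- which(v != 0)
  paste(vapply(nz, function(i) {
    id <- names(v)[i]
    a <- v[i]
    if (a == 1) id
    else if (a == -1) paste0("-", id)
    else if (a > 0) sprintf("(%s %s)", format(a), id)
    else sprintf("(%s -%s)", format(-a), id)
  }, character(1)), collapse = " ")
}

render_overall <- function(ov) {
  fmt <- function(ids, coefs) {
    paste(ifelse(coefs == 1, ids, paste(format(coefs), ids)), collapse = " + ")
  }
  lhs <- ov[ov < 0]; rhs <- ov[ov > 0]
  paste0(fmt(names(lhs), -unname(lhs)), " --> ", fmt(names(rhs), unname(rhs)))
}

new_efm_set <- function(modes, net) {
  structure(list(modes = modes, network_id = net$id, network = net),
            class = "efm_set")
}

#' @export
print.efm_set <- function(x, ...) {
  cat(sprintf("<efm_set: %d elementary flux modes of '%s'>\n",
              length(x$modes), x$network_id))
  cat(efm_listing(x), sep = "\n")
  invisible(x)
}

#' @export
length.efm_set <- function(x) length(x$modes)

#' Plain-text listing of an EFM set
#'
#' One line per mode, `"EFM n<TAB>support"`, in the deterministic package
#' order (support size, then lexicographic signed support).
#'
#' @param efms an `efm_set`.
#' @return character vector of lines.
#' @export
efm_listing <- function(efms) {
  stopifnot(inherits(efms, "efm_set"))
  vapply(seq_along(efms$modes), function(i) {
    sprintf("EFM %d\t%s", i, render_support(efms$modes[[i]]$coeffs))
  }, character(1))
}

#' Structured report of an EFM set
#'
#' @param efms an `efm_set`.
#' @return a list (JSON-ready) with one entry per mode: coefficients over
#'   the support, signed support, and overall external reaction.
#' @export
efm_report <- function(efms) {
  stopifnot(inherits(efms, "efm_set"))
  list(
    network = efms$network_id,
    n_modes = length(efms$modes),
    modes = lapply(seq_along(efms$modes), function(i) {
      m <- efms$modes[[i]]
      nz <- m$coeffs[m$coeffs != 0]
      list(label = sprintf("EFM %d", i),
           coefficients = as.list(nz),
           support = m$support,
           overall = as.list(m$overall))
    })
  )
}

# deterministic ordering: support size, then signed-support string
order_modes <- function(modes) {
  sizes <- vapply(modes, function(m) length(m$support), integer(1))
  keys <- vapply(modes, function(m) support_key(sort(m$support)), character(1))
  modes[order(sizes, keys)]
}

# integer stoichiometric matrix over internal metabolites
integer_stoich <- function(net) {
  integerize_rows(stoichiometric_matrix(net))
}

#' Enumerate all elementary flux modes
#'
#' Computes the complete set of elementary modes of the flux cone
#' `{v : S v = 0, v_r >= 0 for irreversible r}`, up to positive scaling.
#' Reversible reactions may carry negative flux (rendered with a leading
#' `-`); a mode whose support is entirely reversible is reported once. The
#' spurious forward+backward two-cycles introduced by splitting reversible
#' reactions are excluded.
#'
#' @param net an `efm_network`.
#' @return an `efm_set`; modes are coprime integer vectors sorted by
#'   (support size, lexicographic signed support).
#' @examples
#' net <- build_network(
#'   list(metabolite("A", external = TRUE), metabolite("B"),
#'        metabolite("C", external = TRUE)),
#'   list(reaction("R1", c(A = -1, B = 1)),
#'        reaction("R2", c(B = -1, C = 1))))
#' enumerate_efms(net)
#' @export
enumerate_efms <- function(net) {
  stopifnot(inherits(net, "efm_network"))
  ids <- reaction_ids(net)
  n <- length(ids)
  if (n == 0L) return(new_efm_set(list(), net))
  S <- integer_stoich(net)
  rev <- reversibility(net)
  # split: forward columns for all reactions, backward for reversible
  back <- which(rev)
  Ssplit <- cbind(S, -S[, back, drop = FALSE])
  nsplit <- ncol(Ssplit)

  rays <- diag(nsplit)               # rows are rays of the current cone
  supp <- rays != 0
  for (i in seq_len(nrow(Ssplit))) {
    s <- Ssplit[i, ]
    if (all(s == 0)) next
    d <- as.vector(rays %*% s)
    zero <- which(d == 0)
    pos <- which(d > 0)
    neg <- which(d < 0)
    kept <- rays[zero, , drop = FALSE]
    kept_supp <- supp[zero, , drop = FALSE]
    new_rays <- list()
    if (length(pos) > 0L && length(neg) > 0L) {
      for (p in pos) {
        for (q in neg) {
          u <- supp[p, ] | supp[q, ]
          # combinatorial adjacency: no third ray inside the union support
          adjacent <- TRUE
          for (k in seq_len(nrow(rays))) {
            if (k == p || k == q) next
            if (!any(supp[k, ] & !u)) { adjacent <- FALSE; break }
          }
          if (!adjacent) next
          r <- d[p] * rays[q, ] - d[q] * rays[p, ]
          .chk_int_range(r)
          g <- gcd_vec(r)
          if (g > 1) r <- r / g
          new_rays[[length(new_rays) + 1L]] <- r
        }
      }
    }
    if (length(new_rays) > 0L) {
      rays <- rbind(kept, do.call(rbind, new_rays))
    } else {
      rays <- kept
    }
    supp <- rays != 0
    if (nrow(rays) == 0L) break
  }

  modes <- list()
  seen <- character(0)
  if (nrow(rays) > 0L) {
    for (k in seq_len(nrow(rays))) {
      r <- rays[k, ]
      fwd <- r[seq_len(n)]
      bwd <- numeric(n)
      if (length(back) > 0L) bwd[back] <- r[n + seq_along(back)]
      if (any(fwd > 0 & bwd > 0)) next   # futile two-cycle of a split pair
      v <- stats::setNames(fwd - bwd, ids)
      if (all(v == 0)) next
      v <- canonicalize(v, net)
      key <- support_key(signed_support(v))
      if (key %in% seen) next
      seen <- c(seen, key)
      modes[[length(modes) + 1L]] <- new_flux_mode(v, net)
    }
  }
  new_efm_set(order_modes(modes), net)
}

#' Test whether a flux vector is an elementary mode
#'
#' A vector is elementary iff it is non-zero, satisfies `S v = 0` exactly,
#' respects irreversibility signs, and the nullspace of `S` restricted to
#' its support columns is one-dimensional (exact rank test).
#'
#' @param v flux vector (named or in network reaction order).
#' @param net an `efm_network`.
#' @return logical scalar.
#' @export
is_elementary <- function(v, net) {
  stopifnot(inherits(net, "efm_network"))
  v <- align_flux(v, net)
  if (all(v == 0)) return(FALSE)
  vi <- to_coprime_integers(v)
  S <- integer_stoich(net)
  if (nrow(S) > 0L && any(as.vector(S %*% vi) != 0)) return(FALSE)
  rev <- reversibility(net)
  if (any(vi < 0 & !rev)) return(FALSE)
  nz <- which(vi != 0)
  Ssub <- S[, nz, drop = FALSE]
  int_rank(Ssub) == length(nz) - 1L
}

#' Brute-force elementary mode enumeration (independent oracle)
#'
#' Enumerates candidate supports directly: every reaction subset up to
#' `max_support` whose restricted stoichiometric matrix has a
#' one-dimensional exact kernel with a full-support, sign-feasible
#' generator is an elementary mode. Intended as an oracle for small
#' networks; refuses more than 15 reactions.
#'
#' @param net an `efm_network`.
#' @param max_support largest support size to consider; defaults to the
#'   number of reactions.
#' @return an `efm_set` in the same canonical form and order as
#'   [enumerate_efms()].
#' @export
brute_force_efms <- function(net, max_support = NULL) {
  stopifnot(inherits(net, "efm_network"))
  ids <- reaction_ids(net)
  n <- length(ids)
  if (n > 15L) {
    stop("brute_force_efms is an oracle for small networks (> 15 reactions refused)",
         call. = FALSE)
  }
  if (is.null(max_support)) max_support <- n
  if (n == 0L) return(new_efm_set(list(), net))
  S <- integer_stoich(net)
  rev <- reversibility(net)
  modes <- list()
  seen <- character(0)
  for (size in seq_len(min(max_support, n))) {
    subsets <- utils::combn(n, size)
    for (ci in seq_len(ncol(subsets))) {
      J <- subsets[, ci]
      Ssub <- S[, J, drop = FALSE]
      # a row with exactly one nonzero over J can never balance
      nz_per_row <- rowSums(Ssub != 0)
      if (any(nz_per_row == 1L)) next
      gen <- int_kernel_1d(Ssub)
      if (is.null(gen) || any(gen == 0)) next
      irr <- !rev[J]
      if (any(irr)) {
        sgn <- sign(gen[irr])
        if (length(unique(sgn)) > 1L) next
        if (sgn[1] < 0) gen <- -gen
      }
      v <- stats::setNames(numeric(n), ids)
      v[J] <- gen
      v <- canonicalize(v, net)
      key <- support_key(signed_support(v))
      if (key %in% seen) next
      seen <- c(seen, key)
      modes[[length(modes) + 1L]] <- new_flux_mode(v, net)
    }
  }
  new_efm_set(order_modes(modes), net)
}

# signed-support keys of an efm_set, sorted — used throughout the tests to
# compare mode sets independent of ordering
#' Canonical signed-support keys of an EFM set
#' @param efms an `efm_set`.
#' @return sorted character vector, one space-separated signed support per mode.
#' @export
support_keys <- function(efms) {
  stopifnot(inherits(efms, "efm_set"))
  sort(vapply(efms$modes, function(m) support_key(sort(m$support)),
              character(1)))
}
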