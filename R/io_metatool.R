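# Reader/writer for the metatool plain-text network dialect:
#   -ENZREV / -ENZIRREV : reversible / irreversible reaction ids
#   -METINT / -METEXT   : internal / external metabolite ids
#   -CAT                : equations "id : a A + b B = c C ."
# Blank lines and '#' comments are ignored; section structure is strict.

# Parse one side of an equation ("2 ATP + Pyr") into a named coefficient
# vector. Multipliers precede species; whitespace-separated.
parse_side <- function(txt, line_no) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(stats::setNames(numeric(0), character(0)))
  terms <- strsplit(txt, "\\s*\\+\\s*")[[1]]
  out <- numeric(0)
  for (tm in terms) {
    tm <- trimws(tm)
    if (!nzchar(tm)) {
      stop("line ", line_no, ": empty term in equation", call. = FALSE)
    }
    parts <- strsplit(tm, "\\s+")[[1]]
    if (length(parts) == 1L) {
      coef <- 1
      sp <- parts[1]
    } else if (length(parts) == 2L &&
               grepl("^[0-9]+([./][0-9]+)?$", parts[1])) {
      coef <- if (grepl("/", parts[1])) {
        nm <- as.numeric(strsplit(parts[1], "/")[[1]])
        nm[1] / nm[2]
      } else as.numeric(parts[1])
      sp <- parts[2]
    } else {
      stop("line ", line_no, ": cannot parse term '", tm, "'", call. = FALSE)
    }
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0) + coef
  }
  out
}

# "id : lhs = rhs" -> list(id, stoich)
parse_cat_line <- function(line, line_no) {
  m <- regmatches(line, regexec("^\\s*(\\S+)\\s*:\\s*(.*)$", line))[[1]]
  if (length(m) == 0L) {
    stop("line ", line_no, ": CAT entry lacks 'id :' prefix", call. = FALSE)
  }
  id <- m[2]
  body <- sub("\\s*\\.\\s*$", "", m[3])   # optional '.' terminator
  sides <- strsplit(body, "=", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("line ", line_no, ": equation must contain exactly one '='",
         call. = FALSE)
  }
  lhs <- parse_side(sides[1], line_no)
  rhs <- parse_side(sides[2], line_no)
  stoich <- numeric(0)
  for (sp in names(lhs)) stoich[sp] <- -lhs[[sp]]
  for (sp in names(rhs)) {
    stoich[sp] <- (if (sp %in% names(stoich)) stoich[[sp]] else 0) + rhs[[sp]]
  }
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0L) {
    stop("line ", line_no, ": reaction '", id,
         "' has empty net stoichiometry", call. = FALSE)
  }
  list(id = id, stoich = stoich)
}

#' Read a metatool network file
#'
#' @param source path to a `.dat` file, or the file content as a character
#'   vector of lines (a single string is split on newlines).
#' @param id network identifier for the result.
#' @return an `efm_network`. Reversibility comes from ENZREV/ENZIRREV
#'   membership, externality from METEXT; declaration order is preserved.
#' @export
read_metatool <- function(source, id = "metatool") {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (id == "metatool") id <- sub("\\.dat$", "", basename(source))
  } else {
    # collapse-then-split keeps empty lines, preserving line numbers
    lines <- strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  sections <- list(ENZREV = character(0), ENZIRREV = character(0),
                   METINT = character(0), METEXT = character(0),
                   CAT = list())
  seen <- character(0)
  current <- NULL
  for (i in seq_along(lines)) {
    raw <- lines[i]
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^-", line)) {
      sec <- toupper(sub("^-", "", line))
      if (!(sec %in% names(sections))) {
        stop("line ", i, ": unknown section header '", raw, "'", call. = FALSE)
      }
      if (sec %in% seen) {
        stop("line ", i, ": duplicate section -", sec, call. = FALSE)
      }
      seen <- c(seen, sec)
      current <- sec
      next
    }
    if (is.null(current)) {
      stop("line ", i, ": content before any section header", call. = FALSE)
    }
    if (current == "CAT") {
      sections$CAT[[length(sections$CAT) + 1L]] <- parse_cat_line(line, i)
    } else {
      sections[[current]] <- c(sections[[current]],
                               strsplit(line, "\\s+")[[1]])
    }
  }
  missing <- setdiff(names(sections), seen)
  if (length(missing) > 0L) {
    stop("missing section header(s): ",
         paste0("-", missing, collapse = ", "), call. = FALSE)
  }
  both_enz <- intersect(sections$ENZREV, sections$ENZIRREV)
  if (length(both_enz) > 0L) {
    stop("reaction(s) in both -ENZREV and -ENZIRREV: ",
         paste(both_enz, collapse = ", "), call. = FALSE)
  }
  both_met <- intersect(sections$METINT, sections$METEXT)
  if (length(both_met) > 0L) {
    stop("metabolite(s) in both -METINT and -METEXT: ",
         paste(both_met, collapse = ", "), call. = FALSE)
  }
  declared <- c(sections$ENZREV, sections$ENZIRREV)
  cat_ids <- vapply(sections$CAT, `[[`, character(1), "id")
  undeclared <- setdiff(cat_ids, declared)
  if (length(undeclared) > 0L) {
    stop("CAT reaction(s) absent from -ENZREV/-ENZIRREV: ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  no_cat <- setdiff(declared, cat_ids)
  if (length(no_cat) > 0L) {
    stop("declared reaction(s) without a CAT equation: ",
         paste(no_cat, collapse = ", "), call. = FALSE)
  }
  mets <- c(lapply(sections$METINT, metabolite),
            lapply(sections$METEXT, function(m) metabolite(m, external = TRUE)))
  rxns <- lapply(sections$CAT, function(ct) {
    reaction(ct$id, ct$stoich, reversible = ct$id %in% sections$ENZREV)
  })
  build_network(mets, rxns, id = id)
}

fmt_coef <- function(x) {
  if (x == round(x)) return(format(round(x)))
  r <- as_rational(x)
  paste0(format(r[1]), "/", format(r[2]))
}

#' Write a network in metatool format
#'
#' Canonical section order (`-ENZREV`, `-ENZIRREV`, `-METINT`, `-METEXT`,
#' `-CAT`); reactions and metabolites in declaration order; integer
#' coefficients emitted without multipliers of 1. The output re-parses to an
#' identical network (catalyst annotations are not part of the dialect and
#' are dropped).
#'
#' @param net an `efm_network`.
#' @param path optional file path; when `NULL` the text is returned.
#' @return character vector of lines (invisibly when writing to a file).
#' @export
write_metatool <- function(net, path = NULL) {
  stopifnot(inherits(net, "efm_network"))
  rev <- reversibility(net)
  side_txt <- function(coefs, ids) {
    paste(vapply(seq_along(ids), function(i) {
      if (coefs[i] == 1) ids[i] else paste(fmt_coef(coefs[i]), ids[i])
    }, character(1)), collapse = " + ")
  }
  cat_lines <- vapply(net$reactions, function(r) {
    lhs <- r$stoich[r$stoich < 0]
    rhs <- r$stoich[r$stoich > 0]
    sprintf("%s : %s = %s .", r$id,
            side_txt(-unname(lhs), names(lhs)),
            side_txt(unname(rhs), names(rhs)))
  }, character(1))
  lines <- c(
    "-ENZREV",
    paste(reaction_ids(net)[rev], collapse = " "),
    "",
    "-ENZIRREV",
    paste(reaction_ids(net)[!rev], collapse = " "),
    "",
    "-METINT",
    paste(internal_ids(net), collapse = " "),
    "",
    "-METEXT",
    paste(external_ids(net), collapse = " "),
    "",
    "-CAT",
    unname(cat_lines)
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
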