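#' Read a model from the native structured-text format
#'
#' The native format is a UTF-8 text document with `#` comments and two
#' sections:
#'
#' ```
#' model <name>                      # optional header
#' metabolites
#' <id>  x0=<num> [xmin=<num>] [xmax=<num>] [name="..."]
#' reactions
#' <id>: <equation>  [vmin=<bound>] [vmax=<bound>]
#' ```
#'
#' An equation looks like `A + 0.6 B -> C`; a bound is either a number or
#' a piecewise-constant time profile `piecewise(t1:v1,t2:v2,...)` whose
#' value switches at each breakpoint (needed for light/dark capacities,
#' which no standard exchange format covers compactly).  Parse errors
#' report the offending line number.
#'
#' @param path File path.
#' @return A [stoich_model()].
#' @seealso [write_model()] for the inverse, [read_sbml()] for SBML.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    dynfba_abort(sprintf("model file '%s' does not exist", path),
                 class = "dynfba_parse_error")
  }
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  section <- ""
  mets <- list(); rxns <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "") next
    low <- tolower(s)
    if (grepl("^model\\b", low)) next
    if (low == "metabolites") { section <- "met"; next }
    if (low == "reactions") { section <- "rxn"; next }
    if (section == "met") {
      mets[[length(mets) + 1]] <- parse_met_line(s, ln)
    } else if (section == "rxn") {
      rxns[[length(rxns) + 1]] <- parse_rxn_line(s, ln)
    } else {
      dynfba_abort(sprintf("line %d: content before any section header", ln),
                   class = "dynfba_parse_error")
    }
  }
  if (length(rxns) == 0) {
    dynfba_abort("model has no reactions", class = "dynfba_parse_error")
  }
  metabolites <- dplyr::bind_rows(mets)
  reactions <- tibble::tibble(
    id = vapply(rxns, `[[`, "", "id"),
    equation = vapply(rxns, `[[`, "", "equation"),
    v_min = lapply(rxns, `[[`, "v_min"),
    v_max = lapply(rxns, `[[`, "v_max")
  )
  # collapse all-scalar bound columns
  for (col in c("v_min", "v_max")) {
    if (all(vapply(reactions[[col]], function(b)
      is.numeric(b) && length(b) == 1, logical(1)))) {
      reactions[[col]] <- unlist(reactions[[col]])
    }
  }
  stoich_model(metabolites, reactions)
}

parse_kv <- function(tokens, line) {
  out <- list()
  for (tk in tokens) {
    kv <- strsplit(tk, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      dynfba_abort(sprintf("line %d: expected key=value, got '%s'", line, tk),
                   class = "dynfba_parse_error")
    }
    out[[tolower(kv[1])]] <- kv[2]
  }
  out
}

parse_bound_token <- function(s, line) {
  s <- trimws(s)
  if (grepl("^piecewise\\(", s)) {
    body <- sub("^piecewise\\((.*)\\)$", "\\1", s)
    parts <- strsplit(body, ",", fixed = TRUE)[[1]]
    tv <- vapply(parts, function(p) {
      x <- as.numeric(strsplit(p, ":", fixed = TRUE)[[1]])
      if (length(x) != 2 || any(is.na(x))) {
        dynfba_abort(sprintf("line %d: bad piecewise segment '%s'", line, p),
                     class = "dynfba_parse_error")
      }
      x
    }, numeric(2))
    return(piecewise_bound(unname(tv[1, ]), unname(tv[2, ])))
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) {
    dynfba_abort(sprintf("line %d: cannot parse bound '%s'", line, s),
                 class = "dynfba_parse_error")
  }
  v
}

parse_met_line <- function(s, line) {
  # quoted name first, so it can contain blanks
  name <- NA_character_
  nm <- regmatches(s, regexpr('name="[^"]*"', s))
  if (length(nm) == 1 && nzchar(nm)) {
    name <- sub('name="([^"]*)"', "\\1", nm)
    s <- trimws(sub('name="[^"]*"', "", s))
  }
  tokens <- strsplit(s, "[[:space:]]+")[[1]]
  id <- tokens[1]
  kv <- parse_kv(tokens[-1], line)
  if (is.null(kv$x0)) {
    dynfba_abort(sprintf("line %d: metabolite '%s' needs x0=", line, id),
                 class = "dynfba_parse_error")
  }
  tibble::tibble(
    id = id, name = if (is.na(name)) id else name,
    x0 = as.numeric(kv$x0),
    x_min = if (is.null(kv$xmin)) 0 else as.numeric(kv$xmin),
    x_max = if (is.null(kv$xmax)) 20 else as.numeric(kv$xmax)
  )
}

parse_rxn_line <- function(s, line) {
  colon <- regexpr(":", s, fixed = TRUE)
  if (colon < 0) {
    dynfba_abort(sprintf("line %d: reaction line needs '<id>: <equation>'",
                         line), class = "dynfba_parse_error")
  }
  id <- trimws(substr(s, 1, colon - 1))
  rest <- trimws(substr(s, colon + 1, nchar(s)))
  # bound tokens are the trailing key=value pairs
  kv_pat <- "(vmin|vmax)=((piecewise\\([^)]*\\))|([^[:space:]]+))"
  kvs <- list()
  m <- gregexpr(kv_pat, rest)[[1]]
  if (m[1] > 0) {
    for (tok in regmatches(rest, gregexpr(kv_pat, rest))[[1]]) {
      kv <- sub("=.*", "", tok)
      kvs[[kv]] <- parse_bound_token(sub("^[a-z]+=", "", tok), line)
    }
    rest <- trimws(gsub(kv_pat, "", rest))
  }
  if (is.null(kvs$vmax)) {
    dynfba_abort(sprintf("line %d: reaction '%s' needs vmax=", line, id),
                 class = "dynfba_parse_error")
  }
  list(id = id, equation = rest,
       v_min = kvs$vmin %||% 0, v_max = kvs$vmax)
}

#' Write a model in the native structured-text format
#'
#' Round-trips exactly with [read_model()]: numbers are written with 12
#' significant digits so the reconstructed stoichiometric matrix is
#' bit-identical.
#'
#' @param model A [stoich_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "stoich_model"))
  met <- model$metabolites
  lines <- c("# dynfba native model format", "metabolites")
  for (i in seq_len(model$N)) {
    lines <- c(lines, sprintf(
      '%s x0=%s xmin=%s xmax=%s name="%s"',
      met$id[i], format(met$x0[i], digits = 12),
      format(met$x_min[i], digits = 12), format(met$x_max[i], digits = 12),
      met$name[i]))
  }
  lines <- c(lines, "reactions")
  rxn <- model$reactions
  for (k in seq_len(model$F)) {
    lines <- c(lines, sprintf(
      "%s: %s vmin=%s vmax=%s",
      rxn$id[k], rxn$equation[k],
      format_bound(reaction_bound(rxn$v_min, k)),
      format_bound(reaction_bound(rxn$v_max, k))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Import stoichiometry from an SBML file
#'
#' A deliberately minimal SBML (Level 2/3) reader: species become
#' metabolites (initialConcentration when present, else 1), reactions
#' become reactions with the stoichiometry of their reactant/product
#' lists.  Flux bounds are taken from `fbc` parameters when present,
#' otherwise `v_min = 0`, `v_max = default_vmax`.  Time-varying bounds,
#' compartments, gene rules and kinetic laws are not imported; use the
#' native format when those matter.
#'
#' @param path SBML file path.
#' @param default_vmax Flux capacity used when the file carries none.
#' @param default_xmax Concentration ceiling assigned to all species.
#' @return A [stoich_model()].
#' @export
read_sbml <- function(path, default_vmax = 1000, default_xmax = 20) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp) == 0) {
    dynfba_abort("SBML file declares no species",
                 class = "dynfba_parse_error")
  }
  conc <- as.numeric(xml2::xml_attr(sp, "initialConcentration"))
  conc[is.na(conc)] <- 1
  metabolites <- tibble::tibble(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"),
                           xml2::xml_attr(sp, "id")),
    x0 = conc, x_min = 0, x_max = default_xmax
  )
  # fbc bound parameters, if any
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx) == 0) {
    dynfba_abort("model has no reactions", class = "dynfba_parse_error")
  }
  rxns <- purrr::map(rx, function(r) {
    take <- function(xp, sign) {
      refs <- xml2::xml_find_all(r, xp)
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, xml2::xml_attr(refs, "species"))
    }
    st0 <- c(take(".//listOfReactants/speciesReference", -1),
             take(".//listOfProducts/speciesReference", +1))
    st <- tapply(st0, names(st0), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    st <- st[st != 0]
    lb <- xml2::xml_attr(r, "lowerFluxBound")
    ub <- xml2::xml_attr(r, "upperFluxBound")
    list(
      id = xml2::xml_attr(r, "id"),
      stoich = st,
      v_min = if (!is.na(lb) && lb %in% names(parval))
        max(0, parval[[lb]]) else 0,
      v_max = if (!is.na(ub) && ub %in% names(parval))
        parval[[ub]] else default_vmax
    )
  })
  reactions <- tibble::tibble(
    id = vapply(rxns, `[[`, "", "id"),
    equation = vapply(rxns, function(r) stoich_to_equation(r$stoich), ""),
    stoich = lapply(rxns, `[[`, "stoich"),
    v_min = vapply(rxns, `[[`, numeric(1), "v_min"),
    v_max = vapply(rxns, `[[`, numeric(1), "v_max")
  )
  stoich_model(metabolites, reactions)
}

stoich_to_equation <- function(st) {
  fmt <- function(v) paste(
    ifelse(abs(v) == 1, names(v),
           paste(format(abs(v), digits = 12), names(v))), collapse = " + ")
  lhs <- st[st < 0]; rhs <- st[st > 0]
  paste(if (length(lhs)) fmt(lhs) else "",
        "->", if (length(rhs)) fmt(rhs) else "")
}
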