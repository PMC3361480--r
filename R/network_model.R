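#' Piecewise-constant time profile for a flux bound
#'
#' Reaction bounds may vary over the horizon (e.g. a photosynthetic input
#' that is only active during the light phase).  A piecewise bound holds
#' breakpoint times and the value that applies from each breakpoint
#' onward; times before the first breakpoint take the first value.
#'
#' @param times Strictly increasing breakpoint times.
#' @param values Values applying from each breakpoint onward.
#' @return An object of class `piecewise_bound`, callable via
#'   [bound_at()].
#' @examples
#' light <- piecewise_bound(c(0, 16), c(1.0, 0))  # light until hour 16
#' bound_at(light, c(8, 20))                      # 1 0
#' @export
piecewise_bound <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 1,
            !is.unsorted(times, strictly = TRUE), all(is.finite(values)))
  structure(list(times = times, values = values), class = "piecewise_bound")
}

#' Evaluate a (possibly time-varying) bound at given times
#'
#' @param b A numeric scalar, a `piecewise_bound`, or a function of time.
#' @param t Times at which to evaluate.
#' @return Numeric vector of length `length(t)`.
#' @export
bound_at <- function(b, t) {
  if (is.numeric(b) && length(b) == 1) return(rep(b, length(t)))
  if (inherits(b, "piecewise_bound")) {
    idx <- pmax(findInterval(t, b$times), 1)
    return(b$values[idx])
  }
  if (is.function(b)) return(vapply(t, b, numeric(1)))
  dynfba_abort("bound must be a scalar, a piecewise_bound or a function",
               class = "dynfba_model_error")
}

format_bound <- function(b) {
  if (is.numeric(b) && length(b) == 1) return(format(b, digits = 12))
  if (inherits(b, "piecewise_bound")) {
    fmt1 <- function(v) vapply(v, format, "", digits = 12)
    return(paste0("piecewise(",
                  paste0(fmt1(b$times), ":", fmt1(b$values),
                         collapse = ","),
                  ")"))
  }
  dynfba_abort("only scalar or piecewise bounds can be serialized",
               class = "dynfba_model_error")
}

# "A + 0.6 B -> C" -> named stoichiometry vector (consumed negative)
parse_equation <- function(eq, line = NA) {
  where <- if (is.na(line)) "" else sprintf(" (line %d)", line)
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    dynfba_abort(sprintf("reaction equation '%s' must contain one '->'%s",
                         eq, where), class = "dynfba_parse_error")
  }
  side_terms <- function(s, sign) {
    s <- trimws(s)
    if (s == "") return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      toks <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(toks) == 1) {
        coef <- 1; id <- toks
      } else if (length(toks) == 2 &&
                 !is.na(suppressWarnings(as.numeric(toks[1])))) {
        coef <- as.numeric(toks[1]); id <- toks[2]
      } else {
        dynfba_abort(sprintf("cannot parse term '%s' in '%s'%s",
                             tm, eq, where), class = "dynfba_parse_error")
      }
      cur <- if (id %in% names(out)) out[[id]] else 0
      out[id] <- cur + sign * coef
    }
    out
  }
  lhs <- side_terms(sides[1], -1)
  rhs <- side_terms(sides[2], +1)
  st <- lhs
  for (id in names(rhs)) st[id] <- (if (id %in% names(st)) st[id] else 0) + rhs[id]
  st <- st[st != 0]
  if (length(st) == 0) {
    dynfba_abort(sprintf("reaction '%s' has empty net stoichiometry%s",
                         eq, where), class = "dynfba_parse_error")
  }
  st
}

#' Stoichiometric metabolic model
#'
#' Assembles a constraint-based model from a metabolite table and a
#' reaction table and validates all structural invariants: unique ids,
#' referential integrity of the reaction equations, ordered bounds,
#' non-negative and finite concentration envelopes (finite `x_max` is
#' required by the on/off threshold constraints of the R-DFBA family).
#'
#' @param metabolites Data frame with columns `id`, `x0` and optionally
#'   `name`, `x_min` (default 0) and `x_max` (default 20 mmol l-1).
#' @param reactions Data frame with columns `id`, `equation` (e.g.
#'   `"RuBP -> 2 PGA"`) and optionally `v_min` (default 0) and `v_max`.
#'   `v_max`/`v_min` entries may be scalars, [piecewise_bound()] objects
#'   or functions of time (use a list column for non-scalars).
#' @return An object of class `stoich_model` with fields `metabolites`,
#'   `reactions` (with a parsed `stoich` list column), `N` and `F`.
#' @seealso [calvin_model()], [carbohydrate_model()], [stoich_matrix()]
#' @export
stoich_model <- function(metabolites, reactions) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (nrow(reactions) == 0) {
    dynfba_abort("model has no reactions", class = "dynfba_model_error")
  }
  if (nrow(metabolites) == 0) {
    dynfba_abort("model has no metabolites", class = "dynfba_model_error")
  }
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"x_min" %in% names(metabolites)) metabolites$x_min <- 0
  if (!"x_max" %in% names(metabolites)) metabolites$x_max <- 20
  if (!"v_min" %in% names(reactions)) reactions$v_min <- 0
  if (!"v_max" %in% names(reactions)) {
    dynfba_abort("reactions need a v_max column",
                 class = "dynfba_model_error")
  }
  if (anyDuplicated(metabolites$id)) {
    dynfba_abort("metabolite ids must be unique",
                 class = "dynfba_model_error")
  }
  if (anyDuplicated(reactions$id)) {
    dynfba_abort("reaction ids must be unique", class = "dynfba_model_error")
  }
  with(metabolites, {
    if (any(x_min < 0)) dynfba_abort("x_min must be >= 0",
                                     class = "dynfba_model_error")
    if (any(!is.finite(x_max))) {
      dynfba_abort("x_max must be finite (required by R-DFBA thresholds)",
                   class = "dynfba_model_error")
    }
    if (any(x0 < x_min - 1e-12) || any(x0 > x_max + 1e-12)) {
      dynfba_abort("initial concentrations must satisfy x_min <= x0 <= x_max",
                   class = "dynfba_model_error")
    }
  })
  if (!"stoich" %in% names(reactions)) {
    reactions$stoich <- lapply(reactions$equation, parse_equation)
  }
  for (k in seq_len(nrow(reactions))) {
    st <- reactions$stoich[[k]]
    unknown <- setdiff(names(st), metabolites$id)
    if (length(unknown)) {
      dynfba_abort(
        sprintf("reaction '%s' references undeclared metabolite '%s'",
                reactions$id[k], unknown[1]),
        class = "dynfba_model_error")
    }
    if (!all(is.finite(st))) {
      dynfba_abort(sprintf("reaction '%s' has non-finite coefficients",
                           reactions$id[k]), class = "dynfba_model_error")
    }
  }
  # v_min <= v_max wherever both are constants; time-varying bounds are
  # checked at solve time on the node grid
  vlo <- reactions$v_min; vhi <- reactions$v_max
  for (k in seq_len(nrow(reactions))) {
    lo <- if (is.list(vlo)) vlo[[k]] else vlo[k]
    hi <- if (is.list(vhi)) vhi[[k]] else vhi[k]
    if (is.numeric(lo) && is.numeric(hi) && length(lo) == 1 &&
        length(hi) == 1 && lo > hi) {
      dynfba_abort(sprintf("reaction '%s': v_min > v_max",
                           reactions$id[k]), class = "dynfba_model_error")
    }
  }
  structure(
    list(metabolites = metabolites, reactions = reactions,
         N = nrow(metabolites), F = nrow(reactions)),
    class = "stoich_model"
  )
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("<stoich_model> %d metabolites x %d reactions\n", x$N, x$F))
  cat(" metabolites:", paste(x$metabolites$id, collapse = ", "), "\n")
  cat(" reactions:  ", paste(x$reactions$id, collapse = ", "), "\n")
  invisible(x)
}

#' Dense stoichiometric matrix of a model
#'
#' Entry (i, l) is the signed coefficient of metabolite i in reaction l;
#' zero when the metabolite does not participate.
#'
#' @param model A [stoich_model()].
#' @return N x F numeric matrix with metabolite/reaction dimnames.
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "stoich_model"))
  S <- matrix(0, model$N, model$F,
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (k in seq_len(model$F)) {
    st <- model$reactions$stoich[[k]]
    S[names(st), k] <- st
  }
  S
}

# reaction bound (v_min/v_max) for reaction k as stored, list column aware
reaction_bound <- function(col, k) if (is.list(col)) col[[k]] else col[k]

# F x M matrices of flux bounds evaluated at node times
flux_bounds_at <- function(model, times) {
  Fn <- model$F
  lo <- matrix(0, Fn, length(times))
  hi <- matrix(0, Fn, length(times))
  for (k in seq_len(Fn)) {
    lo[k, ] <- bound_at(reaction_bound(model$reactions$v_min, k), times)
    hi[k, ] <- bound_at(reaction_bound(model$reactions$v_max, k), times)
  }
  if (any(lo > hi + 1e-12)) {
    dynfba_abort("v_min > v_max at some node time",
                 class = "dynfba_model_error")
  }
  rownames(lo) <- rownames(hi) <- model$reactions$id
  list(lower = lo, upper = hi)
}

# N x M matrices of concentration bounds (constants replicated over nodes)
conc_bounds_at <- function(model, M) {
  lo <- matrix(model$metabolites$x_min, model$N, M)
  hi <- matrix(model$metabolites$x_max, model$N, M)
  rownames(lo) <- rownames(hi) <- model$metabolites$id
  list(lower = lo, upper = hi)
}

#' Simplified Calvin-Benson cycle model
#'
#' Six metabolites (Ru5P, RuBP, PGA, DPGA, GAP and a lumped sink for
#' sucrose/starch precursors) connected by seven irreversible reactions:
#' carboxylation of RuBP to two PGA, reduction of PGA via DPGA to GAP,
#' regeneration of Ru5P and RuBP, and two sink exports.  Cofactors (ATP,
#' NADPH, CO2, P) are taken as abundant and are not balanced.  Flux
#' capacities and initial concentrations follow the published simplified
#' scheme (v_max = 3.78, 11.75, 5.04, 3.05, 8, 3, 0.1 mmol l-1 s-1;
#' RuBP 2.0, PGA 2.4, all others 1.0 mmol l-1).
#'
#' @return A [stoich_model()] with N = 6, F = 7.
#' @examples
#' m <- calvin_model()
#' stoich_matrix(m)["PGA", "v1"]   # +2
#' @export
calvin_model <- function() {
  stoich_model(
    metabolites = tibble::tibble(
      id = c("Ru5P", "RuBP", "PGA", "DPGA", "GAP", "Sink"),
      name = c("ribulose-5-phosphate", "ribulose-1,5-bisphosphate",
               "3-phosphoglycerate", "1,3-diphosphoglycerate",
               "glyceraldehyde-3-phosphate", "sink"),
      x0 = c(1.0, 2.0, 2.4, 1.0, 1.0, 1.0),
      x_min = 0, x_max = 20
    ),
    reactions = tibble::tibble(
      id = paste0("v", 1:7),
      equation = c("RuBP -> 2 PGA", "PGA -> DPGA", "DPGA -> GAP",
                   "GAP -> 0.6 Ru5P", "Ru5P -> RuBP",
                   "PGA -> Sink", "GAP -> Sink"),
      v_min = 0,
      v_max = c(3.78, 11.75, 5.04, 3.05, 8, 3, 0.1)
    )
  )
}

#' Diurnal carbohydrate metabolism model (reconstructed topology)
#'
#' A lumped model of leaf carbohydrate metabolism with six pools (sugar
#' phosphates, sucrose, glucose, fructose, starch and a sink export) and
#' seven reactions over a 24 h day starting at 06:00 with a 16 h light /
#' 8 h dark phase.  The photosynthetic input is only available during the
#' light phase (piecewise v_max).  The `inv4` genotype knocks out the
#' vacuolar invertase (its v_max is 0 at all times).
#'
#' The exact published 7-reaction topology is not publicly available; the
#' wiring used here is a documented minimal reconstruction consistent
#' with the listed metabolite pools, the reaction count and the invertase
#' knockout: photosynthetic input into sugar phosphates, sucrose and
#' starch synthesis from sugar phosphates, starch degradation, vacuolar
#' invertase (sucrose to glucose + fructose), hexose phosphorylation
#' (glucose + fructose to 2 sugar phosphates) and sink export of sucrose.
#' Rate constants are order-of-magnitude choices, not fitted values.
#'
#' @param genotype `"wild"` or `"inv4"`.
#' @return A [stoich_model()] with N = 6, F = 7 and time in hours.
#' @export
carbohydrate_model <- function(genotype = c("wild", "inv4")) {
  genotype <- match.arg(genotype)
  inv_vmax <- if (genotype == "inv4") 0 else 1.2
  stoich_model(
    metabolites = tibble::tibble(
      id = c("SugarP", "Sucrose", "Glucose", "Fructose", "Starch", "Sink"),
      name = c("sugar phosphates", "sucrose", "glucose", "fructose",
               "starch", "sink export"),
      x0 = c(0.5, 2.0, 1.0, 1.0, 5.0, 1.0),
      x_min = 0, x_max = 20
    ),
    reactions = tibble::tibble(
      id = c("photo", "suc_syn", "sta_syn", "sta_deg",
             "invertase", "hexokinase", "export"),
      equation = c("-> SugarP", "2 SugarP -> Sucrose", "SugarP -> Starch",
                   "Starch -> SugarP", "Sucrose -> Glucose + Fructose",
                   "Glucose + Fructose -> 2 SugarP", "Sucrose -> Sink"),
      v_min = 0,
      v_max = list(piecewise_bound(c(0, 16), c(1.0, 0)),
                   1.5, 1.0, 0.6, inv_vmax, 1.0, 0.8)
    )
  )
}
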