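#' Residual sum of squares between two node sequences
#'
#' \eqn{RSS = \sum_{j=1}^{M} (y_j - f_j)^2} over the collocation nodes,
#' with the reference values \eqn{y} and the predicted values \eqn{f}.
#'
#' @param reference,predicted Equal-length numeric vectors (length >= 1).
#' @return A non-negative number.
#' @export
rss <- function(reference, predicted) {
  if (length(reference) != length(predicted) || length(reference) < 1) {
    dynfba_abort("rss needs two equal-length sequences of length >= 1",
                 class = "dynfba_eval_error")
  }
  sum((reference - predicted)^2)
}

#' Time-resolved Kendall rank correlation between two trajectories
#'
#' At every collocation node the metabolite concentrations and the
#' reaction fluxes are concatenated into one length-(N+F) state vector
#' per trajectory and the Kendall rank correlation between the two
#' vectors is computed.  The tie-adjusted tau-b variant is used because
#' constant-concentration predictions (common among the relaxed NLP
#' variants) produce ties; a node where one state vector is entirely
#' tied has no defined rank correlation and yields `NA`.
#'
#' @param reference,predicted `dfba_trajectory` objects on the same
#'   model and node grid (the reference typically from
#'   [sample_states()]).
#' @return Tibble with columns `time` and `tau` (each in [-1, 1] or NA).
#' @export
kendall_tau_timecourse <- function(reference, predicted) {
  check_same_shape(reference, predicted)
  tau <- vapply(seq_along(reference$times), function(j) {
    a <- c(reference$conc[, j], reference$flux[, j])
    b <- c(predicted$conc[, j], predicted$flux[, j])
    suppressWarnings(stats::cor(a, b, method = "kendall"))
  }, numeric(1))
  tibble::tibble(time = reference$times, tau = tau)
}

check_same_shape <- function(a, b) {
  ok <- inherits(a, "dfba_trajectory") && inherits(b, "dfba_trajectory") &&
    length(a$times) == length(b$times) &&
    max(abs(a$times - b$times)) < 1e-9 &&
    all(dim(a$conc) == dim(b$conc)) && all(dim(a$flux) == dim(b$flux))
  if (!ok) {
    dynfba_abort("trajectories must share the model and node grid",
                 class = "dynfba_eval_error")
  }
}

#' Compare constraint-based trajectories against a reference
#'
#' Computes per-metabolite and per-reaction RSS at the collocation nodes
#' and the time-resolved Kendall tau-b series for every method, and
#' ranks the methods separately by total concentration RSS and total
#' flux RSS.
#'
#' @param trajectories List of `dfba_trajectory` objects (one per
#'   method; names default to the method tags).
#' @param reference A `dfba_trajectory` sampled at the same nodes, e.g.
#'   from [sample_states()], or a `reference_trajectory` (then sampled
#'   automatically).
#' @return An object of class `dfba_comparison` with tibbles `rss`
#'   (method, kind, id, rss), `tau` (method, time, tau) and `summary`
#'   (method, rss_conc, rss_flux, rank_conc, rank_flux), plus the
#'   reference provenance.
#' @export
compare_methods <- function(trajectories, reference) {
  if (inherits(trajectories, "dfba_trajectory")) {
    trajectories <- list(trajectories)
  }
  if (inherits(reference, "reference_trajectory")) {
    grid <- trajectories[[1]]$grid %||% trajectories[[1]]$times
    reference <- sample_states(reference, grid)
  }
  nms <- names(trajectories) %||%
    vapply(trajectories, `[[`, "", "method")
  if (is.null(names(trajectories))) names(trajectories) <- nms
  rss_tbl <- purrr::imap_dfr(trajectories, function(tr, nm) {
    check_same_shape(reference, tr)
    dplyr::bind_rows(
      tibble::tibble(method = nm, kind = "metabolite",
                     id = rownames(reference$conc),
                     rss = vapply(seq_len(nrow(reference$conc)),
                                  function(i) rss(reference$conc[i, ],
                                                  tr$conc[i, ]),
                                  numeric(1))),
      tibble::tibble(method = nm, kind = "reaction",
                     id = rownames(reference$flux),
                     rss = vapply(seq_len(nrow(reference$flux)),
                                  function(l) rss(reference$flux[l, ],
                                                  tr$flux[l, ]),
                                  numeric(1))))
  })
  tau_tbl <- purrr::imap_dfr(trajectories, function(tr, nm) {
    dplyr::mutate(kendall_tau_timecourse(reference, tr),
                  method = nm, .before = 1)
  })
  summary_tbl <- rss_tbl |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      rss_conc = sum(.data$rss[.data$kind == "metabolite"]),
      rss_flux = sum(.data$rss[.data$kind == "reaction"]),
      .groups = "drop") |>
    dplyr::mutate(rank_conc = rank(.data$rss_conc, ties.method = "min"),
                  rank_flux = rank(.data$rss_flux, ties.method = "min")) |>
    dplyr::arrange(.data$rank_conc)
  structure(list(rss = rss_tbl, tau = tau_tbl, summary = summary_tbl,
                 reference_provenance = reference$provenance %||%
                   "reference"),
            class = "dfba_comparison")
}

#' @export
print.dfba_comparison <- function(x, ...) {
  cat(sprintf("<dfba_comparison> %d method(s) vs %s\n",
              nrow(x$summary), x$reference_provenance))
  print(x$summary)
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `rss.csv` (long format: method, kind, id, rss), `tau.csv`
#' (method, time, tau) and `summary.json`.
#'
#' @param comparison A [compare_methods()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(comparison, dir) {
  stopifnot(inherits(comparison, "dfba_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(comparison$rss, file.path(dir, "rss.csv"))
  readr::write_csv(comparison$tau, file.path(dir, "tau.csv"))
  jsonlite::write_json(
    list(reference = comparison$reference_provenance,
         summary = comparison$summary),
    file.path(dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
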