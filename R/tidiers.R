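#' Tidy a node trajectory into a long tibble
#'
#' @param x A `dfba_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `kind` (`conc`/`flux`), `id`,
#'   `value`, one row per node and state.
#' @exportS3Method generics::tidy
tidy.dfba_trajectory <- function(x, ...) {
  if (is.null(x$conc)) {
    return(tibble::tibble(time = numeric(0), kind = character(0),
                          id = character(0), value = numeric(0)))
  }
  dplyr::bind_rows(mat_to_long(x$conc, x$times, "conc"),
                   mat_to_long(x$flux, x$times, "flux")) |>
    dplyr::arrange(.data$time, .data$kind, .data$id)
}

#' One-row summary of a solved trajectory
#'
#' @param x A `dfba_trajectory`.
#' @param ... Unused.
#' @return Tibble: method, status, objective, residuals, node count.
#' @exportS3Method generics::glance
glance.dfba_trajectory <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    status = x$status,
    objective = x$objective,
    dynamics_residual = x$residuals$dynamics %||% NA_real_,
    continuity_residual = x$residuals$continuity %||% NA_real_,
    bound_violation = x$residuals$bounds %||% NA_real_,
    n_nodes = length(x$times))
}

#' @exportS3Method ggplot2::autoplot
#' @rdname tidy.dfba_trajectory
autoplot.dfba_trajectory <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(title = sprintf("method: %s", object$method),
                  x = "time", y = "value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy / summarize a method comparison
#'
#' @param x A `dfba_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the long per-element RSS table; `glance()`: the
#'   ranked per-method summary.
#' @exportS3Method generics::tidy
tidy.dfba_comparison <- function(x, ...) x$rss

#' @rdname tidy.dfba_comparison
#' @exportS3Method generics::glance
glance.dfba_comparison <- function(x, ...) x$summary

#' @rdname tidy.dfba_comparison
#' @exportS3Method ggplot2::autoplot
autoplot.dfba_comparison <- function(object, ...) {
  ggplot2::ggplot(object$tau, ggplot2::aes(x = .data$time, y = .data$tau,
                                      colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "time", y = "Kendall tau-b",
                  title = sprintf("state-vector rank agreement vs %s",
                                  object$reference_provenance)) +
    ggplot2::theme_minimal()
}
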