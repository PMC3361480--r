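# Shared Calvin-Benson study context, solved lazily and cached so the
# acceptance tests do not repeat expensive solves.

.calvin_cache <- new.env(parent = emptyenv())

calvin_context <- function() {
  if (!is.null(.calvin_cache$ctx)) return(.calvin_cache$ctx)
  model <- calvin_model()
  grid <- collocation_grid(0, 10, elements = 5, order = 5)
  ref <- simulate_kinetic(kinetic_model(model, K = 1), 0, 10)
  eb <- envelope_bounds(model, grid, ref, "GAP", 0.1)
  .calvin_cache$ctx <- list(model = model, grid = grid, ref = ref,
                            x_lower = eb$x_lower, x_upper = eb$x_upper)
  .calvin_cache$ctx
}

calvin_solution <- function(method, seed = 1) {
  key <- paste0(method, "_", seed)
  if (!is.null(.calvin_cache[[key]])) return(.calvin_cache[[key]])
  ctx <- calvin_context()
  prog <- build_method(method, ctx$model, ctx$grid,
                       x_lower = ctx$x_lower, x_upper = ctx$x_upper)
  .calvin_cache[[key]] <- solve_dfba(prog, seed = seed)
  .calvin_cache[[key]]
}
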