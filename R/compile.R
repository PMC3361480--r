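# Compilation of a dfba_program into an opt_problem.
#
# The program is stated over node concentrations x_{i,j}, element start
# values, node fluxes v_{l,j} and indicators.  The backend works in the
# reduced space (v, indicators): the collocated dynamics, continuity and
# initial condition are eliminated exactly through the integration
# operator, x = x0 + G (S v), so every returned trajectory satisfies
# them to machine precision and the concentration box becomes a set of
# linear inequalities in v.  Variable layout in u:
#   v:  F blocks of M (reaction-major),
#   y:  N blocks of M (R-DFBA conc indicators, j = 1..M),
#   z:  F blocks of M-1 (R-DFBA flux indicators, j = 2..M).

program_workspace <- function(program) {
  m <- program$model; g <- program$grid
  S <- stoich_matrix(m)
  ops <- integration_operator(g)
  M <- g$M; N <- m$N; Fn <- m$F
  # P: (N*M) x (F*M), x_flat = x0rep + P u_v  (x_flat metabolite-major)
  P <- matrix(0, N * M, Fn * M)
  for (i in seq_len(N)) for (l in seq_len(Fn)) {
    if (S[i, l] != 0) {
      P[((i - 1) * M + 1):(i * M), ((l - 1) * M + 1):(l * M)] <-
        S[i, l] * ops$G
    }
  }
  # index of the previous node in x_flat; 0 means the initial condition
  prev <- as.vector(vapply(seq_len(N), function(i)
    c(0L, ((i - 1) * M + 1):((i - 1) * M + M - 1)), integer(M)))
  list(S = S, ops = ops, P = P, M = M, N = N, Fn = Fn,
       x0rep = rep(m$metabolites$x0, each = M), prev = prev,
       xlo = as.vector(t(program$x_lower)),
       xhi = as.vector(t(program$x_upper)),
       vlo = as.vector(t(program$v_lower)),
       vhi = as.vector(t(program$v_upper)))
}

# rows of the concentration box as linear inequalities in u; rows that
# interval arithmetic over the flux box proves vacuous are dropped
conc_box_rows <- function(ws, n_u) {
  nv <- ws$Fn * ws$M
  pad <- function(A) cbind(A, matrix(0, nrow(A), n_u - nv))
  Ppos <- pmax(ws$P, 0); Pneg <- pmin(ws$P, 0)
  x_hi_reach <- ws$x0rep + as.vector(Ppos %*% ws$vhi + Pneg %*% ws$vlo)
  x_lo_reach <- ws$x0rep + as.vector(Ppos %*% ws$vlo + Pneg %*% ws$vhi)
  up_active <- is.finite(ws$xhi) & x_hi_reach > ws$xhi - 1e-12
  lo_active <- is.finite(ws$xlo) & x_lo_reach < ws$xlo + 1e-12
  A <- rbind(pad(ws$P[up_active, , drop = FALSE]),
             pad(-ws$P[lo_active, , drop = FALSE]))
  b <- c(ws$xhi[up_active] - ws$x0rep[up_active],
         ws$x0rep[lo_active] - ws$xlo[lo_active])
  list(A = A, b = b)
}

compile_program <- function(program) {
  ws <- program_workspace(program)
  M <- ws$M; N <- ws$N; Fn <- ws$Fn
  nv <- Fn * M
  ny <- if (program$has_y) N * M else 0
  nz <- if (program$has_z) Fn * (M - 1) else 0
  n_u <- nv + ny + nz
  iv <- seq_len(nv)
  iy <- if (ny) nv + seq_len(ny) else integer(0)
  iz <- if (nz) nv + ny + seq_len(nz) else integer(0)
  lb <- c(ws$vlo, rep(0, ny + nz))
  ub <- c(ws$vhi, rep(1, ny + nz))
  box <- conc_box_rows(ws, n_u)

  meta <- list(ws = ws, iv = iv, iy = iy, iz = iz, n_u = n_u)

  if (program$method == "dfba") {
    i <- match(program$sink, program$model$metabolites$id)
    crow <- as.vector(t(ws$ops$quadrature) %*%
                        ws$P[((i - 1) * M + 1):(i * M), , drop = FALSE])
    const <- sum(ws$ops$quadrature) * program$model$metabolites$x0[i]
    prob <- opt_problem(
      n_u, list(type = "linear", c = c(crow), const = const),
      sense = "max", lb = lb, ub = ub, lin_ineq = box,
      name = program$method)
    return(list(prob = prob, meta = meta))
  }

  if (grepl("^mdfba", program$method)) {
    Q <- matrix(0, n_u, n_u)
    if (program$mode %in% c("conc", "both")) {
      D <- diag(M)
      D[cbind(2:M, 1:(M - 1))] <- -1
      H <- D %*% ws$ops$G
      Q[iv, iv] <- Q[iv, iv] + kronecker(t(ws$S) %*% ws$S, t(H) %*% H)
    }
    if (program$mode %in% c("flux", "both")) {
      Dv <- matrix(0, M - 1, M)
      Dv[cbind(seq_len(M - 1), seq_len(M - 1))] <- -1
      Dv[cbind(seq_len(M - 1), 2:M)] <- 1
      Q[iv, iv] <- Q[iv, iv] + kronecker(diag(Fn), t(Dv) %*% Dv)
    }
    prob <- opt_problem(
      n_u, list(type = "quadratic", Q = 2 * Q, c = rep(0, n_u),
                const = 0),
      sense = "min", lb = lb, ub = ub, lin_ineq = box,
      name = program$method)
    return(list(prob = prob, meta = meta))
  }

  # R-DFBA family
  th <- program$thresholds
  a <- program$alpha
  wy <- if (program$mode == "both") 2 * a else 1
  wz <- if (program$mode == "both") 2 * (1 - a) else 1
  cvec <- rep(0, n_u)
  if (ny) cvec[iy] <- wy
  if (nz) cvec[iz] <- wz

  nl <- rdfba_constraints(program, ws, iv, iy, iz, n_u)
  heur <- rdfba_heuristic(program, ws, iv, iy, iz, n_u)
  leaf <- if (program$binary)
    rdfba_compile_leaf(program, ws, iv, iy, iz, n_u, box, cvec) else NULL

  prob <- opt_problem(
    n_u, list(type = "linear", c = cvec, const = 0), sense = "min",
    lb = lb, ub = ub, lin_ineq = box, nl_ineq = nl,
    binary = if (program$binary) c(iy, iz) else integer(0),
    heuristic = heur, compile_leaf = leaf, name = program$method)
  list(prob = prob, meta = meta)
}

# threshold quantities for the concentration indicators:
# w^u = clip(x_prev (1+gamma_x) + eps_x), w^l = clip(x_prev (1-gamma_x)
# - eps_x), clip into the node's [x_min, x_max].  Returns value and the
# derivative of the clipped threshold w.r.t. x_prev.
conc_thresholds <- function(xprev, gx, ex, xlo, xhi) {
  wu_raw <- xprev * (1 + gx) + ex
  wl_raw <- xprev * (1 - gx) - ex
  wu <- pmin(pmax(wu_raw, xlo), xhi)
  wl <- pmin(pmax(wl_raw, xlo), xhi)
  list(wu = wu, wl = wl,
       dwu = (1 + gx) * (wu_raw >= xlo & wu_raw <= xhi),
       dwl = (1 - gx) * (wl_raw >= xlo & wl_raw <= xhi))
}

flux_thresholds <- function(vprev, gv, ev, vlo, vhi) {
  bu_raw <- vprev * (1 + gv) + ev
  bl_raw <- vprev * (1 - gv) - ev
  bu <- pmin(pmax(bu_raw, vlo), vhi)
  bl <- pmin(pmax(bl_raw, vlo), vhi)
  list(bu = bu, bl = bl,
       dbu = (1 + gv) * (bu_raw >= vlo & bu_raw <= vhi),
       dbl = (1 - gv) * (bl_raw >= vlo & bl_raw <= vhi))
}

rdfba_constraints <- function(program, ws, iv, iy, iz, n_u) {
  M <- ws$M; Fn <- ws$Fn
  th <- program$thresholds
  has_y <- program$has_y; has_z <- program$has_z
  P <- ws$P; x0rep <- ws$x0rep; prev <- ws$prev
  xlo <- ws$xlo; xhi <- ws$xhi
  # flux indicator bookkeeping: z_{l,j} for j = 2..M; previous-node and
  # current-node positions inside the v block
  zcur <- as.vector(vapply(seq_len(Fn), function(l)
    ((l - 1) * M + 2):(l * M), integer(M - 1)))
  zprev <- zcur - 1L
  vlo_z <- ws$vlo[zcur]; vhi_z <- ws$vhi[zcur]
  m_y <- if (has_y) 2 * length(iy) else 0
  m_z <- if (has_z) 2 * length(iz) else 0

  fn <- function(u) {
    out <- numeric(0)
    if (has_y) {
      xf <- x0rep + as.vector(P %*% u[iv])
      xp <- ifelse(prev == 0L, x0rep, xf[pmax(prev, 1L)])
      y <- u[iy]
      thx <- conc_thresholds(xp, th$gamma_x, th$eps_x, xlo, xhi)
      g_up <- xf - y * (xhi - thx$wu) - thx$wu
      g_lo <- thx$wl - xf + y * (xlo - thx$wl)
      out <- c(out, g_up, g_lo)
    }
    if (has_z) {
      v <- u[iv]
      z <- u[iz]
      thv <- flux_thresholds(v[zprev], th$gamma_v, th$eps_v, vlo_z, vhi_z)
      g_up <- v[zcur] - z * (vhi_z - thv$bu) - thv$bu
      g_lo <- thv$bl - v[zcur] + z * (vlo_z - thv$bl)
      out <- c(out, g_up, g_lo)
    }
    out
  }

  jac <- function(u) {
    blocks <- NULL
    if (has_y) {
      xf <- x0rep + as.vector(P %*% u[iv])
      xp <- ifelse(prev == 0L, x0rep, xf[pmax(prev, 1L)])
      y <- u[iy]
      thx <- conc_thresholds(xp, th$gamma_x, th$eps_x, xlo, xhi)
      Pprev <- P[pmax(prev, 1L), , drop = FALSE]
      Pprev[prev == 0L, ] <- 0
      # g_up: d/dxf = I, d/dxp = (y - 1) dwu ; g_lo: d/dxf = -I,
      # d/dxp = (1 - y) dwl
      Jup_v <- P + ((y - 1) * thx$dwu) * Pprev
      Jlo_v <- -P + ((1 - y) * thx$dwl) * Pprev
      Jup <- matrix(0, length(iy), n_u)
      Jlo <- matrix(0, length(iy), n_u)
      Jup[, iv] <- Jup_v; Jlo[, iv] <- Jlo_v
      Jup[cbind(seq_along(iy), iy)] <- -(xhi - thx$wu)
      Jlo[cbind(seq_along(iy), iy)] <- xlo - thx$wl
      blocks <- rbind(blocks, Jup, Jlo)
    }
    if (has_z) {
      v <- u[iv]
      z <- u[iz]
      thv <- flux_thresholds(v[zprev], th$gamma_v, th$eps_v, vlo_z, vhi_z)
      mz <- length(iz)
      Jup <- matrix(0, mz, n_u)
      Jlo <- matrix(0, mz, n_u)
      rows <- seq_len(mz)
      Jup[cbind(rows, iv[zcur])] <- 1
      Jup[cbind(rows, iv[zprev])] <- (z - 1) * thv$dbu
      Jup[cbind(rows, iz)] <- -(vhi_z - thv$bu)
      Jlo[cbind(rows, iv[zcur])] <- -1
      Jlo[cbind(rows, iv[zprev])] <- (1 - z) * thv$dbl
      Jlo[cbind(rows, iz)] <- vlo_z - thv$bl
      blocks <- rbind(blocks, Jup, Jlo)
    }
    blocks
  }

  list(fn = fn, jac = jac, m = m_y + m_z)
}

# rounding heuristic: indicators forced on wherever the off-state
# constraints are violated at the relaxation's continuous point
rdfba_heuristic <- function(program, ws, iv, iy, iz, n_u) {
  th <- program$thresholds
  M <- ws$M; Fn <- ws$Fn
  zcur <- as.vector(vapply(seq_len(Fn), function(l)
    ((l - 1) * M + 2):(l * M), integer(M - 1)))
  zprev <- zcur - 1L
  vlo_z <- ws$vlo[zcur]; vhi_z <- ws$vhi[zcur]
  function(u) {
    out <- numeric(0)
    tol <- 1e-7
    if (program$has_y) {
      xf <- ws$x0rep + as.vector(ws$P %*% u[iv])
      xp <- ifelse(ws$prev == 0L, ws$x0rep, xf[pmax(ws$prev, 1L)])
      thx <- conc_thresholds(xp, th$gamma_x, th$eps_x, ws$xlo, ws$xhi)
      out <- c(out, as.numeric(xf > thx$wu + tol | xf < thx$wl - tol))
    }
    if (program$has_z) {
      v <- u[iv]
      thv <- flux_thresholds(v[zprev], th$gamma_v, th$eps_v, vlo_z, vhi_z)
      out <- c(out, as.numeric(v[zcur] > thv$bu + tol |
                                 v[zcur] < thv$bl - tol))
    }
    out
  }
}

# leaf problems: with the indicators fixed, the on/off constraints are
# linear in v (off rows become raw-threshold rows; the clip adds only
# box rows that are already present), so leaves go to the QP path with a
# small projection objective for determinism
rdfba_compile_leaf <- function(program, ws, iv, iy, iz, n_u, box, cvec) {
  th <- program$thresholds
  M <- ws$M; Fn <- ws$Fn; nv <- length(iv)
  zcur <- as.vector(vapply(seq_len(Fn), function(l)
    ((l - 1) * M + 2):(l * M), integer(M - 1)))
  zprev <- zcur - 1L
  function(vals, center = NULL) {
    yv <- if (program$has_y) vals[seq_along(iy)] else numeric(0)
    zv <- if (program$has_z) vals[length(iy) + seq_along(iz)] else numeric(0)
    A <- NULL; b <- numeric(0)
    if (program$has_y) {
      off <- which(yv < 0.5)
      if (length(off)) {
        Pprev <- ws$P[pmax(ws$prev, 1L), , drop = FALSE]
        Pprev[ws$prev == 0L, ] <- 0
        # x_j <= x_prev (1+g) + e  and  x_j >= x_prev (1-g) - e, in v;
        # the x0 constants of node and predecessor belong to the same
        # metabolite, so only the g * x0 term survives on the right
        Au <- ws$P[off, , drop = FALSE] -
          (1 + th$gamma_x) * Pprev[off, , drop = FALSE]
        bu <- th$eps_x + th$gamma_x * ws$x0rep[off]
        Al <- (1 - th$gamma_x) * Pprev[off, , drop = FALSE] -
          ws$P[off, , drop = FALSE]
        bl <- th$eps_x + th$gamma_x * ws$x0rep[off]
        A <- rbind(A, cbind(Au, matrix(0, length(off), n_u - nv)),
                   cbind(Al, matrix(0, length(off), n_u - nv)))
        b <- c(b, bu, bl)
      }
    }
    if (program$has_z) {
      off <- which(zv < 0.5)
      if (length(off)) {
        mzo <- length(off)
        Au <- matrix(0, mzo, n_u); Al <- matrix(0, mzo, n_u)
        Au[cbind(seq_len(mzo), iv[zcur[off]])] <- 1
        Au[cbind(seq_len(mzo), iv[zprev[off]])] <- -(1 + th$gamma_v)
        Al[cbind(seq_len(mzo), iv[zcur[off]])] <- -1
        Al[cbind(seq_len(mzo), iv[zprev[off]])] <- 1 - th$gamma_v
        A <- rbind(A, Au, Al)
        b <- c(b, rep(th$eps_v, mzo), rep(th$eps_v, mzo))
      }
    }
    lin <- list(A = rbind(box$A, A), b = c(box$b, b))
    lb <- c(ws$vlo, vals)
    ub <- c(ws$vhi, vals)
    ctr <- if (is.null(center)) rep(0, n_u) else center
    # projection objective keeps leaves deterministic; the true
    # objective value at a leaf is the fixed indicator count
    opt_problem(
      n_u,
      list(type = "quadratic", Q = diag(1e-4, n_u), c = -1e-4 * ctr,
           const = sum(cvec * c(rep(0, nv), vals))),
      sense = "min", lb = lb, ub = ub, lin_ineq = lin,
      name = paste0(program$method, "_leaf"))
  }
}
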