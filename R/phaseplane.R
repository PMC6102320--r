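# Phase-plane analysis of the clamped-sodium model: nullclines, equilibria
# with stability, basins of attraction, and bistability maps over membrane
# potential and internal sodium.
#
# The h-nullcline is simply h = h_inf(Ca, Na_i). The Ca-nullcline solves
# 0 = J_ncx + (Ca_rest - Ca)/tau_Ca for h:
#
#   h_ca(Ca) = (Ca - Ca_rest) / (tau_Ca * Jbar * n_inf(Ca) * J_dE(Ca, Na_i))
#
# It is discontinuous where J_dE = 0 (the exchanger's reversal point); the
# grid is split there and h values outside [0, 1] are kept but flagged
# unphysical (only [0,1] intersections are equilibria).

#' h-nullcline of the clamped-sodium model
#'
#' @param ca_grid increasing vector of internal calcium values (mM), > 0.
#' @param Na_i clamped internal sodium (mM).
#' @param p an [ncx_params()] object.
#' @return A data.frame `(Ca, h)` with attribute `label = "h_nullcline"`.
#' @export
h_nullcline <- function(ca_grid, Na_i, p) {
  .check_pos(ca_grid, "ca_grid")
  structure(data.frame(Ca = ca_grid, h = h_inf(ca_grid, Na_i, p)),
            label = "h_nullcline")
}

#' Ca-nullcline of the clamped-sodium model
#'
#' @inheritParams h_nullcline
#' @param env,hp environment and homeostasis parameters.
#' @return A list of branch data.frames `(Ca, h, physical)` split at the
#'   reversal discontinuity (grid points landing exactly on it are dropped);
#'   attribute `discontinuity` holds the reversal calcium [reversal_ca()],
#'   and each branch has attribute `label = "ca_nullcline"`.
#' @export
ca_nullcline <- function(ca_grid, Na_i, env, p, hp) {
  .check_pos(ca_grid, "ca_grid")
  ca_grid <- sort(ca_grid)
  ca_star <- reversal_ca(Na_i, env)
  keep <- ca_grid != ca_star
  ca <- ca_grid[keep]
  h <- (ca - hp$Ca_rest) /
    (hp$tau_Ca * p$Jbar * n_inf(ca, p) * j_delta_e(ca, Na_i, env, p))
  side <- ca > ca_star
  branches <- lapply(split(seq_along(ca), side), function(idx) {
    structure(data.frame(Ca = ca[idx], h = h[idx],
                         physical = h[idx] >= 0 & h[idx] <= 1),
              label = "ca_nullcline")
  })
  branches <- unname(branches)
  structure(branches, discontinuity = ca_star)
}

# 2x2 Jacobian of the clamped model by central differences.
.jac_clamped <- function(state, Na_i, env, p, hp, h_rel = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    dh <- h_rel * max(abs(state[j]), 1e-8)
    xp <- state; xp[j] <- state[j] + dh
    xm <- state; xm[j] <- state[j] - dh
    # h may poke outside [0,1] at the box edge; evaluate the smooth extension
    fp <- .rhs_clamped_unsafe(xp, Na_i, env, p, hp)
    fm <- .rhs_clamped_unsafe(xm, Na_i, env, p, hp)
    J[, j] <- (fp - fm) / (2 * dh)
  }
  J
}

# rhs_clamped without the [0,1] gate guard (smooth extension for FD
# Jacobians at boundary equilibria).
.rhs_clamped_unsafe <- function(state, Na_i, env, p, hp) {
  Ca <- state[[1]]; h <- state[[2]]
  J <- p$Jbar * n_inf(Ca, p) * h * j_delta_e(Ca, Na_i, env, p)
  c(J + (hp$Ca_rest - Ca) / hp$tau_Ca,
    (h_inf(Ca, Na_i, p) - h) / tau_h(Ca, p))
}

#' Equilibria of the clamped-sodium model
#'
#' Finds all intersections of the two nullclines with `h` in \[0, 1\] by a
#' dense sign-change scan of `h_ca(Ca) - h_inf(Ca)` on a log-spaced calcium
#' grid (excluding the reversal discontinuity), refines each root with
#' [stats::uniroot()] and a 2D Newton polish, deduplicates (pairwise
#' distance above `dedup_tol` in scaled (uM, -) coordinates), and classifies
#' stability from the eigenvalues of the finite-difference Jacobian.
#'
#' @param Na_i clamped internal sodium (mM).
#' @param env,p,hp model parameters.
#' @param ca_range search interval for calcium (mM).
#' @param n_scan number of scan-grid points.
#' @param dedup_tol deduplication radius in (Ca in uM, h) coordinates.
#' @param marginal_tol eigenvalue real parts within this value of zero are
#'   labelled `"marginal"` rather than silently stable.
#' @return A data.frame with columns `Ca`, `h`, `eig1`, `eig2` (real parts),
#'   `stability` (`"stable"`, `"saddle"`, `"unstable"`, `"marginal"`).
#' @export
find_equilibria <- function(Na_i, env, p, hp,
                            ca_range = c(1e-6, 0.05), n_scan = 2000,
                            dedup_tol = 1e-6, marginal_tol = 1e-9) {
  if (p$Jbar == 0) {
    # linear system: the unique equilibrium is the nominal rest point
    st <- c(hp$Ca_rest, h_inf(hp$Ca_rest, Na_i, p))
    ev <- eigen(.jac_clamped(st, Na_i, env, p, hp),
                only.values = TRUE)$values
    re <- sort(Re(ev))
    return(data.frame(Ca = st[1], h = st[2], eig1 = re[1], eig2 = re[2],
                      stability = if (all(re < 0)) "stable" else "unstable"))
  }
  ca <- exp(seq(log(ca_range[1]), log(ca_range[2]), length.out = n_scan))
  ca_star <- reversal_ca(Na_i, env)
  ca <- ca[ca != ca_star]
  denom <- hp$tau_Ca * p$Jbar * n_inf(ca, p) * j_delta_e(ca, Na_i, env, p)
  g <- (ca - hp$Ca_rest) / denom - h_inf(ca, Na_i, p)
  side <- ca > ca_star
  gfun <- function(x)
    (x - hp$Ca_rest) /
      (hp$tau_Ca * p$Jbar * n_inf(x, p) * j_delta_e(x, Na_i, env, p)) -
      h_inf(x, Na_i, p)
  roots <- numeric(0)
  for (i in seq_len(length(ca) - 1)) {
    if (side[i] != side[i + 1]) next      # discontinuity, not a root
    if (!is.finite(g[i]) || !is.finite(g[i + 1])) next
    if (g[i] == 0) { roots <- c(roots, ca[i]); next }
    if (sign(g[i]) * sign(g[i + 1]) < 0) {
      r <- tryCatch(
        stats::uniroot(gfun, c(ca[i], ca[i + 1]), tol = 1e-15)$root,
        error = function(e) NULL)
      if (!is.null(r)) roots <- c(roots, r)
    }
  }
  out <- NULL
  for (r in roots) {
    h0 <- h_inf(r, Na_i, p)
    pol <- newton_polish(function(x)
      .rhs_clamped_unsafe(x, Na_i, env, p, hp), c(r, h0), tol = 1e-13)
    if (is.null(pol)) {
      warning(sprintf("equilibrium candidate at Ca = %.4g dropped: %s",
                      r, "root polishing failed"))
      next
    }
    if (pol[2] < -1e-9 || pol[2] > 1 + 1e-9) next   # outside the gate range
    out <- rbind(out, pol)
  }
  if (is.null(out))
    return(data.frame(Ca = numeric(), h = numeric(), eig1 = numeric(),
                      eig2 = numeric(), stability = character()))
  # deduplicate in scaled coordinates (Ca in uM, h as-is)
  scaled <- cbind(out[, 1] * 1e3, out[, 2])
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1)) {
      if (keep[j] && sqrt(sum((scaled[i, ] - scaled[j, ])^2)) < dedup_tol)
        keep[i] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out[, 1]), , drop = FALSE]
  cls <- t(apply(out, 1, function(st) {
    ev <- eigen(.jac_clamped(st, Na_i, env, p, hp),
                only.values = TRUE)$values
    re <- sort(Re(ev))
    lab <- if (any(abs(re) < marginal_tol)) "marginal"
    else if (all(re < 0)) "stable"
    else if (all(re > 0)) "unstable"
    else "saddle"
    c(re[1], re[2], lab)
  }))
  data.frame(Ca = out[, 1], h = out[, 2],
             eig1 = as.numeric(cls[, 1]), eig2 = as.numeric(cls[, 2]),
             stability = cls[, 3], row.names = NULL)
}

#' Basin-of-attraction map of the clamped-sodium model
#'
#' Integrates a grid of initial conditions forward until each trajectory
#' enters the capture radius of a stable equilibrium (label = index of that
#' equilibrium in `eq`) or the horizon is exceeded (label `NA`, counted as
#' unresolved).
#'
#' @param eq equilibrium table from [find_equilibria()]; at least two stable
#'   equilibria are required.
#' @param Na_i,env,p,hp model parameters (must match those used for `eq`).
#' @param ca_lim,h_lim grid limits; calcium spacing is logarithmic.
#' @param n_ca,n_h grid resolution.
#' @param horizon integration horizon (s); default `10 * max(tau_Ca, tau0)`.
#' @param capture_frac capture radius as a fraction of the smallest
#'   inter-equilibrium distance (scaled coordinates: Ca in uM).
#' @return A data.frame `(Ca0, h0, basin)`; attribute `unresolved` counts
#'   cells that ran out of horizon.
#' @export
basin_map <- function(eq, Na_i, env, p, hp,
                      ca_lim = NULL, h_lim = c(0, 1),
                      n_ca = 20, n_h = 20,
                      horizon = NULL, capture_frac = 0.01) {
  stable <- eq[eq$stability == "stable", , drop = FALSE]
  if (nrow(stable) < 2)
    stop("basin_map requires at least two stable equilibria", call. = FALSE)
  if (is.null(horizon)) horizon <- 10 * max(hp$tau_Ca, p$tau0)
  if (is.null(ca_lim)) ca_lim <- c(min(eq$Ca) / 5, max(eq$Ca) * 5)
  sc <- function(s) c(s[1] * 1e3, s[2])
  dmin <- min(stats::dist(t(apply(stable[, c("Ca", "h")], 1, sc))))
  rad <- capture_frac * dmin
  ca0 <- exp(seq(log(ca_lim[1]), log(ca_lim[2]), length.out = n_ca))
  h0 <- seq(h_lim[1], h_lim[2], length.out = n_h)
  grid <- expand.grid(Ca0 = ca0, h0 = h0)
  targets <- t(apply(stable[, c("Ca", "h")], 1, sc))
  capture_root <- function(t, y, parms) {
    d <- sqrt((y[1] * 1e3 - targets[, 1])^2 + (y[2] - targets[, 2])^2)
    min(d) - rad
  }
  basin <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sol <- deSolve::lsoda(
      y = c(grid$Ca0[i], min(max(grid$h0[i], 0), 1)),
      times = c(0, horizon),
      func = function(t, y, parms)
        list(.rhs_clamped_unsafe(y, Na_i, env, p, hp)),
      rootfunc = capture_root, rtol = 1e-8, atol = 1e-12)
    yf <- sol[nrow(sol), -1]
    d <- sqrt((yf[1] * 1e3 - targets[, 1])^2 + (yf[2] - targets[, 2])^2)
    basin[i] <- if (min(d) <= rad * 1.0001) which.min(d) else NA_integer_
  }
  res <- data.frame(Ca0 = grid$Ca0, h0 = grid$h0, basin = basin)
  structure(res, unresolved = sum(is.na(basin)), capture_radius = rad,
            stable_equilibria = stable)
}

#' Bistability map over membrane potential and internal sodium
#'
#' Runs [find_equilibria()] on every cell of a `(V, Na_i)` grid at fixed
#' exchanger strength and records the number of equilibria, the number of
#' stable ones, the highest stable calcium, and a bistability flag
#' (>= 2 stable equilibria).
#'
#' @param V_mV_range,Na_range grid limits: membrane potential (mV) and
#'   clamped sodium (mM).
#' @param n_V,n_Na grid resolution.
#' @param env,p,hp model parameters; `Jbar` is taken from `p`.
#' @param ... further arguments passed to [find_equilibria()].
#' @return A data.frame `(V_mV, Na_i, n_eq, n_stable, highest_stable_Ca,
#'   bistable, valid)`; per-cell failures are caught, logged as warnings and
#'   marked `valid = FALSE`.
#' @export
bifurcation_scan <- function(V_mV_range, Na_range, n_V = 20, n_Na = 20,
                             env = cell_env(), p = ncx_params(),
                             hp = homeostasis_params(), ...) {
  stopifnot(n_V >= 1, n_Na >= 1)
  Vs <- seq(V_mV_range[1], V_mV_range[2], length.out = n_V)
  Nas <- seq(Na_range[1], Na_range[2], length.out = n_Na)
  grid <- expand.grid(V_mV = Vs, Na_i = Nas)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    e2 <- cell_env(Ca_o = env$Ca_o, Na_o = env$Na_o,
                   V_mV = grid$V_mV[i], T = env$T)
    eq <- tryCatch(find_equilibria(grid$Na_i[i], e2, p, hp, ...),
                   error = function(e) NULL)
    if (is.null(eq)) {
      warning(sprintf("bifurcation cell (V = %g mV, Na = %g mM) failed",
                      grid$V_mV[i], grid$Na_i[i]))
      return(data.frame(V_mV = grid$V_mV[i], Na_i = grid$Na_i[i],
                        n_eq = NA_integer_, n_stable = NA_integer_,
                        highest_stable_Ca = NA_real_, bistable = NA,
                        valid = FALSE))
    }
    ns <- sum(eq$stability == "stable")
    data.frame(V_mV = grid$V_mV[i], Na_i = grid$Na_i[i],
               n_eq = nrow(eq), n_stable = ns,
               highest_stable_Ca = if (ns) max(eq$Ca[eq$stability ==
                                                       "stable"]) else NA_real_,
               bistable = ns >= 2, valid = TRUE)
  })
  do.call(rbind, rows)
}
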