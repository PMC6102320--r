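# Cell models: clamped-sodium two-variable model, full point model, and the
# allosteric-regulation-off control, plus the integration layer.
#
#   clamped_na:          d[Ca]/dt = J_ncx + (Ca_rest - Ca)/tau_Ca
#                        dh/dt    = (h_inf - h)/tau_h          (Na_i fixed)
#   point_full:          d[Ca]/dt = J_ncx + J_ext_Ca + (Ca_rest - Ca)/tau_Ca
#                        d[Na]/dt = J_ext_Na - 3 J_ncx + (Na_rest - Na)/tau_Na
#                        dh/dt    = (h_inf - h)/tau_h
#   point_no_allostery:  as point_full with n = h = 1 and Jbar scaled down
#                        to match the full model's NCX flux at rest.
#
# The -3 coefficient is the exchanger's stoichiometry (3 Na+ per Ca2+) and
# is the only place it enters the equations.

#' Model variant descriptor
#'
#' @param tag one of `"clamped_na"`, `"point_full"`, `"point_no_allostery"`.
#' @param scale for `point_no_allostery`, the factor applied to `Jbar` to
#'   compensate for the higher fraction of active transporters; defaults to
#'   the rest-state matching rule of [allostery_off_scale()] evaluated at
#'   integration time.
#' @return An object of class `model_variant`.
#' @export
model_variant <- function(tag = c("point_full", "clamped_na",
                                  "point_no_allostery"),
                          scale = NULL) {
  tag <- match.arg(tag)
  if (!is.null(scale)) .check_num(scale, "scale", lower = 0,
                                  strict_lower = TRUE)
  structure(list(tag = tag, scale = scale), class = "model_variant")
}

#' Rest-state matching factor for the allosteric-off control
#'
#' The control model removes both gates (`n = h = 1`), which would multiply
#' the resting NCX flux by `1 / (n_inf(Ca_rest) h_inf(Ca_rest, Na_rest))`.
#' To compare like with like, its `Jbar` is scaled by
#' `n_inf(Ca_rest) * h_inf(Ca_rest, Na_rest)` so that both variants carry
#' identical NCX flux at the nominal rest state.
#'
#' @param p an [ncx_params()] object.
#' @param hp a [homeostasis_params()] object.
#' @return Scalar scale factor in (0, 1).
#' @export
allostery_off_scale <- function(p, hp) {
  n_inf(hp$Ca_rest, p) * h_inf(hp$Ca_rest, hp$Na_rest, p)
}

#' Right-hand side of the clamped-sodium model
#'
#' Two-variable model in `(Ca_i, h)` with internal sodium held as a
#' parameter; the phase-plane object of the bistability analysis.
#'
#' @param state numeric `c(Ca_i, h)` (mM, -).
#' @param Na_i clamped internal sodium (mM).
#' @param env,p,hp environment, NCX and homeostasis parameters.
#' @param stim_Ca additive external Ca2+ flux (mM/s), default 0.
#' @return Numeric `c(dCa, dh)` (mM/s, 1/s).
#' @export
rhs_clamped <- function(state, Na_i, env, p, hp, stim_Ca = 0) {
  Ca <- state[[1]]; h <- state[[2]]
  J <- j_ncx(Ca, Na_i, h, env, p)
  c(J + stim_Ca + (hp$Ca_rest - Ca) / hp$tau_Ca,
    dh_dt(h, Ca, Na_i, p))
}

#' Right-hand side of the point model
#'
#' @param state numeric `c(Ca_i, Na_i, h)`.
#' @param stim numeric `c(J_ext_Ca, J_ext_Na)` external fluxes (mM/s).
#' @param env,p,hp environment, NCX and homeostasis parameters.
#' @param variant a [model_variant()]; `clamped_na` is not valid here.
#' @return Numeric `c(dCa, dNa, dh)`.
#' @export
rhs_point <- function(state, stim, env, p, hp,
                      variant = model_variant("point_full")) {
  Ca <- state[[1]]; Na <- state[[2]]; h <- state[[3]]
  if (any(!is.finite(stim)))
    stop("stimulus fluxes must be finite", call. = FALSE)
  if (variant$tag == "point_no_allostery") {
    s <- if (is.null(variant$scale)) allostery_off_scale(p, hp) else
      variant$scale
    J <- s * p$Jbar * j_delta_e(Ca, Na, env, p)
    dh <- 0   # gate frozen at 1; not part of this variant's dynamics
  } else {
    J <- j_ncx(Ca, Na, h, env, p)
    dh <- dh_dt(h, Ca, Na, p)
  }
  c(J + stim[[1]] + (hp$Ca_rest - Ca) / hp$tau_Ca,
    stim[[2]] - 3 * J + (hp$Na_rest - Na) / hp$tau_Na,
    dh)
}

#' @rdname rhs_point
#' @export
rhs_no_allostery <- function(state, stim, env, p, hp, scale = NULL) {
  rhs_point(state, stim, env, p, hp,
            model_variant("point_no_allostery", scale = scale))
}

# Damped Newton root polish with central-difference Jacobian; returns NULL
# on failure. Used for rest states and equilibrium polishing.
newton_polish <- function(f, x0, tol = 1e-12, maxit = 60, h_rel = 1e-6) {
  x <- x0
  n <- length(x0)
  for (it in seq_len(maxit)) {
    fx <- f(x)
    if (any(!is.finite(fx))) return(NULL)
    if (max(abs(fx)) < tol) return(x)
    Jm <- matrix(0, n, n)
    for (j in seq_len(n)) {
      dh <- h_rel * max(abs(x[j]), 1e-8)
      xp <- x; xp[j] <- x[j] + dh
      xm <- x; xm[j] <- x[j] - dh
      fp <- tryCatch(f(xp), error = function(e) NULL)
      fm <- tryCatch(f(xm), error = function(e) NULL)
      if (is.null(fp) || is.null(fm)) return(NULL)
      Jm[, j] <- (fp - fm) / (2 * dh)
    }
    step <- tryCatch(solve(Jm, fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      fn <- tryCatch(f(xn), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) &&
          max(abs(fn)) < max(abs(fx)) * (1 - 0.25 * lambda) + tol) break
      lambda <- lambda / 2
      if (lambda < 1e-6) return(NULL)
    }
    x <- x - lambda * step
  }
  fx <- f(x)
  if (max(abs(fx)) < 1e-8) x else NULL
}

#' Rest state of a model variant
#'
#' The unstimulated equilibrium nearest the nominal resting point. With the
#' exchanger active the true rest state differs slightly from
#' `(Ca_rest, Na_rest)` (the NCX is generally not at its reversal point at
#' rest), so simulations and superposition analyses start here rather than
#' at the nominal values. Found by relaxing the unstimulated system and
#' polishing with Newton iteration.
#'
#' @param variant a [model_variant()].
#' @param env,p,hp model parameters.
#' @param Na_i clamped sodium (mM), used only for `clamped_na`.
#' @return Named numeric state vector: `c(Ca, h)` for `clamped_na`,
#'   otherwise `c(Ca, Na, h)`.
#' @export
find_rest_state <- function(variant, env, p, hp, Na_i = hp$Na_rest) {
  if (variant$tag == "clamped_na") {
    f <- function(x) rhs_clamped(x, Na_i, env, p, hp)
    x0 <- c(hp$Ca_rest, h_inf(hp$Ca_rest, Na_i, p))
    relax <- .relax(f, x0, t_end = 50 * max(hp$tau_Ca, p$tau0))
    x <- newton_polish(f, relax)
    if (is.null(x)) stop("rest-state search failed to converge",
                         call. = FALSE)
    c(Ca = x[1], h = x[2])
  } else {
    f <- function(x) rhs_point(x, c(0, 0), env, p, hp, variant)
    h0 <- if (variant$tag == "point_no_allostery") 1 else
      h_inf(hp$Ca_rest, hp$Na_rest, p)
    x0 <- c(hp$Ca_rest, hp$Na_rest, h0)
    relax <- .relax(f, x0,
                    t_end = 50 * max(hp$tau_Ca, hp$tau_Na, p$tau0))
    x <- newton_polish(f, relax)
    if (is.null(x)) stop("rest-state search failed to converge",
                         call. = FALSE)
    c(Ca = x[1], Na = x[2], h = x[3])
  }
}

.relax <- function(f, x0, t_end) {
  sol <- deSolve::lsoda(
    y = x0, times = c(0, t_end),
    func = function(t, y, parms) list(f(y)),
    rtol = 1e-10, atol = 1e-13)
  unname(sol[nrow(sol), -1])
}

#' Integrate a cell model under a stimulation protocol
#'
#' Method-of-lines-free single-compartment integration with a stiff solver
#' (`deSolve::lsoda`, default relative tolerance 1e-8). Pulse edges are
#' declared as integration breakpoints: the trajectory is integrated piecewise
#' between consecutive protocol discontinuities with the applied flux constant
#' on each piece, so the solver never steps across a pulse edge.
#'
#' @param variant a [model_variant()].
#' @param protocol a [stim_protocol()] (spatial intervals, if any, are
#'   ignored by the point models).
#' @param t_span numeric `c(t0, t1)` (s).
#' @param env,p,hp model parameters.
#' @param init initial state; the string `"rest"` (default) starts from
#'   [find_rest_state()], otherwise a numeric state vector as returned by it.
#' @param Na_i clamped sodium (only for `clamped_na`).
#' @param dt_out output sampling interval (s).
#' @param rtol,atol solver tolerances.
#' @return A data.frame of class `ncx_series` with columns `t`, `Ca`, `Na`,
#'   `h`, `J_ncx`, and attributes `rest_state`, `variant`, `params` (full
#'   parameter echo).
#' @export
integrate_model <- function(variant, protocol, t_span,
                            env = cell_env(), p = ncx_params(),
                            hp = homeostasis_params(),
                            init = "rest", Na_i = hp$Na_rest,
                            dt_out = 0.25, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(protocol, "stim_protocol"),
            length(t_span) == 2, t_span[2] > t_span[1])
  clamped <- variant$tag == "clamped_na"
  rest <- find_rest_state(variant, env, p, hp, Na_i = Na_i)
  y <- if (identical(init, "rest")) rest else {
    stopifnot(is.numeric(init), length(init) == length(rest))
    stats::setNames(as.numeric(init), names(rest))
  }
  scale <- if (variant$tag == "point_no_allostery" && is.null(variant$scale))
    allostery_off_scale(p, hp) else variant$scale
  variant_eff <- model_variant(variant$tag, scale)

  rhs_fun <- if (clamped) {
    function(t, yy, parms)
      list(rhs_clamped(yy, Na_i, env, p, hp, stim_Ca = parms[["Ca"]]))
  } else {
    function(t, yy, parms)
      list(rhs_point(yy, c(parms[["Ca"]], parms[["Na"]]), env, p, hp,
                     variant_eff))
  }

  bks <- protocol_breakpoints(protocol, t_span)
  out <- NULL
  for (k in seq_len(length(bks) - 1)) {
    flux <- protocol_flux_at(protocol, (bks[k] + bks[k + 1]) / 2)
    tt <- seq(bks[k], bks[k + 1], by = dt_out)
    if (tt[length(tt)] < bks[k + 1]) tt <- c(tt, bks[k + 1])
    seg <- deSolve::lsoda(y = y, times = tt, func = rhs_fun, parms = flux,
                          rtol = rtol, atol = atol)
    if (attr(seg, "istate")[1] < 0)
      stop(sprintf("integration failed at t = %.6g (state: %s)",
                   seg[nrow(seg), 1],
                   paste(signif(seg[nrow(seg), -1], 6), collapse = ", ")),
           call. = FALSE)
    y <- seg[nrow(seg), -1]
    out <- rbind(out, seg[if (is.null(out)) TRUE else -1, , drop = FALSE])
  }
  conc_cols <- if (clamped) 2L else 2:3
  if (any(out[, conc_cols] <= 0))
    stop("integrator produced non-positive concentrations; refusing to clip",
         call. = FALSE)
  res <- if (clamped) {
    data.frame(t = out[, 1], Ca = out[, 2], Na = Na_i, h = out[, 3])
  } else {
    data.frame(t = out[, 1], Ca = out[, 2], Na = out[, 3], h = out[, 4])
  }
  res$J_ncx <- if (variant$tag == "point_no_allostery")
    scale * p$Jbar * j_delta_e(res$Ca, res$Na, env, p)
  else
    j_ncx(res$Ca, res$Na, pmin(pmax(res$h, 0), 1), env, p)
  structure(res,
            class = c("ncx_series", "data.frame"),
            rest_state = rest,
            variant = variant_eff,
            params = list(ncx = unclass(p), env = unclass(env),
                          homeostasis = unclass(hp),
                          solver = list(rtol = rtol, atol = atol,
                                        dt_out = dt_out)))
}
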