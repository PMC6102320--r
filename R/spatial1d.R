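# One-dimensional reaction-diffusion model of a thin astrocytic process:
# the point model in every element plus Fickian diffusion of Ca2+ and Na+
# (the gate h is membrane-bound and does not diffuse). Method of lines with
# the same stiff-solver contract as the point models.

#' Spatial grid for the thin-process model
#'
#' Uniform 1D grid centred on `x = 0` with element size `dx`. The domain is
#' trimmed to a whole number of elements with one element centred exactly at
#' the origin, so a "central element" stimulus is well defined.
#'
#' @param length domain length (um).
#' @param dx element size (um), default 0.35.
#' @param D_Ca,D_Na effective diffusion coefficients (um^2/s). The shipped
#'   defaults (13 and 50) are effective cytosolic values: calcium is slowed
#'   by buffering, sodium by macromolecular crowding/tortuosity relative to
#'   free solution, but remains several-fold faster than calcium.
#' @param boundary `"noflux"` (sealed ends, mirrored ghost cells) or
#'   `"periodic"`.
#' @return An object of class `spatial_grid` with fields `x` (element
#'   centres), `dx`, `n`, `D_Ca`, `D_Na`, `boundary`.
#' @export
spatial_grid <- function(length = 40, dx = 0.35, D_Ca = 13, D_Na = 50,
                         boundary = c("noflux", "periodic")) {
  .check_num(dx, "dx", lower = 0, strict_lower = TRUE)
  .check_num(D_Ca, "D_Ca", lower = 0)
  .check_num(D_Na, "D_Na", lower = 0)
  boundary <- match.arg(boundary)
  nh <- floor((length / 2) / dx)
  if (2 * nh + 1 < 3) stop("grid needs at least 3 elements", call. = FALSE)
  x <- seq.int(-nh, nh) * dx
  structure(list(x = x, dx = dx, n = base::length(x),
                 D_Ca = D_Ca, D_Na = D_Na, boundary = boundary),
            class = "spatial_grid")
}

# Fraction of each element covered by [x_min, x_max]; stimulus amplitudes
# are flux densities, so the injected amount is independent of dx.
mask_weights <- function(grid, x_min, x_max) {
  lo <- grid$x - grid$dx / 2
  hi <- grid$x + grid$dx / 2
  w <- (pmin(hi, x_max) - pmax(lo, x_min)) / grid$dx
  pmin(pmax(w, 0), 1)
}

# Second-difference Laplacian. No-flux ends use ghost cells mirrored across
# the boundary face (ghost = first/last cell), which makes the scheme
# exactly conservative: the sum of second differences telescopes to zero.
.laplacian <- function(u, grid) {
  n <- grid$n
  if (grid$boundary == "periodic") {
    (c(u[n], u[-n]) - 2 * u + c(u[-1], u[1])) / grid$dx^2
  } else {
    (c(u[1], u[-n]) - 2 * u + c(u[-1], u[n])) / grid$dx^2
  }
}

#' Right-hand side of the 1D thin-process model
#'
#' Per-element point-model dynamics plus second-difference diffusion for
#' calcium and sodium. Mainly exposed for testing; [simulate_wave()] drives
#' the integration.
#'
#' @param state numeric vector `c(Ca[1..n], Na[1..n], h[1..n])`.
#' @param stim list with vectors `Ca`, `Na` of per-element external flux
#'   densities (mM/s), e.g. from an active protocol; zeros when quiescent.
#' @param grid a [spatial_grid()].
#' @param env,p,hp model parameters.
#' @param variant a [model_variant()] (`point_full` or
#'   `point_no_allostery`).
#' @return Derivative vector in the same layout.
#' @export
rhs_spatial <- function(state, stim, grid, env, p, hp,
                        variant = model_variant("point_full")) {
  n <- grid$n
  Ca <- state[1:n]; Na <- state[n + 1:n]; h <- state[2 * n + 1:n]
  if (variant$tag == "point_no_allostery") {
    s <- if (is.null(variant$scale)) allostery_off_scale(p, hp) else
      variant$scale
    J <- s * p$Jbar * j_delta_e(Ca, Na, env, p)
    dh <- numeric(n)
  } else {
    J <- j_ncx(Ca, Na, h, env, p)
    dh <- dh_dt(h, Ca, Na, p)
  }
  dCa <- J + stim$Ca + (hp$Ca_rest - Ca) / hp$tau_Ca +
    grid$D_Ca * .laplacian(Ca, grid)
  dNa <- stim$Na - 3 * J + (hp$Na_rest - Na) / hp$tau_Na +
    grid$D_Na * .laplacian(Na, grid)
  c(dCa, dNa, dh)
}

# Per-element stimulus flux densities for all pulses active at time t.
.protocol_flux_spatial <- function(protocol, t, grid) {
  fCa <- numeric(grid$n); fNa <- numeric(grid$n)
  act <- which(protocol$start <= t & t < protocol$start + protocol$duration)
  for (i in act) {
    w <- if (is.na(protocol$x_min[i])) rep(1, grid$n) else
      mask_weights(grid, protocol$x_min[i], protocol$x_max[i])
    if (protocol$species[i] == "Ca")
      fCa <- fCa + protocol$amplitude[i] * w
    else
      fNa <- fNa + protocol$amplitude[i] * w
  }
  list(Ca = fCa, Na = fNa)
}

#' Simulate the 1D thin-process model
#'
#' Method-of-lines integration of [rhs_spatial()] under a (possibly
#' spatially restricted) stimulation protocol, starting from the uniform
#' rest state of the chosen variant. Protocol edges are integration
#' breakpoints as in [integrate_model()].
#'
#' @param grid a [spatial_grid()].
#' @param protocol a [stim_protocol()]; pulses with spatial intervals act
#'   only there (fractional element coverage is weighted), pulses without
#'   act uniformly.
#' @param t_span numeric `c(t0, t1)` (s).
#' @param env,p,hp model parameters.
#' @param variant a [model_variant()].
#' @param dt_out output sampling interval (s).
#' @param rtol,atol solver tolerances.
#' @param reactions if `FALSE`, all local dynamics (NCX, homeostasis) and
#'   stimuli are switched off, leaving pure diffusion; used for
#'   conservation checks.
#' @param init optional initial state vector (layout as [rhs_spatial()]);
#'   default is the uniform rest state.
#' @return An object of class `ncx_field`: list with `t`, `x`, and
#'   matrices `Ca`, `Na`, `h` (rows = times, columns = elements), plus a
#'   `rest_state` attribute (per-species rest values).
#' @export
simulate_wave <- function(grid, protocol, t_span,
                          env = cell_env(), p = ncx_params(),
                          hp = homeostasis_params(),
                          variant = model_variant("point_full"),
                          dt_out = 0.5, rtol = 1e-8, atol = 1e-12,
                          reactions = TRUE, init = NULL) {
  stopifnot(inherits(grid, "spatial_grid"),
            inherits(protocol, "stim_protocol"))
  if (nrow(protocol) && !all(is.na(protocol$x_min))) {
    xr <- range(grid$x)
    bad <- !is.na(protocol$x_min) &
      (protocol$x_max < xr[1] - grid$dx / 2 |
         protocol$x_min > xr[2] + grid$dx / 2)
    if (any(bad))
      stop("protocol spatial interval lies outside the domain",
           call. = FALSE)
  }
  n <- grid$n
  if (is.null(init)) {
    rest <- find_rest_state(variant, env, p, hp)
    y <- c(rep(rest[["Ca"]], n), rep(rest[["Na"]], n), rep(rest[["h"]], n))
  } else {
    stopifnot(length(init) == 3 * n)
    rest <- c(Ca = init[1], Na = init[n + 1], h = init[2 * n + 1])
    y <- init
  }
  scale <- if (variant$tag == "point_no_allostery" && is.null(variant$scale))
    allostery_off_scale(p, hp) else variant$scale
  variant_eff <- model_variant(variant$tag, scale)

  rhs_fun <- if (reactions) {
    function(t, yy, parms)
      list(rhs_spatial(yy, parms, grid, env, p, hp, variant_eff))
  } else {
    function(t, yy, parms) {
      Ca <- yy[1:n]; Na <- yy[n + 1:n]
      list(c(grid$D_Ca * .laplacian(Ca, grid),
             grid$D_Na * .laplacian(Na, grid),
             numeric(n)))
    }
  }
  bks <- protocol_breakpoints(protocol, t_span)
  out <- NULL
  for (k in seq_len(length(bks) - 1)) {
    stim <- if (reactions)
      .protocol_flux_spatial(protocol, (bks[k] + bks[k + 1]) / 2, grid)
    else list(Ca = numeric(n), Na = numeric(n))
    tt <- seq(bks[k], bks[k + 1], by = dt_out)
    if (tt[length(tt)] < bks[k + 1]) tt <- c(tt, bks[k + 1])
    seg <- deSolve::ode.1D(y = y, times = tt, func = rhs_fun, parms = stim,
                           nspec = 3, dimens = n, method = "lsoda",
                           rtol = rtol, atol = atol)
    if (attr(seg, "istate")[1] < 0)
      stop(sprintf("spatial integration failed at t = %.6g",
                   seg[nrow(seg), 1]), call. = FALSE)
    y <- seg[nrow(seg), -1]
    out <- rbind(out, seg[if (is.null(out)) TRUE else -1, , drop = FALSE])
  }
  Ca <- out[, 1 + 1:n, drop = FALSE]
  Na <- out[, 1 + n + 1:n, drop = FALSE]
  if (any(Ca <= 0) || any(Na <= 0))
    stop("integrator produced non-positive concentrations; refusing to clip",
         call. = FALSE)
  structure(list(t = out[, 1], x = grid$x, Ca = unname(Ca),
                 Na = unname(Na),
                 h = unname(out[, 1 + 2 * n + 1:n, drop = FALSE])),
            class = "ncx_field", grid = grid, rest_state = rest,
            variant = variant_eff)
}

#' Superposition (amplification) field
#'
#' Runs the joint protocol and the two single-species controls on the same
#' grid and returns the space-time field
#' `Ca(joint) - [Ca(ca_only) + Ca(na_only) - Ca_rest]`. Positive values mark
#' supra-linear amplification of the calcium response by the sodium pulse.
#'
#' @param grid a [spatial_grid()].
#' @param ca_protocol,na_protocol the two single-species protocols; their
#'   union (row-bind) is the joint protocol.
#' @param t_span time span (s).
#' @param ... passed to [simulate_wave()] (parameters, variant, solver).
#' @return A list with `t`, `x`, `amplification` (matrix), and the three
#'   component fields `joint`, `ca_only`, `na_only`.
#' @export
superposition_comparison <- function(grid, ca_protocol, na_protocol, t_span,
                                     ...) {
  joint <- stim_protocol(rbind(as.data.frame(ca_protocol),
                               as.data.frame(na_protocol)))
  fj <- simulate_wave(grid, joint, t_span, ...)
  fc <- simulate_wave(grid, ca_protocol, t_span, ...)
  fn <- simulate_wave(grid, na_protocol, t_span, ...)
  base <- attr(fj, "rest_state")[["Ca"]]
  list(t = fj$t, x = fj$x,
       amplification = fj$Ca - (fc$Ca + fn$Ca - base),
       joint = fj, ca_only = fc, na_only = fn)
}

#' Half-maximum extent of a spatial profile
#'
#' Distance from the origin to the outermost point, on each side, where the
#' profile stays above baseline plus half its peak elevation (linear
#' interpolation between elements).
#'
#' @param profile concentration profile over `x`.
#' @param x element centres (um), containing 0.
#' @param baseline reference level.
#' @return Named numeric `c(left, right)` (um, both positive).
#' @export
half_max_extent <- function(profile, x, baseline) {
  profile <- as.numeric(profile)
  ctr <- which.min(abs(x))
  pk <- max(profile) - baseline
  if (pk <= 0) return(c(left = 0, right = 0))
  lvl <- baseline + pk / 2
  iR <- ctr
  while (iR < length(x) && profile[iR + 1] >= lvl) iR <- iR + 1
  right <- if (iR == length(x)) x[iR] else
    x[iR] + (lvl - profile[iR]) / (profile[iR + 1] - profile[iR]) *
      (x[iR + 1] - x[iR])
  iL <- ctr
  while (iL > 1 && profile[iL - 1] >= lvl) iL <- iL - 1
  left <- if (iL == 1) x[iL] else
    x[iL] + (lvl - profile[iL]) / (profile[iL - 1] - profile[iL]) *
      (x[iL - 1] - x[iL])
  c(left = -left, right = right)
}

#' Total ion content of a field
#'
#' Sum of a species over elements times `dx`, per output time; constant in
#' diffusion-only runs with sealed boundaries.
#'
#' @param field an `ncx_field` from [simulate_wave()].
#' @param species `"Ca"` or `"Na"`.
#' @return Numeric vector, one total (mM um) per stored time.
#' @export
total_content <- function(field, species = c("Ca", "Na")) {
  species <- match.arg(species)
  rowSums(field[[species]]) * attr(field, "grid")$dx
}

#' Explicit-Euler diffusion stability bound
#'
#' For the optional fixed-step explicit mode: the forward-Euler diffusion
#' limit `dt <= dx^2 / (2 max(D))`. [simulate_wave_explicit()] refuses any
#' larger step.
#'
#' @param grid a [spatial_grid()].
#' @return Maximal admissible explicit time step (s).
#' @export
explicit_dt_limit <- function(grid) {
  Dmax <- max(grid$D_Ca, grid$D_Na)
  if (Dmax == 0) Inf else grid$dx^2 / (2 * Dmax)
}

#' Fixed-step explicit integration of the 1D model
#'
#' Forward-Euler method of lines; intended for cross-checks of the stiff
#' solver on short horizons, not for production runs. The step must satisfy
#' [explicit_dt_limit()].
#'
#' @inheritParams simulate_wave
#' @param dt fixed time step (s).
#' @return As [simulate_wave()].
#' @export
simulate_wave_explicit <- function(grid, protocol, t_span, dt,
                                   env = cell_env(), p = ncx_params(),
                                   hp = homeostasis_params(),
                                   variant = model_variant("point_full"),
                                   dt_out = 0.5) {
  lim <- explicit_dt_limit(grid)
  if (dt > lim)
    stop(sprintf(
      "explicit step dt = %g violates the diffusion stability bound %g",
      dt, lim), call. = FALSE)
  n <- grid$n
  rest <- find_rest_state(variant, env, p, hp)
  y <- c(rep(rest[["Ca"]], n), rep(rest[["Na"]], n), rep(rest[["h"]], n))
  times <- seq(t_span[1], t_span[2], by = dt)
  keep_every <- max(1L, round(dt_out / dt))
  rec_t <- c(); rec <- NULL
  for (i in seq_along(times)) {
    t <- times[i]
    if ((i - 1L) %% keep_every == 0L) {
      rec_t <- c(rec_t, t); rec <- rbind(rec, y)
    }
    stim <- .protocol_flux_spatial(protocol, t, grid)
    y <- y + dt * rhs_spatial(y, stim, grid, env, p, hp, variant)
  }
  structure(list(t = rec_t, x = grid$x,
                 Ca = unname(rec[, 1:n, drop = FALSE]),
                 Na = unname(rec[, n + 1:n, drop = FALSE]),
                 h = unname(rec[, 2 * n + 1:n, drop = FALSE])),
            class = "ncx_field", grid = grid, rest_state = rest,
            variant = variant)
}
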