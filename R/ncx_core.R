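# Core NCX flux model: electrochemical cycle plus two allosteric gates.
#
# The exchanger moves 3 Na+ against 1 Ca2+ per cycle. The net Ca2+ flux is
#
#   J_ncx = Jbar * n_inf(Ca_i) * h * J_dE(Ca_i, Na_i, V)
#
# where J_dE is the normalized net rate of the ping-pong bi-bi transport
# cycle (sign > 0: reverse mode, Ca2+ entry; < 0: forward mode, Ca2+ exit),
# n_inf is the instantaneous high-affinity Ca2+ activation gate, and h is
# the slow gate tracking Na+-dependent inactivation relieved by Ca2+ at the
# low-affinity site.
#
# All functions are vectorized over the state arguments and reject negative
# concentrations rather than clipping them: a negative concentration always
# indicates an integrator or caller failure that must surface.

.check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be finite and non-negative", name), call. = FALSE)
  invisible(x)
}

.check_pos <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be finite and strictly positive", name),
         call. = FALSE)
  invisible(x)
}

#' Instantaneous high-affinity calcium activation gate
#'
#' Steady-state occupancy of the fast, high-affinity cytosolic Ca2+
#' regulatory site: `n_inf = 1 / (1 + (Kn/Ca_i)^2)`. The gate is treated as
#' instantaneous because its kinetics are an order of magnitude faster than
#' the slow gate's.
#'
#' @param Ca_i internal calcium (mM), >= 0 (vectorized).
#' @param p an [ncx_params()] object.
#' @return Gate value(s) in \[0, 1\]; 0 at `Ca_i = 0`, 1/2 at `Ca_i = Kn`.
#' @export
n_inf <- function(Ca_i, p) {
  .check_nonneg(Ca_i, "Ca_i")
  Ca_i^2 / (Ca_i^2 + p$Kn^2)
}

#' Steady state of the slow gate
#'
#' Fraction of exchangers not Na+-inactivated at equilibrium:
#' `h_inf = 1 - [1/(1+(Ca_i/KCa)^HCa)] * [1/(1+(KNa/Na_i)^HNa)]`.
#' Internal Na+ drives inactivation (second factor); internal Ca2+ binding
#' at the low-affinity site relieves it (first factor).
#'
#' @param Ca_i,Na_i internal concentrations (mM), >= 0 (vectorized).
#' @param p an [ncx_params()] object.
#' @return Gate steady state in \[0, 1\]; 1 at `Na_i = 0` or `Ca_i -> Inf`.
#' @export
h_inf <- function(Ca_i, Na_i, p) {
  .check_nonneg(Ca_i, "Ca_i")
  .check_nonneg(Na_i, "Na_i")
  ca_term <- 1 / (1 + (Ca_i / p$KCa)^p$HCa)
  # (KNa/0)^HNa = Inf -> block factor 0, so h_inf(., 0) = 1 exactly
  na_term <- 1 / (1 + (p$KNa / Na_i)^p$HNa)
  na_term[Na_i == 0] <- 0
  1 - ca_term * na_term
}

#' Calcium-dependent time constant of the slow gate
#'
#' `tau_h = tau_min + tau0 / (1 + (Ca_i/Ktau)^Htau)`: slow recovery at
#' resting calcium (`tau_min + tau0`), fast at high calcium (`tau_min`,
#' 0.25 s by default).
#'
#' @inheritParams n_inf
#' @return Time constant(s) in seconds, in `(tau_min, tau_min + tau0]`.
#' @export
tau_h <- function(Ca_i, p) {
  .check_nonneg(Ca_i, "Ca_i")
  p$tau_min + p$tau0 / (1 + (Ca_i / p$Ktau)^p$Htau)
}

#' Electrochemical flux factor of the transport cycle
#'
#' Normalized net rate of the main (ping-pong bi-bi) NCX cycle:
#'
#' \deqn{J_{\Delta E} = \frac{Na_i^3\,Ca_o\,e^{\eta V F/RT} -
#'   Na_o^3\,Ca_i\,e^{(\eta-1) V F/RT}}{K_X\,(1 + k_{sat}\,
#'   e^{(\eta-1) V F/RT})}}
#'
#' with the denominator scale
#' `K_X = KM_Cao*Na_i^3 + KM_Nao^3*Ca_i + KM_Nai^3*Ca_o*(1 + Ca_i/KM_Cai)
#'  + KM_Cai*Na_o^3*(1 + Na_i^3/KM_Nai^3) + Na_i^3*Ca_o + Na_o^3*Ca_i`.
#'
#' Positive values correspond to the reverse mode (Ca2+ entry), negative to
#' the forward mode (Ca2+ extrusion). The factor vanishes exactly on the
#' reversal manifold `(Na_i/Na_o)^3 = (Ca_i/Ca_o) exp(-VF/RT)`; see
#' [reversal_na()].
#'
#' @param Ca_i,Na_i internal concentrations (mM), > 0 (vectorized).
#' @param env a [cell_env()] object.
#' @param p an [ncx_params()] object.
#' @return Signed dimensionless flux factor.
#' @export
j_delta_e <- function(Ca_i, Na_i, env, p) {
  .check_pos(Ca_i, "Ca_i")
  .check_pos(Na_i, "Na_i")
  vfrt <- env$V * env$F / (env$R * env$T)
  e_eta <- exp(p$eta * vfrt)
  e_eta1 <- exp((p$eta - 1) * vfrt)
  nai3 <- Na_i^3
  nao3 <- env$Na_o^3
  num <- nai3 * env$Ca_o * e_eta - nao3 * Ca_i * e_eta1
  KX <- p$KM_Cao * nai3 +
    p$KM_Nao^3 * Ca_i +
    p$KM_Nai^3 * env$Ca_o * (1 + Ca_i / p$KM_Cai) +
    p$KM_Cai * nao3 * (1 + nai3 / p$KM_Nai^3) +
    nai3 * env$Ca_o +
    nao3 * Ca_i
  num / (KX * (1 + p$ksat * e_eta1))
}

#' NCX-mediated calcium flux
#'
#' Product form `J_ncx = Jbar * n_inf(Ca_i) * h * J_dE`. Sign convention as
#' in [j_delta_e()]: positive = Ca2+ entry. The corresponding sodium flux is
#' `-3 * J_ncx` (3:1 stoichiometry).
#'
#' @inheritParams j_delta_e
#' @param h slow-gate value in \[0, 1\] (vectorized).
#' @return Calcium flux (mM/s).
#' @export
j_ncx <- function(Ca_i, Na_i, h, env, p) {
  if (any(!is.finite(h)) || any(h < 0) || any(h > 1))
    stop("'h' must be within [0, 1]", call. = FALSE)
  p$Jbar * n_inf(Ca_i, p) * h * j_delta_e(Ca_i, Na_i, env, p)
}

#' Relaxation rate of the slow gate
#'
#' `dh/dt = (h_inf(Ca_i, Na_i) - h) / tau_h(Ca_i)`.
#'
#' @inheritParams j_ncx
#' @return Time derivative of `h` (1/s).
#' @export
dh_dt <- function(h, Ca_i, Na_i, p) {
  if (any(!is.finite(h)) || any(h < 0) || any(h > 1))
    stop("'h' must be within [0, 1]", call. = FALSE)
  (h_inf(Ca_i, Na_i, p) - h) / tau_h(Ca_i, p)
}

#' Reversal locus of the exchanger
#'
#' The electrochemical factor changes sign where the free energy of one
#' cycle vanishes, i.e. where `(Na_i/Na_o)^3 = (Ca_i/Ca_o) exp(-VF/RT)`.
#' `reversal_na()` returns the internal sodium at reversal for given
#' internal calcium; `reversal_ca()` the internal calcium at reversal for
#' given internal sodium. Below `reversal_ca` (or above `reversal_na`) the
#' exchanger runs in reverse mode (Ca2+ entry).
#'
#' @param Ca_i,Na_i internal concentration (mM), > 0.
#' @param env a [cell_env()] object.
#' @return Concentration (mM) on the reversal manifold.
#' @export
reversal_na <- function(Ca_i, env) {
  .check_pos(Ca_i, "Ca_i")
  vfrt <- env$V * env$F / (env$R * env$T)
  env$Na_o * ((Ca_i / env$Ca_o) * exp(-vfrt))^(1 / 3)
}

#' @rdname reversal_na
#' @export
reversal_ca <- function(Na_i, env) {
  .check_pos(Na_i, "Na_i")
  vfrt <- env$V * env$F / (env$R * env$T)
  env$Ca_o * (Na_i / env$Na_o)^3 * exp(vfrt)
}
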