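# Parameter containers and validation.
#
# All concentrations are in mM, times in seconds, fluxes in mM/s. Membrane
# potential is given in mV at the interface and stored in volts (field `V`),
# so that V*F/(R*T) is dimensionless; this is the single unit-conversion
# point in the package.

#' Physical constants
#'
#' Faraday constant (C/mol) and molar gas constant (J/(mol K)), CODATA values.
#' @keywords internal
#' @name physical-constants
NULL

.FARADAY <- 96485.33212
.RGAS <- 8.314462618

.ncx_fields <- c("Jbar", "KM_Cao", "KM_Nao", "KM_Nai", "KM_Cai", "eta",
                 "ksat", "Kn", "KCa", "HCa", "KNa", "HNa",
                 "tau0", "Ktau", "Htau", "tau_min")

.check_num <- function(x, name, lower = -Inf, upper = Inf,
                       strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g (got %g)", name, lower, x), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g (got %g)", name, lower, x), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g (got %g)", name, upper, x), call. = FALSE)
  invisible(x)
}

#' Shipped default parameter file
#'
#' Path of the versioned YAML file with the package's default NCX, environment
#' and homeostasis parameters, including provenance notes for every value.
#'
#' @return Path to the installed `default_params.yaml`.
#' @export
default_param_file <- function() {
  system.file("extdata", "default_params.yaml", package = "ncxdyn",
              mustWork = TRUE)
}

.default_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- yaml::read_yaml(default_param_file())
    cache
  }
})

#' NCX kinetic and allosteric parameters
#'
#' Constructs the full parameter set of the exchanger flux model: the maximal
#' flux scale `Jbar`, the Michaelis constants and electrochemical shape
#' parameters of the main transport cycle, and the constants of the two
#' allosteric calcium-regulatory gates (fast high-affinity gate `n`, slow
#' low-affinity gate `h` with sodium-dependent inactivation).
#'
#' Any subset of fields can be overridden; unspecified fields come from the
#' shipped default parameter file (see [default_param_file()]).
#'
#' @param ... named overrides of parameter fields. Valid names:
#'   `Jbar` (mM/s), `KM_Cao`, `KM_Nao`, `KM_Nai`, `KM_Cai` (mM),
#'   `eta` (in \[0,1\]), `ksat` (>= 0), `Kn`, `KCa`, `KNa`, `Ktau` (mM),
#'   `HCa`, `HNa`, `Htau` (Hill coefficients >= 1), `tau0`, `tau_min` (s).
#' @return An object of class `ncx_params`.
#' @examples
#' p <- ncx_params()           # shipped defaults
#' p2 <- ncx_params(Jbar = 0.05)
#' @export
ncx_params <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  p <- .default_config()$ncx
  unknown <- setdiff(names(over), .ncx_fields)
  if (length(unknown))
    stop("unknown ncx_params field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(over)] <- over
  p <- lapply(p, as.numeric)
  for (f in c("KM_Cao", "KM_Nao", "KM_Nai", "KM_Cai",
              "Kn", "KCa", "KNa", "tau0", "Ktau", "tau_min"))
    .check_num(p[[f]], f, lower = 0, strict_lower = TRUE)
  # Jbar = 0 is admitted as the exchanger-disabled control
  .check_num(p$Jbar, "Jbar", lower = 0)
  .check_num(p$eta, "eta", lower = 0, upper = 1)
  .check_num(p$ksat, "ksat", lower = 0)
  for (f in c("HCa", "HNa", "Htau")) .check_num(p[[f]], f, lower = 1)
  structure(p[.ncx_fields], class = "ncx_params")
}

#' Ionic environment and membrane potential
#'
#' Extracellular ion concentrations, membrane potential and temperature.
#' The potential is supplied in millivolts and stored in volts (`$V`)
#' together with the Faraday and gas constants, so downstream code uses the
#' dimensionless ratio `V*F/(R*T)` directly.
#'
#' @param Ca_o extracellular calcium (mM).
#' @param Na_o extracellular sodium (mM).
#' @param V_mV membrane potential (mV).
#' @param T absolute temperature (K).
#' @return An object of class `cell_env` with fields `Ca_o`, `Na_o`, `V`
#'   (volts), `T`, `F`, `R`.
#' @examples
#' env <- cell_env()              # defaults: 2 mM Ca, 140 mM Na, -80 mV, 310 K
#' dep <- cell_env(V_mV = -60)    # depolarized
#' @export
cell_env <- function(Ca_o = NULL, Na_o = NULL, V_mV = NULL, T = NULL) {
  d <- .default_config()$environment
  Ca_o <- if (is.null(Ca_o)) d$Ca_o else Ca_o
  Na_o <- if (is.null(Na_o)) d$Na_o else Na_o
  V_mV <- if (is.null(V_mV)) d$V_mV else V_mV
  T    <- if (is.null(T)) d$T else T
  .check_num(Ca_o, "Ca_o", lower = 0, strict_lower = TRUE)
  .check_num(Na_o, "Na_o", lower = 0, strict_lower = TRUE)
  .check_num(V_mV, "V_mV")
  .check_num(T, "T", lower = 0, strict_lower = TRUE)
  structure(list(Ca_o = as.numeric(Ca_o), Na_o = as.numeric(Na_o),
                 V = as.numeric(V_mV) / 1000, T = as.numeric(T),
                 F = .FARADAY, R = .RGAS),
            class = "cell_env")
}

#' Resting-state homeostasis parameters
#'
#' Lumped linear relaxation terms standing in for the calcium pump (plus
#' buffering, in the excess-buffer approximation) and the Na/K-pump: each ion
#' relaxes to its resting concentration with a single time constant.
#'
#' @param Ca_rest resting internal calcium (mM).
#' @param tau_Ca calcium equilibration time (s).
#' @param Na_rest resting internal sodium (mM).
#' @param tau_Na sodium equilibration time (s).
#' @return An object of class `homeostasis_params`.
#' @export
homeostasis_params <- function(Ca_rest = NULL, tau_Ca = NULL,
                               Na_rest = NULL, tau_Na = NULL) {
  d <- .default_config()$homeostasis
  vals <- list(
    Ca_rest = if (is.null(Ca_rest)) d$Ca_rest else Ca_rest,
    tau_Ca  = if (is.null(tau_Ca)) d$tau_Ca else tau_Ca,
    Na_rest = if (is.null(Na_rest)) d$Na_rest else Na_rest,
    tau_Na  = if (is.null(tau_Na)) d$tau_Na else tau_Na)
  for (f in names(vals)) .check_num(vals[[f]], f, lower = 0,
                                    strict_lower = TRUE)
  structure(lapply(vals, as.numeric), class = "homeostasis_params")
}

#' Dynamical state at a point
#'
#' @param Ca_i internal calcium (mM), > 0.
#' @param Na_i internal sodium (mM), > 0.
#' @param h fraction of exchangers not sodium-inactivated, in \[0,1\].
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(Ca_i, Na_i, h) {
  .check_num(Ca_i, "Ca_i", lower = 0, strict_lower = TRUE)
  .check_num(Na_i, "Na_i", lower = 0, strict_lower = TRUE)
  .check_num(h, "h", lower = 0, upper = 1)
  structure(list(Ca_i = as.numeric(Ca_i), Na_i = as.numeric(Na_i),
                 h = as.numeric(h)), class = "cell_state")
}

#' @export
print.ncx_params <- function(x, ...) {
  cat("NCX parameters (mM, s):\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.cell_env <- function(x, ...) {
  cat(sprintf(
    "Environment: Ca_o = %g mM, Na_o = %g mM, V = %g mV, T = %g K\n",
    x$Ca_o, x$Na_o, x$V * 1000, x$T))
  invisible(x)
}

#' @export
print.homeostasis_params <- function(x, ...) {
  cat(sprintf(
    "Homeostasis: Ca_rest = %g mM (tau %g s), Na_rest = %g mM (tau %g s)\n",
    x$Ca_rest, x$tau_Ca, x$Na_rest, x$tau_Na))
  invisible(x)
}
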