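# Named experiments: reproducible runs of the shipped presets with their
# derived metrics. These are thin drivers over integrate_model() /
# simulate_wave(); all numbers they report are recomputed from the stored
# series at call time.

.scale_protocol <- function(protocol, factor) {
  pl <- as.data.frame(protocol)
  pl$amplitude <- pl$amplitude * factor
  stim_protocol(pl)
}

#' Run the paired short-pulse experiment
#'
#' Simulates the joint, Ca-only and Na-only protocols of [preset_fig2a()]
#' with the chosen model variant and computes the per-event amplification
#' indices and transient metrics.
#'
#' @param variant a [model_variant()] (full model by default; use
#'   `model_variant("point_no_allostery")` for the control).
#' @param amplitude_scale factor applied to every pulse amplitude (the
#'   preset's `small_pulse_scale` gives the small-pulse linearity family).
#' @param env,p,hp model parameters.
#' @param dt_out,rtol,atol solver options passed to [integrate_model()].
#' @return A list: `preset`, `series` (named list of `ncx_series`),
#'   `amplification` (relative index per event window), `metrics`
#'   (per-event [transient_metrics()] of the joint run).
#' @export
run_fig2a <- function(variant = model_variant("point_full"),
                      amplitude_scale = 1,
                      env = cell_env(), p = ncx_params(),
                      hp = homeostasis_params(),
                      dt_out = 0.25, rtol = 1e-8, atol = 1e-12) {
  pr <- preset_fig2a()
  t_span <- c(0, pr$t_end)
  runs <- lapply(list(joint = pr$joint, ca_only = pr$ca_only,
                      na_only = pr$na_only), function(pl)
    integrate_model(variant, .scale_protocol(pl, amplitude_scale), t_span,
                    env, p, hp, dt_out = dt_out, rtol = rtol, atol = atol))
  amp <- vapply(pr$event_windows, function(w)
    amplification_index(runs$joint, runs$ca_only, runs$na_only,
                        window = unlist(w)), numeric(1))
  base <- attr(runs$joint, "rest_state")[["Ca"]]
  metrics <- lapply(pr$event_windows, function(w) {
    keep <- runs$joint$t >= w[[1]] & runs$joint$t <= w[[2]]
    transient_metrics(runs$joint$t[keep], runs$joint$Ca[keep],
                      baseline = base)
  })
  list(preset = pr, series = runs, amplification = amp, metrics = metrics)
}

#' Run the long Na+-elevation experiment
#'
#' Simulates the [preset_fig2b()] amplitude ladder with the full model (and
#' optionally the allosteric-off control) and computes, for each amplitude,
#' the half-maximum duration of the calcium transient triggered by the probe
#' pulse during the Na+ elevation, and whether the response is sustained
#' (calcium above twice the rest level from shortly after the probe until
#' Na+ offset).
#'
#' @param variant a [model_variant()].
#' @param env,p,hp model parameters.
#' @param dt_out,rtol,atol solver options.
#' @return A list: `preset`, `series` (one `ncx_series` per amplitude),
#'   `ca_only` (probe pulses without Na+), and `summary` data.frame
#'   `(na_amplitude, half_width, peak, sustained)`.
#' @export
run_fig2b <- function(variant = model_variant("point_full"),
                      env = cell_env(), p = ncx_params(),
                      hp = homeostasis_params(),
                      dt_out = 0.5, rtol = 1e-8, atol = 1e-12) {
  pr <- preset_fig2b()
  t_span <- c(0, pr$t_end)
  series <- lapply(pr$protocols, function(pl)
    integrate_model(variant, pl, t_span, env, p, hp,
                    dt_out = dt_out, rtol = rtol, atol = atol))
  ca_only <- integrate_model(variant, pr$ca_only, t_span, env, p, hp,
                             dt_out = dt_out, rtol = rtol, atol = atol)
  probe_t <- min(pr$ca_only$start)          # probe during the elevation
  na_off <- pr$na_window[2]
  summary <- do.call(rbind, Map(function(a, s) {
    base <- attr(s, "rest_state")[["Ca"]]
    keep <- s$t >= probe_t - 5 & s$t <= pr$t_end
    m <- transient_metrics(s$t[keep], s$Ca[keep], baseline = base)
    hold <- s$t >= probe_t + 10 & s$t <= na_off - 10
    data.frame(na_amplitude = a, half_width = m$half_width, peak = m$peak,
               sustained = all(s$Ca[hold] > 2 * base))
  }, pr$na_amplitudes, series))
  rownames(summary) <- NULL
  list(preset = pr, series = series, ca_only = ca_only, summary = summary)
}

#' Run the 1D wave experiment
#'
#' Simulates the [preset_wave()] protocol (central Ca2+ pulse, one-sided
#' Na+ influx) together with its single-species controls, and reports the
#' half-maximum spread extents of the calcium elevation on the Na+-pulsed
#' and unpulsed sides at the preset measurement time, plus the superposition
#' (amplification) field.
#'
#' @param variant a [model_variant()].
#' @param env,p,hp model parameters.
#' @param dt_out,rtol,atol solver options.
#' @param grid optionally override the preset [spatial_grid()] (e.g. for
#'   grid-convergence checks).
#' @return A list: `preset`, `superposition` (see
#'   [superposition_comparison()]), `extent` (`c(left, right)` um at the
#'   measurement time), `measure_index` (row of the measurement time).
#' @export
run_wave <- function(variant = model_variant("point_full"),
                     env = cell_env(), p = ncx_params(),
                     hp = homeostasis_params(),
                     dt_out = 0.5, rtol = 1e-8, atol = 1e-12,
                     grid = NULL) {
  pr <- preset_wave()
  g <- if (is.null(grid)) pr$grid else grid
  sup <- superposition_comparison(
    g, pr$ca_only, pr$na_only, c(0, pr$t_end),
    env = env, p = p, hp = hp, variant = variant,
    dt_out = dt_out, rtol = rtol, atol = atol)
  i <- which.min(abs(sup$t - pr$measure_time))
  base <- attr(sup$joint, "rest_state")[["Ca"]]
  ext <- half_max_extent(sup$joint$Ca[i, ], sup$x, base)
  list(preset = pr, superposition = sup, extent = ext, measure_index = i)
}
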