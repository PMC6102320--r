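# Stimulation protocols: declarative pulse lists, shipped presets, and
# metrics for simulated transients.

#' Stimulation protocol
#'
#' A protocol is a list of boxcar flux pulses applied to the point or
#' spatial models. Each pulse injects `amplitude` (mM/s) of the given
#' species over `[start, start + duration)`; spatial pulses additionally
#' carry an interval `[x_min, x_max]` (micrometers) outside of which they do
#' not act.
#'
#' @param pulses a data.frame with columns `species` ("Ca" or "Na"),
#'   `start` (s), `duration` (s), `amplitude` (mM/s) and optionally
#'   `x_min`, `x_max` (um; `NA` for spatially uniform pulses).
#' @return The validated protocol, sorted by pulse start, of class
#'   `stim_protocol`.
#' @seealso [preset_fig2a()], [preset_fig2b()], [preset_wave()]
#' @export
stim_protocol <- function(pulses) {
  if (is.null(pulses) || nrow(as.data.frame(pulses)) == 0L)
    return(empty_protocol())
  pulses <- as.data.frame(pulses, stringsAsFactors = FALSE)
  need <- c("species", "start", "duration", "amplitude")
  miss <- setdiff(need, names(pulses))
  if (length(miss))
    stop("protocol is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(pulses$species %in% c("Ca", "Na")))
    stop("pulse species must be 'Ca' or 'Na'", call. = FALSE)
  if (any(!is.finite(pulses$start)))
    stop("pulse starts must be finite", call. = FALSE)
  if (any(!is.finite(pulses$duration)) || any(pulses$duration <= 0))
    stop("pulse durations must be > 0", call. = FALSE)
  if (any(!is.finite(pulses$amplitude)) || any(pulses$amplitude < 0))
    stop("influx pulse amplitudes must be >= 0", call. = FALSE)
  if (is.null(pulses$x_min)) pulses$x_min <- NA_real_
  if (is.null(pulses$x_max)) pulses$x_max <- NA_real_
  bad_x <- xor(is.na(pulses$x_min), is.na(pulses$x_max)) |
    (!is.na(pulses$x_min) & pulses$x_min > pulses$x_max)
  if (any(bad_x))
    stop("pulse spatial intervals must have x_min <= x_max or both NA",
         call. = FALSE)
  pulses <- pulses[order(pulses$start, pulses$species), , drop = FALSE]
  rownames(pulses) <- NULL
  structure(pulses, class = c("stim_protocol", "data.frame"))
}

#' @rdname stim_protocol
#' @export
empty_protocol <- function() {
  structure(
    data.frame(species = character(), start = numeric(),
               duration = numeric(), amplitude = numeric(),
               x_min = numeric(), x_max = numeric(),
               stringsAsFactors = FALSE),
    class = c("stim_protocol", "data.frame"))
}

#' Keep only pulses of one species
#'
#' Used to build the single-pulse control runs whose linear sum is compared
#' with the joint response.
#'
#' @param protocol a [stim_protocol()].
#' @param species `"Ca"` or `"Na"`.
#' @return A `stim_protocol` with the other species' pulses removed.
#' @export
protocol_subset <- function(protocol, species) {
  stopifnot(inherits(protocol, "stim_protocol"))
  species <- match.arg(species, c("Ca", "Na"))
  stim_protocol(protocol[protocol$species == species, , drop = FALSE])
}

# Times at which the applied flux is discontinuous; used as integration
# breakpoints so the solver never steps across a pulse edge.
protocol_breakpoints <- function(protocol, t_span) {
  bks <- c(t_span[1], t_span[2], protocol$start,
           protocol$start + protocol$duration)
  bks <- sort(unique(bks[bks >= t_span[1] & bks <= t_span[2]]))
  bks
}

# Summed flux amplitudes of all pulses active at time t (point models:
# spatial intervals are ignored). Returns c(Ca = ..., Na = ...).
protocol_flux_at <- function(protocol, t) {
  act <- protocol$start <= t & t < protocol$start + protocol$duration
  c(Ca = sum(protocol$amplitude[act & protocol$species == "Ca"]),
    Na = sum(protocol$amplitude[act & protocol$species == "Na"]))
}

.read_preset <- function(file) {
  yaml::read_yaml(system.file("extdata", file, package = "ncxdyn",
                              mustWork = TRUE))
}

#' Paired short-pulse preset (joint Na+/Ca2+ stimulation)
#'
#' Two events: short Na+ pulses of different amplitude, each paired with a
#' simultaneous short Ca2+ pulse. Returns the protocol family needed for the
#' superposition analysis: the joint protocol, the Ca-only and Na-only
#' controls (which partition the joint pulse list), and the amplitude scale
#' of the companion small-pulse family.
#'
#' @return A list with elements `name`, `joint`, `ca_only`, `na_only`
#'   (protocols), `t_end`, `event_windows` (list of two time windows, one
#'   per event) and `small_pulse_scale`.
#' @export
preset_fig2a <- function() {
  y <- .read_preset("fig2a.yaml")
  joint <- stim_protocol(do.call(rbind, lapply(y$pulses, as.data.frame)))
  list(name = y$name,
       joint = joint,
       ca_only = protocol_subset(joint, "Ca"),
       na_only = protocol_subset(joint, "Na"),
       t_end = y$t_end,
       event_windows = y$event_windows,
       small_pulse_scale = y$small_pulse_scale)
}

#' Long Na+-elevation preset
#'
#' Sustained Na+ influx over a fixed window at one of several preset
#' amplitudes, with short Ca2+ probe pulses during and after the elevation.
#'
#' @return A list with `name`, `t_end`, `na_window`, `na_amplitudes`, and
#'   `protocols`: one joint protocol per Na+ amplitude (named by amplitude),
#'   plus `ca_only` (probe pulses alone).
#' @export
preset_fig2b <- function() {
  y <- .read_preset("fig2b.yaml")
  ca <- do.call(rbind, lapply(y$ca_pulses, as.data.frame))
  ca$species <- "Ca"
  protocols <- lapply(y$na_amplitudes, function(a) {
    na <- data.frame(species = "Na", start = y$na_window[1],
                     duration = diff(unlist(y$na_window)), amplitude = a)
    stim_protocol(rbind(na, ca[names(na)]))
  })
  names(protocols) <- sprintf("na_%g", unlist(y$na_amplitudes))
  list(name = y$name, t_end = y$t_end,
       na_window = unlist(y$na_window),
       na_amplitudes = unlist(y$na_amplitudes),
       protocols = protocols,
       ca_only = stim_protocol(ca[c("species", "start", "duration",
                                    "amplitude")]))
}

#' One-dimensional wave preset
#'
#' Central Ca2+ pulse plus one-sided sustained Na+ influx on a sealed thin
#' process. See the package vignette for the rationale behind the pulse
#' timing and the diffusion constants.
#'
#' @return A list with `name`, `grid` (a [spatial_grid()]), `protocol`,
#'   `ca_only`, `na_only`, `t_end` and `measure_time`.
#' @export
preset_wave <- function() {
  y <- .read_preset("wave.yaml")
  g <- spatial_grid(length = y$grid$length, dx = y$grid$dx,
                    D_Ca = y$grid$D_Ca, D_Na = y$grid$D_Na,
                    boundary = y$grid$boundary)
  pl <- do.call(rbind, lapply(y$pulses, function(pu) {
    data.frame(species = pu$species, start = pu$start,
               duration = pu$duration, amplitude = pu$amplitude,
               x_min = pu$x[[1]], x_max = pu$x[[2]])
  }))
  joint <- stim_protocol(pl)
  list(name = y$name, grid = g, protocol = joint,
       ca_only = protocol_subset(joint, "Ca"),
       na_only = protocol_subset(joint, "Na"),
       t_end = y$t_end, measure_time = y$measure_time)
}

#' Transient metrics of a calcium time series
#'
#' Peak above baseline, full width at half of the peak-above-baseline
#' (linear interpolation between samples) and the time integral above
#' baseline. A series that never returns to within 5% of its peak excursion
#' above baseline by the end of the window is flagged `bounded = FALSE` and
#' its width is measured to the window edge.
#'
#' @param time,value numeric vectors of equal length (s, mM).
#' @param baseline reference level; defaults to the first sample.
#' @return A list: `peak` (mM above baseline), `half_width` (s),
#'   `integral` (mM s), `bounded` (logical).
#' @export
transient_metrics <- function(time, value, baseline = value[1]) {
  stopifnot(length(time) == length(value), length(time) >= 2)
  dev <- value - baseline
  pk <- max(dev)
  if (pk <= 0)
    return(list(peak = 0, half_width = 0, integral = 0, bounded = TRUE))
  half <- pk / 2
  above <- dev >= half
  # outermost crossings around the global maximum, interpolated
  imax <- which.max(dev)
  i0 <- imax
  while (i0 > 1 && above[i0 - 1]) i0 <- i0 - 1
  i1 <- imax
  while (i1 < length(dev) && above[i1 + 1]) i1 <- i1 + 1
  t_lo <- if (i0 == 1) time[1] else
    time[i0 - 1] + (half - dev[i0 - 1]) / (dev[i0] - dev[i0 - 1]) *
      (time[i0] - time[i0 - 1])
  t_hi <- if (i1 == length(dev)) time[length(dev)] else
    time[i1] + (half - dev[i1]) / (dev[i1 + 1] - dev[i1]) *
      (time[i1 + 1] - time[i1])
  integ <- sum(diff(time) * (pmax(dev[-1], 0) + pmax(dev[-length(dev)], 0)) / 2)
  bounded <- dev[length(dev)] <= 0.05 * pk
  list(peak = pk, half_width = t_hi - t_lo, integral = integ,
       bounded = bounded)
}

#' Amplification index of a joint response
#'
#' Compares the joint response with the linear sum of the single-species
#' responses: `peak(joint) - peak(ca_only + na_only - baseline)`, optionally
#' normalized by the joint peak excursion. Positive values indicate
#' supra-linear amplification.
#'
#' @param joint,ca_only,na_only `ncx_series` objects from [integrate_model()]
#'   run over the same time grid from the same rest state.
#' @param window optional time window `c(t0, t1)` restricting the comparison.
#' @param relative if `TRUE` (default) return the index as a fraction of the
#'   joint peak excursion above baseline.
#' @return Signed scalar amplification index.
#' @export
amplification_index <- function(joint, ca_only, na_only, window = NULL,
                                relative = TRUE) {
  stopifnot(all(abs(joint$t - ca_only$t) < 1e-9),
            all(abs(joint$t - na_only$t) < 1e-9))
  base <- attr(joint, "rest_state")[["Ca"]]
  keep <- if (is.null(window)) rep(TRUE, length(joint$t)) else
    joint$t >= window[1] & joint$t <= window[2]
  lin <- ca_only$Ca + na_only$Ca - base
  pk_joint <- max(joint$Ca[keep])
  idx <- pk_joint - max(lin[keep])
  if (relative) idx / (pk_joint - base) else idx
}

#' Sodium deflection caused by a calcium pulse
#'
#' Measures the NCX-mediated deflection of internal Na+ attributable to a
#' Ca2+ pulse by comparing the run against a matched control in which the
#' Ca2+ pulse is withheld (all other pulses identical). The raw trace is not
#' used as its own reference because the homeostatic relaxation toward the
#' Na+ plateau dominates the pre/post difference and would mask the
#' exchanger's contribution.
#'
#' Under Na+-loaded, reverse-mode conditions the extra Ca2+ entry removes
#' Na+ (deflection < 0); at resting Na+ the exchanger extrudes the pulse in
#' forward mode and imports Na+ (small deflection > 0).
#'
#' @param with_pulse,without_pulse `ncx_series` over the same time grid.
#' @param window time window `c(t0, t1)` over which to evaluate (typically
#'   from pulse onset to a few tens of seconds after it).
#' @return Signed deflection (mM): the largest-magnitude difference
#'   `Na(with) - Na(without)` in the window.
#' @export
sodium_drop_check <- function(with_pulse, without_pulse, window) {
  stopifnot(all(abs(with_pulse$t - without_pulse$t) < 1e-9))
  keep <- with_pulse$t >= window[1] & with_pulse$t <= window[2]
  d <- with_pulse$Na[keep] - without_pulse$Na[keep]
  d[which.max(abs(d))]
}
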