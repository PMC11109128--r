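# Stimulus protocols: a source shape + irradiance + pulse timing.

#' Define a stimulation protocol
#'
#' A protocol couples a light-source shape with a stimulus irradiance and
#' square-pulse timing.  Light enters the models only through the effective
#' photon flux, which is piecewise constant in time: `flux` during pulses,
#' 0 otherwise.
#'
#' @param source A `light_spectrum` (shape; any absolute scale is ignored)
#'   or a source kind string accepted by [light_source()].
#' @param irradiance Stimulus irradiance in W mm^-2 (see [set_irradiance()]
#'   for what this means for broadband sources).
#' @param onset Light-on time of the first pulse (ms).
#' @param width Pulse width (ms).
#' @param frequency Pulse rate in Hz; 0 means a single pulse.
#' @param n_pulses Number of pulses when `frequency > 0`.
#' @param duration Total simulated time (ms); defaults to the end of the
#'   last pulse plus `tail`.
#' @param tail Dark time simulated after the last pulse (ms).
#' @param irradiance_mode `"band"` (default) or `"integrated"`, see
#'   [set_irradiance()].
#' @param ref_band Reference bandwidth (nm) for the band convention.
#' @return An object of class `stimulus_protocol`.
#' @export
#' @examples
#' stimulus_protocol("white", irradiance = 1e-7, width = 1000)
stimulus_protocol <- function(source, irradiance, onset = 10, width = 1000,
                              frequency = 0, n_pulses = 1, duration = NULL,
                              tail = 300,
                              irradiance_mode = c("band", "integrated"),
                              ref_band = 20) {
  if (is.character(source)) source <- light_source(source)
  stopifnot(inherits(source, "light_spectrum"),
            is.numeric(irradiance), irradiance >= 0,
            width > 0, onset >= 0, n_pulses >= 1)
  irradiance_mode <- match.arg(irradiance_mode)
  if (frequency > 0) {
    period <- 1000 / frequency
    if (width > period)
      stop("pulse width exceeds the pulse period", call. = FALSE)
    starts <- onset + (seq_len(n_pulses) - 1) * period
  } else {
    n_pulses <- 1
    starts <- onset
  }
  last_end <- starts[length(starts)] + width
  if (is.null(duration)) duration <- last_end + tail
  if (duration < last_end)
    stop("pulses do not fit within total_duration", call. = FALSE)
  structure(list(source = source, irradiance = irradiance, onset = onset,
                 width = width, frequency = frequency, n_pulses = n_pulses,
                 duration = duration, pulse_starts = starts,
                 irradiance_mode = irradiance_mode, ref_band = ref_band),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> %s, %.3g W mm^-2 (%s), %d pulse(s) of %g ms%s, %g ms total\n",
    attr(x$source, "kind"), x$irradiance, x$irradiance_mode, x$n_pulses,
    x$width,
    if (x$frequency > 0) sprintf(" at %g Hz", x$frequency) else "",
    x$duration))
  invisible(x)
}

# Piecewise-constant timeline: data.frame(t0, t1, on)
stim_segments <- function(stim) {
  stopifnot(inherits(stim, "stimulus_protocol"))
  edges <- sort(unique(c(0, stim$pulse_starts,
                         stim$pulse_starts + stim$width, stim$duration)))
  edges <- edges[edges <= stim$duration]
  t0 <- edges[-length(edges)]
  t1 <- edges[-1]
  mid <- (t0 + t1) / 2
  on <- vapply(mid, function(m)
    any(m >= stim$pulse_starts & m < stim$pulse_starts + stim$width),
    logical(1))
  data.frame(t0 = t0, t1 = t1, on = on)
}

# Effective photon flux of the protocol's light-on plateau for one opsin.
stimulus_flux <- function(stim, opsin) {
  stopifnot(inherits(stim, "stimulus_protocol"),
            inherits(opsin, "opsin_params"))
  stim$irradiance * flux_per_irradiance(stim$source, opsin$action_fit,
                                        mode = stim$irradiance_mode,
                                        ref_band = stim$ref_band)
}
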