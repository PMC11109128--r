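# Stimulation protocols and derived metrics: firing-rate curves, irradiance
# and pulse-width thresholds, wavelength tuning, latency, pulse-train
# fidelity and high-frequency one-spike-per-pulse limits.
#
# All threshold searches are log-space bisections after a decade pre-scan,
# to 2% relative tolerance (thresholds are reported to two significant
# figures); the returned value is the upper bracket end, i.e. the smallest
# irradiance/width known to satisfy the criterion, so the bracketing
# property "value passes, 0.9x value fails" holds.

.bisect_log <- function(pred, grid, ratio_tol = 1.02) {
  ok <- FALSE
  lo <- NA_real_; hi <- NA_real_
  for (g in grid) {
    if (pred(g)) { hi <- g; ok <- TRUE; break }
    lo <- g
  }
  if (!ok) return(NULL)
  if (is.na(lo)) return(list(value = hi, bracket = c(NA_real_, hi)))
  while (hi / lo > ratio_tol) {
    mid <- sqrt(lo * hi)
    if (pred(mid)) hi <- mid else lo <- mid
  }
  list(value = hi, bracket = c(lo, hi))
}

.threshold_result <- function(opsin, source, quantity, value, units,
                              bracket, tolerance) {
  structure(list(opsin = opsin$name,
                 source = if (is.character(source)) source
                          else attr(source, "kind"),
                 quantity = quantity, value = value, units = units,
                 bracket = bracket, tolerance = tolerance),
            class = "threshold_result")
}

.as_source <- function(source, opsin) {
  if (inherits(source, "light_spectrum")) return(source)
  if (identical(source, "led"))
    light_source("led", center = opsin$lambda_peak)
  else light_source(source)
}

#' Average firing rate versus irradiance
#'
#' Simulates a single light pulse at each irradiance and reports the
#' average firing rate (spike count during the pulse divided by the pulse
#' duration).
#'
#' @param opsin An `opsin_params` object.
#' @param source A `light_spectrum` or kind string; `"led"` uses a 20 nm
#'   band at the opsin's peak activation wavelength.
#' @param irradiances Irradiance grid in W mm^-2.
#' @param pulse_width Pulse width (ms).
#' @param rgn RGN parameters.
#' @param ... Passed to [simulate_rgn()].
#' @return Data frame with `irradiance`, `rate_Hz`, `n_spikes`; the
#'   attribute `peak` holds the irradiance of maximal rate.
#' @export
firing_vs_irradiance <- function(opsin, source,
                                 irradiances = 10^seq(-9, -4, by = 0.5),
                                 pulse_width = 1000, rgn = rgn_params(),
                                 ...) {
  src <- .as_source(source, opsin)
  rows <- lapply(irradiances, function(E) {
    st <- stimulus_protocol(src, E, width = pulse_width, tail = 50)
    sim <- simulate_rgn(opsin, st, rgn = rgn, ...)
    sp <- detect_spikes(sim)
    n <- sum(sp >= st$onset & sp <= st$onset + pulse_width)
    data.frame(irradiance = E, rate_Hz = n / (pulse_width / 1000),
               n_spikes = n)
  })
  out <- do.call(rbind, rows)
  attr(out, "peak") <- out$irradiance[which.max(out$rate_Hz)]
  out
}

#' Maximum sustained firing rate
#'
#' Sweeps irradiance upward on a half-decade grid until the average firing
#' rate over a 1 s pulse plateaus, and reports the plateau (maximum) rate.
#' The sweep stops early once the rate has stopped increasing by more than
#' 2% over two consecutive steps.
#'
#' @inheritParams firing_vs_irradiance
#' @return List with `rate_Hz`, `irradiance` (at the maximum) and the
#'   sweep `table`.
#' @export
max_firing_rate <- function(opsin, source,
                            irradiances = 10^seq(-9, -3, by = 0.5),
                            pulse_width = 1000, rgn = rgn_params(), ...) {
  src <- .as_source(source, opsin)
  rates <- numeric(0)
  used <- numeric(0)
  flat <- 0
  for (E in irradiances) {
    st <- stimulus_protocol(src, E, width = pulse_width, tail = 50)
    sim <- simulate_rgn(opsin, st, rgn = rgn, ...)
    sp <- detect_spikes(sim)
    n <- sum(sp >= st$onset & sp <= st$onset + pulse_width)
    rates <- c(rates, n / (pulse_width / 1000))
    used <- c(used, E)
    k <- length(rates)
    if (k >= 2 && rates[k - 1] > 0 &&
        rates[k] <= rates[k - 1] * 1.02) flat <- flat + 1 else flat <- 0
    if (flat >= 2) break
  }
  i <- which.max(rates)
  list(rate_Hz = rates[i], irradiance = used[i],
       table = data.frame(irradiance = used, rate_Hz = rates))
}

#' Minimum irradiance threshold (MIT) for a single spike
#'
#' Smallest irradiance at which a 1 s pulse evokes at least one action
#' potential, by decade pre-scan and log-bisection to 2% relative
#' tolerance.
#'
#' @inheritParams firing_vs_irradiance
#' @param decades Log10 pre-scan grid bounds (W mm^-2).
#' @return A `threshold_result` (value in W mm^-2), or an error if no
#'   spiking occurs within the searched range.
#' @export
minimum_irradiance_threshold <- function(opsin, source, pulse_width = 1000,
                                         rgn = rgn_params(),
                                         decades = c(-13, -3), ...) {
  src <- .as_source(source, opsin)
  pred <- function(E) {
    st <- stimulus_protocol(src, E, width = pulse_width, tail = 100)
    length(detect_spikes(simulate_rgn(opsin, st, rgn = rgn, ...))) >= 1
  }
  res <- .bisect_log(pred, 10^seq(decades[1], decades[2], by = 1))
  if (is.null(res))
    stop(opsin$name, " is non-excitable up to ",
         format(10^decades[2]), " W mm^-2 with this source", call. = FALSE)
  .threshold_result(opsin, src, "MIT", res$value, "W mm^-2",
                    res$bracket, 0.02)
}

#' Per-wavelength firing rate and irradiance threshold
#'
#' Steps a 20 nm LED across the given centre wavelengths and reports the
#' average firing rate at a fixed irradiance (and optionally the MIT) at
#' each wavelength.
#'
#' @inheritParams firing_vs_irradiance
#' @param centers LED centre wavelengths (nm).
#' @param irradiance Fixed irradiance for the rate curve (W mm^-2).
#' @param bandwidth LED bandwidth (nm).
#' @param mit If `TRUE`, also run a threshold search per wavelength.
#' @return Data frame with `wavelength`, `rate_Hz` and (if requested)
#'   `MIT_W_mm2`.
#' @export
wavelength_tuning <- function(opsin, centers = seq(390, 650, by = 20),
                              irradiance = 1e-6, pulse_width = 1000,
                              bandwidth = 20, mit = FALSE,
                              rgn = rgn_params(), ...) {
  rows <- lapply(centers, function(cw) {
    src <- light_source("led", center = cw, bandwidth = bandwidth)
    st <- stimulus_protocol(src, irradiance, width = pulse_width,
                            tail = 50)
    sim <- simulate_rgn(opsin, st, rgn = rgn, ...)
    sp <- detect_spikes(sim)
    n <- sum(sp >= st$onset & sp <= st$onset + pulse_width)
    row <- data.frame(wavelength = cw,
                      rate_Hz = n / (pulse_width / 1000))
    if (mit) {
      row$MIT_W_mm2 <- tryCatch(
        minimum_irradiance_threshold(opsin, src, pulse_width = pulse_width,
                                     rgn = rgn, ...)$value,
        error = function(e) NA_real_)
    }
    row
  })
  do.call(rbind, rows)
}

#' First-spike latency
#'
#' Time from light onset to the first detected spike.
#'
#' @inheritParams firing_vs_irradiance
#' @param irradiance Stimulus irradiance (W mm^-2), at or above the MIT.
#' @return Latency in ms, or `NA` if no spike occurs.
#' @export
first_spike_latency <- function(opsin, source, irradiance,
                                pulse_width = 1000, rgn = rgn_params(),
                                ...) {
  src <- .as_source(source, opsin)
  st <- stimulus_protocol(src, irradiance, width = pulse_width, tail = 50)
  sp <- detect_spikes(simulate_rgn(opsin, st, rgn = rgn, ...))
  if (length(sp) == 0) return(NA_real_)
  sp[1] - st$onset
}

# Per-pulse spike counts for a pulse train (spikes assigned to the period
# window of each pulse).
.train_counts <- function(opsin, src, irradiance, pulse_width, frequency,
                          n_pulses, rgn, ...) {
  period <- 1000 / frequency
  st <- stimulus_protocol(src, irradiance, width = pulse_width,
                          frequency = frequency, n_pulses = n_pulses,
                          tail = period - pulse_width)
  sp <- detect_spikes(simulate_rgn(opsin, st, rgn = rgn, ...))
  starts <- st$pulse_starts
  vapply(starts, function(s) sum(sp >= s & sp < s + period), integer(1))
}

#' Spike probability under pulsed stimulation
#'
#' Fraction of pulses in a train that evoke at least one spike within their
#' own period; extra (doublet) spikes are tracked separately.
#'
#' @inheritParams first_spike_latency
#' @param pulse_width Pulse width (ms).
#' @param frequency Pulse rate (Hz).
#' @param n_pulses Number of pulses.
#' @return List with `probability` (in `[0, 1]`), `spikes_per_pulse`
#'   (integer vector) and `extra_spikes` (total beyond one per pulse).
#' @export
pulse_train_fidelity <- function(opsin, source, irradiance, pulse_width = 5,
                                 frequency = 10, n_pulses = 10,
                                 rgn = rgn_params(), ...) {
  src <- .as_source(source, opsin)
  cnt <- .train_counts(opsin, src, irradiance, pulse_width, frequency,
                       n_pulses, rgn, ...)
  list(probability = mean(cnt >= 1), spikes_per_pulse = cnt,
       extra_spikes = sum(pmax(cnt - 1, 0)))
}

#' Minimum irradiance for 100% spike probability (MIT100)
#'
#' Smallest irradiance at which every pulse of a train (default 5 ms
#' pulses at 10 Hz) evokes at least one spike within its period, by decade
#' pre-scan and log-bisection to 2% relative tolerance.  Doublets do not
#' disqualify.
#'
#' @inheritParams pulse_train_fidelity
#' @param decades Log10 pre-scan bounds (W mm^-2).
#' @return A `threshold_result` (value in W mm^-2).
#' @export
mit100 <- function(opsin, source, pulse_width = 5, frequency = 10,
                   n_pulses = 10, rgn = rgn_params(),
                   decades = c(-11, -2), ...) {
  src <- .as_source(source, opsin)
  pred <- function(E)
    all(.train_counts(opsin, src, E, pulse_width, frequency, n_pulses,
                      rgn, ...) >= 1)
  res <- .bisect_log(pred, 10^seq(decades[1], decades[2], by = 1))
  if (is.null(res))
    stop(opsin$name, " cannot reach 100% spiking up to ",
         format(10^decades[2]), " W mm^-2", call. = FALSE)
  .threshold_result(opsin, src, "MIT100", res$value, "W mm^-2",
                    res$bracket, 0.02)
}

#' Minimum pulse width for 100% spike probability
#'
#' Smallest pulse width at which every pulse of a 10 Hz train at fixed
#' irradiance evokes a spike, by geometric pre-scan and log-bisection to
#' 2% relative tolerance.
#'
#' @inheritParams pulse_train_fidelity
#' @param irradiance Fixed irradiance (W mm^-2), default 0.1 uW/mm^2.
#' @return A `threshold_result` (value in ms).
#' @export
min_pulse_width <- function(opsin, source, irradiance = 1e-7,
                            frequency = 10, n_pulses = 10,
                            rgn = rgn_params(), ...) {
  src <- .as_source(source, opsin)
  period <- 1000 / frequency
  pred <- function(w)
    all(.train_counts(opsin, src, irradiance, w, frequency, n_pulses,
                      rgn, ...) >= 1)
  widths <- 0.25 * 2^(0:9)
  widths <- widths[widths <= 0.9 * period]
  res <- .bisect_log(pred, widths)
  if (is.null(res))
    stop("100% spiking not reached at any width up to ",
         max(widths), " ms", call. = FALSE)
  .threshold_result(opsin, src, "min_pulse_width", res$value, "ms",
                    res$bracket, 0.02)
}

#' High-frequency limit for one-spike-per-pulse fidelity
#'
#' For each frequency on the grid, searches irradiance (up to
#' `max_irradiance`) for exact 1:1 spiking — every pulse of a 0.2 ms train
#' evokes exactly one spike, with no extras — and returns the highest
#' frequency at which such an irradiance exists.  The irradiance search
#' first bisects for the 100%-probability threshold and then probes a short
#' ladder of multiples of it for exactness.
#'
#' @inheritParams pulse_train_fidelity
#' @param frequencies Frequency grid in Hz.
#' @param pulse_width Pulse width (ms).
#' @param max_irradiance Irradiance search cap (W mm^-2); the default is
#'   the long-exposure retinal safety bound (~0.77 mW mm^-2).
#' @return A `threshold_result` (value in Hz) with the per-frequency table
#'   in `$table`.
#' @export
max_fidelity_frequency <- function(opsin, source,
                                   frequencies = seq(10, 150, by = 10),
                                   pulse_width = 0.2, n_pulses = 10,
                                   max_irradiance = 7.7e-4,
                                   rgn = rgn_params(), ...) {
  src <- .as_source(source, opsin)
  one_freq <- function(f) {
    counts <- function(E) .train_counts(opsin, src, E, pulse_width, f,
                                        n_pulses, rgn, ...)
    pred <- function(E) all(counts(E) >= 1)
    grid <- 10^seq(-9, log10(max_irradiance), by = 1)
    if (max(grid) < max_irradiance) grid <- c(grid, max_irradiance)
    res <- .bisect_log(pred, grid, ratio_tol = 1.1)
    if (is.null(res)) return(c(ok = FALSE, E = NA_real_))
    for (mult in c(1, 1.1, 1.25, 1.5, 2, 3, 5)) {
      E <- res$value * mult
      if (E > max_irradiance) break
      if (all(counts(E) == 1)) return(c(ok = TRUE, E = E))
    }
    c(ok = FALSE, E = NA_real_)
  }
  tab <- do.call(rbind, lapply(frequencies, function(f) {
    r <- one_freq(f)
    data.frame(frequency = f, one_to_one = as.logical(r[["ok"]]),
               irradiance = r[["E"]])
  }))
  ok <- tab$frequency[tab$one_to_one]
  if (length(ok) == 0)
    stop("no 1:1 fidelity at any frequency on the grid", call. = FALSE)
  out <- .threshold_result(opsin, src, "max_frequency", max(ok), "Hz",
                           c(NA_real_, NA_real_), NA_real_)
  out$table <- tab
  out
}

#' Firing-rate adaptation over a sustained pulse
#'
#' Instantaneous rate is the reciprocal of each interspike interval
#' (assigned to its midpoint); adaptation is the percent drop from the mean
#' instantaneous rate in the first 250 ms of the pulse to that in the last
#' 250 ms.
#'
#' @inheritParams first_spike_latency
#' @param pulse_width Pulse width (ms), default 5 s.
#' @param window Averaging window at each end of the pulse (ms).
#' @param g_scale Opsin expression-level multiplier (the published
#'   protocol uses an order-lower expression, `g_scale = 0.1`).
#' @return Adaptation in percent, or `NA` if either window holds fewer
#'   than two spikes.
#' @export
firing_adaptation <- function(opsin, source, irradiance,
                              pulse_width = 5000, window = 250,
                              g_scale = 1, rgn = rgn_params(), ...) {
  src <- .as_source(source, opsin)
  st <- stimulus_protocol(src, irradiance, width = pulse_width, tail = 50)
  sp <- detect_spikes(simulate_rgn(opsin, st, rgn = rgn,
                                   g_scale = g_scale, ...))
  sp <- sp[sp >= st$onset & sp <= st$onset + pulse_width]
  if (length(sp) < 2) return(NA_real_)
  mids <- (sp[-1] + sp[-length(sp)]) / 2
  inst <- 1000 / diff(sp)
  first <- inst[mids <= st$onset + window]
  last <- inst[mids >= st$onset + pulse_width - window]
  if (length(first) < 1 || length(last) < 1) return(NA_real_)
  r1 <- mean(first); r2 <- mean(last)
  (r1 - r2) / r1 * 100
}
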