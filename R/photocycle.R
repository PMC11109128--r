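# Four-state opsin photocycle: light-dependent rates, ODEs, voltage-clamp
# photocurrent and photocurrent-level metrics.
#
# States are fractional occupancies C1 (dark ground state), O1 (high-
# conductance open), O2 (low-conductance, long-lived open) and C2 (desensit-
# ized closed); C1+O1+O2+C2 = 1 is conserved exactly by the equations.

.pc_parms <- function(opsin, phi) {
  c(opsin$Gd1, opsin$Gd2, opsin$Gr, opsin$phi_m, opsin$k1, opsin$k2,
    opsin$kf, opsin$kb, opsin$Gf0, opsin$Gb0, opsin$p, opsin$q, phi)
}

#' Light-dependent photocycle rate functions
#'
#' Hill-type saturation of the light-driven transitions:
#' `Ga1 = k1 phi^p / (phi^p + phi_m^p)` (C1 -> O1),
#' `Ga2 = k2 phi^p / (phi^p + phi_m^p)` (C2 -> O2),
#' `Gf = Gf0 + kf phi^q / (phi^q + phi_m^q)` (O1 -> O2),
#' `Gb = Gb0 + kb phi^q / (phi^q + phi_m^q)` (O2 -> O1).
#'
#' @param phi Effective photon flux (photons mm^-2 s^-1), scalar >= 0.
#' @param opsin An `opsin_params` object.
#' @return Named list with `Ga1`, `Ga2`, `Gf`, `Gb` in ms^-1.
#' @export
#' @examples
#' with(light_rates(opsin("ChRmine")$phi_m, opsin("ChRmine")),
#'      Ga1)  # k1/2 at half-saturation
light_rates <- function(phi, opsin) {
  stopifnot(inherits(opsin, "opsin_params"), is.numeric(phi),
            length(phi) == 1L)
  if (phi < 0) stop("phi must be >= 0", call. = FALSE)
  if (phi == 0) {
    hp <- hq <- 0
  } else {
    hp <- phi^opsin$p / (phi^opsin$p + opsin$phi_m^opsin$p)
    hq <- phi^opsin$q / (phi^opsin$q + opsin$phi_m^opsin$q)
  }
  list(Ga1 = opsin$k1 * hp, Ga2 = opsin$k2 * hp,
       Gf = opsin$Gf0 + opsin$kf * hq, Gb = opsin$Gb0 + opsin$kb * hq)
}

#' Photocycle time derivatives
#'
#' Rate equations of the 4-state cycle.  The desensitized-state equation is
#' `C2' = Gd2 O2 - (Ga2 + Gr) C2`, the only form consistent with occupancy
#' conservation (the four derivatives sum to zero exactly).
#'
#' @param state Numeric vector `c(C1, O1, O2, C2)`.
#' @param phi Effective photon flux (photons mm^-2 s^-1).
#' @param opsin An `opsin_params` object.
#' @return Named derivative vector (ms^-1).
#' @export
photocycle_derivatives <- function(state, phi, opsin) {
  stopifnot(length(state) == 4L)
  r <- light_rates(phi, opsin)
  C1 <- state[[1]]; O1 <- state[[2]]; O2 <- state[[3]]; C2 <- state[[4]]
  c(C1 = opsin$Gd1 * O1 - r$Ga1 * C1 + opsin$Gr * C2,
    O1 = r$Ga1 * C1 - (opsin$Gd1 + r$Gf) * O1 + r$Gb * O2,
    O2 = r$Gf * O1 - (opsin$Gd2 + r$Gb) * O2 + r$Ga2 * C2,
    C2 = opsin$Gd2 * O2 - (r$Ga2 + opsin$Gr) * C2)
}

# Segment-by-segment stiff integration against the compiled rhs.
# Returns a matrix with columns time, <state names>.
.ode_segments <- function(y0, segs, parms, phi_index, func, initfunc,
                          dt, rtol, atol) {
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    t0 <- segs$t0[i]; t1 <- segs$t1[i]
    times <- seq(t0, t1, by = dt)
    if (times[length(times)] < t1) times <- c(times, t1)
    parms[phi_index] <- if (segs$on[i]) segs$phi[i] else 0
    sol <- deSolve::ode(y = y0, times = times, func = func, parms = parms,
                        dllname = "optorgn", initfunc = initfunc,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 500000)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failed in segment [", t0, ", ", t1, "] ms",
           call. = FALSE)
    y0 <- sol[nrow(sol), -1]
    out[[i]] <- if (i == 1) sol else sol[-1, , drop = FALSE]
  }
  do.call(rbind, out)
}

#' Voltage-clamp photocurrent simulation
#'
#' Integrates the photocycle from the dark-adapted state (C1 = 1) under a
#' piecewise-constant stimulus, restarting the stiff adaptive integrator at
#' every flux discontinuity, and evaluates the photocurrent
#' `I = g_opsin (O1 + gamma O2) (V_hold - E_opsin)` in pA (negative =
#' inward at the default holding potential of -70 mV).
#'
#' @param opsin An `opsin_params` object.
#' @param stimulus A `stimulus_protocol`.
#' @param v_hold Holding potential (mV).
#' @param dt Output sampling interval (ms).
#' @param rtol,atol Solver tolerances.
#' @return A `photocurrent` object: data frame with columns `time` (ms),
#'   `current` (pA, signed), `flux` (photons mm^-2 s^-1) and the four state
#'   occupancies; attributes carry the opsin, stimulus and holding
#'   potential.
#' @export
#' @examples
#' \donttest{
#' st <- stimulus_protocol("white", 1e-7, width = 1000)
#' pc <- simulate_voltage_clamp(opsin("ChRmine"), st)
#' summary(pc)
#' }
simulate_voltage_clamp <- function(opsin, stimulus, v_hold = -70,
                                   dt = 0.1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(opsin, "opsin_params"),
            inherits(stimulus, "stimulus_protocol"))
  segs <- stim_segments(stimulus)
  segs$phi <- stimulus_flux(stimulus, opsin)
  y0 <- c(C1 = 1, O1 = 0, O2 = 0, C2 = 0)
  sol <- .ode_segments(y0, segs, .pc_parms(opsin, 0), phi_index = 13L,
                       func = "pc_derivs", initfunc = "pc_initmod",
                       dt = dt, rtol = rtol, atol = atol)
  consv <- rowSums(sol[, c("C1", "O1", "O2", "C2"), drop = FALSE])
  if (max(abs(consv - 1)) > 1e-6)
    stop("photocycle occupancy conservation violated", call. = FALSE)
  tm <- sol[, "time"]
  on <- vapply(tm, function(t)
    any(t >= stimulus$pulse_starts &
        t < stimulus$pulse_starts + stimulus$width), logical(1))
  d <- data.frame(time = tm,
                  current = opsin$g_opsin *
                    (sol[, "O1"] + opsin$gamma * sol[, "O2"]) *
                    (v_hold - opsin$E_opsin),
                  flux = ifelse(on, segs$phi[1], 0),
                  C1 = sol[, "C1"], O1 = sol[, "O1"],
                  O2 = sol[, "O2"], C2 = sol[, "C2"])
  structure(d, opsin = opsin, stimulus = stimulus, v_hold = v_hold,
            class = c("photocurrent", "data.frame"))
}

#' Photocurrent metrics: peak, plateau, kinetics
#'
#' For a single-pulse trace: `I_peak` is the maximal current magnitude
#' during light; `t_peak` the time from light-on to that maximum;
#' `I_plateau` the mean magnitude over the final 5% of the pulse;
#' `t_off` the interpolated time after light-off for the magnitude to fall
#' to 1/e of its light-off value; `adaptation_ratio` is plateau/peak (it
#' decreases with irradiance and pulse width as O2/C2 occupancy builds up).
#'
#' @param trace A `photocurrent` object (or data frame with `time` and
#'   `current`) covering the full pulse and several dark time constants
#'   after light-off.
#' @param stimulus The stimulus; defaults to the one stored in `trace`.
#' @return Named list: `I_peak` (pA), `I_plateau` (pA), `t_peak` (ms),
#'   `t_off` (ms), `adaptation_ratio`.
#' @export
photocurrent_metrics <- function(trace, stimulus = attr(trace, "stimulus")) {
  stopifnot(!is.null(stimulus))
  t_on <- stimulus$pulse_starts[1]
  t_end <- t_on + stimulus$width
  tm <- trace$time
  cur <- abs(trace$current)

  lit <- tm >= t_on & tm <= t_end
  I_peak <- max(cur[lit])
  t_peak <- tm[lit][which.max(cur[lit])] - t_on

  plat_win <- tm >= t_end - 0.05 * stimulus$width & tm <= t_end
  I_plateau <- if (sum(plat_win) >= 3) mean(cur[plat_win]) else NA_real_

  post <- which(tm >= t_end)
  t_off <- NA_real_
  if (length(post) > 2) {
    I0 <- cur[post[1]]
    tgt <- I0 / exp(1)
    below <- post[cur[post] <= tgt]
    if (length(below) > 0) {
      j <- below[1]
      t_off <- if (j == post[1]) 0 else
        stats::approx(cur[c(j - 1, j)], tm[c(j - 1, j)], xout = tgt)$y -
          t_end
    }
  }
  list(I_peak = I_peak, I_plateau = I_plateau, t_peak = t_peak,
       t_off = t_off,
       adaptation_ratio = if (is.na(I_plateau)) NA_real_ else
         I_plateau / I_peak)
}

#' @export
summary.photocurrent <- function(object, ...) {
  m <- photocurrent_metrics(object)
  structure(m, class = "summary.photocurrent")
}

#' @export
print.summary.photocurrent <- function(x, ...) {
  cat(sprintf(
    "peak %.3g pA (t_peak %.3g ms), plateau %.3g pA, t_off %.3g ms, adaptation %.3g\n",
    x$I_peak, x$t_peak, x$I_plateau, x$t_off, x$adaptation_ratio))
  invisible(x)
}

#' @export
print.photocurrent <- function(x, ...) {
  st <- attr(x, "stimulus")
  cat(sprintf("<photocurrent> %s, %s at %.3g W mm^-2, V_hold %g mV, %d samples\n",
              attr(x, "opsin")$name, attr(st$source, "kind"),
              st$irradiance, attr(x, "v_hold"), nrow(x)))
  invisible(x)
}

#' @export
plot.photocurrent <- function(x, ...) {
  graphics::plot(x$time, x$current, type = "l", xlab = "time (ms)",
                 ylab = "photocurrent (pA)", ...)
  st <- attr(x, "stimulus")
  graphics::abline(v = c(st$pulse_starts, st$pulse_starts + st$width),
                   col = "grey70", lty = 3)
  invisible(x)
}

# Peak photocurrent magnitude at a given irradiance (single pulse).
.peak_current <- function(opsin, source, irradiance, pulse_width, v_hold,
                          mode, dt = 0.2) {
  st <- stimulus_protocol(source, irradiance, width = pulse_width,
                          tail = 5, irradiance_mode = mode)
  tr <- simulate_voltage_clamp(opsin, st, v_hold = v_hold, dt = dt)
  photocurrent_metrics(tr)$I_peak
}

#' Effective power density for half-saturated photocurrent (EPD50)
#'
#' Sweeps irradiance upward in decades until the peak photocurrent
#' saturates (relative increase below 1% per decade), then root-finds on
#' log-irradiance for the irradiance at which the peak current is half the
#' saturated value, by bisection to 1% relative tolerance.
#'
#' @param opsin An `opsin_params` object.
#' @param source A `light_spectrum` or source kind string.
#' @param pulse_width Pulse width in ms.
#' @param v_hold Holding potential (mV).
#' @param irradiance_mode Irradiance convention, see [set_irradiance()].
#' @param bracket Log10 search range for irradiance (W mm^-2).
#' @return A `threshold_result` with the EPD50 in W mm^-2.
#' @export
epd50 <- function(opsin, source, pulse_width = 1000, v_hold = -70,
                  irradiance_mode = "band", bracket = c(-10, 0)) {
  if (is.character(source)) source <- light_source(source)
  f <- function(E) .peak_current(opsin, source, E, pulse_width, v_hold,
                                 irradiance_mode)
  decades <- 10^seq(bracket[1], bracket[2], by = 1)
  I <- vapply(decades, f, numeric(1))
  n <- length(I)
  if ((I[n] - I[n - 1]) / I[n] > 0.01)
    stop("photocurrent not saturated within the searched range",
         call. = FALSE)
  I_sat <- I[n]
  half <- I_sat / 2
  lo_i <- max(which(I < half)); hi_i <- min(which(I >= half))
  lo <- decades[lo_i]; hi <- decades[hi_i]
  while (hi / lo > 1.01) {
    mid <- sqrt(lo * hi)
    if (f(mid) >= half) hi <- mid else lo <- mid
  }
  structure(list(opsin = opsin$name, source = attr(source, "kind"),
                 quantity = "EPD50", value = sqrt(lo * hi),
                 units = "W mm^-2", bracket = c(lo, hi), tolerance = 0.01,
                 I_sat = I_sat),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s | %s, %s: %.4g %s (bracket %.4g-%.4g)\n",
              x$quantity, x$opsin, x$source, x$value, x$units,
              x$bracket[1], x$bracket[2]))
  invisible(x)
}
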