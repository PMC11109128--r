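# Fohlmeister-Miller-type retinal ganglion neuron model with an opsin
# photocurrent density term: membrane equation with Na, K, A-type K, Ca,
# Ca-gated K and leak currents, first-order voltage-gated kinetics, and
# intracellular Ca dynamics driving the K(Ca) conductance.

.RGAS <- 8.314462618
.FARADAY <- 96485.33212

#' Retinal ganglion neuron model parameters
#'
#' Defaults are the published constants of the soma model: maximal
#' conductances in mS cm^-2, reversal potentials in mV, capacitance in
#' uF cm^-2, Ca concentrations in mM, `tau_Ca` in ms.  `flux_factor` is the
#' printed composite 3/(2 F r) = 1.5e-5 converting Ca current density
#' (uA cm^-2) to mM ms^-1 (the cell radius r is never given separately, so
#' the composite is used verbatim).  `membrane_area` (um^2) converts the
#' whole-cell opsin conductance (nS) to a density.
#'
#' @param C_m,g_Na,g_K,g_Ca,g_KA,g_KCa_bar,g_L,E_Na,E_K,E_L Membrane
#'   constants.
#' @param Ca_e,Ca_res,Ca_diss,tau_Ca,flux_factor Ca handling constants.
#' @param T_K Temperature in kelvin.
#' @param membrane_area Membrane area in um^2.
#' @return An object of class `rgn_params`.
#' @export
rgn_params <- function(C_m = 1, g_Na = 50, g_K = 12, g_Ca = 2.2, g_KA = 36,
                       g_KCa_bar = 0.05, g_L = 0.147, E_Na = 35, E_K = -75,
                       E_L = -61, Ca_e = 1.8, Ca_res = 1e-4, Ca_diss = 1e-3,
                       tau_Ca = 50, flux_factor = 1.5e-5, T_K = 295,
                       membrane_area = 1000) {
  out <- as.list(environment())
  class(out) <- "rgn_params"
  out
}

#' Voltage-gated channel rate functions
#'
#' Evaluates the alpha/beta pairs for the six gates (Na activation m and
#' inactivation h, delayed-rectifier K activation n, Ca activation c,
#' A-type K activation a and inactivation hA).  Expressions of the form
#' `x / (exp(kx) - 1)` are evaluated by their analytic limit at the
#' removable singularity.
#'
#' @param v Membrane potential in mV (scalar or vector).
#' @return A data frame with columns `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`, `alpha_c`, `beta_c`, `alpha_a`,
#'   `beta_a`, `alpha_hA`, `beta_hA` (ms^-1).
#' @export
#' @examples
#' gating_rates(-30)$alpha_m  # removable singularity: limit value 6
gating_rates <- function(v) {
  lin_exp <- function(a, k, u) {
    ku <- k * u
    ifelse(abs(ku) < 1e-7, (a / k) * (1 - ku / 2), a * u / expm1(ku))
  }
  data.frame(
    alpha_m = lin_exp(-0.6, -0.1, v + 30),
    beta_m = 20 * exp(-0.055 * (v + 55)),
    alpha_h = 0.4 * exp(-0.05 * (v + 50)),
    beta_h = 6 / (exp(-0.1 * (v + 20)) + 1),
    alpha_n = lin_exp(-0.02, -0.1, v + 40),
    beta_n = 0.4 * exp(-0.0125 * (v + 50)),
    alpha_c = lin_exp(-0.3, -0.1, v + 13),
    beta_c = 10 * exp(-0.055 * (v + 38)),
    alpha_a = lin_exp(-0.006, -0.1, v + 90),
    beta_a = 0.1 * exp(-0.1 * (v + 30)),
    alpha_hA = 0.04 * exp(-0.05 * (v + 70)),
    beta_hA = 0.6 / (1 + exp(-0.1 * (v + 40))))
}

# Steady-state gate values x_inf = alpha/(alpha+beta) at a voltage.
.gate_inf <- function(v) {
  r <- gating_rates(v)
  c(m = r$alpha_m / (r$alpha_m + r$beta_m),
    h = r$alpha_h / (r$alpha_h + r$beta_h),
    n = r$alpha_n / (r$alpha_n + r$beta_n),
    c = r$alpha_c / (r$alpha_c + r$beta_c),
    a = r$alpha_a / (r$alpha_a + r$beta_a),
    hA = r$alpha_hA / (r$alpha_hA + r$beta_hA))
}

# Opsin conductance density in mS cm^-2 from whole-cell nS and area in um^2.
.opsin_density <- function(opsin, rgn) {
  opsin$g_opsin * 1e-6 / (rgn$membrane_area * 1e-8)
}

.rgn_parms <- function(opsin, rgn, phi, g_scale = 1) {
  c(.pc_parms(opsin, phi), opsin$gamma, opsin$E_opsin,
    .opsin_density(opsin, rgn) * g_scale,
    rgn$C_m, rgn$g_Na, rgn$g_K, rgn$g_Ca, rgn$g_KA, rgn$g_KCa_bar, rgn$g_L,
    rgn$E_Na, rgn$E_K, rgn$E_L, rgn$Ca_e, rgn$Ca_res, rgn$Ca_diss,
    rgn$tau_Ca, rgn$flux_factor, rgn$T_K)
}

#' Full model time derivatives
#'
#' Reference R implementation of the coupled membrane + photocycle system
#' (the integrators use an equivalent compiled version).  The opsin current
#' enters the membrane equation with the sign that makes illumination
#' depolarizing; `E_Ca` follows the Nernst relation from the instantaneous
#' intracellular Ca, and the K(Ca) current reverses at `E_K`.
#'
#' @param state Named numeric vector `c(V, m, h, n, c, a, hA, Ca, C1, O1,
#'   O2, C2)` (V in mV, Ca in mM).
#' @param phi Effective photon flux (photons mm^-2 s^-1).
#' @param opsin An `opsin_params` object.
#' @param rgn An `rgn_params` object.
#' @return Named derivative vector (per ms).
#' @export
rgn_derivatives <- function(state, phi, opsin, rgn = rgn_params()) {
  stopifnot(length(state) == 12L)
  V <- state[[1]]; m <- state[[2]]; h <- state[[3]]; n <- state[[4]]
  cc <- state[[5]]; a <- state[[6]]; hA <- state[[7]]; Ca <- state[[8]]
  if (Ca <= 0) stop("intracellular Ca must stay positive", call. = FALSE)
  r <- gating_rates(V)
  E_Ca <- 1000 * .RGAS * rgn$T_K / (2 * .FARADAY) * log(rgn$Ca_e / Ca)
  rca2 <- (Ca / rgn$Ca_diss)^2
  g_KCa <- rgn$g_KCa_bar * rca2 / (1 + rca2)
  I_Na <- rgn$g_Na * m^3 * h * (V - rgn$E_Na)
  I_K <- rgn$g_K * n^4 * (V - rgn$E_K)
  I_Ca <- rgn$g_Ca * cc^3 * (V - E_Ca)
  I_KA <- rgn$g_KA * a^3 * hA * (V - rgn$E_K)
  I_KCa <- g_KCa * (V - rgn$E_K)
  I_L <- rgn$g_L * (V - rgn$E_L)
  O1 <- state[[10]]; O2 <- state[[11]]
  I_opsin <- .opsin_density(opsin, rgn) * (O1 + opsin$gamma * O2) *
    (V - opsin$E_opsin)
  dpc <- photocycle_derivatives(state[9:12], phi, opsin)
  c(V = (-(I_Na + I_K + I_KA + I_Ca + I_KCa + I_L) - I_opsin) / rgn$C_m,
    m = -(r$alpha_m + r$beta_m) * m + r$alpha_m,
    h = -(r$alpha_h + r$beta_h) * h + r$alpha_h,
    n = -(r$alpha_n + r$beta_n) * n + r$alpha_n,
    c = -(r$alpha_c + r$beta_c) * cc + r$alpha_c,
    a = -(r$alpha_a + r$beta_a) * a + r$alpha_a,
    hA = -(r$alpha_hA + r$beta_hA) * hA + r$alpha_hA,
    Ca = -rgn$flux_factor * I_Ca - (Ca - rgn$Ca_res) / rgn$tau_Ca,
    dpc)
}

.rgn_state_names <- c("V", "m", "h", "n", "c", "a", "hA", "Ca",
                      "C1", "O1", "O2", "C2")

#' Ionic current densities at a given state
#'
#' Diagnostic decomposition of the membrane equation: the six ionic current
#' densities (uA cm^-2), the opsin current density, the instantaneous Ca
#' reversal potential `E_Ca` (Nernst) and the Ca-gated K conductance
#' `g_KCa` (half its maximum at `Ca = Ca_diss`).
#'
#' @inheritParams rgn_derivatives
#' @return Named list of current densities and derived quantities.
#' @export
rgn_currents <- function(state, opsin, rgn = rgn_params()) {
  stopifnot(length(state) == 12L)
  V <- state[[1]]
  Ca <- state[[8]]
  E_Ca <- 1000 * .RGAS * rgn$T_K / (2 * .FARADAY) * log(rgn$Ca_e / Ca)
  rca2 <- (Ca / rgn$Ca_diss)^2
  g_KCa <- rgn$g_KCa_bar * rca2 / (1 + rca2)
  list(
    I_Na = rgn$g_Na * state[[2]]^3 * state[[3]] * (V - rgn$E_Na),
    I_K = rgn$g_K * state[[4]]^4 * (V - rgn$E_K),
    I_Ca = rgn$g_Ca * state[[5]]^3 * (V - E_Ca),
    I_KA = rgn$g_KA * state[[6]]^3 * state[[7]] * (V - rgn$E_K),
    I_KCa = g_KCa * (V - rgn$E_K),
    I_L = rgn$g_L * (V - rgn$E_L),
    I_opsin = .opsin_density(opsin, rgn) *
      (state[[10]] + opsin$gamma * state[[11]]) * (V - opsin$E_opsin),
    E_Ca = E_Ca, g_KCa = g_KCa)
}

# Cache for dark-equilibrated initial states (keyed on the RGN parameters;
# the photocycle is inert in darkness so the opsin does not enter).
.dark_cache <- new.env(parent = emptyenv())

#' Dark-equilibrated resting state
#'
#' Integrates the autonomous dark system for `t_eq` ms starting from
#' V = -65 mV with gates at their steady-state values, Ca = 1e-4 mM and the
#' photocycle fully dark-adapted (C1 = 1); the endpoint is the initial
#' state used by every illumination protocol.  In darkness the photocycle
#' stays at C1 = 1 exactly, so the equilibrium does not depend on the
#' opsin; a dummy opsin with zero conductance is used internally.
#'
#' @param rgn An `rgn_params` object.
#' @param t_eq Equilibration time (ms).
#' @param rtol,atol Solver tolerances.
#' @return Named state vector (see [rgn_derivatives()]).
#' @export
dark_rest_state <- function(rgn = rgn_params(), t_eq = 2000,
                            rtol = 1e-8, atol = 1e-10) {
  key <- paste(unlist(rgn), t_eq, collapse = "|")
  if (!is.null(.dark_cache[[key]])) return(.dark_cache[[key]])
  op0 <- opsin("ChRmine")
  y0 <- c(V = -65, .gate_inf(-65), Ca = 1e-4,
          C1 = 1, O1 = 0, O2 = 0, C2 = 0)
  names(y0) <- .rgn_state_names
  segs <- data.frame(t0 = 0, t1 = t_eq, on = FALSE, phi = 0)
  sol <- .ode_segments(y0, segs, .rgn_parms(op0, rgn, 0, g_scale = 0),
                       phi_index = 13L, func = "rgn_derivs",
                       initfunc = "rgn_initmod", dt = t_eq / 200,
                       rtol = rtol, atol = atol)
  st <- sol[nrow(sol), -1]
  names(st) <- .rgn_state_names
  .dark_cache[[key]] <- st
  st
}

#' Simulate an opsin-expressing retinal ganglion neuron
#'
#' Joint stiff integration of the 12-dimensional system (membrane potential,
#' six gating variables, intracellular Ca, four photocycle states) from the
#' dark-equilibrated resting state, with the integration restarted at every
#' stimulus edge.
#'
#' @param opsin An `opsin_params` object.
#' @param stimulus A `stimulus_protocol`.
#' @param rgn An `rgn_params` object.
#' @param dt Output sampling interval (ms); 0.02 ms resolves spike timing.
#' @param g_scale Multiplier on the opsin conductance density (1 = nominal
#'   expression level).
#' @param rtol,atol Solver tolerances.
#' @return An `rgn_sim` object: data frame with `time` (ms), `Vm` (mV),
#'   gating variables, `Ca` (mM) and photocycle occupancies; attributes
#'   carry opsin, stimulus, and parameters.
#' @export
#' @examples
#' \donttest{
#' st <- stimulus_protocol("white", 1e-7, width = 200, tail = 50)
#' sim <- simulate_rgn(opsin("ChRmine"), st)
#' detect_spikes(sim)
#' }
simulate_rgn <- function(opsin, stimulus, rgn = rgn_params(), dt = 0.02,
                         g_scale = 1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(opsin, "opsin_params"),
            inherits(stimulus, "stimulus_protocol"))
  segs <- stim_segments(stimulus)
  segs$phi <- stimulus_flux(stimulus, opsin)
  y0 <- dark_rest_state(rgn)
  sol <- .ode_segments(y0, segs, .rgn_parms(opsin, rgn, 0, g_scale),
                       phi_index = 13L, func = "rgn_derivs",
                       initfunc = "rgn_initmod", dt = dt,
                       rtol = rtol, atol = atol)
  d <- as.data.frame(sol)
  names(d) <- c("time", "Vm", .rgn_state_names[-1])
  if (min(d$Ca) <= 0)
    stop("intracellular Ca became non-positive during the simulation",
         call. = FALSE)
  structure(d, opsin = opsin, stimulus = stimulus, rgn = rgn,
            g_scale = g_scale, class = c("rgn_sim", "data.frame"))
}

#' Detect spikes in a voltage trace
#'
#' A spike is an upward crossing of `threshold` (default 0 mV); crossings
#' closer than `dead_time` to the previous accepted spike are merged.
#' Crossing times are refined by linear interpolation between samples.
#'
#' @param x An `rgn_sim`, or a data frame with `time` and `Vm` columns.
#' @param threshold Crossing threshold (mV).
#' @param dead_time Minimum spike separation (ms).
#' @return Numeric vector of spike times (ms), possibly empty.
#' @export
detect_spikes <- function(x, threshold = 0, dead_time = 2) {
  tm <- x$time
  v <- x$Vm
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (length(up) == 0) return(numeric(0))
  times <- tm[up] + (threshold - v[up]) / (v[up + 1] - v[up]) *
    (tm[up + 1] - tm[up])
  keep <- times[1]
  if (length(times) > 1) {
    for (t in times[-1]) if (t - keep[length(keep)] >= dead_time)
      keep <- c(keep, t)
  }
  keep
}

#' @export
print.rgn_sim <- function(x, ...) {
  st <- attr(x, "stimulus")
  sp <- detect_spikes(x)
  cat(sprintf(
    "<rgn_sim> %s + %s at %.3g W mm^-2 | %g ms, %d spikes, rest %.1f mV\n",
    attr(x, "opsin")$name, attr(st$source, "kind"), st$irradiance,
    max(x$time), length(sp), x$Vm[1]))
  invisible(x)
}

#' @export
plot.rgn_sim <- function(x, ...) {
  graphics::plot(x$time, x$Vm, type = "l", xlab = "time (ms)",
                 ylab = expression(V[m] ~ "(mV)"), ...)
  st <- attr(x, "stimulus")
  graphics::abline(v = c(st$pulse_starts, st$pulse_starts + st$width),
                   col = "grey70", lty = 3)
  invisible(x)
}
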