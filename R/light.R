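# Light-source spectra and action-spectrum-weighted photon flux.

# CODATA
.planck <- 6.62607015e-34   # J s
.clight <- 2.99792458e8     # m s^-1

.trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Coarse AM1.5-like visible solar shape (synthetic approximation, unit peak
# at 550 nm).  The authors' exact spectrum is not tabulated; this fixed table
# captures the broadband character and ~550 nm maximum of terrestrial
# sunlight and is spline-interpolated onto the simulation grid.
.sunlight_table <- data.frame(
  wavelength = c(380, 400, 420, 440, 460, 480, 500, 520, 540, 550,
                 560, 580, 600, 620, 640, 660, 680, 700),
  irradiance = c(0.45, 0.70, 0.83, 0.90, 0.95, 0.97, 0.98, 0.985, 0.99, 1,
                 0.99, 0.98, 0.96, 0.94, 0.92, 0.89, 0.86, 0.83))

#' Default wavelength grid
#'
#' Uniform 1 nm grid over 380-700 nm; covers the reported 390-650 nm opsin
#' activation range with margin, and makes trapezoidal quadrature error
#' negligible relative to parameter uncertainty.
#'
#' @param from,to,by Grid limits and spacing in nm.
#' @return Numeric vector of wavelengths (nm).
#' @export
light_grid <- function(from = 380, to = 700, by = 1) {
  stopifnot(to > from, by > 0)
  seq(from, to, by = by)
}

new_light_spectrum <- function(wavelength, irradiance, kind = "custom",
                               params = list()) {
  stopifnot(length(wavelength) == length(irradiance))
  if (any(irradiance < 0)) stop("spectral irradiance must be >= 0",
                                call. = FALSE)
  d <- diff(wavelength)
  if (any(d <= 0) || diff(range(d)) > 1e-9 * mean(d))
    stop("wavelength grid must be strictly increasing and uniform",
         call. = FALSE)
  structure(list(wavelength = as.numeric(wavelength),
                 irradiance = as.numeric(irradiance)),
            kind = kind, params = params, class = "light_spectrum")
}

#' Construct a light-source spectrum
#'
#' Builds the unit-peak (unnormalized) spectral shape of one of the five
#' supported source kinds on a uniform wavelength grid:
#' \describe{
#'   \item{led}{rectangular band of full width `bandwidth` centred at
#'     `center` (default 20 nm, i.e. center +/- 10 nm).}
#'   \item{white}{spectrally flat over the whole grid.}
#'   \item{rgb}{sum of three Gaussians at 458/521/628 nm, 20 nm FWHM,
#'     relative amplitudes `rgb_amplitudes`.}
#'   \item{sunlight}{fixed AM1.5-like broadband shape peaking at 550 nm
#'     (synthetic tabulated approximation, spline-interpolated).}
#'   \item{lamp}{halogen-lamp-like Gaussian centred at 600 nm with 150 nm
#'     FWHM, truncated to the grid.}
#' }
#' The returned spectrum is a shape only; scale it to an absolute
#' irradiance with [set_irradiance()] or [scale_to_irradiance()].
#'
#' @param kind One of `"led"`, `"sunlight"`, `"lamp"`, `"rgb"`, `"white"`.
#' @param center LED centre wavelength (nm).
#' @param bandwidth LED full bandwidth (nm).
#' @param rgb_peaks,rgb_fwhm,rgb_amplitudes RGB peak positions (nm), full
#'   widths at half maximum (nm) and relative amplitudes.
#' @param lamp_center,lamp_fwhm Lamp peak (nm) and FWHM (nm).
#' @param grid Wavelength grid (nm), see [light_grid()]. Must cover at
#'   least 390-700 nm.
#' @return A `light_spectrum` object (fields `wavelength`, `irradiance`).
#' @export
#' @examples
#' led <- light_source("led", center = 513)
#' range(led$wavelength[led$irradiance > 0])  # 503-523 nm
light_source <- function(kind = c("led", "sunlight", "lamp", "rgb", "white"),
                         center = 520, bandwidth = 20,
                         rgb_peaks = c(458, 521, 628),
                         rgb_fwhm = c(20, 20, 20),
                         rgb_amplitudes = c(1, 1, 1),
                         lamp_center = 600, lamp_fwhm = 150,
                         grid = light_grid()) {
  kind <- match.arg(kind)
  if (min(grid) > 390 || max(grid) < 700)
    stop("grid must cover at least 390-700 nm", call. = FALSE)
  irr <- switch(kind,
    white = rep(1, length(grid)),
    led = {
      lo <- center - bandwidth / 2
      hi <- center + bandwidth / 2
      if (lo < min(grid) || hi > max(grid))
        stop("LED band [", lo, ", ", hi, "] nm extends beyond the grid",
             call. = FALSE)
      # half-height edge samples make the trapezoidal integral of the
      # discrete top-hat equal the nominal band exactly
      ifelse(grid > lo & grid < hi, 1,
             ifelse(grid == lo | grid == hi, 0.5, 0))
    },
    rgb = {
      sig <- rgb_fwhm / (2 * sqrt(2 * log(2)))
      s <- rep(0, length(grid))
      for (i in seq_along(rgb_peaks))
        s <- s + rgb_amplitudes[i] *
          exp(-(grid - rgb_peaks[i])^2 / (2 * sig[i]^2))
      s
    },
    lamp = {
      sig <- lamp_fwhm / (2 * sqrt(2 * log(2)))
      exp(-(grid - lamp_center)^2 / (2 * sig^2))
    },
    sunlight = {
      f <- stats::splinefun(.sunlight_table$wavelength,
                            .sunlight_table$irradiance, method = "natural")
      pmax(0, f(pmin(pmax(grid, 380), 700)))
    })
  irr <- irr / max(irr)
  prm <- switch(kind,
    led = list(center = center, bandwidth = bandwidth),
    rgb = list(peaks = rgb_peaks, fwhm = rgb_fwhm,
               amplitudes = rgb_amplitudes),
    lamp = list(center = lamp_center, fwhm = lamp_fwhm),
    list())
  new_light_spectrum(grid, irr, kind = kind, params = prm)
}

#' Scale a spectrum so its integral equals a total irradiance
#'
#' Multiplies the spectral irradiance by a constant so that the trapezoidal
#' integral over the wavelength grid equals `total_irradiance`.
#'
#' @param spec A `light_spectrum`.
#' @param total_irradiance Target integrated irradiance in W mm^-2.
#' @return The rescaled `light_spectrum`.
#' @seealso [set_irradiance()] for the band-referenced normalization used
#'   by the stimulation protocols.
#' @export
scale_to_irradiance <- function(spec, total_irradiance) {
  stopifnot(inherits(spec, "light_spectrum"),
            is.numeric(total_irradiance), total_irradiance >= 0)
  if (total_irradiance == 0) {
    spec$irradiance <- spec$irradiance * 0
    return(spec)
  }
  tot <- .trapz(spec$wavelength, spec$irradiance)
  if (tot <= 0)
    stop("cannot scale an all-zero spectrum to a positive irradiance",
         call. = FALSE)
  spec$irradiance <- spec$irradiance * (total_irradiance / tot)
  spec
}

#' Normalize a spectrum to a stated stimulus irradiance
#'
#' Two conventions are supported for what the scalar "irradiance" of a
#' stimulus means for a broadband source:
#' \describe{
#'   \item{band (default)}{the unit-peak spectral shape is scaled so that
#'     its *peak spectral density* equals `irradiance / ref_band`, i.e. the
#'     density of a `ref_band`-wide (20 nm) reference LED carrying the
#'     stated irradiance.  Equal-irradiance comparisons between sources are
#'     then equal-peak-spectral-density comparisons of the normalized
#'     spectra, and for an LED the two conventions coincide.}
#'   \item{integrated}{the spectral integral equals `irradiance`
#'     ([scale_to_irradiance()]).}
#' }
#' All bundled protocols use the band convention.
#'
#' @param spec A `light_spectrum`.
#' @param irradiance Stimulus irradiance in W mm^-2.
#' @param mode `"band"` or `"integrated"`.
#' @param ref_band Reference bandwidth in nm for the band convention.
#' @return The scaled `light_spectrum`.
#' @export
set_irradiance <- function(spec, irradiance,
                           mode = c("band", "integrated"), ref_band = 20) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "light_spectrum"),
            is.numeric(irradiance), irradiance >= 0)
  if (mode == "integrated") return(scale_to_irradiance(spec, irradiance))
  pk <- max(spec$irradiance)
  if (pk <= 0 && irradiance > 0)
    stop("cannot scale an all-zero spectrum to a positive irradiance",
         call. = FALSE)
  if (irradiance == 0) {
    spec$irradiance <- spec$irradiance * 0
    return(spec)
  }
  spec$irradiance <- spec$irradiance / pk * (irradiance / ref_band)
  spec
}

#' Wavelength-dependent activation efficiency
#'
#' Evaluates the summed-Gaussian action-spectrum fit
#' eps(lambda) = sum_i A_i exp(-(lambda - B_i)^2 / (2 sigma_i^2)),
#' skipping zero-amplitude terms and flooring the sum at 0 (negative
#' amplitudes are fitting artifacts outside the data range).
#'
#' @param fit An `action_spectrum_fit` or `opsin_params` object.
#' @param wavelength Wavelength(s) in nm.
#' @return Dimensionless efficiency, same length as `wavelength`.
#' @export
#' @examples
#' action_spectrum(opsin("ChRmine"), 515)
action_spectrum <- function(fit, wavelength) {
  if (inherits(fit, "opsin_params")) fit <- fit$action_fit
  stopifnot(inherits(fit, "action_spectrum_fit"))
  eps <- numeric(length(wavelength))
  for (i in seq_along(fit$A)) {
    if (fit$A[i] == 0) next
    eps <- eps + fit$A[i] *
      exp(-(wavelength - fit$B[i])^2 / (2 * fit$sigma[i]^2))
  }
  pmax(eps, 0)
}

#' Effective photon flux density of a spectrum for an opsin
#'
#' Action-spectrum-weighted photon flux
#' phi = integral of eps(lambda) I(lambda) lambda / (h c) d lambda,
#' evaluated by trapezoidal quadrature over the grid, with I in
#' W mm^-2 nm^-1.  This scalar is the only way light enters the photocycle
#' model, so spectrally different stimuli with equal phi are equivalent.
#'
#' @param spec A `light_spectrum` scaled to an absolute irradiance.
#' @param fit An `action_spectrum_fit` or `opsin_params`.
#' @return Photon flux in photons mm^-2 s^-1.
#' @export
effective_photon_flux <- function(spec, fit) {
  stopifnot(inherits(spec, "light_spectrum"))
  eps <- action_spectrum(fit, spec$wavelength)
  .trapz(spec$wavelength,
         eps * spec$irradiance * spec$wavelength * 1e-9) /
    (.planck * .clight)
}

# phi per unit stimulus irradiance for a unit-peak source shape; protocols
# exploit linearity of phi in irradiance.
flux_per_irradiance <- function(spec, fit, mode = "band", ref_band = 20) {
  effective_photon_flux(set_irradiance(spec, 1, mode = mode,
                                       ref_band = ref_band), fit)
}

#' @export
print.light_spectrum <- function(x, ...) {
  cat("<light_spectrum> kind:", attr(x, "kind"),
      sprintf("| %d points, %.0f-%.0f nm | integral %.4g W mm^-2\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              .trapz(x$wavelength, x$irradiance)))
  invisible(x)
}

#' @export
as.data.frame.light_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength,
             spectral_irradiance_W_per_mm2_per_nm = x$irradiance)
}

#' @export
plot.light_spectrum <- function(x, ...) {
  graphics::plot(x$wavelength, x$irradiance, type = "l",
                 xlab = "wavelength (nm)",
                 ylab = expression(paste("spectral irradiance (W ",
                                         mm^-2, " ", nm^-1, ")")),
                 main = attr(x, "kind"), ...)
  invisible(x)
}

#' Export a spectrum as a two-column CSV
#'
#' @param spec A `light_spectrum`.
#' @param path Output file path.
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE)
  invisible(path)
}

#' Read light-source definitions from a YAML/JSON config
#'
#' Each entry needs a `kind` plus kind-specific settings accepted by
#' [light_source()]; an optional `grid: [from, to, by]` overrides the
#' default grid.
#'
#' @param path Path to a YAML (or JSON) file with a list of source entries.
#' @return Named list of `light_spectrum` objects.
#' @export
read_source_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.list(cfg) || length(cfg) == 0)
    stop("source config must be a non-empty list", call. = FALSE)
  out <- lapply(cfg, function(e) {
    if (is.null(e$kind)) stop("source entry lacks 'kind'", call. = FALSE)
    grid <- if (!is.null(e$grid))
      light_grid(e$grid[[1]], e$grid[[2]], e$grid[[3]]) else light_grid()
    args <- e[setdiff(names(e), c("kind", "grid", "name"))]
    do.call(light_source, c(list(kind = e$kind, grid = grid), args))
  })
  names(out) <- vapply(seq_along(cfg), function(i)
    if (!is.null(cfg[[i]]$name)) cfg[[i]]$name else cfg[[i]]$kind, "")
  out
}
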