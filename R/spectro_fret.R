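# FRET efficiency / Forster distance analysis and CD renaturation melting.

#' Construct an emission spectrum
#'
#' @param wavelengths strictly increasing nm grid.
#' @param intensities fluorescence intensities (arbitrary units).
#' @param label optional text label.
#' @return object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities, label = "") {
  if (length(wavelengths) != length(intensities))
    stopf("wavelengths and intensities must have equal length")
  if (any(diff(wavelengths) <= 0))
    stopf("wavelengths must be strictly increasing")
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = as.numeric(intensities),
                 label = label),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("Emission spectrum '%s': %d points, %g-%g nm\n", x$label,
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Subtract a background spectrum
#'
#' Pointwise subtraction of a buffer background measured on the identical
#' wavelength grid.
#'
#' @param spec,background `emission_spectrum` objects with identical grids.
#' @return background-corrected `emission_spectrum`.
#' @export
subtract_background <- function(spec, background) {
  if (!identical(spec$wavelengths, background$wavelengths))
    stopf("wavelength grids differ; spectra cannot be aligned")
  emission_spectrum(spec$wavelengths,
                    spec$intensities - background$intensities,
                    label = paste0(spec$label, " - bg"))
}

#' Donor intensity at the readout wavelength
#'
#' @param spec `emission_spectrum`.
#' @param wavelength readout wavelength in nm (default 568, the usual Cy3
#'   donor emission readout).
#' @param interpolate linear interpolation between grid points; otherwise
#'   nearest grid point.
#' @return intensity.
#' @export
intensity_at <- function(spec, wavelength = 568, interpolate = FALSE) {
  w <- spec$wavelengths
  if (wavelength < min(w) || wavelength > max(w))
    stopf("wavelength %g nm outside spectrum range [%g, %g]",
          wavelength, min(w), max(w))
  if (interpolate)
    return(approx(w, spec$intensities, xout = wavelength)$y)
  spec$intensities[which.min(abs(w - wavelength))]
}

#' FRET efficiency from donor-only and donor-acceptor intensities
#'
#' E = 1 - F_DA / F_D, where F_D and F_DA are the donor emission intensity
#' without and with the acceptor present. Noisy near-zero-transfer samples
#' can produce F_DA slightly above F_D; the raw value is then clamped to 0
#' with a warning rather than erroring.
#'
#' @param F_DA donor intensity in the presence of the acceptor (>= 0).
#' @param F_D donor-only intensity (> 0).
#' @return efficiency in \[0, 1\].
#' @export
fret_efficiency <- function(F_DA, F_D) {
  if (!is.numeric(F_D) || length(F_D) != 1L || F_D <= 0)
    stopf("`F_D` must be a single positive intensity")
  if (!is.numeric(F_DA) || length(F_DA) != 1L || F_DA < 0)
    stopf("`F_DA` must be a single non-negative intensity")
  E <- 1 - F_DA / F_D
  if (E < 0) {
    warnf("F_DA > F_D gives raw E = %.4f; clamped to 0", E)
    E <- 0
  }
  E
}

#' Donor-acceptor distance from FRET efficiency
#'
#' d = R0 * ((1 - E) / E)^(1/6), with R0 the Forster distance (50%%
#' transfer). Strictly decreasing in E; d = R0 at E = 0.5.
#'
#' @param E efficiency strictly inside (0, 1).
#' @param R0 Forster distance in nm (default 5.1, Cy3/Cy5).
#' @return distance in nm.
#' @examples
#' fret_distance(0.5)          # 5.1 nm
#' @export
fret_distance <- function(E, R0 = 5.1) {
  assert_scalar_num(R0, "R0", lower = 0, strict_lower = TRUE)
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0 || E >= 1)
    stopf("`E` must lie strictly inside (0, 1); E = 0 or 1 maps to an infinite/zero distance")
  R0 * ((1 - E) / E)^(1 / 6)
}

#' Bundle a FRET measurement
#'
#' Convenience constructor computing E and d from raw intensities.
#'
#' @param F_DA,F_D donor intensities with/without acceptor.
#' @param R0 Forster distance nm.
#' @return object of class `fret_measurement` with fields F_D, F_DA, E, d, R0.
#' @export
fret_measurement <- function(F_DA, F_D, R0 = 5.1) {
  E <- fret_efficiency(F_DA, F_D)
  d <- if (E > 0 && E < 1) fret_distance(E, R0) else NA_real_
  structure(list(F_DA = F_DA, F_D = F_D, E = E, d = d, R0 = R0),
            class = "fret_measurement")
}

#' @export
print.fret_measurement <- function(x, ...) {
  cat(sprintf("FRET: E = %.3f, d = %s nm (R0 = %.2f nm)\n", x$E,
              if (is.na(x$d)) "NA" else sprintf("%.3f", x$d), x$R0))
  invisible(x)
}

#' Efficiency change implied by a fold increase
#'
#' Delta-E = E_baseline * (fold - 1): the absolute efficiency change when a
#' perturbation multiplies a baseline efficiency by `fold`. Clamped so the
#' final efficiency does not exceed 1.
#'
#' @param E_baseline baseline efficiency (>= 0).
#' @param fold multiplicative change (>= 0).
#' @return Delta-E.
#' @examples
#' efficiency_change(0.10, 4.0)  # 0.30
#' @export
efficiency_change <- function(E_baseline, fold) {
  if (!is.numeric(E_baseline) || length(E_baseline) != 1L || E_baseline < 0)
    stopf("`E_baseline` must be a single non-negative number")
  if (!is.numeric(fold) || length(fold) != 1L || fold < 0)
    stopf("`fold` must be a single non-negative number")
  E_final <- E_baseline * fold
  if (E_final > 1) {
    warnf("E_baseline * fold = %.3f exceeds 1; clamped", E_final)
    E_final <- 1
  }
  E_final - E_baseline
}

#' Boltzmann sigmoid fit of a renaturation melt curve
#'
#' Least-squares fit of y(T) = A2 + (A1 - A2) / (1 + exp((T - Tm)/dT)) to
#' ellipticity (or any renaturation signal) versus temperature, the
#' standard model for a two-state melting transition. Initial values are
#' derived from the data (plateaus from the first/last 10% of points, Tm
#' from the half-amplitude crossing, dT from the 10-90% width), so no user
#' guesses are needed.
#'
#' @param temps temperatures in degrees C (>= 6 points spanning the
#'   transition).
#' @param signal signal values, same length.
#' @return object of class `melt_fit`: list with `Tm`, `Tm_se`, `A1`,
#'   `A2`, `dT`, `fitted`, `residuals`.
#' @export
boltzmann_melt_fit <- function(temps, signal) {
  if (length(temps) != length(signal))
    stopf("temps and signal must have equal length")
  if (length(temps) < 6L) stopf("need at least 6 points to fit a sigmoid")
  ord <- order(temps)
  temps <- as.numeric(temps)[ord]; signal <- as.numeric(signal)[ord]
  n <- length(temps)
  k <- max(2L, ceiling(0.1 * n))
  A1_0 <- mean(signal[seq_len(k)])          # low-temperature plateau
  A2_0 <- mean(signal[seq(n - k + 1L, n)])  # high-temperature plateau
  amp <- A1_0 - A2_0
  if (abs(amp) < 1e-9 * max(1, abs(A1_0), abs(A2_0)) ||
      abs(amp) < 1e-3 * max(stats::sd(signal), .Machine$double.eps))
    stopf("degenerate fit: signal shows no transition between the plateaus")
  crossing <- function(frac) {
    target <- A2_0 + frac * amp
    idx <- which(diff(sign(signal - target)) != 0)
    if (!length(idx)) return(NA_real_)
    i <- idx[1L]
    approx(signal[c(i, i + 1L)], temps[c(i, i + 1L)], xout = target)$y
  }
  Tm_0 <- crossing(0.5)
  if (is.na(Tm_0)) Tm_0 <- stats::median(temps)
  w10 <- crossing(0.9); w90 <- crossing(0.1)
  dT_0 <- if (!is.na(w10) && !is.na(w90)) abs(w90 - w10) / (2 * log(9)) else
    diff(range(temps)) / 10
  dT_0 <- max(dT_0, 1e-3)
  df <- data.frame(T = temps, y = signal)
  fit <- tryCatch(
    nls(y ~ A2 + (A1 - A2) / (1 + exp((T - Tm) / dT)), data = df,
        start = list(A1 = A1_0, A2 = A2_0, Tm = Tm_0, dT = dT_0),
        algorithm = "port",
        lower = c(A1 = -Inf, A2 = -Inf, Tm = min(temps), dT = 1e-4),
        upper = c(A1 = Inf, A2 = Inf, Tm = max(temps), dT = Inf),
        control = nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stopf("Boltzmann fit failed to converge: %s",
                              conditionMessage(e)))
  co <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["Tm", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(Tm = unname(co["Tm"]), Tm_se = unname(se),
                 A1 = unname(co["A1"]), A2 = unname(co["A2"]),
                 dT = unname(co["dT"]),
                 fitted = as.numeric(predict(fit)),
                 residuals = signal - as.numeric(predict(fit)),
                 temps = temps, signal = signal),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Boltzmann melt fit: Tm = %.2f +/- %s degC (dT = %.2f)\n",
              x$Tm, if (is.na(x$Tm_se)) "NA" else sprintf("%.2f", x$Tm_se),
              x$dT))
  invisible(x)
}

#' Relative ellipticity change versus a reference temperature
#'
#' 100 * (I_final - I_ref) / I_ref, with I_ref the signal at the reference
#' temperature (conventionally the fully denatured high-temperature
#' measurement) and I_final the last point of the series.
#'
#' @param temps temperatures.
#' @param signal signal series (e.g. 274 nm ellipticity).
#' @param reference_temp temperature whose signal is the reference
#'   (default 90).
#' @return percent change.
#' @export
relative_ellipticity_change <- function(temps, signal, reference_temp = 90) {
  if (length(temps) != length(signal))
    stopf("temps and signal must have equal length")
  i <- which(abs(temps - reference_temp) < 1e-8)
  if (!length(i))
    stopf("reference temperature %g not present in series", reference_temp)
  I_ref <- signal[i[1L]]
  if (I_ref == 0) stopf("reference signal is zero; relative change undefined")
  100 * (signal[length(signal)] - I_ref) / I_ref
}
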