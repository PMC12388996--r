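#' Spectrometer configuration
#'
#' Bundle of instrument constants shared by every off-resonance and
#' relaxometry computation: the proton Larmor frequency of the spectrometer,
#' the amplitude of the locking radiofrequency field B1, the gyromagnetic
#' ratio of the observed nucleus, and the sample temperature.
#'
#' Defaults describe the pulse spectrometer used throughout this package's
#' reference analyses: 30.2 MHz proton resonance, B1 = 5 G, T = 303 K.
#'
#' @param larmor_frequency_hz Proton Larmor frequency in Hz.
#' @param b1_gauss Amplitude of the RF field B1, in gauss (stored internally
#'   in tesla; 1 G = 1e-4 T).
#' @param gyromagnetic_ratio Gyromagnetic ratio in rad s^-1 T^-1 (default:
#'   proton).
#' @param temperature_k Sample temperature in kelvin.
#'
#' @return An object of class `spectrometer_config` with fields
#'   `larmor_frequency_hz`, `b1_tesla`, `gyromagnetic_ratio`,
#'   `temperature_k`, and the derived `omega0` (angular Larmor frequency,
#'   rad/s) and `nutation_hz` ((gamma/2pi) * B1, the on-resonance nutation
#'   frequency in Hz).
#' @examples
#' cfg <- spectrometer_config()
#' cfg$nutation_hz # ~21.3 kHz for 5 G proton
#' @export
spectrometer_config <- function(larmor_frequency_hz = 3.02e7,
                                b1_gauss = 5,
                                gyromagnetic_ratio = 2.6752218744e8,
                                temperature_k = 303) {
  stopifnot(
    is.numeric(larmor_frequency_hz), length(larmor_frequency_hz) == 1L,
    is.numeric(b1_gauss), length(b1_gauss) == 1L,
    is.numeric(gyromagnetic_ratio), length(gyromagnetic_ratio) == 1L,
    is.numeric(temperature_k), length(temperature_k) == 1L
  )
  if (larmor_frequency_hz <= 0 || b1_gauss <= 0 ||
      gyromagnetic_ratio <= 0 || temperature_k <= 0) {
    stop("all spectrometer constants must be strictly positive", call. = FALSE)
  }
  b1_tesla <- b1_gauss * 1e-4
  structure(
    list(
      larmor_frequency_hz = larmor_frequency_hz,
      b1_tesla = b1_tesla,
      gyromagnetic_ratio = gyromagnetic_ratio,
      temperature_k = temperature_k,
      omega0 = 2 * pi * larmor_frequency_hz,
      nutation_hz = gyromagnetic_ratio / (2 * pi) * b1_tesla
    ),
    class = "spectrometer_config"
  )
}

#' @export
print.spectrometer_config <- function(x, ...) {
  cat("<spectrometer_config>\n")
  cat(sprintf("  Larmor frequency : %.4g MHz\n", x$larmor_frequency_hz / 1e6))
  cat(sprintf("  B1 amplitude     : %.4g G (%.3g T)\n",
              x$b1_tesla * 1e4, x$b1_tesla))
  cat(sprintf("  gamma            : %.10g rad/s/T\n", x$gyromagnetic_ratio))
  cat(sprintf("  temperature      : %g K\n", x$temperature_k))
  cat(sprintf("  (gamma/2pi)*B1   : %.6g kHz\n", x$nutation_hz / 1e3))
  invisible(x)
}

#' Longitudinal component of the effective field
#'
#' The off-resonance offset Delta f maps onto a fictitious longitudinal field
#' Delta B = 2 pi Delta f / gamma, the z-component of the effective field in
#' the rotating frame. The sign of the offset is preserved.
#'
#' @param offset_hz Frequency offset(s) Delta f from resonance, in Hz.
#' @param config A [spectrometer_config()].
#' @return Field in tesla, same length as `offset_hz`.
#' @examples
#' delta_b(21288.74, spectrometer_config()) # ~5e-4 T, i.e. B1 of 5 G
#' @export
delta_b <- function(offset_hz, config = spectrometer_config()) {
  stopifnot(inherits(config, "spectrometer_config"), is.numeric(offset_hz))
  offset_hz * 2 * pi / config$gyromagnetic_ratio
}

#' Tilt angle of the effective field
#'
#' Angle theta = arctan(B1 / Delta B) between the effective field and the
#' static field. On resonance (Delta f = 0) the effective field is B1 itself,
#' perpendicular to B0, and theta is exactly pi/2; far off resonance theta
#' tends to 0.
#'
#' @inheritParams delta_b
#' @return Angle(s) in radians, in (0, pi/2].
#' @export
tilt_angle <- function(offset_hz, config = spectrometer_config()) {
  db <- delta_b(offset_hz, config)
  ifelse(db == 0, pi / 2, atan(config$b1_tesla / abs(db)))
}

#' Magnitude of the effective field in the rotating frame
#'
#' B_ef = sqrt(B1^2 + Delta B^2); used for the omega_e * tau_c regime
#' diagnostic.
#'
#' @inheritParams delta_b
#' @return Field magnitude(s) in tesla.
#' @export
effective_field <- function(offset_hz, config = spectrometer_config()) {
  sqrt(config$b1_tesla^2 + delta_b(offset_hz, config)^2)
}
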