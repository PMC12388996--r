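#' Relaxation enhancement factor K
#'
#' Dipolar relaxation enhancement factor for isotropic rotational diffusion,
#'
#' \deqn{K = \frac{10 + 37\,\omega^2\tau_c^2 + 12\,\omega^4\tau_c^4}
#'                {10 + 16\,\omega^2\tau_c^2}}
#'
#' with \eqn{\omega} the angular Larmor frequency of the spectrometer and
#' \eqn{\tau_c} the rotational correlation time. K equals 1 in the
#' fast-motion limit and increases strictly monotonically as motion slows,
#' approaching \eqn{0.75\,\omega^2\tau_c^2} for slow tumbling.
#'
#' @param tau_c Rotational correlation time(s) in seconds, >= 0.
#' @param config A [spectrometer_config()]; supplies omega = 2*pi*f0.
#' @return Dimensionless K, same length as `tau_c`; always >= 1.
#' @examples
#' compute_k_factor(1.8e-9) # ~1.22 at 30.2 MHz
#' @seealso [invert_k_for_tau()] for the inverse map.
#' @export
compute_k_factor <- function(tau_c, config = spectrometer_config()) {
  stopifnot(inherits(config, "spectrometer_config"), is.numeric(tau_c))
  if (any(tau_c < 0)) {
    stop("tau_c must be non-negative", call. = FALSE)
  }
  x <- (config$omega0 * tau_c)^2
  (10 + 37 * x + 12 * x^2) / (10 + 16 * x)
}

#' Invert the K factor for the rotational correlation time
#'
#' Solves K(tau_c) = k for tau_c by bracketed root search (uniroot) on
#' [0, `tau_max`]. Because K is strictly increasing in tau_c, the root is
#' unique. The result carries the search bracket and the dimensionless
#' diagnostics omega * tau_c (Larmor) and, when the locking field is of
#' interest, omega_1 * tau_c (nutation), so the fast-motion regime
#' assumption (omega_e * tau_c << 1) can be audited. A warning is emitted
#' when omega_e * tau_c exceeds 0.1 — the equilibrium-ratio model is stated
#' for the fast regime — but the value is still returned.
#'
#' @param k Target K value, must be >= 1 (K = 1 corresponds to tau_c = 0).
#' @param config A [spectrometer_config()].
#' @param tau_max Upper end of the search bracket in seconds (default 1 us,
#'   far beyond any liposomal lipid correlation time).
#' @param tol Relative tolerance of the root search.
#' @return An object of class `correlation_time_result`: list with `tau_c`
#'   (seconds), `k`, `bracket`, `omega_tau` (omega0 * tau_c) and
#'   `omega_e_tau` (gamma * B1 * tau_c).
#' @examples
#' invert_k_for_tau(1.61)$tau_c * 1e9 # ~3.27 ns
#' @export
invert_k_for_tau <- function(k, config = spectrometer_config(),
                             tau_max = 1e-6, tol = 1e-12) {
  stopifnot(is.numeric(k), length(k) == 1L, inherits(config, "spectrometer_config"))
  if (!is.finite(k) || k < 1) {
    stop("K below its theoretical minimum of 1; no correlation time exists",
         call. = FALSE)
  }
  if (k == 1) {
    tau <- 0
  } else {
    k_hi <- compute_k_factor(tau_max, config)
    if (k > k_hi) {
      stop(sprintf("K = %g exceeds K(tau_max = %g s) = %g; enlarge tau_max",
                   k, tau_max, k_hi), call. = FALSE)
    }
    tau <- stats::uniroot(
      function(tau) compute_k_factor(tau, config) - k,
      interval = c(0, tau_max), tol = tau_max * tol
    )$root
  }
  omega_e_tau <- config$gyromagnetic_ratio * config$b1_tesla * tau
  if (omega_e_tau > 0.1) {
    warning(sprintf(
      "omega_e * tau_c = %.3g > 0.1: outside the stated fast-motion regime",
      omega_e_tau), call. = FALSE)
  }
  structure(
    list(
      tau_c = tau,
      k = k,
      bracket = c(0, tau_max),
      omega_tau = config$omega0 * tau,
      omega_e_tau = omega_e_tau
    ),
    class = "correlation_time_result"
  )
}

#' @export
print.correlation_time_result <- function(x, ...) {
  cat("<correlation_time_result>\n")
  cat(sprintf("  tau_c      : %.4g ns (K = %.4g)\n", x$tau_c * 1e9, x$k))
  cat(sprintf("  omega*tau  : %.3g (Larmor), %.3g (omega_e, B1)\n",
              x$omega_tau, x$omega_e_tau))
  invisible(x)
}

#' Equilibrium off-resonance magnetization ratio
#'
#' Model for the ratio of the locked equilibrium magnetization M_rho to the
#' full equilibrium magnetization M0 as a function of the offset Delta f:
#'
#' \deqn{\frac{M_\rho}{M_0} =
#'   \frac{\Delta f^2}{\Delta f^2 + K\,[(\gamma/2\pi) B_1]^2}}
#'
#' The ratio is 0 on resonance, rises monotonically with |Delta f|, and
#' saturates at 1 far off resonance. The half-saturation offset is
#' (gamma/2pi) B1 sqrt(K).
#'
#' @param offset_hz Offset(s) Delta f in Hz (enters squared, sign ignored).
#' @param k Relaxation enhancement factor, >= 1.
#' @param config A [spectrometer_config()].
#' @return Ratio(s) in [0, 1).
#' @export
model_offres_ratio <- function(offset_hz, k, config = spectrometer_config()) {
  stopifnot(is.numeric(offset_hz), is.numeric(k), length(k) == 1L)
  if (!is.finite(k) || k < 1) {
    stop("K must be >= 1", call. = FALSE)
  }
  f2 <- offset_hz^2
  f2 / (f2 + k * config$nutation_hz^2)
}
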