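#' Saturation-recovery magnetization model
#'
#' Longitudinal magnetization regrowth after saturation,
#' \deqn{M(t) = M_0\,[1 - \exp(-t/T_1)]}
#' with equilibrium magnetization M0 and spin-lattice relaxation time T1.
#'
#' @param t Time(s) since saturation, seconds, >= 0.
#' @param t1 Spin-lattice relaxation time, seconds, > 0.
#' @param m0 Equilibrium magnetization, arbitrary units.
#' @return Magnetization, same length as `t`.
#' @examples
#' model_t1(2.5 * log(2), t1 = 2.5, m0 = 1) # half recovery
#' @export
model_t1 <- function(t, t1, m0) {
  stopifnot(is.numeric(t), is.numeric(t1), is.numeric(m0))
  if (t1 <= 0) stop("t1 must be > 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  m0 * (1 - exp(-t / t1))
}

#' Two-component transverse decay model
#'
#' Gaussian + Lorentzian decomposition of the transverse magnetization decay,
#' \deqn{M(t) = M_{0G}\,\exp[-(t/T_{2G})^2] + M_{0L}\,\exp(-t/T_{2L})}
#' where the Gaussian kernel (squared-argument exponential) captures rigid,
#' ordered environments and the simple exponential (Lorentzian linewidth)
#' captures mobile ones. Amplitudes are expressed as percentages of the total
#' extrapolated magnetization at t = 0.
#'
#' @param t Time(s), seconds, >= 0.
#' @param m0g_percent Gaussian amplitude fraction in percent of the total.
#' @param t2g Gaussian transverse relaxation time, seconds, > 0.
#' @param t2l Lorentzian transverse relaxation time, seconds, > 0.
#' @param m0_total Total magnetization at t = 0 (arbitrary units).
#' @return Magnetization, same length as `t`.
#' @examples
#' model_t2_mixture(0, 77, 0.232, 0.0076) # = m0_total at t = 0
#' @export
model_t2_mixture <- function(t, m0g_percent, t2g, t2l, m0_total = 1) {
  stopifnot(is.numeric(t), is.numeric(m0g_percent))
  if (m0g_percent < 0 || m0g_percent > 100) {
    stop("m0g_percent must lie in [0, 100]", call. = FALSE)
  }
  if (t2g <= 0 || t2l <= 0) stop("t2g and t2l must be > 0", call. = FALSE)
  m0g <- m0_total * m0g_percent / 100
  m0l <- m0_total - m0g
  m0g * exp(-(t / t2g)^2) + m0l * exp(-t / t2l)
}

#' Two-parameter logistic viability model
#'
#' Dose-response viability in percent of untreated control with asymptotes
#' fixed at 100 (no drug) and 0 (complete kill):
#' \deqn{V(c) = \frac{100}{1 + (c/\mathrm{IC}_{50})^{h}}}
#' By construction V(IC50) = 50.
#'
#' @param conc Concentration(s), any consistent unit (conventionally uM).
#' @param ic50 Half-maximal inhibitory concentration, same unit, > 0.
#' @param hill Hill slope, > 0.
#' @return Viability in percent of control.
#' @export
model_viability <- function(conc, ic50, hill) {
  stopifnot(is.numeric(conc))
  if (ic50 <= 0) stop("ic50 must be > 0", call. = FALSE)
  if (hill <= 0) stop("hill must be > 0", call. = FALSE)
  100 / (1 + (conc / ic50)^hill)
}
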