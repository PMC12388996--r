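#' Noise specification for synthetic generators
#'
#' All generators add i.i.d. Gaussian noise with standard deviation
#' `sigma_relative` times the signal amplitude scale (the t = 0 magnetization
#' for decays, the equilibrium magnetization for recovery curves, 1 for
#' saturation ratios, 100% for viability). A fixed `seed` makes the draw
#' bit-reproducible; `seed = NULL` uses (and advances) the session RNG.
#'
#' @param sigma_relative Noise SD as a fraction of the amplitude scale, >= 0.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_relative = 0, seed = NULL) {
  stopifnot(is.numeric(sigma_relative), length(sigma_relative) == 1L)
  if (sigma_relative < 0) stop("sigma_relative must be >= 0", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(sigma_relative = sigma_relative, seed = seed),
            class = "noise_spec")
}

.add_noise <- function(values, noise, scale) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma_relative == 0) return(values)
  draw <- function() {
    values + stats::rnorm(length(values), sd = noise$sigma_relative * scale)
  }
  if (is.null(noise$seed)) draw() else withr::with_seed(noise$seed, draw())
}

#' Default sampling grids for synthetic experiments
#'
#' Log-spaced grids matching how the experiments are sampled in practice:
#' recovery curves span `[0.01, 5] * T1` (equilibrium is reached at about
#' five T1), decays span `[0.1 * min(T2), 5 * max(T2)]` so both components
#' are resolved, and offsets span `[0.05, 20] * (gamma/2pi) B1` around the
#' half-saturation knee.
#'
#' @param t1,t2g,t2l Time constants in seconds.
#' @param n Number of points.
#' @param config A [spectrometer_config()] (offset grid only).
#' @return Numeric vector of times (s) or offsets (Hz).
#' @name sampling_grids
NULL

#' @rdname sampling_grids
#' @export
default_t1_times <- function(t1, n = 40L) {
  exp(seq(log(0.01 * t1), log(5 * t1), length.out = n))
}

#' @rdname sampling_grids
#' @export
default_t2_times <- function(t2g, t2l, n = 40L) {
  lo <- 0.1 * min(t2g, t2l)
  hi <- 5 * max(t2g, t2l)
  exp(seq(log(lo), log(hi), length.out = n))
}

#' @rdname sampling_grids
#' @export
default_offsets <- function(config = spectrometer_config(), n = 12L) {
  exp(seq(log(0.05), log(20), length.out = n)) * config$nutation_hz
}

#' Generate a synthetic saturation-recovery curve
#'
#' Evaluates the recovery model [model_t1()] on a time grid and adds Gaussian
#' noise scaled to the equilibrium magnetization `m0`.
#'
#' @param t1 Spin-lattice relaxation time, seconds, > 0.
#' @param m0 Equilibrium magnetization, > 0.
#' @param times Sampling times (seconds, >= 8 points); defaults to
#'   [default_t1_times()].
#' @param noise A [noise_spec()].
#' @param label Curve label.
#' @return A [relaxation_curve()] of kind `saturation_recovery`.
#' @examples
#' gen_t1_curve(2.5, noise = noise_spec(0.01, seed = 1))
#' @export
gen_t1_curve <- function(t1, m0 = 1, times = default_t1_times(t1),
                         noise = noise_spec(), label = "") {
  if (t1 <= 0 || m0 <= 0) stop("t1 and m0 must be > 0", call. = FALSE)
  clean <- model_t1(times, t1, m0)
  relaxation_curve(times, .add_noise(clean, noise, scale = m0),
                   kind = "saturation_recovery", label = label)
}

#' Generate a synthetic two-component transverse decay
#'
#' Evaluates [model_t2_mixture()] on a time grid and adds Gaussian noise
#' scaled to the total t = 0 magnetization.
#'
#' @param m0g_frac Gaussian amplitude fraction in percent, in [0, 100].
#' @param t2g,t2l Gaussian and Lorentzian transverse times, seconds, > 0.
#' @param m0_total Total magnetization at t = 0.
#' @param times Sampling times; defaults to [default_t2_times()].
#' @param noise A [noise_spec()].
#' @param label Curve label.
#' @return A [relaxation_curve()] of kind `transverse_decay`.
#' @export
gen_t2_decay <- function(m0g_frac, t2g, t2l, m0_total = 1,
                         times = default_t2_times(t2g, t2l),
                         noise = noise_spec(), label = "") {
  if (m0g_frac < 0 || m0g_frac > 100) {
    stop("m0g_frac must lie in [0, 100]", call. = FALSE)
  }
  clean <- model_t2_mixture(times, m0g_frac, t2g, t2l, m0_total)
  relaxation_curve(times, .add_noise(clean, noise, scale = m0_total),
                   kind = "transverse_decay", label = label)
}

#' Generate a synthetic off-resonance saturation profile
#'
#' Computes K from the correlation time via [compute_k_factor()], evaluates
#' the equilibrium ratio model [model_offres_ratio()] at the given offsets,
#' and adds Gaussian noise on the ratio scale (amplitude 1).
#'
#' @param tau_c Rotational correlation time, seconds, >= 0.
#' @param config A [spectrometer_config()].
#' @param offsets Offsets Delta f (Hz, nonzero); defaults to
#'   [default_offsets()].
#' @param noise A [noise_spec()].
#' @param label Profile label.
#' @return An [offres_profile()].
#' @export
gen_offres_profile <- function(tau_c, config = spectrometer_config(),
                               offsets = default_offsets(config),
                               noise = noise_spec(), label = "") {
  if (tau_c < 0) stop("tau_c must be >= 0", call. = FALSE)
  k <- compute_k_factor(tau_c, config)
  clean <- model_offres_ratio(offsets, k, config)
  noisy <- .add_noise(clean, noise, scale = 1)
  # keep noisy draws inside the container's physical allowance
  offres_profile(offsets, pmin(pmax(noisy, -0.1), 1.1), label = label)
}

#' Generate a synthetic formulation characterization table
#'
#' Emulates a stability study table: one row per formulation x timepoint with
#' hydrodynamic size, polydispersity index and zeta potential, jittered
#' around the stated means. Replicate SD columns are populated with the noise
#' SD actually used.
#'
#' @param n_formulations,n_timepoints Row-grid dimensions, >= 1.
#' @param size_mean Mean hydrodynamic diameter, nm.
#' @param pdi_mean Mean polydispersity index.
#' @param zeta_mean Mean zeta potential, mV.
#' @param timepoints_days Timepoints in days (recycled/truncated to
#'   `n_timepoints`).
#' @param noise A [noise_spec()]; the relative SD is applied to each metric's
#'   own mean (|mean| for zeta).
#' @return A data.frame in the standard characterization layout:
#'   `formulation`, `timepoint_days`, `size_nm`, `size_sd`, `pdi`, `pdi_sd`,
#'   `zeta_mv`, `zeta_sd`.
#' @export
gen_dls_table <- function(n_formulations, n_timepoints,
                          size_mean = 130, pdi_mean = 0.2, zeta_mean = 35,
                          timepoints_days = c(0, 7, 14, 21),
                          noise = noise_spec()) {
  if (n_formulations < 1 || n_timepoints < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  tp <- rep_len(timepoints_days, n_timepoints)
  grid <- expand.grid(
    formulation = sprintf("F%02d", seq_len(n_formulations)),
    timepoint_days = tp,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  sds <- noise$sigma_relative * c(size_mean, pdi_mean, abs(zeta_mean))
  vals <- cbind(rep(size_mean, n), rep(pdi_mean, n), rep(zeta_mean, n))
  if (noise$sigma_relative > 0) {
    jitter <- function() {
      vals + cbind(stats::rnorm(n, sd = sds[1]),
                   stats::rnorm(n, sd = sds[2]),
                   stats::rnorm(n, sd = sds[3]))
    }
    vals <- if (is.null(noise$seed)) jitter() else withr::with_seed(noise$seed, jitter())
  }
  data.frame(
    formulation = grid$formulation,
    timepoint_days = grid$timepoint_days,
    size_nm = pmax(vals[, 1], 1e-3),
    size_sd = sds[1],
    pdi = pmin(pmax(vals[, 2], 0), 1),
    pdi_sd = sds[2],
    zeta_mv = vals[, 3],
    zeta_sd = sds[3]
  )
}

#' Generate a synthetic MTT dose-response set
#'
#' Viability in percent of untreated control from the two-parameter logistic
#' [model_viability()], with Gaussian noise scaled to 100% viability.
#'
#' @param ic50 True half-maximal concentration, uM, > 0.
#' @param hill Hill slope, > 0.
#' @param concentrations Tested concentrations (uM, strictly increasing,
#'   >= 4 distinct values).
#' @param n_replicates Replicate wells per concentration (default 3,
#'   matching standard MTT triplicate practice).
#' @param noise A [noise_spec()].
#' @param cell_line,formulation Labels.
#' @param timepoint_h Exposure time in hours.
#' @return A [dose_response_set()].
#' @export
gen_dose_response <- function(ic50, hill = 1,
                              concentrations = c(0.5, 1, 2, 5, 10, 20, 35, 50),
                              n_replicates = 3L,
                              noise = noise_spec(),
                              cell_line = "", formulation = "",
                              timepoint_h = 48) {
  if (ic50 <= 0 || hill <= 0) stop("ic50 and hill must be > 0", call. = FALSE)
  conc <- rep(concentrations, each = n_replicates)
  clean <- model_viability(conc, ic50, hill)
  viab <- .add_noise(clean, noise, scale = 100)
  dose_response_set(
    concentrations = conc,
    viability_percent = viab,
    replicate = rep(seq_len(n_replicates), times = length(concentrations)),
    cell_line = cell_line, formulation = formulation,
    timepoint_h = timepoint_h
  )
}

#' Write a generator output as a long-format fixture
#'
#' Long CSV layout (`sample_id`, `x`, `y`, `y_sd`) with the seed recorded in
#' a header comment, plus an optional JSON twin carrying the same metadata.
#'
#' @param x A `relaxation_curve` or `offres_profile`.
#' @param path Output CSV path.
#' @param sample_id Identifier written in the `sample_id` column.
#' @param seed Seed to record (`NA` if the draw was unseeded).
#' @return `path`, invisibly.
#' @export
write_fixture_csv <- function(x, path, sample_id = attr(x, "label") %||% "sample",
                              seed = NA) {
  if (inherits(x, "relaxation_curve")) {
    df <- data.frame(sample_id = sample_id, x = x$t_s, y = x$M, y_sd = NA_real_)
  } else if (inherits(x, "offres_profile")) {
    df <- data.frame(sample_id = sample_id, x = x$delta_f_hz, y = x$ratio,
                     y_sd = NA_real_)
  } else {
    stop("unsupported fixture object", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", as.character(seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
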