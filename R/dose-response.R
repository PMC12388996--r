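#' Dose-response container
#'
#' Replicate-resolved viability (percent of untreated control) across a
#' concentration series for one cell line x formulation x timepoint. At
#' least 4 distinct non-negative concentrations are required for fitting.
#'
#' @param concentrations Concentrations in uM, >= 0.
#' @param viability_percent Viability in percent of control.
#' @param replicate Replicate index per well.
#' @param cell_line,formulation Labels.
#' @param timepoint_h Exposure time in hours.
#' @return A data.frame of class `dose_response_set` with columns `conc_um`,
#'   `viability_pct`, `replicate` and attributes `cell_line`, `formulation`,
#'   `timepoint_h`.
#' @export
dose_response_set <- function(concentrations, viability_percent,
                              replicate = 1L, cell_line = "",
                              formulation = "", timepoint_h = 48) {
  stopifnot(is.numeric(concentrations), is.numeric(viability_percent))
  if (length(concentrations) != length(viability_percent)) {
    stop("concentrations and viability must have the same length", call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (length(unique(concentrations)) < 4L) {
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  }
  df <- data.frame(conc_um = as.numeric(concentrations),
                   viability_pct = as.numeric(viability_percent),
                   replicate = rep_len(as.integer(replicate),
                                       length(concentrations)))
  df <- df[order(df$conc_um, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, cell_line = cell_line, formulation = formulation,
            timepoint_h = timepoint_h,
            class = c("dose_response_set", "data.frame"))
}

#' @export
print.dose_response_set <- function(x, ...) {
  cat(sprintf("<dose_response_set> %s / %s / %g h\n",
              attr(x, "cell_line"), attr(x, "formulation"),
              attr(x, "timepoint_h")))
  cat(sprintf("  %d wells, %d concentrations in [%.3g, %.3g] uM\n",
              nrow(x), length(unique(x$conc_um)), min(x$conc_um), max(x$conc_um)))
  invisible(x)
}

#' Normalize raw absorbances to the untreated control
#'
#' MTT plate normalization: viability = 100 * (A - blank)/(A_control -
#' blank), where A_control is the mean absorbance of the untreated control
#' wells after blank subtraction.
#'
#' @param raw_absorbance Numeric matrix, one column per condition, rows =
#'   replicate wells.
#' @param control_column Index (or name) of the untreated-control column.
#' @param blank Background absorbance to subtract (scalar, default 0).
#' @param concentrations Concentration (uM) of each non-control column, in
#'   column order.
#' @param ... Labels passed to [dose_response_set()].
#' @return A [dose_response_set()] covering the non-control columns.
#' @export
normalize_to_control <- function(raw_absorbance, control_column, blank = 0,
                                 concentrations, ...) {
  A <- as.matrix(raw_absorbance)
  ctrl <- mean(A[, control_column]) - blank
  if (ctrl <= 0) {
    stop("control absorbance does not exceed blank: cannot normalize",
         call. = FALSE)
  }
  idx <- setdiff(seq_len(ncol(A)),
                 if (is.character(control_column)) {
                   match(control_column, colnames(A))
                 } else control_column)
  if (length(idx) != length(concentrations)) {
    stop("one concentration per non-control column is required", call. = FALSE)
  }
  viab <- 100 * (A[, idx, drop = FALSE] - blank) / ctrl
  dose_response_set(
    concentrations = rep(concentrations, each = nrow(A)),
    viability_percent = as.numeric(viab),
    replicate = rep(seq_len(nrow(A)), times = length(idx)),
    ...
  )
}

#' Fit IC50 by logistic regression of viability on concentration
#'
#' Two-parameter logistic with asymptotes fixed at 100/0 (percent of
#' control), [model_viability()]; `ic50` and the Hill slope are estimated by
#' bounded Levenberg-Marquardt on log(IC50). Replicates are averaged per
#' concentration before fitting. When the set carries externally measured
#' per-concentration SDs (a `viability_sd` column), the means are weighted
#' by inverse variance; variances re-estimated from a handful of replicate
#' wells are too noisy to weight by and are deliberately not used. With
#' `four_parameter = TRUE` the
#' asymptotes are estimated too (looser 4PL), and the reported `ic50` is
#' still the absolute IC50 — the concentration at 50% of control — obtained
#' from the fitted curve.
#'
#' The viability data must cross 50% of control: if every mean viability
#' stays above (or below) 50%, the IC50 is not estimable and an error
#' reports the nearest bound.
#'
#' @param data A [dose_response_set()].
#' @param four_parameter Fit the 4-parameter logistic instead.
#' @return An object of class `ic50_fit`: `ic50` (uM), `hill`, `ic50_se`,
#'   `hill_se`, `rms`, `four_parameter`, plus `cell_line`, `formulation`,
#'   `timepoint_h` carried from the input.
#' @examples
#' d <- gen_dose_response(5, 1.5, noise = noise_spec(0.05, seed = 3))
#' fit_ic50(d)
#' @export
fit_ic50 <- function(data, four_parameter = FALSE) {
  stopifnot(inherits(data, "dose_response_set"))
  df <- as.data.frame(data)
  agg <- stats::aggregate(viability_pct ~ conc_um, data = df, FUN = mean)
  w <- rep(1, nrow(agg))
  if ("viability_sd" %in% names(df)) {
    nrep <- stats::aggregate(viability_pct ~ conc_um, data = df,
                             FUN = length)$viability_pct
    sd <- stats::aggregate(viability_sd ~ conc_um, data = df,
                           FUN = mean)$viability_sd
    if (all(is.finite(sd)) && all(sd > 0)) w <- nrep / sd^2
  }
  conc <- agg$conc_um
  viab <- agg$viability_pct
  pos <- conc > 0
  if (!any(viab < 50) || !any(viab > 50)) {
    nearest <- viab[which.min(abs(viab - 50))]
    stop(sprintf(
      "IC50 not estimable: viability never crosses 50%% (nearest mean %.1f%%)",
      nearest), call. = FALSE)
  }

  # start IC50 at the concentration whose mean viability is nearest 50%
  lic0 <- log(conc[pos][which.min(abs(viab[pos] - 50))])
  if (four_parameter) {
    fit <- minpack.lm::nlsLM(
      viab ~ bottom + (top - bottom) / (1 + (conc / exp(lic))^hill),
      start = list(lic = lic0, hill = 1, top = 100, bottom = 0),
      lower = c(lic = log(1e-6), hill = 0.05, top = 50, bottom = -20),
      upper = c(lic = log(1e6), hill = 20, top = 150, bottom = 49),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    cf <- stats::coef(fit)
    # absolute IC50: concentration where the fitted curve crosses 50% of control
    ic50 <- exp(cf[["lic"]]) *
      ((cf[["top"]] - 50) / (50 - cf[["bottom"]]))^(1 / cf[["hill"]])
  } else {
    fit <- minpack.lm::nlsLM(
      viab ~ 100 / (1 + (conc / exp(lic))^hill),
      start = list(lic = lic0, hill = 1),
      lower = c(lic = log(1e-6), hill = 0.05),
      upper = c(lic = log(1e6), hill = 20),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    cf <- stats::coef(fit)
    ic50 <- exp(cf[["lic"]])
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                     names(cf)))
  structure(
    list(ic50 = unname(ic50), hill = unname(cf[["hill"]]),
         ic50_se = unname(ic50 * se[["lic"]]), # delta method on log scale
         hill_se = unname(se[["hill"]]),
         rms = sqrt(mean(stats::resid(fit)^2)),
         four_parameter = four_parameter,
         cell_line = attr(data, "cell_line"),
         formulation = attr(data, "formulation"),
         timepoint_h = attr(data, "timepoint_h")),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("<ic50_fit> %s / %s / %g h%s\n",
              x$cell_line, x$formulation, x$timepoint_h,
              if (x$four_parameter) " (4PL)" else ""))
  cat(sprintf("  IC50 = %.3g +/- %.2g uM, hill = %.3g, RMS = %.3g\n",
              x$ic50, x$ic50_se, x$hill, x$rms))
  invisible(x)
}

#' Tumor-vs-fibroblast selectivity summary
#'
#' Selectivity index per formulation and timepoint: the ratio of the IC50 in
#' the non-cancerous reference line to the IC50 in each tumor line. Ratios
#' above 1 indicate the formulation is more potent against the tumor line
#' than against normal cells.
#'
#' @param results List of `ic50_fit` objects (or a data.frame with columns
#'   `cell_line`, `formulation`, `timepoint_h`, `ic50`).
#' @param reference_line Name of the non-cancerous line (default "MRC-5").
#' @return A data.frame `formulation`, `timepoint_h`, `tumor_line`,
#'   `ic50_tumor`, `ic50_reference`, `selectivity`. Tumor results without a
#'   matched reference fit are skipped with a warning.
#' @export
selectivity_summary <- function(results, reference_line = "MRC-5") {
  df <- if (is.data.frame(results)) {
    results
  } else {
    do.call(rbind, lapply(results, function(r) {
      data.frame(cell_line = r$cell_line, formulation = r$formulation,
                 timepoint_h = r$timepoint_h, ic50 = r$ic50)
    }))
  }
  ref <- df[df$cell_line == reference_line, , drop = FALSE]
  tum <- df[df$cell_line != reference_line, , drop = FALSE]
  if (nrow(ref) == 0L || nrow(tum) == 0L) {
    stop("need results for at least one tumor line and the reference line",
         call. = FALSE)
  }
  out <- NULL
  for (i in seq_len(nrow(tum))) {
    m <- ref$formulation == tum$formulation[i] &
      ref$timepoint_h == tum$timepoint_h[i]
    if (!any(m)) {
      warning(sprintf("no %s IC50 for %s at %g h; skipped", reference_line,
                      tum$formulation[i], tum$timepoint_h[i]), call. = FALSE)
      next
    }
    out <- rbind(out, data.frame(
      formulation = tum$formulation[i], timepoint_h = tum$timepoint_h[i],
      tumor_line = tum$cell_line[i], ic50_tumor = tum$ic50[i],
      ic50_reference = ref$ic50[m][1],
      selectivity = ref$ic50[m][1] / tum$ic50[i]
    ))
  }
  out
}
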