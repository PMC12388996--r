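#' Parse "mean ± sd" cells
#'
#' Characterization tables are commonly exported with each cell as a
#' `"m ± s"` string (the SD part optional). Accepts the Unicode plus-minus
#' sign or the ASCII `+/-` spelling.
#'
#' @param x Character vector of cells.
#' @return A data.frame with numeric columns `mean` and `sd` (`sd` is `NA`
#'   where absent).
#' @examples
#' parse_mean_sd(c("126.0 ± 7.7", "0.17", "33.3 +/- 3.6"))
#' @export
parse_mean_sd <- function(x) {
  x <- trimws(as.character(x))
  parts <- strsplit(x, "±|\\+/-")
  mean <- vapply(parts, function(p) as.numeric(trimws(p[1])), numeric(1))
  sd <- vapply(parts, function(p) {
    if (length(p) >= 2L) as.numeric(trimws(p[2])) else NA_real_
  }, numeric(1))
  data.frame(mean = mean, sd = sd)
}

#' Construct formulation characterization records
#'
#' One row per formulation x timepoint with hydrodynamic size, PDI and zeta
#' potential (each mean, with optional replicate SD). Basic physical bounds
#' are enforced: positive size, PDI in [0, 1], non-negative timepoints.
#'
#' @param formulation Formulation labels.
#' @param timepoint_days Timepoints in days.
#' @param size_nm,pdi,zeta_mv Metric means.
#' @param size_sd,pdi_sd,zeta_sd Optional replicate SDs.
#' @return A data.frame of class `formulation_records`.
#' @export
formulation_records <- function(formulation, timepoint_days, size_nm, pdi,
                                zeta_mv, size_sd = NA_real_, pdi_sd = NA_real_,
                                zeta_sd = NA_real_) {
  df <- data.frame(
    formulation = as.character(formulation),
    timepoint_days = as.integer(timepoint_days),
    size_nm = as.numeric(size_nm), size_sd = as.numeric(size_sd),
    pdi = as.numeric(pdi), pdi_sd = as.numeric(pdi_sd),
    zeta_mv = as.numeric(zeta_mv), zeta_sd = as.numeric(zeta_sd)
  )
  if (any(df$size_nm <= 0)) stop("size_nm must be > 0", call. = FALSE)
  if (any(df$pdi < 0 | df$pdi > 1)) stop("pdi must lie in [0, 1]", call. = FALSE)
  if (any(df$timepoint_days < 0)) stop("timepoint_days must be >= 0", call. = FALSE)
  class(df) <- c("formulation_records", "data.frame")
  df
}

#' Read a formulation characterization table
#'
#' CSV layout: `formulation`, `timepoint_days`, `size_nm`, `size_sd`, `pdi`,
#' `pdi_sd`, `zeta_mv`, `zeta_sd` (SD columns optional). Size/PDI/zeta
#' columns given as `"m ± s"` strings are split automatically.
#'
#' Instrument exports occasionally drop a decimal separator, turning e.g.
#' 127.3 nm into 1273 nm. Rather than silently editing, the loader flags any
#' size more than `outlier_factor` times its formulation's median; with
#' `repair_decimal = TRUE` a flagged value is divided by the power of ten
#' that brings it closest to that median, and the repair is recorded in the
#' `size_repaired` column (and messaged).
#'
#' @param path CSV path.
#' @param repair_decimal Apply the decimal repair to flagged sizes.
#' @param outlier_factor Flag threshold as a multiple of the per-formulation
#'   median size.
#' @return A `formulation_records` data.frame with an extra logical column
#'   `size_repaired`.
#' @export
read_formulation_table <- function(path, repair_decimal = TRUE,
                                   outlier_factor = 5) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  split_col <- function(col, sd_col) {
    if (col %in% names(df) && is.character(df[[col]])) {
      ms <- parse_mean_sd(df[[col]])
      df[[col]] <<- ms$mean
      if (!sd_col %in% names(df)) df[[sd_col]] <<- ms$sd
    }
  }
  split_col("size_nm", "size_sd")
  split_col("pdi", "pdi_sd")
  split_col("zeta_mv", "zeta_sd")
  for (sd_col in c("size_sd", "pdi_sd", "zeta_sd")) {
    if (!sd_col %in% names(df)) df[[sd_col]] <- NA_real_
  }

  med <- stats::ave(df$size_nm, df$formulation, FUN = stats::median)
  flagged <- df$size_nm > outlier_factor * med
  repaired <- rep(FALSE, nrow(df))
  if (any(flagged)) {
    if (repair_decimal) {
      for (i in which(flagged)) {
        pow <- round(log10(df$size_nm[i] / med[i]))
        fixed <- df$size_nm[i] / 10^max(pow, 1)
        message(sprintf(
          "size outlier in '%s' day %s: %g nm > %g x median; decimal-repaired to %g nm",
          df$formulation[i], df$timepoint_days[i], df$size_nm[i],
          outlier_factor, fixed))
        df$size_nm[i] <- fixed
        repaired[i] <- TRUE
      }
    } else {
      warning(sprintf(
        "%d size value(s) exceed %g x their formulation median; a missing decimal separator is likely (set repair_decimal = TRUE to fix)",
        sum(flagged), outlier_factor), call. = FALSE)
    }
  }
  out <- formulation_records(df$formulation, df$timepoint_days, df$size_nm,
                             df$pdi, df$zeta_mv, df$size_sd, df$pdi_sd,
                             df$zeta_sd)
  out$size_repaired <- repaired
  out
}

#' Summarize a characterization table
#'
#' Global min/max/mean for each metric plus per-formulation time trends
#' (first and last value, net drift over the study window).
#'
#' @param records A `formulation_records` data.frame (or compatible).
#' @return List with `global` (data.frame metric x min/mean/max) and
#'   `trends` (data.frame formulation x metric with first/last/drift).
#' @export
summarize_formulations <- function(records) {
  if (NROW(records) < 1L) stop("no records to summarize", call. = FALSE)
  metrics <- c(size_nm = "size_nm", pdi = "pdi", zeta_mv = "zeta_mv")
  global <- do.call(rbind, lapply(names(metrics), function(m) {
    v <- records[[metrics[[m]]]]
    data.frame(metric = m, min = min(v), mean = mean(v), max = max(v))
  }))
  trends <- do.call(rbind, lapply(split(records, records$formulation), function(g) {
    g <- g[order(g$timepoint_days), ]
    do.call(rbind, lapply(names(metrics), function(m) {
      v <- g[[metrics[[m]]]]
      data.frame(formulation = g$formulation[1], metric = m,
                 first = v[1], last = v[length(v)],
                 drift = v[length(v)] - v[1])
    }))
  }))
  rownames(trends) <- NULL
  list(global = global, trends = trends)
}

#' Stability / injectability criteria
#'
#' Conventional acceptance thresholds for injectable liposomal carriers:
#' hydrodynamic diameter below 200 nm, PDI at or below 0.3 (homogeneous
#' population), and zeta potential magnitude above 30 mV (electrostatic
#' colloidal stability, regardless of sign).
#'
#' @param max_size_nm Maximum acceptable diameter, nm.
#' @param max_pdi Maximum acceptable polydispersity index.
#' @param min_abs_zeta_mv Minimum acceptable |zeta|, mV.
#' @return An object of class `qc_criteria`.
#' @export
qc_criteria <- function(max_size_nm = 200, max_pdi = 0.3,
                        min_abs_zeta_mv = 30) {
  stopifnot(max_size_nm > 0, max_pdi > 0, min_abs_zeta_mv > 0)
  structure(list(max_size_nm = max_size_nm, max_pdi = max_pdi,
                 min_abs_zeta_mv = min_abs_zeta_mv),
            class = "qc_criteria")
}

#' Screen a characterization table against stability criteria
#'
#' Flags each record on the three criteria (size strictly below the maximum,
#' PDI at or below the maximum, |zeta| strictly above the minimum). A
#' formulation passes overall only if all of its records pass all criteria.
#'
#' @param records A `formulation_records` data.frame.
#' @param criteria A [qc_criteria()].
#' @return List with `records` (input plus logical columns `size_ok`,
#'   `pdi_ok`, `zeta_ok`, `pass`) and `formulations` (data.frame
#'   `formulation`, `pass`).
#' @export
check_stability <- function(records, criteria = qc_criteria()) {
  if (NROW(records) < 1L) stop("no records to check", call. = FALSE)
  stopifnot(inherits(criteria, "qc_criteria"))
  rec <- as.data.frame(records)
  rec$size_ok <- rec$size_nm < criteria$max_size_nm
  rec$pdi_ok <- rec$pdi <= criteria$max_pdi
  rec$zeta_ok <- abs(rec$zeta_mv) > criteria$min_abs_zeta_mv
  rec$pass <- rec$size_ok & rec$pdi_ok & rec$zeta_ok
  forms <- stats::aggregate(pass ~ formulation, data = rec, FUN = all)
  list(records = rec, formulations = forms)
}

#' Encapsulation efficiency
#'
#' EE = 100 * C_en / C_in, the percentage of the loaded compound actually
#' retained in the carrier: C_en is the concentration recovered from the
#' disrupted liposomes (by HPLC) and C_in the concentration used in the
#' preparation. Values above 100% are physically impossible but can arise
#' from assay noise; they are returned as-is with a warning, never clamped.
#'
#' @param c_encapsulated Measured (encapsulated) concentration, >= 0.
#' @param c_initial Initial (loading) concentration, > 0. Units cancel as
#'   long as they match.
#' @param compound Optional label used in the warning.
#' @return EE in percent.
#' @examples
#' encapsulation_efficiency(53.019, 62.5) # 84.83%
#' @export
encapsulation_efficiency <- function(c_encapsulated, c_initial, compound = "") {
  stopifnot(is.numeric(c_encapsulated), is.numeric(c_initial))
  if (any(c_initial <= 0)) {
    stop("c_initial must be > 0 (EE is undefined without loading)", call. = FALSE)
  }
  if (any(c_encapsulated < 0)) {
    stop("c_encapsulated must be >= 0", call. = FALSE)
  }
  ee <- 100 * c_encapsulated / c_initial
  if (any(ee > 100)) {
    warning(sprintf(
      "EE above 100%% (%s): measurement noise, reported unclamped",
      paste(sprintf("%.2f%%", ee[ee > 100]), collapse = ", ")),
      call. = FALSE)
  }
  ee
}
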