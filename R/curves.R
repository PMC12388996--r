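#' Relaxation curve container
#'
#' Time-stamped magnetization samples from a T1 (saturation-recovery) or T2
#' (transverse-decay) experiment. Times must be strictly increasing and at
#' least 8 points are required so the curves are fittable.
#'
#' @param times Sampling times in seconds, strictly increasing, >= 0.
#' @param magnetization Magnetization values (arbitrary units), same length.
#' @param kind One of `"saturation_recovery"` or `"transverse_decay"`.
#' @param label Free-text label carried into fit messages and reports.
#' @return A data.frame of class `relaxation_curve` with columns `t_s`, `M`
#'   and attributes `kind` and `label`.
#' @export
relaxation_curve <- function(times, magnetization,
                             kind = c("saturation_recovery", "transverse_decay"),
                             label = "") {
  kind <- match.arg(kind)
  stopifnot(is.numeric(times), is.numeric(magnetization))
  if (length(times) != length(magnetization)) {
    stop("times and magnetization must have the same length", call. = FALSE)
  }
  if (length(times) < 8L) {
    stop("a relaxation curve needs at least 8 points", call. = FALSE)
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  }
  structure(
    data.frame(t_s = as.numeric(times), M = as.numeric(magnetization)),
    kind = kind, label = label,
    class = c("relaxation_curve", "data.frame")
  )
}

#' @export
print.relaxation_curve <- function(x, ...) {
  cat(sprintf("<relaxation_curve: %s> %s\n", attr(x, "kind"), attr(x, "label")))
  cat(sprintf("  %d points, t in [%.4g, %.4g] s, M in [%.4g, %.4g]\n",
              nrow(x), min(x$t_s), max(x$t_s), min(x$M), max(x$M)))
  invisible(x)
}

#' Read / write a relaxation curve as CSV
#'
#' CSV layout: columns `t_s` (seconds) and `M` (arbitrary units); `kind` and
#' `label` round-trip through `#`-prefixed header comments.
#'
#' @param path File path.
#' @param curve A [relaxation_curve()].
#' @return `read_relaxation_curve` returns a `relaxation_curve`;
#'   `write_relaxation_curve` returns `path` invisibly.
#' @export
read_relaxation_curve <- function(path) {
  header <- readLines(path, n = 10L)
  meta <- .parse_hash_meta(header)
  df <- utils::read.csv(path, comment.char = "#")
  relaxation_curve(df$t_s, df$M,
                   kind = meta[["kind"]] %||% "saturation_recovery",
                   label = meta[["label"]] %||% "")
}

#' @rdname read_relaxation_curve
#' @export
write_relaxation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "relaxation_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", attr(curve, "kind")),
               sprintf("# label: %s", attr(curve, "label"))), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' Off-resonance saturation profile container
#'
#' Pairs of offset frequency Delta f and measured equilibrium magnetization
#' ratio M_rho/M0. Offsets must be nonzero and strictly increasing in
#' magnitude; ratios may spill slightly outside [0, 1] through noise, but
#' values outside [-0.1, 1.1] are rejected as non-physical.
#'
#' @param offsets_hz Offsets Delta f in Hz, nonzero, strictly increasing in
#'   absolute value.
#' @param ratios Measured M_rho/M0 values.
#' @param label Free-text label.
#' @return A data.frame of class `offres_profile` with columns `delta_f_hz`,
#'   `ratio` and a `label` attribute.
#' @export
offres_profile <- function(offsets_hz, ratios, label = "") {
  stopifnot(is.numeric(offsets_hz), is.numeric(ratios))
  if (length(offsets_hz) != length(ratios)) {
    stop("offsets and ratios must have the same length", call. = FALSE)
  }
  if (any(offsets_hz == 0)) {
    stop("offsets must be nonzero (the on-resonance ratio is identically 0)",
         call. = FALSE)
  }
  if (any(diff(abs(offsets_hz)) <= 0)) {
    stop("offsets must be strictly increasing in magnitude", call. = FALSE)
  }
  if (any(ratios < -0.1 | ratios > 1.1)) {
    stop("ratios outside [-0.1, 1.1] are not physical M_rho/M0 values",
         call. = FALSE)
  }
  structure(
    data.frame(delta_f_hz = as.numeric(offsets_hz), ratio = as.numeric(ratios)),
    label = label,
    class = c("offres_profile", "data.frame")
  )
}

#' @export
print.offres_profile <- function(x, ...) {
  cat(sprintf("<offres_profile> %s\n", attr(x, "label")))
  cat(sprintf("  %d offsets, |df| in [%.4g, %.4g] kHz, ratio in [%.3f, %.3f]\n",
              nrow(x), min(abs(x$delta_f_hz)) / 1e3, max(abs(x$delta_f_hz)) / 1e3,
              min(x$ratio), max(x$ratio)))
  invisible(x)
}

#' Read / write an off-resonance profile as CSV
#'
#' CSV layout: columns `delta_f_hz`, `ratio`; the label round-trips through a
#' `#`-prefixed header comment.
#'
#' @param path File path.
#' @param profile An [offres_profile()].
#' @return `read_offres_profile` returns an `offres_profile`;
#'   `write_offres_profile` returns `path` invisibly.
#' @export
read_offres_profile <- function(path) {
  meta <- .parse_hash_meta(readLines(path, n = 10L))
  df <- utils::read.csv(path, comment.char = "#")
  offres_profile(df$delta_f_hz, df$ratio, label = meta[["label"]] %||% "")
}

#' @rdname read_offres_profile
#' @export
write_offres_profile <- function(profile, path) {
  stopifnot(inherits(profile, "offres_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label: %s", attr(profile, "label")), con)
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_hash_meta <- function(lines) {
  lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([a-zA-Z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}
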