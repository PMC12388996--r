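#' Packaged reference datasets
#'
#' The package ships the reference characterization of the DOTAP:POPC (2:8)
#' cationic liposome formulations carrying acteoside (ACT) alone or co-loaded
#' with cannabidiol (CBD) or naringenin (NG), as plain-text CSVs under
#' `inst/extdata`:
#'
#' * `reference_stability()` — 21-day size/PDI/zeta table (4 formulations x
#'   4 timepoints). One instrument-exported size cell is missing its decimal
#'   separator; by default the loader's decimal-repair rule fixes and flags
#'   it (see [read_formulation_table()]).
#' * `reference_relaxation()` — laboratory-frame T1 and Gaussian/Lorentzian
#'   T2 decomposition per material.
#' * `reference_offresonance()` — fitted K (with uncertainty) and rotational
#'   correlation time per material.
#' * `reference_ic50()` — IC50 (uM) per formulation x cell line x timepoint.
#' * `reference_encapsulation()` — encapsulation efficiencies and loading
#'   concentrations per compound.
#'
#' These tables serve both as realistic parameter sets for the synthetic
#' generators and as the comparison column in [render_comparison()].
#'
#' @param repair_decimal Passed to [read_formulation_table()]
#'   (`reference_stability` only).
#' @return A data.frame (for `reference_stability`, a
#'   `formulation_records`).
#' @name reference_data
NULL

.extdata <- function(file) {
  system.file("extdata", file, package = "liporelax", mustWork = TRUE)
}

#' @rdname reference_data
#' @export
reference_stability <- function(repair_decimal = TRUE) {
  suppressMessages(
    read_formulation_table(.extdata("dotap_popc_stability.csv"),
                           repair_decimal = repair_decimal)
  )
}

#' @rdname reference_data
#' @export
reference_relaxation <- function() {
  utils::read.csv(.extdata("reference_relaxation.csv"), comment.char = "#")
}

#' @rdname reference_data
#' @export
reference_offresonance <- function() {
  utils::read.csv(.extdata("reference_offresonance.csv"), comment.char = "#")
}

#' @rdname reference_data
#' @export
reference_ic50 <- function() {
  utils::read.csv(.extdata("reference_ic50.csv"), comment.char = "#",
                  check.names = FALSE)
}

#' @rdname reference_data
#' @export
reference_encapsulation <- function() {
  utils::read.csv(.extdata("reference_encapsulation.csv"), comment.char = "#")
}
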