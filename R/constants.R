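#' Physical constants used throughout the package
#'
#' Avogadro's number (exact SI value) and the gas constant in
#' kcal mol^-1 K^-1, the unit in which allosteric coupling free energies
#' are conventionally reported for metal sensors.
#'
#' @name metalsens-constants
#' @keywords internal
NULL

AVOGADRO <- 6.02214076e23          # mol^-1
RGAS_KCAL <- 1.98720e-3            # kcal mol^-1 K^-1

#' Dissociation constants of the spectroscopic metal probes
#'
#' The chelator/fluorophore probes used for competition determination of
#' sensor metal affinities, with their conditional dissociation constants at
#' pH 7.0: fura-2 for Co(II), EGTA for Co(II) (conditional constant by the
#' alpha-coefficient method, taken as given), and magfura-2 and quin-2 for
#' Zn(II).
#'
#' @return A data.frame with columns \code{probe}, \code{metal} and
#'   \code{kd_M} (molar).
#' @export
#' @examples
#' chelator_constants()
chelator_constants <- function() {
  data.frame(
    probe = c("fura-2", "EGTA", "magfura-2", "quin-2"),
    metal = c("Co", "Co", "Zn", "Zn"),
    kd_M  = c(8.64e-9, 7.89e-9, 2e-8, 3.7e-12),
    stringsAsFactors = FALSE
  )
}

#' Cell context for copies-to-concentration conversion
#'
#' @param volume Cell volume in litres. Default 1 fl (1e-15 l), the volume
#'   used to convert sensor assemblies and DNA targets per cell to molar.
#' @param temperature Temperature in kelvin, used for free-energy
#'   calculations. Default 298.15 K.
#' @return An object of class \code{cell_context}.
#' @export
cell_context <- function(volume = 1e-15, temperature = 298.15) {
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0)
    stop("`volume` must be a single positive number (litres)")
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("`temperature` must be a single positive number (kelvin)")
  structure(list(volume = volume, temperature = temperature),
            class = "cell_context")
}

#' Convert copies per cell to a molar concentration
#'
#' @param copies Number of molecules (assemblies, DNA targets) per cell;
#'   non-negative.
#' @param cell A \code{\link{cell_context}}.
#' @return Concentration in molar: \code{copies / (N_A * volume)}.
#' @export
#' @examples
#' copies_to_concentration(21)   # 21 dimers in 1 fl -> ~3.5e-8 M
copies_to_concentration <- function(copies, cell = cell_context()) {
  stopifnot(inherits(cell, "cell_context"))
  if (!is.numeric(copies) || any(!is.finite(copies)) || any(copies < 0))
    stop("`copies` must be non-negative and finite")
  copies / (AVOGADRO * cell$volume)
}
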