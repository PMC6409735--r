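#' @keywords internal
#' @useDynLib adcpkpd
"_PACKAGE"

#' Physical constants
#'
#' `AVOGADRO` is the 2019 SI definition of Avogadro's number.  `SF` is the
#' scaling factor that converts a count of molecules to nanomoles
#' (`1e9 / AVOGADRO`, about 1.66e-15 nmol/molecule); it is the bridge between
#' per-cell species (molecules/cell) and the extracellular balances (nmol, nM).
#'
#' @format Numeric scalars.
#' @export
AVOGADRO <- 6.02214076e23

#' @rdname AVOGADRO
#' @export
SF <- 1e9 / AVOGADRO

#' Convert an mg/kg antibody dose to nanomoles
#'
#' Intravenous bolus doses are prescribed in mg/kg while the disposition
#' model runs in molar amounts; this converts using the conjugate's molar
#' mass and, optionally, the animal's body weight.
#'
#' @param dose_mg_per_kg Dose in mg antibody per kg body weight.
#' @param MW_ADC Molar mass of the conjugate in g/mol.
#' @param body_weight Body weight in kg.
#' @return A list with `nmol_per_kg` and `nmol` (per-animal amount).
#' @examples
#' dose_to_nmol(10, 150000, 0.02)  # 66.67 nmol/kg, 1.333 nmol/animal
#' @export
dose_to_nmol <- function(dose_mg_per_kg, MW_ADC = 150000, body_weight = 0.02) {
  if (any(dose_mg_per_kg < 0)) stop("dose must be non-negative")
  if (MW_ADC <= 0 || body_weight <= 0) {
    stop("MW_ADC and body_weight must be positive")
  }
  nmol_per_kg <- dose_mg_per_kg * 1e6 / MW_ADC
  list(nmol_per_kg = nmol_per_kg, nmol = nmol_per_kg * body_weight)
}

#' Radius of a spherical tumor from its volume
#'
#' @param TV_liters Tumor volume in litres.
#' @return Radius in cm of a sphere with that volume.
#' @examples
#' radius_from_volume(0.001)  # 1000 mm^3 -> 0.6204 cm
#' @export
radius_from_volume <- function(TV_liters) {
  if (any(TV_liters <= 0)) stop("tumor volume must be positive")
  (3 * TV_liters * 1000 / (4 * pi))^(1 / 3)
}

#' Tumor volume from radius (round-trip companion of [radius_from_volume()])
#' @param R_cm Radius in cm.
#' @return Volume in litres.
#' @export
volume_from_radius <- function(R_cm) {
  4 / 3 * pi * R_cm^3 / 1000
}

#' Number of tumor cells in a given volume
#'
#' Assumes a fixed cell density; the default 1e5 cells/mm^3 corresponds to
#' 1e8 cells per gram of tumor at unit density.
#'
#' @param TV_mm3 Tumor volume in mm^3.
#' @param cells_per_mm3 Cell density, cells per mm^3.
#' @return Cell count.
#' @export
cells_from_volume <- function(TV_mm3, cells_per_mm3 = 1e5) {
  if (any(TV_mm3 < 0)) stop("tumor volume must be non-negative")
  if (cells_per_mm3 <= 0) stop("cells_per_mm3 must be positive")
  TV_mm3 * cells_per_mm3
}

#' Tubulin copies per cell from its intracellular concentration
#'
#' @param Tub_tot_conc Total tubulin concentration in nM.
#' @param V_cell Single-cell volume in litres.
#' @return Molecules per cell.
#' @examples
#' tubulin_molecules_per_cell(65, 1e-12)  # ~39,144 molecules
#' @export
tubulin_molecules_per_cell <- function(Tub_tot_conc, V_cell = 1e-12) {
  if (any(Tub_tot_conc < 0) || V_cell <= 0) {
    stop("tubulin concentration must be non-negative and V_cell positive")
  }
  Tub_tot_conc * 1e-9 * V_cell * AVOGADRO
}
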