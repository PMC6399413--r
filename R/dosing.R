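# Label-dose arithmetic for the chamber CO2 pulses and the 15N solution.

#' Chamber CO2 mixing ratio from an injected gas volume
#'
#' Converts a volume of gas injected into a closed labeling chamber into the
#' resulting mixing ratio in parts per million by volume. Chamber dimensions
#' are given in millimetres; a 1350 x 545 x 320 mm chamber receiving 60 ml
#' of 13C-CO2 corresponds to roughly 255 ppm per injection.
#'
#' @param injected_volume_ml Injected gas volume in ml, `>= 0`.
#' @param chamber_dims_mm Numeric vector of three chamber edge lengths in mm,
#'   all `> 0`.
#'
#' @return Mixing ratio in ppm by volume.
#'
#' @examples
#' chamber_mixing_ratio(60, c(1350, 545, 320))
#' @export
chamber_mixing_ratio <- function(injected_volume_ml, chamber_dims_mm) {
  check_finite_numeric(injected_volume_ml, "injected_volume_ml")
  check_finite_numeric(chamber_dims_mm, "chamber_dims_mm")
  if (length(chamber_dims_mm) != 3L) {
    abort("`chamber_dims_mm` must contain three edge lengths.")
  }
  if (any(chamber_dims_mm <= 0)) abort("Chamber dimensions must be > 0.")
  if (any(injected_volume_ml < 0)) abort("`injected_volume_ml` must be >= 0.")
  chamber_ml <- prod(chamber_dims_mm) / 1000  # mm^3 -> ml
  injected_volume_ml / chamber_ml * 1e6
}

#' Nitrogen mass delivered by a dosing solution
#'
#' Mass of elemental N (mg) contained in a volume of solution at a given
#' molar N concentration. With the default molar mass of 14.003 g/mol, 12 ml
#' of a 1 mM N solution delivers 0.168 mg N.
#'
#' @param volume_ml Solution volume in ml, `>= 0`.
#' @param concentration_mM Nitrogen concentration in mmol N per litre, `>= 0`.
#' @param n_molar_mass Molar mass used for the elemental accounting, g/mol.
#'
#' @return Nitrogen mass in mg.
#'
#' @examples
#' dose_nitrogen_mass(12, 1)  # 0.168 mg N
#' @export
dose_nitrogen_mass <- function(volume_ml, concentration_mM,
                               n_molar_mass = 14.003) {
  check_finite_numeric(volume_ml, "volume_ml")
  check_finite_numeric(concentration_mM, "concentration_mM")
  check_finite_numeric(n_molar_mass, "n_molar_mass")
  if (any(volume_ml < 0) || any(concentration_mM < 0) || any(n_molar_mass < 0)) {
    abort("All dose arguments must be >= 0.")
  }
  # ml -> l, mM -> M, mol -> g, g -> mg
  (volume_ml / 1000) * (concentration_mM / 1000) * n_molar_mass * 1000
}

#' Molar N concentration of a substrate solution
#'
#' Converts a mass concentration of an N-bearing substrate into mmol of N
#' per litre. 54.5 mg/l of NH4Cl (53.49 + 1 g/mol for the 15N salt, approx
#' 54.49) is 1 mM N; 140 mg/l of an amino acid mixture with an assumed mean
#' molar weight of 140 g/mol is likewise 1 mM N.
#'
#' @param mass_conc Substrate concentration in mg per litre, `>= 0`.
#' @param molar_mass Substrate molar mass in g/mol, `> 0`.
#' @param n_atoms_per_molecule N atoms per substrate molecule, integer
#'   `>= 1`.
#'
#' @return N concentration in mM.
#'
#' @examples
#' molar_n_concentration(54.5, 54.49)   # 15NH4Cl
#' molar_n_concentration(140, 140)      # amino acid mixture
#' @export
molar_n_concentration <- function(mass_conc, molar_mass,
                                  n_atoms_per_molecule = 1L) {
  check_finite_numeric(mass_conc, "mass_conc")
  check_finite_numeric(molar_mass, "molar_mass")
  if (any(molar_mass <= 0)) abort("`molar_mass` must be > 0.")
  if (any(mass_conc < 0)) abort("`mass_conc` must be >= 0.")
  if (any(n_atoms_per_molecule < 1)) {
    abort("`n_atoms_per_molecule` must be >= 1.")
  }
  mass_conc / molar_mass * n_atoms_per_molecule
}
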