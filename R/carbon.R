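# Elemental carbon bookkeeping for the end-point carbon balance.
#
# C-mol contents are derived from molecular formulas: glucose C6H12O6,
# citrate C6H8O7, lactate C3H6O3, acetate C2H4O2, ethanol C2H6O, succinate
# C4H6O4. Biomass defaults to the generic composition CH1.8O0.5N0.2
# (24.6 g per C-mol), overridable where the balance is computed.

.carbon_atoms <- c(glucose = 6, citrate = 6, lactate = 3, acetate = 2,
                   ethanol = 2, succinate = 4)
.molar_mass <- c(glucose = 180.156, citrate = 192.124, lactate = 90.078,
                 acetate = 60.052, ethanol = 46.068, succinate = 118.088)

#' C-mol per gram of a fermentation compound
#'
#' @param compound one of `"glucose"`, `"citrate"`, `"lactate"`,
#'   `"acetate"`, `"ethanol"`, `"succinate"`, or `"biomass"`.
#' @param biomass_gram_per_cmol grams of cell dry weight per C-mol of
#'   biomass (default 24.6, the generic composition CH1.8O0.5N0.2).
#' @return C-mol contained in one gram of the compound.
#' @examples
#' cmol_per_gram("glucose") # 6 / 180.156
#' @export
cmol_per_gram <- function(compound, biomass_gram_per_cmol = 24.6) {
  if (identical(compound, "biomass")) {
    return(1 / biomass_gram_per_cmol)
  }
  if (!compound %in% names(.carbon_atoms)) {
    abort("unknown compound '%s'; known: %s, biomass", compound,
          paste(names(.carbon_atoms), collapse = ", "))
  }
  unname(.carbon_atoms[compound] / .molar_mass[compound])
}

# Moles (not C-mol) per gram, for the CO2 estimate.
mol_per_gram <- function(compound) {
  unname(1 / .molar_mass[compound])
}
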