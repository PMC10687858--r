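# Physical constants and element data used throughout.
# Internal units: bohr for lengths, Hartree for energies, electron masses
# for particle masses.  XYZ files are read/written in Angstrom.

#' Bohr per Angstrom conversion factor
#' @export
BOHR_PER_ANGSTROM <- 1 / 0.52917721092

#' kcal/mol per Hartree conversion factor
#' @export
HARTREE_TO_KCALMOL <- 627.509474

#' Mass of the proton in electron masses (CODATA)
#' @export
PROTON_MASS <- 1836.15267343

#' Mass of the deuteron in electron masses (CODATA)
#' @export
DEUTERON_MASS <- 3670.48296788

# element symbol -> nuclear charge
.element_z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18
)

# covalent radii in Angstrom (Cordero et al. style values), used only for
# bond detection when extending local-fitting domains
.covalent_radius <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06
)

`%||%` <- function(a, b) if (is.null(a)) b else a

element_charge <- function(sym) {
  z <- .element_z[sym]
  if (any(is.na(z))) {
    stop("unknown element symbol(s): ", paste(sym[is.na(z)], collapse = ", "))
  }
  unname(z)
}
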