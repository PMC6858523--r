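# Physical constants and element tables (CODATA 2018).

HARTREE_EV <- 27.211386245988
BOHR_ANGSTROM <- 0.529177210903
KB_EV <- 8.617333262e-5            # Boltzmann constant, eV/K
EANG_DEBYE <- 4.803204             # 1 e*Angstrom in Debye
ACC_UNIT <- 9.648533212e-3         # (eV/Angstrom)/amu -> Angstrom/fs^2
KE_UNIT <- 1.036426966e2           # amu*(Angstrom/fs)^2 -> eV

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

# Standard atomic masses (amu) for Z = 1..36, used by the MD integrator.
ELEMENT_MASSES <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798
)

symbol_to_z <- function(sym) {
  z <- match(sym, ELEMENT_SYMBOLS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ", paste(unique(sym[is.na(z)]), collapse = ", "))
  }
  z
}

z_to_symbol <- function(z) {
  if (any(z < 1L | z > length(ELEMENT_SYMBOLS))) {
    stop("nuclear charge outside supported range 1..", length(ELEMENT_SYMBOLS))
  }
  ELEMENT_SYMBOLS[z]
}

element_mass <- function(z) ELEMENT_MASSES[z]
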