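# Physical constants (CODATA 2018) and mass constants used throughout.
# Energies are kJ/mol everywhere; entropies J/mol/K; lengths in Angstrom.

.const <- list(
  h       = 6.62607015e-34,     # J s
  c_cm    = 2.99792458e10,      # cm/s (frequencies arrive in cm^-1)
  kB      = 1.380649e-23,       # J/K
  N_A     = 6.02214076e23,      # 1/mol
  R       = 8.314462618,        # J/mol/K
  amu     = 1.66053906660e-27,  # kg
  atm_Pa  = 101325,             # Pa per atm
  hartree_kJmol = 2625.4996,    # kJ/mol per hartree
  kcal_kJ = 4.184,
  eV_kJmol = 96.48533212,
  water_mono = 18.010565,       # Da
  water_avg  = 18.01528,
  proton_mono = 1.007276,       # Da, charge carrier
  proton_avg  = 1.00739,
  co_mono = 27.994915,          # Da, a-ion = b-ion - CO
  co_avg  = 28.0101
)

# gas constant in kJ/mol/K, used for Boltzmann factors
.R_kJ <- .const$R / 1000

# Standard atomic weights for the elements that occur in (protonated)
# peptides, used for molecular mass and moments of inertia.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.973761998, F = 18.998403163, Cl = 35.45, Se = 78.971,
  Na = 22.98976928, K = 39.0983, Ar = 39.948
)

element_mass <- function(elements) {
  m <- .element_masses[elements]
  if (anyNA(m)) {
    bad <- unique(elements[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}

# unit -> kJ/mol conversion for ensemble input energies
energy_to_kjmol <- function(value, unit) {
  fac <- switch(tolower(unit),
    "hartree" = .const$hartree_kJmol,
    "kcal/mol" = , "kcal_mol" = , "kcal.mol-1" = .const$kcal_kJ,
    "kj/mol" = , "kj_mol" = , "kj.mol-1" = 1,
    "ev" = .const$eV_kJmol,
    stop("unknown energy unit: '", unit, "'", call. = FALSE)
  )
  value * fac
}
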