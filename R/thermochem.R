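#' Thermochemical conditions
#'
#' Temperature and pressure for the harmonic-oscillator / rigid-rotor /
#' ideal-gas corrections. Defaults are the ion-trap operating point read
#' off the instrument: 443.15 K (transfer-tube temperature) and
#' 2.2e-8 atm (trap pressure).
#'
#' @param temperature Kelvin (> 0).
#' @param pressure atm (> 0).
#' @param frequency_scale Multiplicative scaling of harmonic frequencies
#'   (default 1, i.e. unscaled).
#' @param low_frequency_floor Optional floor in cm^-1: real modes below
#'   it are raised to the floor before the vibrational sums, a crude way
#'   to probe the sensitivity of entropies to the low-frequency modes of
#'   floppy molecules. `NULL` (default) leaves modes untouched.
#' @param on_imaginary `"drop"` (default; imaginary modes are removed
#'   and counted) or `"error"`.
#' @return A list of class `thermo_conditions`.
#' @export
thermo_conditions <- function(temperature = 443.15, pressure = 2.2e-8,
                              frequency_scale = 1.0,
                              low_frequency_floor = NULL,
                              on_imaginary = c("drop", "error")) {
  stopifnot(temperature > 0, pressure > 0, frequency_scale > 0)
  structure(list(temperature = temperature, pressure = pressure,
                 frequency_scale = frequency_scale,
                 low_frequency_floor = low_frequency_floor,
                 on_imaginary = match.arg(on_imaginary)),
            class = "thermo_conditions")
}

#' Harmonic vibrational contributions
#'
#' For each real mode with wavenumber v and x = h c v / (kB T): the
#' zero-point term is N_A h c v / 2, the thermal energy term
#' N_A h c v / (exp(x) - 1), and the entropy term
#' R * (x / (exp(x) - 1) - log(1 - exp(-x))). Negative wavenumbers
#' encode imaginary modes and are dropped (counted) or raise an error,
#' depending on the conditions.
#'
#' @param frequencies Wavenumbers in cm^-1; negatives = imaginary modes.
#' @param conditions A [thermo_conditions()] object.
#' @return List with `zpe` and `thermal_vib` (kJ/mol), `vib_entropy`
#'   (J/mol/K) and `n_imaginary_dropped`.
#' @export
vibrational_terms <- function(frequencies, conditions = thermo_conditions()) {
  temp <- conditions$temperature
  imag <- frequencies <= 0
  n_imag <- sum(imag)
  if (n_imag > 0L && conditions$on_imaginary == "error") {
    stop(n_imag, " imaginary mode(s) present", call. = FALSE)
  }
  nu <- frequencies[!imag] * conditions$frequency_scale
  if (length(nu) == 0L) {
    if (length(frequencies) > 0L) {
      stop("all vibrational modes are imaginary", call. = FALSE)
    }
    warning("empty frequency list: vibrational terms are zero")
    return(list(zpe = 0, thermal_vib = 0, vib_entropy = 0,
                n_imaginary_dropped = 0L))
  }
  if (!is.null(conditions$low_frequency_floor)) {
    nu <- pmax(nu, conditions$low_frequency_floor)
  }
  if (n_imag > 0L) {
    warning("dropped ", n_imag, " imaginary mode(s)")
  }
  hc_nu <- .const$h * .const$c_cm * nu            # J per molecule
  x <- hc_nu / (.const$kB * temp)
  zpe <- sum(.const$N_A * hc_nu / 2) / 1000       # kJ/mol
  thermal <- sum(.const$N_A * hc_nu / expm1(x)) / 1000
  s_vib <- .const$R * sum(x / expm1(x) - log1p(-exp(-x)))
  list(zpe = zpe, thermal_vib = thermal, vib_entropy = s_vib,
       n_imaginary_dropped = as.integer(n_imag))
}

# principal moments of inertia in amu * Angstrom^2
principal_moments <- function(elements, coords) {
  m <- element_mass(elements)
  com <- colSums(coords * m) / sum(m)
  x <- sweep(coords, 2, com)
  ixx <- sum(m * (x[, 2]^2 + x[, 3]^2))
  iyy <- sum(m * (x[, 1]^2 + x[, 3]^2))
  izz <- sum(m * (x[, 1]^2 + x[, 2]^2))
  ixy <- -sum(m * x[, 1] * x[, 2])
  ixz <- -sum(m * x[, 1] * x[, 3])
  iyz <- -sum(m * x[, 2] * x[, 3])
  tens <- matrix(c(ixx, ixy, ixz, ixy, iyy, iyz, ixz, iyz, izz), 3, 3)
  sort(eigen(tens, symmetric = TRUE, only.values = TRUE)$values)
}

#' Rigid-rotor rotational contributions (nonlinear molecules)
#'
#' Principal moments of inertia come from the eigenvalues of the
#' mass-weighted inertia tensor; the symmetry number is fixed at 1
#' (peptides are asymmetric). Linear/collinear geometries are rejected.
#'
#' @param elements Element symbols.
#' @param coords N x 3 coordinates, Angstrom.
#' @param temperature Kelvin.
#' @return List with `rot_energy` = 3/2 R T (kJ/mol), `rot_entropy`
#'   (J/mol/K) and `moments` (amu Angstrom^2).
#' @export
rotational_terms <- function(elements, coords, temperature = 443.15) {
  if (length(elements) < 3L) {
    stop("rotational terms need >= 3 non-collinear atoms", call. = FALSE)
  }
  mom <- principal_moments(elements, coords)
  if (mom[1] < 1e-8 * mom[3]) {
    stop("collinear geometry: linear-rotor thermochemistry not supported",
         call. = FALSE)
  }
  i_si <- mom * .const$amu * 1e-20                # kg m^2
  theta <- .const$h^2 / (8 * pi^2 * i_si * .const$kB)   # rotational temps
  q_rot <- sqrt(pi) * sqrt(temperature^3 / prod(theta)) # sigma = 1
  list(rot_energy = 1.5 * .const$R * temperature / 1000,
       rot_entropy = .const$R * (1.5 + log(q_rot)),
       moments = mom)
}

#' Ideal-gas translational contributions
#'
#' Sackur-Tetrode entropy at the stated temperature and pressure, and
#' the classical translational energy 3/2 R T.
#'
#' @param molecular_mass g/mol.
#' @param temperature Kelvin.
#' @param pressure atm.
#' @return List with `trans_energy` (kJ/mol) and `trans_entropy`
#'   (J/mol/K).
#' @export
translational_terms <- function(molecular_mass, temperature = 443.15,
                                pressure = 2.2e-8) {
  stopifnot(molecular_mass > 0, temperature > 0, pressure > 0)
  m_kg <- molecular_mass / 1000 / .const$N_A
  p_pa <- pressure * .const$atm_Pa
  lambda3 <- (2 * pi * m_kg * .const$kB * temperature / .const$h^2)^1.5
  q_trans <- lambda3 * .const$kB * temperature / p_pa
  list(trans_energy = 1.5 * .const$R * temperature / 1000,
       trans_entropy = .const$R * (log(q_trans) + 2.5))
}

#' Thermochemical corrections for every conformer of an ensemble
#'
#' Converts harmonic frequencies plus geometry into the corrections that
#' turn an electronic energy into an enthalpy or Gibbs free energy:
#' `enthalpy_correction = ZPE + thermal vibrational energy + 3/2 RT
#' (rotation) + 3/2 RT (translation) + RT (pV)`, `entropy = vibrational
#' + rotational + translational`, `gibbs_correction =
#' enthalpy_correction - T * entropy`.
#'
#' @param ens Ensemble tibble; every conformer must carry frequencies.
#' @param conditions A [thermo_conditions()] object.
#' @param include Character subset of
#'   `c("vibrational", "rotational", "translational")` to include in the
#'   corrections; dropping components supports sensitivity checks of the
#'   corrections at trap pressure.
#' @return A tibble with one row per conformer: `id`, `isomer_label`,
#'   `energy`, `zpe`, `enthalpy_correction`, `entropy`,
#'   `gibbs_correction`, `n_imaginary_dropped` (energies kJ/mol,
#'   entropy J/mol/K).
#' @export
thermo_corrections <- function(ens, conditions = thermo_conditions(),
                               include = c("vibrational", "rotational",
                                           "translational")) {
  ens <- validate_ensemble(ens)
  include <- match.arg(include, several.ok = TRUE)
  temp <- conditions$temperature
  rt_kj <- .R_kJ * temp
  rows <- purrr::pmap(ens, function(id, isomer_label, energy, elements,
                                    coords, freqs, ...) {
    if (is.null(freqs) || length(freqs) == 0L) {
      stop("conformer '", id, "' has no frequencies; thermochemical ",
           "corrections need a vibrational analysis", call. = FALSE)
    }
    h_corr <- rt_kj  # pV = RT for an ideal gas
    s_tot <- 0
    zpe <- 0
    n_imag <- 0L
    if ("vibrational" %in% include) {
      vib <- vibrational_terms(freqs, conditions)
      zpe <- vib$zpe
      h_corr <- h_corr + vib$zpe + vib$thermal_vib
      s_tot <- s_tot + vib$vib_entropy
      n_imag <- vib$n_imaginary_dropped
    }
    if ("rotational" %in% include) {
      rot <- rotational_terms(elements, coords, temp)
      h_corr <- h_corr + rot$rot_energy
      s_tot <- s_tot + rot$rot_entropy
    }
    if ("translational" %in% include) {
      trans <- translational_terms(sum(element_mass(elements)), temp,
                                   conditions$pressure)
      h_corr <- h_corr + trans$trans_energy
      s_tot <- s_tot + trans$trans_entropy
    }
    tibble::tibble(
      id = id, isomer_label = isomer_label, energy = energy,
      zpe = zpe, enthalpy_correction = h_corr, entropy = s_tot,
      gibbs_correction = h_corr - temp * s_tot / 1000,
      n_imaginary_dropped = n_imag
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "temperature") <- temp
  attr(out, "pressure") <- conditions$pressure
  out
}
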