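# Seeded synthetic fixtures: ensembles with known isomer populations,
# geometries, frequency sets and noisy peak lists. Everything here is a
# pure function of its arguments plus the seed, so pipeline tests have
# exact ground truth without any quantum-chemistry input.

#' Synthetic conformer ensemble with exact target populations
#'
#' Builds an ensemble by inverse-Boltzmann construction: within-isomer
#' conformer energies are drawn uniformly on `[0, spread]`, then each
#' isomer's energies are shifted by the closed-form offset
#' `-RT * log(target / q)` (q = the isomer's partial partition sum) so
#' that the global Boltzmann aggregation at `temperature` reproduces the
#' target populations exactly. Recovery failures downstream therefore
#' indicate pipeline bugs, not fixture slack. Geometries and harmonic
#' frequencies are generated with [synth_geometry()] and
#' [synth_frequencies()].
#'
#' @param targets Named numeric vector: isomer label -> population
#'   fraction; non-negative, summing to 1 (within 1e-9).
#' @param peptide Peptide sequence carried by the ensemble.
#' @param conformers_per_isomer Conformers per isomer (>= 1).
#' @param temperature Kelvin at which the targets hold.
#' @param spread Width of the within-isomer energy band, kJ/mol.
#' @param n_atoms Atoms per synthetic geometry.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return An ensemble tibble (variant `"E"` aggregation at
#'   `temperature` recovers `targets`).
#' @export
synth_ensemble <- function(targets, peptide = "GAVLK",
                           conformers_per_isomer = 5L,
                           temperature = 443.15, spread = 5,
                           n_atoms = 12L, seed = 1L) {
  stopifnot(!is.null(names(targets)), all(targets >= 0),
            conformers_per_isomer >= 1L, spread >= 0, n_atoms >= 4L)
  if (abs(sum(targets) - 1) > 1e-9) {
    stop("target populations must sum to 1", call. = FALSE)
  }
  rt <- .R_kJ * temperature
  elements <- rep(c("C", "N", "O"), length.out = n_atoms)
  n_modes <- max(3L * n_atoms - 6L, 1L)
  withr::with_seed(seed, {
    rows <- purrr::imap(as.list(targets), function(target, lab) {
      e_rel <- stats::runif(conformers_per_isomer, 0, spread)
      q <- sum(exp(-e_rel / rt))
      offset <- if (target > 0) -rt * log(target / q) else {
        warning("zero-population isomer '", lab,
                "' given a prohibitive energy offset")
        1e6
      }
      tibble::tibble(
        id = sprintf("%s_c%03d", lab, seq_len(conformers_per_isomer)),
        isomer_label = lab,
        stage = "dft",
        energy = e_rel + offset,
        elements = rep(list(elements), conformers_per_isomer),
        coords = lapply(seq_len(conformers_per_isomer), function(i)
          synth_geometry(n_atoms, seed = NULL)),
        freqs = lapply(seq_len(conformers_per_isomer), function(i)
          synth_frequencies(n_modes, seed = NULL))
      )
    })
    conformer_ensemble(dplyr::bind_rows(rows), peptide = peptide)
  })
}

#' Random synthetic geometry
#'
#' Coordinates drawn uniformly in a 10 Angstrom box with a minimum
#' pairwise distance of 0.8 Angstrom enforced by rejection sampling.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param seed Integer seed, or `NULL` to use the current RNG stream
#'   (as [synth_ensemble()] does inside its own seeded scope).
#' @param box Box edge, Angstrom.
#' @param min_dist Minimum pairwise distance, Angstrom.
#' @return An `n_atoms` x 3 matrix.
#' @export
synth_geometry <- function(n_atoms, seed = 1L, box = 10, min_dist = 0.8) {
  stopifnot(n_atoms >= 1L)
  draw <- function() {
    xyz <- matrix(NA_real_, n_atoms, 3L)
    for (i in seq_len(n_atoms)) {
      repeat {
        p <- stats::runif(3, 0, box)
        if (i == 1L) break
        d2 <- rowSums(sweep(xyz[seq_len(i - 1L), , drop = FALSE], 2,
                            p)^2)
        if (min(d2) >= min_dist^2) break
      }
      xyz[i, ] <- p
    }
    xyz
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Gaussian perturbation of a geometry
#'
#' Adds independent normal displacements with standard deviation
#' `sigma` to every coordinate; `sigma = 0` returns an identical copy.
#' Useful for making near-duplicate conformers for the deduplication
#' rule: `sigma` around 0.005 Angstrom lands in the align-score > 0.98
#' duplicate regime.
#'
#' @param coords N x 3 matrix.
#' @param sigma Displacement standard deviation, Angstrom (>= 0).
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @return Perturbed N x 3 matrix.
#' @export
perturb_geometry <- function(coords, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  draw <- function() coords + stats::rnorm(length(coords), 0, sigma)
  if (sigma == 0) return(coords)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Plausible synthetic harmonic frequency set
#'
#' Positive wavenumbers drawn log-uniformly on \[20, 3600\] cm^-1 (the
#' physically occupied range from torsions to X-H stretches), with an
#' optional count of imaginary modes encoded as negative entries for
#' testing imaginary-mode handling. No attempt is made to mimic a real
#' peptide's spectrum.
#'
#' @param n_modes Positive modes to draw (>= 1).
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @param include_imaginary Number of negative entries to append.
#' @return Numeric vector of length `n_modes + include_imaginary`.
#' @export
synth_frequencies <- function(n_modes, seed = 1L, include_imaginary = 0L) {
  stopifnot(n_modes >= 1L, include_imaginary >= 0L)
  draw <- function() {
    pos <- exp(stats::runif(n_modes, log(20), log(3600)))
    imag <- if (include_imaginary > 0L)
      -exp(stats::runif(include_imaginary, log(20), log(200))) else
        numeric(0)
    c(sort(imag), sort(pos))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Synthetic peak list from predicted intensities
#'
#' One peak per predicted ion at its theoretical monoisotopic m/z, with
#' mean-preserving multiplicative log-normal intensity noise of
#' coefficient of variation `noise_cv`. With `noise_cv = 0` the
#' annotate-and-normalise round trip reproduces the predicted relative
#' intensities exactly.
#'
#' @param predicted [predict_intensities()] output (or any tibble with
#'   `series`, `index`, `rel_intensity`).
#' @param seq Peptide sequence (for the theoretical m/z values).
#' @param noise_cv Coefficient of variation of the noise (>= 0).
#' @param seed Integer seed.
#' @return A peak-list tibble (`mz`, `intensity`) sorted by m/z.
#' @export
synth_spectrum <- function(predicted, seq, noise_cv = 0, seed = 1L) {
  stopifnot(noise_cv >= 0)
  if (nrow(predicted) == 0L) {
    return(tibble::tibble(mz = numeric(0), intensity = numeric(0)))
  }
  seq <- parse_sequence(seq)
  mz <- purrr::map2_dbl(predicted$series, predicted$index,
                        ~ fragment_mz(seq, .x, .y))
  noise <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    withr::with_seed(seed,
      exp(stats::rnorm(nrow(predicted), -sdlog^2 / 2, sdlog)))
  } else rep(1, nrow(predicted))
  out <- tibble::tibble(mz = mz,
                        intensity = predicted$rel_intensity * noise)
  out[order(out$mz), ]
}
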