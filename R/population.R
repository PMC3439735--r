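.variants <- c("E", "EHC", "GE", "GEEC")

#' Effective energy of a conformer under an energy variant
#'
#' Four variants feed the Boltzmann weighting: `E` (electronic energy
#' only), `EHC` (E plus the enthalpic correction), `GE` (E plus the
#' Gibbs correction), and `GEEC` (as GE, but only the single lowest-G
#' conformer per isomer enters the distribution; the reduction happens
#' in [aggregate_populations()]).
#'
#' @param energy Electronic energy, kJ/mol.
#' @param thermo Matching row(s) of a [thermo_corrections()] table, or
#'   `NULL` for variant `"E"`.
#' @param variant One of `"E"`, `"EHC"`, `"GE"`, `"GEEC"`.
#' @return Effective energy in kJ/mol.
#' @export
effective_energy <- function(energy, thermo = NULL,
                             variant = c("E", "EHC", "GE", "GEEC")) {
  variant <- match.arg(variant)
  if (variant == "E") return(energy)
  if (is.null(thermo)) {
    stop("variant '", variant, "' needs thermochemical corrections",
         call. = FALSE)
  }
  switch(variant,
    EHC = energy + thermo$enthalpy_correction,
    GE = ,
    GEEC = energy + thermo$gibbs_correction
  )
}

#' Boltzmann weights of a set of energies
#'
#' `w_i = exp(-(E_i - E_min)/RT) / sum_j exp(-(E_j - E_min)/RT)`; the
#' minimum shift makes the exponentials overflow-safe and leaves the
#' weights unchanged.
#'
#' @param energies kJ/mol, non-empty.
#' @param temperature Kelvin (> 0).
#' @return Weights summing to 1.
#' @examples
#' boltzmann_weights(c(0, 5), 443.15)
#' @export
boltzmann_weights <- function(energies, temperature = 443.15) {
  if (length(energies) == 0L) stop("empty energy list", call. = FALSE)
  stopifnot(temperature > 0, all(is.finite(energies)))
  w <- exp(-(energies - min(energies)) / (.R_kJ * temperature))
  w / sum(w)
}

#' Aggregate conformer Boltzmann weights into isomer populations
#'
#' A single Boltzmann distribution is taken over all conformers of all
#' isomers (populations of different isomers are directly comparable
#' only under one global distribution), and each isomer's population is
#' the sum of its conformers' weights. For variant `"GEEC"` each isomer
#' is first reduced to its single lowest effective-energy conformer.
#'
#' @param ens Ensemble tibble.
#' @param thermo [thermo_corrections()] table (required for variants
#'   other than `"E"`); joined to the ensemble by conformer `id`.
#' @param variant Energy variant, see [effective_energy()].
#' @param temperature Kelvin.
#' @param isomers Optional character vector of expected isomer labels;
#'   labels absent from the ensemble are reported with population 0 (a
#'   warning is raised).
#' @return A tibble `isomer_label`, `n_conformers`, `population`, with
#'   attributes `variant` and `temperature`.
#' @export
aggregate_populations <- function(ens, thermo = NULL,
                                  variant = c("E", "EHC", "GE", "GEEC"),
                                  temperature = 443.15, isomers = NULL) {
  variant <- match.arg(variant)
  ens <- validate_ensemble(ens)
  if (nrow(ens) == 0L) stop("empty ensemble", call. = FALSE)
  if (variant == "E") {
    eff <- ens$energy
  } else {
    if (is.null(thermo)) {
      stop("variant '", variant, "' needs a thermo_corrections() table",
           call. = FALSE)
    }
    idx <- match(ens$id, thermo$id)
    if (anyNA(idx)) {
      stop("missing thermochemistry for conformer(s): ",
           paste(ens$id[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    eff <- effective_energy(ens$energy, thermo[idx, ], variant)
  }
  tab <- tibble::tibble(id = ens$id, isomer_label = ens$isomer_label,
                        eff = eff)
  if (variant == "GEEC") {
    tab <- tab |>
      dplyr::group_by(.data$isomer_label) |>
      dplyr::arrange(.data$eff, .data$id, .by_group = TRUE) |>
      dplyr::slice_head(n = 1L) |>
      dplyr::ungroup()
  }
  tab$weight <- boltzmann_weights(tab$eff, temperature)
  pop <- tab |>
    dplyr::group_by(.data$isomer_label) |>
    dplyr::summarise(n_conformers = dplyr::n(),
                     population = sum(.data$weight)) |>
    dplyr::ungroup()
  if (!is.null(isomers)) {
    missing <- setdiff(isomers, pop$isomer_label)
    if (length(missing)) {
      warning("isomer(s) with no surviving conformers get population 0: ",
              paste(missing, collapse = ", "))
      pop <- dplyr::bind_rows(pop,
        tibble::tibble(isomer_label = missing, n_conformers = 0L,
                       population = 0))
    }
    pop <- pop[order(match(pop$isomer_label, isomers)), ]
  }
  attr(pop, "variant") <- variant
  attr(pop, "temperature") <- temperature
  pop
}

#' Predicted relative fragment-ion intensities from isomer populations
#'
#' Each amide-protonated isomer's population is assigned to its mapped y
#' ion (position k on an n-residue peptide cleaves to y(n+1-k) and
#' b(k-1); the b ion is reported with the same relative value, since the
#' y/b pair comes from the same cleavage and no independent branching
#' ratio is modelled). Intensities are normalised so the most populated
#' y ion — the reference ion — has relative intensity 1.
#'
#' @param populations Output of [aggregate_populations()] (or any tibble
#'   with `isomer_label` and `population`).
#' @param seq Peptide sequence.
#' @return A tibble `ion`, `series`, `index`, `isomer_label`,
#'   `population`, `rel_intensity`, sorted by descending intensity
#'   within series; attribute `reference_ion` names the y ion set to 1.
#' @export
predict_intensities <- function(populations, seq) {
  seq <- parse_sequence(seq)
  n <- nchar(seq)
  pos <- isomer_position(populations$isomer_label)
  amide <- !is.na(pos) & pos >= 2L
  if (!any(amide)) stop("no amide-site isomers in populations",
                        call. = FALSE)
  pop <- populations[amide, ]
  pos <- pos[amide]
  if (all(pop$population <= 0)) stop("all isomer populations are zero",
                                     call. = FALSE)
  mapping <- map_isomer_to_ions(pos, n)
  ref <- max(pop$population)
  mk <- function(series, index) {
    tibble::tibble(
      ion = paste0(series, index), series = series, index = index,
      isomer_label = pop$isomer_label, population = pop$population,
      rel_intensity = pop$population / ref
    )
  }
  out <- dplyr::bind_rows(mk("y", mapping$y_index), mk("b", mapping$b_index))
  out <- out |>
    dplyr::arrange(.data$series, dplyr::desc(.data$rel_intensity),
                   .data$ion)
  ref_ion <- out$ion[out$series == "y"][1]
  attr(out, "reference_ion") <- ref_ion
  out
}

# position integer parsed from labels like GAVLK_NH_3 / GAVLK_C-OH_2;
# NA when the label does not follow the scheme
isomer_position <- function(labels) {
  pos <- rep(NA_integer_, length(labels))
  hit <- grepl("_(NH|C-OH)_[0-9]+$", labels)
  pos[hit] <- as.integer(sub(".*_([0-9]+)$", "\\1", labels[hit]))
  pos
}
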