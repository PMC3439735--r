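# Conformer ensembles are tibbles with one row per conformer:
#   id           chr   unique identifier
#   isomer_label chr   protonation isomer the conformer belongs to
#   stage        chr   forcefield | semiempirical | dft
#   energy       dbl   electronic energy, kJ/mol
#   elements     list  chr vector of element symbols
#   coords       list  N x 3 numeric matrix, Angstrom
#   freqs        list  harmonic frequencies in cm^-1 (negative =
#                      imaginary) or NULL when not computed
# The peptide sequence rides along as attr(ens, "peptide").

.stages <- c("forcefield", "semiempirical", "dft")

#' Build a conformer ensemble from per-conformer records
#'
#' @param conformers A data frame with columns `id`, `isomer_label`,
#'   `stage`, `energy` (kJ/mol), and list-columns `elements`, `coords`,
#'   and optionally `freqs`.
#' @param peptide Peptide sequence the ensemble belongs to (optional).
#' @return A validated ensemble tibble.
#' @export
conformer_ensemble <- function(conformers, peptide = NULL) {
  ens <- tibble::as_tibble(conformers)
  if (!"freqs" %in% names(ens)) ens$freqs <- vector("list", nrow(ens))
  if (!"stage" %in% names(ens)) ens$stage <- "dft"
  attr(ens, "peptide") <- peptide
  validate_ensemble(ens)
}

validate_ensemble <- function(ens) {
  needed <- c("id", "isomer_label", "stage", "energy", "elements", "coords")
  miss <- setdiff(needed, names(ens))
  if (length(miss)) stop("ensemble is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ens$id)) {
    stop("duplicate conformer id(s): ",
         paste(unique(ens$id[duplicated(ens$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(ens$energy))) stop("non-finite conformer energy",
                                        call. = FALSE)
  bad_stage <- setdiff(unique(ens$stage), .stages)
  if (length(bad_stage)) stop("unknown stage(s): ",
                              paste(bad_stage, collapse = ", "),
                              call. = FALSE)
  ok <- purrr::map2_lgl(ens$elements, ens$coords, function(el, xyz) {
    is.matrix(xyz) && ncol(xyz) == 3L && nrow(xyz) == length(el)
  })
  if (!all(ok)) {
    stop("conformer(s) with mismatched elements/coordinates: ",
         paste(ens$id[!ok], collapse = ", "), call. = FALSE)
  }
  ens
}

#' Read a conformer ensemble from the JSON interchange format
#'
#' One JSON file per ensemble: a top-level `peptide` string and a
#' `conformers` array whose records carry `id`, `isomer_label`, `stage`,
#' `energy` (`{"value": .., "unit": ..}`; accepted units hartree,
#' kcal/mol, kJ/mol, eV), `elements`, `coordinates` (N x 3, Angstrom)
#' and optional `frequencies` (cm^-1, negatives = imaginary modes).
#' Energies are converted to kJ/mol on input. Populate the format from
#' quantum-chemistry output with any log-parsing tool (e.g. cclib via
#' reticulate or a short script); the fields map one-to-one onto parsed
#' attributes: final SCF energy, atom symbols, optimised coordinates,
#' vibrational frequencies.
#'
#' @param path Path to a JSON ensemble file.
#' @return An ensemble tibble (see [conformer_ensemble()]).
#' @seealso [write_ensemble()], [write_xyz()]
#' @export
read_ensemble <- function(path) {
  doc <- jsonlite::read_json(path)
  recs <- doc$conformers
  if (is.null(recs)) stop("no 'conformers' array in ", path, call. = FALSE)
  rows <- purrr::imap(recs, function(r, i) {
    for (f in c("id", "isomer_label", "energy", "elements", "coordinates")) {
      if (is.null(r[[f]])) {
        stop(sprintf("record %d: missing field '%s'", i, f), call. = FALSE)
      }
    }
    if (is.null(r$energy$value) || is.null(r$energy$unit)) {
      stop(sprintf("record %d: energy needs 'value' and 'unit'", i),
           call. = FALSE)
    }
    xyz <- do.call(rbind, lapply(r$coordinates, unlist))
    storage.mode(xyz) <- "double"
    freqs <- if (is.null(r$frequencies)) NULL else
      as.numeric(unlist(r$frequencies))
    tibble::tibble(
      id = as.character(r$id),
      isomer_label = as.character(r$isomer_label),
      stage = if (is.null(r$stage)) "dft" else as.character(r$stage),
      energy = energy_to_kjmol(as.numeric(r$energy$value), r$energy$unit),
      elements = list(as.character(unlist(r$elements))),
      coords = list(xyz),
      freqs = list(freqs)
    )
  })
  conformer_ensemble(dplyr::bind_rows(rows), peptide = doc$peptide)
}

#' Write a conformer ensemble to the JSON interchange format
#'
#' Energies are written in kJ/mol; [read_ensemble()] round-trips them
#' exactly (unit tag `"kJ/mol"`, full double precision).
#'
#' @param ens Ensemble tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  ens <- validate_ensemble(ens)
  recs <- purrr::pmap(ens, function(id, isomer_label, stage, energy,
                                    elements, coords, freqs, ...) {
    r <- list(
      id = id, isomer_label = isomer_label, stage = stage,
      energy = list(value = energy, unit = "kJ/mol"),
      elements = elements,
      coordinates = lapply(seq_len(nrow(coords)),
                           function(i) unname(coords[i, ]))
    )
    if (!is.null(freqs)) r$frequencies <- freqs
    r
  })
  jsonlite::write_json(list(peptide = attr(ens, "peptide"),
                            conformers = recs),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export one conformer as an XYZ file
#'
#' @param ens Ensemble tibble.
#' @param id Conformer id to export.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(ens, id, path) {
  row <- ens[ens$id == id, ]
  if (nrow(row) != 1L) stop("no conformer with id '", id, "'",
                            call. = FALSE)
  el <- row$elements[[1]]
  xyz <- row$coords[[1]]
  lines <- c(
    length(el),
    sprintf("%s %s E = %.6f kJ/mol", row$id, row$isomer_label, row$energy),
    sprintf("%-2s %14.8f %14.8f %14.8f", el, xyz[, 1], xyz[, 2], xyz[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Keep the n lowest-energy conformers per isomer
#'
#' Mirrors the conformer-search pruning step in which only the lowest-
#' energy structures per protonation site are carried forward. Ties are
#' broken by id so the result is deterministic.
#'
#' @param ens Ensemble tibble.
#' @param n Conformers to keep per isomer label (default 1000, the
#'   production pruning depth after a 100,000-conformer search).
#' @return Filtered ensemble, sorted by isomer then ascending energy.
#' @export
keep_lowest <- function(ens, n = 1000L) {
  stopifnot(n >= 1L)
  ens <- validate_ensemble(ens)
  out <- ens |>
    dplyr::arrange(.data$isomer_label, .data$energy, .data$id) |>
    dplyr::group_by(.data$isomer_label) |>
    dplyr::slice_head(n = n) |>
    dplyr::ungroup()
  attr(out, "peptide") <- attr(ens, "peptide")
  out
}

#' Drop conformers outside an energy window
#'
#' Keeps conformers within `window` kJ/mol of the minimum energy, per
#' isomer by default. Defaults match the production pipeline: 40 kJ/mol
#' after the semi-empirical stage, 20 kJ/mol for the final DFT set.
#'
#' @param ens Ensemble tibble.
#' @param window Window width in kJ/mol (> 0).
#' @param scope `"per_isomer"` (default) or `"global"`.
#' @return Filtered ensemble.
#' @export
filter_energy_window <- function(ens, window,
                                 scope = c("per_isomer", "global")) {
  stopifnot(window > 0)
  scope <- match.arg(scope)
  ens <- validate_ensemble(ens)
  if (nrow(ens) == 0L) return(ens)
  out <- if (scope == "global") {
    dplyr::filter(ens, .data$energy <= min(.data$energy) + window)
  } else {
    ens |>
      dplyr::group_by(.data$isomer_label) |>
      dplyr::filter(.data$energy <= min(.data$energy) + window) |>
      dplyr::ungroup()
  }
  attr(out, "peptide") <- attr(ens, "peptide")
  out
}

# Kabsch optimal superposition of two N x 3 coordinate matrices:
# centre both, SVD of the covariance, determinant-corrected proper
# rotation, then RMSD of the superposed pair.
kabsch_superpose <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)),
            ncol(x) == 3L)
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  diffs <- yc %*% rot - xc
  sqrt(sum(diffs^2) / nrow(x))
}

#' Minimal RMSD between two conformers after optimal superposition
#'
#' Kabsch algorithm: both structures are centred at their centroids and
#' the proper rotation minimising the RMSD is found from the SVD of the
#' coordinate covariance. Atom ordering must be identical in both inputs
#' (ensembles derived from one starting structure preserve it); no
#' graph-matching is attempted.
#'
#' @param a,b One-row ensemble slices, or lists with `elements` and
#'   `coords` fields.
#' @param atom_subset `"heavy"` (default, hydrogens excluded) or `"all"`.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b, atom_subset = c("heavy", "all")) {
  atom_subset <- match.arg(atom_subset)
  get <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1L)
      list(el = x$elements[[1]], xyz = x$coords[[1]])
    } else {
      list(el = x$elements, xyz = x$coords)
    }
  }
  ca <- get(a); cb <- get(b)
  if (length(ca$el) != length(cb$el) || any(ca$el != cb$el)) {
    stop("element sequences differ; atom correspondence is required",
         call. = FALSE)
  }
  keep <- if (atom_subset == "heavy") ca$el != "H" else
    rep(TRUE, length(ca$el))
  if (!any(keep)) keep <- rep(TRUE, length(ca$el))
  xa <- ca$xyz[keep, , drop = FALSE]
  xb <- cb$xyz[keep, , drop = FALSE]
  if (nrow(xa) == 1L) return(0)
  kabsch_superpose(xa, xb)
}

#' Structure-similarity score from an RMSD
#'
#' `exp(-rmsd / sigma)`: 1 for identical structures, strictly decreasing
#' in RMSD. With the default `sigma` = 1 Angstrom the duplicate cutoff
#' of 0.98 corresponds to RMSD < 0.0202 Angstrom — a near-identical-
#' geometry regime.
#'
#' @param rmsd RMSD in Angstrom (>= 0).
#' @param sigma Length scale in Angstrom.
#' @return Score in (0, 1].
#' @export
align_score <- function(rmsd, sigma = 1.0) {
  if (any(rmsd < 0)) stop("rmsd must be non-negative", call. = FALSE)
  stopifnot(sigma > 0)
  exp(-rmsd / sigma)
}

#' Remove duplicate conformers
#'
#' Within each isomer, pairs whose energies agree within `energy_tol`
#' and whose align score exceeds `score_threshold` are treated as the
#' same structure and only one member is kept, so that no conformer
#' enters the Boltzmann distribution more than once. The survivor is the
#' lower-energy member (ties: lexicographically smaller id); the rule is
#' applied transitively until stable.
#'
#' @param ens Ensemble tibble.
#' @param energy_tol Energy gate in kJ/mol (default 0.03).
#' @param score_threshold Align-score cutoff (default 0.98).
#' @param sigma Align-score length scale passed to [align_score()].
#' @param atom_subset Passed to [kabsch_rmsd()].
#' @return Deduplicated ensemble.
#' @export
deduplicate <- function(ens, energy_tol = 0.03, score_threshold = 0.98,
                        sigma = 1.0, atom_subset = "heavy") {
  stopifnot(energy_tol > 0, score_threshold > 0)
  ens <- validate_ensemble(ens)
  if (nrow(ens) < 2L) return(ens)
  ord <- order(ens$isomer_label, ens$energy, ens$id)
  ens_o <- ens[ord, ]
  keep <- rep(TRUE, nrow(ens_o))
  for (i in seq_len(nrow(ens_o) - 1L)) {
    if (!keep[i]) next
    for (j in (i + 1L):nrow(ens_o)) {
      if (!keep[j]) next
      if (ens_o$isomer_label[j] != ens_o$isomer_label[i]) break
      if (ens_o$energy[j] - ens_o$energy[i] > energy_tol) break
      rmsd <- kabsch_rmsd(ens_o[i, ], ens_o[j, ], atom_subset)
      if (align_score(rmsd, sigma) > score_threshold) keep[j] <- FALSE
    }
  }
  out <- ens_o[keep, ]
  attr(out, "peptide") <- attr(ens, "peptide")
  out
}
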