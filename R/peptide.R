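#' Parse and validate a peptide sequence
#'
#' Accepts one-letter amino-acid codes (case-insensitive, surrounding
#' whitespace ignored) or the path to a single-record FASTA file.
#'
#' @param text Sequence string such as `"GAVLK"`, or a FASTA path when
#'   `from_fasta = TRUE`.
#' @param from_fasta Read the sequence from a single-record FASTA file.
#' @return Validated upper-case sequence string.
#' @examples
#' parse_sequence("gavlk")
#' @export
parse_sequence <- function(text, from_fasta = FALSE) {
  if (from_fasta) {
    lines <- readLines(text, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    headers <- grepl("^>", lines)
    if (sum(headers) != 1L || !headers[1L]) {
      stop("expected a single-record FASTA file", call. = FALSE)
    }
    text <- paste(lines[!headers], collapse = "")
  }
  seq <- toupper(trimws(text))
  if (!nzchar(seq)) stop("empty peptide sequence", call. = FALSE)
  res <- strsplit(seq, "")[[1]]
  bad <- which(!res %in% names(.residue_mono))
  if (length(bad)) {
    stop(sprintf("unknown residue code '%s' at position %d",
                 res[bad[1]], bad[1]), call. = FALSE)
  }
  if (length(res) < 2L) stop("peptide must have at least 2 residues",
                             call. = FALSE)
  seq
}

peptide_residues <- function(seq) strsplit(seq, "")[[1]]

check_basic_cterm <- function(seq, allow_nonbasic = FALSE) {
  res <- peptide_residues(seq)
  last <- res[length(res)]
  if (!last %in% c("K", "R") && !allow_nonbasic) {
    stop("C-terminal residue is '", last, "', not K/R: the model assumes ",
         "the second proton is sequestered on a basic C-terminal side ",
         "chain (set allow_nonbasic = TRUE to override)", call. = FALSE)
  }
  invisible(seq)
}

#' Enumerate doubly protonated backbone isomers
#'
#' For an n-residue peptide the mobile proton can sit at the N-terminal
#' amine (position 1) or at one of the n - 1 backbone amides (positions
#' 2..n, counted N to C); the second proton stays sequestered on the
#' basic C-terminal side chain. Amide sites come in an oxygen-protonated
#' (`<SEQ>_C-OH_<pos>`) and a nitrogen-protonated (`<SEQ>_NH_<pos>`)
#' series.
#'
#' @param seq Peptide sequence (validated by [parse_sequence()]).
#' @param series `"nitrogen"`, `"oxygen"`, or `"both"`.
#' @param allow_nonbasic Permit a non-K/R C-terminus.
#' @return A tibble with columns `label`, `series`, `site_kind`,
#'   `position`, `peptide`.
#' @examples
#' enumerate_protonation_isomers("GAVLK", "nitrogen")
#' @export
enumerate_protonation_isomers <- function(seq,
                                          series = c("nitrogen", "oxygen",
                                                     "both"),
                                          allow_nonbasic = FALSE) {
  series <- match.arg(series)
  seq <- parse_sequence(seq)
  check_basic_cterm(seq, allow_nonbasic)
  n <- nchar(seq)
  one_series <- function(ser) {
    tag <- if (ser == "nitrogen") "NH" else "C-OH"
    tibble::tibble(
      label = paste0(seq, "_", tag, "_", seq_len(n)),
      series = ser,
      site_kind = c("n_terminal_amine", rep(if (ser == "nitrogen")
        "amide_nitrogen" else "amide_oxygen", n - 1L)),
      position = seq_len(n),
      peptide = seq
    )
  }
  if (series == "both") {
    dplyr::bind_rows(one_series("nitrogen"), one_series("oxygen"))
  } else {
    one_series(series)
  }
}

#' Map a protonation isomer to its fragment-ion pair
#'
#' Cleavage at the amide in position k of an n-residue peptide yields the
#' y ion of index n + 1 - k (which retains the sequestered C-terminal
#' proton) and the b ion of index k - 1 (which carries the mobile
#' proton). Position 1 (N-terminal amine) implies no amide cleavage and
#' maps to no ions; so does a b index of 0.
#'
#' @param position Site position(s), 1..n.
#' @param n Peptide length.
#' @return A tibble with columns `position`, `y_index`, `b_index`
#'   (`NA` where no ion is implied).
#' @examples
#' map_isomer_to_ions(2:5, 5)
#' @export
map_isomer_to_ions <- function(position, n) {
  stopifnot(all(position >= 1L), all(position <= n))
  y <- ifelse(position >= 2L, n + 1L - position, NA_integer_)
  b <- ifelse(position >= 2L, position - 1L, NA_integer_)
  tibble::tibble(position = as.integer(position),
                 y_index = as.integer(y), b_index = as.integer(b))
}

#' Theoretical fragment-ion m/z
#'
#' Standard b/y/a rules: y = (sum of the last `index` residues + water +
#' charge protons)/charge; b = (sum of the first `index` residues +
#' charge protons)/charge; a = b - CO/charge.
#'
#' @param seq Peptide sequence.
#' @param series `"y"`, `"b"` or `"a"`.
#' @param index Fragment index, 1..n-1.
#' @param charge Positive integer charge, default 1.
#' @param mass_mode `"mono"` or `"average"`.
#' @return m/z in Da per charge.
#' @examples
#' fragment_mz("GAVLK", "y", 3)
#' @export
fragment_mz <- function(seq, series = c("y", "b", "a"), index, charge = 1L,
                        mass_mode = c("mono", "average")) {
  series <- match.arg(series)
  mass_mode <- match.arg(mass_mode)
  seq <- parse_sequence(seq)
  res <- peptide_residues(seq)
  n <- length(res)
  if (any(index < 1L) || any(index > n - 1L)) {
    stop("fragment index out of range 1..", n - 1L, call. = FALSE)
  }
  stopifnot(charge >= 1L)
  water <- if (mass_mode == "mono") .const$water_mono else .const$water_avg
  prot <- if (mass_mode == "mono") .const$proton_mono else .const$proton_avg
  co <- if (mass_mode == "mono") .const$co_mono else .const$co_avg
  m <- residue_masses(res, mass_mode)
  vapply(index, function(i) {
    base <- switch(series,
      y = sum(m[(n - i + 1L):n]) + water,
      b = sum(m[seq_len(i)]),
      a = sum(m[seq_len(i)]) - co
    )
    (base + charge * prot) / charge
  }, numeric(1))
}

#' Precursor m/z
#'
#' @inheritParams fragment_mz
#' @return (sum of residues + water + charge protons)/charge.
#' @examples
#' precursor_mz("GAVLK", charge = 2, mass_mode = "average")
#' @export
precursor_mz <- function(seq, charge = 2L,
                         mass_mode = c("mono", "average")) {
  mass_mode <- match.arg(mass_mode)
  seq <- parse_sequence(seq)
  stopifnot(charge >= 1L)
  water <- if (mass_mode == "mono") .const$water_mono else .const$water_avg
  prot <- if (mass_mode == "mono") .const$proton_mono else .const$proton_avg
  (sum(residue_masses(peptide_residues(seq), mass_mode)) + water +
     charge * prot) / charge
}

#' Full fragment-ion table for a peptide
#'
#' All y/b/a ions at the given charge with monoisotopic and average m/z,
#' plus the nitrogen-series isomer label mapped to each y/b ion.
#'
#' @inheritParams fragment_mz
#' @param series Ion series to include.
#' @return A tibble with columns `ion`, `series`, `index`, `charge`,
#'   `mz_mono`, `mz_average`, `mapped_isomer_label`.
#' @examples
#' ion_table("GAVLK")
#' @export
ion_table <- function(seq, series = c("y", "b", "a"), charge = 1L) {
  seq <- parse_sequence(seq)
  n <- nchar(seq)
  chg <- as.integer(charge)
  grid <- tidyr::expand_grid(series = series, index = seq_len(n - 1L))
  grid |>
    dplyr::mutate(
      ion = paste0(.data$series, .data$index),
      charge = chg,
      mz_mono = purrr::map2_dbl(.data$series, .data$index,
        ~ fragment_mz(seq, .x, .y, chg, "mono")),
      mz_average = purrr::map2_dbl(.data$series, .data$index,
        ~ fragment_mz(seq, .x, .y, chg, "average")),
      mapped_isomer_label = dplyr::case_when(
        .data$series == "y" ~ paste0(seq, "_NH_", n + 1L - .data$index),
        .data$series == "b" ~ paste0(seq, "_NH_", .data$index + 1L),
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select("ion", "series", "index", "charge", "mz_mono",
                  "mz_average", "mapped_isomer_label")
}
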