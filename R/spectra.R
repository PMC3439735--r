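#' Read an experimental peak list
#'
#' Supports two-column CSV (m/z, intensity; with or without a header)
#' and Mascot Generic Format. For MGF, the first `BEGIN IONS`/`END IONS`
#' block is read unless `block` selects another; `PEPMASS`, `CHARGE` and
#' `TITLE` headers are kept as metadata attributes.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"csv"` or `"mgf"`.
#' @param block MGF block number to read (default 1).
#' @return A tibble with columns `mz`, `intensity`, sorted by m/z, with
#'   a `metadata` attribute.
#' @export
read_peaks <- function(path, format = c("auto", "csv", "mgf"), block = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf"
      else "csv"
  }
  if (format == "csv") {
    first <- readLines(path, n = 1L)
    header <- grepl("[A-Za-z]", sub(",.*", "", first))
    df <- utils::read.csv(path, header = header,
                          col.names = c("mz", "intensity"))
    meta <- list(source = path)
  } else {
    parsed <- parse_mgf(path)
    if (block > length(parsed)) {
      stop("MGF file has only ", length(parsed), " block(s)", call. = FALSE)
    }
    df <- parsed[[block]]$peaks
    meta <- c(parsed[[block]]$meta, list(source = path))
  }
  if (any(df$mz <= 0)) stop("non-positive m/z value in peak list",
                            call. = FALSE)
  if (any(df$intensity < 0)) stop("negative intensity in peak list",
                                  call. = FALSE)
  out <- tibble::as_tibble(df[order(df$mz), ])
  attr(out, "metadata") <- meta
  out
}

# minimal MGF reader: BEGIN IONS / KEY=value headers / "mz int" rows /
# END IONS, one element per block
parse_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  inblock <- FALSE
  meta <- list(); mz <- c(); int <- c()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      inblock <- TRUE; meta <- list(); mz <- c(); int <- c()
    } else if (ln == "END IONS") {
      if (!inblock) stop("line ", i, ": END IONS outside a block",
                         call. = FALSE)
      blocks[[length(blocks) + 1L]] <-
        list(meta = meta,
             peaks = data.frame(mz = mz, intensity = int))
      inblock <- FALSE
    } else if (inblock && grepl("=", ln, fixed = TRUE)) {
      key <- sub("=.*", "", ln)
      meta[[tolower(key)]] <- sub("^[^=]*=", "", ln)
    } else if (inblock) {
      vals <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
      if (length(vals) < 2L || anyNA(vals[1:2])) {
        stop("line ", i, ": cannot parse peak '", ln, "'", call. = FALSE)
      }
      mz <- c(mz, vals[1]); int <- c(int, vals[2])
    } else {
      stop("line ", i, ": unexpected content outside BEGIN/END IONS",
           call. = FALSE)
    }
  }
  if (inblock) stop("unterminated BEGIN IONS block", call. = FALSE)
  if (!length(blocks)) stop("no BEGIN IONS block found", call. = FALSE)
  blocks
}

#' Write a peak list as MGF
#'
#' @param peaks Tibble with `mz` and `intensity`.
#' @param path Output path.
#' @param pepmass,charge,title Optional header values.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(peaks, path, pepmass = NULL, charge = NULL,
                      title = NULL) {
  hdr <- c("BEGIN IONS",
           if (!is.null(title)) paste0("TITLE=", title),
           if (!is.null(pepmass)) paste0("PEPMASS=", pepmass),
           if (!is.null(charge)) paste0("CHARGE=", charge))
  body <- sprintf("%.6f %.6f", peaks$mz, peaks$intensity)
  writeLines(c(hdr, body, "END IONS"), path)
  invisible(path)
}

#' Annotate a peak list with theoretical fragment ions
#'
#' Each theoretical ion is matched to the most intense unassigned peak
#' within the m/z tolerance; ties go to the closest m/z. A peak is
#' consumed by at most one ion; ions with no peak in tolerance are
#' flagged not-detected.
#'
#' @param peaks Peak-list tibble (`mz`, `intensity`).
#' @param ions Theoretical ion tibble (e.g. [ion_table()]) with columns
#'   `ion`, `series`, `index` and an m/z column.
#' @param tolerance Matching half-window in Da per charge (> 0);
#'   default 0.5, unit resolution of an ion trap.
#' @param mz_column Which ion-table column holds the m/z to match on.
#' @return The ion tibble plus `mz_theoretical`, `mz_observed`,
#'   `intensity`, `delta_mz`, `detected`; attribute `tolerance`.
#' @export
annotate_peaks <- function(peaks, ions, tolerance = 0.5,
                           mz_column = "mz_mono") {
  stopifnot(tolerance > 0)
  mz_theo <- ions[[mz_column]]
  if (is.null(mz_theo)) stop("no column '", mz_column, "' in ions",
                             call. = FALSE)
  n_ion <- nrow(ions)
  assigned_peak <- rep(NA_integer_, n_ion)
  peak_free <- rep(TRUE, nrow(peaks))
  repeat {
    best <- NULL  # (ion, peak, intensity, |dmz|)
    for (i in seq_len(n_ion)) {
      if (!is.na(assigned_peak[i])) next
      cand <- which(peak_free & abs(peaks$mz - mz_theo[i]) <= tolerance)
      if (!length(cand)) next
      dmz <- abs(peaks$mz[cand] - mz_theo[i])
      ord <- order(-peaks$intensity[cand], dmz)
      j <- cand[ord[1]]
      score <- c(peaks$intensity[j], -abs(peaks$mz[j] - mz_theo[i]))
      if (is.null(best) || score[1] > best$score[1] ||
          (score[1] == best$score[1] && score[2] > best$score[2])) {
        best <- list(ion = i, peak = j, score = score)
      }
    }
    if (is.null(best)) break
    assigned_peak[best$ion] <- best$peak
    peak_free[best$peak] <- FALSE
  }
  out <- ions |>
    dplyr::mutate(
      mz_theoretical = mz_theo,
      mz_observed = ifelse(is.na(assigned_peak), NA_real_,
                           peaks$mz[assigned_peak]),
      intensity = ifelse(is.na(assigned_peak), NA_real_,
                         peaks$intensity[assigned_peak]),
      delta_mz = .data$mz_observed - .data$mz_theoretical,
      detected = !is.na(assigned_peak)
    )
  attr(out, "tolerance") <- tolerance
  out
}

#' Reference-normalised relative intensities of annotated ions
#'
#' Detected intensities divided by the largest detected y-ion intensity,
#' so the reference y ion has relative intensity exactly 1.
#'
#' @param annotated Output of [annotate_peaks()].
#' @return Tibble `ion`, `series`, `index`, `rel_intensity` for the
#'   detected ions; attribute `reference_ion`.
#' @export
relative_intensities <- function(annotated) {
  det <- annotated[annotated$detected, ]
  y <- det[det$series == "y", ]
  if (nrow(y) == 0L) stop("no detected y ions to normalise against",
                          call. = FALSE)
  ref <- max(y$intensity)
  out <- det |>
    dplyr::transmute(.data$ion, .data$series, .data$index,
                     rel_intensity = .data$intensity / ref)
  attr(out, "reference_ion") <- y$ion[which.max(y$intensity)]
  out
}

#' Log relative errors between predicted and measured intensities
#'
#' For every ion present in both tables with positive intensities, the
#' per-ion error is log10(predicted / measured); the headline statistic
#' is the sum of their absolute values. Also reported: the largest
#' absolute linear discrepancy |predicted - measured|, whether the
#' descending-intensity orderings agree exactly, and Kendall's tau
#' between the two intensity rankings (a diagnostic extra).
#'
#' @param predicted,measured Tibbles with columns `ion` and
#'   `rel_intensity` (e.g. [predict_intensities()] output and
#'   [relative_intensities()] output). Duplicate ion labels (the b
#'   copies of y populations) are dropped with preference for y ions.
#' @return A `comparison_report` object; see [tidy.comparison_report()]
#'   and [glance.comparison_report()].
#' @export
log_error <- function(predicted, measured) {
  pick <- function(df) {
    if ("series" %in% names(df)) df <- df[order(df$series != "y"), ]
    df[!duplicated(df$ion), c("ion", "rel_intensity")]
  }
  p <- pick(predicted)
  m <- pick(measured)
  shared <- dplyr::inner_join(p, m, by = "ion",
                              suffix = c("_predicted", "_measured"))
  if (nrow(shared) == 0L) stop("no shared ions between predicted and ",
                               "measured tables", call. = FALSE)
  zero <- shared$rel_intensity_measured <= 0 |
    shared$rel_intensity_predicted <= 0
  if (any(zero)) {
    warning("ion(s) with non-positive intensity excluded from the sum: ",
            paste(shared$ion[zero], collapse = ", "))
  }
  ok <- shared[!zero, ]
  if (nrow(ok) == 0L) stop("no shared ions with positive intensities",
                           call. = FALSE)
  per_ion <- ok |>
    dplyr::mutate(
      log_err = log10(.data$rel_intensity_predicted /
                        .data$rel_intensity_measured),
      abs_discrepancy = abs(.data$rel_intensity_predicted -
                              .data$rel_intensity_measured)
    )
  ord_p <- per_ion$ion[order(-per_ion$rel_intensity_predicted,
                             per_ion$ion)]
  ord_m <- per_ion$ion[order(-per_ion$rel_intensity_measured,
                             per_ion$ion)]
  tau <- if (nrow(per_ion) >= 2L) {
    suppressWarnings(stats::cor(per_ion$rel_intensity_predicted,
                                per_ion$rel_intensity_measured,
                                method = "kendall"))
  } else NA_real_
  structure(list(
    per_ion = per_ion,
    sum_abs_log_err = sum(abs(per_ion$log_err)),
    max_abs_discrepancy = max(per_ion$abs_discrepancy),
    order_match = identical(ord_p, ord_m),
    kendall_tau = tau,
    predicted_order = ord_p,
    measured_order = ord_m,
    n_ions = nrow(per_ion)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparison over", x$n_ions, "ions\n")
  cat("  sum |log10 err| :", format(x$sum_abs_log_err, digits = 5), "\n")
  cat("  max |discrepancy|:", format(x$max_abs_discrepancy, digits = 4),
      "\n")
  cat("  order match     :", x$order_match,
      sprintf("(predicted %s)", paste(x$predicted_order, collapse = " > ")),
      "\n")
  invisible(x)
}

#' Random-match baseline probabilities
#'
#' How likely a random prediction reproduces the observed spectrum: the
#' probability of guessing the full descending-intensity order of
#' `n_ions` ions is `1/n_ions!`; the probability of guessing the
#' `n_ions - 1` non-reference relative intensities, each to within one
#' part in `bins`, is `(1/bins)^(n_ions - 1)`.
#'
#' @param n_ions Number of compared ions (>= 2).
#' @param bins Relative-intensity resolution (default 25, i.e. 4%
#'   accuracy per intensity).
#' @return List with `order_probability` and `intensity_probability`.
#' @examples
#' random_match_baseline(4)
#' @export
random_match_baseline <- function(n_ions, bins = 25L) {
  stopifnot(n_ions >= 2L, bins >= 1L)
  list(order_probability = 1 / factorial(n_ions),
       intensity_probability = (1 / bins)^(n_ions - 1L))
}
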