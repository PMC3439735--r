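test_that("CSV and MGF peak lists parse with metadata and validation", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,intensity",
               sprintf("%.3f,%.1f", seq(100, 550, by = 50),
                       stats::runif(10, 1, 100))), csv)
  pk <- read_peaks(csv)
  expect_equal(nrow(pk), 10L)
  expect_true(!is.unsorted(pk$mz))

  bare <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("147.113,90", "359.265,2000"), bare)
  expect_equal(nrow(read_peaks(bare)), 2L)

  mgf <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=run1", "PEPMASS=244.3",
               "CHARGE=2+", "147.113 90", "359.265 2000", "END IONS"),
             mgf)
  pk2 <- read_peaks(mgf)
  expect_equal(nrow(pk2), 2L)
  expect_equal(attr(pk2, "metadata")$pepmass, "244.3")
  expect_equal(attr(pk2, "metadata")$charge, "2+")

  bad <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "147.113 90", "oops", "END IONS"), bad)
  expect_error(read_peaks(bad), "line 3")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("100,-5"), neg)
  expect_error(read_peaks(neg), "negative intensity")
})

test_that("MGF writing round-trips through the reader", {
  pk <- tibble::tibble(mz = c(147.113, 359.265), intensity = c(90, 2000))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(pk, path, pepmass = 244.3, charge = "2+")
  back <- read_peaks(path)
  expect_equal(back$mz, pk$mz, tolerance = 1e-6)
  expect_equal(back$intensity, pk$intensity, tolerance = 1e-6)
})

test_that("annotation matches ions to peaks within tolerance", {
  ions <- ion_table("GAVLK")
  peaks <- tibble::tibble(
    mz = c(359.30, 260.20, 147.15, 129.10, 500.0),
    intensity = c(2000, 281, 90, 150, 7)
  )
  ann <- annotate_peaks(peaks, ions, tolerance = 0.5)
  expect_equal(ann$mz_observed[ann$ion == "y3"], 359.30)
  expect_equal(ann$intensity[ann$ion == "y2"], 281)
  expect_false(ann$detected[ann$ion == "b1"])  # nothing near b1
  # each peak consumed at most once
  obs <- ann$mz_observed[ann$detected]
  expect_equal(anyDuplicated(obs), 0L)
})

test_that("tightening the tolerance never adds assignments", {
  withr::local_seed(8)
  ions <- ion_table("GAVLK")
  for (rep in 1:5) {
    peaks <- tibble::tibble(
      mz = stats::runif(12, 100, 500),
      intensity = stats::runif(12, 1, 100)
    )
    tols <- c(2, 1, 0.5, 0.1)
    counts <- vapply(tols, function(tol)
      sum(annotate_peaks(peaks, ions, tol)$detected), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("assignment agrees with exhaustive best-match search", {
  withr::local_seed(14)
  for (rep in 1:10) {
    n_pk <- sample(3:6, 1)
    n_ion <- sample(2:5, 1)
    peak_mz <- sort(stats::runif(n_pk, 100, 120))
    peak_int <- stats::runif(n_pk, 1, 100)
    ion_mz <- stats::runif(n_ion, 100, 120)
    ions <- tibble::tibble(ion = paste0("y", seq_len(n_ion)),
                           series = "y", index = seq_len(n_ion),
                           mz_mono = ion_mz)
    tol <- stats::runif(1, 1, 6)
    ann <- annotate_peaks(tibble::tibble(mz = peak_mz,
                                         intensity = peak_int),
                          ions, tol)
    want <- assign_bruteforce(peak_mz, peak_int, ion_mz, tol)
    got <- match(ann$mz_observed, peak_mz)
    expect_equal(got, want)
  }
})

test_that("relative intensities are normalised to the strongest y ion", {
  ions <- ion_table("GAVLK")
  ymz <- vapply(1:4, function(i) fragment_mz("GAVLK", "y", i), numeric(1))
  peaks <- tibble::tibble(mz = ymz[c(4, 3, 2, 1)],
                          intensity = c(19, 2000, 281, 90))
  rel <- relative_intensities(annotate_peaks(peaks, ions, 0.1))
  expect_equal(rel$rel_intensity[match(paste0("y", 4:1), rel$ion)],
               c(0.0095, 1.0, 0.1405, 0.045), tolerance = 1e-9)
  expect_equal(attr(rel, "reference_ion"), "y3")
  # exactly one ion sits at 1.0, always
  expect_equal(sum(rel$rel_intensity == 1), 1L)

  single <- tibble::tibble(mz = ymz[1], intensity = 123)
  rel1 <- relative_intensities(annotate_peaks(single, ions, 0.1))
  expect_equal(rel1$rel_intensity, 1)

  bonly <- tibble::tibble(mz = fragment_mz("GAVLK", "b", 2),
                          intensity = 10)
  expect_error(relative_intensities(annotate_peaks(bonly, ions, 0.1)),
               "no detected y ions")
})

test_that("log errors reproduce the benchmark scoring arithmetic", {
  bench <- gavlk_benchmark()
  meas <- tibble::tibble(ion = bench$ion, rel_intensity = bench$measured)
  self <- log_error(meas, meas)
  expect_equal(self$sum_abs_log_err, 0)
  expect_true(self$order_match)

  for (col in c("EHC", "E", "GE", "GEEC")) {
    pred <- tibble::tibble(ion = bench$ion, rel_intensity = bench[[col]])
    rep <- log_error(pred, meas)
    want <- sum(abs(log10(bench[[col]] / bench$measured)))
    expect_equal(rep$sum_abs_log_err, want, tolerance = 1e-12)
  }
})

test_that("log errors are antisymmetric under swapping the inputs", {
  withr::local_seed(23)
  for (rep in 1:5) {
    ions <- paste0("y", 1:4)
    a <- tibble::tibble(ion = ions, rel_intensity = stats::runif(4, 0.01, 1))
    b <- tibble::tibble(ion = ions, rel_intensity = stats::runif(4, 0.01, 1))
    ab <- log_error(a, b)
    ba <- log_error(b, a)
    expect_equal(ab$per_ion$log_err, -ba$per_ion$log_err,
                 tolerance = 1e-12)
    expect_equal(ab$sum_abs_log_err, ba$sum_abs_log_err,
                 tolerance = 1e-12)
  }
})

test_that("non-positive measured intensities are excluded with warning", {
  pred <- tibble::tibble(ion = c("y1", "y2"), rel_intensity = c(1, 0.5))
  meas <- tibble::tibble(ion = c("y1", "y2"), rel_intensity = c(1, 0))
  expect_warning(rep <- log_error(pred, meas), "y2")
  expect_equal(rep$n_ions, 1L)
  expect_error(log_error(pred,
                         tibble::tibble(ion = "zz", rel_intensity = 1)),
               "no shared ions")
})

test_that("tidy and glance expose the comparison report as tibbles", {
  bench <- gavlk_benchmark()
  rep <- log_error(
    tibble::tibble(ion = bench$ion, rel_intensity = bench$EHC),
    tibble::tibble(ion = bench$ion, rel_intensity = bench$measured))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4L)
  expect_true(all(c("ion", "log_err", "abs_discrepancy") %in% names(td)))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$order_match)
  expect_equal(gl$kendall_tau, 1)
})

test_that("random-match baselines follow the combinatorics", {
  base4 <- random_match_baseline(4)
  expect_equal(base4$order_probability, 1 / 24)
  expect_equal(base4$intensity_probability, 1 / 15625)
  expect_equal(random_match_baseline(2)$order_probability, 0.5)
  expect_equal(random_match_baseline(4, bins = 10)$intensity_probability,
               1e-3)
})
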