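# Independent oracles and small fixture builders shared by the tests.
# These re-derive expected values by brute force or from first
# principles, deliberately avoiding the code paths they check.

# --- geometry -------------------------------------------------------

rotation_from_quaternion <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

random_rotation <- function() rotation_from_quaternion(stats::rnorm(4))

# minimal RMSD by multi-start numerical search over Euler angles;
# independent of the SVD-based implementation
rmsd_bruteforce <- function(x, y, n_starts = 60) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  euler <- function(a) {
    rz <- matrix(c(cos(a[1]), -sin(a[1]), 0,
                   sin(a[1]), cos(a[1]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0,
                   -sin(a[2]), 0, cos(a[2])), 3, 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cos(a[3]), -sin(a[3]),
                   0, sin(a[3]), cos(a[3])), 3, 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(a) sqrt(sum((yc %*% euler(a) - xc)^2) / nrow(x))
  best <- Inf
  for (i in seq_len(n_starts)) {
    start <- stats::runif(3, -pi, pi)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 500))
    best <- min(best, fit$value)
  }
  best
}

make_conf <- function(elements, coords) {
  list(elements = elements, coords = coords)
}

# --- vibrational thermochemistry ------------------------------------

# thermal vibrational energy and entropy from numerical differentiation
# of the (ZPE-excluded) harmonic partition function ln Q
vib_oracle <- function(nu, temp, step = 1e-3) {
  h <- 6.62607015e-34; c_cm <- 2.99792458e10
  kb <- 1.380649e-23; r <- 8.314462618
  lnq <- function(tt) sum(-log1p(-exp(-h * c_cm * nu / (kb * tt))))
  dlnq <- (lnq(temp + step) - lnq(temp - step)) / (2 * step)
  u <- r * temp^2 * dlnq                       # J/mol
  list(thermal_vib = u / 1000,                 # kJ/mol
       vib_entropy = r * lnq(temp) + u / temp) # J/mol/K
}

# --- Boltzmann aggregation ------------------------------------------

# direct enumeration over a tiny explicit conformer list
aggregate_bruteforce <- function(energies, labels, temp) {
  rt <- 8.314462618e-3 * temp
  w <- exp(-(energies - min(energies)) / rt)
  w <- w / sum(w)
  vapply(split(w, labels), sum, numeric(1))
}

# --- peak assignment ------------------------------------------------

# exhaustive search over injective ion -> peak assignments: an
# assignment is scored by its matched pairs sorted by (intensity
# descending, |delta m/z| ascending) and compared lexicographically on
# (intensity, -|delta m/z|); the maximum is the best-match assignment.
# Returns peak index per ion (NA = not detected).
assign_bruteforce <- function(peak_mz, peak_int, ion_mz, tol) {
  n_ion <- length(ion_mz)
  cands <- lapply(ion_mz, function(m) which(abs(peak_mz - m) <= tol))
  best <- NULL
  score_of <- function(assign) {
    hit <- which(!is.na(assign))
    ints <- peak_int[assign[hit]]
    dmz <- abs(peak_mz[assign[hit]] - ion_mz[hit])
    ord <- order(-ints, dmz)
    list(ints = ints[ord], dmz = dmz[ord])
  }
  better <- function(a, b) { # TRUE if score a beats score b
    la <- length(a$ints); lb <- length(b$ints)
    for (i in seq_len(min(la, lb))) {
      if (a$ints[i] != b$ints[i]) return(a$ints[i] > b$ints[i])
      if (a$dmz[i] != b$dmz[i]) return(a$dmz[i] < b$dmz[i])
    }
    la > lb
  }
  recurse <- function(i, assign) {
    if (i > n_ion) {
      sc <- score_of(assign)
      if (is.null(best) || better(sc, best$score)) {
        best <<- list(assign = assign, score = sc)
      }
      return(invisible())
    }
    for (j in c(cands[[i]][!cands[[i]] %in% assign], NA_integer_)) {
      assign[i] <- j
      recurse(i + 1L, assign)
    }
  }
  recurse(1L, rep(NA_integer_, n_ion))
  best$assign
}

# --- fixtures -------------------------------------------------------

# tiny hand-built ensemble: explicit energies, one shared geometry
tiny_ensemble <- function(energies, labels,
                          ids = sprintf("c%02d", seq_along(energies)),
                          coords = NULL, freqs = NULL) {
  n_at <- 4L
  base <- if (is.null(coords)) {
    matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0, 0, 0, 1.5), n_at, 3,
           byrow = TRUE)
  } else coords
  conformer_ensemble(tibble::tibble(
    id = ids, isomer_label = labels, stage = "dft", energy = energies,
    elements = rep(list(rep("C", nrow(base))), length(energies)),
    coords = rep(list(base), length(energies)),
    freqs = rep(list(freqs), length(energies))
  ))
}

table1_targets <- function() {
  raw <- c(GAVLK_NH_2 = 0.0102, GAVLK_NH_3 = 1.0000,
           GAVLK_NH_4 = 0.1780, GAVLK_NH_5 = 0.0382)
  raw / sum(raw)
}
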