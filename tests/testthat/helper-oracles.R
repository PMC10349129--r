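# Independent oracles used across the test suite. These deliberately avoid
# the package's own mass/match/digestion code paths.

# Published monoisotopic residue masses (Da, 6 d.p., Expasy/Unimod values),
# frozen as literals. Used only to cross-check the package's atomic-table
# derived masses.
ORACLE_RESIDUE_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.0072765

oracle_peptide_mass <- function(sequence) {
  sum(ORACLE_RESIDUE_MASS[strsplit(sequence, "")[[1]]]) + ORACLE_WATER
}

random_peptide <- function(len) {
  paste(sample(names(ORACLE_RESIDUE_MASS)[1:20], len, replace = TRUE),
        collapse = "")
}

# Exhaustive digestion oracle: enumerate every substring and keep those
# whose ends are cleavage boundaries and whose internal boundary count is
# within max_missed.
oracle_digest <- function(protein, protease, max_missed) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  targets <- if (protease == "trypsin_p") c("K", "R") else "K"
  boundary <- c(0, which(aa %in% targets & seq_len(n) < n), n)
  out <- character()
  for (i in seq_len(n)) for (j in i:n) {
    if (!(i - 1) %in% boundary || !j %in% boundary) next
    internal <- sum(boundary > (i - 1) & boundary < j)
    if (internal <= max_missed) {
      out <- c(out, substring(protein, i, j))
    }
  }
  sort(out)
}

# Brute-force all-pairs nearest-peak matcher (quadratic, no sorting tricks).
oracle_match_count <- function(peak_mz, theo_mz, ppm_tol) {
  sum(vapply(theo_mz, function(m) {
    if (length(peak_mz) == 0) return(FALSE)
    d <- abs(peak_mz - m)
    best <- peak_mz[which.min(d)]
    abs(best - m) / m * 1e6 <= ppm_tol
  }, TRUE))
}

# Full (untruncated) isotope distribution by direct polynomial convolution,
# written independently of the package's truncated-power routine.
oracle_isotope_dist <- function(counts, iso) {
  poly_mult <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) {
      out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
    }
    out
  }
  dist <- 1
  for (el in names(counts)) {
    for (k in seq_len(counts[[el]])) dist <- poly_mult(dist, iso[[el]])
  }
  dist
}

closed_form_gaussian_area <- function(amplitude, sigma) {
  amplitude * sigma * sqrt(2 * pi)
}

# Hand-computed two-sample equal-variance t statistic for one row.
oracle_student_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
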