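#' Construct a modified peptide
#'
#' A peptide over the twenty canonical one-letter amino acids together with
#' positioned variable modifications. All residue and modification positions
#' are 1-based, matching the His1 nomenclature of N-terminal histidines.
#'
#' @param sequence Peptide sequence (uppercase one-letter codes).
#' @param mods Optional data frame with columns `position` (1-based residue
#'   index) and `mod_name`, or `NULL` for an unmodified peptide.
#' @param n_term_free Logical; `TRUE` when position 1 carries a free
#'   alpha-amine (no N-terminal acetylation). Recorded for provenance.
#' @param mod_table Modification table, see [modification_table()].
#' @return An object of class `modified_peptide`.
#' @examples
#' modified_peptide("HTVIVYPGYR",
#'                  mods = data.frame(position = 1, mod_name = "methyl_his"))
#' @export
modified_peptide <- function(sequence, mods = NULL, n_term_free = TRUE,
                             mod_table = modification_table()) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    stop("sequence must be a single non-empty string")
  }
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, rownames(residue_formulas()))
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  if (is.null(mods)) {
    mods <- data.frame(position = integer(), mod_name = character(),
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("position", "mod_name") %in% names(mods)))
  if (nrow(mods) > 0) {
    if (any(mods$position < 1 | mods$position > nchar(sequence))) {
      stop("modification position outside 1..", nchar(sequence))
    }
    if (anyDuplicated(mods$position)) {
      stop("at most one modification per position")
    }
    i <- match(mods$mod_name, mod_table$mod_name)
    if (any(is.na(i))) {
      stop("unknown modification name: ",
           paste(mods$mod_name[is.na(i)], collapse = ", "))
    }
    legal <- mod_table$residues[i]
    res <- aa[mods$position]
    ok <- mapply(grepl, res, legal, MoreArgs = list(fixed = TRUE))
    if (!all(ok)) {
      stop("modification ", mods$mod_name[!ok][1], " not legal on residue ",
           res[!ok][1], " at position ", mods$position[!ok][1])
    }
  }
  structure(
    list(sequence = sequence, mods = mods, n_term_free = isTRUE(n_term_free)),
    class = "modified_peptide"
  )
}

as_peptide <- function(p) {
  if (inherits(p, "modified_peptide")) p else modified_peptide(p)
}

#' @export
print.modified_peptide <- function(x, ...) {
  m <- if (nrow(x$mods) == 0) "unmodified" else
    paste(sprintf("%s@%d", x$mods$mod_name, x$mods$position), collapse = ", ")
  cat("modified_peptide:", x$sequence, "(", m, ")\n")
  invisible(x)
}

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of the residue monoisotopic masses, one water, and all modification
#' mass deltas.
#'
#' @param p A [modified_peptide()] (or a plain sequence string).
#' @param mod_table Modification table, see [modification_table()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_neutral_mass("G")  # free glycine, 75.0320 Da
#' @export
peptide_neutral_mass <- function(p, mod_table = modification_table()) {
  p <- as_peptide(p)
  aa <- strsplit(p$sequence, "")[[1]]
  rm <- residue_masses()
  mass <- sum(rm[aa]) + water_mass()
  if (nrow(p$mods) > 0) {
    mass <- mass + sum(mod_delta(p$mods$mod_name, mod_table))
  }
  unname(mass)
}

#' Mass-to-charge ratio of a protonated ion
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge state.
#' @return m/z in Thomson: `(neutral_mass + charge * proton) / charge`.
#' @examples
#' mz_of(peptide_neutral_mass("HTVIVYPGYR"), 2)
#' @export
mz_of <- function(neutral_mass, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer")
  }
  (neutral_mass + charge * atomic_masses()$proton) / charge
}

#' Immonium ion m/z of a residue
#'
#' Standard immonium (a1-type) ion: residue monoisotopic mass minus CO plus
#' one proton, plus the modification delta when a modification is given. For
#' methylated histidine this reproduces the diagnostic ion near m/z 124.0869
#' used for high-confidence localization.
#'
#' @param residue One-letter amino acid code.
#' @param mod_name Modification name, or `NULL` for the unmodified residue.
#' @param mod_table Modification table, see [modification_table()].
#' @return m/z of the singly charged immonium ion.
#' @examples
#' immonium_mz("H", "methyl_his")  # ~124.0869
#' @export
immonium_mz <- function(residue, mod_name = NULL,
                        mod_table = modification_table()) {
  rm <- residue_masses()
  if (!residue %in% names(rm)) stop("unknown residue letter: ", residue)
  mz <- rm[[residue]] - co_mass() + atomic_masses()$proton
  if (!is.null(mod_name)) {
    i <- match(mod_name, mod_table$mod_name)
    if (is.na(i)) stop("unknown modification name: ", mod_name)
    if (!grepl(residue, mod_table$residues[i], fixed = TRUE)) {
      stop("modification ", mod_name, " not legal on residue ", residue)
    }
    mz <- mz + mod_table$delta[i]
  }
  unname(mz)
}

#' Theoretical b- and y-fragment ions of a peptide
#'
#' Generates the complete b1..b(n-1) and y1..y(n-1) series at each requested
#' charge state. Modification deltas are carried by every fragment whose
#' covered sub-sequence includes the modified position, so an N-terminal
#' modification shifts the whole b series and no y ion.
#'
#' @param p A [modified_peptide()] (or sequence string) of length >= 2.
#' @param charges Integer vector of fragment charge states (default 1).
#' @param mod_table Modification table, see [modification_table()].
#' @return Data frame with columns `series` ("b"/"y"), `index`, `charge`,
#'   `mz`, `composition_peptide` and `carries_mod`, sorted by `mz`.
#' @examples
#' fragment_ions("GH")
#' @export
fragment_ions <- function(p, charges = 1L, mod_table = modification_table()) {
  p <- as_peptide(p)
  n <- nchar(p$sequence)
  if (n < 2) stop("peptide must have at least 2 residues")
  if (length(charges) == 0) stop("charge set must be non-empty")
  if (any(charges < 1)) stop("charges must be positive integers")
  aa <- strsplit(p$sequence, "")[[1]]
  rm <- residue_masses()
  res <- unname(rm[aa])
  delta <- numeric(n)
  if (nrow(p$mods) > 0) {
    delta[p$mods$position] <- mod_delta(p$mods$mod_name, mod_table)
  }
  cum_b <- cumsum(res + delta)          # neutral b fragment = residue sum
  total <- cum_b[n] + water_mass()
  idx <- seq_len(n - 1)
  b_neutral <- cum_b[idx]
  y_neutral <- total - cum_b[n - idx]   # residue sum of suffix + water
  b_mod <- cumsum(delta != 0)[idx] > 0
  y_mod <- rev(cumsum(rev(delta != 0)))[n - idx + 1] > 0
  out <- do.call(rbind, lapply(charges, function(z) {
    data.frame(
      series = rep(c("b", "y"), each = n - 1),
      index = c(idx, idx),
      charge = as.integer(z),
      mz = c(mz_of(b_neutral, z), mz_of(y_neutral, z)),
      composition_peptide = c(
        substring(p$sequence, 1, idx),
        substring(p$sequence, n - idx + 1, n)
      ),
      carries_mod = c(b_mod, y_mod),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Isotope envelope of a peptide
#'
#' First `n_peaks` isotopologue abundances of the peptide computed from its
#' elemental composition by polynomial expansion (repeated convolution) of
#' the per-element isotope distributions, aggregated by neutron-number
#' offset. The monoisotopic peak comes first; abundances are on the scale of
#' the full (untruncated) distribution, so the returned values sum to at
#' most 1.
#'
#' @param p A [modified_peptide()] (or sequence string).
#' @param n_peaks Number of isotopologue peaks to return (>= 1).
#' @param mod_table Modification table, see [modification_table()].
#' @return Data frame with columns `mz_offset_index` (0 = monoisotopic) and
#'   `relative_abundance`.
#' @examples
#' isotope_envelope("HTVIVYPGYR", n_peaks = 3)
#' @export
isotope_envelope <- function(p, n_peaks = 3L,
                             mod_table = modification_table()) {
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  p <- as_peptide(p)
  comp <- peptide_composition(p, mod_table)
  iso <- isotope_abundances()
  dist <- 1
  for (el in names(comp)) {
    k <- comp[[el]]
    if (k == 0) next
    dist <- convolve_power(iso[[el]], k, n_peaks, dist)
  }
  length(dist) <- n_peaks
  dist[is.na(dist)] <- 0
  data.frame(
    mz_offset_index = seq_len(n_peaks) - 1L,
    relative_abundance = dist
  )
}

# Elemental composition (H,C,N,O,S counts) of a peptide including water and
# modification atoms. Modifications are mapped to compositions here;
# methyl_his adds CH2.
peptide_composition <- function(p, mod_table = modification_table()) {
  p <- as_peptide(p)
  aa <- strsplit(p$sequence, "")[[1]]
  rf <- residue_formulas()
  counts <- colSums(rf[aa, , drop = FALSE])
  counts[["H"]] <- counts[["H"]] + 2  # water
  counts[["O"]] <- counts[["O"]] + 1
  if (nrow(p$mods) > 0) {
    for (m in p$mods$mod_name) {
      if (m == "methyl_his") {
        counts[["C"]] <- counts[["C"]] + 1
        counts[["H"]] <- counts[["H"]] + 2
      } else {
        stop("no elemental composition known for modification: ", m)
      }
    }
  }
  counts
}

# dist * base^k truncated to the first n terms (offsets only grow, so
# truncation is exact for the retained terms).
convolve_power <- function(base, k, n, dist = 1) {
  pw <- base
  while (k > 0) {
    if (k %% 2 == 1) dist <- truncated_conv(dist, pw, n)
    k <- k %/% 2
    if (k > 0) pw <- truncated_conv(pw, pw, n)
  }
  dist
}

truncated_conv <- function(a, b, n) {
  la <- min(length(a), n); lb <- min(length(b), n)
  out <- numeric(min(la + lb - 1, n))
  for (i in seq_len(la)) {
    jmax <- min(lb, n - i + 1)
    if (jmax < 1) break
    j <- seq_len(jmax)
    out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
  }
  out
}
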