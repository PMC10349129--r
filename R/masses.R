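# Single source of truth for all mass constants used across the package.
# Every other module obtains masses through these accessors; no mass is
# defined anywhere else.

#' Monoisotopic atomic mass table
#'
#' Standard monoisotopic masses (Da) of the elements occurring in the twenty
#' canonical amino acid residues, plus the mass of the proton used for m/z
#' conversion. These IUPAC/CODATA values are the single source of truth for
#' all mass arithmetic in the package.
#'
#' @return Named list with elements `masses` (named numeric vector, Da per
#'   element symbol) and `proton` (proton mass, Da).
#' @examples
#' atomic_masses()$masses[["C"]]
#' @export
atomic_masses <- function() {
  list(
    masses = c(
      H = 1.00782503207,
      C = 12.0,
      N = 14.0030740048,
      O = 15.9949146196,
      S = 31.97207100
    ),
    proton = 1.00727646688
  )
}

# Isotope abundance vectors indexed by neutron-number offset from the
# lightest isotope (IUPAC 2013 representative abundances). Used only by
# isotope_envelope().
isotope_abundances <- function() {
  list(
    H = c(0.999885, 0.000115),
    C = c(0.9893, 0.0107),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
  )
}

# Elemental composition of each amino acid residue (the in-chain residue,
# i.e. amino acid minus water). Counts are in the order H, C, N, O, S.
residue_formulas <- function() {
  el <- c("H", "C", "N", "O", "S")
  m <- rbind(
    G = c(3, 2, 1, 1, 0),
    A = c(5, 3, 1, 1, 0),
    S = c(5, 3, 1, 2, 0),
    P = c(7, 5, 1, 1, 0),
    V = c(9, 5, 1, 1, 0),
    T = c(7, 4, 1, 2, 0),
    C = c(5, 3, 1, 1, 1),
    L = c(11, 6, 1, 1, 0),
    I = c(11, 6, 1, 1, 0),
    N = c(6, 4, 2, 2, 0),
    D = c(5, 4, 1, 3, 0),
    Q = c(8, 5, 2, 2, 0),
    K = c(12, 6, 2, 1, 0),
    E = c(7, 5, 1, 3, 0),
    M = c(9, 5, 1, 1, 1),
    H = c(7, 6, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(12, 6, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(10, 11, 2, 1, 0)
  )
  colnames(m) <- el
  m
}

# Monoisotopic mass of a composition given as named counts over H,C,N,O,S.
composition_mass <- function(counts) {
  am <- atomic_masses()$masses
  sum(counts * am[names(counts)])
}

# Monoisotopic residue masses derived from the formula table.
residue_masses <- function() {
  rf <- residue_formulas()
  am <- atomic_masses()$masses
  drop(rf %*% am[colnames(rf)])
}

water_mass <- function() {
  am <- atomic_masses()$masses
  2 * am[["H"]] + am[["O"]]
}

co_mass <- function() {
  am <- atomic_masses()$masses
  am[["C"]] + am[["O"]]
}

#' Modification table
#'
#' Variable modifications known to the package: a mapping from modification
#' name to its monoisotopic mass delta and the residues it may occupy. The
#' `methyl_his` entry is the net CH2 addition of histidine imidazole
#' methylation, computed from the atomic mass table (never hard-coded); tau-
#' and pi-methylation are isobaric, so a single mass delta represents both.
#'
#' @return A data frame with columns `mod_name`, `delta` (Da) and `residues`
#'   (string of one-letter codes the modification is legal on).
#' @examples
#' modification_table()
#' @export
modification_table <- function() {
  am <- atomic_masses()$masses
  methyl <- am[["C"]] + 2 * am[["H"]]
  data.frame(
    mod_name = "methyl_his",
    delta = methyl,
    residues = "H",
    stringsAsFactors = FALSE
  )
}

mod_delta <- function(mod_name, mods = modification_table()) {
  i <- match(mod_name, mods$mod_name)
  if (any(is.na(i))) {
    stop("unknown modification name: ",
         paste(mod_name[is.na(i)], collapse = ", "))
  }
  mods$delta[i]
}
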