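test_that("peptide neutral mass matches hand-derived compositions", {
  # free glycine C2H5NO2, summed from atomic masses by hand
  expect_equal(peptide_neutral_mass("G"), 75.03203, tolerance = 1e-6)
  # methylated minus unmethylated peptide equals exactly the CH2 delta
  meth <- modified_peptide("HTVIVYPGYR",
                           data.frame(position = 1, mod_name = "methyl_his"))
  delta <- peptide_neutral_mass(meth) - peptide_neutral_mass("HTVIVYPGYR")
  expect_equal(delta, modification_table()$delta[1], tolerance = 1e-10)
})

test_that("peptide masses agree with the residue-summation oracle", {
  set.seed(42)
  for (i in 1:20) {
    pep <- random_peptide(sample(5:15, 1))
    expect_equal(peptide_neutral_mass(pep), unname(oracle_peptide_mass(pep)),
                 tolerance = 1e-5 / peptide_neutral_mass(pep))
  }
})

test_that("methyl delta is one constant for all peptides", {
  set.seed(7)
  deltas <- replicate(25, {
    pep <- paste0("H", random_peptide(sample(4:12, 1)))
    m <- modified_peptide(pep, data.frame(position = 1,
                                          mod_name = "methyl_his"))
    peptide_neutral_mass(m) - peptide_neutral_mass(pep)
  })
  expect_equal(max(deltas) - min(deltas), 0, tolerance = 1e-12)
  expect_equal(deltas[1], modification_table()$delta[1], tolerance = 1e-12)
})

test_that("invalid peptides and mods are rejected", {
  expect_error(peptide_neutral_mass(""), "non-empty")
  expect_error(modified_peptide("AXC"), "unknown residue")
  expect_error(modified_peptide("GH", data.frame(position = 3,
                                                 mod_name = "methyl_his")),
               "position")
  expect_error(modified_peptide("GH", data.frame(position = 1,
                                                 mod_name = "methyl_his")),
               "not legal")
  expect_error(
    modified_peptide("HH", data.frame(position = c(1, 1),
                                      mod_name = c("methyl_his",
                                                   "methyl_his"))),
    "one modification per position")
  expect_error(modified_peptide("H", data.frame(position = 1,
                                                mod_name = "phospho")),
               "unknown modification")
})

test_that("m/z conversion follows the proton arithmetic", {
  proton <- atomic_masses()$proton
  expect_equal(mz_of(0, 1), proton)
  for (M in c(500.123, 1234.5678, 2999.9)) {
    expect_equal(2 * mz_of(M, 2) - mz_of(M, 1), proton, tolerance = 1e-10)
  }
  M <- oracle_peptide_mass("HTVIVYPGYR")
  expect_equal(mz_of(peptide_neutral_mass("HTVIVYPGYR"), 2),
               unname((M + 2 * ORACLE_PROTON) / 2), tolerance = 1e-5)
  expect_error(mz_of(100, 0), "positive")
})

test_that("immonium ions reproduce the diagnostic methyl-His mass", {
  expect_equal(round(immonium_mz("H", "methyl_his"), 4), 124.0869)
  d <- immonium_mz("H", "methyl_his") - immonium_mz("H")
  expect_equal(d, modification_table()$delta[1], tolerance = 1e-10)
  expect_lt(abs(immonium_mz("H") - 110.0713), 1e-3)
  expect_error(immonium_mz("H", "phospho"), "unknown modification")
  expect_error(immonium_mz("B"), "unknown residue")
})

test_that("fragment ions cover both series with correct mod bookkeeping", {
  expect_equal(nrow(fragment_ions("GH")), 2)
  meth <- modified_peptide("HTVIVYPGYR",
                           data.frame(position = 1, mod_name = "methyl_his"))
  f <- fragment_ions(meth)
  expect_true(all(f$carries_mod[f$series == "b"]))
  expect_false(any(f$carries_mod[f$series == "y"]))
  # shifted vs unshifted series: every b shifted by the delta, y unchanged
  fu <- fragment_ions("HTVIVYPGYR")
  key <- function(d) d[order(d$series, d$index), ]
  f <- key(f); fu <- key(fu)
  delta <- modification_table()$delta[1]
  shift <- f$mz - fu$mz
  expect_equal(shift[f$series == "b"], rep(delta, 9), tolerance = 1e-9)
  expect_equal(shift[f$series == "y"], rep(0, 9), tolerance = 1e-9)
  expect_false(is.unsorted(fragment_ions(meth, charges = c(1, 2))$mz))
  expect_error(fragment_ions("GH", charges = integer()), "non-empty")
  expect_error(fragment_ions("G"), "at least 2")
})

test_that("b/y complementarity holds for random peptides", {
  set.seed(11)
  proton <- atomic_masses()$proton
  for (i in 1:10) {
    pep <- random_peptide(sample(4:12, 1))
    n <- nchar(pep)
    f <- fragment_ions(pep)
    M <- peptide_neutral_mass(pep)
    for (j in seq_len(n - 1)) {
      b <- f$mz[f$series == "b" & f$index == j]
      y <- f$mz[f$series == "y" & f$index == n - j]
      expect_equal(b + y, M + 2 * proton, tolerance = 1e-6)
    }
  }
})

test_that("digestion matches the exhaustive enumeration oracle", {
  expect_equal(digest("HTVIVYPGYRK", "trypsin_p", 0)$sequence,
               c("HTVIVYPGYR", "K"))
  expect_setequal(digest("AKRG", "trypsin_p", 1)$sequence,
                  c("AK", "R", "G", "AKR", "RG"))
  # Trypsin/P cleaves before proline; LysC ignores R
  expect_equal(digest("AKPG", "trypsin_p", 0)$sequence, c("AK", "PG"))
  expect_equal(digest("ARGKP", "lysc", 0)$sequence, c("ARGK", "P"))
  set.seed(5)
  for (i in 1:15) {
    prot <- random_peptide(sample(6:20, 1))
    mm <- sample(0:2, 1)
    for (enz in c("trypsin_p", "lysc")) {
      expect_equal(sort(digest(prot, enz, mm)$sequence),
                   oracle_digest(prot, enz, mm))
    }
  }
  expect_error(digest("AKG", "trypsin_p", -1), ">= 0")
})

test_that("zero-missed-cleavage peptides reconstruct the protein", {
  set.seed(99)
  for (i in 1:100) {
    prot <- random_peptide(sample(5:30, 1))
    d <- digest(prot, "trypsin_p", 0)
    d <- d[order(d$start), ]
    expect_identical(paste(d$sequence, collapse = ""), prot)
    expect_true(all(d$missed_cleavages == 0))
  }
})

test_that("signal peptide trimming exposes the mature N-terminus", {
  expect_identical(trim_signal_peptide("MKFAHTVIVYPGYR", 4), "HTVIVYPGYR")
  expect_identical(trim_signal_peptide("ABCDE", 0), "ABCDE")
  expect_error(trim_signal_peptide("AB", 2), "cleavage_after")
})

test_that("isotope envelope matches direct polynomial convolution", {
  iso <- list(
    H = c(0.999885, 0.000115), C = c(0.9893, 0.0107),
    N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
  )
  # glycine: C2H5NO2 (residue C2H3NO + water)
  full <- oracle_isotope_dist(c(H = 5, C = 2, N = 1, O = 2), iso)
  env <- isotope_envelope("G", 4)
  expect_equal(env$relative_abundance, full[1:4], tolerance = 1e-12)
  # larger peptide with sulfur
  comp <- c(H = 5 + 5 + 12 + 2, C = 3 + 3 + 6, N = 1 + 1 + 2,
            O = 1 + 1 + 1 + 1, S = 1)  # ACK + water
  full2 <- oracle_isotope_dist(comp, iso)
  env2 <- isotope_envelope("ACK", 5)
  expect_equal(env2$relative_abundance, full2[1:5], tolerance = 1e-12)
})

test_that("isotope envelope is normalized, positive, monoisotopic-first", {
  env <- isotope_envelope("HTVIVYPGYR", 6)
  expect_true(all(env$relative_abundance > 0))
  expect_lte(sum(env$relative_abundance), 1)
  expect_equal(env$mz_offset_index, 0:5)
  # n_peaks = 1: product of lightest-isotope probabilities
  comp <- hismet:::peptide_composition(modified_peptide("G"))
  iso <- hismet:::isotope_abundances()
  expected <- prod(vapply(names(comp),
                          function(el) iso[[el]][1]^comp[[el]], 1.0))
  expect_equal(isotope_envelope("G", 1)$relative_abundance, expected,
               tolerance = 1e-12)
  expect_error(isotope_envelope("G", 0), "n_peaks")
})
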