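# File I/O: FASTA via Biostrings; MGF, long-format chromatogram TSV,
# abundance/design TSV and isotope-area TSV as plain tables.

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences (names are the FASTA
#'   record identifiers up to the first whitespace).
#' @export
read_proteins <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_proteins <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Write spectra to an MGF file
#'
#' @param spectra A list of [spectrum()] objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$id),
      paste0("PEPMASS=", format(s$precursor_mz, digits = 12)),
      paste0("CHARGE=", s$precursor_charge, "+"),
      sprintf("%.6f %.4f", s$peaks$mz, s$peaks$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' Minimal Mascot generic format reader for centroided peak lists with
#' TITLE, PEPMASS and CHARGE headers.
#'
#' @param path MGF file path.
#' @return A list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("malformed MGF: unbalanced blocks")
  lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1):(ends[i] - 1)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    pk <- do.call(rbind, strsplit(trimws(block[!hdr]), "[ \t]+"))
    peaks <- data.frame(
      mz = as.numeric(pk[, 1]),
      intensity = as.numeric(pk[, 2])
    )
    spectrum(
      peaks = peaks,
      precursor_mz = as.numeric(vals[keys == "PEPMASS"][1]),
      precursor_charge = as.integer(sub("\\+$", "", vals[keys == "CHARGE"][1])),
      id = vals[keys == "TITLE"][1]
    )
  })
}

#' Write a PRM panel as a long-format trace TSV
#'
#' Columns: strain, form, fragment, rt, intensity.
#'
#' @param panel List of `chromatogram_set` objects (see
#'   [simulate_prm_panel()]).
#' @param path Output path.
#' @export
write_traces <- function(panel, path) {
  rows <- lapply(panel, function(cs) {
    do.call(rbind, lapply(names(cs$traces), function(fr) {
      tr <- cs$traces[[fr]]
      data.frame(strain = cs$strain_id, form = cs$form, fragment = fr,
                 rt = tr$rt, intensity = tr$intensity,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format trace TSV into a PRM panel
#'
#' @param path TSV with columns strain, form, fragment, rt, intensity.
#' @return List of `chromatogram_set` objects.
#' @export
read_traces <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  keys <- unique(d[, c("strain", "form")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- d[d$strain == keys$strain[i] & d$form == keys$form[i], ]
    traces <- lapply(split(sub, sub$fragment), function(x) {
      x <- x[order(x$rt), ]
      data.frame(rt = x$rt, intensity = x$intensity)
    })
    chromatogram_set(keys$strain[i], keys$form[i], traces)
  })
}

#' Read an abundance matrix with its design
#'
#' @param matrix_path TSV whose first column is the protein id and remaining
#'   columns are samples.
#' @param design_path TSV with columns sample, condition, replicate.
#' @param mode `"lfq"` or `"tmt"`.
#' @return An [abundance_matrix()] object.
#' @export
read_abundance <- function(matrix_path, design_path, mode = "lfq") {
  m <- utils::read.delim(matrix_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  intens <- as.matrix(m[, -1, drop = FALSE])
  rownames(intens) <- m[[1]]
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  abundance_matrix(intens, design, mode = mode)
}

#' Write an abundance matrix and design to TSV
#'
#' @param m An [abundance_matrix()] object.
#' @param matrix_path,design_path Output paths.
#' @export
write_abundance <- function(m, matrix_path, design_path) {
  out <- data.frame(protein = rownames(m$intensities),
                    m$intensities, check.names = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}
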