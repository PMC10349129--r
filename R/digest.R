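#' In-silico proteolytic digestion
#'
#' Digests a protein with Trypsin/P or LysC and returns all peptides with up
#' to `max_missed` internal missed cleavage sites. Trypsin/P cleaves
#' C-terminal to K and R including before proline (the "/P" convention);
#' LysC cleaves after K only. Coordinates are 1-based inclusive.
#'
#' @param protein Protein sequence string.
#' @param protease `"trypsin_p"` or `"lysc"`.
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @return Data frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`.
#' @examples
#' digest("HTVIVYPGYRK", "trypsin_p", max_missed = 0)
#' @export
digest <- function(protein, protease = c("trypsin_p", "lysc"),
                   max_missed = 2L) {
  protease <- match.arg(protease)
  if (!is.character(protein) || length(protein) != 1 || nchar(protein) == 0) {
    stop("protein must be a single non-empty string")
  }
  if (max_missed < 0) stop("max_missed must be >= 0")
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  cut_after <- switch(protease,
    trypsin_p = which(aa %in% c("K", "R")),
    lysc = which(aa == "K")
  )
  cut_after <- cut_after[cut_after < n]
  bounds <- c(0L, cut_after, n)     # peptide i spans bounds[i]+1 .. bounds[i+1]
  npep <- length(bounds) - 1
  out <- list()
  for (i in seq_len(npep)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > npep) break
      out[[length(out) + 1]] <- data.frame(
        sequence = substring(protein, bounds[i] + 1, bounds[j + 1]),
        start = bounds[i] + 1L,
        end = bounds[j + 1],
        missed_cleavages = m,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove a signal peptide from a protein sequence
#'
#' Drops the N-terminal secretion leader so that position 1 of the mature
#' protein is the residue exposed after ER cleavage (His1 for LPMOs).
#' Cleavage positions are inputs (e.g. SignalP predictions supplied in a
#' companion table); the package does not predict them.
#'
#' @param protein Protein sequence string.
#' @param cleavage_after 0-based count of leader residues to remove
#'   (`0` returns the protein unchanged).
#' @return The mature protein sequence.
#' @examples
#' trim_signal_peptide("MKFAHTVIVYPGYR", 4)
#' @export
trim_signal_peptide <- function(protein, cleavage_after) {
  n <- nchar(protein)
  if (cleavage_after < 0 || cleavage_after >= n) {
    stop("cleavage_after must be in 0..", n - 1)
  }
  substring(protein, cleavage_after + 1, n)
}
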