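# Candidate funnel: staged elimination from annotated differential-abundance
# results down to the knockout shortlist. Acceptor-atom, yeast-homology and
# LPMO-fungi-uniqueness calls are input flags derived from external
# resources, not computed here.

#' Default methyltransferase keyword ruleset
#'
#' Case-insensitive substrings matched against annotation terms to flag
#' putative S-adenosylmethionine (SAM) dependent methyltransferases. Shipped
#' as an editable plain-text config in
#' `system.file("extdata", "mtase_keywords.txt", package = "hismet")`.
#'
#' @return Character vector of keywords.
#' @export
default_mtase_keywords <- function() {
  path <- system.file("extdata", "mtase_keywords.txt", package = "hismet")
  if (nzchar(path)) {
    kw <- readLines(path)
    kw <- trimws(kw[!grepl("^\\s*(#|$)", kw)])
    if (length(kw) > 0) return(kw)
  }
  c("methyltransferase", "SAM", "S-adenosyl")
}

#' Flag methyltransferases from annotation terms
#'
#' A protein is flagged when any of its annotation terms contains any
#' ruleset keyword (case-insensitive substring match), emulating the manual
#' curation of SAM-dependent methyltransferase annotations from
#' InterPro/Pfam/PROSITE/GO terms.
#'
#' @param annotations Data frame with columns `protein` and `terms`
#'   (annotation strings; multiple terms may be separated by `;`), one row
#'   per protein.
#' @param keywords Character vector of keywords
#'   (default [default_mtase_keywords()]).
#' @return Logical vector `is_mtase`, one element per row, named by protein.
#' @export
flag_mtases <- function(annotations, keywords = default_mtase_keywords()) {
  stopifnot(all(c("protein", "terms") %in% names(annotations)))
  if (anyDuplicated(annotations$protein)) {
    stop("one row per protein required")
  }
  terms <- tolower(annotations$terms)
  hit <- rep(FALSE, nrow(annotations))
  for (kw in tolower(keywords)) {
    hit <- hit | grepl(kw, terms, fixed = TRUE)
  }
  stats::setNames(hit, annotations$protein)
}

#' Validate a candidate record table
#'
#' @param records Data frame with columns `protein`, `is_mtase`,
#'   `identified`, `significant_up`, `acceptor_atom` ("N"/"O"/"unknown"),
#'   `has_yeast_homolog`, `unique_to_lpmo_fungi`, `manual_add`.
#' @return The validated records (invisibly usable downstream).
#' @export
validate_candidates <- function(records) {
  need <- c("protein", "is_mtase", "identified", "significant_up",
            "acceptor_atom", "has_yeast_homolog", "unique_to_lpmo_fungi",
            "manual_add")
  missing <- setdiff(need, names(records))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(records$protein)) stop("duplicate protein ids")
  bad <- !records$acceptor_atom %in% c("N", "O", "unknown")
  if (any(bad)) {
    stop("invalid acceptor_atom for record ", records$protein[bad][1])
  }
  viol <- records$significant_up & !records$identified
  if (any(viol)) {
    stop("record ", records$protein[viol][1],
         " violates significant_up => identified")
  }
  records
}

#' Run the methyltransferase candidate funnel
#'
#' Applies the staged elimination that shortlists knockout candidates:
#' (1) keep annotated methyltransferases; (2) keep proteins identified in
#' the proteomics data; (3) keep those significantly more abundant in the
#' cellulose-like condition; (4) drop predicted oxygen-acceptor
#' methyltransferases (unknown acceptors are retained); (5) drop those with
#' homologs in *S. cerevisiae* or *K. phaffii* (hosts incapable of the
#' modification); (6) keep those unique to LPMO-encoding fungi; (7) add the
#' manually curated extras. Per-stage accounting records, for each stage,
#' the incoming and surviving counts and the removed ids.
#'
#' @param records Candidate record data frame, see [validate_candidates()].
#' @return A list of class `funnel_report`: `report` (data frame with
#'   columns stage, rule, count_in, count_out and a list-column `removed`)
#'   and `shortlist` (character vector of protein ids).
#' @export
run_funnel <- function(records) {
  records <- validate_candidates(records)
  stages <- list(
    list(name = "annotated_mtase", rule = "keep is_mtase",
         keep = function(d) d$is_mtase),
    list(name = "identified", rule = "keep identified in proteomics",
         keep = function(d) d$identified),
    list(name = "significant_up",
         rule = "keep significantly more abundant on cellulose",
         keep = function(d) d$significant_up),
    list(name = "acceptor_atom", rule = "drop predicted O-acceptor",
         keep = function(d) d$acceptor_atom != "O"),
    list(name = "yeast_homolog", rule = "drop with S.cerevisiae/K.phaffii homolog",
         keep = function(d) !d$has_yeast_homolog),
    list(name = "lpmo_fungi_unique", rule = "keep unique to LPMO-encoding fungi",
         keep = function(d) d$unique_to_lpmo_fungi)
  )
  cur <- records[order(records$protein), , drop = FALSE]
  rows <- list()
  for (st in stages) {
    keep <- st$keep(cur)
    rows[[st$name]] <- data.frame(
      stage = st$name, rule = st$rule,
      count_in = nrow(cur), count_out = sum(keep),
      stringsAsFactors = FALSE
    )
    rows[[st$name]]$removed <- list(cur$protein[!keep])
    cur <- cur[keep, , drop = FALSE]
  }
  manual <- records$protein[records$manual_add]
  shortlist <- sort(union(cur$protein, manual))
  rows[["manual_addition"]] <- data.frame(
    stage = "manual_addition", rule = "union with manually curated additions",
    count_in = nrow(cur), count_out = length(shortlist),
    stringsAsFactors = FALSE
  )
  rows[["manual_addition"]]$removed <- list(character())
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, shortlist = shortlist),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("candidate funnel:\n")
  print(x$report[, c("stage", "count_in", "count_out")])
  cat("shortlist:", length(x$shortlist), "candidates\n")
  invisible(x)
}

#' Attach differential-abundance calls to candidate records
#'
#' Sets `identified` (protein present in the volcano table) and
#' `significant_up` (significant with positive log2 fold change toward the
#' cellulose-like condition, i.e. the first condition of the comparison).
#'
#' @param records Candidate record data frame (any `identified` /
#'   `significant_up` columns are overwritten).
#' @param volcano A [volcano_table()] data frame.
#' @return The updated records.
#' @export
attach_diffexpr <- function(records, volcano) {
  if (anyDuplicated(volcano$protein)) {
    stop("duplicate protein ids in volcano table")
  }
  i <- match(records$protein, volcano$protein)
  records$identified <- !is.na(i)
  records$significant_up <- !is.na(i) &
    volcano$significant[i] & volcano$log2fc[i] > 0
  records$significant_up[is.na(records$significant_up)] <- FALSE
  records
}
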