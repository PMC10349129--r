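#' Construct an abundance matrix with its experimental design
#'
#' @param intensities Numeric matrix, proteins x samples; entries positive
#'   or `NA` (missing). Row names are protein ids, column names sample ids.
#' @param design Data frame with columns `sample`, `condition`, `replicate`;
#'   one row per column of `intensities`.
#' @param mode `"lfq"` (label-free MS1 intensities) or `"tmt"` (reporter
#'   intensities, quantile-normalized before log transform).
#' @param logged Logical; whether intensities are already log2 scale.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(intensities, design, mode = c("lfq", "tmt"),
                             logged = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(intensities),
            all(c("sample", "condition", "replicate") %in% names(design)))
  if (!setequal(colnames(intensities), design$sample)) {
    stop("design samples must match matrix columns")
  }
  design <- design[match(colnames(intensities), design$sample), ]
  reps <- table(design$condition)
  if (length(reps) < 2) stop("at least 2 conditions required")
  if (max(reps) < 2) stop("at least 2 replicates in one condition required")
  if (!logged && any(intensities <= 0, na.rm = TRUE)) {
    stop("raw intensities must be positive or missing")
  }
  structure(list(intensities = intensities, design = design, mode = mode,
                 logged = logged),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix:", nrow(x$intensities), "proteins x",
      ncol(x$intensities), "samples (", x$mode,
      if (x$logged) ", log2" else ", raw", "),",
      sum(is.na(x$intensities)), "missing\n")
  invisible(x)
}

#' Filter proteins on minimum valid values per condition
#'
#' Keeps proteins observed in at least `min_valid` replicates of at least
#' one condition; all others are removed. Row order is preserved and the
#' operation is idempotent.
#'
#' @param m An [abundance_matrix()].
#' @param min_valid Minimum observed values required in some condition
#'   (default 2).
#' @return The filtered `abundance_matrix`.
#' @export
filter_valid <- function(m, min_valid = 2L) {
  stopifnot(inherits(m, "abundance_matrix"))
  conds <- unique(m$design$condition)
  keep <- rep(FALSE, nrow(m$intensities))
  for (cond in conds) {
    cols <- m$design$sample[m$design$condition == cond]
    nobs <- rowSums(!is.na(m$intensities[, cols, drop = FALSE]))
    keep <- keep | nobs >= min_valid
  }
  m$intensities <- m$intensities[keep, , drop = FALSE]
  m
}

#' Log2-transform intensities
#'
#' @param m An [abundance_matrix()] with positive raw intensities.
#' @return The matrix on log2 scale; missing values stay missing.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$logged) stop("matrix already log2 transformed")
  bad <- which(m$intensities <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive intensity at protein ",
         rownames(m$intensities)[bad[1, 1]], ", sample ",
         colnames(m$intensities)[bad[1, 2]])
  }
  m$intensities <- log2(m$intensities)
  m$logged <- TRUE
  m
}

#' Impute left-censored missing values from a downshifted normal
#'
#' Missing values are assumed to arise from intensities below the detection
#' limit and are drawn, per sample, from a normal distribution whose mean is
#' shifted down from the sample mean and whose spread is narrowed, both in
#' units of the sample standard deviation of the observed values:
#' `Normal(mean - downshift * sd, width * sd)`. The Perseus-style defaults
#' are width 0.3 and downshift 1.8. Observed cells are never altered.
#'
#' @param m A log2-scale [abundance_matrix()].
#' @param width Imputation SD as a fraction of the sample SD (> 0).
#' @param downshift Downshift in multiples of the sample SD (>= 0).
#' @param seed Integer seed for reproducibility.
#' @return The completed `abundance_matrix`.
#' @export
impute_downshift <- function(m, width = 0.3, downshift = 1.8, seed = 1L) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (!m$logged) stop("impute_downshift expects a log2-transformed matrix")
  if (width <= 0 || downshift < 0) stop("invalid width/downshift")
  x <- m$intensities
  set.seed(seed)
  for (j in seq_len(ncol(x))) {
    obs <- x[, j][!is.na(x[, j])]
    miss <- which(is.na(x[, j]))
    if (length(miss) == 0) next
    if (length(obs) < 2) {
      stop("sample ", colnames(x)[j], " has fewer than 2 observed values")
    }
    mu <- mean(obs); s <- stats::sd(obs)
    x[miss, j] <- stats::rnorm(length(miss), mu - downshift * s, width * s)
  }
  m$intensities <- x
  m
}

#' Quantile normalization of reporter intensities
#'
#' Forces every sample (column) to share the identical intensity
#' distribution — each rank is replaced by the mean of the values at that
#' rank across samples, with ties averaged — while preserving within-sample
#' ranks. Used for multiplexed (TMT) reporter intensities before log
#' transformation. Backed by `limma::normalizeQuantiles`.
#'
#' @param m An [abundance_matrix()] (typically `mode = "tmt"`), or a plain
#'   numeric matrix.
#' @return The normalized object, of the same kind as the input.
#' @export
quantile_normalize <- function(m) {
  if (is.matrix(m)) {
    norm <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(norm) <- dimnames(m)
    return(norm)
  }
  stopifnot(inherits(m, "abundance_matrix"))
  norm <- limma::normalizeQuantiles(m$intensities, ties = TRUE)
  dimnames(norm) <- dimnames(m$intensities)
  m$intensities <- norm
  m
}

# All distinct assignments of samples to group 1 (size n1) out of n, as a
# logical matrix with one column per assignment; capped by sampling when
# their number exceeds n_max.
label_permutations <- function(n, n1, n_max) {
  total <- choose(n, n1)
  if (total < 10) {
    warning("degenerate permutation space (", total,
            " distinct label assignments); exhaustive enumeration used")
  }
  if (total <= n_max) {
    comb <- utils::combn(n, n1)
  } else {
    picked <- new.env()
    comb <- matrix(0L, n1, 0)
    while (ncol(comb) < n_max) {
      cand <- sort(sample.int(n, n1))
      key <- paste(cand, collapse = ",")
      if (!exists(key, envir = picked)) {
        assign(key, TRUE, envir = picked)
        comb <- cbind(comb, cand)
      }
    }
  }
  apply(comb, 2, function(i) seq_len(n) %in% i)
}

#' Two-sample moderated t-test with permutation-based FDR
#'
#' For each protein, a two-sided Student (equal-variance) t statistic is
#' computed between the two conditions, with a small constant `s0` added to
#' the pooled standard error (SAM-style variance stabilization, guarding
#' against tiny-variance proteins). The null distribution is built by
#' permuting the condition labels (all distinct assignments when there are
#' no more than `n_perm`, otherwise `n_perm` sampled without replacement).
#' The significance cutoff is the most inclusive observed |t| for which the
#' estimated FDR — the median permutation count of statistics at or above
#' the cutoff, divided by the observed count — stays at or below `alpha`.
#' Per-protein p-values are pooled permutation p-values.
#'
#' @param m A complete (imputed) log2-scale [abundance_matrix()].
#' @param conditions Character vector of the two conditions to compare; the
#'   log2 fold change is `conditions[1] - conditions[2]`. Defaults to the
#'   first two conditions in the design.
#' @param alpha FDR cut-off (default 0.05).
#' @param n_perm Maximum number of label permutations (default 250).
#' @param s0 Variance-stabilizing offset on the log2 scale (default 0.1;
#'   set 0 for the plain Student t statistic).
#' @param seed Integer seed (used only when permutations are sampled).
#' @return A list of class `diffexpr_result`: `table` (data frame with
#'   protein, log2fc, t, p, significant), `cutoff` (|t| threshold, `Inf`
#'   when nothing is significant), and the run parameters.
#' @export
permutation_fdr_ttest <- function(m, conditions = NULL, alpha = 0.05,
                                  n_perm = 250L, s0 = 0.1, seed = 1L) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (!m$logged) stop("expects log2 scale data")
  if (any(is.na(m$intensities))) {
    stop("matrix contains missing values; impute first")
  }
  if (is.null(conditions)) conditions <- unique(m$design$condition)[1:2]
  stopifnot(length(conditions) == 2)
  cols <- m$design$condition %in% conditions
  x <- m$intensities[, cols, drop = FALSE]
  grp1 <- m$design$condition[cols] == conditions[1]
  n1 <- sum(grp1); n2 <- sum(!grp1)
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per condition")

  tstat <- function(g1) {
    x1 <- x[, g1, drop = FALSE]; x2 <- x[, !g1, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
    sp <- sqrt((ss1 + ss2) / (n1 + n2 - 2))
    (m1 - m2) / (s0 + sp * sqrt(1 / n1 + 1 / n2))
  }

  set.seed(seed)
  perms <- label_permutations(ncol(x), n1, n_perm)
  t_obs <- tstat(grp1)
  abs_obs <- abs(t_obs)
  null_abs <- abs(apply(perms, 2, tstat))        # proteins x perms
  if (is.null(dim(null_abs))) null_abs <- matrix(null_abs, nrow = 1)

  # FDR at each candidate cutoff (the observed |t| values, descending)
  ord <- order(abs_obs, decreasing = TRUE)
  cand <- abs_obs[ord]
  fp <- apply(null_abs, 2, function(v) {
    # count of null statistics >= each candidate cutoff
    length(v) - findInterval(cand, sort(v), left.open = TRUE)
  })
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = length(cand))
  fp_med <- apply(fp, 1, stats::median)
  fdr_at <- fp_med / seq_along(cand)
  ok <- which(fdr_at <= alpha)
  cutoff <- if (length(ok) == 0) Inf else cand[max(ok)]
  significant <- abs_obs >= cutoff

  pool <- sort(as.vector(null_abs))
  npool <- length(pool)
  p <- (1 + npool - findInterval(abs_obs, pool, left.open = TRUE)) / (1 + npool)

  tab <- data.frame(
    protein = rownames(x),
    log2fc = rowMeans(x[, grp1, drop = FALSE]) -
             rowMeans(x[, !grp1, drop = FALSE]),
    t = t_obs,
    p = p,
    significant = significant,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(
    list(table = tab, cutoff = cutoff, conditions = conditions,
         alpha = alpha, n_perm = ncol(perms), s0 = s0, seed = seed),
    class = "diffexpr_result"
  )
}

#' @export
print.diffexpr_result <- function(x, ...) {
  cat("diffexpr:", nrow(x$table), "proteins,",
      sum(x$table$significant), "significant at permutation FDR",
      x$alpha, "(", x$conditions[1], "vs", x$conditions[2], ")\n")
  invisible(x)
}

#' Volcano table of a differential-abundance result
#'
#' @param result A [permutation_fdr_ttest()] result.
#' @param annotations Optional data frame keyed by `protein` to join.
#' @return Data frame sorted by p-value with columns protein, log2fc,
#'   neg_log10_p, significant (plus any annotation columns).
#' @export
volcano_table <- function(result, annotations = NULL) {
  stopifnot(inherits(result, "diffexpr_result"))
  tab <- result$table
  out <- data.frame(
    protein = tab$protein,
    log2fc = tab$log2fc,
    neg_log10_p = -log10(tab$p),
    significant = tab$significant,
    stringsAsFactors = FALSE
  )
  if (!is.null(annotations)) {
    i <- match(out$protein, annotations$protein)
    extra <- annotations[i, setdiff(names(annotations), "protein"),
                         drop = FALSE]
    out <- cbind(out, extra)
  }
  out <- out[order(tab$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
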