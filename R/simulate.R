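# Synthetic-data generators. Every generator is seed-reproducible and
# returns its ground truth in a `truth` attribute (a machine-readable
# sidecar consumed by validation code only, never by the pipeline).

#' Simulation parameters for MS/MS spectra
#'
#' @param ppm_jitter_sd Gaussian m/z perturbation SD in ppm (>= 0).
#' @param n_noise_peaks Number of uniform random noise peaks (>= 0).
#' @param noise_intensity_range Intensity range `c(lo, hi)` of noise peaks.
#' @param base_intensity Base fragment intensity (arbitrary units).
#' @param include_immonium Add the diagnostic immonium peak for methylated
#'   peptides.
#' @param seed Integer seed.
#' @return A list of class `spectrum_sim_params`.
#' @export
spectrum_sim_params <- function(ppm_jitter_sd = 5, n_noise_peaks = 10,
                                noise_intensity_range = c(1, 20),
                                base_intensity = 100,
                                include_immonium = TRUE, seed = 1L) {
  if (ppm_jitter_sd < 0 || n_noise_peaks < 0) {
    stop("ppm_jitter_sd and n_noise_peaks must be non-negative")
  }
  structure(list(ppm_jitter_sd = ppm_jitter_sd,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 noise_intensity_range = noise_intensity_range,
                 base_intensity = base_intensity,
                 include_immonium = isTRUE(include_immonium),
                 seed = as.integer(seed)),
            class = "spectrum_sim_params")
}

#' Simulate an MS/MS spectrum of a peptide
#'
#' Places peaks at all singly charged theoretical b/y fragment m/z with
#' multiplicative log-normal intensity variation and Gaussian ppm jitter on
#' m/z; adds the diagnostic methyl-histidine immonium peak when the peptide
#' carries `methyl_his` (and `include_immonium` is on) and uniform random
#' noise peaks.
#'
#' @param p A [modified_peptide()] (or sequence string).
#' @param params A [spectrum_sim_params()].
#' @param id Spectrum identifier.
#' @return A [spectrum()]; attribute `truth` records the peptide and flags.
#' @export
simulate_msms <- function(p, params = spectrum_sim_params(), id = "sim") {
  p <- as_peptide(p)
  set.seed(params$seed)
  theo <- fragment_ions(p, charges = 1L)
  mz <- theo$mz
  intensity <- params$base_intensity * exp(stats::rnorm(length(mz), 0, 0.3))
  has_methyl <- any(p$mods$mod_name == "methyl_his")
  if (has_methyl && params$include_immonium) {
    mz <- c(mz, immonium_mz("H", "methyl_his"))
    intensity <- c(intensity,
                   0.5 * params$base_intensity * exp(stats::rnorm(1, 0, 0.3)))
  }
  if (params$ppm_jitter_sd > 0) {
    mz <- mz * (1 + stats::rnorm(length(mz), 0, params$ppm_jitter_sd) / 1e6)
  }
  if (params$n_noise_peaks > 0) {
    mz <- c(mz, stats::runif(params$n_noise_peaks, 100, max(theo$mz) + 50))
    intensity <- c(intensity,
                   stats::runif(params$n_noise_peaks,
                                params$noise_intensity_range[1],
                                params$noise_intensity_range[2]))
  }
  s <- spectrum(data.frame(mz = mz, intensity = intensity),
                precursor_mz = mz_of(peptide_neutral_mass(p), 2L),
                precursor_charge = 2L, id = id)
  attr(s, "truth") <- list(sequence = p$sequence, methylated = has_methyl,
                           seed = params$seed)
  s
}

#' Ground truth for a simulated knockout panel
#'
#' @param strain_ids Character vector of strain identifiers.
#' @param causal_strain Strain whose knockout abolishes methylation, or
#'   `NULL` for an all-reference panel.
#' @param expression_lost_strains Strains in which the target protein is not
#'   expressed at all.
#' @param reference_fraction True methylated fraction in unaffected strains
#'   (default 0.95, i.e. methylated form dominates).
#' @return A list of class `panel_truth` with a per-strain `meth_fraction`.
#' @export
panel_truth <- function(strain_ids, causal_strain = NULL,
                        expression_lost_strains = character(),
                        reference_fraction = 0.95) {
  if (!is.null(causal_strain) && !causal_strain %in% strain_ids) {
    stop("causal_strain must be one of strain_ids")
  }
  frac <- stats::setNames(rep(reference_fraction, length(strain_ids)),
                          strain_ids)
  if (!is.null(causal_strain)) frac[causal_strain] <- 0
  structure(list(strain_ids = strain_ids, causal_strain = causal_strain,
                 expression_lost_strains = expression_lost_strains,
                 meth_fraction = frac),
            class = "panel_truth")
}

gaussian_trace <- function(rt, apex, sigma, amplitude, noise_level) {
  y <- amplitude * exp(-(rt - apex)^2 / (2 * sigma^2))
  if (noise_level > 0) y <- y + stats::runif(length(rt), 0, noise_level)
  data.frame(rt = rt, intensity = y)
}

#' Simulate a PRM knockout panel
#'
#' For each strain and each peptide form, generates per-fragment extracted
#' ion chromatograms as Gaussian peaks sharing one retention apex, plus a
#' uniform baseline noise floor. In unaffected strains the methylated form
#' dominates; in the causal knockout the methylated amplitude is zero while
#' the unmethylated form appears well above detection; in expression-lost
#' strains both forms are noise only.
#'
#' @param target Peptide sequence of the monitored N-terminal peptide
#'   (used to derive fragment labels from its y-ion series).
#' @param truth A [panel_truth()].
#' @param total_amplitude Summed peak amplitude across forms (default 1000).
#' @param sigma_rt Chromatographic peak SD in minutes (default 0.1).
#' @param sampling_step Retention time sampling step in minutes
#'   (default 0.02).
#' @param rt_range Retention window `c(lo, hi)` in minutes.
#' @param apex Shared retention apex in minutes.
#' @param n_fragments Number of monitored fragments (default 6).
#' @param noise_level Uniform baseline noise upper bound (default 1).
#' @param seed Integer seed.
#' @return List of [chromatogram_set()] objects (two per strain); attributes
#'   `truth` (the `panel_truth`) and `blanks` (noise-only traces for
#'   deriving a detection threshold).
#' @export
simulate_prm_panel <- function(target = "HTVIVYPGYR", truth,
                               total_amplitude = 1000, sigma_rt = 0.1,
                               sampling_step = 0.02, rt_range = c(0, 4),
                               apex = 2, n_fragments = 6, noise_level = 1,
                               seed = 1L) {
  stopifnot(inherits(truth, "panel_truth"))
  set.seed(seed)
  rt <- seq(rt_range[1], rt_range[2], by = sampling_step)
  n <- nchar(target)
  frag_names <- paste0("y", seq_len(min(n_fragments, n - 1)))
  panel <- list()
  for (st in truth$strain_ids) {
    lost <- st %in% truth$expression_lost_strains
    frac <- truth$meth_fraction[[st]]
    for (form in c("methylated", "unmethylated")) {
      amp_total <- if (lost) 0 else
        total_amplitude * (if (form == "methylated") frac else 1 - frac)
      # split total amplitude over fragments with log-normal variation
      w <- exp(stats::rnorm(length(frag_names), 0, 0.3))
      w <- w / sum(w)
      traces <- stats::setNames(lapply(seq_along(frag_names), function(i) {
        gaussian_trace(rt, apex, sigma_rt, amp_total * w[i], noise_level)
      }), frag_names)
      panel[[length(panel) + 1]] <- chromatogram_set(st, form, traces)
    }
  }
  blanks <- lapply(seq_len(20), function(i) {
    gaussian_trace(rt, apex, sigma_rt, 0, noise_level)
  })
  attr(panel, "truth") <- truth
  attr(panel, "blanks") <- blanks
  panel
}

#' Simulate paired MS1 isotope areas at a known methylated fraction
#'
#' Areas of the first three isotopologues of the methylated and unmethylated
#' precursor, proportional to `meth_fraction` (resp. `1 - meth_fraction`)
#' times the isotope envelope of each form, with multiplicative log-normal
#' noise of the given coefficient of variation (mean-one noise factors).
#'
#' @param p Peptide sequence (unmodified base sequence with His1).
#' @param meth_fraction True methylated fraction in `[0, 1]`.
#' @param total_area Total summed precursor area (default 1e6).
#' @param area_noise_cv Coefficient of variation of the multiplicative area
#'   noise (default 0.05).
#' @param seed Integer seed.
#' @return A list with `meth` and `unmeth` (each three areas for M, M+1,
#'   M+2); attribute `truth` records the planted fraction.
#' @export
simulate_ms1_pair <- function(p, meth_fraction, total_area = 1e6,
                              area_noise_cv = 0.05, seed = 1L) {
  if (meth_fraction < 0 || meth_fraction > 1) {
    stop("meth_fraction must be in [0, 1]")
  }
  seq <- if (inherits(p, "modified_peptide")) p$sequence else p
  meth_pep <- modified_peptide(seq, data.frame(position = 1,
                                               mod_name = "methyl_his"))
  env_m <- isotope_envelope(meth_pep, 3)$relative_abundance
  env_u <- isotope_envelope(seq, 3)$relative_abundance
  set.seed(seed)
  noisy <- function(x) {
    if (area_noise_cv == 0) return(x)
    sdlog <- sqrt(log(1 + area_noise_cv^2))
    x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  out <- list(
    meth = noisy(total_area * meth_fraction * env_m / sum(env_m)),
    unmeth = noisy(total_area * (1 - meth_fraction) * env_u / sum(env_u))
  )
  attr(out, "truth") <- list(meth_fraction = meth_fraction, seed = seed)
  out
}

#' Simulate a two-condition protein abundance matrix
#'
#' Log-normal intensities (normal on the log2 scale) with protein-specific
#' baselines, a planted log2 effect on an upregulated set in the
#' cellulose-like (first) condition, and left-censored missingness: within
#' each sample, values below that sample's `censor_quantile` quantile are
#' set missing, so missingness concentrates in the low-intensity tail.
#'
#' @param n_proteins Number of proteins.
#' @param conditions Two condition names; the first receives the planted
#'   upregulation (default `c("cellulose", "glucose")`).
#' @param replicates Replicates per condition (>= 2).
#' @param n_upregulated Number of planted upregulated proteins.
#' @param effect_size Planted shift in log2 units (default 2).
#' @param base_mean,protein_sd Mean and SD of protein baseline log2
#'   abundances (defaults 25 and 2, typical of LFQ intensities).
#' @param residual_sd Replicate-to-replicate SD in log2 units (default 0.5).
#' @param censor_quantile Per-sample fraction censored to missing
#'   (default 0.05; 0 disables missingness).
#' @param mtase_fraction Fraction of background proteins additionally
#'   flagged as methyltransferases in the truth annotation (default 0.1).
#' @param seed Integer seed.
#' @return An [abundance_matrix()] (raw scale, `mode = "lfq"`); attribute
#'   `truth` holds `upregulated_set`, `effect_size`, per-protein annotation
#'   flags (`is_mtase`, `acceptor_atom`, `has_yeast_homolog`,
#'   `unique_to_lpmo_fungi`) and the pre-censoring value summary.
#' @export
simulate_abundance_matrix <- function(n_proteins = 1000,
                                      conditions = c("cellulose", "glucose"),
                                      replicates = 4,
                                      n_upregulated = 50,
                                      effect_size = 2,
                                      base_mean = 25, protein_sd = 2,
                                      residual_sd = 0.5,
                                      censor_quantile = 0.05,
                                      mtase_fraction = 0.1,
                                      seed = 1L) {
  if (replicates < 2) stop("at least 2 replicates per condition required")
  stopifnot(length(conditions) == 2, n_upregulated <= n_proteins)
  set.seed(seed)
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  up <- sample(proteins, n_upregulated)
  samples <- paste(rep(conditions, each = replicates),
                   rep(seq_len(replicates), 2), sep = "_")
  design <- data.frame(
    sample = samples,
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), 2),
    stringsAsFactors = FALSE
  )
  mu <- stats::rnorm(n_proteins, base_mean, protein_sd)
  logx <- matrix(stats::rnorm(n_proteins * length(samples), mu, residual_sd),
                 nrow = n_proteins, dimnames = list(proteins, samples))
  logx[proteins %in% up, design$condition == conditions[1]] <-
    logx[proteins %in% up, design$condition == conditions[1]] + effect_size
  censored_values <- numeric(0)
  if (censor_quantile > 0) {
    for (j in seq_along(samples)) {
      thr <- stats::quantile(logx[, j], censor_quantile)
      cens <- logx[, j] < thr
      censored_values <- c(censored_values, logx[cens, j])
      logx[cens, j] <- NA
    }
  }
  intens <- 2^logx
  m <- abundance_matrix(intens, design, mode = "lfq")
  is_mtase <- proteins %in% up |
    stats::runif(n_proteins) < mtase_fraction
  attr(m, "truth") <- list(
    upregulated_set = sort(up),
    effect_size = effect_size,
    annotations = data.frame(
      protein = proteins,
      is_mtase = is_mtase,
      acceptor_atom = sample(c("N", "O", "unknown"), n_proteins, TRUE,
                             prob = c(0.6, 0.2, 0.2)),
      has_yeast_homolog = stats::runif(n_proteins) < 0.3,
      unique_to_lpmo_fungi = stats::runif(n_proteins) < 0.5,
      stringsAsFactors = FALSE
    ),
    censored_value_mean = if (length(censored_values)) mean(censored_values)
                          else NA_real_,
    overall_value_mean = mean(logx, na.rm = TRUE),
    seed = seed
  )
  m
}

#' Simulate a candidate cohort with planted funnel counts
#'
#' Builds a candidate record table whose staged elimination reproduces a
#' chosen count trajectory: `n_mtase` annotated methyltransferases of which
#' `n_identified` are seen in the proteomics data, `n_sig_up` are
#' significantly upregulated, `n_acceptor_o` of those are predicted
#' O-acceptor methyltransferases, `n_homolog` of the survivors have yeast
#' homologs, `n_unique` of the remainder are unique to LPMO-encoding fungi,
#' and `n_manual` extra manually curated candidates (drawn from
#' methyltransferases eliminated before the significance stage) are added
#' at the end. Defaults emulate a 225 -> 120 -> 41 -> 34 -> 28 -> 19 -> +5
#' = 24 trajectory.
#'
#' @param n_background Non-methyltransferase proteins (default 775).
#' @param n_mtase,n_identified,n_sig_up,n_acceptor_o,n_homolog,n_unique,n_manual
#'   Stage counts as described above.
#' @param seed Integer seed.
#' @return A candidate record data frame (see [validate_candidates()]);
#'   attribute `truth` records the planted stage counts.
#' @export
simulate_funnel_cohort <- function(n_background = 775, n_mtase = 225,
                                   n_identified = 120, n_sig_up = 41,
                                   n_acceptor_o = 7, n_homolog = 6,
                                   n_unique = 19, n_manual = 5, seed = 1L) {
  stopifnot(n_identified <= n_mtase, n_sig_up <= n_identified,
            n_acceptor_o + n_homolog <= n_sig_up,
            n_unique <= n_sig_up - n_acceptor_o - n_homolog)
  set.seed(seed)
  n_total <- n_background + n_mtase
  proteins <- sprintf("C%04d", seq_len(n_total))
  rec <- data.frame(
    protein = proteins,
    is_mtase = c(rep(TRUE, n_mtase), rep(FALSE, n_background)),
    identified = FALSE, significant_up = FALSE,
    acceptor_atom = "N", has_yeast_homolog = FALSE,
    unique_to_lpmo_fungi = FALSE, manual_add = FALSE,
    stringsAsFactors = FALSE
  )
  mt <- which(rec$is_mtase)
  ident <- mt[seq_len(n_identified)]
  rec$identified[ident] <- TRUE
  # background proteins are mostly identified too
  bg <- which(!rec$is_mtase)
  rec$identified[sample(bg, round(0.6 * length(bg)))] <- TRUE
  sig <- ident[seq_len(n_sig_up)]
  rec$significant_up[sig] <- TRUE
  accO <- sig[seq_len(n_acceptor_o)]
  rec$acceptor_atom[accO] <- "O"
  after4 <- setdiff(sig, accO)
  hom <- after4[seq_len(n_homolog)]
  rec$has_yeast_homolog[hom] <- TRUE
  after5 <- setdiff(after4, hom)
  uniq <- after5[seq_len(n_unique)]
  rec$unique_to_lpmo_fungi[uniq] <- TRUE
  # manual additions: curated methyltransferases without yeast homologs that
  # fell out before the significance stage
  pool <- setdiff(mt, ident)
  manual <- pool[seq_len(n_manual)]
  rec$manual_add[manual] <- TRUE
  attr(rec, "truth") <- list(
    counts = c(mtase = n_mtase, identified = n_identified,
               significant_up = n_sig_up,
               after_acceptor = n_sig_up - n_acceptor_o,
               after_homolog = n_sig_up - n_acceptor_o - n_homolog,
               unique = n_unique, shortlist = n_unique + n_manual),
    shortlist = sort(proteins[c(uniq, manual)]),
    seed = seed
  )
  rec
}
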