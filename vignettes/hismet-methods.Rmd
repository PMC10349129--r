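---
title: "Methods: detecting and quantifying N-terminal histidine methylation"
author: "hismet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying N-terminal histidine methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hismet)
```

## Overview

Secreted lytic polysaccharide monooxygenases (LPMOs) coordinate their
catalytic copper through histidine 1, the residue exposed after
signal-peptide cleavage. In filamentous fungi this His1 is methylated on an
imidazole nitrogen. `hismet` implements the computational chain by which
such a modification is detected, localized, quantified and traced back to
its methyltransferase: peptide mass arithmetic, spectrum matching with a
diagnostic immonium ion, parallel-reaction-monitoring (PRM) quantification
with a knockout-screen decision rule, MS1-based stoichiometry, a
permutation-FDR differential-abundance workflow, and a staged candidate
funnel. A synthetic-data module generates all inputs with recorded ground
truth, so each stage is validated against planted truth rather than against
irreproducible raw data.

## Mass arithmetic

All masses derive from one table of standard monoisotopic atomic masses
(`atomic_masses()`); no other constant is defined anywhere in the package.
Residues are mapped to elemental compositions, a peptide's neutral mass is
the residue sum plus water plus modification deltas, and m/z is
`(M + z·proton)/z`.

Histidine methylation is modeled as a single mass delta,
`methyl_his = m(C) + 2·m(H) = 14.01565 Da`, computed from the atomic table
at call time. τ- (Nε2) and π- (Nδ1) methylation are isobaric; the package
makes no claim about which nitrogen carries the methyl group, because mass
spectrometry cannot distinguish them by mass alone.

The diagnostic marker of methylated histidine is its immonium ion, modeled
as the standard a1-type fragment: residue mass − CO + proton (+ the methyl
delta), which evaluates to m/z 124.0869 at four decimals. Coordinates are
1-based throughout, matching the His1 nomenclature.

Fragment generation covers the complete singly-and-higher charged b and y
series (no a/c/x/z ions, no neutral losses). A modification delta is
carried by every fragment whose covered subsequence includes the modified
position; hence an N-terminal methyl shifts all b ions and no y ion, the
key asymmetry the localization module exploits. The b/y complementarity
identity `mz(b_i, 1+) + mz(y_{n−i}, 1+) = M + 2·proton` is enforced by
property tests to 1e-6 Da.

Digestion implements Trypsin/P (cleavage C-terminal to K/R, *including*
before proline, per the "/P" convention) and LysC (after K only), with all
peptides up to a configurable number of missed cleavages. Isotope envelopes
are computed by polynomial expansion of per-element isotope distributions,
aggregated by neutron-number offset and truncated after the requested
number of peaks; since each element's distribution sums to one, the
returned abundances are on the scale of the full distribution and sum to at
most one. The truncated exponentiation-by-squaring is exact for the
retained offsets because convolution only moves mass to higher offsets.

Signal-peptide cleavage positions are *inputs* (e.g. SignalP predictions
supplied alongside the FASTA); the package only applies the trim.

## MS/MS localization

`match_spectrum()` assigns each theoretical ion to its nearest observed
peak and accepts the match within a relative tolerance (default 20 ppm,
the conventional Orbitrap fragment setting). One observed peak may satisfy
several isobaric theoretical ions — genuinely coincident fragments (e.g.
b3 = y2 of HTVIVYPGYR to within a ppm) are a property of the peptide, not a
bug, and the brute-force all-pairs oracle in the tests treats them the same
way. The score is the matched-ion fraction in [0, 1]. This deliberately
replaces probabilistic search-engine scoring: the scientific argument for
localization rests on fragment coverage plus the diagnostic ion, both of
which the simple score captures in a directly testable way.

`localize_nterm_methyl()` scores both His1 hypotheses. The winner must
exceed the loser by a margin (default 0.1 on the matched-ion-fraction
scale, i.e. about two fragments for a 10-mer — small enough to tolerate a
few noise-obscured fragments, large enough that the ~0.5-score wrong
hypothesis never wins), and a methylated call additionally requires the
diagnostic immonium ion within its own ppm window. The diagnostic
requirement is a policy flag (default on): the ion assists localization
rather than defining it, and turning the flag off reproduces the
coverage-only behaviour. Any matched diagnostic peak above zero intensity
counts as present; no intensity threshold is imposed, since the simulated
and real spectra differ too much in intensity scale for a fixed cutoff to
be meaningful.

Only singly charged fragments are matched by default (configurable); the
synthetic spectra place 1+ fragments, which keeps the matching oracle
simple. In targeted acquisition two precursor charge states per peptide are
typically monitored; the PRM module abstracts over charge because its
quantity is the summed fragment area, which is charge-agnostic once traces
are extracted.

## PRM quantification and the knockout decision rule

Traces are integrated trapezoidally after subtracting the per-trace
minimum — the simplest shift-invariant baseline; a target's abundance is
the sum of its fragment areas. Detection needs an explicit threshold where
manual practice says "unambiguous observation": the default is five times
the median integrated area of blank (noise-only) traces, scaled by the
number of fragments summed, so that the threshold and the statistic live on
the same scale. The factor 5 sits comfortably between the noise floor and
the faint residual signal of an off-target form in the simulations, and is
configurable.

The decision rule is a total function on the two detection flags:
methylated detected → `not_nhmt` (the knockout did not abolish
methylation); methylated lost and unmethylated observed → `nhmt_hit`;
neither → `inconclusive` (the target protein itself may not be expressed).
Requiring the *appearance of the unmethylated form*, not merely the loss of
the methylated one, is what distinguishes a methyltransferase knockout from
loss of the substrate protein. Retention-time alignment across strains is
not performed; simulated traces share an apex, and real PRM exports are
expected to be pre-aligned by the acquisition software.

## Stoichiometry

The methylated fraction is `Σmeth / (Σmeth + Σunmeth)` over the summed
areas of the first three isotopologues (M, M+1, M+2) of one charge state —
the three dominant peaks for tryptic peptides. The fraction is invariant to
common scaling, monotone in the methylated sum, and undefined (flagged)
when both sums are zero. Replicates are computed per sample and then
averaged (mean ± sample SD), the convention for biological triplicates;
pooling areas before dividing would weight replicates by their total
signal. No envelope-overlap deconvolution is applied: the two forms differ
by the full methyl mass, far beyond the three-isotope window at the
peptide level.

## Differential abundance

The workflow mirrors the standard label-free/TMT pipeline:

* **Filtering** — keep proteins observed in ≥ 2 replicates of at least one
  condition (idempotent, order-preserving).
* **Quantile normalization** (TMT reporter intensities) — every column is
  forced to the per-rank row-mean distribution, ties averaged; delegated to
  `limma::normalizeQuantiles`.
* **log2 transform** — missing stays missing; non-positive values are
  rejected naming the offending cell.
* **Left-censored imputation** — missing values are drawn per sample from
  `Normal(mean − 1.8·SD, 0.3·SD)`, the downshifted-normal model with the
  conventional width 0.3 and downshift 1.8 in units of the sample SD of
  the *observed* values. This encodes the mechanism of missingness: values
  are absent because they fell below detection, so they are imputed into
  the low tail. Observed cells are never altered, and draws are
  seed-reproducible.
* **Test** — per protein, a two-sided equal-variance Student t statistic
  with a small constant `s0` added to the pooled standard error (SAM-style
  variance stabilization; default 0.1 on the log2 scale, configurable, 0
  recovers the textbook t for oracle checks). Equal-variance rather than
  Welch matches the conventional implementation of this workflow.
* **Permutation FDR** — the null distribution comes from condition-label
  permutations: all distinct assignments when there are no more than
  `n_perm` (e.g. all 70 for a 4-vs-4 design), otherwise `n_perm` sampled
  without replacement; fewer than 10 distinct assignments triggers a
  warning and exhaustive enumeration. Candidate cutoffs are the observed
  |t| values in decreasing order; the estimated FDR at a cutoff is the
  *median* permutation count of null statistics at or above it (median
  rather than mean, so tests are deterministic and outlier permutations do
  not inflate the estimate) divided by the observed count. The chosen
  threshold is the most inclusive cutoff whose estimate stays ≤ α; when no
  cutoff qualifies, nothing is significant. Reported p-values are pooled
  permutation p-values with the +1 correction, consistent with the null
  the FDR uses.

## Candidate funnel

The funnel formalizes staged shortlisting: (1) keep annotation-flagged
methyltransferases (case-insensitive keyword match over annotation terms;
the default ruleset — "methyltransferase", "SAM", "S-adenosyl" — ships as
an editable text config); (2) keep proteins identified in the proteomics
data; (3) keep those significantly *up* in the cellulose-like condition
(significance and positive fold change, attached from the volcano table);
(4) drop predicted O-acceptor methyltransferases, retaining "unknown"
acceptors since only positive O predictions are evidence against
N-methylation; (5) drop proteins with homologs in *S. cerevisiae* or
*K. phaffii*, hosts that cannot perform the modification; (6) keep those
unique to LPMO-encoding fungi; (7) add manually curated extras. The
acceptor-atom, homology and uniqueness calls are input flags: they derive
from external annotation, BLAST and phylogenetic resources, and computing
them is out of scope — keeping them as inputs keeps the funnel honest about
provenance. The report satisfies a chain rule (each stage's output count is
the next stage's input count; counts are non-increasing except at the
manual-addition stage), and the shortlist is order-independent of the input
record order.

## What the generators emulate — and what they do not

* `simulate_msms()` places peaks at all 1+ b/y m/z with log-normal
  intensity variation and Gaussian ppm jitter, adds the diagnostic immonium
  peak for methylated peptides and uniform noise peaks. Defaults (5 ppm
  jitter, 10 noise peaks, base intensity 100) represent a clean Orbitrap
  MS2 of an abundant peptide. It does not simulate chimeric spectra,
  multiply charged fragments, neutral losses or intensity models of
  fragmentation chemistry — so passing localization tests demonstrates the
  decision logic, not robustness to co-isolation.
* `simulate_prm_panel()` uses Gaussian peaks in retention time with a
  shared apex (the simplest shape with a closed-form area,
  `A·σ·√(2π)`, used as the integration oracle), log-normal amplitude
  variation across fragments, and a uniform baseline noise floor.
  Unaffected strains carry a 0.95 methylated fraction, the causal knockout
  0 with the unmethylated form well above detection, expression-lost
  strains noise only. Real chromatography adds tailing, interference and
  retention drift that the generator does not model.
* `simulate_ms1_pair()` distributes a total precursor area over the first
  three isotopologues of each form proportionally to the computed envelope
  and the planted fraction, with mean-one log-normal noise at a chosen CV
  (default 5%, a typical area-reproducibility figure for replicate PRM
  quantification).
* `simulate_abundance_matrix()` draws protein baselines at log2 ≈ 25 ± 2
  with replicate noise SD 0.5 — magnitudes typical of LFQ intensity tables
  — plants a +2 log2 effect on an upregulated set in the cellulose-like
  condition, and censors each sample below its 5% quantile, making
  missingness intensity-dependent by construction. It does not model
  protein-correlated effects, batch structure or shared-peptide inference.

Every generator is bit-reproducible under its seed and attaches its ground
truth as an attribute consumed only by validation code, never by the
pipeline.

## Numerical and testing choices

Simulation sizes in the test suite are chosen to give stable Monte-Carlo
estimates at interactive runtimes: 200 spectra for localization accuracy,
50 panels of 22 strains for screen recall, 100 seeds per point on the
stoichiometry grid {0, 0.15, 0.30, 0.5, 1}, 20 seeds of a 1000-protein
4-vs-4 null for FDR control, and 1e5 draws for the imputation moment
check. Oracles are independent implementations frozen in the test helpers:
literature residue masses for mass summation, exhaustive substring
enumeration for digestion, direct polynomial convolution for isotope
envelopes, the closed-form Gaussian integral for areas, a quadratic
all-pairs matcher for spectrum matching, and a hand-computed t statistic.

Degenerate inputs are rejected loudly rather than coerced: empty
sequences, out-of-range modification positions, illegal residue/mod
combinations, unsorted spectra, non-increasing retention grids,
non-positive intensities before log transform, samples with fewer than two
observed values at imputation, and mismatched strains at the decision step.

## Known limitations

The package does not perform database search, target-decoy PSM FDR, other
variable modifications (oxidation, acetylation, phosphorylation,
deamidation), retention-time alignment, isotope-envelope deconvolution,
protein inference, or any of the external-resource computations behind the
funnel's input flags (annotation mining beyond keyword matching, BLAST
homology, phylogenetic uniqueness). Stoichiometry assumes equal ionization
efficiency of the methylated and unmethylated forms; a systematic
ionization bias would shift the estimated fraction and cannot be detected
from the areas alone.
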