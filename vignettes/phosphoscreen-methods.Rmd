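---
title: "Methods: differential phosphoproteomics, KSEA and biomarker confirmation"
author: "phosphoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential phosphoproteomics, KSEA and biomarker confirmation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoscreen)
```

## The scientific problem

In neoadjuvant breast-cancer therapy, a subset of patients achieves a
pathologic complete response (pCR) to taxane-based chemotherapy while the
rest retain residual disease. `phosphoscreen` implements a
discovery-to-confirmation pipeline for phosphoproteomic response
biomarkers around four statistical stages:

1. **Differential phosphopeptide analysis** — per-peptide comparison of
   spectral intensities between responders (pCR) and nonresponders.
2. **Kinase-set enrichment analysis (KSEA)** — a GSEA-style running-sum
   statistic over peptides grouped by kinase-recognition motifs, exposing
   differentially active kinases.
3. **IHC biomarker confirmation** — H-score quantification of candidate
   markers, upper-quartile dichotomization, and chi-square association
   with pCR under Bonferroni control.
4. **Pull-down interactor enrichment** — bait-versus-IgG quantitative
   comparison of affinity-purified complexes with a median-of-ratio
   normalization and a psm-floor candidate filter.

A seeded synthetic-data module generates inputs with known planted
structure for each stage, so the whole pipeline is testable end to end
without access to any patient-level data.

## Data model

Intensities are nonnegative spectral intensities with an exact `0`
meaning *not detected*. No `NA` state exists: the downstream zero-to-one
substitution rule presupposes zeros, and keeping a single missing-value
convention avoids silent divergence between stages. Phosphosites carry a
15-residue sequence window (site centred, `_`-padded at protein termini)
and a phosphoacceptor in `{S, T, Y}`; site positions are 1-based protein
coordinates. Windows of 15 residues cover every linear motif constraint
the matcher accepts (offsets −7..+7), which is wider than typical
kinase-recognition motifs.

## Differential stage

The pooled intensity distribution is gated once with the Shapiro–Wilk
test (at most 5000 values; larger matrices are subsampled under a named
seed substream). Phosphoproteomic intensity distributions are
heavy-tailed and fail the gate in practice, selecting the nonparametric
branch; the gate decision is recorded on the fitted object.

Per peptide:

* **Medians and fold change.** Group medians are computed on raw
  intensities, zeros included as observations. Only for the ratio, a
  median of 0 is replaced by 1, so a peptide undetected in one group
  appears at \(x = \pm\log_2(\text{median of the detecting group})\) —
  the lateral clouds of the volcano plot. A change of one intensity unit
  is negligible against the \(2^{10}\)–\(2^{20}\) range of detected
  intensities, so the substituted ratio keeps its meaning. Inside the
  rank test, zeros are *retained* (they tie at the bottom ranks); the
  substitution affects the ratio only.
* **Permutation Mann–Whitney–Wilcoxon.** The two-sided statistic is
  \(|W - E[W]|\) with midrank ties, calibrated by Monte-Carlo label
  permutation (default 100,000 permutations, so p-values resolve to five
  decimals) with the add-one estimator
  \(p = (1 + \#\text{extreme}) / (n_{\text{perm}} + 1)\), which never
  returns 0. `mww_exact_p()` provides the exhaustive-enumeration
  counterpart used as an oracle in the test suite. Across a matrix, one
  shared seeded permutation stream drives all peptides through a
  rank-matrix product; the permutation set is ancillary to each
  peptide's data, so marginal p-values are unaffected, and the shared
  stream keeps the computation tractable.
* **FDR and hits.** Benjamini–Hochberg q-values (via `p.adjust`)
  preserve input order. Hits require, with strict inequalities,
  \(|\log_2 FC| > 4\) (16-fold), raw \(p < 10^{-2.5}\), and
  \(q < 0.25\). Per-arm analyses are the same code path under a sample
  filter.

## KSEA stage

Peptides are ranked by the pooled-variance two-sample t statistic of
responders minus nonresponders on \(\log_2(x + 1)\) (the transform is a
switch, `log_transform = FALSE`, for sensitivity analysis; the +1 offset
keeps zeros finite). Zero-variance peptides get \(t = 0\); all ties are
broken lexicographically by peptide id so rankings are deterministic.

Kinase sets are built purely from motif matching and enter the analysis
only at sizes >5 and <1000. The enrichment statistic is the *classic*
(unweighted) running sum: \(+1/n_{hit}\) at members, \(-1/(N - n_{hit})\)
at non-members, score = signed extreme. Internally the running sum is
held as an integer numerator over the common denominator
\(n_{hit}(N - n_{hit})\), so scores are exact in floating point and a
positive sign is preferred on an exact \(\pm\) tie.

Calibration permutes phenotype labels with full re-ranking (set-label
permutation is available as an option); when the number of distinct
relabelings is at most `n_perm`, they are enumerated exhaustively.
Normalization follows the familiar enrichment-framework conventions,
which the per-kinase outputs (NES, FDR) are named after: NES divides the
observed score by the mean magnitude of same-sign permutation scores of
the same set; the permutation p is the add-one same-sign tail fraction;
the FDR q is the ratio of pooled-null to observed tail fractions at the
set's NES, clipped to \([0, 1]\). Significance defaults to
\(q < 0.20\).

## IHC stage

The H-score is \(((\%high \times 3) + (\%med \times 2) + (\%low \times
1))/100 \in [0, 3]\). Dichotomization uses the cohort's 75th percentile
(linear-interpolation quantile, `type = 7`); values exactly at the
cutoff are *Low*, since only scores *above* the percentile count as
High. The association test reports both the risk ratio of pCR
proportions and the cross-product odds ratio — a deliberate double
report, because a "k-fold higher chance" phrasing does not determine
which measure is meant; the risk ratio is treated as the headline
column. The chi-square is Pearson's without continuity correction
(df = 1); zero cells in the odds-ratio cross-product get the
Haldane–Anscombe 0.5 correction and are flagged. Bonferroni defaults to
m = 5 comparisons per confirmation set; the adjusted p is called
significant below 0.01 and borderline between 0.01 and 0.1.

## Pull-down stage

After the 0 → 1 psm substitution (idempotent; detection flags always
refer to the pre-substitution data), each bait/control replicate pair is
normalized by the median of the protein-wise bait/IgG ratios, scaling
bait intensities so the post-normalization median ratio is exactly 1.
Scatter coordinates are \(x = \log_2\) of the ratio of
replicate-averaged intensities and \(y = \log_{10}\) of their sum.
"Average ratio" is the ratio of replicate means, not the mean of
per-replicate ratios — deterministic and robust to single-replicate
dropouts. The candidate rule is parsed as *(evidence) and (abundance)*:
(x above the log2 threshold **or** absent from every IgG replicate)
**and** (total bait psm ≥ 3 **or** ≥ 1 psm in every replicate). The
abundance clause applies to both evidence branches: a 1-psm protein
absent from IgG is noise, not a candidate.

## Synthetic-data generators

The generators define the study conditions under which the pipeline is
validated:

* **Phospho matrices.** Per-peptide baselines \(\log_2\)-normal around
  15 (sd 2) with within-group sd 1, matching the \(2^{10}\)–\(2^{20}\)
  intensity range of label-free phosphoproteomics; detection dropout
  with probability \(\max(0, 0.8 - 0.05 \cdot \log_2 x)\), i.e. ~5% at
  the mean and rising steeply for dim signals
  (missing-not-at-random); optional group-exclusive peptides and
  planted kinase effects added to responders' substrates. Kinase
  substrate sets are disjoint by construction: each kinase owns a unique
  two-residue anchor at offsets −3/−2 drawn from 17 letters, while
  non-substrates carry reserved letters (A, C, G) there, so truth
  checking is unambiguous. The emitted motif library is consistent with
  the assignment by construction.
* **IHC cohorts.** Latent multivariate-normal patient scores with
  configurable inter-marker correlation (default 0.8), mapped
  monotonically to staining fractions so H-scores are continuous in
  \([0, 3]\); pCR is Bernoulli at the configured upper-quartile and
  below-quartile rates of the first (driver) marker.
* **Pull-down tables.** Shared per-protein baselines (log2 sd 2) with
  replicate noise of 0.35 log2 units; planted interactors add their
  enrichment to bait; an optional subset is absent from IgG.

What the generators deliberately do **not** emulate: peptide-to-spectrum
matching artifacts, retention-time structure, batch effects, correlated
peptides within a protein, or cohort covariates. Passing tests therefore
demonstrate the correctness and calibration of the statistics under the
stated model, not robustness to every artifact of real acquisitions.

One global integer seed fans out to named substreams
(`substream_seed(seed, name)`) per generator and per permutation stream,
so adding a stage never shifts the random numbers of another, and every
stage is independently reproducible.

## Numerical and design choices

* Enrichment scores use exact integer numerators (above); the test
  oracle recomputes them by brute-force cumulative sum with identical
  tie convention, and an independent cross-check against the unweighted
  statistic of the `fgsea` package guards the convention itself.
* The Monte-Carlo MWW test deliberately does **not** fall back to
  exhaustive enumeration (only `ksea()` does): keeping the sampled and
  exact estimators separate is what makes their agreement a meaningful
  oracle test at small n.
* Degenerate inputs: constant vectors are rejected by the normality
  gate; all-tied rank tests return p = 1; zero-variance peptides rank
  at t = 0; single-protein tables skip normalization with a warning;
  empty combined-marker strata are reported as such, not as errors.
* Validation sizes, chosen once as the conditions of the calibration
  experiments: null calibration uses 2000 peptides in a 20-vs-20 cohort
  with 250 kinase sets of size 8 (differential p-values at 10,000
  permutations — resolution 1e-4 is ample for a 0.05 band — and KSEA at
  its default 1000); planted-kinase recovery uses 50 sets of 30
  substrates with a +2 log2 effect over 20 seeded replicates; pull-down
  precision uses 50 planted interactors (log2 enrichment 3–6, ten of
  them IgG-absent) among 950 background proteins; the IHC recovery
  cohort has 400 patients at pCR rates 0.90/0.30.

## Known limitations

* Kinase-set membership gives every peptide full weight in every
  matching set; peptides matching several kinases are not down-weighted.
* The parametric branch of the normality gate is a recorded decision
  only; the comparison itself is always the rank test, which is the
  appropriate branch for intensity data and the only one the pipeline
  implements.
* The IHC stage implements univariate confirmation only — no
  multivariable models, survival endpoints, or image analysis.
* Cross-cell-line fold changes compare replicate-averaged bait
  intensities; with single replicates and proteins near the detection
  floor they inherit the full substitution coarseness.
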