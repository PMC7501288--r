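---
title: "Absolute multi-omics quantification: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute multi-omics quantification: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(absomics)
```

## Why absolute units

Relative omics — RPKM for transcripts, LFQ intensity for proteins — can
rank features within a layer but cannot answer questions that compare
layers or samples: how many protein molecules exist per transcript, or
whether the whole transcriptome grew between two time points. This
package implements the two anchoring strategies that make the layers
commensurable in molecules per sample, plus the integration and dynamics
analyses built on top of them.

## The transcript layer

An in-vitro transcript of known length `I_Nt` is added at a known dose
`I_M` molecules to a fixed aliquot of the sample before RNA extraction.
The central assumption is that sequencing read yield is proportional to
the nucleotide mass of the starting material, so within a sample

$$\frac{\sum T_{Nt}}{\sum T_R} = \frac{I_M \cdot I_{Nt}}{I_R},$$

which gives the total transcriptome size $\sum T_{Nt} = I_M \cdot I_{Nt}
\cdot \sum T_R / I_R$ (nucleotides). RPKM is itself a nucleotide-mass
fraction per kilobase, so molecules follow as $T_M = (\mathrm{RPKM}/10^9)
\cdot \sum T_{Nt}$. Two consequences shape the implementation:

* the RPKM denominator must count only transcriptome-mapped reads
  (spike-in and rRNA excluded), or the inversion double-counts the
  standard;
* the identity $\sum_i T_{M,i} \cdot L_i = \sum T_{Nt}$ holds *exactly*
  whenever RPKM and the transcriptome size come from the same read
  table. This conservation law is asserted in the tests to $10^{-9}$
  relative tolerance and is the fastest way to detect a broken
  normalization.

Counts are finally multiplied by the aliquot factor (default 10: a 6 ml
aliquot of a 60 ml sample) to refer to the whole sample. `I_R = 0` is an
explicit error, not a zero: without spike-in reads the sample carries no
absolute anchor.

## The protein layer

The total protein approach distributes a measured total protein mass over
proteins according to their LFQ share, converts to moles through the
molecular weight, and to molecules through Avogadro's number. The total
mass comes from a Bradford assay (concentration × sample volume). The
assumption that the quantified proteins account for all of that mass
fails in a community — the reference catalog is incomplete and many MS
peaks go unidentified — so the total mass is first corrected to a
*detected* mass by the intensity-weighted mass share of identified peaks:

$$\mathrm{Detected\ mass} = \mathrm{Total\ mass} \times
\frac{\sum_{i \in \mathrm{identified}} \mathrm{BPI}_i \cdot m_i}
     {\sum_{j \in \mathrm{all}} \mathrm{BPI}_j \cdot m_j}.$$

The corresponding closure, $\sum_i \mathrm{copies}_i \cdot
\mathrm{MW}_i / N_A = \mathrm{Detected\ mass}$, is asserted in the tests.
Molecular weights use average (not monoisotopic) residue masses plus one
water, because the method operates at whole-protein mass scale; ambiguous
residues B/Z take the mean of their candidate masses and X a generic
110 Da (policy configurable, `compute_mw(..., ambiguous = "error")`
rejects them). Per-cell normalization is deliberately omitted: the
community is heterogeneous and no cell-count denominator exists.

## Integration choices

The harmonization pipeline runs in a fixed order: unique-hit filter →
log10(x+1) → minimum-expression thresholds → sample screen → singleton
matching. Decisions a user should know about:

* **Thresholds are inclusive** (≥ 10⁵ transcript molecules, ≥ 10⁸
  protein molecules on the log10(x+1) scale). The bound is a minimum, so
  boundary values are kept.
* **Replicate averaging is on the linear scale** by default: the
  quantity of interest is a molecule count, and the arithmetic mean is
  its unbiased summary. A geometric-mean option
  (`log_scale_mean = TRUE`) exists for users who prefer symmetry in log
  space.
* **Thresholds are applied per replicate sample, before averaging** —
  a low-quality replicate is removed rather than diluted into the mean.
* **Outlier screening defaults to a manual list** (`drop_samples =`),
  with a PCA assist: samples whose robust z-distance (median/MAD per
  component) in the first two principal components exceeds
  `pc_sd_cutoff` (default 3) are flagged. The automated rule is
  calibrated on the null — for Gaussian profiles the false-flag rate at
  3 SD is ~1–3 % — but outlier removal is ultimately a judgement call,
  so the manual list always wins and is always honored.
* **Only doubly-singleton ORFs are paired.** An ORF inside a
  multi-member ORF-group in either layer has no unambiguous expression
  value there, so it cannot enter gene-level comparisons.

## Dynamics

Protein-to-RNA ratios are computed per ORF on replicate means and
summarized per MAG (median, quartiles), with a pooled summary over
bacterial MAGs. The monomial model $P = a \cdot R^k$ is fitted as
ordinary least squares of $\log_{10} P$ on $\log_{10} R$; the slope is
the linearity $k$ and the intercept is stored as `a_log10`
($a = 10^{\mathrm{a\_log10}}$ — the multiplicative form's constant and
the log form's intercept are the same object on different scales). Cells
with fewer than 30 matched ORFs are skipped by default: below that the
slope's standard error approaches the effect sizes of interest. The
time course of $k$ is summarized by a degree-3 polynomial (enough
curvature for two bends; no regularization), and prediction outside the
observed time range is refused rather than extrapolated.

Rank preservation across layers uses Kendall τ-b with tie correction
(`stats::cor.test`), with category abundance defined as ORF counts in
the metagenome layer and summed absolute molecules in MT/MP. ORF counts
were chosen for MG because they require no coverage model; a
coverage-weighted variant would be a one-line change in
`ko_category_abundance()`.

## What the simulator emulates — and what it does not

`generate_community()` draws, per MAG: ORF lengths (log-normal, median
~900 nt, consistent nt/aa sequences with aa = nt/3 − 1), per-ORF
transcript copies (log-normal in log10, default mean 8, sd 0.8 — the
multi-order-of-magnitude spread real expression shows), and protein
copies through $P = a \cdot R^k$ with multiplicative log10 noise. When
`true_a_log10` is not given, $a$ is derived per time point from the
MAG's `median_ratio_target` as $\log_{10}a = \log_{10}\mathrm{target} +
(1-k_t)\mu_R$, so the median protein-to-RNA ratio hits the target at
every $k$; defaults put bacteria at 10³ and the archaeon at 10⁴,
reproducing the domain-level ratio contrast. The observation layers then
invert the quantification models: reads are allocated multinomially over
nucleotide mass (ORFs + spike-in) at the aliquot scale, and LFQ is
proportional to protein mass with Bernoulli detection
(`detect_fraction_mp`, default 0.6) and a peak table whose identified
intensity-mass share equals `identified_peak_fraction` (default 0.7)
times the detected mass share.

Two simulator parameters deserve emphasis:

* `count_noise = FALSE` replaces multinomial sampling with exact
  expected read counts. This is what "noiseless" means for a counting
  process, and it is what makes the zero-noise round trip exact to
  machine precision — with sampling on, even a noise-free community
  yields Poisson-scale deviations.
* `identified_peak_fraction < 1` deflates *all* recovered copy numbers
  by that factor, by construction: mass carried by unidentified peaks is
  invisible to the correction. This is a property of the method, not a
  bug in the simulator, and it is why recovered totals sit below truth
  under realistic settings while ratios and fits (which compare within a
  sample) are unaffected.

The simulator does **not** emulate: raw reads or spectra, rRNA
contamination, chimeric assembly, mapping ambiguity beyond exact
duplicates (a `dup_orf_fraction` of identical ORFs, default 5 %, plants
multi-member ORF-groups), protease or extraction bias, or compositional
batch effects. Passing tests therefore demonstrate correctness of the
computations and identifiability under the stated generative model —
not robustness to every artifact of real data.

The spike-in defaults (10¹⁰ molecules, 994 nt) are configurable rather
than authoritative: real experiments should set them from the actual
standard used, and `spike_mass_fraction` can instead target a read-mass
share directly.

## Numerical choices and degenerate inputs

* Zero-variance series make a Pearson correlation undefined; it is
  reported as `NA` and counted, never coerced to ±1.
* Monomial fits require ≥ 3 positive pairs and nonzero RNA variance;
  violations are errors, not silent `NA`s.
* Kendall p-values follow `cor.test`: exact for small untied samples,
  normal approximation with tie correction otherwise.
* ORF-group length (MT) and molecular weight (MP) of a multi-member
  group are member means — members are 100 %-identical sequences, so in
  practice the mean is the common value.
* All tabular I/O is TSV with a `#` comment header (tool version, seed),
  round-tripping 15 significant digits.

## Problem sizes

The test suite and analysis scripts run at desk scale by choice: 2–7
MAGs with 40–500 ORFs, 3–7 time points, 2–3 replicates, read depths of
5×10⁵–2×10⁶. Parameter-recovery checks use 100 independent seeds at
7 MAGs × 500 ORFs; at that size the fitted k per MAG × time cell has an
empirical error well inside ±0.05. These sizes were chosen as the
smallest at which the asymptotic behavior of the estimators is already
visible; all of them scale linearly in ORFs × samples.

## Known limitations

* Probabilistic read/peptide reassignment across ORF-groups (posterior
  abundance estimation) is accepted as input, not recomputed; only
  100 %-identity collapsing is implemented.
* The MG ranking of functional categories is ORF-count based; coverage
  weighting is not implemented.
* Translation/degradation rate modeling (change-point analysis of the
  paired series) is out of scope.
* The detected-mass correction assumes the peak table's identified flags
  are trustworthy; no FDR modeling is performed downstream of them.
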