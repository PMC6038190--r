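---
title: "Methods: piRNA signature analysis with pirsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA signature analysis with pirsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirsig)
```

## What the package computes

PIWI-interacting RNAs (piRNAs) are a class of small RNAs, canonically
24–32 nt long, that silence retrotransposons and are detectable outside the
germline, including in brain tissue and cultured neurons. `pirsig` analyses
small RNA sequencing count data for disease-associated piRNA signatures.
The pipeline has four analysis stages plus a generator:

1. **Reference and annotation.** A piRNA reference (FASTA) is joined with a
   per-sequence element-of-origin annotation (SINE, LINE, LTR, GENIC,
   OTHER, UNKNOWN). Sequence-level QC covers the 5′-uridine bias of primary
   piRNAs, the canonical-length (24–32 nt) fraction — species matching the
   reference but shorter are kept as "piRNA-like" — and a screen for
   snoRNA degradation fragments (a reference sequence counts as
   contaminated only when it is an exact full-length substring of a snoRNA,
   the most conservative reproducible rule; strand-aware or mismatch-
   tolerant screens would only enlarge the flagged set).
2. **Quantification.** Adapter-trimmed reads are assigned to reference
   piRNAs of identical length within one substitution (Hamming distance
   ≤ 1). Insertions/deletions are not considered: for ≤ 32-nt molecules,
   substitution-only matching at equal length is the standard contract.
   Because piRNA catalogs contain near-duplicate sequences, a read may
   match several piRNAs; the default credits every match (`all`), with
   `unique` and `fractional` modes available. Fractional totals are rounded
   half-to-even so count matrices stay integral.
3. **Differential expression.** A self-contained negative-binomial Wald
   stage (details below) with additive covariates, Benjamini–Hochberg
   adjustment, and the deregulation call rule |log2FC| ≥ 0.6 (inclusive)
   with adjusted p < 0.1 (strict).
4. **Signature statistics.** Element-of-origin enrichment of a deregulated
   set against the genome-wide class proportions; positional cytosine
   composition of up-/downregulated sets against all piRNAs (positions
   1–29); the memory fraction (deregulated features already deregulated in
   the parental fibroblast comparison); direction-stratified cross-cohort
   overlaps; and hierarchical clustering of samples over the TOP-N
   deregulated features, scored by the adjusted Rand index against the
   known groups.

## The differential expression model

For feature $i$ and sample $j$ with counts $K_{ij}$,

$$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i), \qquad
  \log \mu_{ij} = x_j^\top \beta_i + \log s_j,$$

with variance $\mu + \alpha\mu^2$, size factors $s_j$ from median-of-ratios
normalisation (the median over all-sample-expressed features of the ratio
of a sample's count to the feature's geometric mean), and a design matrix
holding an intercept, the additive covariates, and last the two-level
contrast (second level vs first; the reported effect is
$\beta_{\text{contrast}}/\log 2$, the log2 fold change). Note that the
median-of-ratios construction fixes only *relative* normalisation:
multiplying one sample's column by $c$ multiplies its factor by $c$
relative to every other sample's, while the absolute factors move by
$c^{(m-1)/m}$ because the geometric-mean reference itself shifts.

**Dispersion** is estimated per feature by the method of moments on
normalised counts, pooled within the contrast levels (so genuine group
differences do not inflate it): $\hat\alpha = (\widehat{var} - \bar m)/\bar
m^2$, combined across levels with $n_\ell - 1$ weights. A mean–dispersion
trend $\alpha(\mu) = a_1/\mu + a_0$ is fitted by robust regression
(`MASS::rlm`) over features with positive raw estimates, and each feature's
estimate is shrunk 50/50 toward the trend on the log scale, floored at
$10^{-8}$. With fewer than 10 usable features the trend is skipped and raw
floored moments are used.

**Testing.** Each feature is fitted by iteratively reweighted least squares
with the dispersion held fixed, and the contrast coefficient is tested with
a two-sided normal Wald test. Because the plug-in dispersion is itself
estimated from the $m - g$ within-level residual degrees of freedom ($m$
samples, $g$ contrast levels), the naive information-matrix standard error
is anti-conservative at study-sized designs; the reported standard error
carries the finite-sample inflation $\sqrt{m/(m-g)}$. This choice was
calibrated by simulation: across ten independent null data sets
(2000 features, 8 vs 8 samples, dispersion 0.1) the raw p < 0.05 rate
averages 0.046 with this factor, against 0.062 uncorrected. Features with
all-zero counts, or whose fit fails to converge within 50 iterations, are
reported `untested` and excluded from the BH adjustment.

The package deliberately omits fold-change shrinkage, independent
filtering, outlier refitting and likelihood-ratio tests: the downstream
call rule is threshold-based on the maximum-likelihood log2FC, and the
validation criteria are simulation-calibrated properties, not numerical
equivalence with any particular implementation. `DESeq2` serves as an
independent cross-check in the test suite (log2FC correlation > 0.98 and
concordant calls on shared thresholds).

The "rlog" used for clustering and top-variable selection is approximated
by $\log_2(\text{count}/s_j + 1)$; only rank structure matters for these
consumers.

## Enrichment, composition and clustering

Element-of-origin enrichment is a per-class one-vs-rest goodness-of-fit
chi-square with 1 df and no continuity correction: with $k$ of $n$ query
features in a class of null proportion $p_0$,

$$\chi^2 = \frac{(k - np_0)^2}{np_0(1-p_0)},$$

with an upper-tail p-value — the conventional reading of a two-sided
chi-square test. The null proportions are treated as fixed (the genome-wide
abundance among all piRNAs analysed), not estimated; classes with $p_0 \in
\{0, 1\}$ are untestable and flagged. Classes are reported per class
without cross-class multiplicity correction (a BH flag exists but defaults
off), mirroring per-class reporting practice. Both the full reference and
any restricted universe are supported through the `universe` argument of
`origin_proportions()`, since "genome-wide" can reasonably mean either all
catalogued piRNAs or all piRNAs detected in a study.

Positional composition profiles are 1-based from the 5′ end; the
denominator at position $k$ counts only sequences of length ≥ $k$, so
profiles of mixed-length sets remain interpretable (the convention is
configurable nowhere — it is the only one that avoids conflating length
and composition). The memory fraction defaults to direction-agnostic
membership ("already deregulated earlier"), with a direction-matched mode
because the stricter reading is also defensible; the matched fraction is
never larger, which the tests assert as an invariant.

Clustering uses $1 - $ Pearson correlation between sample columns over the
selected features, average linkage, a two-cluster cut, and the adjusted
Rand index against the known labels. This dialect is fixed for
reproducibility; a zero-variance sample column is an error that names the
offending sample rather than a silent NA.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, so
every stage is testable without external downloads:

- **Reference:** sequences drawn i.i.d. per position from uniform base
  probabilities, with position 1 = U with probability 0.8 (the 5′U bias;
  the non-U branch draws from A/C/G so the probability is exact); 60% of
  features carry canonical lengths uniform on 24–32 nt, the rest
  piRNA-like lengths on 18–23 nt (disjoint ranges keep the decomposition
  unambiguous in tests); planted upregulated features have cytosine
  probability 0.6 at positions 2–9; planted downregulated features draw
  their origin class with SINE probability 0.5 against 0.2 genome-wide.
- **Counts:** baseline means $2^{N(\log_2 100,\, 1)}$, NB dispersion 0.1,
  per-sample library-size multipliers log-uniform on [0.5, 2], planted
  |log2FC| of 1.5, and (in the disease scenario) per-feature sex effects
  with SD 0.2 so the covariate is worth adjusting for.
- **Scenarios:** `null` (2000 features, 8 vs 8, no effects) for type-I
  calibration; `pd_neuron` (5000 features, 8 vs 8, 4% planted effects, 60%
  down) mirroring a patient-vs-control neuronal comparison at its
  approximate sample scale; `differentiation` (two 8-vs-8 stage contrasts,
  8% planted effects each, sharing exactly 8% of the second stage's
  planted set with matched directions) as ground truth for the memory
  fraction. The sharing is exact by construction: the first stage's free
  planted pool excludes the second stage's non-shared planted features,
  otherwise accidental overlap would inflate the realised sharing well
  above its nominal value.

All randomness flows from one integer seed; reference and count generation
use fixed seed offsets so each step is independently reproducible. Problem
sizes (2000–5000 features, 16 samples) were chosen as the smallest at
which the binomial tolerance bands used in validation are meaningfully
tight.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: mapping ambiguity from genuinely homologous
piRNA families, expression-dependent dispersion trends beyond $a_1/\mu +
a_0$, batch structure, adapter artefacts, and any correlation between a
sequence's composition and its expression. Recovery results on synthetic
data are a correctness check of the machinery, not an effect-size claim
about any cohort.

```{r example}
params <- scenario("pd_neuron", seed = 1)
sr <- simulate_reference(params)
sim <- simulate_counts(sr$reference, params, sr$truth)
de <- nb_wald(sim$counts, sim$sample_sheet, design_spec("group", "sex"))
call <- call_deregulated(de)
c(up = length(call$up), down = length(call$down))

enr <- origin_enrichment(call$down, sr$reference,
                         origin_proportions(sr$reference))
subset(enr, origin_class %in% c("SINE", "LINE"))
```

## Numerical and degenerate-input choices

- IRLS: linear predictor clamped to $[-30, 30]$; convergence at a maximum
  coefficient change below $10^{-4}$ within 50 iterations; singular or
  non-finite information matrices mark the feature `untested`.
- Ties: top-variable and top-DE rankings break ties by feature id
  (lexicographic) after variance / (padj, raw p); this makes every report
  reproducible to the byte.
- Thresholds are inclusive on |log2FC| (a feature at exactly 0.6 is
  called) and strict on the adjusted p (exactly 0.1 is not).
- Reads containing N never match; reference sequences with characters
  outside the nucleotide alphabet, duplicate ids, or lengths outside a
  15–45 nt sanity window are rejected at load time.
- `positional_base_content` marks positions with zero denominator `NaN`
  rather than 0, so plots cannot silently show an absence of sequence as
  an absence of cytosine.

## Known limitations

- The DE stage targets calibration, not equivalence with any specific
  tool; at very small $n$ (< 4 per group) the moment dispersion estimator
  is noisy and the SE correction only partially compensates.
- The enrichment test treats the null proportions as known; if the
  universe is small, the extra variance of estimated proportions is
  ignored.
- The snoRNA screen is exact-substring on the given strand only.
- RPKM uses the mature sequence length as the model length, the only
  sensible unit for small RNAs, but that makes values incomparable with
  locus-based RPKM of mRNA data.
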