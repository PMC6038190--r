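# pirsig

Analysis of disease-associated **piRNA / piRNA-like small RNA signatures**
from small RNA sequencing count data.

PIWI-interacting RNAs (piRNAs) are small RNAs, canonically 24–32 nt, that
silence SINE/LINE/LTR retrotransposons and are detectable in brain tissue
and patient-derived neuronal cultures. In neurodegenerative disease models
built from patient fibroblasts via induced pluripotent stem cells (iPSCs)
to neurons, piRNA expression differences between patient and control lines
carry a characteristic signature: transposon-derived (SINE/LINE) piRNAs
over-represented among the downregulated species, a cytosine excess at
sequence positions 2–9 of the upregulated species, a 5′-uridine bias
confirming bona fide piRNAs, and only a small "memory" fraction of
deregulated piRNAs inherited from the parental fibroblasts. `pirsig` is
aimed at bioinformaticians who want that whole analysis — quantification,
differential expression, and the signature statistics — as tested,
reusable, seedable code.

## What it computes

- **Reference & QC** (`load_reference`, `origin_proportions`,
  `u1_fraction`, `canonical_fraction`, `snorna_overlap`): piRNA FASTA +
  element-of-origin annotation (SINE / LINE / LTR / GENIC / OTHER /
  UNKNOWN); 5′U bias; canonical 24–32 nt fraction; exact-substring snoRNA
  contamination screen.
- **Quantification** (`match_read`, `quantify_sample`,
  `build_count_matrix`, `rpkm`, `marker_content_score`,
  `positional_base_content`): read-to-reference assignment allowing one
  substitution at equal length, with `all` / `unique` / `fractional`
  multi-match handling.
- **Differential expression** (`size_factors`, `estimate_dispersions`,
  `nb_wald`, `bh_adjust`, `call_deregulated`, `top_de`, `top_variable`,
  `top_abundant_de`): negative-binomial Wald tests with additive
  covariates. For feature *i*, sample *j*:

  `K_ij ~ NB(mu_ij, alpha_i)`, `log mu_ij = x_j' beta_i + log s_j`

  with median-of-ratios size factors `s_j`, method-of-moments dispersions
  shrunk toward an `a1/mu + a0` trend, and the deregulation call
  **|log2FC| ≥ 0.6 and BH-adjusted p < 0.1**.
- **Signature statistics** (`origin_enrichment`, `composition_bias`,
  `memory_fraction`, `direction_overlap`, `hcluster`): per-class
  one-vs-rest chi-square enrichment `chi2 = (k − n·p0)² / (n·p0·(1−p0))`
  against genome-wide origin proportions; positional cytosine profiles of
  up/down sets vs all piRNAs; memory fractions across differentiation
  stages; direction-stratified cross-cohort overlaps; TOP-N clustering
  with adjusted Rand index.
- **Synthetic data** (`sim_params`, `scenario`, `simulate_reference`,
  `simulate_counts`, `simulate_differentiation`, `simulate_reads`): a
  fully seeded generator planting all of the above structure, with ground
  truth, so the pipeline is testable end to end.

## Worked example

```r
library(pirsig)

params <- scenario("pd_neuron", seed = 1)      # 5000 piRNAs, 8 CTRL vs 8 PD
sr  <- simulate_reference(params)
sim <- simulate_counts(sr$reference, params, sr$truth)

de   <- nb_wald(sim$counts, sim$sample_sheet, design_spec("group", "sex"))
call <- call_deregulated(de)                   # |log2FC| >= 0.6, padj < 0.1
c(up = length(call$up), down = length(call$down))
#>   up down
#>   86  125

enr <- origin_enrichment(call$down, sr$reference,
                         origin_proportions(sr$reference))
subset(enr, origin_class %in% c("SINE", "LINE"))
#>   origin_class  k   n     p0 expected   chi2         p direction untestable
#> 1         SINE 65 125 0.2038    25.48 77.021 1.692e-18  enriched      FALSE
#> 2         LINE 12 125 0.1526    19.08  3.097 7.845e-02  depleted      FALSE

cb <- composition_bias(call$up, call$down, sr$reference$id, sr$reference)
round(cb$diff_up[2:9], 3)                      # cytosine excess, positions 2-9
#> [1] 0.335 0.312 0.259 0.273 0.302 0.286 0.284 0.430

logm <- log_transform(sim$counts, attr(de, "size_factors"))
hcluster(logm, top_de(de, 100), sim$sample_sheet)$ari
#> [1] 1
```

Reading the output: 211 piRNAs are called deregulated; the downregulated
set is strongly SINE-enriched against the genome-wide share of 20% (65
observed vs 25.5 expected, chi-square p ≈ 2e-18) while LINE here happens
to fall below expectation; the upregulated set carries a 0.26–0.43
cytosine excess at every position 2–9; and hierarchical clustering on the
TOP100 deregulated piRNAs separates patient from control samples perfectly
(adjusted Rand index 1).

A command-line wrapper with `simulate | quantify | de | signature | all`
subcommands is installed at `system.file("cli", "pirsig.R", package =
"pirsig")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pirsig.R",package="pirsig"))')" \
    all --scenario pd_neuron --seed 1 --out-dir run1
```

which writes `de_results.tsv`, `enrichment.tsv`, `composition.tsv`,
`clusters.tsv`, a manifest and a summary; identical config and seed
reproduce identical bytes.

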