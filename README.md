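# cpgflex

Predicting gene body DNA methylation from CpG depletion, and testing how
it relates to gene-expression flexibility.

## Why

Methylated cytosines in CpG context deaminate to thymine at an elevated
rate, so gene bodies that have been heavily methylated in the germline
lose CpG dinucleotides over evolutionary time. In non-model organisms
with only a de novo transcriptome — here, the motivating case is marine
plants under heat stress — the **observed/expected CpG ratio** of each
transcript is a practical proxy for gene body methylation (gbM): low
CpG O/E predicts hypermethylation, high CpG O/E predicts
hypomethylation. A recurring observation across plants and invertebrates
is that weakly methylated genes are the environmentally *flexible* ones,
while heavily methylated genes skew toward housekeeping functions.

`cpgflex` is a tested, reusable implementation of that whole analysis
for R users: sequence profiling, mixture-based gene classification,
functional (GO-slim) enrichment, a simplified differential-expression
stage, the quantile-bin "flexibility" analyses that tie everything
together, and a synthetic-data generator with known truth for every
stage.

## The statistics at the core

Per gene, with `n_cpg` overlapping CG dinucleotides, `n_c` C's, `n_g`
G's and `l` counted bases:

    CpG_O/E = n_cpg / (n_c * n_g) * l^2 / (l - 1)

The per-gene ratios are fitted with 1- and 2-component Gaussian mixtures
(EM, unequal variances, BIC selection). Solving
`lambda1 * N(x | mu1, sigma1) = lambda2 * N(x | mu2, sigma2)` gives the
component-density intersection used as an objective classification
threshold: genes below it form the low-CpG (predicted hypermethylated)
component. Component enrichment per GO-slim term uses Fisher's exact
test against the background of all classified annotated genes, with BH
FDR. Differential expression per contrast runs CPM filtering (≥ 1 CPM in
≥ 3 samples), TMM normalization, method-of-moments NB dispersion with
shrinkage, a conditional exact negative-binomial test and BH correction.
Finally, genes are cut into CpG O/E quantile bins (25 for DEG frequency,
12 for expression magnitude) and the bin statistics are related to
CpG O/E by correlation, ANOVA, Welch t component contrasts and
population slope ratios.

## Worked example

Simulate a small study with known truth and run the chain:

```r
library(cpgflex)

study   <- simulate_study(sim_config(n_genes = 3000, seed = 42))
profile <- profile_transcriptome(study$seqs)

fit1 <- fit_single_gaussian(profile$cpg_oe)
fit2 <- fit_mixture_em(profile$cpg_oe)
select_model(fit1, fit2)$selected_k   # 2: bimodal wins by BIC

thr   <- component_intersection(fit2)
split <- classify_genes(profile, thr)
print(fit2)
print(split)

de <- run_contrast(study$counts, study$design, "origin")
shared <- profile[profile$gene_id %in% de$gene_id, ]
bf <- bin_frequency(quantile_bins(shared, 25), de, threshold = thr)
bf$correlation
```

which prints

```
2-component Gaussian mixture (n = 3,000)
  comp-1: lambda = 0.655, mu = 0.453, sigma = 0.153
  comp-2: lambda = 0.345, mu = 0.701, sigma = 0.224
  loglik = 428.13, BIC = -816.22, converged = TRUE (477 iterations)
component split at CpG O/E threshold 0.6728: 2269 low / 731 high (96.77% CpG-depleted)
frequency correlation: r = 0.847 (N = 25, p = 9.5e-08)
```

Read it as: the CpG O/E distribution is better described by two
Gaussians than one (BIC), their densities cross at 0.67 — the
classification threshold — and the number of differentially expressed
genes per CpG O/E bin rises strongly with the bin's CpG O/E: the genes
predicted to be weakly methylated are the transcriptionally flexible
ones, which is exactly the structure the generator planted.

The same chain runs end to end from one YAML/list config (either a
`simulate` block or `inputs` pointing at FASTA / annotation / counts /
design files), writing per-stage TSVs plus a JSON summary, byte-identical
under a fixed seed:

```r
run_pipeline(list(seed = 7, out_dir = "run1",
                  simulate = list(n_genes = 10000)))
```

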