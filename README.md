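# pcaFE

PCA-based unsupervised feature extraction for two-arm time-course
expression data, with a probe-wise linear-regression baseline, a GEO
series-matrix reader/writer, and a synthetic generator with planted
ground truth.

## What it does, and for whom

Time-course microarray experiments often have too few replicates per time
point (1–4 in the reference design, GEO series GSE6432: IMR90 fibroblasts
in contact with a collagen–glycosaminoglycan mesh vs. ordinary culture)
for probe-wise testing to have power. This package implements the
alternative of borrowing strength across probes through a singular value
decomposition:

1. standardize each sample column of the probes × samples matrix
   (∑ᵢ xᵢⱼ = 0, ∑ᵢ xᵢⱼ² = N);
2. decompose xᵢⱼ = ∑ₗ sₗ uₗᵢ vₗⱼ (probe scores uₗ, sample loadings vₗ);
3. regress every loading vector on time, vₗⱼ = aₗ + bₗ tⱼ, and keep the
   components whose slope is significant after Benjamini–Hochberg
   adjustment (adjusted p < 0.05);
4. score probes on the retained components,
   Pᵢ = P[χ²_d > ∑ₗ (uₗᵢ/σₗ)²], BH-adjust across probes, and select at
   adjusted p < 0.01.

Each arm is analysed separately; a control arm whose expression does not
develop in time yields an empty selection with an explicit status, which is
a result, not an error. `run_linreg_fe()` provides the conventional
comparator (probe-wise OLS of expression on time). The methods vignette
(`vignettes/pca-unsupervised-fe.Rmd`) documents the model, every tunable
parameter, the synthetic world, and a power analysis of the method's
detectability window.

## Worked example

```r
library(pcaFE)
ds  <- generate_synthetic(synthetic_spec(slope_scale = 0.125, seed = 7))
res <- run_pca_fe(ds$treated)
res
#> PCA-based unsupervised feature extraction
#>   components tested: 19; time-associated (BH < 0.05): 2
#>   probes selected (BH < 0.01): 38 of 2000
subset(res$associations, selected)
#>   component  intercept      slope      p_value  adjusted_p selected
#> 2         2 -0.1955524 0.01597463 4.578537e-12 8.69922e-11     TRUE
evaluate_recovery(res$scores$probe_id[res$scores$selected], ds$truth)
#> $recall 0.95;  $precision 1;  $f1 0.9743...
run_pca_fe(ds$control)
#> PCA-based unsupervised feature extraction
#>   components tested: 13; time-associated (BH < 0.05): none
#>   status: no time-associated component; empty probe selection
```

Reading: in the treated arm the second principal component's sample
loadings rise with time (slope 0.016 per hour, BH-adjusted p ≈ 9 × 10⁻¹¹),
and 38 probes score significantly on it — all 38 are planted probes (95% of
the 40 planted recovered, no false positives). The control arm, which has
no planted trend, correctly selects nothing.

With real data: read the series matrix and a sample annotation
(`sample_id`, `condition`, `time_h` TSV), split by condition, and run each
arm — `read_series_matrix()`, `split_by_condition()`, `run_pca_fe()`,
`export_gene_list()`. Expected GSE6432 results are listed in the vignette.

## Command line

```sh
Rscript -e 'pcaFE::fe_main()' simulate --n-probes 2000 --seed 7 --out-dir sim
Rscript -e 'pcaFE::fe_main()' run-pca-fe --matrix sim/treated_series_matrix.txt \
    --annotation sim/annotation.tsv --condition treated --out-dir fe
Rscript -e 'pcaFE::fe_main()' evaluate --selected fe/gene_list.txt \
    --truth sim/truth.tsv --out-dir eval
```

(or the installed wrapper script `system.file("cli", "pca-fe", package = "pcaFE")`).
Subcommands: `run-pca-fe`, `run-linreg-fe`, `simulate`, `evaluate`. Reports
are byte-deterministic given inputs, config and seed; every report header
embeds the thresholds and mode flags; a run manifest (config snapshot,
input digests, outputs, timestamps) is written alongside.

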