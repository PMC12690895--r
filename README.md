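# gemvar

Dissecting **g**enetic and **e**nvironmental contributions to DNA
**m**ethylome **var**iability.

`gemvar` is for epigenomics researchers with matched data from one cohort —
a DNA methylation microarray (M values), genotype dosages, an exposome
table, and concomitant variables (sex, gestational age, cell-type
proportions, ancestry components). It finds the variably methylated loci
(VMLs) of the methylome and classifies each one by the linear model that
best explains its methylation:

| Class | Model |
|-------|------------------------------------------|
| B     | DNAme ~ covars                            |
| G     | DNAme ~ SNP + covars                      |
| E     | DNAme ~ exposure + covars                 |
| G+E   | DNAme ~ SNP + exposure + covars           |
| GxE   | DNAme ~ SNP + exposure + SNP\*exposure + covars |

where DNAme is the per-sample median M value of the locus. The stages:

1. **HVP detection** — per-probe variance of covariate-residualized M
   values; probes above the 90th percentile are highly variable probes.
2. **VML identification** — HVPs < 1 kb apart with adjacent-pair Pearson
   r > 0.15 chain into variably methylated regions (VMRs); isolated HVPs
   with no array probe within 1 kb are kept as sparse VMPs.
3. **cis SNP mapping** — SNPs within 1 Mb of the locus span.
4. **LASSO screening** — per VML, three scenarios (G only, E only, G∪E)
   with unpenalized covariates; nonzero-coefficient variables are pooled.
5. **AIC model competition** — every G/E/G+E/GxE model over the selected
   variables; lowest AIC wins; the winner's R² is decomposed into per-term
   partial R² by the LMG (Lindeman–Merenda–Gold) ordering average, with
   covariates always entered first.
6. **Permutation null filter** — genotype and exposome rows are shuffled
   jointly, the analysis re-run (10×), and winners whose ΔR² over the
   covariates-only baseline falls below the 95th percentile of the
   stratified null (marginal G/E vs joint G+E/GxE) are demoted to B.

A synthetic-data generator with planted B/G/E/G+E/GxE architectures makes
every stage testable without access to cohort data.

## Worked example

```r
library(gemvar)

cfg <- sim_config(n_samples = 300,
                  loci_per_class = c(B = 4, G = 4, E = 4, GE_ADD = 4, GXE = 4),
                  n_exposures = 10, decoy_snps_per_locus = 5)
sim <- simulate_ge_dataset(cfg, seed = 2)
pl  <- run_ge_pipeline(sim$dataset, seed = 2, n_perm = 10)
pl
#> gene-environment methylome pipeline
#>   HVPs: 49 of 490 probes
#>   VML:  20 ( 17 VMR, 3 sVMP )
#>   class proportions:
#>  kind n_vml         B         G         E    GE_ADD       GXE
#>   all    20 0.2000000 0.2000000 0.2000000 0.1500000 0.2500000
#>   VMR    17 0.2352941 0.1176471 0.1764706 0.1764706 0.2941176
#>  sVMP     3 0.0000000 0.6666667 0.3333333 0.0000000 0.0000000

head(pl$results[, c("vml_id", "model_class", "snp_id", "exposure_id", "delta_r2")])
#>                        vml_id model_class         snp_id exposure_id  delta_r2
#> 1   chr1:1000000-1000423(VMR)      GE_ADD rs00001_causal        EE_4 0.4109703
#> 2   chr1:3500000-3500438(VMR)           E           <NA>        EE_4 0.2737016
#> 3   chr1:6000000-6000475(VMR)           B           <NA>        <NA> 0.0000000
#> 4   chr1:8500000-8500372(VMR)      GE_ADD rs00013_causal        EE_8 0.3763800
#> 5 chr1:11000000-11000546(VMR)         GXE rs00017_causal        EE_9 0.5950220
#> 6  chr2:1000000-1000000(sVMP)           E           <NA>        EE_9 0.1888814

evaluate_recovery(pl$results, pl$vml, sim$truth)
#> recovery against planted truth
#>         called
#> truth    B G E GE_ADD GXE
#>   B      4 0 0      0   0
#>   G      0 4 0      0   0
#>   E      0 0 4      0   0
#>   GE_ADD 0 0 0      3   1
#>   GXE    0 0 0      0   4
#> sensitivity:
#>      B      G      E GE_ADD    GXE
#>   1.00   1.00   1.00   0.75   1.00
#> causal-variable recovery: 1
```

Reading the output: 20 of the 20 planted loci were re-identified as VMLs;
`delta_r2` is the winner's R² improvement over the covariates-only
baseline, the quantity thresholded by the permutation filter; the one
additive locus called GxE illustrates the known ~16% chance rate at which
AIC admits a spurious interaction term (its LMG interaction share is near
zero in such cases — see `partial_gxe` in `pl$results`).

Real data enters through `load_dataset()` (TSV matrices with a leading
sample-id column, plus BED-like probe/SNP manifests), or the thin runner at
`inst/scripts/run-pipeline.R` for shell use:

```sh
Rscript inst/scripts/run-pipeline.R --config inputs.yaml --out results/ --seed 1
```

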