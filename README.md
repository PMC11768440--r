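# dustrisk

Health-risk screening and multivariate profiling of heavy-metal concentrations
in urban dust.

Street and settled dust in dense cities carries Ba, Cd, Co, Cr, Cu, Fe, Mn,
Ni, Pb and Zn at concentrations that vary strongly from site to site. Two
questions drive the analysis this package implements, aimed at environmental
health scientists and exposure modellers:

1. **Does the dust pose a non-carcinogenic risk to adults living nearby?**
   For each site and metal the average daily dose (ADD, mg/kg/day) is computed
   for three exposure paths,

   - ingestion: `ADD_ing = c · R_ing · EF · ED / (BW · AT) · 1e-6`
   - inhalation: `ADD_inh = c · R_inh · EF · ED / (PEF · BW · AT)`
   - dermal contact: `ADD_derm = c · SA · SL · ABS · EF · ED / (BW · AT) · 1e-6`

   where `c` is the concentration in mg/kg and the exposure factors carry
   their conventional meanings (see `?exposure_factors`). Each dose is scored
   against a path-specific reference dose, `HQ_path = ADD_path / RfD_path`;
   per-metal hazard quotients sum the three paths, and the site-level hazard
   index `HI = Σ_k HQ_k` flags a potential non-carcinogenic effect when it
   strictly exceeds 1.

2. **Which sites and which metals behave alike?** The same concentration
   matrix is profiled by correlation-matrix PCA with four component-selection
   rules (Kaiser, cumulative variance, AIC/BIC over a profile likelihood, and
   sequential eigenvalue thresholds `exp(-2/n)` / `n^(1/n)`),
   maximum-likelihood factor analysis with oblimin rotation plus a full
   retention battery (parallel analysis, VSS, `BIC = χ² − 2df` /
   `AIC = χ² + 2df`), and a from-scratch t-SNE whose perplexity, learning rate
   and momentum can be tuned by Gaussian-process Bayesian optimization under
   three embedding-quality objectives (KL divergence, silhouette, Sammon
   error). A concordance report then compares the embedding clusters with the
   per-site hazard index.

Because field concentration matrices of this kind are rarely published, the
package ships a synthetic generator (`synthetic_config()`,
`generate_dataset()`) that plants latent metal factors and site clusters on
the log scale, so the entire pipeline is exercisable and testable end to end.

## Worked example

The ingestion hazard quotients for Fe across typical urban sites span
6.10e-5 to 2.57e-4, which corresponds to dust concentrations of 29.89 and
125.93 mg/kg. Pushing those two concentrations through the full chain:

```r
library(dustrisk)
conc <- matrix(fe_reference_concentrations(), ncol = 1,
               dimnames = list(c("Dmin", "Dmax"), "Fe"))
hz <- hazard_quotients(conc)
signif(hz$HQ_path[, "Fe", ], 3)
#>           ing      inh     derm
#> Dmin 0.000061 8.97e-07 0.000774
#> Dmax 0.000257 3.78e-06 0.003260
hazard_index(hz)
#>   site_id           HI risk_flag
#> 1    Dmin 0.0008363198     FALSE
#> 2    Dmax 0.0035235112     FALSE
```

The ingestion column reproduces the published Fe range, the inhalation column
follows independently (ratio `R_inh / (R_ing · PEF · 1e-6) ≈ 1.47e-4`), and
both sites sit far below the `HI > 1` screening threshold.

A full pipeline run on a synthetic 14-site survey:

```r
cfg <- pipeline_config(synthetic = synthetic_config(seed = 1),
                       tsne = tsne_params(max_iter = 300),
                       stages = c("risk", "pca", "fa", "tsne", "cluster"),
                       outdir = "run1", seed = 42)
res <- run_pipeline(cfg)
res$results$pca$selection
#> Component selection:
#>   Kaiser (lambda > 1): 3
#>   cumulative variance >= 80%: 4
#>   AIC argmin: 8; BIC argmin: 8
#>   eigenvalue thresholds: AIC form exp(-2/n)=0.8669 -> 4; BIC form n^(1/n)=1.2074 -> 2
res$results$cluster$concordance
#> Cluster vs hazard-index concordance
#>   cluster n    mean_HI      min_HI     max_HI
#> 1       1 9 0.04197224 0.009868559 0.08037894
#> 2       2 5 0.15074227 0.123784850 0.17733472
#>   ranking by mean HI: 2 > 1
```

Three planted factors surface as three Kaiser components; the embedding
clusters order cleanly by mean hazard index. Every stage writes CSV/JSON
tables (`hazard_hi.csv`, `pca_selection.json`, `fa_loadings.csv`,
`tsne_embedding.csv`, `cluster_quality.json`, `concordance.json`) plus a
`run_manifest.json` with the seed, configuration echo and per-stage wall
times. A thin command-line wrapper lives at `inst/cli/dustrisk.R`.

## Vignette

`vignettes/dust-risk-methods.Rmd` documents the models, the numerical
choices (perplexity bisection, oblimin gradient projection, GP surrogate),
the synthetic generator's design, and known limitations.
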