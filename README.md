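# macrogd

Macrogenetic analysis of barcode-derived mitochondrial genetic diversity.

Global collections of georeferenced DNA barcodes (COI sequences with
BIN/OTU assignments, as served by BOLD) make it possible to map
*intraspecific* genetic variation for thousands of taxa at once — the
"class III" macrogenetic design. `macrogd` is for researchers doing that
kind of analysis on insects or other hyper-diverse groups: it takes a
BOLD-style specimen table, applies the standard quality filters, assigns
specimens to equal-area grid cells, and summarises each cell's assemblage
with two complementary statistics:

- **GDM**, the genetic diversity mean: the average nucleotide diversity
  π (mean per-site pairwise difference) over the OTUs of a cell,
  square-root transformed for analysis;
- **GDE**, the genetic diversity evenness: the first-order Hill number of
  the per-OTU diversities corrected by OTU richness N,

  GDE = exp(−Σᵢ pᵢ ln pᵢ) / N,  pᵢ = πᵢ / Σⱼ πⱼ,

  which is 1 when every OTU is equally diverse and 1/N when a single OTU
  carries all the diversity. High-GDM/low-GDE cells are dominated by a few
  hyper-diverse taxa; high-GDM/high-GDE cells are uniformly diverse.

Around these two metrics the package provides the rest of the workflow:
spatially corrected correlation tests (Dutilleul's modified t-test with
fractional effective degrees of freedom; Moran's I permutation tests), a
Bayesian spatial GLMM (knot-based random field with multivariate-t tails,
regularising slope priors, blocked Gibbs sampling) for environmental
regression and posterior prediction with 95% HDIs, multivariate
environmental similarity (MESS) masking of non-analog environments, and a
coalescent synthetic-data generator that plants known truths — filter
violations, per-OTU θ, environment→diversity slopes — so every stage can be
tested against them. See the methods vignette
(`vignettes/macrogenetic-methods.Rmd`) for the models and design decisions.

## Worked example

Simulate a barcode survey with planted pathologies, run the pipeline, and
fit the environmental model on a cell-level world:

```r
library(macrogd)

world <- inject_pathologies(
  generate_world(world_spec(n_rows = 3, n_cols = 6, otus_per_cell = 30,
                            samples_per_otu = c(3, 6)), seed = 11))
cfg <- pipeline_config(records = world$records, env = world$env,
                       invasive_list = world$truth$pathology$invasive_list,
                       min_otus = 25, seed = 11)
res <- run_pipeline(cfg)
res$filter_report
#>   n_input duplicate_record too_long too_short ungeoreferenced invasive retained
#> 1    2504                0        5         7               4        6     2482
head(res$summaries[, c("cell", "n_otus", "n_individuals", "gdm", "gde")], 4)
#>   cell n_otus n_individuals   gdm   gde
#> 1 r0c0     30           130 0.110 0.711
#> 2 r0c1     30           142 0.128 0.775
#> 3 r0c2     30           141 0.119 0.756
#> 4 r0c3     30           148 0.132 0.705
```

Every injected violation is caught (5 over-length, 7 under-length including
the end-gap-padded fragments, 4 ungeoreferenced, 6 copies of a
two-continent invasive), and each retained cell reports its OTU richness,
sampling depth, sqrt-transformed GDM and GDE.

The spatial regression, on a 250-cell world with planted standardised
slopes 0.5 (MTWM), −0.3 (PWM) and 0 (human modification), field sd 0.2 and
noise sd 0.1, fitted on 200 cells:

```r
d <- simulate_cell_data(n_cells = 250,
                        slopes = c(MTWM = 0.5, PWM = -0.3, human_mod = 0),
                        field_sd = 0.2, noise_sd = 0.1, seed = 42)
tr <- 1:200; te <- 201:250
fit <- fit_spatial_glmm(d$y[tr], d$X[tr, ], d$coords[tr, ], n_knots = 50,
                        chains = 2, iter_warmup = 400, iter_sampling = 600,
                        seed = 42)
summary(fit)
#> Posterior summary (median and 95% HDI):
#>              median   lower   upper   rhat       ess
#> (Intercept) -0.0305 -0.2143  0.1461 1.0002 1200.0000
#> MTWM         0.5129  0.4786  0.5453 0.9989 1049.8297
#> PWM         -0.2720 -0.3009 -0.2451 1.0010 1076.3767
#> human_mod   -0.0046 -0.0337  0.0290 1.0008 1018.4138
#> sigma        0.1229  0.1107  0.1368 1.0034  788.8069
#> sigma_w      0.2072  0.0941  0.3103 0.9986  131.8538
#> Bayesian R2: 0.954 [0.944, 0.964]; converged: TRUE

pr <- predict(fit, as.data.frame(d$X[te, ]), d$coords[te, ])
coef(lm(d$y[te] ~ pr$median))      # observed ~ predicted calibration
#> (Intercept)   pr$median
#>      0.0045      0.9837
```

All three slope posteriors bracket their planted values, the null slope is
tightly centred on zero, and withheld-cell predictions are calibrated
(slope ≈ 0.98, intercept ≈ 0.005). `prior_posterior_overlap(fit)` reports
3.6–11.7% overlap for the slopes — well-identified parameters.

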