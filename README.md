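# cladediv

Comparative analysis of why species differ in the average genetic
divergence among their populations.

Given (i) gene trees of within-species samples, (ii) a table linking
samples to clades and georeferenced localities, (iii) per-locality
environmental variables, and (iv) an ultrametric species chronogram,
`cladediv` builds one row per independent monophyletic clade — average
between-locality genetic divergence (the response), average great-circle
distance among localities, environmental heterogeneity (mean Euclidean
distance on the first five PCA axes of 20 standardized environmental
variables), age of origin (stem age from the chronogram), and an ecomorph
label — and fits phylogenetic generalized least squares (PGLS) regressions
under Brownian motion, reducing the full model by backward elimination
with log-likelihood ratio tests.

The core model, for clade-level response $y$ with design $X$:

$$y = X\beta + \varepsilon,\qquad \varepsilon \sim N(0,\ \sigma^2 C^*),$$

where $C^*_{ij}$ is proportional to the branch length shared by clades
$i$ and $j$ from the root — read off a chronogram, or built from a
species distance matrix by UPGMA ultrametrization
($C_{ij} = T - u_{ij}/2$ with cophenetic distances $u$ and depth
$T = \max(u)/2$). Estimation is ML with $\sigma^2$ profiled out, so nested
models are comparable by likelihood-ratio tests; coefficient tables and
sequential (type-I) F tests follow standard GLS conventions (verified
against `nlme::gls` in the tests).

A synthetic-data generator (`simulate_clade_dataset()`) produces all of
these inputs with known effect sizes — Yule chronogram, spatially
structured localities and environments, divergence linear in age /
distance / heterogeneity with partly phylogenetic residual noise, and
within-species trees whose between-locality patristic distances equal the
generated divergence exactly — so the entire pipeline is testable end to
end without any external data.

## Worked example

```r
library(cladediv)

cfg <- sim_config(n_species = 26, seed = 1)   # study-scale synthetic dataset
res <- run_pipeline(pipeline_config(sim = cfg))
res$final
```

```
Phylogenetic GLS (Brownian motion, tree-vcv covariance)
Formula: avg_divergence ~ avg_geodist + age + env_het + avg_geodist:ecomorph 
n = 26, logLik (ML) = 111.7787, sigma^2 = 2.74017e-05

Coefficients:
                             term   estimate std.error statistic   p.value
                      (Intercept) -3.644e-03 2.019e-02   -0.1805 8.590e-01
                      avg_geodist  2.273e-05 1.378e-05    1.6493 1.186e-01
                              age  1.475e-03 6.087e-05   24.2300 4.877e-14
                          env_het  9.322e-04 3.146e-03    0.2963 7.708e-01
   avg_geodist:ecomorphgrass-bush -1.108e-05 1.558e-05   -0.7109 4.874e-01
  ...
```

The generating age effect was 0.0015 substitutions/site per Myr; the
fitted coefficient is 1.475e-03 with t = 24.2 — the age signal is
recovered almost exactly, while the true-zero environment effect is tiny
and nonsignificant. `res$trace` records every eliminated term with its
LRT statistic and p-value, and `res$clade_summary` is the one-row-per-clade
table the model was fitted to. `tidy()`, `glance()`, `pgls_anova()` and
`autoplot()` work on any fit; `plot_divergence_age()` draws the
divergence–age relation, optionally as residuals net of geographic
distance.

Worked-example correlation statistics are one call:

```r
correlation_test(r = 0.0428, df = 24)
#>        r df statistic   p.value
#> 1 0.0428 24 0.2098686 0.8355416
```

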