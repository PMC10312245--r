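# coopnet

Physician cooperation assessment from outpatient claims, via patient-sharing
network analysis and dynamic panel models.

## What it does and for whom

Integrated healthcare systems (IHSs) organize regional provider networks on
the premise that cooperating physicians deliver better, more efficient care —
but cooperation itself is rarely measured. For health-services researchers
and system evaluators with access to claims data, `coopnet` implements a
complete, reproducible assessment design:

1. **Network construction.** Build one undirected network per calendar year
   from outpatient claims: practices are nodes, and an edge connects two
   practices sharing at least 9 distinct patients that year (the count at
   which patient sharing reliably indicates a genuine information-sharing
   relationship). Emergency visits and visits to Anaesthesiology, Radiology
   and Neuropathology are excluded, as are practices serving fewer than 30
   patients a year.
2. **Cooperation indicators.** Per year: network density
   |E|/(n(n−1)/2); mean shortest-path distance; and a *transformed mean
   distance* — the observed mean distance expressed in standard deviations
   from the mean of G(n, m) random graphs with identical node and edge
   counts, isolating path-efficiency changes from mechanical density
   effects. Per practice-year: degree, eigenvector and betweenness
   centrality, with within-year percentage rankings in (0, 1].
3. **Dynamic panel model.** For a cooperation indicator *y* of practice *i*
   in year *t*:

   y_it = θ₁ y_{i,t−1} (+ θ₁ᵦ y_{i,t−2}) + θ₂ year_it + θ₃ IP_i·year_it
        + θ₄ Npatients_it + θ₅ Charlson_it + FE_i + ε_it

   where IP marks practices participating in the integrated system. θ₃
   measures whether IPs became more cooperative than their peers. The model
   is estimated by two-step Blundell–Bond **system GMM** (differenced
   equations instrumented by lagged levels, level equations by lagged
   differences), with Windmeijer-corrected standard errors and the full
   diagnostic battery: Sargan–Hansen overidentification test, Arellano–Bond
   AR(1)/AR(2) tests, joint Wald test, pseudo R² = corr(y, ŷ)².
4. **Sensitivity analysis** over the edge-threshold ladder 3/6/9/12/15, and
   a **synthetic claims generator** that emulates a 14-wave regional
   IHS setting (≈200 practices, ≈26,000 patients, latent community
   structure, an IP cooperation drift) so the whole pipeline is testable
   without proprietary data.

## Worked example

```r
library(coopnet)

cfg <- pipeline_config(simulation = test_scale_config(seed = 42),
                       null_replicates = 200, global_seed = 42)
res <- run_pipeline(cfg)
print(res$summary)
```

```
Network-level cooperation indicators
     year density mean_distance transformed_mean_distance n_nodes n_ip_nodes n_patients
 1:  2004  0.1589         2.630                     52.68      55          9       1932
 2:  2005  0.1623         2.543                     39.56      56          9       1962
 ...
14:  2017  0.1384         3.024                     85.56      64         11       2175

Average percentage change (% per year):
                  density             mean_distance transformed_mean_distance
                    -0.96                      1.25                      6.99
                  n_nodes                n_ip_nodes                n_patients
                     1.18                      1.62                      0.92
```

Each row is one yearly network built from the synthetic claims; the final
block is the average year-over-year percentage change of each indicator —
the headline descriptive of how cooperation evolved. The node-level model
for normalized degree:

```r
print(res$fits$degree)
```

```
System GMM (two-step, Windmeijer-corrected SEs)
              coefficient       se     z       p
y_lag1           0.302000 0.072400  4.17 0.00003 ***
y_lag2           0.283000 0.070600  4.01 0.00006 ***
year_index      -0.000951 0.000309 -3.08 0.00210  **
ip_year          0.001160 0.000569  2.04 0.04100   *
n_patients       0.000357 0.000101  3.52 0.00042 ***
mean_charlson    0.014300 0.007570  1.89 0.05900   .
#Obs 708   nodes 63   instruments 72 (Lags 4:11; 52 diff-GMM + 12 level-GMM + 8 IV columns)
Sargan test: chisq(66) 59.11 (p-value: 0.71)
Autocorrelation test (1): normal -3.97 (p-value: 7.1e-05)
Autocorrelation test (2): normal -2.16 (p-value: 0.031)
Wald test for coefficients: chisq(6) 3576.71 (p-value: 0)
R2 corr(y, yhat)^2: 0.60
```

Here the positive `ip_year` coefficient (θ₃ = 1.16e-03, p = 0.04) recovers
the cooperation drift built into this synthetic scenario: integrated
practices gained cooperation relationships faster than their peers. The
Sargan p-value of 0.71 does not reject instrument validity, AR(1) is
negative as expected under serially uncorrelated errors, and the borderline
AR(2) would, on real data, prompt deeper instrument lags.

A published yearly indicator table for a real regional IHS ships in
`inst/extdata/regional_summary_2004_2017.csv` (accessor
`regional_summary_reference()`); `render_table1()` reproduces its
average-percentage-change row from the per-year columns.

A thin command-line wrapper lives at `inst/scripts/coopnet-cli.R`
(`simulate`, `run`, `sensitivity` verbs).

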