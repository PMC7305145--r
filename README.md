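# cybgrowth

Tools for asking whether the order in which a bacterium consumes a mixture
of nutrients is explained by uptake kinetics alone, or requires active
regulation of the cell's assimilatory machinery. The package targets
microbial physiologists and systems biologists working with batch-culture
time series: OD curves plus per-nutrient concentration profiles (e.g. from
NMR of spent medium), possibly with several replicates.

It implements, as a tested and fully reproducible pipeline:

- **Two competing growth models** on four lumped substrate pools. An
  unregulated Michaelis–Menten–Monod (MMM) model,

  dφP/dt = Σᵢ βᵢ φSᵢ² / (kᵢ + φSᵢ) · φP − d·φP,  dφSᵢ/dt = −βᵢ φSᵢ²/(kᵢ+φSᵢ)·φP,

  with 9 free parameters, and a **cybernetic** model (19 free parameters)
  in which each pool's key enzyme φEᵢ is synthesized and activated under
  optimality-derived control variables

  uᵢ = rᵢ / Σⱼ rⱼ (resource allocation),  vᵢ = rᵢ / maxⱼ rⱼ (activity),

  where rᵢ = V_max,i φEᵢ φSᵢ/(K_S,i + φSᵢ). Both are integrated with an
  adaptive Runge–Kutta 4(5) scheme over compiled right-hand sides.
- **Parameter estimation** by a hybrid Nelder–Mead simplex / simulated
  annealing search in log-parameter space (`fit_model()`), seeded and
  bit-reproducible.
- **Model comparison** per species by Pearson r and AIC = N·log(SSE/N) + 2p
  (`compare_models()`).
- **Time-series utilities**: natural-spline interpolation, log-linear
  growth rates, growth-lag detection (`detect_lags()`).
- **Co-utilization group recovery**: average-linkage hierarchical
  clustering of normalized depletion profiles with silhouette-selected k,
  ordered by depletion time (`cluster_profiles()`, `order_clusters()`).
- **Regulon co-expression coherence**: mean pairwise Fisher-Z-transformed
  Pearson correlation of log2 TPM profiles (`coherence_score()`).
- **A synthetic-data generator** (`generate_experiment()`) emulating a
  19-amino-acid, 0.2 mM-each depletion experiment with four kinetic groups
  (3/4/9/3 members), two replicates, 5% measurement noise and a triauxic
  biomass curve, with full ground-truth metadata for recovery testing.

See `vignettes/growth-modelling.Rmd` for the models, the optimizer
schedule, and every numerical design choice.

## Worked example

Generate the default synthetic experiment, fit both models, and compare:

```r
library(cybgrowth)

exper <- generate_experiment(seed = 42)
obs   <- interpolate_replicates(lump_observed(exper$data), n_out = 49)

fit_mmm <- fit_model(obs, "mmm",        fit_options(seed = 42))
fit_cyb <- fit_model(obs, "cybernetic", fit_options(seed = 42))
compare_models(fit_mmm, fit_cyb, obs)
#> Model comparison: a = mmm, b = cybernetic (5 species, N = 49 each)
#>   species_id pearson_a pearson_b    r2_a    r2_b   aic_a  aic_b winner_r winner_aic
#> 1    biomass    0.9628    0.9999 0.92695 0.99978  -93.23 -368.1        b          b
#> 2         C1    0.9773    0.9972 0.95509 0.99441 -298.73 -365.3        b          b
#> 3         C2    0.9620    0.9997 0.92547 0.99946 -191.72 -404.8        b          b
#> 4         C3    0.8968    0.9998 0.80433 0.99952  -81.73 -366.8        b          b
#> 5         C4    0.1492    0.1444 0.02225 0.02085 -417.09 -400.7        a          a
#> wins by Pearson r:   a 1, b 4, ties 0
#> wins by AIC:         a 1, b 4, ties 0
```

The data were generated by the cybernetic model, and the comparison says
so: the regulated model wins 4 of the 5 fitted species by both metrics.
(The exception, pool C4, is barely consumed within the horizon — an
almost flat, noise-dominated profile that neither model can correlate
with.)

Recover the co-utilization groups from the noisy per-amino-acid profiles:

```r
prof <- exper$truth$aa_profiles          # amino acid x time matrix
cl <- order_clusters(
  cluster_profiles(prof, k_range = 2:8),
  depletion_times(exper$truth$times, prof)
)
cl
#> amino-acid clustering: k = 4 (silhouette-selected)
#>   cluster 1 (3): Gln, Glu, Arg
#>   cluster 2 (4): Asn, Asp, Leu, Pro
#>   cluster 3 (9): Ala, Gly, Ile, Lys, Phe, Ser, Thr, Tyr, Val
#>   cluster 4 (3): His, Met, Trp
```

The silhouette criterion selects k = 4 on its own, and the four groups —
ordered by when they are depleted — match the generator's ground truth,
with the large third group of nine amino acids in third place. The biomass
curve is triauxic: two internal growth lags at the first two substrate
switches,

```r
tr <- exper$truth$trajectory
io <- interpolate_series(tr$times, tr$biomass, n_out = 201)
detect_lags(io$time_h, io$value)
#>   start  end
#> 1   2.4 2.50
#> 2   4.7 5.45
```

`run_pipeline(pipeline_config(seed = 42), "out/")` chains all of the above
and writes tidy CSV/JSON artifacts plus a manifest with file checksums.

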