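# socioscape

Does the landscape an animal lives in shape how social it is? `socioscape`
is an R package for answering that question with GPS collar data. It was
built around the study design used for female white-tailed deer
(*Odocoileus virginianus*), which live in matrilineal social groups whose
contacts with neighbouring groups drive disease spread (e.g. chronic
wasting disease), but every stage is generic: any species monitored with
scheduled GPS fixes over a categorical land-cover map can be analysed the
same way.

The package covers the full pipeline:

1. **Telemetry** — fix tables (`animal_id`, ISO 8601 UTC timestamp,
   projected x/y in metres), seasonal windowing (gestation Jan 1–May 14,
   fawning May 15–Aug 31, rut Sep 1–Dec 31, early gestation Jan 1–Mar 10),
   and regularization to a 2-hour schedule.
2. **Association networks** — the *association rate* of a dyad is the
   number of simultaneous fixes (|Δt| ≤ 3 min) at which the two animals
   were within 25 m, divided by the number of simultaneous fixes. Includes
   the data-sufficiency diagnostics (subsampling curves with a ±1-event
   tolerance band, bi-monthly bias checks) and the ≥600-fix / positive-
   overlap dyad filter.
3. **Home ranges** — kernel utilization distributions with the reference
   bandwidth h = σ·n^(−1/6), 95% isopleths, and the two overlap indices:
   directional PHR (probability of animal *i* being in *j*'s range) and the
   symmetric volume of intersection VI = ∫ min(UD_i, UD_j).
4. **Landscape connectivity** — binary forest/agriculture/edge layers,
   conductance coding (101 presence / 1 absence), and omnidirectional
   circuit-theory current density: unit currents are passed between all
   pairs of sites ringing a buffered study region (e.g. 50 sites every
   3.6 km around a 30 km square with a 7.5 km buffer), cell currents are
   summed, and the buffer is clipped off.
5. **Network metrics** — local: average weighted degree (mean incident
   edge weight, with zero-rate dyads carried at 1×10⁻⁵); global: weighted
   closeness C(i) = Σ_j 1/d_ij with edge cost 1/weight (Dijkstra), averaged
   over all exhaustive 4-node subsets to remove network-size effects, on
   edges weighted by standardized residuals of log(rate) ~ VI.
6. **Inference** — Box-Cox transformation (profile-likelihood λ), the
   14-model candidate set (null, six landscape variables singly, home-range
   overlap, and each landscape variable + overlap), AICc selection with
   Akaike weights, model averaging with relative importance, 9999-rep
   permutation F-tests, |r| > 0.5 collinearity screening, and univariate
   cross-network regressions compared by R².
7. **Synthetic data** — a generator producing patchy landscapes (smoothed
   Gaussian random fields) and group-structured movement (mean-reverting
   walks plus scheduled meetings) with *known* per-dyad association rates,
   2-hourly fixes, ±minutes of time jitter and 8.8 m median position error,
   so the whole pipeline can be validated end to end without any field data.

## Worked example

Simulate a small collared population (3 groups × 2 deer, 60 days of
2-hourly fixes), estimate the association network, and summarise it:

```r
library(socioscape)

pop   <- population_config(n_groups = 3, deer_per_group = 2,
                           monitoring_days = 60, seed = 42)
study <- simulate_study(pop)

dyads <- dyad_table(study$fixes)          # all 15 dyads
merge(dyads, study$truth)                  # estimated vs configured rates
#>  animal_i animal_j n_simultaneous association_rate true_rate
#>   g01_d01  g01_d02            694       0.19740634      0.20
#>   g03_d01  g03_d02            696       0.18534483      0.20
#>   g02_d01  g02_d02            699       0.18454936      0.20
#>   g01_d01  g02_d02            697       0.02008608      0.02
#>   g01_d02  g02_d02            693       0.01875902      0.02
#>   ...

net <- build_local_network(dyads[dyads$n_simultaneous >= 600, ])
round(average_weighted_degree(net), 4)
#> g01_d01 g01_d02 g02_d01 g02_d02 g03_d01 g03_d02
#>  0.0532  0.0538  0.0438  0.0447  0.0436  0.0439

subsampled_closeness(net, k = 4)$mean      # 15 four-node subsets
#> [1] 0.148
```

Groupmates (rate ≈ 0.19 vs a configured 0.20 — the small shortfall is the
25 m detection threshold interacting with collar position error) dominate
each animal's average weighted degree; animals in the middle group
(adjacent to both others) score slightly higher than the peripheral ones.

The same objects feed the landscape side: `gen_landscape()` →
`binary_layer()` / `edge_layer()` → `conductance_surface()` →
`omnidirectional_current()` gives current-density maps, and `kde_ud()` →
`isopleth()` → `phr()` / `vi()` gives the overlap predictors for
`fit_local_models()` and `global_univariate()`.

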