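# cascadenet

Event-occurrence processes with self-excitation — epidemics with
reinfection, message storms, spontaneous neural activity — undergo a
*stationary–nonstationary (SN) transition* far below the classic epidemic
threshold: beyond a critical reproduction ratio
`R_c ≈ 1 − 1/√2 ≈ 0.29`, the pooled event stream develops intermittent
cascades of activity even though its mean rate stays finite.  Where that
transition sits depends strongly on how individuals are connected.

`cascadenet` is for modellers of such systems (epidemiologists,
computational neuroscientists, social-dynamics researchers) and provides
the full tool chain:

* **Simulators** — microscopic SIS Markov process with spontaneous
  activation (`simulate_markov()`), univariate Hawkes processes in original
  and refractory-revised form (`simulate_hawkes()`), and the multivariate
  Hawkes process on a weighted directed network
  (`simulate_multivariate()`).
* **Detection** — stationarity verdict for an observed event series via
  MSE-optimal histogram bin size (`optimal_binsize()`): a diverging optimal
  bin width means no resolvable rate fluctuation (stationary); a finite one
  flags cascades.
* **Prediction** — the cascading statistic computed from the Leontief
  inverse `L = (I − A)⁻¹` of the interaction matrix `A = {α_ij}`,

  ```
  C = Σ_i u_i² ⟨λ_i⟩ / Σ_i ⟨λ_i⟩,   u_i = Σ_k L_ki,   ⟨λ⟩ = Lρ,
  ```

  with critical value 2: the superposed stream is nonstationary iff `C > 2`
  (`cascading_C()`, `critical_R()`).
* **Control** — greedy reallocation of connections at fixed density that
  drives `C` up or down across the critical value (`rewire_optimize()`),
  with exact Sherman–Morrison evaluation of every accepted exchange.
* **Network builders** — uniform, Erdős–Rényi, Barabási–Albert,
  Watts–Strogatz, ring lattice, analytic block "extreme" configurations,
  and the bundled Zachary Karate Club graph (`make_network()`,
  `make_extreme()`), plus a degree-based mean-field critical point
  (`scale_free_Rc_meanfield()`).

## Worked example: taming the Karate Club

Calibrate Zachary's Karate Club to criticality, then rewire the
friendships to incite or impede communication cascades:

```r
library(cascadenet)

net <- make_network("karate", R0 = 0.2)
rc  <- critical_R(net)          # reproduction ratio putting the club at C = 2
rc
#> [1] 0.2228881

k <- make_network("karate", R0 = rc)
cascading_C(k)
#> Cascading statistic C = 2.0003 -> nonstationary (cascading) (critical value 2)
#> Mean rates: total 45.6996, range [1.099, 2.084]

rewire_optimize(k, "ascent", max_steps = 40)    # incite cascades
#> Rewiring (ascent): 34 accepted exchanges, converged
#> C: 2 -> 3.189 (max 3.189)

rewire_optimize(k, "descent", max_steps = 40)   # impede cascades
#> Rewiring (descent): 35 accepted exchanges, converged
#> C: 2 -> 1.66 (max 2); crosses the critical value 2 at step 1
```

Ascent concentrates connections on a few hub individuals (and raises the
average clustering coefficient); descent spreads them evenly, and the club
drops back into the stationary regime.

The detector side, on simulated streams 10% below and well above the
univariate critical point `1 − 1/√2`:

```r
hi <- simulate_hawkes(hawkes_params(rho = 0.5, R0 = 0.5), T = 2000, seed = 7)
optimal_binsize(hi$events)
#> Optimal bin size: delta* = 3.458 (1/delta* = 0.2892)
#> Verdict: finite -> nonstationary (rate fluctuations detected)

lo <- simulate_hawkes(hawkes_params(rho = 0.5, R0 = 0.15), T = 2000, seed = 7)
optimal_binsize(lo$events)
#> Optimal bin size: delta* = 505.1 (1/delta* = 0)
#> Verdict: diverging -> stationary
```

The optimal bin width of the subcritical stream grows to a quarter of the
whole recording (no structure to resolve), while the supercritical stream
pins it near the cascade correlation time of a few time units.

## Documentation

The methods vignette (`vignettes/event-cascades.Rmd`) derives the models,
the bin-size cost, the cascading condition and the rewiring machinery, and
records all numerical design choices (divergence cutoff calibration,
tolerances, problem sizes) and limitations.
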