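# dgnet

`dgnet` is a simulator of epileptogenesis in the dentate gyrus (DG) of the
hippocampus. It models the DG microcircuit — granule cells (GC), mossy
cells (MC) and GABAa-/GABAb-type interneurons (IN) — as a network of
stochastic binary (McCulloch–Pitts) neurons whose synapses, held in a
connectivity matrix `C` partitioned into nine class-to-class groups
(I GC→GC … IX IN→IN), are continuously rewired by three activity-dependent
rules: a homeostatic compensation rule operating on pools of free and
bound synaptic elements, and Hebbian/anti-Hebbian reinforcement of
excitatory synapses. Slow non-synaptic excitatory and inhibitory processes
(NSE/NSI) ignite and terminate ictal episodes. The package exists to run
the classic *status epilepticus* (SE) → latent period → spontaneous
epileptiform activity experiment: a 70-min depolarising stimulus
(`α = 1.0`) at day 1.5, followed by a transient excitatory-GABAa period in
which the interneuron→granule-cell weight of a chosen fraction of granule
cells follows

    φ(t) = φ̄ · (tanh((t − t_i)/0.2) + 1) · (tanh((t_f − t)/1.5) + 1)

(entering the membrane sum as `φ(t) − φ̄`, i.e. inhibitory at baseline and
excitatory mid-window), and to measure what 100 days of simulated
rewiring do: spontaneous discharge counts, latencies, and per-group
connectivity changes 64 days after SE, with parameter sweeps over the
compensation rate ν ∈ [0, 0.1], the Hebbian rate ρ ∈ [0, 0.5], the
inverted fraction {5–85 %} and the excitatory-GABAa duration, including
blockage ("withdrawal") of selected connectivity groups.

It is aimed at computational neuroscientists studying structural
plasticity in epilepsy — in particular the hypothesis that transient
GABAa excitation drives abnormal mossy-fibre sprouting (GC→GC coupling,
Group I) together with mossy-cell disconnection and interneuron–interneuron
inhibition.

## A worked example

```r
library(dgnet)

cfg   <- network_config()        # 100 GC + 3 MC + 2 IN_A + 1 IN_B,
                                 # nu = 0.1, rho = 0.3, calibrated weights
proto <- experiment_protocol()   # SE at day 1.5; 25% of GC excitatory-GABAa
                                 # for 14 days; 100 days of follow-up
res <- run_experiment(cfg, proto, seed = 1)
res
#> <dg_result>
#>   2707 morphogenetic steps (101.5 days), seed 1, engine cpp
#>   events: 22 detected, 21 spontaneous

ns_episodes(res)[1, ]            # the stimulus-driven SE episode
#> # A tibble: 1 × 3
#>   onset_days offset_days duration_min
#>        <dbl>       <dbl>        <dbl>
#> 1       1.54        1.56         39.6

event_latency(res)
#> # A tibble: 1 × 3
#>   latency_days censored reference_days
#>          <dbl> <lgl>             <dbl>
#> 1          4.8 FALSE              1.54

connectivity_change(res)
#> # A tibble: 9 × 3
#>   group  change metric
#>   <fct>   <dbl> <chr>
#> 1 I       0.198 rel_network_baseline
#> 2 II    -13.5   pct_vs_baseline
#> 3 III   -18.0   pct_vs_baseline
#> 4 IV    -24.0   pct_vs_baseline
#> 5 V      -4.25  pct_vs_baseline
#> 6 VI    -47.2   pct_vs_baseline
#> 7 VII   105.    pct_vs_baseline
#> 8 VIII   -7.58  pct_vs_baseline
#> 9 IX    148.    pct_vs_baseline
```

Read: the 70-min stimulus triggers a self-terminating ~40-min SE episode;
after a latent period of ~5 days the network produces recurring
spontaneous discharges (21 within 100 days); and 64 days after SE the
granule cells have sprouted mutual synapses (Group I, reported in units of
the network-wide baseline mean because its own baseline is zero), every
mossy-cell group (II, IV–VI) and the inhibition onto mossy cells (VIII)
have shrunk, while inhibition onto granule cells (VII) and among
interneurons (IX) has grown.

`autoplot(res)`, `autoplot(res, "ns")` and `autoplot(res, "connectivity")`
draw the activity, NSE/NSI and per-group connectivity traces;
`tidy(res, ...)` and `glance(res)` expose the underlying tibbles. Sweeps:

```r
grid <- expand.grid(inverted_fraction = c(.05, .25, .45, .65, .85),
                    gabaa_duration_days = c(1, 7, 14, 21))
sw <- run_sweep(cfg, proto, grid, n_reps = 12, base_seed = 20180308)
summarize_replicates(sw, "n_events", "inverted_fraction", control = "0.05")
```

A thin command-line front end (`inst/cli/dgnet-cli.R`) wraps `simulate`,
`sweep` and `analyze` for shell use; configurations are YAML files read by
`read_config()`.

## Scope

Neurons are binary and probabilistic; there are no conductances, ionic
concentrations, synaptic delays or spatial geometry, and no neurogenesis
or cell death — mossy-cell vulnerability appears as connectivity loss
only. See the methods vignette (`vignettes/epileptogenesis-model.Rmd`) for
the model equations, the calibration choices and their rationale, and
known limitations.
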