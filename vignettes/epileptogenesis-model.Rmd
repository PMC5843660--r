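---
title: "A stochastic network model of dentate gyrus epileptogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic network model of dentate gyrus epileptogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dgnet` simulates the microcircuit of the hippocampal dentate gyrus with
four populations of stochastic binary (McCulloch–Pitts) neurons: granule
cells (GC, excitatory, 100 by default), mossy cells (MC, excitatory, 3),
GABAa-type interneurons (IN_A, inhibitory, 2 — the class whose synapses
onto granule cells can transiently become excitatory) and one GABAb-type
interneuron (IN_B). Every ordered pair of cell classes defines one of nine
connectivity groups: I GC→GC, II GC→MC, III GC→IN, IV MC→GC, V MC→MC,
VI MC→IN, VII IN→GC, VIII IN→MC, IX IN→IN. All synapses live in a single
nonnegative connectivity matrix $C$, with $c_{ij}$ the connectivity from
presynaptic $j$ to postsynaptic $i$. Group I starts empty — healthy granule
cells do not contact one another — and all other groups are initialised
i.i.d. Normal(1.0, 0.2), truncated at zero.

Each iteration (0.36 min) every neuron computes a membrane potential

$$V_{m,i} = \sum_j W(i,j)\, c_{ij}\, z_j + \mathrm{NS}_i + \alpha_i,$$

where $z_j \in \{0,1\}$ is the previous firing state, $W(i,j)$ is the
signed group weight (positive for groups I–VI, negative for VII–IX),
$\mathrm{NS}_i$ is the non-synaptic contribution (granule and mossy cells
only) and $\alpha_i$ an external stimulus drive. The firing probability is
a logistic sigmoid $p_i = \sigma((V_{m,i} - \theta_i)/\kappa_i)$ and the
neuron fires if a uniform draw falls below it. A second, slower timescale
aggregates 150 iterations (54 min) into one *morphogenetic step*: the
activity level $s_i$ is the mean firing probability over the completed
step, held constant in between, and all rewiring is applied at step
boundaries. A neuron is at REST while $0.15 < s_i < 0.25$ (boundaries
inclusive to REST), LOW below and HIGH above.

### Membrane details and calibration

The published description of this model family leaves the firing function
and its constants unspecified, so the package fixes a concrete form and
calibrates it to the stated behaviour: the unstimulated network must rest
inside the activity band indefinitely.

* Per-class thresholds $\theta$ are set so that, at the baseline
  connectivity and with every neuron firing at `p_rest = 0.2`, the
  expected membrane potential maps exactly to probability 0.2 (the
  midpoint of the band).
* The membrane potential entering the sigmoid is an exponential moving
  average with per-class weight `vm_smooth` (default 0.2, i.e. a membrane
  time constant of ~5 iterations ≈ 1.8 min). The three mossy cells and
  three interneurons are shared input hubs, so their iteration-scale
  firing noise is *common* to the whole granule-cell population; without
  membrane integration this common noise drives large excursions of the
  interneuron activity out of the rest band at rest. Ictal episodes last
  ~110 iterations, so the smoothing leaves event responses essentially
  unchanged.
* Interneurons keep a slightly flatter slope (`kappa` 1.2 vs 1.0): they
  integrate ~100 granule-cell inputs and would otherwise amplify residual
  population wobble out of the band.

With the default calibration, every $s_i$ of an unstimulated network stays
within [0.15, 0.25] for at least 10 simulated days across seeds, and a
100-day unstimulated control run produces no detected events and group
mean connectivities within a few percent of baseline.

## Non-synaptic mechanisms (NSE/NSI)

Ictal episodes are ignited and terminated by two slow phenomenological
variables per granule/mossy cell, abstracting activity-dependent ionic
processes (K⁺/Na⁺/Cl⁻ shifts) rather than modelling them mechanistically:

$$\frac{d\,\mathrm{NSE}}{dt} = a_e \max(s - L, 0)
  + b_e\,\mathrm{NSE}\,[\mathrm{NSE}>0 \lor s>L] - \mathrm{NSE}/\tau_e,
\qquad
\frac{d\,\mathrm{NSI}}{dt} = a_i\,\mathrm{NSE} - \mathrm{NSI}/\tau_i,$$

Euler-stepped at the iteration duration (adequate because all time
constants are two orders of magnitude above 0.36 min) and clipped at zero.
The actuation threshold is $L = 0.32$ on the activity level $s$. NSE
rises first under supra-threshold activity and self-amplifies (episode
ignition); NSI integrates NSE more slowly, outlasts it, terminates the
episode and produces the post-ictal silence. An episode is the period
with $g_e\,\mathrm{NSE} > g_i\,\mathrm{NSI}$; because $a_i > b_e +
1/\tau_i$, NSI always overtakes and every episode is finite.

The defaults ($a_e = 1$, $b_e = 0.03$, $\tau_e = 20$ min, $a_i = 0.05$,
$\tau_i = 120$ min, $g_e = g_i = 1$) are calibrated to three targets: a
stimulus-driven status epilepticus episode of ≈ 40 min, terminated by NSI
rather than by stimulus offset (ignition follows the first activity
update after stimulus onset, one morphogenetic step in), a clear
post-ictal silence with recovery to rest in
well under half a day, and no self-ignition from rest. The NSI decay
constant doubles as the inter-event refractory period: shortening it makes
spontaneous discharges cluster, lengthening it suppresses them.

## Rewiring rules

Three rules rewire $C$ once per morphogenetic step; their per-group mean
contributions are recorded separately (`r_ct`, `r_hebb`, `r_antihebb`).

**Compensation (homeostatic) rule.** Each neuron carries pools of *free*
excitatory-postsynaptic, inhibitory-postsynaptic and presynaptic elements;
*bound* element counts are identified with row/column sums of $C$ (one
element per unit connectivity), so bookkeeping cannot drift. At REST
nothing happens. A HIGH neuron (deviation $d = s - 0.25$) dismantles a
fraction $\nu d$ of every excitatory input synapse (the mass is credited
to its free excitatory-postsynaptic pool), and offers new free
inhibitory-postsynaptic and presynaptic elements at rate $\nu d$ times a
per-class gain. A LOW neuron ($d = 0.15 - s$) offers free
excitatory-postsynaptic elements, removes a fraction of its inhibitory
input synapses, loses free presynaptic elements, and has a fraction of its
output synapses removed. Free elements decay by 30 % per step if they fail
to bind. Formation is a deterministic bipartite pairing: free presynaptic
elements of excitatory cells pair with free excitatory-postsynaptic
elements, interneuron presynaptic elements with inhibitory-postsynaptic
elements; the paired mass is `min(supply, demand)` allocated across
compatible pairs proportionally to the offer product, moved free → bound
exactly (conservative), with granule–granule pairs explicitly allowed —
this is the route by which abnormal mossy-fibre sprouting emerges from the
empty Group I block.

The per-class offer gains and removal scales are this package's concrete
stand-in for the unpublished element-turnover table of the original model
family. They were calibrated once against the directional behaviour the
experiments must reproduce, and encode standard dentate gyrus biology:
granule cells sprout readily (mossy-fibre sprouting substrate), mossy
cells offer few elements and their synapses — input and output — are
vulnerable, interneurons have a high presynaptic offer rate (GABAergic
sprouting) and sprouted GABAergic terminals onto granule cells and
interneurons are durable (small inhibitory pruning rates), while
inhibition onto mossy cells shares their vulnerability.

**Hebbian / anti-Hebbian rules.** If presynaptic $j$ fired in the previous
iteration and postsynaptic $i$ fires now, each existing synapse is
reinforced multiplicatively, $\Delta c_{ij} = \rho\,\eta\,c_{ij}$ per
coincidence; if $i$ fires without $j$ having fired, it is depressed with
gain $\eta' = \eta\,p_{rest}/(1-p_{rest})$, which makes the two rules
balance exactly when the presynaptic rate sits at `p_rest`. Coincidences
are accumulated per iteration and applied at the step boundary; synapses
are never created by this rule and never driven negative. Two deliberate
choices:

* $\eta = 2\times10^{-4}$ keeps the Hebbian drift inside the rest band
  (where the compensation rule is silent by definition) slow compared with
  the homeostatic response just outside it. With a substantially larger
  gain the network creeps into a chronically elevated state in which all
  excitatory groups inflate — a regime inconsistent with the episodic
  discharge phenomenology the model is meant to produce.
* The rules apply only to synapses with an excitatory presynaptic neuron
  (groups I–VI; `hebb_on_inhibitory = FALSE`). Hebbian plasticity is
  classically a property of glutamatergic synapses, and applying it to
  interneuron outputs makes the inhibitory connectivity decay whenever the
  interneurons rest below the balance rate, which contradicts the
  increased inhibition that epileptogenesis should produce. Inhibitory
  rewiring is therefore governed by compensation alone.

Blockage experiments zero the changes of selected groups across all three
rules (and exclude those pairs from element bookkeeping), emulating the
withdrawal of specific connectivity changes.

## The experimental schedule

`experiment_protocol()` encodes the epileptogenesis experiment: rest
warm-up to day 1.5; a depolarising stimulus $\alpha = 1$ applied to every
neuron for 70 min (the induced episode — the status epilepticus —
self-terminates after ≈ 40 min); then, from $t_i = 2$ days, a transient
excitatory-GABAa period for a randomly selected fraction of granule cells.
The weight of their IN_A synapses follows

$$\varphi(t) = \bar\varphi\,(\tanh((t - t_i)/0.2) + 1)
  (\tanh((t_f - t)/1.5) + 1),$$

with $t$ in days, entering the membrane sum as the signed weight
$\varphi(t) - \bar\varphi$: equal to the inhibitory baseline $-\bar\varphi$
far outside the window, excitatory (up to $+3\bar\varphi$) mid-window, and
back to baseline after $t_f$. This sign convention is the package's
reading of how the envelope acts on the membrane potential; it is the most
consequential free interpretation in the build, chosen because it matches
the baseline exactly in both tails and reproduces the rise-and-return
shape of measured GABAa reversal-potential shifts. Non-inverted granule
cells keep the constant weight $-\bar\varphi$; GABAb-interneuron synapses
are never inverted.

The emergent sequence under the default parameters ($\nu = 0.1$,
$\rho = 0.3$, 25 % inverted for 14 days) is: rest → SE episode → elevated
activity of the inverted cells during the excitatory-GABAa window, during
which the interneurons form additional (currently excitatory!) synapses
onto them — a positive feedback that is the core mechanism under study —
→ deep silence when inhibition snaps back after $t_f$ → compensation-driven
formation of granule–granule synapses (abnormal mossy-fibre sprouting)
from the excitatory demand accumulated in the silence → a latent period of
days → recurring spontaneous discharges paced by the NSI refractory. At 64
days post-SE the connectivity pattern shows Group I increased, all
mossy-cell groups (II, IV, V, VI) and inhibition onto mossy cells (VIII)
decreased, and inhibition onto granule cells (VII) and among interneurons
(IX) increased.

## Event detection and statistics

An epileptiform event is a maximal run of morphogenetic steps in which the
mean granule-cell activity exceeds 0.25; episodes self-terminate within
~40 min (less than one 54-min step), so the minimum duration is one step.
Events overlapping the stimulus window are the SE episode (non-
spontaneous); spontaneous events are counted for 100 days after the
stimulus. Latency is measured from the end of the SE episode to the first
spontaneous onset (configurable to stimulus onset); runs without events
are censored and excluded from latency means with their count reported.
Ictal episodes proper are measured at iteration resolution by the
NSE/NSI crossing rule (`ns_episodes()`).

Replicate summaries report mean ± SEM, a one-way ANOVA across conditions,
and Dunnett many-to-one comparisons against the control at $\alpha = 0.05$
(via `multcomp`). Sweeps derive per-run seeds deterministically from
`(base_seed, grid point, replicate)`, so every table is exactly
reproducible.

Two sweep-level estimators summarise the dose–response experiments. The
*duration-sensitivity threshold* is the smallest inverted fraction whose
occurrence-on-duration regression is significantly positive with a
non-increasing latency trend (censored latencies imputed at the counting
window). The *saturation duration* is the smallest excitatory-GABAa
duration beyond which the occurrence and every group's 64-day connectivity
change move between adjacent grid durations by less than the combined
replicate SEM.

## Problem sizes and reproducibility

The default network (106 neurons) advances 406,000 iterations for a
101.5-day experiment; one run takes a few seconds in the compiled engine.
The package test-suite exercises the full experiment at 12 seeds and the
dose–response sweeps at 4 replicates per grid point — sizes chosen so the
whole suite, including the sweep-based checks, completes on a single CPU
in well under half an hour while keeping the Monte-Carlo error of every
directional check far from its decision boundary. A pure-R reference
engine, built from the exported module functions and sharing the compiled
engine's RNG call order, is cross-checked against it on small networks.

## What the synthetic conditions do and do not show

All inputs are generated internally; there is no external data. The
simulated conditions reproduce the *qualitative* epileptogenesis
phenomenology: rest stability, a self-terminating SE episode, a latent
period, recurring spontaneous discharges, their dependence on the
excitatory-GABAa dose, and the directional 64-day rewiring pattern.
Because the supplementary closed forms of the original model family are
not published, all quantitative magnitudes (event counts, percentage
connectivity changes) are properties of this package's calibration, not of
real tissue; only directions and the explicitly calibrated targets (rest
band, ~40-min episode) should be compared across implementations. The
model deliberately omits conductance-based membranes, ionic concentration
dynamics, synaptic delays, spatial geometry, neurogenesis and cell death.

## Known limitations

* Blocking the mossy-cell connectivity groups (II, IV–VI, VIII) *increases*
  spontaneous-event counts here instead of reducing them: freezing those
  groups preserves the direct MC→GC excitation that epileptogenesis would
  otherwise prune, and with only three mossy cells supplying a few percent
  of the interneuron drive, the opposing dormant-basket channel (preserved
  MC→IN drive → preserved inhibition) cannot dominate at any weight
  setting compatible with rest stability. Blocking Group I abolishes
  events and blocking Group IX reduces them several-fold, as expected.
  First-event latency rises only under the Group I blockage; the other
  blockages thin events without delaying the first one.

* The spontaneous-event rate is bimodal across seeds: some runs settle
  into sparse discharges (~20 per 100 days), others into dense clusters
  (> 100). Directional results are robust to the regime, but occurrence
  magnitudes have high replicate variance — hence the 12-replicate
  convention for summaries.
* The latent period (≈ 5–10 days) sits at the short end of the "one or
  more weeks" range typical of experimental epileptogenesis.
* Group I changes are reported in units of the network-wide baseline mean
  (its own baseline is exactly zero); they are not directly comparable
  with the percentage changes of groups II–IX.
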