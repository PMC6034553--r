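# pyrcable

Compartmental cable models of cortical pyramidal neurons in R — from
dendritic spines to somatic spikes.

`pyrcable` is for computational neuroscientists who want to run the full
modelling chain used to characterise human layer 2/3 pyramidal cells on
their own morphologies or on built-in synthetic ones:

* **Passive cable models** on SWC morphologies with the global spine-area
  correction `F_spines = (dendritic area + spine area) / dendritic area`
  (C_m scaled up, R_m scaled down on dendrites ≥ 60 µm from the soma), an
  implicit tree-ordered (Hines) solver, and steady-state transfer-resistance
  maps `R[i,j]`.
* **Kinetic synapses**: `g(t) = B·g_max·N·(e^{−t/τ_d} − e^{−t/τ_r})`, with
  the Jahr–Stevens magnesium block
  `B(V) = 1/(1 + n·[Mg²⁺]·e^{−γV})` for NMDA receptors, and explicit
  two-compartment spines (neck 1.35 × 0.25 µm, head 2.8 µm²,
  R_neck ≈ 50–80 MΩ at 200–300 Ω·cm).
* **EPSP analysis**: Rall shape-index curves (rise time vs. half-width),
  membrane-time-constant peeling, synapse localisation, shared-conductance
  fitting for five-contact connections, and the two-stage NMDA-kinetics fit
  against blocked/unblocked composite EPSPs.
* **NMDA spikes**: plateau detection (V > −40 mV for ≥ 20 ms), minimal
  synapse counts per branch, and counting of simultaneously *independent*
  NMDA spikes (non-linear dendritic subunits).
* **Active models**: a 29-parameter soma/axon conductance model over nine
  configurable channel archetypes, the 17 spike-train features, normalised
  I–F curves, and a non-dominated-sorting evolutionary fitter with
  SD-normalised objectives.
* **Synapses-to-spike curves**: somatic spike probability vs. the number of
  simultaneously activated spinous synapses, distributed vs. clustered, and
  the 50% threshold N₅₀.
* **Storage capacity**: one- and two-layer combinatorial bounds,
  `B₂ = 2·m·log₂ C(d + k − 1, k)` with `k = s/m`, `d = s/5`.
* **Synthetic generators** for morphologies (human-like: 44.5 ± 8.1 basal
  terminals with elongated tips; rat-like: 31.4 ± 8.6), spine geometries,
  paired-recording EPSPs, blocked/unblocked NMDA targets and jittered
  spike-train targets — each a pure function of its seed, shipping its
  ground truth, so every fit is testable closed-loop.

## Worked example

```r
library(pyrcable)

# storage capacity of the two-layer neuron abstraction
two_layer_capacity(capacity_inputs(s = 30000, m = 25, d = 6000)) / 1e4
#> [1] 23.36795     # x 10^4 bits (human case)
two_layer_capacity(capacity_inputs(s = 10000, m = 14, d = 2000)) / 1e4
#> [1] 6.301603     # x 10^4 bits (rat case)

# prototypical spine neck resistance at 200 Ohm cm
neck_resistance(spine_geometry(), 200)
#> [1] 55.00395     # MOhm

# magnesium block available at 0 mV (1 mM Mg, n = 0.28 / mM)
mg_block(default_synapse_kinetics()$nmda, 0)
#> [1] 0.78125

# a human-like synthetic cell, spine-corrected
m   <- generate_morphology(tree_recipe("human", seed = 1))
mod <- apply_spine_correction(build_cable_model(m))
mod
#> cable_model: 390 compartments, 83 sections, 0 spines; spine-corrected; passive

# one axo-spinous synapse: EPSP at spine head, base, soma
r <- activate_spinous_synapse(mod, dendritic_comps(mod)[200],
                              default_synapse_kinetics()[c("ampa", "nmda")])
round(c(head = r$epsp_head, base = r$epsp_base, soma = r$epsp_soma), 2)
#> head base soma
#> 7.89 4.21 0.35   # mV: strong local depolarisation, ~20-fold attenuation

# how many clustered synapses for a dendritic NMDA spike at a basal tip?
tip <- terminal_comps(mod, "basal")[5]
min_synapses_for_nmda_spike(mod, tip, seed = 1)$n
#> [1] 15
```

(The numbers above are what the calls print for these seeds; spine EPSPs
and synapse counts vary from branch to branch exactly as the per-branch
input resistance does.)

The methods vignette (`vignettes/methods.Rmd`) documents the model,
parameters, numerical choices and the limits of what the synthetic tests
demonstrate.

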