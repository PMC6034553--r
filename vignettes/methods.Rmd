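---
title: "Methods: compartmental models of pyramidal neurons, from spines to spikes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmental models of pyramidal neurons, from spines to spikes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrcable)
```

# The modelling problem

Human layer 2/3 pyramidal cells differ from their rodent counterparts in
ways that matter electrically: they have far larger and more elaborate
dendritic trees, many more basal terminal branches (44.5 +/- 8.1 versus
31.4 +/- 8.6), distinctively elongated terminals, an unusually low specific
membrane capacitance (~0.5 uF/cm^2), and larger dendritic spines carrying
stronger excitatory synapses. `pyrcable` implements the complete modelling
chain needed to study the consequences: passive cable models on SWC
morphologies, kinetic AMPA/NMDA synapses on explicit spines, localisation
and conductance fitting of somatic EPSPs, dendritic NMDA-spike analysis,
conductance-based somatic/axonal spiking models fitted by multi-objective
evolution, synapse-count-to-spike probability curves, and storage-capacity
estimates for the one- and two-layer neuron abstractions.

Because the underlying physiological recordings are not redistributable,
the package ships synthetic generators that emulate each input modality
with a known, serialised ground truth, so every fitting stage can be
validated closed-loop.

# Passive cable model

A morphology is a validated SWC point tree. `build_cable_model()`
discretises each unbranched section into compartments no longer than
`d_lambda` AC space constants at 100 Hz (default `d_lambda = 0.1`, the
standard rule of thumb in compartmental modelling; the grid-refinement
tests show that peak somatic EPSPs move by well under 1% between 0.1 and
0.02). Surface area per section is conserved exactly; axial resistances use
the tapering-frustum formula. A multi-point soma is collapsed to one
isopotential compartment of equal area. Path distances are measured along
the centreline from the soma centre.

Integration is backward Euler with a fixed default step of 0.025 ms,
chosen for unconditional stability in the presence of the strongly
non-linear NMDA conductance; each step is solved by a single tree-ordered
(children-into-parents) elimination. Gating states and the magnesium-block
factor are advanced from the previous step's voltage (the usual staggered
update). Halving `dt` changes reported EPSP peaks by < 0.5%. The heavier
stochastic analyses (NMDA-spike scans, spike-probability curves,
evolutionary fitting) default to `dt = 0.05` ms in the shipped scripts;
the dt-refinement tests cover this choice.

Default passive parameters are `c_m = 0.5` uF/cm^2, `r_m = 32000` Ohm cm^2
(membrane time constant 16 ms, the human average), `r_a = 250` Ohm cm and a
resting potential of -86 mV. The global spine-area correction multiplies
`c_m` and divides `r_m` by `f_spines = 1.9` on every dendritic compartment
at least 60 um from the soma (spine density is very low more proximally);
the local time constant is untouched by construction.

# Synapses and spines

Synaptic conductances are two-state kinetic (double-exponential) waveforms
normalised so the peak equals `B * g_max` exactly at the analytic peak
time. The NMDA component carries the Jahr-Stevens magnesium block
`B(V) = 1 / (1 + n * [Mg] * exp(-gamma * V))` with `n = 0.28` 1/mM at 1 mM
magnesium. The block steepness `gamma` defaults to 0.0771 1/mV, the value
fitted for human synapses (steeper than the classic rodent 0.062). Default
kinetics: AMPA 0.3/1.8 ms, NMDA 8.02/34.99 ms; default per-contact peak
conductances: AMPA 0.88 nS (connected-pair estimate) or 0.73 nS
(composite-EPSP estimate, 0.13 nS under AMPA block) and NMDA 1.31 nS.

An explicit spine is two full cable compartments: a neck cylinder
(1.35 um x 0.25 um for the prototypical human spine) that carries both its
axial resistance and its own membrane, and an isopotential head of
2.8 um^2. With neck resistivity of 200-300 Ohm cm the neck resistance is
55-83 MOhm, and the +/-0.05 um / +/-100 Ohm cm variation grid spans
19-129 MOhm. Synapses are always placed on the head compartment.

# EPSP analysis

`shape_index()` measures the 10-90% rise time (the conventional
definition; the choice is configurable) and the width at half amplitude,
both against the pre-onset baseline with sample interpolation.
`build_shape_index_curve()` probes every requested dendritic compartment
with a single AMPA synapse; `putative_locations()` returns the sites whose
index falls within a Euclidean radius (default 1 ms — the figure-legend
reading of the acceptance circle; the methods text of the source analysis
could also be read as a 1 ms diameter, so the radius is a parameter) of an
observed index. `peel_time_constant()` fits the log-linear tail.

`fit_connection()` draws five contacts per connection from the putative
pool (the standard multi-contact assumption for cortical connections),
fits one shared peak conductance to the full somatic waveform by bounded
1-D minimisation (tolerance 1e-3 nS), and reports the distribution over
repeats. Full-waveform least squares was chosen over peak-only matching
because the waveform carries the location information.

`fit_nmda_kinetics()` is the two-stage procedure: stage 1 fits
`tau_rise` in [1, 20] ms, `tau_decay` in [20, 100] ms, `gamma` in
[0.03, 0.12] 1/mV and the NMDA and residual-AMPA conductances to the EPSP
recorded under AMPA block (a competitive antagonist leaves a small AMPA
component, so it is fitted rather than forced to zero); stage 2 freezes
those and fits the unblocked AMPA conductance, constrained to at least
five times the residual one; candidates are ranked by summed RMSD against
both targets. The bounds bracket both the human estimates and the rodent
literature values. The full-scale configuration (60,000 seeds, 20,000
carried over) is a parameter; the shipped tests and scripts run reduced
seed counts, which closed-loop recovery shows to be sufficient for
parameter identification on synthetic targets. Stage-1 minimisation is
Nelder-Mead on a logistic transform of the bounded parameters (any
derivative-free local minimiser meeting the tolerance would do).

# NMDA spikes and independent subunits

An NMDA spike is operationalised as local voltage above -40 mV sustained
for at least 20 ms — the criterion that separates brief AMPA-dominated
EPSPs from NMDA plateau potentials. `min_synapses_for_nmda_spike()` places
axo-spinous synapses uniformly within a 20-um stretch of one branch (the
placement list is drawn once, making the response monotone in the count,
so a doubling/bisection search is exact) and reports the smallest count
that triggers the criterion at the stem, with a sentinel above 200.

`count_independent_nmda_spikes()` activates minimal clusters at many
terminals simultaneously (common onset t = 0) and accepts a configuration
only if every activated terminal sustains its own plateau and the *peak*
voltage at every branch point connecting two activated terminals stays
below the threshold over the whole window. The search strategy is greedy
in order of decreasing tip input resistance (an electrotonic-remoteness
proxy) with single-swap backtracking; an exhaustive subset search is
available for small trees. The published analysis mixed manual and
recursive searches without specifying an algorithm, so this strategy is a
documented stand-in whose optimality is only guaranteed when the
exhaustive branch is used.

# Active soma/axon models and multi-objective fitting

No channel identities are attached to the published conductance fits, so
the package defines a generic Hodgkin-Huxley gating framework
(`channel_def()`) plus nine literature-standard cortical archetypes:
transient and persistent Na+, fast (Kv3-like) and slow K+, M-type K+, SK
(calcium-gated, Hill kinetics on a single-pool calcium concentration),
high- and low-threshold Ca2+, and Ih. All kinetics are configuration data.
The 29 free parameters are, per region (soma, axon): nine maximal
densities, three sodium kinetic parameters (activation/inactivation
midpoint shifts and a time-constant scale — a minimal, common
parameterisation), and two calcium-pool parameters (decay time constant
and influx scale); plus one shared leak reversal. A 60-um axon stub
carries the axonal set.

`extract_features()` computes the 17 spike-train features. Bookkeeping
uses a 0 mV peak threshold; the AP begin point is the last upward crossing
of dV/dt = 20 mV/ms before the peak; the half width is measured at half
height between begin voltage and peak. The ISI coefficient of variance is
implemented exactly as printed in the source analysis (ISI mean / ISI SD),
with a switch for the conventional reciprocal. The five normalised-I-F
features are read off the reference population curve at 75-300% of the
normalised input matching the trace's mean rate, which makes them cheap
(no extra simulations per candidate) while still constraining the
operating point of the I-F curve.

`moo_fit()` is an elitist non-dominated-sorting evolutionary search.
Because 17 objectives leave most candidates mutually non-dominated,
selection uses the worst (Chebyshev) SD-distance as the secondary
criterion, the per-objective best individuals are kept in an archive (so
the best distance per objective is non-increasing across generations), and
the run ends with a restarted Nelder-Mead polish of the best individual in
normalised coordinates. Divergent candidates receive capped
effectively-infinite distances rather than crashing the search. The
full-scale profile is 1,000 candidates for 500 generations; the test
profile (20 candidates, 15 generations, used throughout the shipped tests)
is sufficient for closed-loop recovery on the synthetic reference cell.

# Synapses-to-spike curves and storage capacity

`spike_probability_curve()` places synapses either independently and
uniformly over dendritic *length* (the natural reading of a uniform
placement; area-uniform would weight thick branches and is available by
reweighting) or as 20-synapse clusters within 20 um of a uniform anchor,
activates them simultaneously on their own spines, and counts somatic
0 mV crossings over 1,000 trials (reduced in tests). The simulation
window defaults to 300 ms so NMDA plateaus can influence late spiking.
`threshold_at_half()` interpolates the 50% count linearly and flags
extrapolation, which in practice only the shallow clustered curves need.

`two_layer_capacity()` implements the combinatorial storage-capacity bound
B = 2 m log2 C(d + k - 1, k) with k = s/m synapses per subunit and
d = s/5 input lines (five contacts per connection). The cited source
states this bound without restating the equation here; this reconstruction
is validated by reproducing both printed values — 23.4e4 bits for the
human case (s = 30,000, m = 25) and 6.3e4 bits for the rat case
(s = 10,000, m = 14) — to three significant figures. Non-integer k is
handled by log-gamma continuation (nearest-integer k agrees to 3
significant figures); a possible subunit-ordering correction of order
log2 m! bits is omitted because the printed values match without it.

# The synthetic generators, and what passing tests show

Every generator is a pure function of its seed and returns its ground
truth alongside the data.

* `generate_morphology()` grows trees by recursive binomial splitting of a
  drawn terminal quota: human-like trees draw 44.5 +/- 8.1 basal terminals
  with long (180 +/- 40 um) terminal branches, rat-like trees
  31.4 +/- 8.6 with 110 +/- 30 um terminals; internal branches are
  35 +/- 10 um with geometric diameter taper. This reproduces the gross
  statistics that drive the analyses (terminal counts, terminal
  elongation, branch-point structure) and nothing else: no anatomical
  boutons, no 3D space filling, no reconstruction noise.
* `sample_spine_geometries()` draws truncated-normal spine dimensions
  around the reported human means (head 2.88 +/- 1.37 um^2, neck
  1.34 +/- 0.50 um by 0.24 +/- 0.08 um).
* `generate_pair_epsp()` plants five AMPA contacts at path distances drawn
  from the proximal connection territory (140 +/- 78 um) and adds optional
  Gaussian voltage noise.
* `generate_nmda_targets()` plants 15-30 dual-component synapses and
  returns the blocked/unblocked somatic pair.
* `generate_spike_train_targets()` jitters a known 29-parameter model
  (2% multiplicative on positive parameters) over repeats and emits
  per-feature means and SDs with an SD floor of 1e-3 to keep SD-normalised
  distances finite. The reference synthetic cell is a compact rat-like
  tree; its stimulus (0.40 nA) is chosen in the cell's stable tonic regime
  (~30 Hz), because close to rheobase this archetype cell shows a steep
  onset where small parameter jitter swings the rate severalfold and the
  averaged feature targets stop being representative of any single model.
  The ~10 Hz operating point of the real recordings applies to the
  biological cells, not to this synthetic stand-in.

Passing the closed-loop tests therefore shows that each fitting stage can
identify parameters *of data generated by the package's own forward
model* under realistic noise — it does not certify performance on real
recordings, where channel kinetics, morphology errors and electrode
artefacts add model mismatch that the generators deliberately do not
emulate.

# Numerical choices and degenerate inputs

* Conductance fits use bounded derivative-free minimisation with a 1e-3 nS
  convergence scale; zero-amplitude targets fit to (numerically) zero.
* `detect_nmda_spike()` interpolates threshold crossings, so detection is
  stable under dt refinement whenever the margin exceeds ~1 mV / 1 ms.
* Fewer than two spikes leave ISI-based features `NA`; the MOO evaluator
  maps non-finite feature distances to a large cap rather than
  propagating them.
* Clustered placements drop a trailing partial cluster; a cluster whose
  span exceeds its branch is confined to the branch.
* The stage-2 NMDA constraint (unblocked AMPA at least 5x the residual)
  can bind; such fits are flagged, not dropped.

# Problem sizes in the shipped runs

The test-suite and acceptance-script runs use one human-like and one
rat-like synthetic tree (a few hundred compartments each at
`d_lambda = 0.1`), 12-terminal scans for the synapses-per-NMDA-spike
averages, 25-40 trials per point on five-point probability curves, four
placement seeds for the NMDA-kinetics fit, and the 20 x 15 evolutionary
test profile. These sizes were chosen to make the full pipeline
exercisable on a laptop-class single core in minutes; all of them are
function arguments, and the full-scale values quoted above remain the
defaults where the analysis is cheap.

# Known limitations

* Dendrites are passive apart from NMDA synapses: no dendritic Na+ or
  Ca2+ spikes, no back-propagating action potentials (their properties in
  human cells are unmeasured).
* No receptor desensitisation, stochastic gating, spine calcium, or
  electrodiffusion; no inhibition or in-vivo background state.
* The nine channel archetypes are stand-ins for the unpublished kinetics
  of the original fits; quantitative reproduction of the six-cell
  conductance values is out of reach without the original recordings and
  is exposed instead through `extended_validation()`, which runs the full
  pipeline on any directory of SWC reconstructions (for instance ModelDB
  accession 238347).
* The greedy independence search is exact only where the exhaustive
  branch is affordable.
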