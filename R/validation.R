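#' Extended validation: the full pipeline on a directory of SWC cells
#'
#' Reproduces the headline per-cell quantities of the modelling pipeline on
#' reconstructed morphologies: mean synapses per NMDA spike over sampled
#' branches (and over terminals only), the number of simultaneously
#' independent NMDA spikes, the 50%-probability somatic-spike synapse count
#' for distributed and clustered placements, and the spine head/base/soma
#' EPSP amplitudes. Intended for the six reconstructed human L2/L3 cells
#' (ModelDB accession 238347) or for synthetic stand-in trees; sizes are
#' tunable so the suite can be run at reduced scale.
#'
#' @param swc_paths character vector of SWC files (one per cell)
#' @param params passive parameters applied to every cell
#' @param active 29-parameter vector for the spiking stages (default:
#'   [example_active_params()]); set NULL to skip the spike-threshold stage
#' @param n_branch_sample branches sampled per cell for the synapses-per-
#'   NMDA-spike average
#' @param n_spine_sample spine placements sampled per cell for the EPSP
#'   statistics
#' @param counts synapse counts for the spike-probability curves
#' @param trials trials per count
#' @param seed master seed
#' @param d_lambda spatial discretisation
#' @param duration,dt simulation window and step for the stochastic stages, ms
#' @return data.frame, one row per cell, with columns `cell`,
#'   `syn_per_nmda_spike`, `syn_per_nmda_spike_terminal`,
#'   `independent_nmda_spikes`, `n50_distributed`, `n50_clustered`,
#'   `epsp_head_mv`, `epsp_base_mv`, `epsp_soma_mv`
#' @export
extended_validation <- function(swc_paths, params = passive_params(),
                                active = example_active_params(),
                                n_branch_sample = 12, n_spine_sample = 20,
                                counts = c(60, 100, 140, 180, 240),
                                trials = 100, seed = 1, d_lambda = 0.1,
                                duration = 200, dt = 0.05) {
  kin <- default_synapse_kinetics()
  out <- lapply(seq_along(swc_paths), function(ci) {
    morph <- if (inherits(swc_paths[[ci]], "morphology")) swc_paths[[ci]] else
      read_swc(swc_paths[[ci]])
    mod <- apply_spine_correction(build_cable_model(morph, params, d_lambda))
    set.seed(seed + ci)
    dend <- dendritic_comps(mod)
    branches <- dend[sample.int(length(dend), min(n_branch_sample, length(dend)))]
    nmin_all <- vapply(seq_along(branches), function(i) {
      r <- min_synapses_for_nmda_spike(mod, branches[i], seed = seed + 31 * i,
                                       duration = 120, dt = dt)
      if (r$no_spike) NA_real_ else as.numeric(r$n)
    }, 0)
    tips <- terminal_comps(mod)
    tip_s <- tips[sample.int(length(tips), min(n_branch_sample, length(tips)))]
    nmin_tip <- vapply(seq_along(tip_s), function(i) {
      r <- min_synapses_for_nmda_spike(mod, tip_s[i], seed = seed + 53 * i,
                                       duration = 120, dt = dt)
      if (r$no_spike) NA_real_ else as.numeric(r$n)
    }, 0)
    indep <- count_independent_nmda_spikes(mod, seed = seed + ci,
                                           duration = 120, dt = dt)
    spine_sites <- dend[sample.int(length(dend), min(n_spine_sample, length(dend)))]
    ep <- vapply(spine_sites, function(s) {
      r <- activate_spinous_synapse(mod, s, kin[c("ampa", "nmda")])
      c(r$epsp_head, r$epsp_base, r$epsp_soma)
    }, numeric(3))
    n50d <- n50c <- NA_real_
    if (!is.null(active)) {
      am <- apply_active_params(add_axon_stub(mod), active)
      cd <- spike_probability_curve(am, counts, mode = "distributed",
                                    trials = trials, seed = seed + ci,
                                    duration = duration, dt = dt)
      cc <- spike_probability_curve(am, counts, mode = "clustered",
                                    trials = trials, seed = seed + ci,
                                    duration = duration, dt = dt)
      n50d <- tryCatch(threshold_at_half(cd)$n_50, error = function(e) NA_real_)
      n50c <- tryCatch(threshold_at_half(cc)$n_50, error = function(e) NA_real_)
    }
    data.frame(cell = ci,
               syn_per_nmda_spike = mean(nmin_all, na.rm = TRUE),
               syn_per_nmda_spike_terminal = mean(nmin_tip, na.rm = TRUE),
               independent_nmda_spikes = indep$count,
               n50_distributed = n50d, n50_clustered = n50c,
               epsp_head_mv = mean(ep[1, ]), epsp_base_mv = mean(ep[2, ]),
               epsp_soma_mv = mean(ep[3, ]))
  })
  do.call(rbind, out)
}
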