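#' Synapse placement specification
#'
#' Distributed mode places every synapse independently, uniformly over
#' dendritic length. Clustered mode places groups of `cluster_size` synapses:
#' cluster anchors are uniform over dendritic length and members lie within
#' `cluster_span` um of the anchor on the same branch; a trailing partial
#' cluster is dropped.
#'
#' @param mode `"distributed"` or `"clustered"`
#' @param n total synapse count
#' @param cluster_size synapses per cluster (default 20)
#' @param cluster_span within-branch stretch, um (default 20)
#' @param seed placement seed
#' @return an object of class `placement_spec`
#' @export
placement_spec <- function(mode = c("distributed", "clustered"), n,
                           cluster_size = 20, cluster_span = 20, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n >= 0, cluster_size >= 1, cluster_span > 0)
  structure(list(mode = mode, n = n, cluster_size = cluster_size,
                 cluster_span = cluster_span, seed = seed),
            class = "placement_spec")
}

#' Place synapses on the dendritic tree
#'
#' Returns shaft compartment indices (one spine/synapse each) drawn
#' according to the placement spec; sampling is uniform over dendritic *length*
#' (compartments weighted by their cable length).
#'
#' @param model a `cable_model`
#' @param spec a [placement_spec()]
#' @return integer vector of shaft compartment sites (possibly length 0)
#' @export
place_synapses <- function(model, spec) {
  dend <- dendritic_comps(model)
  if (!length(dend)) stop("model has no dendrites")
  if (spec$n == 0L) return(integer(0))
  set.seed(spec$seed)
  seclen <- model$sections$length[model$comp$section[dend]]
  nseg_per_sec <- table(model$comp$section[dend])
  w <- seclen / as.numeric(nseg_per_sec[as.character(model$comp$section[dend])])
  if (spec$mode == "distributed") {
    sample(dend, spec$n, replace = TRUE, prob = w)
  } else {
    n_clusters <- spec$n %/% spec$cluster_size
    if (n_clusters == 0L) return(integer(0))
    anchors <- sample(dend, n_clusters, replace = TRUE, prob = w)
    unlist(lapply(anchors, function(a) {
      cand <- .cluster_candidates(model, a, spec$cluster_span)
      cand[sample.int(length(cand), spec$cluster_size, replace = TRUE)]
    }))
  }
}

#' Somatic spike probability versus synapse count
#'
#' For each count, runs `trials` independent placements of simultaneously
#' activated axo-spinous AMPA+NMDA synapses on an active model and reports
#' the fraction of trials in which the somatic voltage crosses the spike
#' threshold. Trial seeds are derived reproducibly from the master seed.
#'
#' @param model an active `cable_model` (after [apply_active_params()])
#' @param counts synapse counts to probe
#' @param mode `"distributed"` or `"clustered"`
#' @param trials placements per count (default 1000)
#' @param spike_threshold_mv somatic detection threshold, mV (default 0)
#' @param seed master seed
#' @param kinetics per-synapse kinetics list (default AMPA 0.73 + NMDA 1.31 nS)
#' @param cluster_size,cluster_span clustered-mode geometry
#' @param duration,dt simulation settings, ms (default 300 ms window, long
#'   enough for NMDA plateaus to influence spiking)
#' @return data.frame of class `probability_curve` with `n`, `p`, `trials`
#' @export
spike_probability_curve <- function(model, counts,
                                    mode = c("distributed", "clustered"),
                                    trials = 1000, spike_threshold_mv = 0,
                                    seed = 1,
                                    kinetics = default_synapse_kinetics()[c("ampa", "nmda")],
                                    cluster_size = 20, cluster_span = 20,
                                    duration = 300, dt = 0.025) {
  mode <- match.arg(mode)
  p <- vapply(seq_along(counts), function(ci) {
    hits <- vapply(seq_len(trials), function(tr) {
      spec <- placement_spec(mode, counts[ci], cluster_size, cluster_span,
                             seed = (as.numeric(seed) * 100003 + ci * 1009 + tr) %% 2147483647)
      sites <- place_synapses(model, spec)
      if (!length(sites)) return(FALSE)
      ss <- add_spinous_synapses(model, sites, kinetics, onset = 5)
      sim <- simulate_model(ss$model, duration, dt, synapses = ss$synapses,
                            record = 1L)
      max(sim$v[, 1]) >= spike_threshold_mv
    }, logical(1))
    mean(hits)
  }, 0)
  structure(data.frame(n = counts, p = p, trials = trials),
            class = c("probability_curve", "data.frame"))
}

#' Synapse count at 50% spike probability
#'
#' Linear interpolation between the bracketing points of the curve; when 0.5
#' is not bracketed, a linear extrapolation from the last segment is used
#' and the result is flagged.
#'
#' @param curve a [spike_probability_curve()] result (>= 2 points)
#' @param p_target target probability (default 0.5)
#' @return list with `n_50` and `extrapolated` (logical); errors on a
#'   degenerate slope-free curve
#' @export
threshold_at_half <- function(curve, p_target = 0.5) {
  stopifnot(nrow(curve) >= 2)
  o <- order(curve$n)
  n <- curve$n[o]; p <- curve$p[o]
  if (all(diff(p) == 0)) stop("threshold undefined: curve has no slope")
  br <- which(diff(p >= p_target) == 1L)
  if (length(br)) {
    i <- br[1]
    return(list(n_50 = n[i] + (n[i + 1] - n[i]) *
                  (p_target - p[i]) / (p[i + 1] - p[i]),
                extrapolated = FALSE))
  }
  # extrapolate from the last segment with non-zero slope
  seg <- which(diff(p) != 0)
  i <- seg[length(seg)]
  list(n_50 = n[i] + (n[i + 1] - n[i]) * (p_target - p[i]) / (p[i + 1] - p[i]),
       extrapolated = TRUE)
}
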