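#' Attach an explicit two-compartment spine to a dendritic site
#'
#' Adds a neck compartment (a full cable compartment: the neck cylinder
#' carries its own membrane as well as the axial resistance) and an
#' isopotential head compartment to the model. Passive parameters are
#' inherited from the host dendrite's specific parameters (no spine-area
#' correction is applied to the spine's own membrane). Synapses are intended
#' to be placed on the head compartment.
#'
#' @param model a `cable_model`
#' @param site compartment index of the dendritic shaft attachment
#' @param geom a [spine_geometry()] object
#' @return the model with two extra compartments; the new head index is in
#'   `attr(, "head")`, the neck in `attr(, "neck")`
#' @export
attach_spine <- function(model, site, geom = spine_geometry()) {
  stopifnot(inherits(model, "cable_model"))
  if (!model$comp$type[site] %in% c(3L, 4L)) {
    stop("spines can only be attached to dendritic compartments")
  }
  p <- model$params
  rneck <- neck_resistance(geom, p$r_a)
  neck_area <- pi * geom$neck_diameter * geom$neck_length
  n <- nrow(model$comp)
  dist0 <- model$comp$path_dist[site]
  newc <- data.frame(
    parent = c(site, n + 1L),
    ga = c(1 / (rneck / 2), 1 / (rneck / 2)),
    area = c(neck_area, geom$head_area),
    cm = .cm_nF(p$c_m, c(neck_area, geom$head_area)),
    gl = .gl_uS(p$r_m, c(neck_area, geom$head_area)),
    el = p$e_rest,
    type = model$comp$type[site],
    section = model$comp$section[site],
    path_dist = dist0 + c(geom$neck_length / 2, geom$neck_length),
    rhalf = c(rneck / 2, 0),
    is_spine = c(1L, 2L))
  model$comp <- rbind(model$comp, newc)
  model$n_spines <- model$n_spines + 1L
  attr(model, "neck") <- n + 1L
  attr(model, "head") <- n + 2L
  model
}

#' Activate a synapse on a spine head and measure the EPSP chain
#'
#' Attaches a spine at `site`, activates a synapse on its head at t = 5 ms,
#' and reports peak EPSP amplitudes (relative to rest) at the spine head, the
#' spine base (the shaft compartment) and the soma, with the head/base and
#' head/soma attenuation ratios. On a passive model the peaks satisfy
#' head >= base >= soma.
#'
#' @param model a passive `cable_model`
#' @param site dendritic shaft compartment index
#' @param kinetics a [synapse_kinetics()] or list of them (e.g. AMPA + NMDA)
#' @param geom spine geometry
#' @param duration simulation length, ms
#' @param dt time step, ms
#' @return list with `epsp_head`, `epsp_base`, `epsp_soma` (mV),
#'   `ratio_head_base`, `ratio_head_soma`, and the raw `sim` result
#' @export
activate_spinous_synapse <- function(model, site, kinetics,
                                     geom = spine_geometry(),
                                     duration = 100, dt = 0.025) {
  m2 <- attach_spine(model, site, geom)
  head <- attr(m2, "head")
  syn <- synapse_table(head, kinetics, onset = 5)
  sim <- simulate_model(m2, duration, dt, synapses = syn,
                        record = c(head, site, 1L))
  rest <- model$params$e_rest
  pk <- apply(sim$v, 2, max) - rest
  list(epsp_head = pk[[1]], epsp_base = pk[[2]], epsp_soma = pk[[3]],
       ratio_head_base = pk[[1]] / pk[[2]],
       ratio_head_soma = pk[[1]] / pk[[3]],
       sim = sim)
}

#' Attach many spines with synapses in one call
#'
#' Helper used by the cluster and placement routines: attaches one spine per
#' requested shaft site and returns the model plus an engine synapse table
#' targeting the spine heads.
#'
#' @param model a `cable_model`
#' @param sites shaft compartment indices (one spine per entry)
#' @param kinetics a [synapse_kinetics()] or list applied to every spine head
#' @param onset activation time(s), ms
#' @param geom spine geometry
#' @return list with `model` and `synapses` (matrix), and `heads`
#' @export
add_spinous_synapses <- function(model, sites, kinetics, onset = 0,
                                 geom = spine_geometry()) {
  stopifnot(all(model$comp$type[sites] %in% c(3L, 4L)))
  p <- model$params
  ns <- length(sites)
  n <- nrow(model$comp)
  rneck <- neck_resistance(geom, p$r_a)
  neck_area <- pi * geom$neck_diameter * geom$neck_length
  necks <- n + 2L * seq_len(ns) - 1L
  heads <- necks + 1L
  newc <- data.frame(
    parent = as.integer(rbind(sites, necks)),
    ga = rep(2 / rneck, 2L * ns),
    area = rep(c(neck_area, geom$head_area), ns),
    cm = .cm_nF(p$c_m, rep(c(neck_area, geom$head_area), ns)),
    gl = .gl_uS(p$r_m, rep(c(neck_area, geom$head_area), ns)),
    el = p$e_rest,
    type = rep(model$comp$type[sites], each = 2L),
    section = rep(model$comp$section[sites], each = 2L),
    path_dist = rep(model$comp$path_dist[sites], each = 2L) +
      rep(c(geom$neck_length / 2, geom$neck_length), ns),
    rhalf = rep(c(rneck / 2, 0), ns),
    is_spine = rep(c(1L, 2L), ns))
  model$comp <- rbind(model$comp, newc)
  model$n_spines <- model$n_spines + ns
  if (inherits(kinetics, "synapse_kinetics")) kinetics <- list(kinetics)
  tabs <- lapply(kinetics, function(k) synapse_table(heads, k, onset))
  list(model = model, synapses = do.call(rbind, tabs), heads = heads)
}
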