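#' Hodgkin-Huxley-style channel definition
#'
#' Generic gating framework: conductance g = gbar * m^p * h^q with
#' first-order gates. Gate steady states are Boltzmann functions of voltage
#' (slope sign sets activation vs. inactivation) and time constants are
#' bell-shaped in voltage (tau_min + 2*tau_amp / (exp(x) + exp(-x)) with
#' x = (V - tau_v)/tau_k). Calcium-gated channels replace the activation
#' steady state by a Hill function of the intracellular calcium pool.
#' Channels flagged `is_ca` feed the pool.
#'
#' @param name channel label
#' @param erev reversal potential, mV
#' @param p,q gate exponents (q = 0: no inactivation gate)
#' @param act,inact lists with `vhalf`, `k`, `tau_min`, `tau_amp`, `tau_v`,
#'   `tau_k`
#' @param ca_gated logical; activation driven by calcium
#' @param ca_kd,ca_hill Hill parameters of the calcium gate (mM, unitless)
#' @param is_ca logical; the channel carries calcium current
#' @return an object of class `channel_def`
#' @export
channel_def <- function(name, erev, p = 1, q = 0,
                        act = list(vhalf = -40, k = 6, tau_min = 1,
                                   tau_amp = 0, tau_v = -40, tau_k = 15),
                        inact = NULL, ca_gated = FALSE,
                        ca_kd = 4.3e-4, ca_hill = 4, is_ca = FALSE) {
  structure(list(name = name, erev = erev, p = p, q = q, act = act,
                 inact = inact, ca_gated = ca_gated, ca_kd = ca_kd,
                 ca_hill = ca_hill, is_ca = is_ca), class = "channel_def")
}

#' Default set of nine cortical channel archetypes
#'
#' A literature-standard complement for a cortical pyramidal soma/axon:
#' fast transient Na+, persistent Na+, fast delayed-rectifier K+ (Kv3-like),
#' slow/persistent K+, M-type K+, SK (calcium-gated K+), high- and
#' low-voltage-activated Ca2+, and Ih. Kinetic parameters are configuration
#' data carried by the [channel_def()] objects, not code constants; the
#' maximal conductance of each archetype is a free parameter of the
#' 29-parameter active model.
#'
#' @return named list of nine [channel_def()] objects
#' @export
default_channel_set <- function() {
  list(
    na_t = channel_def("na_t", erev = 50, p = 3, q = 1,
      act = list(vhalf = -35, k = 6, tau_min = 0.05, tau_amp = 0.08, tau_v = -35, tau_k = 10),
      inact = list(vhalf = -58, k = -6, tau_min = 0.6, tau_amp = 6, tau_v = -60, tau_k = 15)),
    na_p = channel_def("na_p", erev = 50, p = 3, q = 0,
      act = list(vhalf = -52, k = 4.6, tau_min = 0.8, tau_amp = 4, tau_v = -50, tau_k = 14)),
    k_fast = channel_def("k_fast", erev = -85, p = 2, q = 0,
      act = list(vhalf = -12, k = 11, tau_min = 0.5, tau_amp = 3, tau_v = -40, tau_k = 25)),
    k_slow = channel_def("k_slow", erev = -85, p = 2, q = 1,
      act = list(vhalf = -14, k = 12, tau_min = 2, tau_amp = 8, tau_v = -20, tau_k = 20),
      inact = list(vhalf = -54, k = -11, tau_min = 200, tau_amp = 600, tau_v = -50, tau_k = 25)),
    k_m = channel_def("k_m", erev = -85, p = 1, q = 0,
      act = list(vhalf = -35, k = 10, tau_min = 15, tau_amp = 60, tau_v = -35, tau_k = 20)),
    sk = channel_def("sk", erev = -85, p = 1, q = 0,
      act = list(vhalf = 0, k = 1, tau_min = 4, tau_amp = 0, tau_v = 0, tau_k = 1),
      ca_gated = TRUE, ca_kd = 4.3e-4, ca_hill = 4),
    ca_hva = channel_def("ca_hva", erev = 130, p = 2, q = 1, is_ca = TRUE,
      act = list(vhalf = -20, k = 7, tau_min = 0.5, tau_amp = 2, tau_v = -20, tau_k = 15),
      inact = list(vhalf = -45, k = -12, tau_min = 80, tau_amp = 300, tau_v = -40, tau_k = 20)),
    ca_lva = channel_def("ca_lva", erev = 130, p = 2, q = 1, is_ca = TRUE,
      act = list(vhalf = -42, k = 5, tau_min = 2, tau_amp = 8, tau_v = -45, tau_k = 12),
      inact = list(vhalf = -67, k = -5.5, tau_min = 20, tau_amp = 80, tau_v = -65, tau_k = 14)),
    ih = channel_def("ih", erev = -45, p = 1, q = 0,
      act = list(vhalf = -91, k = -8, tau_min = 30, tau_amp = 120, tau_v = -85, tau_k = 18))
  )
}

#' Names of the 29 free parameters of the active soma/axon model
#'
#' Per region (soma, axon): nine channel conductance densities (S/cm^2),
#' three sodium kinetics parameters (activation and inactivation midpoint
#' shifts in mV, a time-constant scale factor) and two calcium-pool
#' parameters (decay time constant in ms, influx scale); plus one shared
#' leak reversal (mV). 2 x 14 + 1 = 29.
#'
#' @param channel_set channel archetypes (for the density names)
#' @return character vector of length 29
#' @export
active_param_names <- function(channel_set = default_channel_set()) {
  per_region <- c(paste0("g_", names(channel_set)),
                  "na_shift_act", "na_shift_inact", "na_tau_scale",
                  "ca_tau", "ca_influx")
  c(paste0("soma.", per_region), paste0("axon.", per_region), "e_leak")
}

#' Validate and label a 29-parameter active parameter vector
#'
#' @param x numeric vector of length 29, in [active_param_names()] order
#'   (or named, any order)
#' @param channel_set channel archetypes
#' @return named numeric vector of class `active_params`
#' @export
active_params <- function(x, channel_set = default_channel_set()) {
  nm <- active_param_names(channel_set)
  if (length(x) != 29L) stop("active parameter vector must have 29 entries")
  if (!is.null(names(x))) {
    if (!setequal(names(x), nm)) stop("unexpected active parameter names")
    x <- x[nm]
  } else names(x) <- nm
  dens <- grepl("\\.g_", nm)
  if (any(x[dens] < 0)) stop("channel densities must be >= 0")
  structure(x, class = "active_params")
}

# flatten one channel instance into the engine row layout
.chan_row <- function(comp, def, gbar_uS, shift_act = 0, shift_inact = 0,
                      tau_scale = 1) {
  a <- def$act
  i <- def$inact %||% list(vhalf = 0, k = 1, tau_min = 1, tau_amp = 0,
                           tau_v = 0, tau_k = 1)
  c(comp - 1L, gbar_uS, def$erev, def$p, def$q,
    a$vhalf + shift_act, a$k, a$tau_min * tau_scale, a$tau_amp * tau_scale,
    a$tau_v + shift_act, a$tau_k,
    i$vhalf + shift_inact, i$k, i$tau_min * tau_scale, i$tau_amp * tau_scale,
    i$tau_v + shift_inact, i$tau_k,
    as.numeric(def$ca_gated), def$ca_kd, def$ca_hill, as.numeric(def$is_ca))
}

#' Install active mechanisms on the soma and axon of a model
#'
#' Builds the channel-instance table and calcium pools from a 29-parameter
#' vector. Sodium kinetic shifts apply to the transient and persistent Na+
#' archetypes of the region; the leak reversal is set on every compartment.
#' With all densities zero the model's voltage dynamics reduce exactly to
#' the passive model (up to the leak-reversal setting).
#'
#' @param model a `cable_model` with an axon (see [add_axon_stub()]) unless
#'   all axonal densities are zero
#' @param params an [active_params()] vector
#' @param channel_set channel archetypes
#' @return the model with `channels` and `ca` populated
#' @export
apply_active_params <- function(model, params,
                                channel_set = default_channel_set()) {
  params <- active_params(unclass(params), channel_set)
  n <- nrow(model$comp)
  rows <- list()
  ca_tau <- numeric(n); ca_influx <- numeric(n)
  for (region in c("soma", "axon")) {
    comps <- if (region == "soma") 1L else which(model$comp$type == 2L)
    if (!length(comps)) next
    pre <- function(k) params[[paste0(region, ".", k)]]
    for (ci in seq_along(channel_set)) {
      def <- channel_set[[ci]]
      gbar <- pre(paste0("g_", def$name))
      if (gbar <= 0) next
      is_na_chan <- def$name %in% c("na_t", "na_p")
      for (cc in comps) {
        rows[[length(rows) + 1L]] <- .chan_row(
          cc, def, .gbar_uS(gbar, model$comp$area[cc]),
          shift_act = if (is_na_chan) pre("na_shift_act") else 0,
          shift_inact = if (is_na_chan) pre("na_shift_inact") else 0,
          tau_scale = if (is_na_chan) pre("na_tau_scale") else 1)
      }
    }
    ca_tau[comps] <- pre("ca_tau")
    ca_influx[comps] <- pre("ca_influx")
  }
  model$channels <- if (length(rows)) do.call(rbind, rows) else NULL
  model$ca <- list(tau = ca_tau, influx = ca_influx, rest = 1e-4)
  model$comp$el <- params[["e_leak"]]
  model$params$e_rest <- params[["e_leak"]]
  model
}

#' Add a short axon stub to a model
#'
#' Attaches an unbranched axonal cable of the given length at the soma,
#' to carry the axonal mechanism set.
#'
#' @param model a `cable_model` without an axon
#' @param length axon length, um (default 60)
#' @param diam axon diameter, um
#' @param nseg number of axonal compartments
#' @return the model with axonal compartments appended
#' @export
add_axon_stub <- function(model, length = 60, diam = 1, nseg = 5L) {
  if (any(model$comp$type == 2L)) stop("axon already present")
  p <- model$params
  seg_l <- length / nseg
  seg_area <- pi * diam * seg_l
  rseg <- .raxial_MOhm(p$r_a, seg_l, diam)
  n <- nrow(model$comp)
  idx <- n + seq_len(nseg)
  newc <- data.frame(
    parent = c(1L, head(idx, -1L)),
    ga = c(1 / (rseg / 2), rep(1 / rseg, nseg - 1L)),
    area = seg_area, cm = .cm_nF(p$c_m, seg_area),
    gl = .gl_uS(p$r_m, seg_area), el = p$e_rest, type = 2L,
    section = max(model$comp$section) + 1L,
    path_dist = seg_l * (seq_len(nseg) - 0.5),
    rhalf = rseg / 2, is_spine = 0L)
  model$comp <- rbind(model$comp, newc)
  model$sections <- rbind(model$sections,
                          data.frame(section = newc$section[1], type = 2L,
                                     first_comp = idx[1], last_comp = idx[nseg],
                                     length = length))
  model$axon_comps <- idx
  model
}

#' Remove the axon stub added by [add_axon_stub()]
#' @param model a `cable_model` whose axon was appended last
#' @return the model without axonal compartments
#' @export
remove_axon_stub <- function(model) {
  idx <- model$axon_comps
  if (is.null(idx)) stop("no axon stub to remove")
  if (max(idx) != nrow(model$comp)) stop("axon is not the last block of compartments")
  model$comp <- model$comp[-idx, ]
  model$sections <- model$sections[model$sections$type != 2L, ]
  model$axon_comps <- NULL
  model
}

#' Reference active parameter set for synthetic spiking cells
#'
#' A hand-tuned 29-parameter vector that produces regular ~10-12 Hz firing
#' with narrow spikes (half-width well under 1.4 ms), a fast
#' after-hyperpolarisation and mild adaptation on small synthetic cells
#' under a ~0.3 nA somatic step. Axonal transient Na+ and fast K+ densities
#' are set to the magnitudes typical of detailed cortical models (4.9 and
#' 1.9 S/cm^2). Used as the planted ground truth for closed-loop
#' multi-objective fitting tests.
#'
#' @param channel_set channel archetypes
#' @return an [active_params()] vector
#' @export
example_active_params <- function(channel_set = default_channel_set()) {
  gt <- setNames(numeric(29), active_param_names(channel_set))
  gt[c("soma.g_na_t", "soma.g_k_fast", "soma.g_k_slow", "soma.g_k_m")] <-
    c(0.33, 0.28, 0.001, 8e-4)
  gt[c("soma.g_sk", "soma.g_ca_hva", "soma.g_ca_lva", "soma.g_ih",
       "soma.g_na_p")] <- c(0.008, 5e-5, 5e-5, 2e-5, 1e-4)
  gt[c("axon.g_na_t", "axon.g_k_fast", "axon.g_k_slow", "axon.g_k_m")] <-
    c(4.9, 1.9, 0.019, 4e-4)
  gt[c("axon.g_sk", "axon.g_ca_hva", "axon.g_ca_lva", "axon.g_ih",
       "axon.g_na_p")] <- c(0.004, 2e-5, 2e-5, 1e-5, 5e-5)
  gt[c("soma.na_shift_act", "soma.na_shift_inact",
       "axon.na_shift_act", "axon.na_shift_inact")] <- 0
  gt[c("soma.na_tau_scale", "axon.na_tau_scale")] <- 1
  gt[c("soma.ca_tau", "axon.ca_tau")] <- 80
  gt[c("soma.ca_influx", "axon.ca_influx")] <- 2.5
  gt["e_leak"] <- -83.5
  active_params(gt, channel_set)
}

#' A small synthetic spiking cell for active-model work
#'
#' Convenience constructor: a compact rat-like synthetic tree (8 basal
#' terminals) with spine correction and a 60-um axon stub, suitable for
#' spike-train feature extraction and multi-objective fitting exercises.
#'
#' @param seed morphology seed
#' @param params passive parameters
#' @return a `cable_model`
#' @export
small_spiking_cell <- function(seed = 2, params = passive_params()) {
  rec <- tree_recipe("rat", n_terminals_mean = 8, n_terminals_sd = 0.1,
                     terminal_len_mean = 120, apical_n_oblique = 2,
                     seed = seed)
  mod <- build_cable_model(generate_morphology(rec), params)
  mod <- apply_spine_correction(mod)
  add_axon_stub(mod)
}
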