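#' Time of peak synaptic conductance
#'
#' t_peak = tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay /
#' tau_rise), the maximum of the double-exponential waveform.
#' @param kin a [synapse_kinetics()] object
#' @return time of the conductance peak, ms
#' @export
conductance_tpeak <- function(kin) {
  kin$tau_rise * kin$tau_decay / (kin$tau_decay - kin$tau_rise) *
    log(kin$tau_decay / kin$tau_rise)
}

#' Normalisation factor of the double-exponential conductance
#'
#' N = 1 / (exp(-t_peak/tau_decay) - exp(-t_peak/tau_rise)), so that the
#' waveform's maximum equals B * g_max.
#' @param kin a [synapse_kinetics()] object
#' @return the dimensionless normalisation factor
#' @export
conductance_norm <- function(kin) {
  tp <- conductance_tpeak(kin)
  1 / (exp(-tp / kin$tau_decay) - exp(-tp / kin$tau_rise))
}

#' Magnesium-block factor B(V)
#'
#' Jahr-Stevens form B = 1 / (1 + n * Mg * exp(-gamma * V)): the fraction of
#' NMDA conductance available at voltage V. Strictly increasing in V,
#' strictly decreasing in Mg, with B in (0, 1].
#'
#' @param kin a voltage-dependent [synapse_kinetics()] object
#' @param v membrane potential, mV (vectorised)
#' @return B in (0, 1]
#' @export
mg_block <- function(kin, v) {
  if (!isTRUE(kin$voltage_dependent)) {
    stop("mg_block requires a voltage-dependent synapse")
  }
  1 / (1 + kin$n * kin$mg * exp(-kin$gamma * v))
}

#' Synaptic conductance waveform
#'
#' g(t) = B(V) * g_max * N * (exp(-t/tau_decay) - exp(-t/tau_rise)); B = 1
#' for voltage-independent synapses.
#'
#' @param kin a [synapse_kinetics()] object
#' @param t time since activation, ms (vectorised, >= 0)
#' @param v membrane potential, mV (used only when voltage dependent)
#' @return conductance, nS
#' @export
conductance_waveform <- function(kin, t, v = 0) {
  stopifnot(all(t >= 0))
  b <- if (isTRUE(kin$voltage_dependent)) mg_block(kin, v) else 1
  b * kin$g_max * conductance_norm(kin) *
    (exp(-t / kin$tau_decay) - exp(-t / kin$tau_rise))
}

#' Synaptic current
#'
#' I = g(t, V) * (V - E_syn): negative (inward) for V below the reversal.
#' @inheritParams conductance_waveform
#' @return current, nA
#' @export
synaptic_current <- function(kin, v, t) {
  conductance_waveform(kin, t, v) * 1e-3 * (v - kin$e_syn)
}

#' Dendritic spine geometry
#'
#' The default is the prototypical human L3 spine: head membrane area
#' 2.8 um^2, neck a cylinder of length 1.35 um and diameter 0.25 um.
#'
#' @param head_area spine-head membrane area, um^2
#' @param neck_length spine-neck length, um
#' @param neck_diameter spine-neck diameter, um
#' @return an object of class `spine_geometry`
#' @export
spine_geometry <- function(head_area = 2.8, neck_length = 1.35,
                           neck_diameter = 0.25) {
  stopifnot(head_area > 0, neck_length > 0, neck_diameter > 0)
  structure(list(head_area = head_area, neck_length = neck_length,
                 neck_diameter = neck_diameter), class = "spine_geometry")
}

#' Spine neck axial resistance
#'
#' R_neck = 4 * R_a * L / (pi * d^2), converted to MOhm. With the
#' prototypical human spine and R_a of 200-300 Ohm*cm this gives the
#' 50-80 MOhm band.
#'
#' @param geom a [spine_geometry()] object
#' @param r_a axial resistivity of the neck cytoplasm, Ohm*cm
#' @return neck resistance, MOhm
#' @export
neck_resistance <- function(geom, r_a) {
  if (geom$neck_diameter <= 0) stop("domain error: zero neck diameter")
  .raxial_MOhm(r_a, geom$neck_length, geom$neck_diameter)
}
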