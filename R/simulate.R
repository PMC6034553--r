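#' Two-state kinetic synapse parameters
#'
#' Double-exponential conductance g(t) = B * g_max * N * (exp(-t/tau_decay) -
#' exp(-t/tau_rise)), normalised so the peak equals B * g_max at t_peak.
#' For NMDA-type synapses the block factor B(V) follows the Jahr-Stevens
#' magnesium-block form; for AMPA-type synapses B = 1.
#'
#' @param g_max peak conductance, nS
#' @param tau_rise,tau_decay rise and decay time constants, ms
#'   (tau_decay > tau_rise > 0)
#' @param e_syn synaptic reversal potential, mV
#' @param voltage_dependent logical; TRUE for NMDA-type magnesium block
#' @param gamma Mg-block steepness, 1/mV
#' @param n Mg sensitivity, 1/mM
#' @param mg extracellular magnesium concentration, mM
#' @return an object of class `synapse_kinetics`
#' @export
synapse_kinetics <- function(g_max, tau_rise, tau_decay, e_syn = 0,
                             voltage_dependent = FALSE,
                             gamma = 0.0771, n = 0.28, mg = 1) {
  if (tau_rise <= 0 || tau_decay <= tau_rise) {
    stop("domain error: need tau_decay > tau_rise > 0")
  }
  stopifnot(g_max >= 0)
  if (voltage_dependent) stopifnot(gamma > 0, n > 0, mg >= 0)
  structure(list(g_max = g_max, tau_rise = tau_rise, tau_decay = tau_decay,
                 e_syn = e_syn, voltage_dependent = voltage_dependent,
                 gamma = gamma, n = n, mg = mg),
            class = "synapse_kinetics")
}

#' AMPA and NMDA kinetics of human L2/L3 excitatory synapses
#'
#' The per-contact conductances and kinetics estimated for human
#' L2/L3-to-L2/L3 connections: AMPA with tau 0.3/1.8 ms, and voltage-dependent
#' NMDA with tau 8.02/34.99 ms, gamma = 0.0771 1/mV, n = 0.28 1/mM at 1 mM
#' Mg2+. `ampa_pair` carries the 0.88 nS per-contact conductance fitted from
#' connected pairs; the composite-EPSP fit gives AMPA 0.73 nS (0.13 nS under
#' AMPA block) and NMDA 1.31 nS.
#'
#' @return a named list of [synapse_kinetics()] objects
#'   (`ampa_pair`, `ampa`, `ampa_blocked`, `nmda`)
#' @export
default_synapse_kinetics <- function() {
  list(ampa_pair = synapse_kinetics(0.88, 0.3, 1.8),
       ampa = synapse_kinetics(0.73, 0.3, 1.8),
       ampa_blocked = synapse_kinetics(0.13, 0.3, 1.8),
       nmda = synapse_kinetics(1.31, 8.02, 34.99, voltage_dependent = TRUE))
}

# Build one engine synapse row from kinetics
.syn_row <- function(comp, kin, onset = 0, g_max = kin$g_max) {
  c(comp - 1L, g_max * 1e-3, kin$tau_rise, kin$tau_decay,
    conductance_norm(kin), kin$e_syn, onset,
    as.numeric(kin$voltage_dependent), kin$gamma, kin$n * kin$mg)
}

#' Assemble a synapse table for simulation
#'
#' @param comp integer compartment indices (1-based)
#' @param kinetics a single [synapse_kinetics()] or a list, recycled over comp
#' @param onset activation times, ms (recycled)
#' @param g_max optional per-synapse peak conductance override, nS
#' @return a numeric matrix in engine layout (one row per synapse)
#' @export
synapse_table <- function(comp, kinetics, onset = 0, g_max = NULL) {
  if (inherits(kinetics, "synapse_kinetics")) kinetics <- list(kinetics)
  nsyn <- max(length(comp), length(kinetics), length(onset))
  comp <- rep_len(comp, nsyn); onset <- rep_len(onset, nsyn)
  kinetics <- rep_len(kinetics, nsyn)
  if (!is.null(g_max)) g_max <- rep_len(g_max, nsyn)
  rows <- t(vapply(seq_len(nsyn), function(i) {
    .syn_row(comp[i], kinetics[[i]], onset[i],
             if (is.null(g_max)) kinetics[[i]]$g_max else g_max[i])
  }, numeric(10)))
  rows
}

#' Simulate a compartmental model
#'
#' Integrates the cable equation on the model tree with backward Euler
#' (implicit, unconditionally stable) using a single-pass tree-ordered
#' elimination per step. Current steps, kinetic synapses and, if present,
#' the model's active channels are included.
#'
#' @param model a `cable_model`
#' @param duration simulation length, ms
#' @param dt time step, ms (default 0.025)
#' @param stimuli data.frame with columns `comp, onset, offset, amp` (nA),
#'   or NULL
#' @param synapses matrix from [synapse_table()], or NULL
#' @param record integer compartment indices to record (default: soma)
#' @param v_init initial voltage, mV (default: resting potential)
#' @return list of class `sim_result` with `t` (ms) and `v` (matrix, one
#'   column per recorded site, named `c<index>`)
#' @export
simulate_model <- function(model, duration, dt = 0.025, stimuli = NULL,
                           synapses = NULL, record = 1L,
                           v_init = model$params$e_rest) {
  stopifnot(inherits(model, "cable_model"), dt > 0, duration > 0)
  n <- nrow(model$comp)
  if (is.null(stimuli)) {
    stim <- matrix(numeric(0), ncol = 4)
  } else {
    if (any(stimuli$comp < 1 | stimuli$comp > n)) stop("stimulus site does not exist")
    stim <- cbind(stimuli$comp - 1L, stimuli$onset, stimuli$offset, stimuli$amp)
  }
  if (is.null(synapses)) synapses <- matrix(numeric(0), ncol = 10)
  if (nrow(synapses) && any(synapses[, 1] < 0 | synapses[, 1] >= n)) {
    stop("synapse site does not exist")
  }
  if (any(record < 1 | record > n)) stop("recording site does not exist")
  chan <- model$channels %||% matrix(numeric(0), ncol = 21)
  # compartments added after apply_active_params (spines, axon) carry no
  # calcium pool; pad the per-compartment vectors to the current size
  pad <- function(x) { length(x) <- n; x[is.na(x)] <- 0; x }
  ca_tau <- pad(model$ca$tau %||% numeric(n))
  ca_influx <- pad(model$ca$influx %||% numeric(n))
  ca_rest <- model$ca$rest %||% 1e-4
  res <- engine_simulate(as.integer(model$comp$parent - 1L), model$comp$ga,
                         model$comp$cm, model$comp$gl, model$comp$el,
                         model$comp$area, synapses, stim, chan,
                         ca_tau, ca_influx, ca_rest,
                         dt, duration, v_init, as.integer(record - 1L))
  colnames(res$v) <- paste0("c", record)
  res$dt <- dt
  res$sites <- record
  class(res) <- "sim_result"
  res
}

#' Extract one voltage trace from a simulation result
#'
#' @param sim a `sim_result`
#' @param site recorded compartment index (default: first recorded)
#' @return data.frame with columns `t_ms`, `v_mv`
#' @export
get_trace <- function(sim, site = sim$sites[1]) {
  j <- match(site, sim$sites)
  if (is.na(j)) stop("site ", site, " was not recorded")
  data.frame(t_ms = sim$t, v_mv = sim$v[, j])
}

#' Write a voltage trace to a two-column CSV
#'
#' The site is stored in a `# site:` metadata header line.
#' @param trace data.frame with `t_ms`, `v_mv`
#' @param path output path
#' @param site site label written to the header
#' @return `path`, invisibly
#' @export
write_trace_csv <- function(trace, path, site = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# site: %s", site), con)
  writeLines("t_ms,v_mv", con)
  writeLines(sprintf("%.10g,%.10g", trace$t_ms, trace$v_mv), con)
  invisible(path)
}

#' Read a voltage trace written by [write_trace_csv()]
#' @param path CSV path
#' @return data.frame with `t_ms`, `v_mv`; site label in attribute `"site"`
#' @export
read_trace_csv <- function(path) {
  first <- readLines(path, n = 1L)
  site <- if (startsWith(first, "# site:")) trimws(sub("# site:", "", first)) else NA
  df <- read.table(path, header = TRUE, sep = ",", comment.char = "#")
  attr(df, "site") <- site
  df
}

#' Steady-state transfer-resistance matrix
#'
#' R[i, j] is the steady-state voltage at site j per unit steady current
#' injected at site i (MOhm); the diagonal is the input resistance. Only
#' defined for passive models; by reciprocity the matrix is symmetric.
#'
#' @param model a passive `cable_model`
#' @param sites integer compartment indices
#' @return a `length(sites)` square matrix in MOhm
#' @export
resistance_map <- function(model, sites) {
  stopifnot(inherits(model, "cable_model"))
  if (!is.null(model$channels) && nrow(model$channels) > 0) {
    stop("resistance_map is defined for passive models only")
  }
  n <- nrow(model$comp)
  if (any(sites < 1 | sites > n)) stop("site does not exist")
  parent <- as.integer(model$comp$parent - 1L)
  R <- matrix(0, length(sites), length(sites))
  for (i in seq_along(sites)) {
    inj <- numeric(n)
    inj[sites[i]] <- 1
    v <- engine_steady(parent, model$comp$ga, model$comp$gl, inj)
    R[i, ] <- v[sites]
  }
  dimnames(R) <- list(paste0("c", sites), paste0("c", sites))
  R
}

#' Input resistance at one site (MOhm)
#' @param model a passive `cable_model`
#' @param site compartment index
#' @export
input_resistance <- function(model, site) {
  as.numeric(resistance_map(model, site))
}
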