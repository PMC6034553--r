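#' Shape index (rise time, half-width) of an EPSP
#'
#' The rise time is measured from 10% to 90% of the peak amplitude on the
#' rising phase and the half-width is the duration spent above 50% of the
#' peak, both relative to the pre-onset baseline and with linear
#' interpolation between samples.
#'
#' @param trace data.frame with `t_ms`, `v_mv` containing a single EPSP-like
#'   transient
#' @param onset stimulus onset, ms; samples at `t <= onset` define the
#'   baseline (the first sample is used when none are available)
#' @return list with `rise_time` and `half_width` (ms); warns when
#'   `half_width <= 0.5 * rise_time` (physically implausible for an EPSP)
#' @export
shape_index <- function(trace, onset = 0) {
  t <- trace$t_ms; v <- trace$v_mv
  base <- if (any(t <= onset)) mean(v[t <= onset]) else v[1]
  dv <- v - base
  pk <- which.max(dv)
  if (dv[pk] <= 0) stop("analysis error: non-positive EPSP peak")
  amp <- dv[pk]
  t10 <- .cross_time(t, dv, 0.1 * amp, upto = pk, rising = TRUE)
  t90 <- .cross_time(t, dv, 0.9 * amp, upto = pk, rising = TRUE)
  t50a <- .cross_time(t, dv, 0.5 * amp, upto = pk, rising = TRUE)
  t50b <- .cross_time(t, dv, 0.5 * amp, from = pk, rising = FALSE)
  si <- list(rise_time = t90 - t10, half_width = t50b - t50a)
  if (si$half_width <= 0.5 * si$rise_time) {
    warning("half_width <= 0.5 * rise_time: implausible EPSP shape")
  }
  si
}

# interpolated threshold-crossing time; rising scans up to the peak, falling
# scans after it
.cross_time <- function(t, dv, level, upto = length(dv), from = 1L, rising = TRUE) {
  if (rising) {
    i <- which(dv[seq_len(upto)] >= level)
    if (!length(i)) return(t[upto])
    i <- i[1]
    if (i == 1L) return(t[1])
    j <- i - 1L
  } else {
    rel <- which(dv[from:length(dv)] < level)
    if (!length(rel)) return(t[length(dv)])
    i <- from + rel[1] - 1L
    j <- i - 1L
  }
  t[j] + (t[i] - t[j]) * (level - dv[j]) / (dv[i] - dv[j])
}

#' Membrane time constant by peeling an EPSP tail
#'
#' Fits a straight line to ln(V - baseline) over the tail window by least
#' squares; the negative inverse slope is the slowest (membrane) time
#' constant.
#'
#' @param trace data.frame with `t_ms`, `v_mv`
#' @param tail_window numeric length-2, time window (ms) over the decaying tail
#' @param baseline baseline voltage subtracted before taking logs (default 0,
#'   i.e. the trace is already baseline-subtracted)
#' @return tau_m in ms
#' @export
peel_time_constant <- function(trace, tail_window, baseline = 0) {
  sel <- trace$t_ms >= tail_window[1] & trace$t_ms <= tail_window[2]
  if (sum(sel) < 3) stop("analysis error: tail window contains too few samples")
  v <- trace$v_mv[sel] - baseline
  if (any(v <= 0)) stop("analysis error: tail not strictly positive over the window")
  fit <- lm(log(v) ~ trace$t_ms[sel])
  tau <- -1 / coef(fit)[[2]]
  if (tau <= 0) stop("analysis error: non-decaying tail")
  tau
}

#' Theoretical shape-index curve of a model
#'
#' Activates a single AMPA synapse at each requested dendritic compartment in
#' turn and measures the somatic EPSP shape index, reproducing the classical
#' rise-time/half-width localisation curve: proximal inputs are fast and
#' narrow, distal inputs slow and broad.
#'
#' @param model a passive `cable_model`
#' @param ampa_kin AMPA [synapse_kinetics()] (conductance value is irrelevant
#'   to the shape index; only kinetics matter)
#' @param sites compartments to probe (default: all dendritic compartments)
#' @param duration,dt simulation settings, ms
#' @return data.frame with `comp`, `path_dist`, `subtree`, `rise_time`,
#'   `half_width`
#' @export
build_shape_index_curve <- function(model, ampa_kin = default_synapse_kinetics()$ampa,
                                    sites = dendritic_comps(model),
                                    duration = 100, dt = 0.025) {
  onset <- 2
  out <- lapply(sites, function(s) {
    sim <- simulate_model(model, duration, dt,
                          synapses = synapse_table(s, ampa_kin, onset),
                          record = 1L)
    si <- shape_index(get_trace(sim), onset = onset)
    data.frame(comp = s, path_dist = model$comp$path_dist[s],
               subtree = c("3" = "basal", "4" = "apical")[as.character(model$comp$type[s])],
               rise_time = si$rise_time, half_width = si$half_width)
  })
  do.call(rbind, out)
}

#' Putative synapse locations from a shape-index curve
#'
#' All probed sites whose (rise time, half-width) lies within Euclidean
#' distance `radius` of the experimental shape index in the (ms, ms) plane.
#'
#' @param curve a [build_shape_index_curve()] result
#' @param experimental_si list or vector with `rise_time` and `half_width` (ms)
#' @param radius acceptance radius, ms (default 1)
#' @return the matching rows of `curve` (possibly zero rows)
#' @export
putative_locations <- function(curve, experimental_si, radius = 1) {
  stopifnot(radius > 0)
  d <- sqrt((curve$rise_time - experimental_si$rise_time)^2 +
            (curve$half_width - experimental_si$half_width)^2)
  curve[d <= radius, ]
}

#' Fit a shared per-contact AMPA conductance to a somatic EPSP
#'
#' For each repeat, `contacts_per_connection` sites are sampled uniformly
#' without replacement from the pool, activated simultaneously, and a single
#' shared peak conductance is fitted by least squares on the full somatic
#' waveform (derivative-free 1-D minimisation). The target must be
#' baseline-aligned (deviation from rest, mV) with the synapses activated at
#' `onset`.
#'
#' @param model a passive `cable_model`
#' @param target_epsp data.frame `t_ms`, `v_mv` (baseline-aligned, mV)
#' @param site_pool candidate compartments (e.g. from [putative_locations()])
#' @param contacts_per_connection synaptic contacts per connection (default 5)
#' @param repeats number of random contact draws
#' @param seed RNG seed
#' @param kinetics AMPA kinetics (its `g_max` is ignored)
#' @param onset synapse activation time, ms
#' @param g_max_range search interval for the shared conductance, nS
#' @param dt integration step, ms
#' @return list of class `connection_fit` with per-repeat `g_ampa`, `rmsd`,
#'   `sites`, and summary `g_mean`, `g_sd`
#' @export
fit_connection <- function(model, target_epsp, site_pool,
                           contacts_per_connection = 5, repeats = 100,
                           seed = 1, kinetics = default_synapse_kinetics()$ampa,
                           onset = 2, g_max_range = c(0, 10), dt = 0.025) {
  if (length(site_pool) < contacts_per_connection) {
    stop("site_pool smaller than contacts_per_connection")
  }
  set.seed(seed)
  dur <- max(target_epsp$t_ms)
  fits <- lapply(seq_len(repeats), function(r) {
    sites <- sample(site_pool, contacts_per_connection)
    obj <- function(g) {
      syn <- synapse_table(sites, kinetics, onset, g_max = rep(g, length(sites)))
      sim <- simulate_model(model, dur, dt, synapses = syn, record = 1L)
      vi <- approx(sim$t, sim$v[, 1] - model$params$e_rest,
                   xout = target_epsp$t_ms, rule = 2)$y
      sqrt(mean((vi - target_epsp$v_mv)^2))
    }
    opt <- optimize(obj, g_max_range, tol = 1e-3)
    list(g_ampa = opt$minimum, rmsd = opt$objective, sites = sites)
  })
  g <- vapply(fits, `[[`, 0, "g_ampa")
  structure(list(fits = fits, g_ampa = g, rmsd = vapply(fits, `[[`, 0, "rmsd"),
                 g_mean = mean(g), g_sd = sd(g),
                 repeats = repeats, seed = seed),
            class = "connection_fit")
}

#' Two-stage fit of NMDA kinetics and conductances to composite EPSPs
#'
#' Stage 1: for each seed, a synapse count is drawn from `n_syn_range` and
#' that many sites are sampled from `region`; the NMDA kinetics (tau_rise,
#' tau_decay, gamma), the NMDA peak conductance and a residual AMPA
#' conductance are fitted (Nelder-Mead on a bounded transform) against the
#' EPSP recorded under AMPA block. Stage 2: with stage-1 parameters frozen,
#' the unblocked AMPA conductance is fitted against the control EPSP under
#' the constraint g_AMPA >= 5 * g_AMPA_blocked. Candidates are ranked by the
#' summed RMSD against both targets.
#'
#' @param model a passive `cable_model`
#' @param blocked_epsp,unblocked_epsp data.frames `t_ms`, `v_mv`
#'   (baseline-aligned, mV, shared time base)
#' @param region candidate compartments for synapse placement
#' @param n_syn_range integer range of synapse counts (default 15..30)
#' @param n_seeds number of placement seeds (the full-scale default of the
#'   procedure is 60,000; reduced profiles are supplied by the caller)
#' @param seed master RNG seed
#' @param onset synapse activation time, ms
#' @param bounds stage-1 parameter bounds: list with `tau_rise`, `tau_decay`,
#'   `gamma`, `g_nmda`, `g_ampa_blocked` (each length-2)
#' @param top_fraction fraction of candidates returned (default all)
#' @param maxit Nelder-Mead iteration budget per seed
#' @param dt integration step, ms
#' @return list of class `nmda_fit_set`: ranked `fits` (each with sites,
#'   parameters, `rmsd_blocked`, `rmsd_unblocked`, `flagged`), and
#'   `best_typical`, the fit among the best five whose parameters are closest
#'   to the mean of the top 100 (z-scored over the fit set)
#' @export
fit_nmda_kinetics <- function(model, blocked_epsp, unblocked_epsp, region,
                              n_syn_range = c(15, 30), n_seeds = 20, seed = 1,
                              onset = 2,
                              bounds = list(tau_rise = c(1, 20),
                                            tau_decay = c(20, 100),
                                            gamma = c(0.03, 0.12),
                                            g_nmda = c(0, 4),
                                            g_ampa_blocked = c(0, 2)),
                              top_fraction = 1, maxit = 150, dt = 0.025) {
  stopifnot(length(region) >= 1)
  set.seed(seed)
  dur <- max(blocked_epsp$t_ms)
  rest <- model$params$e_rest
  lo <- vapply(bounds, `[`, 0, 1L); hi <- vapply(bounds, `[`, 0, 2L)
  to_par <- function(u) lo + (hi - lo) / (1 + exp(-u))
  rmsd_of <- function(sim_v, target) {
    vi <- approx(seq(0, dur, length.out = length(sim_v)), sim_v - rest,
                 xout = target$t_ms, rule = 2)$y
    sqrt(mean((vi - target$v_mv)^2))
  }
  sim_response <- function(sites, tr, td, gam, g_n, g_a) {
    nm <- synapse_kinetics(g_n, tr, td, voltage_dependent = TRUE, gamma = gam)
    am <- synapse_kinetics(g_a, 0.3, 1.8)
    syn <- rbind(synapse_table(sites, nm, onset), synapse_table(sites, am, onset))
    simulate_model(model, dur, dt, synapses = syn, record = 1L)$v[, 1]
  }
  fits <- lapply(seq_len(n_seeds), function(sd_i) {
    n_syn <- sample(seq(n_syn_range[1], n_syn_range[2]), 1)
    sites <- region[sample.int(length(region), n_syn, replace = length(region) < n_syn)]
    stage1 <- function(u) {
      p <- to_par(u)
      if (p[2] <= p[1]) return(1e6)
      rmsd_of(sim_response(sites, p[1], p[2], p[3], p[4], p[5]), blocked_epsp)
    }
    u0 <- rnorm(5, 0, 0.5)
    opt <- optim(u0, stage1, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-6))
    p <- to_par(opt$par)
    names(p) <- names(bounds)
    # stage 2: only the unblocked AMPA conductance is free, >= 5x blocked
    g_lo <- 5 * p[["g_ampa_blocked"]]
    stage2 <- function(g) {
      rmsd_of(sim_response(sites, p[1], p[2], p[3], p[4], g), unblocked_epsp)
    }
    opt2 <- optimize(stage2, c(g_lo, max(g_lo + 1e-6, 6)), tol = 1e-3)
    flagged <- opt2$minimum <= g_lo + 1e-3 &&
      stage2(g_lo) <= opt2$objective + 1e-9
    list(sites = sites, n_syn = n_syn,
         tau_rise = p[["tau_rise"]], tau_decay = p[["tau_decay"]],
         gamma = p[["gamma"]], g_nmda = p[["g_nmda"]],
         g_ampa_blocked = p[["g_ampa_blocked"]], g_ampa = opt2$minimum,
         rmsd_blocked = opt$value, rmsd_unblocked = opt2$objective,
         rmsd_total = opt$value + opt2$objective, flagged = flagged)
  })
  ord <- order(vapply(fits, `[[`, 0, "rmsd_total"))
  fits <- fits[ord]
  keep <- max(1L, ceiling(top_fraction * length(fits)))
  pmat <- t(vapply(fits, function(f) {
    c(f$tau_rise, f$tau_decay, f$gamma, f$g_nmda, f$g_ampa_blocked)
  }, numeric(5)))
  top100 <- pmat[seq_len(min(100L, nrow(pmat))), , drop = FALSE]
  mu <- colMeans(top100)
  sc <- apply(pmat, 2, sd); sc[!is.finite(sc) | sc == 0] <- 1
  z <- sweep(sweep(pmat, 2, mu), 2, sc, "/")
  best5 <- seq_len(min(5L, nrow(pmat)))
  best_typical <- fits[[which.min(rowSums(z[best5, , drop = FALSE]^2))]]
  structure(list(fits = fits[seq_len(keep)], best_typical = best_typical,
                 n_seeds = n_seeds, seed = seed),
            class = "nmda_fit_set")
}
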