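#' Recipe for synthetic dendritic trees
#'
#' Seedable generator settings emulating the gross statistics of cortical
#' L2/L3 pyramidal dendritic arbors. The human-like style draws the basal
#' terminal count from N(44.5, 8.1) and uses electrotonically elongated
#' terminal branches; the rat-like style draws from N(31.4, 8.6) with
#' shorter terminals. All sampled lengths and diameters are truncated
#' strictly positive.
#'
#' @param style `"human"` or `"rat"` (sets all defaults), or pass fields
#'   explicitly
#' @param n_terminals_mean,n_terminals_sd basal terminal count distribution
#' @param terminal_len_mean,terminal_len_sd terminal branch length, um
#' @param internal_len_mean,internal_len_sd internal branch length, um
#' @param stem_diam basal stem diameter, um
#' @param taper child/parent diameter ratio at branch points
#' @param min_diam diameter floor, um
#' @param soma_radius um
#' @param apical_trunk_len,apical_n_oblique apical trunk length (um) and
#'   number of oblique/tuft terminal branches
#' @param seed RNG seed
#' @return an object of class `tree_recipe`
#' @export
tree_recipe <- function(style = c("human", "rat"),
                        n_terminals_mean = NULL, n_terminals_sd = NULL,
                        terminal_len_mean = NULL, terminal_len_sd = NULL,
                        internal_len_mean = 35, internal_len_sd = 10,
                        stem_diam = 2, taper = 0.8, min_diam = 0.4,
                        soma_radius = NULL,
                        apical_trunk_len = 350, apical_n_oblique = 6,
                        seed = 1) {
  style <- match.arg(style)
  def <- if (style == "human") {
    list(ntm = 44.5, nts = 8.1, tlm = 180, tls = 40, sr = 8)
  } else {
    list(ntm = 31.4, nts = 8.6, tlm = 110, tls = 30, sr = 6.5)
  }
  structure(list(style = style,
                 n_terminals_mean = n_terminals_mean %||% def$ntm,
                 n_terminals_sd = n_terminals_sd %||% def$nts,
                 terminal_len_mean = terminal_len_mean %||% def$tlm,
                 terminal_len_sd = terminal_len_sd %||% def$tls,
                 internal_len_mean = internal_len_mean,
                 internal_len_sd = internal_len_sd,
                 stem_diam = stem_diam, taper = taper, min_diam = min_diam,
                 soma_radius = soma_radius %||% def$sr,
                 apical_trunk_len = apical_trunk_len,
                 apical_n_oblique = apical_n_oblique,
                 seed = seed), class = "tree_recipe")
}

# positive truncated normal draw
.rtnorm <- function(n, mean, sd, lo = .Machine$double.eps) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lo)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic morphology
#'
#' Recursive branching process targeting the drawn basal terminal count:
#' a terminal quota is split binomially at every branch point, internal
#' branches draw their lengths from the internal distribution and terminal
#' branches from the (elongated) terminal distribution, with diameters
#' tapering geometrically to a floor. A simple apical trunk with oblique
#' terminal branches is added. The generated tree has exactly the drawn
#' number of basal terminals, satisfies all morphology invariants and is
#' byte-identical under a fixed seed.
#'
#' @param recipe a [tree_recipe()]
#' @return a [morphology()] object; the drawn basal terminal count is in
#'   `attr(, "n_basal_terminals")`
#' @export
generate_morphology <- function(recipe) {
  set.seed(recipe$seed)
  n_term <- max(2L, as.integer(round(rnorm(1, recipe$n_terminals_mean,
                                           recipe$n_terminals_sd))))
  rows <- list(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                          r = recipe$soma_radius, parent = -1))
  nid <- 1L
  add_point <- function(type, x, y, z, r, parent) {
    nid <<- nid + 1L
    rows[[length(rows) + 1L]] <<- data.frame(id = nid, type = type, x = x,
                                             y = y, z = z, r = r, parent = parent)
    nid
  }
  # grow a branch of given length from a parent point, ~10 um sample spacing
  grow_branch <- function(parent_id, type, x0, y0, z0, dir, len, diam) {
    npts <- max(2L, ceiling(len / 10))
    step <- len / npts
    p <- parent_id
    for (i in seq_len(npts)) {
      dir <- dir + rnorm(3, 0, 0.08)
      dir <- dir / sqrt(sum(dir^2))
      x0 <- x0 + dir[1] * step; y0 <- y0 + dir[2] * step; z0 <- z0 + dir[3] * step
      p <- add_point(type, x0, y0, z0, diam / 2, p)
    }
    list(id = p, x = x0, y = y0, z = z0, dir = dir)
  }
  grow_subtree <- function(parent_id, type, x0, y0, z0, dir, quota, diam) {
    if (quota == 1L) {
      len <- .rtnorm(1, recipe$terminal_len_mean, recipe$terminal_len_sd, 5)
      grow_branch(parent_id, type, x0, y0, z0, dir, len, diam)
      return(invisible(NULL))
    }
    len <- .rtnorm(1, recipe$internal_len_mean, recipe$internal_len_sd, 5)
    tip <- grow_branch(parent_id, type, x0, y0, z0, dir, len, diam)
    q1 <- min(quota - 1L, max(1L, rbinom(1, quota, 0.5)))
    child_diam <- max(recipe$min_diam, diam * recipe$taper)
    for (q in c(q1, quota - q1)) {
      cdir <- tip$dir + rnorm(3, 0, 0.45)
      cdir <- cdir / sqrt(sum(cdir^2))
      grow_subtree(tip$id, type, tip$x, tip$y, tip$z, cdir, q, child_diam)
    }
    invisible(NULL)
  }
  # basal stems around the soma
  n_stems <- max(3L, min(8L, round(n_term / 7)))
  quota <- rep(n_term %/% n_stems, n_stems)
  extra <- n_term - sum(quota)
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  for (s in seq_len(n_stems)) {
    ang <- 2 * pi * s / n_stems + runif(1, -0.2, 0.2)
    dir <- c(cos(ang), sin(ang), runif(1, -0.3, 0.1))
    dir <- dir / sqrt(sum(dir^2))
    x0 <- dir[1] * recipe$soma_radius
    y0 <- dir[2] * recipe$soma_radius
    z0 <- dir[3] * recipe$soma_radius
    grow_subtree(1L, 3L, x0, y0, z0, dir, quota[s], recipe$stem_diam)
  }
  # apical: straight trunk with oblique terminals branching off
  if (recipe$apical_n_oblique > 0) {
    tr_dir <- c(0, 0, 1)
    seg <- recipe$apical_trunk_len / recipe$apical_n_oblique
    p <- 1L; z0 <- recipe$soma_radius
    diam <- recipe$stem_diam * 1.3
    for (k in seq_len(recipe$apical_n_oblique)) {
      tip <- grow_branch(p, 4L, 0, 0, z0, tr_dir, seg, diam)
      p <- tip$id; z0 <- tip$z
      odir <- c(rnorm(2, 0, 1), runif(1, 0.1, 0.5))
      odir <- odir / sqrt(sum(odir^2))
      len <- .rtnorm(1, recipe$terminal_len_mean * 0.7,
                     recipe$terminal_len_sd * 0.7, 5)
      grow_branch(tip$id, 4L, tip$x, tip$y, tip$z, odir,
                  len, max(recipe$min_diam, diam * recipe$taper))
      diam <- max(recipe$min_diam, diam * 0.95)
    }
  }
  m <- morphology(do.call(rbind, rows))
  attr(m, "n_basal_terminals") <- n_term
  m
}

#' Sample human-like spine geometries
#'
#' Truncated-normal draws of the spine head membrane area (2.88 +/- 1.37
#' um^2), neck length (1.34 +/- 0.50 um) and neck diameter (0.24 +/- 0.08
#' um), all strictly positive.
#'
#' @param n number of spines
#' @param seed RNG seed
#' @return data.frame with `head_area`, `neck_length`, `neck_diameter`
#' @export
sample_spine_geometries <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(head_area = .rtnorm(n, 2.88, 1.37, 0.05),
             neck_length = .rtnorm(n, 1.34, 0.50, 0.05),
             neck_diameter = .rtnorm(n, 0.24, 0.08, 0.02))
}

#' Synthetic connected-pair somatic EPSP
#'
#' Stands in for paired-recording EPSPs: `n_contacts` AMPA contacts are
#' planted on dendritic compartments whose path distances are drawn from the
#' proximal connection territory (140 +/- 78 um, truncated >= 0), activated
#' simultaneously, and the somatic response (baseline-subtracted, mV) is
#' returned with optional additive Gaussian noise. The planted ground truth
#' is returned alongside.
#'
#' @param model a passive `cable_model`
#' @param n_contacts contacts per connection (default 5)
#' @param g_per_contact planted per-contact AMPA conductance, nS
#' @param noise_sd additive Gaussian noise SD, mV
#' @param seed RNG seed
#' @param dist_mean,dist_sd contact path-distance distribution, um
#' @param onset activation time, ms
#' @param duration trace length, ms
#' @return list with `trace` (data.frame `t_ms`, `v_mv`) and `ground_truth`
#'   (sites, conductance, noise, seed)
#' @export
generate_pair_epsp <- function(model, n_contacts = 5, g_per_contact = 0.88,
                               noise_sd = 0, seed = 1,
                               dist_mean = 140, dist_sd = 78,
                               onset = 2, duration = 100) {
  set.seed(seed)
  dend <- dendritic_comps(model)
  dvec <- model$comp$path_dist[dend]
  target_d <- .rtnorm(n_contacts, dist_mean, dist_sd, 0)
  target_d <- pmin(target_d, max(dvec))
  sites <- vapply(target_d, function(td) {
    near <- dend[abs(dvec - td) <= 10]
    if (!length(near)) dend[which.min(abs(dvec - td))] else sample(near, 1)
  }, integer(1))
  kin <- synapse_kinetics(g_per_contact, 0.3, 1.8)
  sim <- simulate_model(model, duration, synapses = synapse_table(sites, kin, onset),
                        record = 1L)
  tr <- get_trace(sim)
  tr$v_mv <- tr$v_mv - model$params$e_rest + rnorm(nrow(tr), 0, noise_sd)
  list(trace = tr,
       ground_truth = list(sites = sites, g_per_contact = g_per_contact,
                           target_distances = target_d, noise_sd = noise_sd,
                           onset = onset, seed = seed))
}

#' Synthetic blocked/unblocked composite EPSP pair for NMDA fitting
#'
#' Stands in for extracellular-stimulation recordings: 15-30 axo-spinous
#' synapses (default 21) are planted in the given region, each with NMDA
#' kinetics from `true_kinetics` plus an AMPA component. The blocked trace
#' uses the residual AMPA conductance (at most a fifth of the full one) with
#' the full NMDA conductance; the unblocked trace uses the full AMPA. Both
#' are baseline-subtracted somatic voltages in mV.
#'
#' @param model a passive `cable_model`
#' @param region candidate compartments
#' @param true_kinetics list with `tau_rise`, `tau_decay`, `gamma`, `g_nmda`,
#'   `g_ampa`, `g_ampa_blocked` (defaults: 8.02 ms, 34.99 ms, 0.0771 1/mV,
#'   1.31 nS, 0.73 nS, 0.13 nS)
#' @param n_syn planted synapse count (default 21)
#' @param noise_sd additive Gaussian noise SD, mV
#' @param seed RNG seed
#' @param onset activation time, ms
#' @param duration trace length, ms
#' @param dt integration step, ms
#' @return list with `blocked`, `unblocked` (data.frames) and `ground_truth`
#' @export
generate_nmda_targets <- function(model, region,
                                  true_kinetics = list(tau_rise = 8.02,
                                                       tau_decay = 34.99,
                                                       gamma = 0.0771,
                                                       g_nmda = 1.31,
                                                       g_ampa = 0.73,
                                                       g_ampa_blocked = 0.13),
                                  n_syn = 21, noise_sd = 0, seed = 1,
                                  onset = 2, duration = 200, dt = 0.025) {
  set.seed(seed)
  stopifnot(true_kinetics$g_ampa_blocked <= true_kinetics$g_ampa / 5)
  sites <- region[sample.int(length(region), n_syn, replace = length(region) < n_syn)]
  nm <- synapse_kinetics(true_kinetics$g_nmda, true_kinetics$tau_rise,
                         true_kinetics$tau_decay, voltage_dependent = TRUE,
                         gamma = true_kinetics$gamma)
  one <- function(g_a) {
    am <- synapse_kinetics(g_a, 0.3, 1.8)
    syn <- rbind(synapse_table(sites, nm, onset), synapse_table(sites, am, onset))
    tr <- get_trace(simulate_model(model, duration, dt, synapses = syn, record = 1L))
    tr$v_mv <- tr$v_mv - model$params$e_rest + rnorm(nrow(tr), 0, noise_sd)
    tr
  }
  list(blocked = one(true_kinetics$g_ampa_blocked),
       unblocked = one(true_kinetics$g_ampa),
       ground_truth = c(true_kinetics, list(sites = sites, n_syn = n_syn,
                                            noise_sd = noise_sd, seed = seed)))
}

#' Synthetic spike-train targets from a ground-truth active model
#'
#' Simulates repeated step-current responses of a known active model with
#' small multiplicative parameter jitter (and additive jitter on the shift
#' parameters), extracts the 17 spike-train features per repeat, and emits
#' their mean and SD as multi-objective targets (with an SD floor). A repeat
#' yielding fewer than two spikes is regenerated with a 30% larger current.
#' The normalised I-F reference is computed from the unjittered ground
#' truth.
#'
#' @param model a passive `cable_model` with an axon stub
#' @param true_params ground-truth [active_params()]
#' @param stim list with `onset`, `offset`, `amp` (nA)
#' @param repeats number of jittered repeats (default 10)
#' @param jitter multiplicative jitter SD on positive parameters (default
#'   0.02); shifts receive additive jitter of `jitter * 25` mV
#' @param seed RNG seed
#' @param if_amps currents for the reference I-F curve, nA (default: a sweep
#'   around `stim$amp`)
#' @param channel_set channel archetypes
#' @param sd_floor SD floor passed to [feature_targets()]
#' @param dt integration step, ms
#' @return list with `targets` ([feature_targets()]), `features` (matrix,
#'   repeats x 17), `if_reference`, `traces` (list), `ground_truth`
#' @export
generate_spike_train_targets <- function(model, true_params, stim,
                                         repeats = 10, jitter = 0.02, seed = 1,
                                         if_amps = NULL,
                                         channel_set = default_channel_set(),
                                         sd_floor = 1e-3, dt = 0.025) {
  set.seed(seed)
  nm <- active_param_names(channel_set)
  true_params <- active_params(unclass(true_params), channel_set)
  m0 <- apply_active_params(model, true_params, channel_set)
  if (is.null(if_amps)) if_amps <- stim$amp * c(0.6, 0.8, 1, 1.3, 1.7, 2.2, 3)
  ifc <- normalize_if_curve(compute_if_curve(m0, if_amps, stim$onset,
                                             stim$offset, dt))
  shift_par <- grepl("shift", nm)
  dur <- stim$offset + 100
  feats <- matrix(NA_real_, repeats, 17, dimnames = list(NULL, spike_feature_names()))
  traces <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    p <- unclass(true_params)
    p[!shift_par] <- p[!shift_par] * exp(rnorm(sum(!shift_par), 0, jitter))
    p[shift_par] <- p[shift_par] + rnorm(sum(shift_par), 0, jitter * 25)
    amp <- stim$amp
    for (try_i in 1:5) {
      mr <- apply_active_params(model, setNames(p, nm), channel_set)
      sim <- simulate_model(mr, dur, dt,
                            stimuli = data.frame(comp = 1, onset = stim$onset,
                                                 offset = stim$offset, amp = amp))
      tr <- get_trace(sim)
      fr <- extract_features(tr, stim$onset, stim$offset, ifc)
      if (is.finite(fr[["mean_frequency"]]) && fr[["mean_frequency"]] >=
          2000 / (stim$offset - stim$onset)) break
      amp <- amp * 1.3 # too few spikes: retry with a larger current
    }
    feats[r, ] <- fr
    traces[[r]] <- tr
  }
  mu <- apply(feats, 2, mean, na.rm = TRUE)
  sg <- apply(feats, 2, sd, na.rm = TRUE)
  sg[is.na(sg)] <- sd_floor
  mu[is.na(mu)] <- 0
  list(targets = feature_targets(mu, sg, sd_floor),
       features = feats, if_reference = ifc, traces = traces,
       ground_truth = list(params = true_params, stim = stim,
                           jitter = jitter, seed = seed))
}
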