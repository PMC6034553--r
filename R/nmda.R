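#' NMDA-spike detection criterion
#'
#' A local dendritic voltage excursion counts as an NMDA spike (plateau
#' potential) when it stays above `v_threshold` for at least `min_duration`.
#'
#' @param v_threshold voltage threshold, mV (default -40)
#' @param min_duration minimum plateau duration, ms (default 20)
#' @return an object of class `nmda_criterion`
#' @export
nmda_criterion <- function(v_threshold = -40, min_duration = 20) {
  stopifnot(min_duration > 0)
  structure(list(v_threshold = v_threshold, min_duration = min_duration),
            class = "nmda_criterion")
}

#' Detect an NMDA spike in a voltage trace
#'
#' TRUE iff some contiguous interval of at least `min_duration` has
#' V > `v_threshold`. Crossing times are linearly interpolated.
#'
#' @param trace data.frame with `t_ms`, `v_mv`
#' @param criterion an [nmda_criterion()]
#' @return list with `spike` (logical), `onset` (ms, NA if none) and
#'   `duration` (ms, longest supra-threshold interval; 0 if none)
#' @export
detect_nmda_spike <- function(trace, criterion = nmda_criterion()) {
  t <- trace$t_ms; v <- trace$v_mv
  above <- v > criterion$v_threshold
  if (!any(above)) return(list(spike = FALSE, onset = NA_real_, duration = 0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- c(onset = NA_real_, duration = 0)
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    t0 <- if (i0 > 1L) {
      t[i0 - 1L] + (t[i0] - t[i0 - 1L]) *
        (criterion$v_threshold - v[i0 - 1L]) / (v[i0] - v[i0 - 1L])
    } else t[1L]
    t1 <- if (i1 < length(t)) {
      t[i1] + (t[i1 + 1L] - t[i1]) *
        (criterion$v_threshold - v[i1]) / (v[i1 + 1L] - v[i1])
    } else t[length(t)]
    if (t1 - t0 > best[["duration"]]) best <- c(onset = t0, duration = t1 - t0)
  }
  list(spike = best[["duration"]] >= criterion$min_duration,
       onset = best[["onset"]], duration = best[["duration"]])
}

# Shaft compartments available for cluster placement: same section as `site`,
# within `span` um of dendritic stretch around it.
.cluster_candidates <- function(model, site, span = 20) {
  comp <- model$comp
  sec <- comp$section[site]
  cand <- which(comp$section == sec & comp$is_spine == 0L &
                abs(comp$path_dist - comp$path_dist[site]) <= span / 2)
  if (!length(cand)) site else cand
}

#' Minimal synapse count for a dendritic NMDA spike
#'
#' Places axo-spinous AMPA+NMDA synapses at uniform random positions within
#' a `span`-um stretch of the branch around `site` (one synapse per spine,
#' on the spine head) and finds the smallest number whose simultaneous
#' activation triggers an NMDA spike at the stem. The placement list is drawn
#' once per call, so the response is monotone in n and a doubling/bisection
#' search is exact.
#'
#' @param model a passive `cable_model`
#' @param site stem compartment of the target branch
#' @param criterion an [nmda_criterion()]
#' @param kinetics list of [synapse_kinetics()] per synapse (default AMPA
#'   0.73 nS + NMDA 1.31 nS)
#' @param span dendritic stretch, um (default 20)
#' @param n_max give up beyond this count (default 200)
#' @param seed placement seed
#' @param duration,dt simulation settings, ms
#' @return list with `n` (integer, NA if no spike at `n_max`), `site`, `seed`
#' @export
min_synapses_for_nmda_spike <- function(model, site, criterion = nmda_criterion(),
                                        kinetics = default_synapse_kinetics()[c("ampa", "nmda")],
                                        span = 20, n_max = 200, seed = 1,
                                        duration = 150, dt = 0.025) {
  if (!model$comp$type[site] %in% c(3L, 4L)) stop("site must be dendritic")
  set.seed(seed)
  cand <- .cluster_candidates(model, site, span)
  placement <- cand[sample.int(length(cand), n_max, replace = TRUE)]
  spikes_at <- function(n) {
    if (n == 0L) return(FALSE)
    ss <- add_spinous_synapses(model, placement[seq_len(n)], kinetics, onset = 2)
    sim <- simulate_model(ss$model, duration, dt, synapses = ss$synapses,
                          record = site)
    detect_nmda_spike(get_trace(sim, site), criterion)$spike
  }
  # doubling to bracket, then bisection (monotone for fixed placement)
  hi <- 1L
  while (hi <= n_max && !spikes_at(hi)) hi <- hi * 2L
  if (hi > n_max) {
    if (!spikes_at(n_max)) {
      return(list(n = NA_integer_, site = site, seed = seed, no_spike = TRUE))
    }
    hi <- n_max
  }
  lo <- hi %/% 2L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  list(n = hi, site = site, seed = seed, no_spike = FALSE)
}

# lowest common ancestor compartment of two compartments
.lca_comp <- function(model, a, b) {
  anc <- function(i) {
    path <- i
    while (model$comp$parent[i] > 0L) {
      i <- model$comp$parent[i]
      path <- c(path, i)
    }
    path
  }
  pa <- anc(a)
  pb <- anc(b)
  inter <- pa[pa %in% pb]
  as.integer(inter[1L])
}

#' Count simultaneously independent NMDA spikes
#'
#' Activates minimal spinous clusters at dendritic terminals simultaneously
#' (common onset t = 0) and searches for the largest terminal set such that
#' (i) every activated terminal sustains its own NMDA spike at its stem and
#' (ii) the peak voltage at every branch point connecting two activated
#' terminals stays below the threshold over the whole window. The default
#' strategy is greedy in order of decreasing local input resistance (a proxy
#' for electrotonic remoteness) with single-swap backtracking; an exhaustive
#' subset search is available for small terminal counts.
#'
#' @param model a passive `cable_model`
#' @param criterion an [nmda_criterion()]
#' @param strategy `"greedy"` (default) or `"exhaustive"`
#' @param terminals candidate terminal compartments (default: all dendritic
#'   terminals with a finite minimal cluster)
#' @param kinetics per-synapse kinetics list
#' @param seed placement seed
#' @param span cluster stretch, um
#' @param duration,dt simulation settings, ms
#' @param n_max per-terminal synapse-count cap
#' @param max_backtrack simulation budget for the backtracking stage
#' @return list of class `independence_report`: `count`, `active_terminals`,
#'   `cluster_sizes`, `branch_point_peaks` (data.frame per checked pair), and
#'   the per-terminal minimal counts
#' @export
count_independent_nmda_spikes <- function(model, criterion = nmda_criterion(),
                                          strategy = c("greedy", "exhaustive"),
                                          terminals = NULL,
                                          kinetics = default_synapse_kinetics()[c("ampa", "nmda")],
                                          seed = 1, span = 20,
                                          duration = 150, dt = 0.025,
                                          n_max = 200, max_backtrack = 40) {
  strategy <- match.arg(strategy)
  if (is.null(terminals)) terminals <- terminal_comps(model)
  nmin <- vapply(seq_along(terminals), function(i) {
    res <- min_synapses_for_nmda_spike(model, terminals[i], criterion, kinetics,
                                       span, n_max, seed + i, duration, dt)
    if (res$no_spike) NA_integer_ else res$n
  }, integer(1))
  ok <- !is.na(nmin)
  terminals <- terminals[ok]; nmin <- nmin[ok]
  if (!length(terminals)) {
    return(structure(list(count = 0L, active_terminals = integer(0),
                          cluster_sizes = integer(0),
                          branch_point_peaks = NULL, min_synapses = nmin),
                     class = "independence_report"))
  }
  # placements reproduced per terminal with the same per-terminal seed
  placements <- lapply(seq_along(terminals), function(i) {
    set.seed(seed + i)
    cand <- .cluster_candidates(model, terminals[i], span)
    cand[sample.int(length(cand), n_max, replace = TRUE)]
  })
  check <- function(idx) {
    mm <- model; syn <- NULL; stems <- integer(0)
    for (i in idx) {
      ss <- add_spinous_synapses(mm, placements[[i]][seq_len(nmin[i])],
                                 kinetics, onset = 0)
      mm <- ss$model; syn <- rbind(syn, ss$synapses)
    }
    pairs <- if (length(idx) >= 2) utils::combn(idx, 2) else NULL
    bps <- if (!is.null(pairs)) {
      unique(vapply(seq_len(ncol(pairs)), function(k) {
        .lca_comp(model, terminals[pairs[1, k]], terminals[pairs[2, k]])
      }, integer(1)))
    } else integer(0)
    rec <- unique(c(terminals[idx], bps))
    sim <- simulate_model(mm, duration, dt, synapses = syn, record = rec)
    pk <- apply(sim$v, 2, max)
    names(pk) <- rec
    spikes <- vapply(terminals[idx], function(tc) {
      detect_nmda_spike(get_trace(sim, tc), criterion)$spike
    }, logical(1))
    list(valid = all(spikes) &&
           all(pk[as.character(bps)] < criterion$v_threshold),
         bp_peaks = if (length(bps)) {
           data.frame(branch_point = bps, peak_mv = unname(pk[as.character(bps)]))
         } else NULL)
  }
  ordering <- order(-vapply(terminals, function(s) input_resistance(model, s), 0))
  if (strategy == "exhaustive") {
    nt <- length(terminals)
    best <- integer(0); best_bp <- NULL
    for (size in seq(nt, 1)) {
      if (size <= length(best)) break
      combs <- utils::combn(nt, size)
      for (j in seq_len(ncol(combs))) {
        res <- check(combs[, j])
        if (res$valid) { best <- combs[, j]; best_bp <- res$bp_peaks; break }
      }
      if (length(best)) break
    }
    sel <- best; bp <- best_bp
  } else {
    sel <- integer(0); bp <- NULL; rejected <- integer(0)
    for (i in ordering) {
      res <- check(c(sel, i))
      if (res$valid) { sel <- c(sel, i); bp <- res$bp_peaks } else rejected <- c(rejected, i)
    }
    # single-swap backtracking: a rejected terminal may fit after removing one
    # member; bounded by a simulation budget
    budget <- max_backtrack
    for (r in rejected) {
      if (!length(sel) || budget <= 0) break
      for (s in sel) {
        if (budget <= 0) break
        trial <- c(setdiff(sel, s), r)
        res <- check(trial)
        budget <- budget - 1
        if (res$valid) {
          # try to regain the removed member or other rejects on top
          for (extra in c(s, setdiff(rejected, r))) {
            if (budget <= 0) break
            res2 <- check(c(trial, extra))
            budget <- budget - 1
            if (res2$valid) { trial <- c(trial, extra); res <- res2 }
          }
          if (length(trial) > length(sel)) { sel <- trial; bp <- res$bp_peaks }
          break
        }
      }
    }
  }
  structure(list(count = length(sel), active_terminals = terminals[sel],
                 cluster_sizes = nmin[sel], branch_point_peaks = bp,
                 min_synapses = setNames(nmin, terminals), seed = seed),
            class = "independence_report")
}
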