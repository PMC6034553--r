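#' Feature targets for multi-objective fitting
#'
#' @param mean,sd named numeric vectors over [spike_feature_names()]
#' @param sd_floor lower bound applied to the SDs so SD-normalised distances
#'   stay finite on low-variance synthetic targets (default 1e-3 feature
#'   units)
#' @return data.frame of class `feature_targets` with `feature`, `mean`, `sd`
#' @export
feature_targets <- function(mean, sd, sd_floor = 1e-3) {
  nm <- spike_feature_names()
  stopifnot(setequal(names(mean), nm), setequal(names(sd), nm))
  structure(data.frame(feature = nm, mean = unname(mean[nm]),
                       sd = pmax(unname(sd[nm]), sd_floor)),
            class = c("feature_targets", "data.frame"))
}

# fast non-dominated sort (minimisation); returns integer front index per row
.nds_rank <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  dominated_by <- integer(n)
  dominates <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      le <- all(obj[i, ] <= obj[j, ]); lt <- any(obj[i, ] < obj[j, ])
      if (le && lt) dominates[[i]] <- c(dominates[[i]], j)
      else if (all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])) {
        dominated_by[i] <- dominated_by[i] + 1L
      }
    }
  }
  front <- which(dominated_by == 0L)
  r <- 1L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in dominates[[i]]) {
        dominated_by[j] <- dominated_by[j] - 1L
        if (dominated_by[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- unique(nxt)
    r <- r + 1L
  }
  rank
}

.crowding <- function(obj) {
  n <- nrow(obj); m <- ncol(obj)
  cd <- numeric(n)
  for (k in seq_len(m)) {
    o <- obj[, k]
    if (!any(is.finite(o))) next
    ord <- order(o)
    rng <- max(o[is.finite(o)]) - min(o[is.finite(o)])
    if (rng == 0) next
    cd[ord[1]] <- cd[ord[n]] <- Inf
    for (i in 2:(n - 1)) {
      cd[ord[i]] <- cd[ord[i]] + (o[ord[i + 1]] - o[ord[i - 1]]) / rng
    }
  }
  cd
}

#' Multi-objective evolutionary fit of the active soma/axon model
#'
#' Non-dominated-sorting evolutionary search over the 29 active parameters.
#' Each objective is the distance, in target standard deviations, between a
#' model feature and its target mean. Candidates whose simulation diverges
#' or produces undefined features receive infinite distances. Survivor
#' selection is elitist (mu+lambda, rank then crowding), and the running
#' best-per-objective individuals are always retained, so the best distance
#' per objective is non-increasing over generations.
#'
#' @param model a passive `cable_model` with an axon stub
#' @param targets a [feature_targets()] table
#' @param bounds list/matrix of per-parameter `lower`, `upper` (length 29)
#' @param stim list with `onset`, `offset`, `amp` (nA) of the step stimulus
#' @param if_reference normalised I-F curve used by the feature extraction
#' @param population,generations search size (full defaults 1000/500)
#' @param test_profile logical; TRUE shrinks to population 20, 15 generations
#' @param seed RNG seed
#' @param channel_set channel archetypes
#' @param dt integration step, ms
#' @param p_mut,mut_sd mutation probability per gene and width (fraction of
#'   the bound range)
#' @param polish_evals Nelder-Mead budget for a final local polish of the
#'   minimum-worst-distance individual (0 disables)
#' @return list of class `moo_fit`: `params` (matrix, final population),
#'   `objectives` (matrix), `nondominated` (logical), `best` (params of the
#'   minimum worst-objective individual), `best_objectives`, `history`
#'   (generations x objectives matrix of best-per-objective distances)
#' @export
moo_fit <- function(model, targets, bounds, stim, if_reference,
                    population = 1000, generations = 500,
                    test_profile = FALSE, seed = 1,
                    channel_set = default_channel_set(), dt = 0.025,
                    p_mut = 0.3, mut_sd = 0.15, polish_evals = 1500) {
  if (test_profile) { population <- 20; generations <- 15 }
  lower <- bounds$lower; upper <- bounds$upper
  stopifnot(length(lower) == 29, length(upper) == 29)
  set.seed(seed)
  nm <- active_param_names(channel_set)
  dur <- stim$offset + 100
  evaluate <- function(x) {
    obj <- tryCatch({
      m <- apply_active_params(model, setNames(x, nm), channel_set)
      sim <- simulate_model(m, dur, dt,
                           stimuli = data.frame(comp = 1, onset = stim$onset,
                                                offset = stim$offset,
                                                amp = stim$amp))
      f <- extract_features(get_trace(sim), stim$onset, stim$offset, if_reference)
      abs(f - targets$mean) / targets$sd
    }, error = function(e) rep(1e6, 17))
    # divergent or undefined candidates get an effectively infinite distance
    # (capped so rank and crowding arithmetic stay well defined)
    obj[!is.finite(obj)] <- 1e6
    pmin(obj, 1e6)
  }
  span <- upper - lower
  pop <- sweep(sweep(lhs::randomLHS(population, 29), 2, span, "*"), 2, lower, "+")
  obj <- t(apply(pop, 1, evaluate))
  nobj <- ncol(obj)
  arch_p <- pop[rep(1, nobj), , drop = FALSE]
  arch_o <- obj[rep(1, nobj), , drop = FALSE]
  update_archive <- function(pop, obj) {
    for (k in seq_len(nobj)) {
      i <- which.min(obj[, k])
      if (obj[i, k] < arch_o[k, k]) { arch_p[k, ] <<- pop[i, ]; arch_o[k, ] <<- obj[i, ] }
    }
  }
  update_archive(pop, obj)
  history <- matrix(NA_real_, generations, nobj)
  for (gen in seq_len(generations)) {
    rank <- .nds_rank(obj)
    worstv <- apply(obj, 1, max)
    # with 17 objectives most of the population is mutually non-dominated, so
    # the secondary pressure is the worst (Chebyshev) distance, which drives
    # the search toward models uniformly close to all targets
    tournament <- function() {
      a <- sample(population, 1); b <- sample(population, 1)
      if (rank[a] < rank[b] || (rank[a] == rank[b] && worstv[a] < worstv[b])) a else b
    }
    sigma <- mut_sd * 0.93^gen
    child <- matrix(0, population, 29)
    for (i in seq_len(population)) {
      p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
      w <- runif(29)
      x <- w * p1 + (1 - w) * p2
      mut <- runif(29) < p_mut
      x[mut] <- x[mut] + rnorm(sum(mut), 0, sigma * span[mut])
      child[i, ] <- pmin(pmax(x, lower), upper)
    }
    cobj <- t(apply(child, 1, evaluate))
    allp <- rbind(pop, child, arch_p)
    allo <- rbind(obj, cobj, arch_o)
    r <- .nds_rank(allo)
    wall <- apply(allo, 1, max)
    cdall <- .crowding(allo)
    # half the survivors by uniform quality (rank, then worst distance),
    # half by diversity (rank, then crowding) to avoid premature collapse
    n1 <- ceiling(population / 2)
    k1 <- order(r, wall)[seq_len(n1)]
    k2 <- setdiff(order(r, -cdall), k1)[seq_len(population - n1)]
    keep <- c(k1, k2)
    pop <- allp[keep, , drop = FALSE]
    obj <- allo[keep, , drop = FALSE]
    update_archive(pop, obj)
    history[gen, ] <- vapply(seq_len(nobj), function(k) arch_o[k, k], 0)
  }
  # fold the archive back in for reporting
  allp <- rbind(pop, arch_p)
  allo <- rbind(obj, arch_o)
  worst <- apply(allo, 1, max)
  best_i <- which.min(worst)
  if (polish_evals > 0) {
    # local Nelder-Mead polish of the best individual, run in normalised
    # [0, 1] coordinates (comparable simplex steps across heterogeneous
    # parameters) on a capped sum-of-squares scalarisation
    scal <- function(z) {
      x <- lower + pmin(pmax(z, 0), 1) * span
      sum(pmin(evaluate(x), 50)^2)
    }
    # basin-hopping: Nelder-Mead restarts from the best individual and from
    # perturbed copies of the incumbent, keeping the best scalarised value
    rounds <- max(1L, ceiling(polish_evals / 300))
    z_best <- z <- (allp[best_i, ] - lower) / span
    v_best <- Inf
    for (round in seq_len(rounds)) {
      op <- optim(z, scal, method = "Nelder-Mead",
                  control = list(maxit = 300, reltol = 1e-12))
      if (op$value < v_best) {
        v_best <- op$value
        z_best <- pmin(pmax(op$par, 0), 1)
        xp <- lower + z_best * span
        allp <- rbind(allp, xp)
        allo <- rbind(allo, evaluate(xp))
      }
      z <- pmin(pmax(z_best + rnorm(29, 0, 0.06), 0), 1)
    }
    worst <- apply(allo, 1, max)
    best_i <- which.min(worst)
  }
  r <- .nds_rank(allo)
  colnames(allp) <- nm
  colnames(allo) <- targets$feature
  structure(list(params = allp, objectives = allo, nondominated = r == 1L,
                 best = active_params(allp[best_i, ], channel_set),
                 best_objectives = allo[best_i, ],
                 history = history, seed = seed,
                 population = population, generations = generations),
            class = "moo_fit")
}
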