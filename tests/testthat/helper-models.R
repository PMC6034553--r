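# Shared fixtures, built in code at test time.

# single-compartment soma (isopotential RC)
soma_only_model <- function(r_um = 10, params = passive_params(c_m = 0.5, r_m = 20000, r_a = 200)) {
  m <- morphology(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                             r = r_um, parent = -1))
  build_cable_model(m, params)
}

# sealed uniform cylinder of given electrotonic length L (in DC space
# constants), diameter 2 um, attached to a tiny soma at one end
cylinder_model <- function(L = 1, params = passive_params(c_m = 0.5, r_m = 20000, r_a = 200),
                           npts = 101, d_lambda = 0.02) {
  lam_um <- sqrt(params$r_m * 2e-4 / (4 * params$r_a)) * 1e4
  pts <- data.frame(id = 1:(npts + 1), type = c(1, rep(3, npts)),
                    x = c(-1, seq(1, L * lam_um, length.out = npts)),
                    y = 0, z = 0, r = c(1, rep(1, npts)),
                    parent = c(-1, 1, seq_len(npts - 1) + 1))
  build_cable_model(morphology(pts), params, d_lambda = d_lambda)
}

# symmetric Y: two equal daughters from a common stem
y_tree_points <- function(stem = 50, daughter = 100) {
  n1 <- 6; n2 <- 11
  stem_x <- seq(5, stem, length.out = n1)
  d_x <- seq_len(n2 - 1) / (n2 - 1) * daughter
  pts <- rbind(
    data.frame(id = 1, type = 1, x = 0, y = 0, z = 0, r = 5, parent = -1),
    data.frame(id = 2:(n1 + 1), type = 3, x = stem_x, y = 0, z = 0, r = 1,
               parent = c(1, 2:n1)),
    data.frame(id = (n1 + 2):(n1 + n2), type = 3, x = stem + d_x / sqrt(2),
               y = d_x / sqrt(2), z = 0, r = 0.7,
               parent = c(n1 + 1, (n1 + 2):(n1 + n2 - 1))),
    data.frame(id = (n1 + n2 + 1):(n1 + 2 * n2 - 1), type = 3,
               x = stem + d_x / sqrt(2), y = -d_x / sqrt(2), z = 0, r = 0.7,
               parent = c(n1 + 1, (n1 + n2 + 1):(n1 + 2 * n2 - 2))))
  pts
}

y_tree_model <- function(params = passive_params(), ...) {
  build_cable_model(morphology(y_tree_points(...)), params)
}

# star of k long thin terminals radiating from a small central soma through
# short thick stems: strongly decoupled tips
star_model <- function(k = 6, term_len = 250, term_diam = 0.5,
                       params = passive_params(), soma_r = 12) {
  rows <- list(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0, r = soma_r, parent = -1))
  nid <- 1
  for (arm in seq_len(k)) {
    ang <- 2 * pi * arm / k
    npts <- 20
    xs <- (soma_r + seq_len(npts) / npts * term_len) * cos(ang)
    ys <- (soma_r + seq_len(npts) / npts * term_len) * sin(ang)
    ids <- nid + seq_len(npts)
    rows[[arm + 1]] <- data.frame(id = ids, type = 3, x = xs, y = ys, z = 0,
                                  r = term_diam / 2,
                                  parent = c(1, head(ids, -1)))
    nid <- max(ids)
  }
  build_cable_model(morphology(do.call(rbind, rows)), params)
}

# dense conductance-matrix oracle for the steady state
dense_resistance <- function(model, sites) {
  n <- nrow(model$comp)
  G <- diag(model$comp$gl, n)
  for (i in 2:n) {
    p <- model$comp$parent[i]
    G[i, i] <- G[i, i] + model$comp$ga[i]
    G[p, p] <- G[p, p] + model$comp$ga[i]
    G[i, p] <- G[i, p] - model$comp$ga[i]
    G[p, i] <- G[p, i] - model$comp$ga[i]
  }
  solve(G)[sites, sites, drop = FALSE]
}
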