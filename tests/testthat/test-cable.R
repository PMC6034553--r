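pp <- passive_params(c_m = 0.5, r_m = 20000, r_a = 200)

test_that("single compartment matches the closed-form RC cell", {
  mod <- soma_only_model(params = pp)
  area <- mod$comp$area
  expect_equal(input_resistance(mod, 1), 100 * 20000 / area, tolerance = 1e-9)
  # current step relaxes with tau = R_m * C_m = 10 ms (tail fit within 1%)
  sim <- simulate_model(mod, 100, stimuli = data.frame(comp = 1, onset = 0,
                                                       offset = 100, amp = 0.01))
  tr <- get_trace(sim)
  v <- tr$v_mv - pp$e_rest
  vss <- tail(v, 1)
  sel <- tr$t_ms > 1 & tr$t_ms < 30
  tau <- -1 / coef(lm(log(vss - v[sel]) ~ tr$t_ms[sel]))[[2]]
  expect_lt(abs(tau - 10) / 10, 0.01)
})

test_that("unstimulated models stay at rest", {
  mod <- y_tree_model(pp)
  sim <- simulate_model(mod, 50)
  expect_lt(max(abs(sim$v - pp$e_rest)), 1e-9)
})

test_that("sealed cylinder reproduces cosh/coth cable closed forms", {
  mod <- cylinder_model(L = 1, params = pp, d_lambda = 0.02)
  nc <- nrow(mod$comp)
  R <- resistance_map(mod, c(2, nc))
  expect_lt(abs(R[2, 2] / R[2, 1] - cosh(1)) / cosh(1), 0.01)
  # input resistance at the sealed far end: 1 / (G_inf * tanh(L))
  lam_cm <- sqrt(pp$r_m * 2e-4 / (4 * pp$r_a))
  g_inf_uS <- pi * 2e-4 * lam_cm / pp$r_m * 1e6
  expect_lt(abs(R[2, 2] - 1 / (g_inf_uS * tanh(1))) / R[2, 2], 0.01)
})

test_that("transfer-resistance maps are reciprocal and match a dense solve", {
  for (mod in list(y_tree_model(pp), star_model(4))) {
    sites <- c(1, sample(dendritic_comps(mod), 5))
    R <- resistance_map(mod, sites)
    expect_lt(max(abs(R - t(R))) / max(R), 1e-6)
    Rd <- dense_resistance(mod, sites)
    expect_lt(max(abs(R - Rd)), 1e-10 * max(abs(Rd)) * 1e4)
  }
})

test_that("transfer resistance attenuates away from the injection site", {
  mod <- y_tree_model(pp)
  tips <- terminal_comps(mod)
  R <- resistance_map(mod, tips[1:2])
  expect_lt(R[1, 2], R[1, 1])
})

test_that("halving dt changes EPSP peaks by less than 0.5%", {
  mod <- y_tree_model()
  site <- tail(dendritic_comps(mod), 1)
  kin <- default_synapse_kinetics()$ampa
  pk <- vapply(c(0.025, 0.0125), function(dt) {
    sim <- simulate_model(mod, 60, dt = dt,
                          synapses = synapse_table(site, kin, 2), record = 1L)
    max(sim$v) - mod$params$e_rest
  }, 0)
  expect_lt(abs(pk[1] - pk[2]) / pk[2], 0.005)
})

test_that("coarsening the spatial grid from the default changes peaks < 1%", {
  m <- morphology(y_tree_points())
  kin <- default_synapse_kinetics()$ampa
  pk <- vapply(c(0.1, 0.02), function(dl) {
    mod <- build_cable_model(m, passive_params(), d_lambda = dl)
    site <- tail(dendritic_comps(mod), 1)
    sim <- simulate_model(mod, 60, synapses = synapse_table(site, kin, 2),
                          record = 1L)
    max(sim$v) - mod$params$e_rest
  }, 0)
  expect_lt(abs(pk[1] - pk[2]) / pk[2], 0.01)
})

test_that("spine-area correction scales the right compartments and conserves tau_m", {
  m <- morphology(y_tree_points(stem = 80, daughter = 120))
  prm <- passive_params(c_m = 0.5, f_spines = 1.9, spine_min_dist = 60)
  mod0 <- build_cable_model(m, prm)
  mod <- apply_spine_correction(mod0)
  near <- mod$comp$path_dist < 60 & mod$comp$type %in% c(3, 4)
  far <- mod$comp$path_dist >= 60 & mod$comp$type %in% c(3, 4)
  expect_true(any(near) && any(far))
  expect_equal(mod$comp$cm[near], mod0$comp$cm[near])
  expect_equal(mod$comp$cm[far], mod0$comp$cm[far] * 1.9)
  expect_equal(mod$comp$gl[far], mod0$comp$gl[far] * 1.9)
  # soma untouched; compartment at 59 um vs 61 um boundary behaviour
  expect_equal(mod$comp$cm[1], mod0$comp$cm[1])
  # tau_m = cm/gl unchanged everywhere
  expect_equal(mod$comp$cm / mod$comp$gl, mod0$comp$cm / mod0$comp$gl)
  # F = 1 leaves the model unchanged
  mod1 <- apply_spine_correction(mod0, passive_params(f_spines = 1))
  expect_equal(mod1$comp$cm, mod0$comp$cm)
  # double application is refused
  expect_error(apply_spine_correction(mod), "already applied")
})

test_that("the 60-um rule corrects 61 um but not 59 um", {
  # straight cable with compartments straddling the cutoff
  pts <- data.frame(id = 1:13, type = c(1, rep(3, 12)),
                    x = c(-1, seq(10, 120, by = 10)), y = 0, z = 0,
                    r = c(5, rep(1, 12)), parent = c(-1, 1, 2:12))
  mod0 <- build_cable_model(morphology(pts), passive_params(), d_lambda = 0.02)
  mod <- apply_spine_correction(mod0)
  d <- mod$comp$path_dist
  below <- which(d > 50 & d < 60 & mod$comp$type == 3)
  above <- which(d >= 60 & d < 70 & mod$comp$type == 3)
  expect_true(length(below) > 0 && length(above) > 0)
  expect_equal(mod$comp$cm[below], mod0$comp$cm[below])
  expect_equal(mod$comp$cm[above], mod0$comp$cm[above] * 1.9)
})

test_that("compute_f_spines is the area ratio", {
  expect_equal(compute_f_spines(100, 90), 1.9)
  expect_equal(compute_f_spines(123, 0), 1)
  expect_equal(compute_f_spines(50, 50), 2)
  expect_error(compute_f_spines(0, 10), "dendritic_area")
})
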