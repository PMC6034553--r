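test_that("shape index matches a dense-grid oracle on an analytic EPSP", {
  # V(t) = exp(-t/20) - exp(-t/1): peak near t = 3.15
  tfine <- seq(0, 120, by = 1e-4)
  vfine <- exp(-tfine / 20) - exp(-tfine / 1)
  amp <- max(vfine)
  oracle_cross <- function(level, after_peak = FALSE) {
    pk <- which.max(vfine)
    idx <- if (after_peak) which(vfine[pk:length(vfine)] < level)[1] + pk - 1 else
      which(vfine[1:pk] >= level)[1]
    tfine[idx]
  }
  o_rise <- oracle_cross(0.9 * amp) - oracle_cross(0.1 * amp)
  o_hw <- oracle_cross(0.5 * amp, TRUE) - oracle_cross(0.5 * amp)
  t <- seq(0, 120, by = 0.01)
  si <- shape_index(data.frame(t_ms = t, v_mv = exp(-t / 20) - exp(-t / 1)))
  expect_lt(abs(si$rise_time - o_rise), 1e-3)
  expect_lt(abs(si$half_width - o_hw), 1e-3)
  # amplitude invariance and time-dilation scaling
  si5 <- shape_index(data.frame(t_ms = t, v_mv = 5 * (exp(-t / 20) - exp(-t / 1))))
  expect_equal(si5$rise_time, si$rise_time, tolerance = 1e-9)
  expect_equal(si5$half_width, si$half_width, tolerance = 1e-9)
  t2 <- seq(0, 240, by = 0.01)
  si_d <- shape_index(data.frame(t_ms = t2, v_mv = exp(-t2 / 40) - exp(-t2 / 2)))
  expect_equal(si_d$rise_time, 2 * si$rise_time, tolerance = 1e-2)
  expect_equal(si_d$half_width, 2 * si$half_width, tolerance = 1e-2)
  tneg <- seq(-5, 50, by = 0.01)
  vneg <- ifelse(tneg < 0, 0, -(1 - exp(-tneg / 1)) * exp(-tneg / 10))
  expect_error(shape_index(data.frame(t_ms = tneg, v_mv = vneg)), "non-positive")
})

test_that("peeling recovers single and mixed exponential time constants", {
  t <- seq(0, 150, by = 0.05)
  tr1 <- data.frame(t_ms = t, v_mv = 5 * exp(-t / 16))
  expect_equal(peel_time_constant(tr1, c(10, 120)), 16, tolerance = 1e-9)
  tr2 <- data.frame(t_ms = t, v_mv = 5 * exp(-t / 16) + 3 * exp(-t / 2))
  expect_equal(peel_time_constant(tr2, c(12, 120)), 16, tolerance = 0.02)
  expect_error(peel_time_constant(data.frame(t_ms = t, v_mv = exp(-t / 5) - 0.5),
                                  c(10, 120)), "strictly positive")
  # simulated RC compartment: peeled tau equals R_m * C_m within 1%
  mod <- soma_only_model(params = passive_params(c_m = 0.5, r_m = 20000, r_a = 200))
  sim <- simulate_model(mod, 120, synapses =
    synapse_table(1, default_synapse_kinetics()$ampa, 2), record = 1L)
  tr <- get_trace(sim)
  tr$v_mv <- tr$v_mv - mod$params$e_rest
  expect_equal(peel_time_constant(tr, c(30, 110)), 10, tolerance = 0.01)
})

test_that("shape-index curves grow with distance on a cylinder", {
  mod <- cylinder_model(L = 1.2, d_lambda = 0.05)
  dend <- dendritic_comps(mod)
  probe <- dend[round(seq(1, length(dend), length.out = 8))]
  curve <- build_shape_index_curve(mod, sites = probe)
  expect_equal(nrow(curve), length(probe))
  expect_true(all(diff(curve$rise_time) > 0))
  expect_true(all(diff(curve$half_width) > 0))
})

test_that("putative_locations selects by distance in the SI plane", {
  curve <- data.frame(comp = 1:4, path_dist = 1:4, subtree = "basal",
                      rise_time = c(1, 2, 3, 4), half_width = c(5, 6, 7, 8))
  target <- list(rise_time = 2.1, half_width = 6.1)
  expect_equal(putative_locations(curve, target, radius = 1e9)$comp, 1:4)
  expect_equal(putative_locations(curve, target, radius = 0.2)$comp, 2)
  expect_equal(nrow(putative_locations(curve, list(rise_time = 50, half_width = 50),
                                       radius = 1)), 0)
})

test_that("EPSPs synthesised at a known site localise back to it (round trip)", {
  mod <- y_tree_model()
  dend <- dendritic_comps(mod)
  probe <- dend[round(seq(1, length(dend), length.out = 10))]
  curve <- build_shape_index_curve(mod, sites = probe)
  true_site <- probe[6]
  sim <- simulate_model(mod, 100, synapses =
    synapse_table(true_site, default_synapse_kinetics()$ampa, 2), record = 1L)
  si <- shape_index(get_trace(sim), onset = 2)
  hits <- putative_locations(curve, si, radius = 1)
  expect_true(true_site %in% hits$comp)
})

test_that("fit_connection recovers a planted shared conductance", {
  mod <- y_tree_model()
  pe <- generate_pair_epsp(mod, g_per_contact = 0.6, noise_sd = 0, seed = 3)
  fit <- fit_connection(mod, pe$trace, site_pool = pe$ground_truth$sites,
                        repeats = 3, seed = 1)
  expect_lt(abs(fit$g_mean - 0.6) / 0.6, 0.01)
  # doubling the target roughly doubles the fitted conductance
  tr2 <- pe$trace; tr2$v_mv <- tr2$v_mv * 2
  fit2 <- fit_connection(mod, tr2, pe$ground_truth$sites, repeats = 3, seed = 1)
  expect_gt(fit2$g_mean, fit$g_mean * 1.8)
  # zero-amplitude target fits ~ zero conductance
  tr0 <- pe$trace; tr0$v_mv <- tr0$v_mv * 0
  fit0 <- fit_connection(mod, tr0, pe$ground_truth$sites, repeats = 2, seed = 1)
  expect_lt(fit0$g_mean, 0.01)
  expect_error(fit_connection(mod, pe$trace, site_pool = 1:3), "smaller")
})

test_that("fit_connection stays within 10% bias under 5% noise", {
  mod <- y_tree_model()
  g <- numeric(12)
  for (s in seq_along(g)) {
    pe <- generate_pair_epsp(mod, g_per_contact = 0.6, seed = 100 + s)
    peak <- max(pe$trace$v_mv)
    pe$trace$v_mv <- pe$trace$v_mv + rnorm(nrow(pe$trace), 0, 0.05 * peak)
    g[s] <- fit_connection(mod, pe$trace, pe$ground_truth$sites,
                           repeats = 2, seed = s)$g_mean
  }
  expect_lt(abs(mean(g) - 0.6) / 0.6, 0.1)
})

test_that("two-stage NMDA fit recovers gamma and tau_decay on synthetic targets", {
  mod <- y_tree_model(params = passive_params())
  region <- dendritic_comps(mod)
  tgt <- generate_nmda_targets(mod, region, n_syn = 18, seed = 4, duration = 160)
  fit <- fit_nmda_kinetics(mod, tgt$blocked, tgt$unblocked, region,
                           n_syn_range = c(15, 21), n_seeds = 4, seed = 2,
                           maxit = 120)
  bt <- fit$fits[[1]] # top-ranked candidate
  expect_lt(abs(bt$gamma - 0.0771) / 0.0771, 0.2)
  expect_lt(abs(bt$tau_decay - 34.99) / 34.99, 0.15)
  # ranking contract: the reported best has the smallest total RMSD
  rmsds <- vapply(fit$fits, `[[`, 0, "rmsd_total")
  expect_equal(min(rmsds), rmsds[1])
  # blocked target peak is below the unblocked one
  expect_lt(max(tgt$blocked$v_mv), max(tgt$unblocked$v_mv))
})

test_that("zero-amplitude blocked target drives conductances to zero", {
  mod <- y_tree_model()
  region <- dendritic_comps(mod)
  zero <- data.frame(t_ms = seq(0, 80, 0.5), v_mv = 0)
  fit <- fit_nmda_kinetics(mod, zero, zero, region, n_syn_range = c(15, 16),
                           n_seeds = 1, seed = 1, maxit = 200)
  expect_lt(fit$best_typical$g_nmda, 0.1)
  expect_lt(fit$best_typical$g_ampa_blocked, 0.05)
})
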