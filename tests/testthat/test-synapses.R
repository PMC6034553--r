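kins <- default_synapse_kinetics()

test_that("double-exponential peak time and normalisation match closed forms", {
  # AMPA kinetics 0.3/1.8 ms: t_peak = 0.36 * ln 6, N from the peak condition
  k <- kins$ampa
  expect_equal(conductance_tpeak(k), 0.36 * log(6), tolerance = 1e-12)
  expect_equal(conductance_norm(k), 1.717, tolerance = 1e-3)
  # brute-force grid maximisation agrees with the analytic t_peak to 1e-6 ms
  for (k2 in list(k, kins$nmda, synapse_kinetics(1, 2.5, 70))) {
    tg <- seq(0, 20 * k2$tau_decay, by = 1e-4)
    g <- conductance_waveform(k2, tg, v = 0)
    tp_grid <- optimize(function(t) -conductance_waveform(k2, t, v = 0),
                        tg[c(which.max(g) - 2, which.max(g) + 2)], tol = 1e-10)$minimum
    expect_lt(abs(tp_grid - conductance_tpeak(k2)), 1e-6)
    # peak value equals B * g_max (B = 1 voltage-independent, or B(0))
    b <- if (k2$voltage_dependent) mg_block(k2, 0) else 1
    expect_equal(conductance_waveform(k2, conductance_tpeak(k2), v = 0),
                 b * k2$g_max, tolerance = 1e-10)
  }
  expect_equal(conductance_waveform(k, 0), 0)
  expect_error(synapse_kinetics(1, 2, 1.5), "tau_decay > tau_rise")
})

test_that("magnesium block follows the Jahr-Stevens form", {
  k <- kins$nmda
  expect_equal(mg_block(k, 0), 1 / 1.28, tolerance = 1e-12)
  k2 <- synapse_kinetics(1, 8, 35, voltage_dependent = TRUE,
                         gamma = 0.0771, n = 0.28, mg = 1)
  expect_equal(mg_block(k2, -70), 0.01592, tolerance = 1e-3)
  # no magnesium: no block at any voltage
  k0 <- synapse_kinetics(1, 8, 35, voltage_dependent = TRUE, mg = 0)
  expect_equal(mg_block(k0, c(-90, -40, 0)), rep(1, 3))
  # strictly increasing in V, in (0, 1]
  v <- seq(-100, 60, 1)
  b <- mg_block(k, v)
  expect_true(all(diff(b) > 0))
  expect_true(all(b > 0 & b <= 1))
  # strictly decreasing in Mg
  bs <- vapply(c(0.5, 1, 2), function(mg) {
    mg_block(synapse_kinetics(1, 8, 35, voltage_dependent = TRUE, mg = mg), -60)
  }, 0)
  expect_true(all(diff(bs) < 0))
  expect_error(mg_block(kins$ampa, 0), "voltage-dependent")
})

test_that("synaptic current follows I = g(t,V) (V - E_syn)", {
  k <- kins$ampa
  expect_equal(synaptic_current(k, 0, c(0.2, 1, 5)), rep(0, 3)) # at reversal
  k88 <- synapse_kinetics(0.88, 0.3, 1.8)
  i <- synaptic_current(k88, -86, conductance_tpeak(k88))
  expect_equal(i, 0.88e-3 * -86, tolerance = 1e-10) # ~ -0.0757 nA
  # NMDA current magnitude is non-monotone across the voltage sweep
  i_n <- abs(synaptic_current(kins$nmda, seq(-90, 0, 2), 8))
  pk <- which.max(i_n)
  expect_gt(pk, 1); expect_lt(pk, length(i_n))
})

test_that("spine neck resistance follows the cylinder formula and paper bands", {
  g <- spine_geometry()
  expect_equal(neck_resistance(g, 200), 55.0, tolerance = 1e-3)
  expect_equal(neck_resistance(g, 300), 82.5, tolerance = 1e-3)
  expect_equal(neck_resistance(spine_geometry(neck_diameter = 0.5), 200),
               neck_resistance(g, 200) / 4, tolerance = 1e-12)
  # variation grid (d 0.25 +/- 0.05, R_a 200 +/- 100) spans 19-128 MOhm
  grid <- expand.grid(d = c(0.2, 0.25, 0.3), ra = c(100, 200, 300))
  rn <- mapply(function(d, ra) neck_resistance(spine_geometry(neck_diameter = d), ra),
               grid$d, grid$ra)
  expect_equal(min(rn), 19.1, tolerance = 0.01)
  expect_equal(max(rn), 128.9, tolerance = 0.01)
})

test_that("spinous EPSPs attenuate head >= base >= soma with sane ratios", {
  mod <- y_tree_model()
  sites <- c(dendritic_comps(mod)[3], tail(dendritic_comps(mod), 2)[1])
  for (s in sites) {
    res <- activate_spinous_synapse(mod, s, kins$ampa_pair)
    expect_gte(res$epsp_head, res$epsp_base)
    expect_gte(res$epsp_base, res$epsp_soma)
    expect_gte(res$ratio_head_base, 1)
  }
  # zero conductance: zero EPSPs
  res0 <- activate_spinous_synapse(mod, sites[1], synapse_kinetics(0, 0.3, 1.8))
  expect_lt(abs(res0$epsp_head), 1e-9)
  # distal thin terminal gives a larger head EPSP than a proximal thick site
  r_prox <- activate_spinous_synapse(mod, sites[1], kins$ampa_pair)
  r_dist <- activate_spinous_synapse(mod, sites[2], kins$ampa_pair)
  rin <- diag(resistance_map(mod, sites))
  expect_equal(order(rin), order(c(r_prox$epsp_head, r_dist$epsp_head)))
  # spines only attach to dendrites
  expect_error(attach_spine(mod, 1), "dendritic")
})

test_that("a spinous synapse depolarises the shaft less than the same synapse on the shaft", {
  mod <- y_tree_model()
  site <- tail(dendritic_comps(mod), 3)[1]
  spin <- activate_spinous_synapse(mod, site, kins$ampa_pair)
  sim <- simulate_model(mod, 100, synapses = synapse_table(site, kins$ampa_pair, 5),
                        record = site)
  shaft_direct <- max(sim$v) - mod$params$e_rest
  expect_lte(spin$epsp_base, shaft_direct + 1e-9)
})

test_that("normalisation holds for any admissible kinetics (property)", {
  set.seed(42)
  for (i in 1:25) {
    tr <- runif(1, 0.1, 15)
    td <- tr + runif(1, 0.2, 80)
    k <- synapse_kinetics(runif(1, 0.1, 3), tr, td)
    tg <- seq(0, 10 * td, length.out = 20001)
    g_pk <- max(conductance_waveform(k, tg))
    expect_lt(abs(g_pk - k$g_max) / k$g_max, 1e-3)
  }
})
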