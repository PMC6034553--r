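test_that("axon stub adds measurable load and removal restores the map", {
  mod <- y_tree_model()
  sites <- c(1, dendritic_comps(mod)[5])
  R0 <- resistance_map(mod, sites)
  mod2 <- add_axon_stub(mod)
  expect_equal(sum(mod2$comp$type == 2L), 5)
  axon <- which(mod2$comp$type == 2L)
  expect_equal(max(mod2$comp$path_dist[axon]) + 6, 60, tolerance = 1e-9)
  R1 <- resistance_map(mod2, sites)
  expect_lt(R1[1, 1], R0[1, 1]) # extra membrane loads the soma
  mod3 <- remove_axon_stub(mod2)
  expect_lt(max(abs(resistance_map(mod3, sites) - R0)), 1e-9)
  expect_error(add_axon_stub(mod2), "already present")
})

test_that("all-zero densities reproduce the passive model exactly", {
  mod <- add_axon_stub(y_tree_model())
  zero <- setNames(numeric(29), active_param_names())
  zero[c("soma.na_tau_scale", "axon.na_tau_scale")] <- 1
  zero[c("soma.ca_tau", "axon.ca_tau")] <- 80
  zero["e_leak"] <- mod$params$e_rest
  am <- apply_active_params(mod, zero)
  syn <- synapse_table(dendritic_comps(mod)[4], default_synapse_kinetics()$ampa, 2)
  s_active <- simulate_model(am, 60, synapses = syn, record = 1L)
  s_passive <- simulate_model(mod, 60, synapses = syn, record = 1L)
  expect_lt(max(abs(s_active$v - s_passive$v)), 1e-12)
})

test_that("the active parameter vector is validated", {
  expect_error(active_params(numeric(10)), "29")
  x <- setNames(numeric(29), active_param_names())
  x["soma.g_na_t"] <- -1
  expect_error(active_params(x), ">= 0")
  expect_s3_class(example_active_params(), "active_params")
})

test_that("feature extraction matches hand-built waveforms", {
  # two clean triangular spikes with known geometry at 100 and 200 ms
  dt <- 0.01
  t <- seq(0, 1200, dt)
  v <- rep(-70, length(t))
  spike <- function(v, at) {
    rise <- at - 2 + seq(0, 2, dt)   # 2 ms linear rise from -70 to +30 (50 mV/ms)
    fall <- at + seq(dt, 3, dt)      # 3 ms fall back
    v[round(rise / dt) + 1] <- seq(-70, 30, length.out = length(rise))
    v[round(fall / dt) + 1] <- seq(30, -70, length.out = length(fall))
    v
  }
  v <- spike(v, 100); v <- spike(v, 200)
  f <- extract_features(data.frame(t_ms = t, v_mv = v), 50, 1050)
  expect_equal(f[["voltage_base"]], -70)
  expect_equal(f[["time_to_first_spike"]], 50, tolerance = 0.02)
  expect_equal(f[["burst_isi"]], 100, tolerance = 0.02)
  expect_equal(f[["mean_frequency"]], 2)
  expect_equal(f[["ap_height"]], 30, tolerance = 1e-6)
  expect_equal(f[["ahp_depth"]], -70, tolerance = 1e-6)
  # dV/dt is 50 mV/ms on the whole rise: the 20 mV/ms criterion fires at the
  # first rise sample (voltage -70); half height between begin and peak = -20
  expect_lt(f[["ap_begin_voltage"]], -65)
  half <- (30 + f[["ap_begin_voltage"]]) / 2
  # dense-grid oracle for the half width of the triangular spike
  up <- 2 * (half + 70) / 100; dn <- 3 * (30 - half) / 100
  expect_equal(f[["spike_half_width"]], (2 - up) + dn, tolerance = 0.02)
  # ISI-based features undefined with < 2 ISIs are NA, not fabricated
  expect_true(is.na(f[["isi_cv"]]))
  expect_true(is.na(f[["adaptation_index"]]))
})

test_that("ISI statistics follow the printed conventions", {
  dt <- 0.01
  t <- seq(0, 1200, dt)
  v <- rep(-70, length(t))
  mk <- function(v, at) { v[abs(t - at) < 0.5] <- 40 * (1 - abs(t[abs(t - at) < 0.5] - at) * 2); v }
  peaks <- c(100, 200, 320, 460, 620)
  for (p in peaks) v <- mk(v, p)
  f <- extract_features(data.frame(t_ms = t, v_mv = v), 50, 1050)
  isi <- diff(peaks)
  expect_equal(f[["isi_cv"]], mean(isi) / sd(isi), tolerance = 1e-3)
  f2 <- extract_features(data.frame(t_ms = t, v_mv = v), 50, 1050,
                         isi_cv_form = "sd_over_mean")
  expect_equal(f2[["isi_cv"]], sd(isi) / mean(isi), tolerance = 1e-3)
  expect_equal(f[["adaptation_index"]],
               mean(diff(isi) / (isi[-1] + isi[-length(isi)])), tolerance = 1e-3)
})

test_that("I-F normalisation interpolates the 10 Hz current", {
  curve <- normalize_if_curve(data.frame(current = c(100, 200), rate = c(5, 15)))
  expect_equal(curve$i_10hz, 150)
  expect_equal(if_rate_at_input(curve, 1), 10)
  expect_equal(if_input_at_rate(curve, 10), 1)
  # idempotence: re-normalising an already normalised curve changes nothing
  curve2 <- normalize_if_curve(data.frame(current = curve$input, rate = curve$rate))
  expect_equal(curve2$i_10hz, 1)
  expect_error(normalize_if_curve(data.frame(current = c(1, 2), rate = c(20, 30))),
               "outside")
  # worked pattern: read the curve at 75..300% of a matched input
  curve3 <- normalize_if_curve(data.frame(current = seq(50, 400, 50),
                                          rate = c(0, 2, 6, 10, 14, 19, 25, 32)))
  x <- if_input_at_rate(curve3, 10.4)
  f75 <- if_rate_at_input(curve3, 0.75 * x)
  expect_gt(f75, 0); expect_lt(f75, 10.4)
})

test_that("the reference spiking cell fires regularly in its target band", {
  mod <- small_spiking_cell()
  am <- apply_active_params(mod, example_active_params())
  sim <- simulate_model(am, 1200, stimuli = data.frame(comp = 1, onset = 100,
                                                       offset = 1100, amp = 0.4))
  f <- extract_features(get_trace(sim), 100, 1100)
  expect_gt(f[["mean_frequency"]], 15)
  expect_lt(f[["mean_frequency"]], 60)
  expect_gt(f[["spike_half_width"]], 0.3)
  expect_lt(f[["spike_half_width"]], 1.4)
  expect_lt(f[["ahp_depth"]], f[["ap_begin_voltage"]])
})
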