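crit <- nmda_criterion() # -40 mV, 20 ms

test_that("plateau detection implements the threshold-and-duration rule", {
  t <- seq(0, 100, 0.1)
  flat <- data.frame(t_ms = t, v_mv = -86)
  expect_false(detect_nmda_spike(flat, crit)$spike)
  pulse <- function(width) data.frame(t_ms = t, v_mv = ifelse(t >= 10 & t < 10 + width, -20, -86))
  expect_true(detect_nmda_spike(pulse(25), crit)$spike)
  expect_false(detect_nmda_spike(pulse(15), crit)$spike)
  d <- detect_nmda_spike(pulse(25), crit)
  expect_equal(d$onset, 10, tolerance = 0.11)
  expect_equal(d$duration, 25, tolerance = 0.2)
  # halving dt does not flip a detection with comfortable margins
  t2 <- seq(0, 100, 0.05)
  pulse2 <- data.frame(t_ms = t2, v_mv = ifelse(t2 >= 10 & t2 < 35, -20, -86))
  expect_true(detect_nmda_spike(pulse2, crit)$spike)
})

test_that("clustered spinous synapses evoke a plateau approaching 0 mV", {
  mod <- star_model(k = 4, term_len = 220)
  tip <- terminal_comps(mod)[1]
  res <- min_synapses_for_nmda_spike(mod, tip, crit, seed = 3)
  expect_false(res$no_spike)
  expect_gt(res$n, 1)
  # at the threshold count the stem voltage satisfies the criterion and the
  # peak approaches the NMDA reversal as the cluster grows
  set.seed(3)
  cand <- pyrcable:::.cluster_candidates(mod, tip, 20)
  placement <- sample(cand, 200, replace = TRUE)
  peak_at <- function(n) {
    ss <- add_spinous_synapses(mod, placement[seq_len(n)],
                               default_synapse_kinetics()[c("ampa", "nmda")], onset = 2)
    sim <- simulate_model(ss$model, 150, synapses = ss$synapses, record = tip)
    max(sim$v[, 1])
  }
  p1 <- peak_at(res$n); p2 <- peak_at(min(200, res$n * 3))
  expect_gt(p2, p1)
  expect_gt(p2, -20) # plateau near the 0 mV reversal
})

test_that("minimal synapse count is lower on high-input-resistance terminals", {
  mod <- star_model(k = 3, term_len = 260)
  arm <- which(mod$comp$section == 1 & mod$comp$is_spine == 0L)
  tip <- arm[length(arm)]   # far end of the arm (high input resistance)
  prox <- arm[1]            # next to the soma (low input resistance)
  expect_gt(input_resistance(mod, tip), input_resistance(mod, prox))
  n_tip <- min_synapses_for_nmda_spike(mod, tip, crit, seed = 5)$n
  n_prox <- min_synapses_for_nmda_spike(mod, prox, crit, seed = 5, n_max = 200)$n
  if (is.na(n_prox)) n_prox <- 201L # criterion unreachable counts as larger
  expect_lt(n_tip, n_prox)
})

test_that("doubling NMDA conductance never raises the synapse threshold", {
  mod <- star_model(k = 4)
  tip <- terminal_comps(mod)[2]
  kin1 <- default_synapse_kinetics()[c("ampa", "nmda")]
  kin2 <- kin1
  kin2$nmda <- synapse_kinetics(2 * 1.31, 8.02, 34.99, voltage_dependent = TRUE)
  n1 <- min_synapses_for_nmda_spike(mod, tip, crit, kinetics = kin1, seed = 7)$n
  n2 <- min_synapses_for_nmda_spike(mod, tip, crit, kinetics = kin2, seed = 7)$n
  expect_lte(n2, n1)
})

test_that("zero synapses never produce a spike", {
  mod <- star_model(k = 3)
  tip <- terminal_comps(mod)[1]
  sim <- simulate_model(mod, 100, record = tip)
  expect_false(detect_nmda_spike(get_trace(sim, tip), crit)$spike)
})

test_that("a decoupled star supports one independent spike per terminal", {
  mod <- star_model(k = 5, term_len = 260, term_diam = 0.5)
  rep <- count_independent_nmda_spikes(mod, crit, strategy = "greedy", seed = 2)
  expect_equal(rep$count, 5)
  expect_true(all(rep$branch_point_peaks$peak_mv < crit$v_threshold))
  expect_lte(rep$count, length(terminal_comps(mod)))
})

test_that("tightly coupled sibling terminals cannot both be independent", {
  # two daughters sharing a short thick mother branch
  mod <- y_tree_model(params = passive_params(), stem = 15, daughter = 140)
  rep <- count_independent_nmda_spikes(mod, crit, strategy = "greedy", seed = 2)
  expect_lte(rep$count, 1)
})

test_that("greedy+backtracking never does worse than one-pass greedy", {
  mod <- star_model(k = 4, term_len = 240)
  rep <- count_independent_nmda_spikes(mod, crit, strategy = "greedy", seed = 6)
  expect_gte(rep$count, 1)
  expect_lte(rep$count, 4)
})
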