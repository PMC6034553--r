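test_that("generated trees satisfy morphology invariants and terminal quotas", {
  for (seed in 1:3) {
    m <- generate_morphology(tree_recipe("human", seed = seed))
    expect_s3_class(m, "morphology") # constructor enforces the invariants
    mod <- build_cable_model(m)
    expect_equal(length(terminal_comps(mod, "basal")),
                 attr(m, "n_basal_terminals"))
    expect_true(all(m$points$r > 0))
  }
})

test_that("terminal-count draws track the human and rat statistics", {
  n_h <- vapply(1:50, function(s) {
    attr(generate_morphology(tree_recipe("human", seed = s)), "n_basal_terminals")
  }, 0L)
  n_r <- vapply(1:50, function(s) {
    attr(generate_morphology(tree_recipe("rat", seed = 1000 + s)), "n_basal_terminals")
  }, 0L)
  expect_lt(abs(mean(n_h) - 44.5), 3)
  expect_lt(abs(mean(n_r) - 31.4), 3)
  expect_gt(mean(n_h), mean(n_r))
})

test_that("generation is byte-identical under a fixed seed", {
  p1 <- withr::local_tempfile(fileext = ".swc")
  p2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(generate_morphology(tree_recipe("human", seed = 42)), p1)
  write_swc(generate_morphology(tree_recipe("human", seed = 42)), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("spine geometry sampling matches the reported distributions, truncated positive", {
  g <- sample_spine_geometries(4000, seed = 8)
  expect_true(all(g > 0))
  expect_lt(abs(mean(g$head_area) - 2.88), 0.15)
  expect_lt(abs(mean(g$neck_length) - 1.34), 0.06)
  expect_lt(abs(mean(g$neck_diameter) - 0.24), 0.02)
  expect_identical(g, sample_spine_geometries(4000, seed = 8))
})

test_that("planted pair-EPSP contacts respect the proximal territory", {
  mod <- build_cable_model(generate_morphology(tree_recipe("human", seed = 3)))
  d <- unlist(lapply(1:40, function(s) {
    generate_pair_epsp(mod, seed = s)$ground_truth$target_distances
  }))
  expect_gt(length(d), 150)
  expect_true(all(d >= 0))
  expect_lt(abs(mean(d) - 140), 3 * 78 / sqrt(length(d)) + 15)
})

test_that("NMDA target pairs order blocked below unblocked and carry ground truth", {
  mod <- y_tree_model()
  tgt <- generate_nmda_targets(mod, dendritic_comps(mod), seed = 5)
  expect_lt(max(tgt$blocked$v_mv), max(tgt$unblocked$v_mv))
  expect_equal(tgt$ground_truth$gamma, 0.0771)
  expect_length(tgt$ground_truth$sites, tgt$ground_truth$n_syn)
  # generators are pure functions of the seed
  tgt2 <- generate_nmda_targets(mod, dendritic_comps(mod), seed = 5)
  expect_identical(tgt$blocked, tgt2$blocked)
})

test_that("spike-train targets carry per-feature means, SDs and an SD floor", {
  mod <- small_spiking_cell()
  tg <- generate_spike_train_targets(mod, example_active_params(),
                                     list(onset = 100, offset = 1100, amp = 0.4),
                                     repeats = 3, jitter = 0.01, seed = 2)
  expect_s3_class(tg$targets, "feature_targets")
  expect_equal(nrow(tg$targets), 17)
  expect_true(all(tg$targets$sd >= 1e-3))
  expect_gt(tg$targets$mean[tg$targets$feature == "mean_frequency"], 5)
  # zero jitter: SDs collapse to the floor for the deterministic features
  tg0 <- generate_spike_train_targets(mod, example_active_params(),
                                      list(onset = 100, offset = 1100, amp = 0.4),
                                      repeats = 2, jitter = 0, seed = 2)
  expect_true(any(tg0$targets$sd <= 1e-3 + 1e-12))
})
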