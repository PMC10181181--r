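test_that("arbor mask contains exactly the in-radius offsets", {
  g <- grid_spec()
  arb <- arbor_mask(g, 175)
  # enumeration oracle: integer offsets with dx^2 + dy^2 <= 3.5^2
  off <- expand.grid(-3:3, -3:3)
  n_expected <- sum(off[, 1]^2 + off[, 2]^2 <= 3.5^2)
  expect_equal(nrow(arb$offsets), n_expected)
  expect_equal(arb$k_count[center_neuron(g)], n_expected)
  expect_lt(arb$k_count[pixel_index(g, 1, 1)], n_expected)   # corner clipped
  # tiny radius keeps at least the co-located pixel
  expect_equal(arbor_mask(g, 30)$k_count, rep(1L, 1600))
  # symmetry of the dense mask on a small grid
  M <- as.matrix(arbor_mask(small_grid(), 175))
  expect_identical(M, t(M))
})

test_that("initial weights are uniform on the arbor support", {
  g <- small_grid()
  w <- init_weights(g, learning_params(w0 = 0.1))
  valid <- !is.na(w$arbor$nbr)
  expect_true(all(w$w_on[valid] == 0.1))
  expect_true(all(w$w_on[!valid] == 0))
  expect_identical(w$w_on, w$w_off)
  expect_equal(scwavemap:::weight_totals(w), 0.1 * 2 * w$arbor$k_count)
})

test_that("trial correlations equal the literal time-averaged products", {
  g <- small_grid()
  wp <- wave_params()
  # silent movie
  m0 <- rgc_activity(make_fixture_raster("random", g, rate = 0), wp)
  C0 <- trial_correlations(m0)
  expect_equal(correlation_at(C0, "on", 1:5, "off", 3:7), rep(0, 5))
  # OFF-copy symmetry: C_OFF,OFF == C_ON,ON at gamma = 0
  r <- make_fixture_raster("planar", g, heading = 0)
  m <- rgc_activity(r, wp)
  C <- trial_correlations(m)
  set.seed(20)
  a <- sample(144, 30, replace = TRUE); b <- sample(144, 30, replace = TRUE)
  expect_equal(correlation_at(C, "off", a, "off", b),
               correlation_at(C, "on", a, "on", b))
  # tau_off >= T_wave: same-pixel ON/OFF kernels never overlap
  expect_equal(correlation_at(C, "on", 1:144, "off", 1:144), rep(0, 144))
  expect_gt(min(correlation_at(C, "on", 1:144, "on", 1:144)), 0)
  # literal formula on a noisy movie
  set.seed(21)
  mn <- rgc_activity(make_fixture_raster("random", g, rate = 0.02),
                     wave_params(gamma = 0.4, r = 0.6))
  Cn <- trial_correlations(mn)
  Tt <- ncol(mn$on)
  for (k in 1:10) {
    i <- sample(144, 1); j <- sample(144, 1)
    expect_equal(correlation_at(Cn, "on", i, "off", j),
                 sum(mn$on[i, ] * mn$off[j, ]) / Tt)
  }
  expect_error(trial_correlations(m, window = integer(0)), "window")
})

test_that("the Hebbian update matches a pencil-and-paper two-input case", {
  g <- grid_spec(n_rows = 2, n_cols = 2, pixel_um = 50, nose_um = c(50, 50))
  lp <- learning_params(eta = 0.01, r_radius_um = 50, w0 = 0.1)
  w <- init_weights(g, lp)
  x <- 1L                                   # corner neuron: 3 in-arbor pixels
  expect_equal(w$arbor$k_count[x], 3L)
  pix <- w$arbor$nbr[!is.na(w$arbor$nbr[, x]), x]
  # single-frame activities: V_on = (2, 1, 0) on those pixels, V_off = 0
  von <- matrix(0, 4, 1); von[pix[1:2], 1] <- c(2, 1)
  C <- structure(list(v = list(on = von, off = matrix(0, 4, 1)), t_trial = 1),
                 class = "trial_correlations")
  d <- hebbian_update(w, C, lp, neurons = x)
  # by hand: V_post = 0.1*(2+1) = 0.3; sub = 0.3^2 / (2*3) = 0.015
  # dw_on = 0.01 * (0.3 * V - 0.015); dw_off = -0.00015
  expect_equal(d$d_on[!is.na(w$arbor$nbr[, x]), x],
               0.01 * (0.3 * von[pix, 1] - 0.015))
  expect_equal(unique(d$d_off[!is.na(w$arbor$nbr[, x]), x]), -0.00015)
  # zero correlations give a zero delta
  d0 <- hebbian_update(w, structure(list(v = list(on = matrix(0, 4, 1),
                                                  off = matrix(0, 4, 1)),
                                         t_trial = 1),
                                    class = "trial_correlations"), lp)
  expect_equal(max(abs(d0$d_on)), 0)
  # equal ON/OFF activity gives identical ON and OFF deltas
  Cs <- structure(list(v = list(on = von, off = von), t_trial = 1),
                  class = "trial_correlations")
  ds <- hebbian_update(w, Cs, lp)
  expect_equal(ds$d_on, ds$d_off)
})

test_that("the weight constraint conserves signed totals exactly", {
  g <- small_grid()
  w <- make_weights(g)
  expect_equal(constrain_weights(w), w)     # no negatives: identity
  # forced example: weights {+3, -1} -> {2, 0}
  w2 <- make_weights(g, fill_on = 0, fill_off = 0)
  v <- which(!is.na(w2$arbor$nbr[, 1]))
  w2$w_on[v[1], 1] <- 3; w2$w_on[v[2], 1] <- -1
  out <- constrain_weights(w2)
  expect_equal(out$w_on[v[1], 1], 2)
  expect_equal(out$w_on[v[2], 1], 0)
  # random tensors: per-neuron signed totals preserved, outputs nonnegative
  set.seed(22)
  w3 <- make_weights(g)
  valid <- !is.na(w3$arbor$nbr)
  w3$w_on[valid] <- rnorm(sum(valid)); w3$w_off[valid] <- rnorm(sum(valid))
  tot_before <- scwavemap:::weight_totals(w3)
  out3 <- suppressWarnings(constrain_weights(w3))
  keep <- colSums(pmax(rbind(w3$w_on, w3$w_off), 0)) >
    -colSums(pmin(rbind(w3$w_on, w3$w_off), 0))
  expect_equal(scwavemap:::weight_totals(out3)[keep], tot_before[keep],
               tolerance = 1e-9)
  expect_true(all(out3$w_on >= 0 & out3$w_off >= 0))
  expect_true(all(out3$w_on[!valid] == 0))
})

test_that("the compiled trainer reproduces the literal R composition", {
  g <- small_grid()
  wp <- wave_params()
  lp <- learning_params()
  r <- make_fixture_raster("planar", g, heading = 0)
  fit <- sc_train(g, wp, lp, waves = structure(list(r), class = "wave_ensemble"),
                  neurons = "all", seed = 1)
  # R path: movie -> whole-epoch trial correlations -> update -> constraint
  w <- init_weights(g, lp)
  m <- rgc_activity(r, wp)
  C <- trial_correlations(m)
  d <- hebbian_update(w, C, lp)
  w$w_on <- w$w_on + d$d_on
  w$w_off <- w$w_off + d$d_off
  w <- constrain_weights(w)
  expect_equal(fit$weights$w_on, w$w_on, tolerance = 1e-12)
  expect_equal(fit$weights$w_off, w$w_off, tolerance = 1e-12)
})

test_that("zero OFF delay preserves exact ON/OFF symmetry through training", {
  g <- small_grid()
  wp <- wave_params(tau_off_s = 0)
  fit <- sc_train(g, wp, learning_params(n_waves = 25), seed = 5)
  expect_identical(fit$weights$w_on, fit$weights$w_off)
  rf <- sc_rf(fit$weights, center_neuron(g))
  expect_lt(max(abs(rf$field)), 1e-12)
  expect_equal(max(onoff_input_segregation(fit$weights), na.rm = TRUE), 0)
})

test_that("training is bit-reproducible given a seed", {
  g <- small_grid()
  wp <- wave_params(gamma = 0.2, r = 0.8)
  f1 <- sc_train(g, wp, learning_params(n_waves = 10), seed = 31)
  f2 <- sc_train(g, wp, learning_params(n_waves = 10), seed = 31)
  expect_identical(f1$weights$w_on, f2$weights$w_on)
  expect_identical(f1$weights$w_off, f2$weights$w_off)
})

test_that("a directed ensemble displaces the ON centroid along the heading", {
  g <- grid_spec()
  ctr <- center_neuron(g)
  wp <- wave_params(tau_off_s = 1.5)
  set.seed(33)
  waves <- simulate_waves(g, wp, 120, mode = "ensemble",
                          heading_dist = biased_direction_ensemble(1),
                          target = ctr)
  fit <- sc_train(g, wp, learning_params(), waves = waves, neurons = "center",
                  seed = 6)
  off <- fit$weights$arbor$offsets
  won <- fit$weights$w_on[, ctr]; wof <- fit$weights$w_off[, ctr]
  disp <- colSums(off * won) / sum(won) - colSums(off * wof) / sum(wof)
  # heading 0 (+AP): ON centroid leads along +AP (the dj axis)
  expect_gt(disp["dj"], 0.2)
  expect_lt(abs(atan2(disp["di"], disp["dj"])) * 180 / pi, 22.5)
})

test_that("plasticity noise and update dropout knobs perturb but keep support", {
  g <- small_grid()
  wp <- wave_params()
  f0 <- sc_train(g, wp, learning_params(n_waves = 8), seed = 7)
  fn <- sc_train(g, wp, learning_params(n_waves = 8, plasticity_noise_sd = 0.5,
                                        update_dropout_p = 0.3), seed = 7)
  expect_false(identical(f0$weights$w_on, fn$weights$w_on))
  valid <- !is.na(fn$weights$arbor$nbr)
  expect_true(all(fn$weights$w_on[!valid] == 0))
  expect_true(all(fn$weights$w_on >= 0))
})
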