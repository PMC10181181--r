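test_that("sigma_prop optimisation hits the target propagation bias", {
  s <- optimize_sigma_prop(0.35)
  expect_equal(propagation_bias(s), 0.35, tolerance = 1e-6)
  # uniform limit
  expect_lt(propagation_bias(50), 0.01)
  # module bias matches an independent direct summation of the discrete form
  th <- (1:8) * 2 * pi / 8
  g <- exp(-scwavemap:::wrap_angle(th)^2 / (2 * s^2))
  p <- g / sum(g)
  expect_equal(Mod(sum(p * exp(1i * th))), propagation_bias(s),
               tolerance = 1e-12)
  expect_error(optimize_sigma_prop(1.5), "range")
  expect_error(optimize_sigma_prop(0), "range")
})

test_that("local propagation distribution is normalised, peaked and equivariant", {
  s <- optimize_sigma_prop(0.35)
  p0 <- local_propagation_distribution(s, 0)
  th <- attr(p0, "angles")
  expect_equal(sum(p0), 1)
  expect_equal(th[which.max(p0)], 0)
  # symmetric about the heading
  expect_equal(p0[th == pi / 4], p0[th == -pi / 4])
  expect_equal(p0[th == 3 * pi / 4], p0[th == -3 * pi / 4])
  # rotating the heading permutes the probabilities cyclically
  p1 <- local_propagation_distribution(s, pi / 4)
  for (k in seq_along(th))
    expect_equal(p1[which(abs(scwavemap:::wrap_angle(th - (th[k] + pi / 4))) < 1e-9)],
                 p0[k], ignore_attr = TRUE)
  # resultant bias of the distribution equals b
  expect_equal(polar_bias_index(th, as.numeric(p0)), 0.35, tolerance = 1e-6)
})

test_that("AI-source and initiation sampling have the stated distributions", {
  g <- grid_spec()
  set.seed(10)
  src <- sample_ai_source(g, 150, n = 1e4)
  expect_equal(colMeans(src), g$nose_um, tolerance = 3 * 150 / 100)
  expect_equal(apply(src, 2, sd), c(150, 150), tolerance = 0.05 * 150)
  set.seed(11)
  init <- initiate_wave(g, 2e5)
  expect_true(all(init >= 1 & init <= 1600))
  expect_gt(chisq.test(tabulate(init, 1600))$p.value, 0.001)
  set.seed(12); a <- initiate_wave(g, 50)
  set.seed(12); b <- initiate_wave(g, 50)
  expect_identical(a, b)
})

test_that("wave heading rounds to the nearest neighbour angle, midpoints up", {
  expect_equal(wave_heading(c(500, 0), c(100, 0)), 0)          # posterior init
  # exactly midway between 0 and pi/4 rounds up
  expect_equal(wave_heading(c(cos(pi / 8), sin(pi / 8)), c(0, 0)), pi / 4)
  set.seed(13)
  init <- matrix(runif(2e4, 0, 2000), ncol = 2)
  ai <- matrix(runif(2e4, 0, 2000), ncol = 2)
  h <- wave_heading(init, ai)
  th <- scwavemap:::wrap_angle((1:8) * pi / 4)
  # brute force nearest-angle search
  v <- init - ai
  ang <- atan2(v[, 2], v[, 1])
  brute <- sapply(ang, function(a) th[which.min(abs(scwavemap:::wrap_angle(th - a)))])
  expect_equal(h, brute)
})

test_that("propagation respects threshold, refractoriness and heading", {
  g <- grid_spec()
  wp <- wave_params(n_theta = 9)
  set.seed(14)
  r <- propagate_wave(g, wp, init = center_neuron(g), heading = 0)
  expect_equal(r$n_frames, 1L)            # unreachable threshold
  # refractory invariant over epochs
  wp <- wave_params()
  set.seed(15)
  for (w in 1:30) {
    r <- propagate_wave(g, wp, heading = sample(scwavemap:::wrap_angle((1:8) * pi / 4), 1),
                        on_runaway = "truncate")
    act <- cbind(unlist(r$frames),
                 rep.int(seq_along(r$frames), lengths(r$frames)))
    byp <- split(act[, 2], act[, 1])
    gaps <- unlist(lapply(byp, function(t) diff(sort(t))))
    if (length(gaps)) expect_gt(min(gaps), wp$tau_iei_frames)
    # every activation after frame 1 had enough active Moore neighbours
    nbr <- scwavemap:::neighbor_index(g)
    for (t in seq_len(r$n_frames)[-1]) {
      prev <- r$frames[[t - 1]]
      for (p in r$frames[[t]]) {
        nb <- nbr[p, ]
        expect_gte(sum(nb[!is.na(nb)] %in% prev), wp$n_theta)
      }
    }
  }
  # strong bias: mean front displacement tracks the heading
  wp <- wave_params(b = 0.9)
  set.seed(16)
  pos <- pixel_positions(g)
  errs <- replicate(60, {
    r <- propagate_wave(g, wp, init = center_neuron(g), heading = pi / 2,
                        on_runaway = "truncate")
    com <- colMeans(pos[r$frames[[r$n_frames]], , drop = FALSE])
    d <- com - pos[center_neuron(g), ]
    abs(scwavemap:::wrap_angle(atan2(d[2], d[1]) - pi / 2))
  })
  expect_lt(mean(errs) * 180 / pi, 10)
})

test_that("RGC activity is a delayed boxcar copy with the stated noise", {
  g <- grid_spec()
  wp <- wave_params()                      # tau_off 1 s, frame 0.5 s
  set.seed(17)
  r <- propagate_wave(g, wp, heading = 0, on_runaway = "truncate")
  m <- rgc_activity(r, wp)
  Tt <- ncol(m$on)
  expect_equal(m$off[, 3:Tt], m$on[, 1:(Tt - 2)])        # off[t] == on[t-2]
  # each activation contributes exactly 2 frames of rate r
  expect_equal(sum(m$on), wp$r * 2 * length(unlist(r$frames)))
  expect_true(all(m$on %in% c(0, wp$r)))
  # the OFF-copy holds under background noise too (shared noise trace)
  wpn <- wave_params(gamma = 0.3, r = 0.7)
  set.seed(18)
  mn <- rgc_activity(r, wpn)
  Tt <- ncol(mn$on)
  expect_equal(mn$off[, 3:Tt], mn$on[, 1:(Tt - 2)])
  # noise variance in never-active pixels is ~ gamma^2
  silent <- setdiff(seq_len(1600), unique(unlist(r$frames)))
  expect_equal(var(as.numeric(mn$on[silent, ])), 0.09, tolerance = 0.1)
})

test_that("fixture rasters have their stated structure", {
  g <- grid_spec()
  r <- make_fixture_raster("planar", g, heading = 0, speed = 1)
  # pixel (i, j) activates at frame j
  for (t in c(1, 10, 40))
    expect_setequal(r$frames[[t]], pixel_index(g, 1:40, t))
  rr <- make_fixture_raster("ring", g, center = c(20, 20))
  act <- cbind(unlist(rr$frames), rep.int(seq_along(rr$frames), lengths(rr$frames)))
  rc <- pixel_rc(g, act[, 1])
  d <- sqrt((rc[, "i"] - 20)^2 + (rc[, "j"] - 20)^2)
  expect_equal(act[, 2], floor(d) + 1)     # time is a function of distance only
  expect_equal(sum(lengths(make_fixture_raster("random", g, rate = 0)$frames)), 0)
})

test_that("wave ensembles are reproducible and record headings", {
  g <- grid_spec()
  wp <- wave_params()
  set.seed(19); e1 <- simulate_waves(g, wp, 5)
  set.seed(19); e2 <- simulate_waves(g, wp, 5)
  expect_identical(lapply(e1, `[[`, "frames"), lapply(e2, `[[`, "frames"))
  expect_length(attr(e1, "headings"), 5)
  expect_true(all(attr(e1, "headings") %in% scwavemap:::wrap_angle((1:8) * pi / 4)))
})
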