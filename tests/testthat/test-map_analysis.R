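test_that("net wave vectors track fixture fronts", {
  g <- grid_spec()
  planar <- make_fixture_raster("planar", g, heading = 0, speed = 1)
  fl <- wave_flow_field(planar, g)
  interior <- which(pixel_rc(g, 1:1600)[, "i"] %in% 5:35 &
                      pixel_rc(g, 1:1600)[, "j"] %in% 5:35)
  expect_true(all(fl$u[interior, "ap"] > 0))
  expect_lt(max(abs(fl$u[interior, "ml"])), 1e-9)
  # ring centred on a pixel: net vector there vanishes by symmetry
  ring <- make_fixture_raster("ring", g, center = c(20, 20))
  u0 <- net_wave_vector(ring, g, pixel_index(g, 20, 20))
  expect_lt(sqrt(sum(u0^2)), 15)           # ~0 on the 50 um pixel scale
  # reversing the frame order negates the field
  rev_r <- planar
  rev_r$frames <- rev(planar$frames)
  expect_equal(wave_flow_field(rev_r, g)$u, -fl$u)
  # empty raster set gives a zero field
  expect_equal(max(wave_flow_field(list(), g)$magnitude), 0)
})

test_that("wave direction bias matches closed-form circular statistics", {
  expect_equal(wave_direction_bias(rep(pi / 4, 10)), 1)
  expect_equal(wave_direction_bias(rep(scwavemap:::wrap_angle((1:8) * pi / 4), 25)),
               0, tolerance = 1e-12)
  set.seed(50)
  ang <- seq(-pi, pi, length.out = 2001)[-1]
  p <- exp(3 * cos(ang)); p <- p / sum(p)
  h <- sample(ang, 4e4, replace = TRUE, prob = p)
  expect_equal(wave_direction_bias(h), besselI(3, 1) / besselI(3, 0),
               tolerance = 0.02)
  expect_error(wave_direction_bias(numeric(0)), "heading")
})

test_that("orientation preference is orthogonal to the lobe axis", {
  for (axis in c(0, 30, 60, 90, 120, 150)) {
    f <- two_lobe_field(axis_deg = axis)
    op <- orientation_preference(f)
    expect_equal(acute_orientation_diff(op[["theta_pref"]], (axis + 90) %% 180),
                 0, tolerance = 3)
    # tuning-curve argmax agrees within one bin
    tc <- tuning_curve(f)
    expect_lte(acute_orientation_diff(tc$theta[which.max(tc$L)],
                                      op[["theta_pref"]]), 22.5)
  }
  # rotationally symmetric field is untuned
  xy <- seq(-40, 40)
  blob <- exp(-outer(xy^2, xy^2, "+") / (2 * 8^2))
  expect_lt(orientation_preference(blob)[["mu"]], 0.02)
  expect_error(orientation_preference(matrix(0, 9, 9)), "zero")
})

test_that("tuning curves scale linearly and gOSI matches hand arithmetic", {
  f <- two_lobe_field()
  tc1 <- tuning_curve(f); tc3 <- tuning_curve(3 * f)
  expect_equal(tc3$L, 3 * tc1$L)
  expect_equal(tuning_curve(matrix(0, 11, 11))$L, rep(0, 8))
  expect_equal(gosi(rep(2, 8)), 0, tolerance = 1e-12)
  expect_equal(gosi(c(0, 0, 5, 0, 0, 0, 0, 0)), 1)
  # 8-term arithmetic oracle for L = (2,1,0,1,2,1,0,1) over 22.5 deg bins
  L <- c(2, 1, 0, 1, 2, 1, 0, 1)
  th <- (0:7) * 22.5 * pi / 180
  num <- sqrt(sum(L * cos(2 * th))^2 + sum(L * sin(2 * th))^2)
  expect_equal(gosi(L), num / sum(L))
  expect_true(is.na(gosi(rep(0, 8))))
})

test_that("segregation indices behave at their extremes", {
  g <- small_grid()
  x <- center_neuron(g)
  expect_equal(max(onoff_input_segregation(make_weights(g)), na.rm = TRUE), 0)
  # disjoint equal-mass supports segregate fully
  w <- make_weights(g, fill_on = 0, fill_off = 0)
  v <- which(!is.na(w$arbor$nbr[, x]))
  w$w_on[v[1:3], x] <- 1; w$w_off[v[4:6], x] <- 1
  expect_equal(onoff_input_segregation(w, x), 1)
  # ON-only input: balance factor zero
  w2 <- make_weights(g, fill_on = 0.2, fill_off = 0)
  expect_equal(onoff_input_segregation(w2, x), 0)
  # subfield index: identical parts -> 0, disjoint lobes -> 1
  rf <- list(on_part = matrix(1, 5, 5), off_part = matrix(-1, 5, 5))
  expect_equal(subfield_segregation(rf), 0)
  rf2 <- list(on_part = cbind(matrix(1, 5, 2), matrix(0, 5, 3)),
              off_part = cbind(matrix(0, 5, 3), matrix(-1, 5, 2)))
  expect_equal(subfield_segregation(rf2), 1)
  # random smooth fields: equals the direct pixelwise evaluation
  set.seed(51)
  rf3 <- list(on_part = matrix(rnorm(64), 8), off_part = matrix(rnorm(64), 8))
  on_p <- pmax(rf3$on_part, 0); off_n <- pmax(-rf3$off_part, 0)
  direct <- (sum(abs(on_p - off_n)) - abs(sum(on_p - off_n))) /
    (sum(on_p) + sum(off_n))
  expect_equal(subfield_segregation(rf3), direct)
})

test_that("LHI measures local orientation homogeneity", {
  g <- grid_spec(n_rows = 20, n_cols = 20, nose_um = c(250, 500))
  n <- 400
  expect_equal(lhi(rep(37, n), g), rep(1, n), tolerance = 1e-9)
  set.seed(52)
  v <- lhi(runif(n, 0, 180), g)
  expect_lt(mean(v), 0.25)                 # i.i.d. map decoheres
  expect_true(all(v >= 0 & v <= 1 + 1e-12))
  # 0/90 checkerboard cancels in double angle
  rc <- pixel_rc(g, 1:n)
  chk <- ifelse((rc[, "i"] + rc[, "j"]) %% 2 == 0, 0, 90)
  expect_lt(max(lhi(chk, g)), 0.1)
  # unnormalised form is the plain Gaussian-weighted sum
  raw <- lhi(rep(10, n), g, normalize = FALSE)
  expect_true(all(raw <= 1 + 1e-9) && all(raw > 0))
})

test_that("the singularity is recovered from synthetic flow fields", {
  g <- grid_spec()
  pos <- pixel_positions(g)
  cc <- c(700, 900)
  flow <- structure(list(u = sweep(pos, 2, cc), n_rows = 40, n_cols = 40,
                         pixel_um = 50), class = "wave_flow")
  flow$magnitude <- sqrt(rowSums(flow$u^2))
  s <- find_singularity(flow)
  expect_true(s$ok)
  expect_lt(max(abs(s$position_um - cc)), 25 + 1e-9)   # within half a pixel
  # adding a constant k shifts the zero of ||x - c + k|| to c - k
  k <- c(150, -100)
  flow2 <- flow
  flow2$u <- sweep(flow$u, 2, -k)
  flow2$magnitude <- sqrt(rowSums(flow2$u^2))
  s2 <- find_singularity(flow2)
  expect_lt(max(abs(s2$position_um - (cc - k))), 25 + 1e-9)
  flow0 <- flow; flow0$u[] <- 0; flow0$magnitude[] <- 0
  expect_false(find_singularity(flow0)$ok)
})

test_that("alignment statistics recover chance and perfect alignment", {
  g <- grid_spec()
  fit <- list(weights = make_weights(g), grid = g)
  opm <- orientation_map(make_weights(g), grid = g)
  # theta set exactly to the concentric angles
  opm$theta_pref <- opm$conc_angle
  opm$conc_diff <- acute_orientation_diff(opm$theta_pref, opm$conc_angle)
  st <- alignment_stats(opm)
  expect_equal(st$mean_diff, 0)
  # radial angles are orthogonal everywhere
  opm$theta_pref <- (opm$conc_angle + 90) %% 180
  opm$conc_diff <- acute_orientation_diff(opm$theta_pref, opm$conc_angle)
  expect_equal(alignment_stats(opm)$mean_diff, 90)
  # i.i.d. uniform orientations sit at the 45-degree chance level
  set.seed(53)
  opm$theta_pref <- runif(nrow(opm), 0, 180)
  opm$conc_diff <- acute_orientation_diff(opm$theta_pref, opm$conc_angle)
  expect_equal(alignment_stats(opm)$mean_diff, 45, tolerance = 1.5)
})

test_that("the OFF-to-ON cross-correlogram peaks at the OFF delay", {
  g <- small_grid()
  r <- make_fixture_raster("planar", g, heading = 0)
  m <- rgc_activity(r, wave_params(tau_off_s = 1))
  cc <- off_on_crosscorrelogram(m)
  expect_equal(cc$lag_frames[which.max(cc$cor)], 2)      # +1 s
  expect_equal(cc$lag_s[which.max(cc$cor)], 1)
  m0 <- rgc_activity(r, wave_params(tau_off_s = 0))
  cc0 <- off_on_crosscorrelogram(m0)
  expect_equal(cc0$lag_frames[which.max(cc0$cor)], 0)
  # per-wave randomised delays flatten the correlogram at +2
  set.seed(54)
  movies <- lapply(sample(seq(-2, 2, 0.5), 24, replace = TRUE), function(d)
    rgc_activity(r, wave_params(), tau_off_s = d))
  ccr <- off_on_crosscorrelogram(movies)
  expect_lt(ccr$cor[ccr$lag_frames == 2], cc$cor[cc$lag_frames == 2])
  expect_error(off_on_crosscorrelogram(
    rgc_activity(make_fixture_raster("random", g, rate = 0), wave_params())),
    "silent")
})

test_that("orientation maps expose per-neuron statistics and flow attributes", {
  g <- small_grid()
  set.seed(55)
  wp <- wave_params(sigma_ai_um = 2000)
  fit <- sc_train(g, wp, learning_params(n_waves = 60), seed = 8,
                  keep_waves = TRUE)
  opm <- orientation_map(fit)
  expect_s3_class(opm, "orientation_map")
  expect_equal(nrow(opm), n_pixels(g))
  expect_true(all(na.omit(opm$theta_pref) >= 0 & na.omit(opm$theta_pref) < 180))
  expect_true(all(na.omit(opm$gosi) >= 0 & na.omit(opm$gosi) <= 1))
  expect_true(all(na.omit(opm$i_seg) >= 0 & na.omit(opm$i_seg) <= 1))
  expect_true(all(na.omit(opm$lhi) >= 0 & na.omit(opm$lhi) <= 1 + 1e-12))
  expect_false(is.null(attr(opm, "flow")))
  tmp <- tempfile(fileext = ".csv")
  write_map_csv(opm, tmp)
  re <- read.csv(tmp)
  expect_identical(names(re), c("neuron", "i", "j", "ap_um", "ml_um",
                                "theta_pref", "tuning_strength", "gosi",
                                "i_seg", "lhi", "conc_diff"))
  unlink(tmp)
})
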