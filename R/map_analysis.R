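# Derived statistics: wave-flow vectors and bias, orientation preference via
# Fourier analysis, tuning curves and gOSI, ON/OFF segregation indices, LHI,
# singularity localisation, concentric-angle alignment, and the OFF-to-ON
# cross-correlogram.

# ---- Fourier machinery ------------------------------------------------------

# cached per pad size: |omega|, double-angle phase factor for the stimulus
# orientation convention, DC mask and the 8 orientation-bin indices.
fourier_plan <- function(pad = 128L, n_bins = 8L) {
  key <- paste0("fplan_", pad, "_", n_bins)
  hit <- .scwavemap_cache[[key]]
  if (!is.null(hit)) return(hit)
  fr <- c(seq(0, floor(pad / 2)), seq(-ceiling(pad / 2) + 1, -1)) / pad
  fy <- matrix(fr, pad, pad)          # row index -> y frequency
  fx <- matrix(fr, pad, pad, byrow = TRUE)
  wmag <- sqrt(fx^2 + fy^2)
  # preferred stimulus orientation: stripes orthogonal to the frequency vector
  ori <- (atan2(fy, fx) * 180 / pi + 90) %% 180
  phase <- exp(2i * (atan2(fy, fx) + pi / 2))
  dc <- wmag == 0
  # restrict to the inscribed Nyquist disc so every orientation bin covers
  # the same range of spatial frequencies (a square plane over-counts the
  # diagonal orientations through its corners)
  out <- dc | wmag > 0.5
  # the tuning curve samples |spectrum| along the ray of each orientation:
  # precompute bilinear gather indices/weights on the centred (fft-shifted)
  # plane, radii 1 .. pad/2 - 1 in both directions
  shift_ord <- c((pad / 2 + 1):pad, 1:(pad / 2))
  ctr <- pad / 2 + 1
  centers <- (seq_len(n_bins) - 1L) * 180 / n_bins
  rays <- lapply(centers, function(th) {
    phi <- (th - 90) * pi / 180          # frequency-vector angle of the ray
    r <- c(seq_len(pad / 2 - 1), -seq_len(pad / 2 - 1))
    px <- ctr + r * cos(phi)
    py <- ctr + r * sin(phi)
    x0 <- floor(px); y0 <- floor(py)
    gx <- px - x0; gy <- py - y0
    idx <- function(yy, xx) (pmin(pmax(xx, 1L), pad) - 1L) * pad +
      pmin(pmax(yy, 1L), pad)
    list(i = c(idx(y0, x0), idx(y0 + 1, x0), idx(y0, x0 + 1), idx(y0 + 1, x0 + 1)),
         w = c((1 - gx) * (1 - gy), (1 - gx) * gy, gx * (1 - gy), gx * gy))
  })
  plan <- list(pad = pad, wmag = wmag, phase = phase, dc = dc, out = out,
               shift_ord = shift_ord, rays = rays, centers = centers)
  .scwavemap_cache[[key]] <- plan
  plan
}

rf_spectrum <- function(field, pad = 128L) {
  if (nrow(field) > pad || ncol(field) > pad)
    stop("field larger than the Fourier pad")
  P <- matrix(0, pad, pad)
  P[seq_len(nrow(field)), seq_len(ncol(field))] <- field
  Mod(stats::fft(P))
}

#' Orientation preference of a receptive field
#'
#' Estimated from the Fourier amplitude spectrum of the RF: the
#' frequency-weighted double-angle resultant
#' \eqn{\mu = \sum_\omega |\hat\Psi(\omega)| \|\omega\|
#' e^{2i(\arg\omega + \pi/2)} / \sum_\omega |\hat\Psi(\omega)|} (DC excluded),
#' with \eqn{\theta_{pref} = \arg(\mu)/2} mapped to \code{[0, 180)} degrees.
#' The \eqn{+\pi/2} rotation converts the frequency-vector axis into the
#' stimulus (stripe) orientation, so a two-lobed ON/OFF field with lobes
#' displaced along an axis prefers the orientation orthogonal to that axis.
#'
#' @param rf A \code{receptive_field} or a plain field matrix.
#' @param pad Zero-padding size for the FFT.
#' @param tol Resultant magnitude below which the neuron is flagged untuned.
#' @param on_zero \code{"error"} (default) or \code{"na"}: behaviour for an
#'   all-zero field, whose orientation is undefined.
#' @return Named vector \code{c(theta_pref, mu)} (degrees; resultant
#'   magnitude) with attribute \code{untuned}.
#' @export
orientation_preference <- function(rf, pad = 128L, tol = 1e-4,
                                   on_zero = c("error", "na")) {
  on_zero <- match.arg(on_zero)
  f <- if (inherits(rf, "receptive_field")) rf$field else rf
  if (all(f == 0)) {
    if (on_zero == "error") stop("orientation undefined for an all-zero field")
    out <- c(theta_pref = NA_real_, mu = NA_real_)
    attr(out, "untuned") <- TRUE
    return(out)
  }
  pl <- fourier_plan(pad)
  A <- rf_spectrum(f, pad)
  A[pl$out] <- 0
  mu <- sum(A * pl$wmag * pl$phase) / sum(A)
  out <- c(theta_pref = (Arg(mu) * 90 / pi) %% 180, mu = Mod(mu))
  attr(out, "untuned") <- Mod(mu) < tol
  out
}

#' Orientation tuning curve from the RF spectrum
#'
#' Sums the Fourier amplitudes over the spatial frequencies of each
#' orientation: for every orientation on the \code{n_bins} grid (22.5-degree
#' steps for 8 bins) the centred amplitude spectrum is sampled along the
#' corresponding frequency ray (bilinear interpolation, both directions, DC
#' excluded) and summed.  The tuning strength is \code{max(L)}.
#'
#' @inheritParams orientation_preference
#' @param n_bins Number of orientations.
#' @return A list with orientations \code{theta} (degrees) and amplitudes
#'   \code{L}.
#' @export
tuning_curve <- function(rf, pad = 128L, n_bins = 8L) {
  f <- if (inherits(rf, "receptive_field")) rf$field else rf
  pl <- fourier_plan(pad, n_bins)
  A <- rf_spectrum(f, pad)[pl$shift_ord, pl$shift_ord]
  L <- vapply(pl$rays, function(rr) sum(rr$w * A[rr$i]), 0)
  list(theta = pl$centers, L = L)
}

#' @describeIn tuning_curve Tuning strength: the maximum of the curve.
#' @export
tuning_strength <- function(rf, pad = 128L, n_bins = 8L) {
  max(tuning_curve(rf, pad, n_bins)$L)
}

#' Global orientation selectivity index
#'
#' \eqn{I_{gOS} = |\sum_\theta L(\theta) e^{2i\theta}| / \sum_\theta
#' L(\theta)}: 0 for a flat curve, 1 for a point mass.
#'
#' @param L A tuning curve: the list from \code{\link{tuning_curve}} or a
#'   vector of nonnegative amplitudes over equispaced orientation bins.
#' @return A scalar in \code{[0, 1]}, \code{NA} for an all-zero curve.
#' @export
gosi <- function(L) {
  if (is.list(L)) {
    theta <- L$theta * pi / 180
    L <- L$L
  } else {
    theta <- (seq_along(L) - 1) * pi / length(L)
  }
  if (any(L < 0)) stop("tuning amplitudes must be nonnegative")
  s <- sum(L)
  if (s == 0) return(NA_real_)
  Mod(sum(L * exp(2i * theta))) / s
}

# ---- segregation indices ----------------------------------------------------

#' ON/OFF input segregation index
#'
#' \eqn{I_{SEG} = [\sum_a |W_D| - |\sum_a W_D|] / \sum_a W_S} with
#' \eqn{W_D = w_{ON} - w_{OFF}} and \eqn{W_S = w_{ON} + w_{OFF}}: the product
#' of input balance and spatial non-overlap, in \code{[0, 1]}.
#'
#' @param weights A \code{synaptic_weights} object.
#' @param neuron Optional single neuron index; default: all neurons.
#' @return Scalar (single neuron) or vector over neurons; \code{NA} where the
#'   total input weight is zero.
#' @export
onoff_input_segregation <- function(weights, neuron = NULL) {
  wd <- weights$w_on - weights$w_off
  ws <- colSums(weights$w_on) + colSums(weights$w_off)
  i_seg <- ifelse(ws > 0, (colSums(abs(wd)) - abs(colSums(wd))) / ws, NA_real_)
  if (!is.null(neuron)) {
    if (ws[neuron] == 0) stop("segregation undefined: zero total input weight")
    return(i_seg[neuron])
  }
  i_seg
}

#' ON/OFF subfield segregation of a receptive field
#'
#' The same index evaluated on the rendered subfields, using the positive
#' part of the ON subfield and the absolute negative part of the OFF
#' subfield.
#'
#' @param rf A \code{receptive_field} with polarity parts.
#' @return A scalar in \code{[0, 1]}.
#' @export
subfield_segregation <- function(rf) {
  on_p <- pmax(rf$on_part, 0)
  off_n <- pmax(-rf$off_part, 0)
  s <- sum(on_p) + sum(off_n)
  if (s == 0) stop("subfield segregation undefined: both parts zero")
  d <- on_p - off_n
  (sum(abs(d)) - abs(sum(d))) / s
}

# ---- local homogeneity ------------------------------------------------------

#' Local homogeneity index of an orientation map
#'
#' Gaussian-weighted circular coherence of the orientation preferences around
#' each SC position:
#' \eqn{I_{LH}(x) = |\sum_y G(y; x, \sigma_{LH}) e^{2i\theta_y}|}, divided by
#' \eqn{\sum_y G(y; x, \sigma_{LH})} when \code{normalize = TRUE} (default)
#' so a perfectly uniform map scores exactly 1.  The unnormalised form (the
#' Gaussian-weighted Riemann sum alone) is available with
#' \code{normalize = FALSE}.
#'
#' @param theta_deg Orientation preferences in degrees, one per pixel
#'   (column-major); \code{NA}s are excluded from the sums.
#' @param grid A \code{\link{grid_spec}}.
#' @param sigma_lh_um Gaussian neighbourhood spread, micrometres.
#' @param normalize Divide by the local weight mass (bounded in [0, 1]).
#' @return LHI per pixel.
#' @export
lhi <- function(theta_deg, grid, sigma_lh_um = 100, normalize = TRUE) {
  pos <- pixel_positions(grid)
  n <- nrow(pos)
  stopifnot(length(theta_deg) == n)
  d2 <- outer(pos[, 1], pos[, 1], "-")^2 + outer(pos[, 2], pos[, 2], "-")^2
  W <- exp(-d2 / (2 * sigma_lh_um^2)) / (2 * pi * sigma_lh_um^2)
  z <- exp(2i * theta_deg * pi / 180)
  ok <- !is.na(z)
  z[!ok] <- 0
  num <- Mod(W %*% z)
  if (normalize) {
    den <- W %*% as.numeric(ok)
    out <- ifelse(den > 0, num / den, NA_real_)
  } else {
    out <- num * grid$pixel_um^2     # Riemann sum of the density integral
  }
  as.numeric(out)
}

# ---- wave flow --------------------------------------------------------------

# 3x3 box sum with zero padding
box3 <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  P <- matrix(0, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- M
  out <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    out <- out + P[di + seq_len(nr), dj + seq_len(nc)]
  out
}

flow_accumulate <- function(raster, grid, ux, uy) {
  nr <- grid$n_rows; nc <- grid$n_cols
  pos <- pixel_positions(grid)
  X <- matrix(pos[, 1], nr, nc)
  Y <- matrix(pos[, 2], nr, nc)
  Sp <- NULL; cxp <- NULL; cyp <- NULL
  A <- matrix(0, nr, nc)
  for (t in seq_len(raster$n_frames)) {
    A[] <- 0
    A[raster$frames[[t]]] <- 1
    S <- box3(A)
    cx <- box3(A * X); cy <- box3(A * Y)
    nz <- S > 0
    cx[nz] <- cx[nz] / S[nz]; cy[nz] <- cy[nz] / S[nz]
    if (!is.null(Sp)) {
      both <- nz & (Sp > 0)
      ux[both] <- ux[both] + (cx[both] - cxp[both])
      uy[both] <- uy[both] + (cy[both] - cyp[both])
    }
    Sp <- S; cxp <- cx; cyp <- cy
  }
  list(ux = ux, uy = uy)
}

#' Net wave-flow field
#'
#' For every pixel, the summed frame-to-frame displacement of the activity
#' centre of mass within its 3 x 3 local window, accumulated over frames and
#' epochs.  Frames whose window is empty at t or t-1 contribute nothing, and
#' displacements never cross epoch boundaries.
#'
#' @param rasters A \code{wave_ensemble}, list of \code{wave_raster}s, or a
#'   single raster.
#' @param grid A \code{\link{grid_spec}}.
#' @return An object of class \code{wave_flow}: list with \code{u} (n x 2
#'   matrix of net vectors, micrometres), \code{magnitude} and
#'   \code{direction} views, and the grid dimensions.
#' @export
wave_flow_field <- function(rasters, grid) {
  if (inherits(rasters, "wave_raster")) rasters <- list(rasters)
  nr <- grid$n_rows; nc <- grid$n_cols
  ux <- matrix(0, nr, nc); uy <- matrix(0, nr, nc)
  for (r in rasters) {
    acc <- flow_accumulate(r, grid, ux, uy)
    ux <- acc$ux; uy <- acc$uy
  }
  u <- cbind(ap = as.numeric(ux), ml = as.numeric(uy))
  structure(list(u = u, magnitude = sqrt(rowSums(u^2)),
                 direction = atan2(u[, 2], u[, 1]),
                 n_rows = nr, n_cols = nc, pixel_um = grid$pixel_um),
            class = "wave_flow")
}

#' @describeIn wave_flow_field Net wave vector of a single pixel.
#' @param pixel Linear pixel index.
#' @export
net_wave_vector <- function(rasters, grid, pixel) {
  wave_flow_field(rasters, grid)$u[pixel, ]
}

#' Wave propagation direction bias
#'
#' Polar bias index of the normalised heading histogram, computed as the
#' resultant magnitude of the unit heading vectors.
#'
#' @param headings Wave headings in radians (at least one).
#' @return A scalar in \code{[0, 1]}.
#' @export
wave_direction_bias <- function(headings) {
  if (!length(headings)) stop("at least one heading is required")
  Mod(mean(exp(1i * headings)))
}

# separable Gaussian blur with edge renormalisation
gaussian_blur <- function(M, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  blur1 <- function(A) {
    nr <- nrow(A); nc <- ncol(A)
    out <- matrix(0, nr, nc)
    for (s in -r:r) {
      rows <- pmin(pmax(seq_len(nr) + s, 1L), nr)   # replicate edges
      out <- out + k[s + r + 1] * A[rows, , drop = FALSE]
    }
    out / sum(k)
  }
  t(blur1(t(blur1(M))))
}

#' Locate the map singularity from the wave-flow field
#'
#' The singularity of the concentric orientation map is estimated as the
#' position of minimal wave-flow magnitude.  The magnitude field is smoothed
#' with a 2-pixel Gaussian before taking the argmin; ties are broken by the
#' centroid of the tied set.
#'
#' @param flow A \code{wave_flow}.
#' @param sigma_px Smoothing spread in pixels.
#' @param tol Relative tolerance defining the tied minimal set.
#' @return A list with \code{position_um} (\code{(AP, ML)}), \code{ok}
#'   (\code{FALSE} for a degenerate all-zero field) and the smoothed
#'   magnitude.
#' @export
find_singularity <- function(flow, sigma_px = 2, tol = 1e-9) {
  mag <- matrix(flow$magnitude, flow$n_rows, flow$n_cols)
  if (all(mag == 0))
    return(list(position_um = c(NA_real_, NA_real_), ok = FALSE,
                magnitude_smooth = mag))
  ms <- gaussian_blur(mag, sigma_px)
  mmin <- min(ms)
  tied <- which(ms <= mmin + tol * max(ms))
  pos <- pixel_positions(list(n_rows = flow$n_rows, n_cols = flow$n_cols,
                              pixel_um = flow$pixel_um))
  list(position_um = c(mean(pos[tied, 1]), mean(pos[tied, 2])), ok = TRUE,
       magnitude_smooth = ms)
}

# ---- cross-correlogram ------------------------------------------------------

#' OFF-to-ON population cross-correlogram
#'
#' Pearson correlation between the population-summed OFF and ON rate traces
#' at signed lags: at lag \code{+l} the OFF trace is compared with the ON
#' trace \code{l} frames earlier, so a consistent OFF delay of d frames peaks
#' at lag \code{+d}.
#'
#' @param movie An \code{rgc_movie}, or a list of movies whose population
#'   traces are concatenated epoch-wise (lags never straddle epochs).
#' @param max_lag_frames Maximum lag in frames.
#' @return A data frame with \code{lag_frames}, \code{lag_s}, \code{cor}.
#' @export
off_on_crosscorrelogram <- function(movie, max_lag_frames = 8) {
  movies <- if (inherits(movie, "rgc_movie")) list(movie) else movie
  t_frame <- movies[[1]]$t_frame_s
  lags <- -max_lag_frames:max_lag_frames
  cc <- sapply(lags, function(l) {
    xs <- c(); ys <- c()
    for (m in movies) {
      on <- colSums(m$on); off <- colSums(m$off)
      T <- length(on)
      if (T <= abs(l)) next
      if (l >= 0) { xs <- c(xs, on[seq_len(T - l)]); ys <- c(ys, off[seq_len(T - l) + l]) }
      else { xs <- c(xs, on[seq_len(T + l) - l]); ys <- c(ys, off[seq_len(T + l)]) }
    }
    if (!length(xs) || sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    cor(xs, ys)
  })
  if (all(is.na(cc))) stop("cross-correlogram undefined for a silent movie")
  data.frame(lag_frames = lags, lag_s = lags * t_frame, cor = cc)
}

# ---- orientation map aggregation -------------------------------------------

#' Orientation-preference map of a trained model
#'
#' Renders every SC neuron's receptive field, extracts its orientation
#' preference, tuning strength and gOSI by Fourier analysis, attaches the
#' ON/OFF input segregation and LHI, and (when waves are supplied) the
#' wave-flow field, its singularity and the wave-direction bias.
#'
#' @param fit An \code{sc_fit} from \code{\link{sc_train}}, or a
#'   \code{synaptic_weights} object together with \code{grid}.
#' @param grid Required when \code{fit} is a plain weight tensor.
#' @param canvas An \code{\link{rf_canvas}}.
#' @param waves Optional \code{wave_ensemble} for flow-based statistics
#'   (defaults to \code{fit$waves} when present).
#' @param sigma_lh_um LHI neighbourhood spread, micrometres.
#' @param block Number of neurons per rendering block.
#' @return An object of class \code{orientation_map}: a data frame with one
#'   row per SC neuron (position, \code{theta_pref}, \code{mu},
#'   \code{tuning_strength}, \code{gosi}, \code{i_seg}, \code{lhi},
#'   \code{conc_angle}, \code{conc_diff}) and attributes \code{flow},
#'   \code{singularity}, \code{b_wave}, \code{grid}.
#' @export
orientation_map <- function(fit, grid = NULL, canvas = rf_canvas(),
                            waves = NULL, sigma_lh_um = 100, block = 128L) {
  if (inherits(fit, "sc_fit")) {
    weights <- fit$weights
    grid <- fit$grid
    if (is.null(waves)) waves <- fit$waves
    headings <- fit$headings
  } else {
    weights <- fit
    if (is.null(grid)) stop("'grid' is required with a plain weight tensor")
    headings <- NULL
  }
  arb <- weights$arbor
  n <- ncol(weights$w_on)
  m <- grid$vf_scale_m
  Kmat <- rf_kernel_stack(arb, canvas, m)
  Wd <- weights$w_on - weights$w_off
  Wd[is.na(arb$nbr)] <- 0
  Wside <- 2L * canvas$crop_halfwidth + 1L
  pad <- 2L^ceiling(log2(Wside))
  pl <- fourier_plan(pad)

  theta <- mu <- lmax <- gos <- rep(NA_real_, n)
  P <- matrix(0, pad, pad)
  for (b0 in seq(1L, n, by = block)) {
    cols <- b0:min(b0 + block - 1L, n)
    Fblk <- Kmat %*% Wd[, cols, drop = FALSE]
    for (ci in seq_along(cols)) {
      f <- matrix(Fblk[, ci], Wside, Wside)
      if (max(abs(f)) < 1e-14) next
      P[] <- 0
      P[seq_len(Wside), seq_len(Wside)] <- f
      A <- Mod(stats::fft(P))
      A[pl$out] <- 0
      x <- cols[ci]
      muc <- sum(A * pl$wmag * pl$phase) / sum(A)
      theta[x] <- (Arg(muc) * 90 / pi) %% 180
      mu[x] <- Mod(muc)
      As <- A[pl$shift_ord, pl$shift_ord]
      L <- vapply(pl$rays, function(rr) sum(rr$w * As[rr$i]), 0)
      lmax[x] <- max(L)
      gos[x] <- if (sum(L) > 0) Mod(sum(L * exp(2i * pl$centers * pi / 180))) / sum(L) else NA_real_
    }
  }

  pos <- pixel_positions(grid)
  i_seg <- onoff_input_segregation(weights)
  lh <- lhi(theta, grid, sigma_lh_um)
  off_nose <- rowSums(sweep(pos, 2, grid$nose_um)^2) > 0
  conc <- rep(NA_real_, n)
  conc[off_nose] <- concentric_angle(pos[off_nose, , drop = FALSE], grid$nose_um)
  rc <- pixel_rc(grid, seq_len(n))
  out <- data.frame(neuron = seq_len(n), i = rc[, "i"], j = rc[, "j"],
                    ap_um = pos[, 1], ml_um = pos[, 2], theta_pref = theta,
                    mu = mu, tuning_strength = lmax, gosi = gos,
                    i_seg = i_seg, lhi = lh, conc_angle = conc,
                    conc_diff = acute_orientation_diff(theta, conc))
  flow <- sing <- NULL
  b_wave <- if (!is.null(headings)) wave_direction_bias(headings) else NA_real_
  if (!is.null(waves)) {
    flow <- wave_flow_field(waves, grid)
    sing <- find_singularity(flow)
  }
  structure(out, class = c("orientation_map", "data.frame"), grid = grid,
            flow = flow, singularity = sing, b_wave = b_wave)
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("orientation_map: %d SC neurons\n", nrow(x)))
  cat(sprintf("  mean tuning strength %.4g, mean gOSI %.3f, mean I_SEG %.3f, mean LHI %.3f\n",
              mean(x$tuning_strength, na.rm = TRUE), mean(x$gosi, na.rm = TRUE),
              mean(x$i_seg, na.rm = TRUE), mean(x$lhi, na.rm = TRUE)))
  sing <- attr(x, "singularity")
  if (!is.null(sing) && isTRUE(sing$ok)) {
    g <- attr(x, "grid")
    cat(sprintf("  singularity at (%.0f, %.0f) um; %.0f um from the nose; B_wave = %.3f\n",
                sing$position_um[1], sing$position_um[2],
                sqrt(sum((sing$position_um - g$nose_um)^2)), attr(x, "b_wave")))
  }
  invisible(x)
}

#' @export
plot.orientation_map <- function(x, what = c("theta_pref", "tuning_strength",
                                             "gosi", "i_seg", "lhi"), ...) {
  what <- match.arg(what)
  g <- attr(x, "grid")
  M <- matrix(x[[what]], g$n_rows, g$n_cols)
  if (what == "theta_pref") {
    image(seq_len(g$n_cols), seq_len(g$n_rows), t(M), zlim = c(0, 180),
          col = grDevices::hcl.colors(64, "Roma"), xlab = "AP (px)",
          ylab = "ML (px)", main = "orientation preference (deg)", ...)
  } else {
    image(seq_len(g$n_cols), seq_len(g$n_rows), t(M),
          col = grDevices::hcl.colors(64, "Viridis"), xlab = "AP (px)",
          ylab = "ML (px)", main = what, ...)
  }
  invisible(x)
}

#' Alignment of the map to the concentric angles of the visual field
#'
#' Per-neuron acute difference between the orientation preference and the
#' concentric angle about the nose position, a 10-degree-bin histogram of the
#' differences, and the distance from the nose to the map singularity when a
#' flow field is available.
#'
#' @param opm An \code{orientation_map}.
#' @param flow Optional \code{wave_flow} overriding the one stored in the
#'   map.
#' @return A list with \code{diff_deg}, \code{mean_diff}, \code{hist}
#'   (counts over \code{[0, 90]} in 10-degree bins) and
#'   \code{singularity_dist_um} (\code{NA} without a flow field).
#' @export
alignment_stats <- function(opm, flow = NULL) {
  g <- attr(opm, "grid")
  d <- opm$conc_diff
  h <- hist(d[!is.na(d)], breaks = seq(0, 90, by = 10), plot = FALSE)
  sing <- if (!is.null(flow)) find_singularity(flow) else attr(opm, "singularity")
  dist <- if (!is.null(sing) && isTRUE(sing$ok))
    sqrt(sum((sing$position_um - g$nose_um)^2)) else NA_real_
  list(diff_deg = d, mean_diff = mean(d, na.rm = TRUE), hist = h$counts,
       breaks = h$breaks, singularity_dist_um = dist)
}
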