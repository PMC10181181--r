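# Stage-III-like retinal wave simulator: direction-biased stochastic
# propagation on the lattice with per-pixel refractoriness, plus conversion of
# activation rasters into ON/OFF firing-rate movies with an OFF delay.

# the 8 Moore-neighbour angles theta_k = k * 2*pi/8, k = 1..8 (theta_8 == 2*pi
# is wrapped to 0); offsets are (d_col, d_row) = (cos, sin) rounded.
neighbor_angles <- function(n = 8) wrap_angle(seq_len(n) * 2 * pi / n)

neighbor_offsets <- function() {
  th <- neighbor_angles()
  cbind(dj = round(cos(th)), di = round(sin(th)))
}

# memoised N x 8 matrix of neighbour pixel indices (NA outside the grid)
.scwavemap_cache <- new.env(parent = emptyenv())

neighbor_index <- function(grid) {
  key <- paste0("nbr_", grid$n_rows, "x", grid$n_cols)
  if (!is.null(.scwavemap_cache[[key]])) return(.scwavemap_cache[[key]])
  off <- neighbor_offsets()
  n <- n_pixels(grid)
  rc <- pixel_rc(grid, seq_len(n))
  out <- matrix(NA_integer_, n, 8)
  for (k in 1:8) {
    ii <- rc[, "i"] + off[k, "di"]
    jj <- rc[, "j"] + off[k, "dj"]
    ok <- ii >= 1 & ii <= grid$n_rows & jj >= 1 & jj <= grid$n_cols
    out[ok, k] <- pixel_index(grid, ii[ok], jj[ok])
  }
  .scwavemap_cache[[key]] <- out
  out
}

# truncated 1D Gaussian shape over (-pi, pi] (normalisation cancels when the
# 8-angle distribution is renormalised)
trunc_gauss <- function(theta, sigma) exp(-theta^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))

#' Discrete propagation bias of the truncated-Gaussian neighbour distribution
#'
#' \code{propagation_bias(sigma)} evaluates the polar bias index of the
#' 8-neighbour local propagation distribution obtained by normalising a
#' zero-mean truncated Gaussian over the neighbour angles
#' \eqn{\theta_k = 2\pi k/8}.
#'
#' @param sigma Positive spread of the angular Gaussian (radians).
#' @param n_neighbors Number of equispaced neighbour directions (8 for the
#'   Moore neighbourhood).
#' @return The bias \eqn{B(\sigma) \in [0, 1)}.
#' @export
propagation_bias <- function(sigma, n_neighbors = 8) {
  th <- neighbor_angles(n_neighbors)
  g <- trunc_gauss(th, sigma)
  p <- g / sum(g)
  Mod(sum(p * exp(1i * th)))
}

#' Largest achievable local propagation bias
#'
#' Supremum of \code{\link{propagation_bias}} over spreads for the
#' \code{n_neighbors}-direction family (approached as sigma -> 0).
#'
#' @inheritParams propagation_bias
#' @export
max_propagation_bias <- function(n_neighbors = 8) propagation_bias(1e-4, n_neighbors)

#' Solve for the angular spread giving a target local propagation bias
#'
#' Finds the truncated-Gaussian spread \eqn{\sigma} whose 8-neighbour
#' propagation distribution has polar bias index \code{b}, i.e. the minimiser
#' of \eqn{(b - B(\sigma))^2}.  \eqn{B} is monotone in \eqn{\sigma}, so the
#' minimiser is found by root bracketing; the result satisfies
#' \eqn{|B(\sigma^*) - b| \le 10^{-6}}.
#'
#' @param b Target bias, in \code{(0, max_propagation_bias())}.
#' @inheritParams propagation_bias
#' @return The optimal spread (radians).
#' @examples
#' s <- optimize_sigma_prop(0.35)
#' propagation_bias(s)  # 0.35 to within 1e-6
#' @export
optimize_sigma_prop <- function(b, n_neighbors = 8) {
  if (!is.numeric(b) || length(b) != 1 || b <= 0 ||
      b >= max_propagation_bias(n_neighbors))
    stop("'b' outside the achievable bias range of the ",
         n_neighbors, "-direction family")
  f <- function(s) propagation_bias(s, n_neighbors) - b
  uniroot(f, c(1e-4, 1e3), tol = 1e-12)$root
}

#' Local propagation distribution over the Moore neighbours
#'
#' Probabilities \eqn{p_k \propto g(\theta_k - heading; \sigma)} over the 8
#' neighbour angles, maximal at the neighbour in the heading direction.
#'
#' @param sigma_prop Angular spread (e.g. from
#'   \code{\link{optimize_sigma_prop}}).
#' @param heading Wave heading; must be one of the 8 neighbour angles.
#' @return A length-8 probability vector ordered as
#'   \code{neighbor_angles()}, with the angles as an attribute.
#' @export
local_propagation_distribution <- function(sigma_prop, heading = 0) {
  th <- neighbor_angles()
  if (min(abs(wrap_angle(th - heading))) > 1e-9)
    stop("'heading' must be one of the 8 neighbour angles")
  g <- trunc_gauss(wrap_angle(th - heading), sigma_prop)
  p <- g / sum(g)
  attr(p, "angles") <- th
  p
}

#' Retinal wave parameters
#'
#' Collects the stochastic wave-model parameters.  Defaults follow the model's
#' stage-III operating point: propagation bias \code{b = 0.35} with scaling
#' exponent \code{q = 2.4}, activation threshold 1, a 60-frame (30 s)
#' inter-event refractory interval, 0.5 s frames, 1 s pixel activation, and a
#' 1 s OFF delay.
#'
#' @param b Desired local propagation bias in \code{[0, max_propagation_bias())}.
#' @param q Probability scaling exponent (> 0); neighbour activation
#'   probabilities are \eqn{\rho_k = p_k^{1/q}}.
#' @param n_theta Threshold number of successful neighbour activations.
#' @param tau_iei_frames Per-pixel refractory interval, frames.
#' @param t_frame_s Seconds per frame.
#' @param t_wave_s Pixel activation (firing) duration, seconds.
#' @param tau_on_s,tau_off_s ON and OFF response delays, seconds
#'   (\code{tau_off_s >= tau_on_s >= 0}); converted to frames by rounding.
#' @param r Wave signal amplitude (mean firing rate during activation).
#' @param gamma Noise amplitude (0 disables noise).
#' @param sigma_ai_um Spread (um) of the Gaussian from which the
#'   asymmetric-inhibition source is drawn around the nose position.
#' @param rho_rule How the neighbour activation probabilities are obtained
#'   from the local propagation distribution: \code{"scale"} (default),
#'   \eqn{\rho_k = \min(q \, p_k, 1)}, which preserves the bias \code{b} in
#'   the propagation probabilities and yields compact, direction-following
#'   stage-III-like waves; or \code{"power"}, \eqn{\rho_k = p_k^{1/q}}.
#' @param noise_mode \code{"background"}: independent Gaussian noise scaled by
#'   \code{gamma} on every pixel and frame, rates clipped at 0;
#'   \code{"kernel"}: noise only within active response kernels, unclipped.
#' @param max_frames Hard cap on frames per epoch (runaway guard).
#' @return An object of class \code{wave_params}; \code{sigma_prop} (solved
#'   from \code{b}) is stored as a field.
#' @export
wave_params <- function(b = 0.35, q = 2.4, n_theta = 1, tau_iei_frames = 60,
                        t_frame_s = 0.5, t_wave_s = 1, tau_on_s = 0,
                        tau_off_s = 1, r = 1, gamma = 0, sigma_ai_um = 50,
                        rho_rule = c("scale", "power"),
                        noise_mode = c("background", "background_clipped", "kernel"),
                        max_frames = 400) {
  noise_mode <- match.arg(noise_mode)
  rho_rule <- match.arg(rho_rule)
  stopifnot(q > 0, r >= 0, gamma >= 0, n_theta >= 1, tau_iei_frames >= 0,
            t_frame_s > 0, t_wave_s > 0, sigma_ai_um > 0, max_frames > 1)
  if (b < 0 || b >= max_propagation_bias())
    stop("'b' must be in [0, max_propagation_bias())")
  if (tau_on_s < 0 || tau_off_s < tau_on_s)
    stop("delays must satisfy tau_off_s >= tau_on_s >= 0")
  sigma_prop <- if (b > 0) optimize_sigma_prop(b) else Inf
  structure(list(b = b, q = q, n_theta = as.integer(n_theta),
                 tau_iei_frames = as.integer(tau_iei_frames),
                 t_frame_s = t_frame_s, t_wave_s = t_wave_s,
                 tau_on_s = tau_on_s, tau_off_s = tau_off_s, r = r,
                 gamma = gamma, sigma_ai_um = sigma_ai_um,
                 rho_rule = rho_rule, noise_mode = noise_mode,
                 max_frames = as.integer(max_frames),
                 sigma_prop = sigma_prop),
            class = "wave_params")
}

#' @export
print.wave_params <- function(x, ...) {
  cat(sprintf("wave_params: b = %g (sigma_prop = %.4g), q = %g, N_theta = %d\n",
              x$b, x$sigma_prop, x$q, x$n_theta))
  cat(sprintf("  frame %g s, T_wave %g s, tau_ON %g s, tau_OFF %g s, IEI %d frames\n",
              x$t_frame_s, x$t_wave_s, x$tau_on_s, x$tau_off_s, x$tau_iei_frames))
  cat(sprintf("  amplitude r = %g, noise gamma = %g (%s), sigma_AI = %g um\n",
              x$r, x$gamma, x$noise_mode, x$sigma_ai_um))
  invisible(x)
}

# kernel length and delays in frames (delays rounded to nearest frame)
kernel_frames <- function(params) max(1L, as.integer(round(params$t_wave_s / params$t_frame_s)))
delay_frames <- function(delay_s, params) as.integer(round(delay_s / params$t_frame_s))

#' Sample asymmetric-inhibition source positions
#'
#' Draws source positions from the isotropic 2D Gaussian of spread
#' \code{sigma_ai_um} centred at the grid's nose position.
#'
#' @param grid A \code{\link{grid_spec}}.
#' @param sigma_ai_um Positive spread in micrometres.
#' @param n Number of draws.
#' @return An \code{n} x 2 matrix of \code{(AP, ML)} positions in um.
#' @export
sample_ai_source <- function(grid, sigma_ai_um, n = 1) {
  stopifnot(sigma_ai_um > 0)
  cbind(rnorm(n, grid$nose_um[1], sigma_ai_um),
        rnorm(n, grid$nose_um[2], sigma_ai_um))
}

#' Sample wave initiation pixels
#'
#' Initiation positions are uniform over the lattice (the wave initiation map
#' is flat).
#'
#' @inheritParams sample_ai_source
#' @return Integer pixel indices.
#' @export
initiate_wave <- function(grid, n = 1) sample.int(n_pixels(grid), n, replace = TRUE)

#' Wave heading from initiation and inhibition-source positions
#'
#' The heading points from the asymmetric-inhibition source towards the
#' initiation site, rounded to the nearest of the 8 neighbour angles with the
#' \code{floor(x + 0.5)} rule (exact midpoints round up).
#'
#' @param init_um Initiation position(s), \code{(AP, ML)} um (vector or
#'   matrix of rows).
#' @param ai_um Source position(s), same shape.
#' @return Heading(s) in radians, each one of \code{neighbor_angles()}.
#' @export
wave_heading <- function(init_um, ai_um) {
  if (is.null(dim(init_um))) init_um <- matrix(init_um, ncol = 2)
  if (is.null(dim(ai_um))) ai_um <- matrix(ai_um, ncol = 2)
  v <- init_um - ai_um
  theta <- atan2(v[, 2], v[, 1])
  n <- 8
  wrap_angle(2 * pi / n * floor(n * theta / (2 * pi) + 0.5))
}

#' Propagate one retinal wave epoch
#'
#' Stochastic lattice propagation: the initiation pixel activates
#' unconditionally at frame 1; thereafter a pixel activates at frame t when at
#' least \code{n_theta} of its active Moore neighbours at t-1 succeed in
#' independent Bernoulli trials (neighbour in direction k succeeding with
#' probability \eqn{p_k^{1/q}}) and the pixel's refractory interval has
#' elapsed.  The epoch ends when no pixel is active.  Candidate neighbours
#' outside the grid are dropped without renormalisation, so waves attenuate at
#' the boundary.
#'
#' @param grid A \code{\link{grid_spec}}.
#' @param params A \code{\link{wave_params}}.
#' @param init Initiation pixel index (default: drawn uniformly).
#' @param heading Wave heading, one of the 8 neighbour angles.
#' @param ai_source Optional source position record, \code{(AP, ML)} um.
#' @param on_runaway \code{"error"} (default): raise an error when an epoch
#'   exceeds \code{max_frames} (a re-entrant wave); \code{"truncate"}: stop
#'   the epoch at the cap and flag the raster with attribute
#'   \code{truncated}.
#' @return A \code{wave_raster}: a list with \code{frames} (integer vectors of
#'   pixels activated at each frame), \code{n_frames}, \code{init},
#'   \code{ai_source} and \code{heading}.
#' @export
propagate_wave <- function(grid, params, init = initiate_wave(grid),
                           heading = 0, ai_source = c(NA_real_, NA_real_),
                           on_runaway = c("error", "truncate")) {
  on_runaway <- match.arg(on_runaway)
  p_prop <- local_propagation_distribution(params$sigma_prop, heading)
  rho <- if (identical(params$rho_rule, "power")) p_prop^(1 / params$q)
         else pmin(params$q * p_prop, 1)
  nbr <- neighbor_index(grid)
  n <- n_pixels(grid)
  last_act <- rep(-Inf, n)
  frames <- vector("list", 64L)
  frames[[1L]] <- as.integer(init)
  last_act[init] <- 1
  active <- as.integer(init)
  t <- 1L
  truncated <- FALSE
  repeat {
    t <- t + 1L
    if (t > params$max_frames) {
      if (on_runaway == "error")
        stop("runaway wave: epoch exceeded max_frames = ", params$max_frames)
      truncated <- TRUE
      break
    }
    m <- length(active)
    tg <- nbr[active, , drop = FALSE]                   # m x 8 targets
    succ <- runif(8L * m) < rep(rho, each = m)
    tg <- tg[succ & !is.na(tg)]
    if (length(tg)) {
      counts <- tabulate(tg, nbins = n)
      newly <- which(counts >= params$n_theta & t > last_act + params$tau_iei_frames)
    } else newly <- integer(0)
    if (!length(newly)) break
    if (t > length(frames)) frames <- c(frames, vector("list", length(frames)))
    frames[[t]] <- newly
    last_act[newly] <- t
    active <- newly
  }
  out <- structure(list(frames = frames[seq_len(t - 1L)], n_frames = t - 1L,
                        init = as.integer(init), ai_source = as.numeric(ai_source),
                        heading = heading, n_rows = grid$n_rows,
                        n_cols = grid$n_cols),
                   class = "wave_raster")
  attr(out, "truncated") <- truncated
  out
}

#' @export
print.wave_raster <- function(x, ...) {
  cat(sprintf("wave_raster: %d frames, %d activations, heading %.1f deg\n",
              x$n_frames, length(unlist(x$frames)), x$heading * 180 / pi))
  invisible(x)
}

# activations of a raster as a 2-column matrix (pixel, frame)
raster_activations <- function(raster) {
  lens <- lengths(raster$frames)
  cbind(pixel = unlist(raster$frames, use.names = FALSE),
        frame = rep.int(seq_along(raster$frames), lens))
}

# binary n_pixels x n_frames activation matrix
raster_matrix <- function(raster) {
  A <- matrix(0L, raster$n_rows * raster$n_cols, raster$n_frames)
  act <- raster_activations(raster)
  A[act] <- 1L
  A
}

#' ON/OFF firing-rate movie of a wave epoch
#'
#' Convolves the activation raster with a boxcar response kernel of height
#' \code{r} and duration \code{t_wave_s}, delayed by \code{tau_on_s}
#' (\code{tau_off_s}) for the ON (OFF) channel, and adds noise according to
#' \code{noise_mode}.  With \code{gamma = 0} the OFF movie is exactly the ON
#' movie shifted by \code{(tau_off_s - tau_on_s) / t_frame_s} frames.
#'
#' @param raster A \code{wave_raster} (or fixture raster).
#' @param params A \code{\link{wave_params}}.
#' @param tau_off_s Optional per-call override of the OFF delay (seconds); may
#'   be negative, in which case the time axis is shifted so all contributions
#'   are represented.
#' @return An \code{rgc_movie}: list with matrices \code{on}, \code{off}
#'   (pixels x frames) and the frame duration.
#' @export
rgc_activity <- function(raster, params, tau_off_s = params$tau_off_s) {
  L <- kernel_frames(params)
  d_on <- delay_frames(params$tau_on_s, params)
  d_off <- delay_frames(tau_off_s, params)
  shift <- max(0L, -min(d_on, d_off))
  n <- raster$n_rows * raster$n_cols
  t_total <- raster$n_frames + max(d_on, d_off) + shift + L
  on <- matrix(0, n, t_total)
  off <- matrix(0, n, t_total)
  act <- raster_activations(raster)
  for (l in seq_len(L)) {
    on[cbind(act[, 1], act[, 2] + d_on + shift + l)] <-
      on[cbind(act[, 1], act[, 2] + d_on + shift + l)] + params$r
    off[cbind(act[, 1], act[, 2] + d_off + shift + l)] <-
      off[cbind(act[, 1], act[, 2] + d_off + shift + l)] + params$r
  }
  if (params$gamma > 0) {
    # the OFF channel receives the SAME noise trace delayed by the OFF delay
    # (the OFF movie is a copy of the ON movie, noise included)
    d_rel <- abs(d_off - d_on)
    if (params$noise_mode %in% c("background", "background_clipped")) {
      z <- matrix(rnorm(n * (t_total + d_rel)), n)
      on <- on + params$gamma * z[, d_rel + seq_len(t_total), drop = FALSE]
      off <- off + params$gamma * z[, seq_len(t_total), drop = FALSE]
      if (params$noise_mode == "background_clipped") {
        on <- pmax(on, 0)
        off <- pmax(off, 0)
      }
    } else {
      for (l in seq_len(L)) {
        xi <- params$gamma * rnorm(nrow(act))
        idx_on <- cbind(act[, 1], act[, 2] + d_on + shift + l)
        idx_off <- cbind(act[, 1], act[, 2] + d_off + shift + l)
        on[idx_on] <- on[idx_on] + xi
        off[idx_off] <- off[idx_off] + xi
      }
    }
  }
  structure(list(on = on, off = off, t_frame_s = params$t_frame_s,
                 shift = shift), class = "rgc_movie")
}

#' Deterministic fixture rasters
#'
#' Synthetic activation rasters with known structure for testing and analysis:
#' a full-width planar front, an expanding ring, or independent random
#' activations with the refractory interval respected.
#'
#' @param kind \code{"planar"}, \code{"ring"} or \code{"random"}.
#' @param grid A \code{\link{grid_spec}}.
#' @param heading Front direction (planar), one of the neighbour angles.
#' @param speed Front speed in pixels per frame.
#' @param center Ring centre \code{(i, j)} in pixel row/col units (defaults to
#'   the grid centre).
#' @param rate Per-pixel, per-frame activation probability (random).
#' @param n_frames Number of frames (random).
#' @param tau_iei_frames Refractory interval respected by the random fixture.
#' @return A \code{wave_raster}.
#' @export
make_fixture_raster <- function(kind = c("planar", "ring", "random"),
                                grid = grid_spec(), heading = 0, speed = 1,
                                center = NULL, rate = 0.01, n_frames = 20,
                                tau_iei_frames = 60) {
  kind <- match.arg(kind)
  n <- n_pixels(grid)
  rc <- pixel_rc(grid, seq_len(n))
  if (kind == "planar") {
    proj <- cos(heading) * rc[, "j"] + sin(heading) * rc[, "i"]
    tt <- floor((proj - min(proj)) / speed) + 1L
  } else if (kind == "ring") {
    if (is.null(center)) center <- c((grid$n_rows + 1) / 2, (grid$n_cols + 1) / 2)
    d <- sqrt((rc[, "i"] - center[1])^2 + (rc[, "j"] - center[2])^2)
    tt <- floor(d / speed) + 1L
  } else {
    frames <- vector("list", n_frames)
    last <- rep(-Inf, n)
    for (t in seq_len(n_frames)) {
      hit <- which(runif(n) < rate & t > last + tau_iei_frames)
      frames[[t]] <- hit
      last[hit] <- t
    }
    return(structure(list(frames = frames, n_frames = as.integer(n_frames),
                          init = NA_integer_, ai_source = c(NA_real_, NA_real_),
                          heading = NA_real_, n_rows = grid$n_rows,
                          n_cols = grid$n_cols), class = "wave_raster"))
  }
  tmax <- max(tt)
  frames <- split(seq_len(n), factor(tt, levels = seq_len(tmax)))
  frames <- lapply(frames, as.integer)
  names(frames) <- NULL
  structure(list(frames = frames, n_frames = as.integer(tmax),
                 init = NA_integer_, ai_source = c(NA_real_, NA_real_),
                 heading = if (kind == "planar") heading else NA_real_,
                 n_rows = grid$n_rows, n_cols = grid$n_cols),
            class = "wave_raster")
}

#' Simulate an ensemble of wave epochs
#'
#' Two sampling modes.  The default \code{"ai"} mode follows the full model:
#' initiation uniform over the lattice, an asymmetric-inhibition source drawn
#' from the Gaussian around the nose, and the heading pointing from source to
#' initiation site.  The \code{"ensemble"} mode reproduces the single-neuron
#' experiments: each wave's heading is drawn from \code{heading_dist} (over
#' the 8 neighbour angles) and the initiation pixel is placed
#' \code{init_offset_px} pixels from \code{target} against the heading, so the
#' wave sweeps across the target neuron.
#'
#' @param grid A \code{\link{grid_spec}}.
#' @param params A \code{\link{wave_params}}.
#' @param n_waves Number of epochs.
#' @param mode \code{"ai"} or \code{"ensemble"}.
#' @param heading_dist A \code{\link{direction_distribution}} over the 8
#'   neighbour angles (ensemble mode).
#' @param target Target pixel index (ensemble mode; default grid centre).
#' @param init_offset_px Initiation offset from the target, pixels.
#' @return A \code{wave_ensemble}: list of \code{wave_raster}s with the
#'   heading vector as an attribute.
#' @export
simulate_waves <- function(grid, params, n_waves, mode = c("ai", "ensemble"),
                           heading_dist = NULL, target = NULL,
                           init_offset_px = 15) {
  mode <- match.arg(mode)
  pos <- pixel_positions(grid)
  rasters <- vector("list", n_waves)
  headings <- numeric(n_waves)
  if (mode == "ai") {
    for (w in seq_len(n_waves)) {
      repeat {
        init <- initiate_wave(grid)
        ai <- sample_ai_source(grid, params$sigma_ai_um)
        if (any(pos[init, ] != ai)) break   # heading undefined: resample
      }
      h <- wave_heading(pos[init, ], ai)
      rasters[[w]] <- propagate_wave(grid, params, init, h, as.numeric(ai),
                                     on_runaway = "truncate")
      headings[w] <- h
    }
  } else {
    if (is.null(heading_dist))
      stop("'heading_dist' is required in ensemble mode")
    if (is.null(target))
      target <- pixel_index(grid, ceiling(grid$n_rows / 2), ceiling(grid$n_cols / 2))
    trc <- pixel_rc(grid, target)
    ks <- sample.int(length(heading_dist$angles), n_waves, replace = TRUE,
                     prob = heading_dist$probabilities)
    for (w in seq_len(n_waves)) {
      h <- heading_dist$angles[ks[w]]
      i0 <- round(trc[, "i"] - init_offset_px * sin(h))
      j0 <- round(trc[, "j"] - init_offset_px * cos(h))
      i0 <- min(max(i0, 1L), grid$n_rows)
      j0 <- min(max(j0, 1L), grid$n_cols)
      rasters[[w]] <- propagate_wave(grid, params, pixel_index(grid, i0, j0), h,
                                     on_runaway = "truncate")
      headings[w] <- h
    }
  }
  out <- structure(rasters, headings = headings, class = "wave_ensemble")
  attr(out, "n_truncated") <-
    sum(vapply(rasters, function(r) isTRUE(attr(r, "truncated")), FALSE))
  out
}

#' @export
print.wave_ensemble <- function(x, ...) {
  cat(sprintf("wave_ensemble: %d epochs, heading bias B = %.3f\n",
              length(x), wave_direction_bias(attr(x, "headings"))))
  invisible(x)
}
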