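# Model fitting: simulate (or accept) a wave ensemble and refine the ON/OFF
# retinocollicular weight tensor over epochs via the compiled trial loop.

#' Train the retinocollicular model on retinal waves
#'
#' The main fitting function.  Each epoch simulates (or takes) one retinal
#' wave, converts it to ON/OFF firing-rate movies with the OFF delay and
#' optional activity noise, bins time into trials, and applies the Hebbian
#' update with subtractive normalization followed by the nonnegativity
#' constraint.  Deterministic given \code{seed}.
#'
#' @param grid A \code{\link{grid_spec}}.
#' @param wave A \code{\link{wave_params}}.
#' @param learn A \code{\link{learning_params}}.
#' @param n_waves Number of epochs (default \code{learn$n_waves}).
#' @param waves Optional precomputed \code{wave_ensemble} (or list of
#'   \code{wave_raster}s); otherwise waves are simulated in \code{"ai"} mode.
#' @param neurons SC neurons to train: \code{"all"} (default), \code{"center"}
#'   (the single central neuron), or an integer index vector.
#' @param seed Optional integer seed controlling all randomness of the run.
#' @param off_delays_s Optional per-epoch OFF delays (seconds), overriding
#'   \code{wave$tau_off_s} (used e.g. for wave ensembles with randomised
#'   ON/OFF temporal order).
#' @param off_random_sign If \code{TRUE}, each activation's OFF delay sign is
#'   randomised independently (per-activation random ON/OFF order).
#' @param checkpoint_every Store weight checkpoints every this many epochs
#'   (0 = none).
#' @param keep_waves Keep the wave ensemble in the returned object.
#' @return An object of class \code{sc_fit} with elements \code{weights}
#'   (a \code{synaptic_weights}), \code{grid}, \code{wave}, \code{learn},
#'   \code{headings}, \code{n_waves}, \code{seed}, and optionally
#'   \code{waves} and \code{checkpoints}.
#' @examples
#' \donttest{
#' fit <- sc_train(grid_spec(), wave_params(), learning_params(n_waves = 50),
#'                 neurons = "center", seed = 1)
#' summary(sc_rf(fit$weights, center_neuron(fit$grid)))
#' }
#' @export
sc_train <- function(grid = grid_spec(), wave = wave_params(),
                     learn = learning_params(), n_waves = learn$n_waves,
                     waves = NULL, neurons = "all", seed = NULL,
                     off_delays_s = NULL, off_random_sign = FALSE,
                     checkpoint_every = 0, keep_waves = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(waves)) {
    waves <- simulate_waves(grid, wave, n_waves)
  } else {
    n_waves <- length(waves)
  }
  if (!is.null(off_delays_s) && length(off_delays_s) != n_waves)
    stop("'off_delays_s' must have one entry per epoch")

  weights <- init_weights(grid, learn)
  arb <- weights$arbor
  nbr0 <- arb$nbr
  nbr0[is.na(nbr0)] <- 0L

  if (identical(neurons, "all")) {
    idx <- seq_len(n_pixels(grid))
  } else if (identical(neurons, "center")) {
    idx <- center_neuron(grid)
  } else {
    idx <- as.integer(neurons)
  }

  L <- kernel_frames(wave)
  d_on <- delay_frames(wave$tau_on_s, wave)
  epochs <- vector("list", n_waves)
  for (w in seq_len(n_waves)) {
    act <- raster_activations(waves[[w]])
    d_off <- delay_frames(if (is.null(off_delays_s)) wave$tau_off_s
                          else off_delays_s[w], wave)
    offv <- rep.int(d_off, nrow(act))
    if (off_random_sign && d_off != 0)
      offv <- offv * sample(c(-1L, 1L), nrow(act), replace = TRUE)
    epochs[[w]] <- list(as.integer(act[, 1]), as.integer(act[, 2]),
                        as.integer(offv), d_off)
  }

  noise_seed <- floor(runif(1) * 2^31)
  t_trial <- if (is.null(learn$t_trial_frames)) 0L else as.integer(learn$t_trial_frames)
  res <- cpp_train(nbr0, weights$w_on, weights$w_off, epochs, idx,
                   n_pixels(grid), wave$r, wave$gamma,
                   switch(wave$noise_mode, background = 1L,
                          background_clipped = 2L, kernel = 0L), L, d_on,
                   learn$eta, t_trial, learn$plasticity_noise_sd,
                   learn$update_dropout_p, learn$conserve_total,
                   as.integer(checkpoint_every), noise_seed)
  weights$w_on <- res$w_on
  weights$w_off <- res$w_off

  structure(list(weights = weights, grid = grid, wave = wave, learn = learn,
                 n_waves = n_waves, neurons = idx,
                 headings = attr(waves, "headings"), seed = seed,
                 waves = if (keep_waves) waves else NULL,
                 checkpoints = if (checkpoint_every > 0) res$checkpoints else NULL,
                 call = match.call()),
            class = "sc_fit")
}

#' Index of the central SC neuron
#'
#' @param grid A \code{\link{grid_spec}}.
#' @export
center_neuron <- function(grid) {
  pixel_index(grid, ceiling(grid$n_rows / 2), ceiling(grid$n_cols / 2))
}
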