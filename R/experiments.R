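# Config-driven reproductions of the model experiments: the single-neuron
# OFF-delay x direction-bias sweep, the four map regimes, the
# asymmetric-inhibition spread sweep, and the activity-noise sweep.

#' Deterministic sub-seed derivation
#'
#' Splits one user seed into independent per-cell seeds (always below 2^31).
#'
#' @param seed Base integer seed.
#' @param k Cell index.
#' @export
derive_seed <- function(seed, k) {
  v <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k) * 69621
  as.integer(v %% 2147483646) + 1L
}

#' Discrete von Mises heading ensemble with a target polar bias
#'
#' A von Mises-shaped distribution over the 8 neighbour headings whose polar
#' bias index equals \code{target_bias} to within 1e-6 (the concentration is
#' solved numerically); bias 0 gives the uniform distribution and bias 1 a
#' point mass on the centre heading.
#'
#' @param target_bias Desired bias in \code{[0, 1]}.
#' @param center Centre heading (radians; one of the 8 neighbour angles).
#' @return A \code{\link{direction_distribution}} over the 8 headings.
#' @export
biased_direction_ensemble <- function(target_bias, center = 0) {
  stopifnot(target_bias >= 0, target_bias <= 1)
  th <- neighbor_angles()
  if (target_bias >= 1 - 1e-12) {
    p <- as.numeric(abs(wrap_angle(th - center)) < 1e-9)
    return(direction_distribution(th, p / sum(p)))
  }
  probs <- function(kappa) {
    g <- exp(kappa * (cos(th - center) - 1))
    g / sum(g)
  }
  bias_of <- function(kappa) Mod(sum(probs(kappa) * exp(1i * th)))
  if (target_bias < 1e-12) return(direction_distribution(th, probs(0)))
  kappa <- uniroot(function(k) bias_of(k) - target_bias, c(1e-8, 700),
                   tol = 1e-12)$root
  direction_distribution(th, probs(kappa))
}

#' Estimated number of developmental stage-III waves
#'
#' Stage III spans about 5 days before eye opening at roughly 8 waves per
#' minute, giving around 5 x 24 x 60 x 8 waves.
#'
#' @param days Days of stage-III activity.
#' @param waves_per_minute Mean wave frequency.
#' @return The wave count.
#' @export
developmental_wave_count <- function(days = 5, waves_per_minute = 8) {
  days * 24 * 60 * waves_per_minute
}

#' Experiment configuration
#'
#' Collects everything needed to run one of the four model experiments at a
#' configurable scale.  Serialises to/from YAML with keys named exactly as
#' the fields.
#'
#' @param experiment One of \code{"single_neuron_sweep"},
#'   \code{"map_regimes"}, \code{"ai_spread_sweep"}, \code{"noise_sweep"}.
#' @param grid,wave,learn Component parameter objects.
#' @param off_delays_s OFF delays swept (seconds; single-neuron sweep).
#' @param bias_targets Heading-ensemble biases swept (single-neuron sweep).
#' @param ai_spreads_um Asymmetric-inhibition spreads swept (micrometres).
#' @param noise_fractions Noise fractions gamma swept (with \code{r = 1 -
#'   gamma}).
#' @param n_seeds Seeds per sweep cell.
#' @param n_waves Training epochs per cell (defaults to \code{learn$n_waves}).
#' @param seed Base seed.
#' @param output_dir Optional directory for CSV/YAML outputs.
#' @return An object of class \code{experiment_config}.
#' @export
experiment_config <- function(experiment = c("single_neuron_sweep",
                                             "map_regimes", "ai_spread_sweep",
                                             "noise_sweep"),
                              grid = grid_spec(), wave = wave_params(),
                              learn = learning_params(),
                              off_delays_s = seq(0, 3.5, by = 0.5),
                              bias_targets = c(0, 0.25, 0.5, 0.75, 1),
                              ai_spreads_um = c(5, 25, 50, 150, 250, 350, 500,
                                                600, 750, 1000, 1500, 2000, 3000),
                              noise_fractions = seq(0, 1, by = 0.1),
                              n_seeds = 5, n_waves = NULL, seed = 1,
                              output_dir = NULL) {
  experiment <- match.arg(experiment)
  stopifnot(length(off_delays_s) >= 1, length(bias_targets) >= 1,
            length(ai_spreads_um) >= 1, length(noise_fractions) >= 1,
            n_seeds >= 1)
  if (any(noise_fractions < 0 | noise_fractions > 1))
    stop("'noise_fractions' must lie in [0, 1]")
  structure(list(experiment = experiment, grid = grid, wave = wave,
                 learn = learn, off_delays_s = off_delays_s,
                 bias_targets = bias_targets, ai_spreads_um = ai_spreads_um,
                 noise_fractions = noise_fractions,
                 n_seeds = as.integer(n_seeds),
                 n_waves = if (is.null(n_waves)) learn$n_waves else as.integer(n_waves),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "experiment_config")
}

#' @describeIn experiment_config Read a configuration from a YAML file.
#' @param path File path.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("experiment")
  if (!all(need %in% names(raw)))
    stop("missing required config key(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  args <- raw
  if (!is.null(raw$grid)) args$grid <- do.call(grid_spec, raw$grid)
  if (!is.null(raw$wave)) args$wave <- do.call(wave_params, raw$wave)
  if (!is.null(raw$learn)) args$learn <- do.call(learning_params, raw$learn)
  do.call(experiment_config, args)
}

#' @describeIn experiment_config Write a configuration to a YAML file.
#' @param config An \code{experiment_config}.
#' @export
write_experiment_config <- function(config, path) {
  out <- unclass(config)
  out$grid <- unclass(config$grid)
  out$wave <- unclass(config$wave)[setdiff(names(config$wave), "sigma_prop")]
  out$learn <- unclass(config$learn)
  yaml::write_yaml(out, path)
  invisible(path)
}

# modify one field of a params object, revalidating via the constructor
set_param <- function(obj, constructor, ...) {
  fields <- unclass(obj)
  fields <- fields[names(fields) %in% names(formals(constructor))]
  repl <- list(...)
  fields[names(repl)] <- repl
  do.call(constructor, fields)
}

#' Single-neuron OFF-delay by direction-bias sweep
#'
#' For every (OFF delay, heading bias, seed) cell, trains the central SC
#' neuron on waves whose headings are drawn from the 8-direction von Mises
#' ensemble with the target bias (initiation placed against the heading so
#' each wave sweeps the arbor), and records the receptive-field contrast,
#' ON/OFF input segregation, tuning strength and orientation preference.
#' Wave rasters do not depend on the OFF delay, so one raster set per
#' (bias, seed) is shared across the delay column.
#'
#' @param config An \code{\link{experiment_config}}.
#' @return A data frame with one row per sweep cell.
#' @export
run_single_neuron_sweep <- function(config) {
  grid <- config$grid
  canvas <- rf_canvas()
  ctr <- center_neuron(grid)
  rows <- list()
  for (bi in seq_along(config$bias_targets)) {
    bias <- config$bias_targets[bi]
    ens_dist <- biased_direction_ensemble(bias)
    for (s in seq_len(config$n_seeds)) {
      set.seed(derive_seed(config$seed, 1000L * bi + s))
      waves <- simulate_waves(grid, config$wave, config$n_waves,
                              mode = "ensemble", heading_dist = ens_dist,
                              target = ctr)
      for (delay in config$off_delays_s) {
        wp <- set_param(config$wave, wave_params, tau_off_s = delay)
        fit <- sc_train(grid, wp, config$learn, waves = waves,
                        neurons = "center",
                        seed = derive_seed(config$seed, 7000L * bi + 13L * s))
        rf <- sc_rf(fit$weights, ctr, canvas, m = grid$vf_scale_m)
        op <- orientation_preference(rf, on_zero = "na")
        rows[[length(rows) + 1L]] <- data.frame(
          bias = bias, off_delay_s = delay, seed = s,
          contrast = rf_contrast(rf),
          i_seg = onoff_input_segregation(fit$weights)[ctr],
          tuning_strength = tuning_strength(rf),
          theta_pref = op[["theta_pref"]], mu = op[["mu"]])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: train the full map on a prepared wave set
train_map <- function(grid, wave, learn, waves, seed, off_delays_s = NULL,
                      off_random_sign = FALSE) {
  sc_train(grid, wave, learn, waves = waves, neurons = "all", seed = seed,
           off_delays_s = off_delays_s, off_random_sign = off_random_sign,
           keep_waves = TRUE)
}

#' The four map-formation regimes
#'
#' Trains the full SC map under (A) non-wave-like random retinal activity
#' with per-activation randomised ON/OFF order, (B) uniform waves with
#' per-wave randomised OFF delay, (C) uniform waves with the consistent OFF
#' delay, and (D) direction-biased waves with the consistent OFF delay.
#' "Uniform" waves use an asymmetric-inhibition spread of 2000 um
#' (effectively no overall asymmetric inhibition); regime A's activation rate
#' is matched to regime C's mean per-pixel rate.
#'
#' @param config An \code{\link{experiment_config}}.
#' @return A list with per-regime fits and orientation maps plus a summary
#'   data frame.
#' @export
run_map_regimes <- function(config) {
  grid <- config$grid
  learn <- config$learn
  wave_unif <- set_param(config$wave, wave_params, sigma_ai_um = 2000)
  wave_bias <- config$wave

  set.seed(derive_seed(config$seed, 1L))
  waves_unif <- simulate_waves(grid, wave_unif, config$n_waves)
  set.seed(derive_seed(config$seed, 2L))
  waves_bias <- simulate_waves(grid, wave_bias, config$n_waves)

  # regime A: i.i.d. activations at regime C's mean rate
  n_act <- sum(vapply(waves_unif, function(r) length(unlist(r$frames)), 0))
  n_frames <- vapply(waves_unif, function(r) r$n_frames, 0)
  rate <- n_act / (n_pixels(grid) * sum(n_frames))
  set.seed(derive_seed(config$seed, 3L))
  waves_rand <- structure(lapply(seq_len(config$n_waves), function(w)
    make_fixture_raster("random", grid, rate = rate,
                        n_frames = max(2L, round(mean(n_frames))),
                        tau_iei_frames = config$wave$tau_iei_frames)),
    headings = NULL, class = "wave_ensemble")

  set.seed(derive_seed(config$seed, 4L))
  delays_b <- sample(seq(-2, 2, by = 0.5), config$n_waves, replace = TRUE)

  fits <- list(
    A = train_map(grid, wave_unif, learn, waves_rand,
                  seed = derive_seed(config$seed, 11L), off_random_sign = TRUE),
    B = train_map(grid, wave_unif, learn, waves_unif,
                  seed = derive_seed(config$seed, 12L), off_delays_s = delays_b),
    C = train_map(grid, wave_unif, learn, waves_unif,
                  seed = derive_seed(config$seed, 13L)),
    D = train_map(grid, wave_bias, learn, waves_bias,
                  seed = derive_seed(config$seed, 14L)))
  opms <- lapply(fits, orientation_map)
  summary <- do.call(rbind, lapply(names(opms), function(k) {
    o <- opms[[k]]
    sing <- attr(o, "singularity")
    data.frame(regime = k,
               mean_lhi = mean(o$lhi, na.rm = TRUE),
               mean_gosi = mean(o$gosi, na.rm = TRUE),
               mean_tuning = mean(o$tuning_strength, na.rm = TRUE),
               mean_i_seg = mean(o$i_seg, na.rm = TRUE),
               sing_ap_um = sing$position_um[1],
               sing_ml_um = sing$position_um[2])
  }))
  list(fits = fits, opms = opms, summary = summary)
}

#' Asymmetric-inhibition spread sweep
#'
#' For each spread: the wave ensemble and its direction bias, the trained
#' map, the flow-field singularity and its distance to the nose, and the
#' concentric-alignment statistics.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param train Set \code{FALSE} to skip map training and report only
#'   flow/bias statistics (much faster).
#' @return A list with a summary table and per-spread details.
#' @export
run_ai_spread_sweep <- function(config, train = TRUE) {
  grid <- config$grid
  rows <- list()
  details <- list()
  for (si in seq_along(config$ai_spreads_um)) {
    spread <- config$ai_spreads_um[si]
    wp <- set_param(config$wave, wave_params, sigma_ai_um = spread)
    set.seed(derive_seed(config$seed, 20L + si))
    waves <- simulate_waves(grid, wp, config$n_waves)
    b_wave <- wave_direction_bias(attr(waves, "headings"))
    flow <- wave_flow_field(waves, grid)
    sing <- find_singularity(flow)
    dist <- sqrt(sum((sing$position_um - grid$nose_um)^2))
    opm <- NULL
    if (train) {
      fit <- train_map(grid, wp, config$learn, waves,
                       seed = derive_seed(config$seed, 60L + si))
      opm <- orientation_map(fit)
    }
    rows[[si]] <- data.frame(
      sigma_ai_um = spread, b_wave = b_wave,
      sing_dist_um = dist,
      mean_conc_diff = if (train) mean(opm$conc_diff, na.rm = TRUE) else NA_real_,
      mean_lhi = if (train) mean(opm$lhi, na.rm = TRUE) else NA_real_)
    details[[si]] <- list(flow = flow, singularity = sing, opm = opm)
  }
  list(table = do.call(rbind, rows), details = details)
}

#' Activity-noise sweep
#'
#' Trains the full map on a fixed set of biased wave ensembles (one per seed
#' replicate) at every noise fraction \code{gamma} (with signal amplitude
#' \code{r = 1 - gamma}), and summarises the map-mean LHI, gOSI, tuning
#' strength and concentric alignment per level, averaged over the replicates.
#' With a single replicate the \code{gamma = 0} level reproduces the
#' biased-waves-with-OFF-delay regime exactly when run with the same seeds.
#'
#' @param config An \code{\link{experiment_config}}; \code{config$n_seeds}
#'   sets the number of seed replicates per level.
#' @return A list with the per-level summary table (seed-averaged), the
#'   per-replicate table, and the orientation maps of the first replicate.
#' @export
run_noise_sweep <- function(config) {
  grid <- config$grid
  rows <- list()
  opms <- list()
  for (s in seq_len(config$n_seeds)) {
    wave_key <- if (s == 1L) 2L else 2L + 100L * s
    train_key <- if (s == 1L) 14L else 14L + 100L * s
    set.seed(derive_seed(config$seed, wave_key))
    waves <- simulate_waves(grid, config$wave, config$n_waves)
    for (li in seq_along(config$noise_fractions)) {
      g <- config$noise_fractions[li]
      wp <- set_param(config$wave, wave_params, gamma = g, r = 1 - g)
      fit <- sc_train(grid, wp, config$learn, waves = waves, neurons = "all",
                      seed = derive_seed(config$seed, train_key))
      opm <- orientation_map(fit)   # map metrics only; no flow needed here
      if (s == 1L) opms[[li]] <- opm
      rows[[length(rows) + 1L]] <- data.frame(
        seed_rep = s, gamma = g, noise_pct = 100 * g,
        mean_lhi = mean(opm$lhi, na.rm = TRUE),
        mean_gosi = mean(opm$gosi, na.rm = TRUE),
        mean_tuning = mean(opm$tuning_strength, na.rm = TRUE),
        mean_conc_diff = mean(opm$conc_diff, na.rm = TRUE))
    }
  }
  reps <- do.call(rbind, rows)
  tab <- aggregate(cbind(mean_lhi, mean_gosi, mean_tuning, mean_conc_diff) ~
                     gamma + noise_pct, reps, mean)
  tab <- tab[order(tab$gamma), ]
  rownames(tab) <- NULL
  list(table = tab, replicates = reps, opms = opms)
}

#' Run a configured experiment
#'
#' Dispatches on \code{config$experiment}; when \code{output_dir} is set, the
#' summary table, the resolved configuration and a run manifest are written
#' there.
#'
#' @param config An \code{\link{experiment_config}} or a YAML path.
#' @return The experiment's result object, invisibly when writing outputs.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  res <- switch(config$experiment,
                single_neuron_sweep = run_single_neuron_sweep(config),
                map_regimes = run_map_regimes(config),
                ai_spread_sweep = run_ai_spread_sweep(config),
                noise_sweep = run_noise_sweep(config))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- if (is.data.frame(res)) res else res$table %||% res$summary
    utils::write.csv(tab, file.path(config$output_dir, "summary.csv"),
                     row.names = FALSE)
    write_experiment_config(config, file.path(config$output_dir, "config.yaml"))
    yaml::write_yaml(list(experiment = config$experiment, seed = config$seed,
                          n_waves = config$n_waves,
                          package_version = as.character(utils::packageVersion("scwavemap")),
                          timestamp = format(Sys.time(), tz = "UTC")),
                     file.path(config$output_dir, "manifest.yaml"))
    return(invisible(res))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-neuron map summaries to CSV
#'
#' Fixed-schema export of an orientation map: one row per SC neuron with
#' position, orientation preference, tuning strength, gOSI, input
#' segregation, LHI and concentric-angle difference.
#'
#' @param opm An \code{orientation_map}.
#' @param path Output CSV path.
#' @export
write_map_csv <- function(opm, path) {
  utils::write.csv(as.data.frame(opm)[, c("neuron", "i", "j", "ap_um", "ml_um",
                                          "theta_pref", "tuning_strength",
                                          "gosi", "i_seg", "lhi", "conc_diff")],
                   path, row.names = FALSE)
  invisible(path)
}
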