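# S3 methods for the fitted model object.

#' @export
print.sc_fit <- function(x, ...) {
  cat("Retinocollicular wave-development model fit\n")
  cat(sprintf("  %d x %d lattice, %d wave epochs, %d trained neuron(s)\n",
              x$grid$n_rows, x$grid$n_cols, x$n_waves, length(x$neurons)))
  cat(sprintf("  tau_OFF = %g s, bias b = %g, sigma_AI = %g um, noise gamma = %g\n",
              x$wave$tau_off_s, x$wave$b, x$wave$sigma_ai_um, x$wave$gamma))
  if (!is.null(x$headings))
    cat(sprintf("  ensemble heading bias B_wave = %.3f\n",
                wave_direction_bias(x$headings)))
  invisible(x)
}

#' Summarise a trained model
#'
#' Computes the orientation map of the trained weights and reports map-level
#' statistics (mean tuning strength, gOSI, ON/OFF input segregation, LHI, and
#' the flow singularity when waves were kept).
#'
#' @param object An \code{sc_fit}.
#' @param ... Passed to \code{\link{orientation_map}}.
#' @export
summary.sc_fit <- function(object, ...) {
  opm <- orientation_map(object, ...)
  structure(list(fit = object, opm = opm), class = "summary.sc_fit")
}

#' @export
print.summary.sc_fit <- function(x, ...) {
  print(x$fit)
  print(x$opm)
  invisible(x)
}

#' Extract the synaptic weight tensor
#'
#' @param object An \code{sc_fit}.
#' @param form \code{"packed"} (the K x n arbor-aligned matrices) or
#'   \code{"dense"} (two full n_SC x n_RGC matrices).
#' @param ... Unused.
#' @export
coef.sc_fit <- function(object, form = c("packed", "dense"), ...) {
  form <- match.arg(form)
  w <- object$weights
  if (form == "packed") return(w)
  arb <- w$arbor
  n <- ncol(w$w_on)
  np <- arb$n_rows * arb$n_cols
  on <- off <- matrix(0, n, np)
  for (x in seq_len(n)) {
    v <- which(!is.na(arb$nbr[, x]))
    on[x, arb$nbr[v, x]] <- w$w_on[v, x]
    off[x, arb$nbr[v, x]] <- w$w_off[v, x]
  }
  list(w_on = on, w_off = off)
}

#' Predict receptive fields or orientation preferences
#'
#' @param object An \code{sc_fit}.
#' @param neurons Neuron indices (default: the trained neurons).
#' @param type \code{"rf"} returns the rendered receptive fields;
#'   \code{"orientation"} returns a data frame of orientation preference,
#'   resultant magnitude and tuning strength.
#' @param canvas An \code{\link{rf_canvas}}.
#' @param ... Unused.
#' @export
predict.sc_fit <- function(object, neurons = object$neurons,
                           type = c("rf", "orientation"),
                           canvas = rf_canvas(), ...) {
  type <- match.arg(type)
  rfs <- lapply(neurons, function(x)
    sc_rf(object$weights, x, canvas, m = object$grid$vf_scale_m))
  if (type == "rf") {
    names(rfs) <- neurons
    return(rfs)
  }
  do.call(rbind, lapply(seq_along(neurons), function(k) {
    op <- orientation_preference(rfs[[k]], on_zero = "na")
    data.frame(neuron = neurons[k], theta_pref = op[["theta_pref"]],
               mu = op[["mu"]], tuning_strength = tuning_strength(rfs[[k]]),
               contrast = rf_contrast(rfs[[k]]))
  }))
}

#' Simulate wave epochs from a fitted model's parameters
#'
#' @param object An \code{sc_fit}.
#' @param nsim Number of epochs.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A \code{wave_ensemble}.
#' @export
simulate.sc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_waves(object$grid, object$wave, nsim)
}

#' Plot a trained model
#'
#' @param x An \code{sc_fit}.
#' @param what \code{"map"} (orientation-preference map) or \code{"rf"}
#'   (receptive field of \code{neuron}).
#' @param neuron Neuron index for \code{what = "rf"}.
#' @param ... Passed on to the underlying plot method.
#' @export
plot.sc_fit <- function(x, what = c("map", "rf"),
                        neuron = center_neuron(x$grid), ...) {
  what <- match.arg(what)
  if (what == "rf") {
    plot(sc_rf(x$weights, neuron, m = x$grid$vf_scale_m), ...)
  } else {
    plot(orientation_map(x), ...)
  }
  invisible(x)
}
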