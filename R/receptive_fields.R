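# Visual-field receptive fields: difference-of-Gaussians RGC kernels and
# weighted-sum SC receptive fields.  OFF kernels are the negated ON kernel,
# so an SC field reduces to a single kernel stack applied to w_ON - w_OFF.

#' Receptive-field canvas
#'
#' Geometry of the visual-field (VF) window on which receptive fields are
#' rendered.  Per-neuron fields use a square crop of half-width
#' \code{crop_halfwidth} VF pixels around the neuron's retinotopic VF centre.
#'
#' @param crop_halfwidth Half-width of the per-neuron crop window, VF pixels.
#' @param sigma_rf RGC centre-Gaussian spread, VF pixels (the surround has
#'   spread \code{3 * sigma_rf} and weight 1/5).
#' @param deg_per_pixel Degrees of visual angle per VF pixel.
#' @return An object of class \code{rf_canvas}.
#' @export
rf_canvas <- function(crop_halfwidth = 60, sigma_rf = 17, deg_per_pixel = 0.6) {
  stopifnot(crop_halfwidth >= 1, sigma_rf > 0, deg_per_pixel > 0)
  structure(list(crop_halfwidth = as.integer(crop_halfwidth),
                 sigma_rf = sigma_rf, deg_per_pixel = deg_per_pixel,
                 surround_scale = 3, surround_weight = 1 / 5),
            class = "rf_canvas")
}

# DoG profile at squared distance d2 (VF pixel units), sign h = +-1
dog_value <- function(d2, canvas, h = 1) {
  s1 <- canvas$sigma_rf
  s2 <- canvas$surround_scale * s1
  h * (exp(-d2 / (2 * s1^2)) / (2 * pi * s1^2) -
         canvas$surround_weight * exp(-d2 / (2 * s2^2)) / (2 * pi * s2^2))
}

#' RGC receptive field (difference of Gaussians)
#'
#' \eqn{\Psi_P = h [G(\cdot; c, \sigma) - (1/5) G(\cdot; c, 3\sigma)]} with
#' \eqn{h = +1} for ON and \eqn{-1} for OFF cells.
#'
#' @param polarity \code{"on"} or \code{"off"}.
#' @param center_vf RGC centre in VF pixels, \code{c(x, y)}.
#' @param canvas An \code{\link{rf_canvas}}.
#' @param xs,ys Coordinate vectors of the evaluation window (VF pixels);
#'   default: \code{center_vf +- crop_halfwidth}.
#' @return A matrix (rows = y, cols = x) with coordinate attributes
#'   \code{xs}, \code{ys}.
#' @export
rgc_rf <- function(polarity = c("on", "off"), center_vf = c(0, 0),
                   canvas = rf_canvas(), xs = NULL, ys = NULL) {
  polarity <- match.arg(polarity)
  if (is.null(xs)) xs <- seq(center_vf[1] - canvas$crop_halfwidth,
                             center_vf[1] + canvas$crop_halfwidth)
  if (is.null(ys)) ys <- seq(center_vf[2] - canvas$crop_halfwidth,
                             center_vf[2] + canvas$crop_halfwidth)
  d2 <- outer((ys - center_vf[2])^2, (xs - center_vf[1])^2, "+")
  out <- dog_value(d2, canvas, h = if (polarity == "on") 1 else -1)
  attr(out, "xs") <- xs
  attr(out, "ys") <- ys
  out
}

# Memoised kernel stack: one ON DoG image per arbor offset, evaluated on the
# crop window; columns aligned with the arbor's offset rows.  (W^2) x K.
rf_kernel_stack <- function(arbor, canvas, m) {
  key <- paste0("kstack_", canvas$crop_halfwidth, "_", canvas$sigma_rf, "_",
                m, "_", nrow(arbor$offsets), "_", arbor$r_radius_um)
  hit <- .scwavemap_cache[[key]]
  if (!is.null(hit)) return(hit)
  hw <- canvas$crop_halfwidth
  xy <- seq(-hw, hw)
  K <- nrow(arbor$offsets)
  out <- matrix(0, length(xy)^2, K)
  for (k in seq_len(K)) {
    cx <- m * arbor$offsets[k, "dj"]   # AP offset in VF pixels
    cy <- m * arbor$offsets[k, "di"]   # ML offset
    d2 <- outer((xy - cy)^2, (xy - cx)^2, "+")
    out[, k] <- dog_value(d2, canvas)
  }
  .scwavemap_cache[[key]] <- out
  out
}

#' SC receptive field as a weighted sum of RGC kernels
#'
#' \eqn{\Psi^{SC}_x = \sum_{a,P} w_P(x,a) \Psi_{P,a}} evaluated on the crop
#' window centred at the neuron's retinotopic VF position.  Linear in the
#' weights; the uniform initial weights give an identically zero field
#' because ON and OFF kernels cancel pointwise.
#'
#' @param weights A \code{synaptic_weights} object.
#' @param neuron SC neuron index (linear, column-major).
#' @param canvas An \code{\link{rf_canvas}}.
#' @param m Retina-to-VF scale factor.
#' @return An object of class \code{receptive_field}: list with \code{field}
#'   (matrix, rows = ML, cols = AP), \code{on_part}, \code{off_part},
#'   \code{center_vf}, and window coordinates.
#' @export
sc_rf <- function(weights, neuron, canvas = rf_canvas(), m = 2.5) {
  n <- ncol(weights$w_on)
  if (neuron < 1 || neuron > n) stop("'neuron' outside the grid")
  arb <- weights$arbor
  Kmat <- rf_kernel_stack(arb, canvas, m)
  won <- weights$w_on[, neuron]
  wof <- weights$w_off[, neuron]
  won[is.na(arb$nbr[, neuron])] <- 0
  wof[is.na(arb$nbr[, neuron])] <- 0
  W <- 2L * canvas$crop_halfwidth + 1L
  on_part <- matrix(Kmat %*% won, W, W)
  off_part <- matrix(-(Kmat %*% wof), W, W)
  rc <- pixel_rc(list(n_rows = arb$n_rows, n_cols = arb$n_cols), neuron)
  center_vf <- c(m * (rc[, "j"] - 0.5), m * (rc[, "i"] - 0.5))
  structure(list(field = on_part + off_part, on_part = on_part,
                 off_part = off_part, center_vf = center_vf,
                 halfwidth = canvas$crop_halfwidth,
                 deg_per_pixel = canvas$deg_per_pixel),
            class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf("receptive_field: %d x %d VF px window at (%.1f, %.1f), contrast %.4g\n",
              nrow(x$field), ncol(x$field), x$center_vf[1], x$center_vf[2],
              rf_contrast(x)))
  invisible(x)
}

#' @export
summary.receptive_field <- function(object, ...) {
  op <- orientation_preference(object, on_zero = "na")
  out <- list(contrast = rf_contrast(object),
              theta_pref = op["theta_pref"], mu = op["mu"],
              tuning_strength = max(tuning_curve(object)$L),
              subfield_segregation =
                tryCatch(subfield_segregation(object), error = function(e) NA_real_))
  class(out) <- "summary.receptive_field"
  out
}

#' @export
print.summary.receptive_field <- function(x, ...) {
  cat(sprintf("RF contrast %.4g; theta_pref %.1f deg (|mu| %.3g); L_max %.4g; subfield I_SEG %.3f\n",
              x$contrast, x$theta_pref, x$mu, x$tuning_strength,
              x$subfield_segregation))
  invisible(x)
}

#' @export
plot.receptive_field <- function(x, ...) {
  lim <- max(abs(range(x$field)), .Machine$double.eps)
  image(seq(-x$halfwidth, x$halfwidth), seq(-x$halfwidth, x$halfwidth),
        t(x$field), zlim = c(-lim, lim),
        col = grDevices::hcl.colors(65, "Blue-Red 2"),
        xlab = "VF x (px)", ylab = "VF y (px)", ...)
  invisible(x)
}

#' Receptive-field contrast
#'
#' Difference between the maximal and minimal values of the field.
#'
#' @param rf A \code{receptive_field} (or a plain matrix).
#' @return A nonnegative scalar.
#' @export
rf_contrast <- function(rf) {
  f <- if (inherits(rf, "receptive_field")) rf$field else rf
  max(f) - min(f)
}
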