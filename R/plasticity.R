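# Hebbian plasticity with subtractive normalization: arbor mask, weight
# tensor, trial correlations, the literal update rule, and the
# nonnegativity/conservation constraint.  sc_train() (sc_train.R) composes
# these through a compiled trial loop.

#' Learning parameters
#'
#' @param eta Learning rate (> 0).  Chosen so that single-epoch weight deltas
#'   are small relative to \code{w0}.
#' @param t_trial_frames Trial length in frames; \code{NULL} (default) bins
#'   each full epoch (wave plus kernel tail) into a single trial.
#' @param w0 Initial synaptic weight.
#' @param r_radius_um Arbor (input integration site) radius in micrometres;
#'   175 um corresponds to a 350 um integration-site diameter.
#' @param n_waves Default number of training epochs.
#' @param plasticity_noise_sd Optional multiplicative Gaussian noise on each
#'   weight delta (sd; 0 disables).
#' @param update_dropout_p Optional per-synapse probability of dropping an
#'   update (0 disables).
#' @param conserve_total If \code{TRUE}, rescale each neuron's total weight to
#'   its initial value after the constraint step.  The literal update plus
#'   constraint (the default) conserves the per-neuron signed total through
#'   the constraint only.
#' @return An object of class \code{learning_params}.
#' @export
learning_params <- function(eta = 0.01, t_trial_frames = NULL, w0 = 0.1,
                            r_radius_um = 175, n_waves = 2000,
                            plasticity_noise_sd = 0, update_dropout_p = 0,
                            conserve_total = FALSE) {
  stopifnot(eta > 0, w0 > 0, r_radius_um > 0, n_waves >= 1,
            plasticity_noise_sd >= 0,
            update_dropout_p >= 0, update_dropout_p < 1)
  if (!is.null(t_trial_frames)) stopifnot(t_trial_frames >= 1)
  structure(list(eta = eta, t_trial_frames = t_trial_frames, w0 = w0,
                 r_radius_um = r_radius_um, n_waves = as.integer(n_waves),
                 plasticity_noise_sd = plasticity_noise_sd,
                 update_dropout_p = update_dropout_p,
                 conserve_total = conserve_total),
            class = "learning_params")
}

#' Arbor mask (input integration site)
#'
#' The binary arbor function R(x, a) is 1 when the SC neuron at x and the RGC
#' at a are within \code{r_radius_um} of each other (pixel centres, identity
#' retinotopy), constraining synapses to the retinotopic neighbourhood.  The
#' mask is stored in packed form: the fixed set of in-radius pixel offsets and
#' a K x n matrix of neighbour pixel indices (NA where the offset falls
#' outside the grid, so edge neurons have smaller arbors).
#'
#' @param grid A \code{\link{grid_spec}}.
#' @param r_radius_um Arbor radius, micrometres.
#' @return An object of class \code{arbor} with elements \code{offsets}
#'   (K x 2), \code{nbr} (K x n integer), \code{k_count} (in-arbor pixel count
#'   per neuron) and \code{r_radius_um}.
#' @export
arbor_mask <- function(grid, r_radius_um = 175) {
  stopifnot(r_radius_um > 0)
  rmax <- floor(r_radius_um / grid$pixel_um)
  d <- -rmax:rmax
  off <- as.matrix(expand.grid(di = d, dj = d))
  off <- off[(off[, 1]^2 + off[, 2]^2) * grid$pixel_um^2 <= r_radius_um^2, ,
             drop = FALSE]
  n <- n_pixels(grid)
  rc <- pixel_rc(grid, seq_len(n))
  K <- nrow(off)
  nbr <- matrix(NA_integer_, K, n)
  for (k in seq_len(K)) {
    ii <- rc[, "i"] + off[k, "di"]
    jj <- rc[, "j"] + off[k, "dj"]
    ok <- ii >= 1 & ii <= grid$n_rows & jj >= 1 & jj <= grid$n_cols
    nbr[k, ok] <- pixel_index(grid, ii[ok], jj[ok])
  }
  structure(list(offsets = off, nbr = nbr, k_count = colSums(!is.na(nbr)),
                 r_radius_um = r_radius_um, n_rows = grid$n_rows,
                 n_cols = grid$n_cols), class = "arbor")
}

#' @export
#' @method as.matrix arbor
as.matrix.arbor <- function(x, ...) {
  n <- x$n_rows * x$n_cols
  M <- matrix(FALSE, n, n)
  for (xx in seq_len(n)) {
    j <- x$nbr[, xx]
    M[xx, j[!is.na(j)]] <- TRUE
  }
  M
}

#' Initialise the synaptic weight tensor
#'
#' All in-arbor ON and OFF weights start at \code{w0}; out-of-arbor entries
#' are structurally zero.
#'
#' @param grid A \code{\link{grid_spec}}.
#' @param learn A \code{\link{learning_params}}.
#' @return An object of class \code{synaptic_weights} with packed K x n
#'   matrices \code{w_on}, \code{w_off} aligned with the arbor's \code{nbr}
#'   index matrix.
#' @export
init_weights <- function(grid, learn = learning_params()) {
  arb <- arbor_mask(grid, learn$r_radius_um)
  valid <- !is.na(arb$nbr)
  w <- matrix(0, nrow(arb$nbr), ncol(arb$nbr))
  w[valid] <- learn$w0
  structure(list(w_on = w, w_off = w, arbor = arb, grid_dims =
                   c(grid$n_rows, grid$n_cols)), class = "synaptic_weights")
}

#' @export
print.synaptic_weights <- function(x, ...) {
  cat(sprintf("synaptic_weights: %d SC neurons, <= %d RGCs/polarity in arbor (radius %g um)\n",
              ncol(x$w_on), nrow(x$w_on), x$arbor$r_radius_um))
  cat(sprintf("  total weight: %.4g (ON %.4g, OFF %.4g)\n",
              sum(x$w_on) + sum(x$w_off), sum(x$w_on), sum(x$w_off)))
  invisible(x)
}

#' Trial-averaged presynaptic correlations
#'
#' The correlation structure
#' \eqn{C_{P,P'}(a, b) = T^{-1} \sum_t V_P(a,t) V_{P'}(b,t)} over a trial
#' window.  The object stores the windowed activity and evaluates entries on
#' demand, so only queried pairs are materialised.
#'
#' @param movie An \code{rgc_movie} from \code{\link{rgc_activity}}.
#' @param window Integer vector of frame indices (default: the whole movie).
#' @param t_trial Normalising trial length in frames (defaults to
#'   \code{length(window)}).
#' @return An object of class \code{trial_correlations}.
#' @export
trial_correlations <- function(movie, window = NULL, t_trial = NULL) {
  if (is.null(window)) window <- seq_len(ncol(movie$on))
  if (!length(window) || any(window < 1) || any(window > ncol(movie$on)))
    stop("empty or out-of-range trial window")
  if (is.null(t_trial)) t_trial <- length(window)
  structure(list(v = list(on = movie$on[, window, drop = FALSE],
                          off = movie$off[, window, drop = FALSE]),
                 t_trial = t_trial), class = "trial_correlations")
}

#' @describeIn trial_correlations Evaluate \eqn{C_{P,P'}(a, b)} (vectorised
#'   over pixel pairs \code{a}, \code{b}).
#' @param C A \code{trial_correlations} object.
#' @param p1,p2 Polarities, \code{"on"} or \code{"off"}.
#' @param a,b Pixel indices.
#' @export
correlation_at <- function(C, p1, a, p2, b) {
  rowSums(C$v[[p1]][a, , drop = FALSE] * C$v[[p2]][b, , drop = FALSE]) / C$t_trial
}

# full correlation matrix over the given pixels, blocks ordered [ON, OFF]
correlation_block <- function(C, pixels) {
  V <- rbind(C$v$on[pixels, , drop = FALSE], C$v$off[pixels, , drop = FALSE])
  tcrossprod(V) / C$t_trial
}

#' One Hebbian update with subtractive normalization (reference path)
#'
#' Computes the per-trial weight delta
#' \deqn{\Delta w_P(x,a) = \eta\Big[\sum_{b,P'} w_{P'}(x,b) C_{P,P'}(a,b)
#'   - \frac{\sum_{b,g,P',P''} w_{P'}(x,b) w_{P''}(x,g) C_{P',P''}(b,g)}
#'          {2\sum_g R(x,g)}\Big]}
#' on the arbor support.  This direct implementation is the reference for the
#' compiled trial loop used by \code{\link{sc_train}}.
#'
#' @param weights A \code{synaptic_weights} object.
#' @param C A \code{\link{trial_correlations}} object.
#' @param learn A \code{\link{learning_params}} (supplies \code{eta}).
#' @param neurons Neuron indices to update (default: all).
#' @return A list with delta matrices \code{d_on}, \code{d_off} in the packed
#'   layout of \code{weights}.
#' @export
hebbian_update <- function(weights, C, learn = learning_params(),
                           neurons = NULL) {
  arb <- weights$arbor
  K <- nrow(arb$nbr)
  n <- ncol(arb$nbr)
  if (is.null(neurons)) neurons <- seq_len(n)
  d_on <- matrix(0, K, n)
  d_off <- matrix(0, K, n)
  for (x in neurons) {
    valid <- which(!is.na(arb$nbr[, x]))
    if (!length(valid)) next
    pix <- arb$nbr[valid, x]
    M <- correlation_block(C, pix)
    wv <- c(weights$w_on[valid, x], weights$w_off[valid, x])
    term1 <- as.numeric(M %*% wv)
    term2 <- as.numeric(wv %*% M %*% wv) / (2 * arb$k_count[x])
    delta <- learn$eta * (term1 - term2)
    m <- length(valid)
    d_on[valid, x] <- delta[seq_len(m)]
    d_off[valid, x] <- delta[m + seq_len(m)]
  }
  list(d_on = d_on, d_off = d_off)
}

#' Nonnegativity constraint with conserved signed totals
#'
#' Per SC neuron: negative weights are set to zero and every positive weight
#' is reduced proportionally by the factor
#' \eqn{\sum|negatives| / \sum positives}, so the per-neuron signed total is
#' conserved exactly and all outputs are nonnegative.  A neuron whose
#' negative mass reaches its positive mass has no nonnegative configuration
#' with the same total and is zeroed with a warning.
#'
#' @param weights A \code{synaptic_weights} object (possibly with negative
#'   entries after an update).
#' @return The constrained \code{synaptic_weights}.
#' @export
constrain_weights <- function(weights) {
  w <- rbind(weights$w_on, weights$w_off)
  pos <- pmax(w, 0)
  s_pos <- colSums(pos)
  s_neg <- -colSums(pmin(w, 0))
  degenerate <- s_neg > 0 & s_pos <= s_neg
  if (any(degenerate))
    warning(sum(degenerate), " neuron(s) with no conservable positive ",
            "weight; zeroed")
  f <- ifelse(s_pos > s_neg, 1 - s_neg / s_pos, 0)
  w <- sweep(pos, 2, f, "*")
  K <- nrow(weights$w_on)
  weights$w_on <- w[seq_len(K), , drop = FALSE]
  weights$w_off <- w[K + seq_len(K), , drop = FALSE]
  weights
}

# per-neuron totals (signed) of a packed weight object
weight_totals <- function(weights) colSums(weights$w_on) + colSums(weights$w_off)
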