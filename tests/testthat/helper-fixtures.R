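# shared fixtures: a small lattice for fast plasticity tests and a builder
# for hand-crafted weight tensors

small_grid <- function() grid_spec(n_rows = 12, n_cols = 12, nose_um = c(150, 300))

# weights with all in-arbor entries set from a function of (k, neuron)
make_weights <- function(grid, fill_on = 0.1, fill_off = 0.1,
                         r_radius_um = 175) {
  w <- init_weights(grid, learning_params(r_radius_um = r_radius_um))
  valid <- !is.na(w$arbor$nbr)
  w$w_on[] <- 0; w$w_off[] <- 0
  w$w_on[valid] <- fill_on
  w$w_off[valid] <- fill_off
  w
}

# two-lobed Gabor-like field: positive and negative Gaussian lobes displaced
# by +-delta along the axis at angle `axis_deg`; stimulus orientation is
# orthogonal to that axis.  delta < sigma keeps the spectrum in the linear
# (single-peaked) regime, as for the model RFs
two_lobe_field <- function(axis_deg = 0, delta = 5, sigma = 8, hw = 40) {
  xy <- seq(-hw, hw)
  ax <- axis_deg * pi / 180
  cx <- delta * cos(ax); cy <- delta * sin(ax)
  d2p <- outer((xy - cy)^2, (xy - cx)^2, "+")
  d2n <- outer((xy + cy)^2, (xy + cx)^2, "+")
  exp(-d2p / (2 * sigma^2)) - exp(-d2n / (2 * sigma^2))
}
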