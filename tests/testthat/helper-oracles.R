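# Independent oracles used across tests.

# Lattice-count volume of the ellipsoid with semi-axes (h/2, w/2, w/2):
# counts lattice points at `res` points per mm inside the analytic surface.
lattice_ellipsoid_volume <- function(h, w, res = 40) {
  a <- h / 2; b <- w / 2
  xs <- seq(-a, a, by = 1 / res)
  ys <- seq(-b, b, by = 1 / res)
  cnt <- 0
  for (x in xs) {
    rem <- 1 - (x / a)^2
    if (rem <= 0) next
    # points (y, z) with (y/b)^2 + (z/b)^2 <= rem: count per slice
    inside <- outer((ys / b)^2, (ys / b)^2, `+`) <= rem
    cnt <- cnt + sum(inside)
  }
  cnt / res^3
}

# Two-sided t-test p-value by numerical integration of the t density.
t_pvalue_quadrature <- function(tstat, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(tstat), Inf)$value
}

# A small noiseless synthetic scene with generous resolution.
default_scene <- function(h_mm, w_mm, scale = 12) {
  photo_truth(h_mm, w_mm, scale = scale, tip = c(30, 110),
              width_px = 220, height_px = 280, noise_sd = 0)
}
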