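# Independent oracles and fixture builders shared across tests.

# DIG/AntiDIG slip-bond parameters used as a canonical fixture throughout.
dig_landscape <- function() energy_landscape(k_off = 4.0e-4, delta_x = 0.76)

# Full-grid upsampled cross-correlation: the brute-force reference for the
# localized matrix-DFT refinement. Zero-pads the FFT product to usfac times
# the size and reads the peak off the dense inverse transform.
brute_force_displacement <- function(window, reference, usfac) {
  nr <- nrow(reference); nc <- ncol(reference)
  fprod <- stats::fft(reference) * Conj(stats::fft(window))
  NR <- nr * usfac; NC <- nc * usfac
  freq <- function(n) c(0:(ceiling(n / 2) - 1), seq.int(-floor(n / 2), -1))
  big <- matrix(0 + 0i, NR, NC)
  big[freq(nr) %% NR + 1, freq(nc) %% NC + 1] <- fprod
  cc <- Re(stats::fft(big, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  rs <- pk[[1]] - 1; cs <- pk[[2]] - 1
  if (rs > NR / 2) rs <- rs - NR
  if (cs > NC / 2) cs <- cs - NC
  c(dx = -cs / usfac, dy = -rs / usfac)
}

# Soft-edged disk bead image at a sub-pixel center, same profile as the
# renderer's default.
bead_image <- function(n, y0, x0, radius = 3, amplitude = 0.8) {
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  amplitude * stats::pnorm(radius - sqrt((yy - y0)^2 + (xx - x0)^2))
}

# Grid-search argmax of the rupture density: the mode oracle for the
# closed-form most probable force.
grid_mode_oracle <- function(landscape, f_dot, env, upper = 100, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  grid[which.max(rupture_density(grid, landscape, f_dot, env))]
}

# Trapezoid quadrature of the rupture density: CDF oracle.
quadrature_cdf_oracle <- function(force, landscape, f_dot, env, step = 1e-3) {
  grid <- seq(0, force, by = step)
  p <- rupture_density(grid, landscape, f_dot, env)
  sum((p[-1] + p[-length(p)]) / 2) * step
}
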