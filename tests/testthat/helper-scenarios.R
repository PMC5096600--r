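# Shared small fixtures, built in code. Reduced grids keep unit tests fast;
# the acceptance suite uses the full study-condition grids.

two_layer_stack <- function()
  oa_stack(data.frame(z_start = c(0, 0.05), z_end = c(0.05, 0.1),
                      mu_a = c(10, 20)), L_z = 0.15)

fig_beam <- function() oa_beam(0.15, 0.15 / 4)

small_cyl_grid <- function(N_rho = 800, N_phi = 90, N_z = 150)
  oa_grid_cyl(L_rho = 0.3, N_rho = N_rho, N_phi = N_phi,
              L_z = 0.15, N_z = N_z)

# independent midpoint quadrature of the Poisson-integral volume integral
# (no time binning): sum over a Cartesian voxelization of W * dV / |r_D - r'|
brute_volume_integral <- function(stack, beam, det, const,
                                  L_x, L_y, L_z, N_x, N_y, N_z) {
  x <- (seq_len(N_x) - 0.5) * (L_x / N_x) - L_x / 2
  y <- (seq_len(N_y) - 0.5) * (L_y / N_y) - L_y / 2
  z <- (seq_len(N_z) - 0.5) * (L_z / N_z)
  dV <- (L_x / N_x) * (L_y / N_y) * (L_z / N_z)
  total <- 0
  for (k in seq_along(z)) {
    g <- depth_profile_g(stack, z[k])
    if (g == 0) next
    f <- beam_profile(beam, sqrt(outer(x^2, y^2, "+")))
    r <- sqrt(outer((x - det$x_D)^2, y^2, "+") + (z[k] + abs(det$z_D))^2)
    total <- total + sum(f / r) * g * dV
  }
  const$prefactor / (4 * pi) * total
}

# align two signals sharing a bin lattice on their common ct range
align_signals <- function(a, b) {
  ia <- round(a$ct / a$bin_width - 0.5)
  ib <- round(b$ct / b$bin_width - 0.5)
  common <- intersect(ia, ib)
  list(pa = a$p[match(common, ia)], pb = b$p[match(common, ib)])
}
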