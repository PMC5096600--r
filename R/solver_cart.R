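#' Brute-force Cartesian oracle solver
#'
#' Independent evaluation of the optoacoustic Poisson integral on a voxelized
#' Cartesian source volume: every voxel centre \eqn{r'} with
#' \eqn{W(r') > 0} contributes \eqn{W(r')\,\Delta V / |r_D - r'|} to the
#' propagation-distance bin containing \eqn{|r_D - r'|}, after which the same
#' temporal derivative and foil averaging as the cylindrical solver are
#' applied. Cost \eqn{O(N_x N_y N_z)}; intended to validate the fast solver,
#' not for production runs.
#'
#' The beam is centred on the z-axis of the surface frame, the grid is
#' centred laterally on the beam axis, and the detector sits at
#' \eqn{(x_D, 0, z_D)}. Both solvers share the bin-axis convention, so runs
#' with identical `bin_width` sample the same ct lattice.
#'
#' @inheritParams oa_solve
#' @param grid an [oa_grid_cart()].
#' @param bin_width bin width in ct units (cm); default `max(dx, dy, dz)`.
#' @return an [oa_signal].
#' @export
oa_solve_cart <- function(stack, beam, detection, grid = oa_grid_cart(),
                          const = oa_const(), foil = oa_foil(50),
                          bin_width = NULL, smooth_bins = 3) {
  stopifnot(inherits(stack, "oa_stack"), inherits(beam, "oa_beam"),
            inherits(detection, "oa_detection"),
            inherits(grid, "oa_grid_cart"), inherits(const, "oa_const"))
  if (is.null(bin_width)) bin_width <- max(grid$dx, grid$dy, grid$dz)

  x <- (seq_len(grid$N_x) - 0.5) * grid$dx - grid$L_x / 2
  y <- (seq_len(grid$N_y) - 0.5) * grid$dy - grid$L_y / 2
  z <- (seq_len(grid$N_z) - 0.5) * grid$dz
  g <- depth_profile_g(stack, z)
  if (all(g == 0) || max(mu_a_at(stack, z)) == 0) {
    if (max(optical_depth(stack, grid$L_z)) == 0 || all(g == 0))
      warning("grid contains no absorbing voxels; signal is zero")
  }

  f_xy <- beam_profile(beam, sqrt(outer(x^2, y^2, "+")))   # N_x x N_y
  # lateral squared distance voxel -> detector
  lat2 <- outer((x - detection$x_D)^2, y^2, "+")
  s <- z + abs(detection$z_D)

  r_lo <- abs(detection$z_D)
  r_hi <- sqrt(max(lat2) + (abs(detection$z_D) + grid$L_z)^2)
  ax <- make_bin_axis(r_lo, r_hi, bin_width)
  dV <- grid$dx * grid$dy * grid$dz
  scale <- const$prefactor / (4 * pi) * dV

  q <- numeric(ax$n)
  nz <- which(g > 0)
  for (k in nz) {                       # one lateral slab per absorbing z
    r <- sqrt(lat2 + s[k]^2)
    w <- scale * g[k] * f_xy / r
    idx <- as.integer(floor(r / bin_width)) - ax$k0 + 1L
    acc <- rowsum(as.vector(w), as.vector(idx))
    q[as.integer(rownames(acc))] <- q[as.integer(rownames(acc))] + acc[, 1]
  }
  binned <- structure(list(ct = ax$centers, q = q, bin_width = bin_width,
                           detection = detection, r_min = r_lo, r_max = r_hi),
                      class = "oa_binned")
  sig <- temporal_derivative(binned, smooth_bins = smooth_bins)
  foil_average(sig, foil)
}
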