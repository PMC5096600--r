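# Cylindrical-coordinate evaluation of the optoacoustic Poisson integral.
#
# The pressure at a detection point is the time derivative of a spherical-
# shell integral of W(r)/|r - r'| over the source volume. In detector-centred
# cylindrical coordinates the azimuthal integral of the beam profile can be
# precomputed once per radius (weights F_D), after which the remaining
# (rho, z) sum is binned by propagation distance: the delta constraint acts
# as an indicator assigning each quadrature cell to the distance bin
# containing sqrt(rho^2 + z'^2). Total cost O(N_rho N_phi + N_rho N_z);
# on-axis detection reduces the first term to O(N_rho) via the closed form
# F_D(rho) = 2 pi rho f_I(rho).

#' Precomputed azimuthal weights
#'
#' Integrates the lateral beam profile along closed polar curves of radius
#' \eqn{\rho_i} around the detector axis:
#' \deqn{F_D(\rho_i) = \rho_i \sum_j f_D(\rho_i, \phi_j)\,\Delta\phi,}
#' where \eqn{f_D(\rho,\phi) = f_I(\sqrt{\rho^2 + x_D^2 + 2\rho x_D\cos\phi})}
#' is the beam profile seen from a detector at lateral offset `x_D`. The
#' weight includes the \eqn{\rho} Jacobian. For an on-axis detector
#' (`x_D = 0`) the closed form \eqn{F_D(\rho_i) = 2\pi\rho_i f_I(\rho_i)} is
#' used, avoiding the azimuthal sum.
#'
#' @param beam an [oa_beam()].
#' @param x_D lateral detector offset (cm).
#' @param grid an [oa_grid_cyl()].
#' @return an object of class `oa_weights` with fields `rho` (ring radii, cm)
#'   and `F_D` (weights, cm).
#' @export
azimuthal_weights <- function(beam, x_D, grid) {
  stopifnot(inherits(beam, "oa_beam"), inherits(grid, "oa_grid_cyl"))
  rho <- (seq_len(grid$N_rho) - 0.5) * grid$drho
  if (x_D == 0) {
    F_D <- 2 * pi * rho * beam_profile(beam, rho)
  } else {
    phi <- (seq_len(grid$N_phi) - 1) * grid$dphi
    # squared radial distance from the beam axis for each (rho_i, phi_j):
    # rho^2 + x_D^2 + 2 rho x_D cos(phi)
    r2 <- matrix(rho^2 + x_D^2, grid$N_rho, grid$N_phi) +
      outer(2 * rho * x_D, cos(phi))
    f <- beam_profile(beam, sqrt(pmax(r2, 0)))
    F_D <- rho * rowSums(f) * grid$dphi
  }
  structure(list(rho = rho, F_D = F_D, x_D = x_D), class = "oa_weights")
}

# Common propagation-distance bin axis. Bins are half-open
# [edge, edge + width): a value exactly on an edge goes to the higher bin.
# The axis is anchored at ct = 0 so two solvers sharing bin_width produce
# samples on the same lattice. A pad before the earliest arrival keeps the
# causal leading zeros in the record; beyond the last arrival it gives the
# derivative and foil windows room.
make_bin_axis <- function(r_min, r_max, bin_width, pad = NULL) {
  if (is.null(pad)) pad <- max(0.01, 10 * bin_width)
  k0 <- max(0L, as.integer(floor((r_min - pad) / bin_width)))
  k1 <- as.integer(ceiling((r_max + pad) / bin_width))
  list(k0 = k0, n = k1 - k0,
       centers = (seq_len(k1 - k0) + k0 - 0.5) * bin_width)
}

#' Bin spherical-shell contributions by propagation distance
#'
#' Accumulates the quadrature of the Poisson-integral integrand into
#' propagation-distance bins: each cell \eqn{(\rho_i, z_k)} contributes
#' \eqn{(C/4\pi)\,F_D(\rho_i)\,g(z_k)\,\Delta\rho\,\Delta z / r} to the bin
#' containing its detector distance \eqn{r = \sqrt{\rho_i^2 + z'^2}}, where
#' \eqn{z' = z_k + |z_D|} is the axial source-detector distance. The binned
#' record integrates (sums) to the full volume integral of the integrand to
#' quadrature accuracy.
#'
#' @param weights an [azimuthal_weights()] table.
#' @param stack an [oa_stack()].
#' @param const an [oa_const()].
#' @param detection an [oa_detection()]; `weights` must have been computed for
#'   the same `x_D`.
#' @param grid the [oa_grid_cyl()] used for `weights`.
#' @param bin_width bin width in ct units (cm). Default
#'   `max(drho, dz)` of the grid: bins finer than the spatial quadrature only
#'   add binning noise to the derivative.
#' @param ct_range optional numeric length-2 giving the ct interval the bin
#'   axis must cover; it is an error if this fails to contain the full
#'   source-distance range.
#' @return an object of class `oa_binned` with fields `ct` (bin centres),
#'   `q` (binned integrand), `bin_width`, `detection`, `r_min`, `r_max`.
#' @export
bin_shell_contributions <- function(weights, stack, const, detection, grid,
                                    bin_width = NULL, ct_range = NULL) {
  stopifnot(inherits(weights, "oa_weights"), inherits(stack, "oa_stack"),
            inherits(const, "oa_const"), inherits(detection, "oa_detection"),
            inherits(grid, "oa_grid_cyl"))
  if (!isTRUE(all.equal(weights$x_D, detection$x_D)))
    stop("azimuthal weights were computed for a different x_D")
  if (is.null(bin_width)) bin_width <- max(grid$drho, grid$dz)
  stopifnot(bin_width > 0)

  z <- (seq_len(grid$N_z) - 0.5) * grid$dz     # depth below surface
  g <- depth_profile_g(stack, z)
  s <- z + abs(detection$z_D)                  # axial distance to detector
  r_lo <- abs(detection$z_D)                   # earliest possible arrival
  r_hi <- sqrt(grid$L_rho^2 + (abs(detection$z_D) + grid$L_z)^2)
  ax <- make_bin_axis(r_lo, r_hi, bin_width)
  if (!is.null(ct_range)) {
    if (ct_range[1] > r_lo || ct_range[2] < r_hi)
      stop("requested ct_range does not cover the source-distance range [",
           format(r_lo), ", ", format(r_hi), "] cm")
  }

  q <- numeric(ax$n)
  keep <- which(g > 0)
  if (length(keep)) {
    scale <- const$prefactor / (4 * pi) * grid$drho * grid$dz
    r <- sqrt(outer(weights$rho^2, s[keep]^2, "+"))
    w <- scale * outer(weights$F_D, g[keep]) / r
    idx <- as.integer(floor(r / bin_width)) - ax$k0 + 1L
    if (any(idx < 1L) || any(idx > ax$n))
      stop("bin axis does not cover the source-distance range")
    acc <- rowsum(as.vector(w), as.vector(idx))
    q[as.integer(rownames(acc))] <- acc[, 1]
  }
  structure(list(ct = ax$centers, q = q, bin_width = bin_width,
                 detection = detection, r_min = r_lo, r_max = r_hi),
            class = "oa_binned")
}

#' Differentiate the binned shell integrand in time
#'
#' Converts the binned record to the shell-integral density `q / bin_width`
#' and applies a central finite difference over ct (one-sided at the
#' endpoints). The speed of sound is absorbed in the arbitrary-units
#' amplitude constant, so differentiation in ct stands for the temporal
#' derivative of the Poisson integral.
#'
#' @param binned an `oa_binned` record from [bin_shell_contributions()].
#' @param smooth_bins odd width (in bins) of a short moving average applied to
#'   the binned record before differentiation, damping the staircase noise of
#'   the delta-to-indicator discretization. `1` disables smoothing.
#' @return an [oa_signal].
#' @export
temporal_derivative <- function(binned, smooth_bins = 1) {
  stopifnot(inherits(binned, "oa_binned"))
  n <- length(binned$q)
  if (n < 3) stop("need at least 3 bins to differentiate")
  G <- binned$q / binned$bin_width
  if (smooth_bins > 1) G <- moving_average(G, smooth_bins)
  d <- binned$bin_width
  p <- numeric(n)
  p[2:(n - 1)] <- (G[3:n] - G[1:(n - 2)]) / (2 * d)
  p[1] <- (G[2] - G[1]) / d
  p[n] <- (G[n] - G[n - 1]) / d
  new_oa_signal(ct = binned$ct, p = p, detection = binned$detection,
                bin_width = binned$bin_width)
}

#' Simulate an optoacoustic pressure transient (cylindrical solver)
#'
#' Full forward pipeline: precompute azimuthal weights, bin the shell
#' contributions by propagation distance, differentiate in time, and average
#' over the finite transducer foil thickness. Deterministic; no randomness
#' anywhere.
#'
#' @inheritParams bin_shell_contributions
#' @param beam an [oa_beam()].
#' @param foil an [oa_foil()]; foil thickness 0 skips the averaging.
#' @param smooth_bins pre-derivative smoothing width in bins, see
#'   [temporal_derivative()]. The default 3 stays below the foil-averaging
#'   window so it cannot alter resolved features.
#' @param weights optionally a precomputed [azimuthal_weights()] table for
#'   this beam/offset/grid, to amortize the azimuthal sum over several solves.
#' @return an [oa_signal] with the causal leading zeros retained.
#' @examples
#' st <- oa_stack(data.frame(z_start = c(0, 0.05), z_end = c(0.05, 0.1),
#'                           mu_a = c(10, 20)))
#' sig <- oa_solve(st, oa_beam(0.15, 0.15 / 4), oa_detection(-4),
#'                 grid = oa_grid_cyl(N_rho = 600, N_phi = 90, N_z = 150))
#' summary(to_retarded_depth(sig))
#' @export
oa_solve <- function(stack, beam, detection, grid = oa_grid_cyl(),
                     const = oa_const(), foil = oa_foil(50),
                     bin_width = NULL, smooth_bins = 3, weights = NULL) {
  if (is.null(weights)) weights <- azimuthal_weights(beam, detection$x_D, grid)
  binned <- bin_shell_contributions(weights, stack, const, detection, grid,
                                    bin_width = bin_width)
  sig <- temporal_derivative(binned, smooth_bins = smooth_bins)
  foil_average(sig, foil)
}
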