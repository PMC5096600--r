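# Far-field approximate reconstruction of the initial acoustic stress depth
# profile from a single pressure transient. In the limit of large diffraction
# parameter the transient approaches the temporal derivative of the on-axis
# stress profile, so integrating the signal over the retarded depth recovers
# an approximation p0_FF(z) of the exact p0(z) ~ g(z).

new_oa_profile <- function(z, p0, normalized = FALSE) {
  structure(list(z = z, p0 = p0, normalized = normalized),
            class = "oa_profile")
}

#' Depth-resolved initial acoustic stress profile
#'
#' Container for an exact or far-field-reconstructed stress depth profile on
#' a uniform depth grid.
#'
#' @param x an `oa_profile`.
#' @param ... ignored.
#' @name oa_profile
NULL

#' @rdname oa_profile
#' @export
print.oa_profile <- function(x, ...) {
  cat(sprintf(
    "Initial stress profile: %d samples, z in [%.4g, %.4g] cm%s\n",
    length(x$z), min(x$z), max(x$z),
    if (x$normalized) " (sum-normalized)" else ""))
  invisible(x)
}

#' @rdname oa_profile
#' @export
plot.oa_profile <- function(x, ...) {
  graphics::plot(x$z, x$p0, type = "l", xlab = "z [cm]",
                 ylab = expression(p[0] ~ "[a.u.]"), ...)
  invisible(x)
}

#' Exact initial stress depth profile
#'
#' The on-axis initial acoustic stress is proportional to the Beer-Lambert
#' energy deposition profile (the lateral beam factor is 1 on the axis), so
#' the exact profile is `g(z)` sampled on the axial quadrature grid.
#'
#' @param stack an [oa_stack()].
#' @param grid an [oa_grid_cyl()] (only its axial discretization is used), or
#'   `NULL` to pass `z` directly.
#' @param z optional explicit depth grid (cm); overrides `grid`.
#' @return an unnormalized [oa_profile].
#' @export
exact_p0 <- function(stack, grid = oa_grid_cyl(), z = NULL) {
  stopifnot(inherits(stack, "oa_stack"))
  if (is.null(z)) {
    stopifnot(inherits(grid, "oa_grid_cyl"))
    z <- (seq_len(grid$N_z) - 0.5) * grid$dz
  }
  new_oa_profile(z = z, p0 = depth_profile_g(stack, z))
}

#' Far-field reconstruction of the initial stress profile
#'
#' Cumulative trapezoidal integral of the pressure transient over the
#' retarded depth, mapped to depth \eqn{z = c\tau}. Valid as an approximation
#' in the acoustic far field (diffraction parameter \eqn{D \gg 1}); the
#' reconstruction is returned unnormalized and is linear in the input signal.
#' The integration runs forward from the first sample; the far-field
#' signal's leading compression makes the integral positive over the
#' absorber, so no sign flip is applied.
#'
#' @param signal an [oa_signal] in retarded-depth form (see
#'   [to_retarded_depth()]).
#' @param z_max optional clip depth (cm): samples with \eqn{c\tau} outside
#'   `[0, z_max]` are dropped after integration, restricting the profile to
#'   the domain on which the exact profile is defined.
#' @return an unnormalized [oa_profile] on the `ctau` grid of the signal.
#' @export
reconstruct_p0_ff <- function(signal, z_max = NULL) {
  stopifnot(inherits(signal, "oa_signal"))
  if (is.null(signal$ctau))
    stop("signal must carry a retarded-depth axis; see to_retarded_depth()")
  d <- diff(signal$ctau)
  if (length(d) < 1 || max(abs(d - d[1])) > 1e-9 * abs(d[1]))
    stop("retarded-depth axis must be uniform")
  p <- signal$p
  # cumulative trapezoid over ctau
  cum <- c(0, cumsum((p[-1] + p[-length(p)]) / 2 * d))
  prof <- new_oa_profile(z = signal$ctau, p0 = cum)
  if (!is.null(z_max)) {
    keep <- prof$z >= 0 & prof$z <= z_max
    prof$z <- prof$z[keep]
    prof$p0 <- prof$p0[keep]
  }
  prof
}

#' Sum-normalize a stress profile
#'
#' Divides the profile by its sample sum so that \eqn{\sum_i p_0(z_i) = 1},
#' making exact and reconstructed profiles comparable on the same scale.
#' Scale-invariant: any positive rescaling of the input yields the same
#' output.
#'
#' @param profile an [oa_profile].
#' @return the normalized [oa_profile] (`normalized = TRUE`).
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "oa_profile"))
  s <- sum(profile$p0)
  if (sum(abs(profile$p0)) == 0 || s == 0)
    stop("cannot normalize a zero-sum profile")
  profile$p0 <- profile$p0 / s
  profile$normalized <- TRUE
  profile
}

# Linear interpolation of a profile onto a new depth grid; values outside the
# source support are taken as 0 (the profile vanishes there by construction).
resample_profile <- function(profile, z_new) {
  p0 <- stats::approx(profile$z, profile$p0, xout = z_new, rule = 1)$y
  p0[is.na(p0)] <- 0
  new_oa_profile(z = z_new, p0 = p0, normalized = FALSE)
}

#' Mean squared error between two stress profiles
#'
#' \eqn{\mathrm{MSE} = \sum_i [p_0(z_i) - p_{0,FF}(z_i)]^2 / N_z} on the
#' depth grid of `exact`. Both profiles must be sum-normalized; if the
#' reconstruction lives on a different grid it is first linearly interpolated
#' onto the grid of `exact` and renormalized there.
#'
#' @param exact,recon normalized [oa_profile]s.
#' @return the scalar MSE (dimensionless).
#' @export
profile_mse <- function(exact, recon) {
  stopifnot(inherits(exact, "oa_profile"), inherits(recon, "oa_profile"))
  if (!exact$normalized || !recon$normalized)
    stop("both profiles must be normalized before computing the MSE")
  if (length(recon$z) != length(exact$z) ||
      max(abs(recon$z - exact$z)) > 1e-9) {
    recon <- normalize_profile(resample_profile(recon, exact$z))
  }
  mean((exact$p0 - recon$p0)^2)
}

#' MSE of the far-field reconstruction versus detector distance
#'
#' For each detector position: simulate the transient with the cylindrical
#' solver, convert to retarded depth, integrate to the far-field profile
#' estimate, clip to the absorber domain, normalize, and score against the
#' normalized exact profile. Quantifies how the reconstruction improves as
#' the detector moves deeper into the acoustic far field.
#'
#' @inheritParams oa_solve
#' @param z_D_list detector axial positions (cm), all negative.
#' @param x_D lateral offset applied to every detection point.
#' @return a `data.frame` with columns `z_D` and `mse`.
#' @export
mse_sweep <- function(stack, beam, z_D_list, grid = oa_grid_cyl(),
                      const = oa_const(), foil = oa_foil(50),
                      bin_width = NULL, smooth_bins = 3, x_D = 0) {
  stopifnot(all(z_D_list < 0))
  p0_ref <- normalize_profile(exact_p0(stack, grid))
  weights <- azimuthal_weights(oa_beam(beam$a, beam$d), x_D, grid)
  mse <- vapply(z_D_list, function(zd) {
    sig <- oa_solve(stack, beam, oa_detection(zd, x_D), grid = grid,
                    const = const, foil = foil, bin_width = bin_width,
                    smooth_bins = smooth_bins, weights = weights)
    rec <- reconstruct_p0_ff(to_retarded_depth(sig), z_max = grid$L_z)
    profile_mse(p0_ref, normalize_profile(rec))
  }, numeric(1))
  data.frame(z_D = z_D_list, mse = mse)
}
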