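#' Cylindrical solver grid
#'
#' Discretization of the source volume in detector-centred cylindrical
#' coordinates: radial extent `L_rho` with `N_rho` rings, `N_phi` azimuthal
#' samples, and axial extent `L_z` with `N_z` slabs. Quadrature nodes sit at
#' cell midpoints, \eqn{\rho_i = (i + 1/2)\Delta\rho},
#' \eqn{z_k = (k + 1/2)\Delta z}, which avoids the degenerate \eqn{\rho = 0}
#' ring. `L_rho` must cover the lateral beam support
#' (`L_rho >= x_D + a + 4 d` recommended).
#'
#' @param L_rho radial extent (cm).
#' @param N_rho number of radial rings (>= 2).
#' @param N_phi number of azimuthal samples (>= 2).
#' @param L_z axial extent of the absorber domain (cm).
#' @param N_z number of axial slabs (>= 2).
#' @return an object of class `oa_grid_cyl` with derived spacings `drho`,
#'   `dphi`, `dz`.
#' @export
oa_grid_cyl <- function(L_rho = 0.3, N_rho = 6000, N_phi = 360,
                        L_z = 0.15, N_z = 150) {
  stopifnot(L_rho > 0, L_z > 0, N_rho >= 2, N_phi >= 2, N_z >= 2)
  structure(list(L_rho = L_rho, N_rho = as.integer(N_rho),
                 N_phi = as.integer(N_phi),
                 L_z = L_z, N_z = as.integer(N_z),
                 drho = L_rho / N_rho, dphi = 2 * pi / N_phi,
                 dz = L_z / N_z),
            class = "oa_grid_cyl")
}

#' @export
print.oa_grid_cyl <- function(x, ...) {
  cat(sprintf(
    "Cylindrical grid: L_rho = %g cm (N_rho = %d), N_phi = %d, L_z = %g cm (N_z = %d)\n",
    x$L_rho, x$N_rho, x$N_phi, x$L_z, x$N_z))
  invisible(x)
}

#' Cartesian oracle grid
#'
#' Voxelized cuboid representation of the source volume for the brute-force
#' solver: lateral extents `L_x`, `L_y` centred on the beam axis and axial
#' extent `L_z` below the surface. Voxel centres sit at cell midpoints; the
#' energy density is evaluated at centres without sub-voxel averaging.
#'
#' @param L_x,L_y,L_z side lengths (cm).
#' @param N_x,N_y,N_z voxel counts (>= 2). The default is a reduced grid
#'   sized for validation runs; finer grids are supported.
#' @return an object of class `oa_grid_cart`.
#' @export
oa_grid_cart <- function(L_x = 0.6, L_y = 0.6, L_z = 0.15,
                         N_x = 300, N_y = 300, N_z = 75) {
  stopifnot(L_x > 0, L_y > 0, L_z > 0, N_x >= 2, N_y >= 2, N_z >= 2)
  structure(list(L_x = L_x, L_y = L_y, L_z = L_z,
                 N_x = as.integer(N_x), N_y = as.integer(N_y),
                 N_z = as.integer(N_z),
                 dx = L_x / N_x, dy = L_y / N_y, dz = L_z / N_z),
            class = "oa_grid_cart")
}

#' @export
print.oa_grid_cart <- function(x, ...) {
  cat(sprintf(
    "Cartesian grid: (L_x, L_y, L_z) = (%g, %g, %g) cm, (N_x, N_y, N_z) = (%d, %d, %d)\n",
    x$L_x, x$L_y, x$L_z, x$N_x, x$N_y, x$N_z))
  invisible(x)
}
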