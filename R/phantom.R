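#' Plane-parallel absorbing layer stack
#'
#' Constructs an ordered stack of plane-parallel absorbing layers defining the
#' depth-dependent absorption coefficient \eqn{\mu_a(z)}. Depths are measured
#' from the irradiated surface (\eqn{z = 0}) into the medium, in cm; absorption
#' coefficients are in cm^-1. Layer intervals are half-open
#' \eqn{[z_{start}, z_{end})}, so \eqn{\mu_a(z)} is single-valued at internal
#' boundaries. Gaps (zero absorption) between layers are permitted; overlaps
#' are a validation error.
#'
#' @param layers a `data.frame` with columns `z_start`, `z_end`, `mu_a`
#'   (cm, cm, cm^-1), or a list of lists with those fields.
#' @param L_z axial extent of the computational domain (cm). Defaults to the
#'   end of the deepest layer.
#' @return an object of class `oa_stack`.
#' @examples
#' st <- oa_stack(data.frame(z_start = c(0, 0.05), z_end = c(0.05, 0.1),
#'                           mu_a = c(10, 20)))
#' mu_a_at(st, c(0.02, 0.05, 0.12))
#' @export
oa_stack <- function(layers, L_z = NULL) {
  if (is.list(layers) && !is.data.frame(layers)) {
    layers <- do.call(rbind, lapply(layers, function(l)
      data.frame(z_start = l$z_start, z_end = l$z_end, mu_a = l$mu_a)))
  }
  stopifnot(is.data.frame(layers),
            all(c("z_start", "z_end", "mu_a") %in% names(layers)))
  layers <- layers[order(layers$z_start), c("z_start", "z_end", "mu_a")]
  rownames(layers) <- NULL
  if (any(layers$z_start < 0))
    stop("layer depths must be non-negative")
  if (any(layers$z_end <= layers$z_start))
    stop("each layer needs z_end > z_start")
  if (any(layers$mu_a < 0))
    stop("absorption coefficients must be non-negative")
  if (nrow(layers) > 1 &&
      any(layers$z_start[-1] < layers$z_end[-nrow(layers)] - 1e-12))
    stop("layers overlap; intervals must be disjoint")
  if (is.null(L_z)) L_z <- max(layers$z_end)
  if (L_z < max(layers$z_end) - 1e-12)
    stop("L_z must contain all layers")
  structure(list(layers = layers, L_z = L_z), class = "oa_stack")
}

#' @export
print.oa_stack <- function(x, ...) {
  cat("Layered absorber (", nrow(x$layers), " layer",
      if (nrow(x$layers) != 1) "s", ", domain depth L_z = ",
      format(x$L_z), " cm)\n", sep = "")
  print(x$layers, row.names = FALSE)
  invisible(x)
}

#' Absorption coefficient at depth
#'
#' Evaluates the piecewise-constant \eqn{\mu_a(z)} of a layer stack. A depth
#' belongs to the layer whose half-open interval \eqn{[z_{start}, z_{end})}
#' contains it; outside all layers the coefficient is zero.
#'
#' @param stack an [oa_stack()].
#' @param z depth(s) below the surface (cm), non-negative.
#' @return absorption coefficient(s) in cm^-1, same length as `z`.
#' @export
mu_a_at <- function(stack, z) {
  stopifnot(inherits(stack, "oa_stack"))
  if (any(z < 0)) stop("depth z must be non-negative")
  mu <- numeric(length(z))
  for (i in seq_len(nrow(stack$layers))) {
    l <- stack$layers[i, ]
    sel <- z >= l$z_start & z < l$z_end
    mu[sel] <- l$mu_a
  }
  mu
}

#' Optical depth from the surface
#'
#' Accumulated optical depth \eqn{\int_0^z \mu_a(z')\,dz'} in exact
#' piecewise-linear closed form (sum of `mu_a` times interval overlap over
#' layers). Non-decreasing in `z`.
#'
#' @inheritParams mu_a_at
#' @return dimensionless optical depth(s).
#' @export
optical_depth <- function(stack, z) {
  stopifnot(inherits(stack, "oa_stack"))
  if (any(z < 0)) stop("depth z must be non-negative")
  tau <- numeric(length(z))
  for (i in seq_len(nrow(stack$layers))) {
    l <- stack$layers[i, ]
    tau <- tau + l$mu_a * pmax(0, pmin(z, l$z_end) - l$z_start)
  }
  tau
}

#' Beer-Lambert axial absorption profile g(z)
#'
#' The 1D depth profile of the deposited volumetric energy density for a
#' non-scattering layered absorber,
#' \deqn{g(z) = \mu_a(z) \exp\{-\textstyle\int_0^z \mu_a(z')dz'\},}
#' i.e. local absorption attenuated by the fluence already absorbed above.
#' Zero wherever \eqn{\mu_a = 0}.
#'
#' @inheritParams mu_a_at
#' @return profile value(s) in cm^-1.
#' @export
depth_profile_g <- function(stack, z) {
  mu_a_at(stack, z) * exp(-optical_depth(stack, z))
}

#' Top-hat irradiation beam profile
#'
#' A flat-top beam of radius `a` with a Gaussian edge of width `d`:
#' unity for \eqn{\rho \le a}, \eqn{\exp\{-(\rho-a)^2/d^2\}} beyond.
#'
#' @param a flat-top radius (cm), positive.
#' @param d Gaussian edge width (cm), positive.
#' @return an object of class `oa_beam` with fields `a`, `d` and the derived
#'   edge-to-radius ratio `R = d/a`.
#' @examples
#' b <- oa_beam(a = 0.15, d = 0.15 / 4)
#' beam_profile(b, c(0.1, 0.15, 0.15 + b$d))
#' @export
oa_beam <- function(a, d) {
  stopifnot(is.numeric(a), is.numeric(d), length(a) == 1, length(d) == 1)
  if (a <= 0 || d <= 0) stop("beam parameters a and d must be positive")
  structure(list(a = a, d = d, R = d / a), class = "oa_beam")
}

#' @export
print.oa_beam <- function(x, ...) {
  cat("Top-hat beam: a = ", format(x$a), " cm, d = ", format(x$d),
      " cm (R = d/a = ", format(x$R), ")\n", sep = "")
  invisible(x)
}

#' Evaluate the radial beam profile
#'
#' @param beam an [oa_beam()].
#' @param rho radial distance(s) from the beam axis (cm), non-negative.
#' @return dimensionless profile value(s) in (0, 1].
#' @export
beam_profile <- function(beam, rho) {
  stopifnot(inherits(beam, "oa_beam"))
  if (any(rho < 0)) stop("radius rho must be non-negative")
  ifelse(rho <= beam$a, 1, exp(-(rho - beam$a)^2 / beam$d^2))
}

#' Detection point
#'
#' Position of the (point-like) ultrasound detector in the surface frame:
#' lateral offset `x_D` from the beam axis and axial position `z_D`, which is
#' negative for backward-mode detection on the irradiated side, outside the
#' absorber.
#'
#' @param z_D axial detector position (cm), strictly negative.
#' @param x_D lateral offset from the beam axis (cm). Default 0 (on-axis).
#' @return an object of class `oa_detection`.
#' @export
oa_detection <- function(z_D, x_D = 0) {
  stopifnot(is.numeric(z_D), length(z_D) == 1, is.numeric(x_D),
            length(x_D) == 1)
  if (z_D >= 0) stop("z_D must be negative (detector outside the absorber)")
  structure(list(x_D = x_D, z_D = z_D), class = "oa_detection")
}

#' @export
print.oa_detection <- function(x, ...) {
  cat("Detection point: x_D = ", format(x$x_D), " cm, z_D = ",
      format(x$z_D), " cm\n", sep = "")
  invisible(x)
}

#' Source amplitude constant
#'
#' Single effective constant standing for the product of fluence, Grueneisen
#' parameter and inverse sound speed that scales the pressure amplitude.
#' Signals are reported in arbitrary units; the conventional choice sets the
#' constant to \eqn{4\pi} so it cancels the Poisson-integral prefactor.
#'
#' @param prefactor positive dimensionless scale. Default `4 * pi`.
#' @return an object of class `oa_const`.
#' @export
oa_const <- function(prefactor = 4 * pi) {
  stopifnot(is.numeric(prefactor), length(prefactor) == 1)
  if (prefactor <= 0) stop("prefactor must be positive")
  structure(list(prefactor = prefactor), class = "oa_const")
}

#' Volumetric energy density W at a point
#'
#' The deposited energy density factorizes into the lateral beam profile and
#' the Beer-Lambert depth profile, \eqn{W \propto f(x, y)\,g(z)} with
#' \eqn{f(x,y) = f_I(\sqrt{x^2+y^2})}. The amplitude constant is applied once
#' in the solvers, not here.
#'
#' @param stack an [oa_stack()].
#' @param beam an [oa_beam()].
#' @param x,y lateral coordinates (cm).
#' @param z depth(s) below the surface (cm), non-negative.
#' @return energy density in cm^-1 (arbitrary-units convention).
#' @export
volumetric_energy <- function(stack, beam, x, y, z) {
  beam_profile(beam, sqrt(x^2 + y^2)) * depth_profile_g(stack, z)
}

#' Acoustic diffraction parameter and near-/far-field regime
#'
#' The dimensionless diffraction parameter
#' \deqn{D = 2 |z_D| / (\mu\, a_0^2)}
#' with effective absorption \eqn{\mu = \langle\mu_a(z)\rangle} (thickness-
#' weighted mean over the absorbing layers only) and effective beam radius
#' \eqn{a_0 = 1.25\,a}. \eqn{D < 1} marks the acoustic near field (signals
#' trace the axial absorption profile), \eqn{D > 1} the far field
#' (derivative-like trains of compression peaks and rarefaction dips).
#'
#' @inheritParams volumetric_energy
#' @param z_D axial detector position(s) (cm), negative.
#' @return a `data.frame` with columns `z_D`, `D` and `regime`
#'   (`"NF"`/`"FF"`); a single-row result for scalar `z_D`.
#' @examples
#' st <- oa_stack(data.frame(z_start = c(0, 0.05), z_end = c(0.05, 0.1),
#'                           mu_a = c(10, 20)))
#' diffraction_parameter(st, oa_beam(0.15, 0.15 / 4), c(-0.04, -4))
#' @export
diffraction_parameter <- function(stack, beam, z_D) {
  stopifnot(inherits(stack, "oa_stack"), inherits(beam, "oa_beam"))
  if (any(z_D >= 0)) stop("z_D must be negative")
  abs_layers <- stack$layers[stack$layers$mu_a > 0, ]
  if (nrow(abs_layers) == 0)
    stop("diffraction parameter undefined: stack has no absorbing layer")
  thick <- abs_layers$z_end - abs_layers$z_start
  mu <- sum(abs_layers$mu_a * thick) / sum(thick)
  a0 <- 1.25 * beam$a
  D <- 2 * abs(z_D) / (mu * a0^2)
  data.frame(z_D = z_D, D = D, regime = ifelse(D < 1, "NF", "FF"))
}
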