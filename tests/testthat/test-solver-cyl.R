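test_that("azimuthal weights: on-axis closed form, constant beam, remote ring", {
  g <- small_cyl_grid(N_rho = 200, N_phi = 180)
  b <- fig_beam()
  w <- azimuthal_weights(b, 0, g)
  # closed form 2 pi rho f_I(rho), exactly 2 pi rho on the flat top
  i <- which.min(abs(w$rho - 0.1))
  expect_equal(w$F_D[i], 2 * pi * w$rho[i])
  expect_equal(w$F_D, 2 * pi * w$rho * beam_profile(b, w$rho))
  # constant beam: azimuthal sum of a constant is 2 pi rho for any offset
  wide <- oa_beam(a = 10, d = 1)
  w2 <- azimuthal_weights(wide, 0.2, g)
  expect_equal(w2$F_D, 2 * pi * w2$rho, tolerance = 1e-12)
  # rings entirely outside the beam support carry no weight
  w3 <- azimuthal_weights(oa_beam(0.01, 0.005), 0.25, g)
  expect_true(all(w3$F_D[w3$rho < 0.15] < 1e-10))
  expect_true(all(w3$F_D >= 0))
})

test_that("on-axis shortcut matches the explicit azimuthal sum as N_phi grows", {
  b <- fig_beam()
  ref <- azimuthal_weights(b, 0, small_cyl_grid(N_rho = 100))
  err <- vapply(c(90, 360), function(nphi) {
    g <- small_cyl_grid(N_rho = 100, N_phi = nphi)
    # vanishing offset forces the explicit-sum path
    w <- azimuthal_weights(b, 1e-13, g)
    max(abs(w$F_D - ref$F_D) / max(ref$F_D))
  }, numeric(1))
  expect_lt(err[2], 1e-6)
  expect_lte(err[2], err[1])
})

test_that("shell binning conserves the volume integral and respects semantics", {
  st <- oa_stack(data.frame(z_start = 0, z_end = 0.06, mu_a = 8), L_z = 0.06)
  beam <- oa_beam(0.05, 0.02)
  det <- oa_detection(-0.5)
  cst <- oa_const()
  g <- oa_grid_cyl(L_rho = 0.15, N_rho = 300, N_phi = 90,
                   L_z = 0.06, N_z = 60)
  q <- bin_shell_contributions(azimuthal_weights(beam, 0, g),
                               st, cst, det, g)
  oracle <- brute_volume_integral(st, beam, det, cst,
                                  L_x = 0.3, L_y = 0.3, L_z = 0.06,
                                  N_x = 240, N_y = 240, N_z = 60)
  expect_equal(sum(q$q), oracle, tolerance = 0.01)

  # zero absorption -> identically zero binned record
  clear <- oa_stack(data.frame(z_start = 0, z_end = 0.06, mu_a = 0),
                    L_z = 0.06)
  q0 <- bin_shell_contributions(azimuthal_weights(beam, 0, g),
                                clear, cst, det, g)
  expect_true(all(q0$q == 0))

  # absorber confined within one spherical shell -> exactly one nonzero bin
  thin <- oa_stack(data.frame(z_start = 0.0301, z_end = 0.0305, mu_a = 5),
                   L_z = 0.06)
  narrow <- oa_beam(0.001, 0.0005)
  gn <- oa_grid_cyl(L_rho = 0.01, N_rho = 50, N_phi = 90,
                    L_z = 0.06, N_z = 600)
  qt <- bin_shell_contributions(azimuthal_weights(narrow, 0, gn),
                                thin, cst, det, gn, bin_width = 0.002)
  expect_equal(sum(qt$q > 0), 1)

  # requested coverage that misses the source range is an error
  expect_error(bin_shell_contributions(azimuthal_weights(beam, 0, g),
                                       st, cst, det, g,
                                       ct_range = c(0.5, 0.52)),
               "does not cover")
})

test_that("temporal derivative is second-order accurate against closed form", {
  mk <- function(bw) {
    ct <- (seq_len(round(1 / bw)) - 0.5) * bw
    structure(list(ct = ct, q = sin(6 * ct) * bw, bin_width = bw,
                   detection = oa_detection(-1), r_min = 0, r_max = 1),
              class = "oa_binned")
  }
  err <- vapply(c(0.01, 0.005), function(bw) {
    p <- temporal_derivative(mk(bw))
    n <- length(p$p)
    max(abs(p$p[2:(n - 1)] - 6 * cos(6 * p$ct[2:(n - 1)])))
  }, numeric(1))
  expect_lt(err[1], 1.2 * 6^3 / 6 * 0.01^2)   # |f'''| dct^2 / 6 bound
  expect_gt(err[1] / err[2], 3.5)      # halving the bin ~quarters the error

  # constant record differentiates to zero, linear ramp to a constant
  cst <- mk(0.01); cst$q[] <- 0.3
  expect_true(all(abs(temporal_derivative(cst)$p) < 1e-12))
  ramp <- mk(0.01); ramp$q <- ramp$ct * 0.01
  expect_equal(temporal_derivative(ramp)$p,
               rep(1, length(ramp$q)), tolerance = 1e-9)
  short <- mk(0.01); short$q <- short$q[1:2]; short$ct <- short$ct[1:2]
  expect_error(temporal_derivative(short), "at least 3")
})

test_that("solved signals are causal and linear in the source constant", {
  st <- two_layer_stack()
  b <- fig_beam()
  g <- small_cyl_grid()
  for (zd in c(-0.04, -2)) {
    det <- oa_detection(zd)
    sig <- oa_solve(st, b, det, grid = g)
    # zero before the earliest arrival, up to the smoothing support
    lead <- sig$ct < abs(zd) - 5 * sig$bin_width
    expect_true(any(lead))
    expect_true(all(sig$p[lead] == 0))
    expect_gt(max(abs(sig$p)), 0)
  }
  det <- oa_detection(-2)
  s1 <- oa_solve(st, b, det, grid = g, const = oa_const(4 * pi))
  s2 <- oa_solve(st, b, det, grid = g, const = oa_const(8 * pi))
  expect_equal(s2$p, 2 * s1$p)
})

test_that("wall time grows about linearly in the radial resolution", {
  st <- two_layer_stack()
  b <- fig_beam()
  det <- oa_detection(-4)
  t_for <- function(n) {
    g <- small_cyl_grid(N_rho = n)
    # median of 3 to tame scheduler noise
    stats::median(vapply(1:3, function(i)
      system.time(oa_solve(st, b, det, grid = g))[["elapsed"]], numeric(1)))
  }
  t1 <- t_for(1000); t8 <- t_for(8000)
  # 8x radial work should cost clearly less than a quadratic blow-up
  expect_lt(t8 / max(t1, 0.005), 40)
})

test_that("far-field shell mass decays as 1/|z_D| (spherical spreading)", {
  st <- two_layer_stack()
  b <- fig_beam()
  g <- small_cyl_grid()
  w <- azimuthal_weights(b, 0, g)
  m2 <- sum(bin_shell_contributions(w, st, oa_const(),
                                    oa_detection(-2), g)$q)
  m4 <- sum(bin_shell_contributions(w, st, oa_const(),
                                    oa_detection(-4), g)$q)
  expect_equal(m2 / m4, 2, tolerance = 0.1)
})
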