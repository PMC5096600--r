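test_that("presets carry the printed scenario parameters", {
  p2 <- oa_preset("PII")
  # detector-relative 0.408-0.504 cm at z_D = -0.3 -> surface-relative
  expect_equal(p2$stack$layers$z_start[2], 0.408 - 0.3)
  expect_equal(p2$stack$layers$z_end[2], 0.504 - 0.3)
  expect_equal(p2$stack$layers$mu_a, c(1.4, 11))
  expect_equal(p2$beam$a, 0.056)
  expect_equal(p2$beam$R, 1.2)
  p1 <- oa_preset("PI")
  expect_equal(p1$stack$layers$mu_a, 11)
  expect_equal(p1$beam$R, 1.5)
  expect_equal(p1$detections[[1]]$z_D, -0.3)
  a <- oa_preset("fig3a"); b <- oa_preset("fig3b")
  expect_equal(b$stack$layers$mu_a, rev(a$stack$layers$mu_a))
  expect_equal(b$stack$layers[c("z_start", "z_end")],
               a$stack$layers[c("z_start", "z_end")])
  expect_error(oa_preset("nope"), "fig3a")
})

test_that("scenario JSON round trip is lossless", {
  path <- withr::local_tempfile(fileext = ".json")
  for (name in c("fig3a", "PI", "fig4")) {
    sc <- oa_preset(name)
    write_scenario(sc, path)
    back <- read_scenario(path)
    expect_equal(back, sc)
  }
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "x"), bad, auto_unbox = TRUE)
  expect_error(read_scenario(bad), "missing key")
})

test_that("feature extraction finds ordered peaks and dips", {
  mk <- function(p) {
    s <- oasim:::new_oa_signal(ct = (seq_along(p) - 0.5) * 1e-3 + 0.3,
                               p = p, detection = oa_detection(-0.3),
                               bin_width = 1e-3)
    to_retarded_depth(s)
  }
  expect_equal(nrow(extract_features(mk(rep(0, 50)))), 0)
  # synthetic N-shape: one compression peak then one rarefaction dip
  x <- seq(-3, 3, length.out = 201)
  nshape <- -x * exp(-x^2)
  f <- extract_features(mk(nshape))
  expect_equal(f$kind, c("compression_peak", "rarefaction_dip"))
  expect_true(all(diff(f$ctau) > 0))
  expect_gt(f$amplitude[1], 0)
  expect_lt(f$amplitude[2], 0)
  # prominence threshold suppresses small wiggles
  wig <- nshape + 0.02 * sin(40 * x)
  expect_equal(nrow(extract_features(mk(wig), min_prominence = 0.2)), 2)
})

test_that("signal CSV round trip preserves data and metadata", {
  st <- two_layer_stack()
  sig <- to_retarded_depth(oa_solve(st, fig_beam(), oa_detection(-2),
                                    grid = small_cyl_grid(N_rho = 300)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, path)
  back <- read_signal_csv(path)
  expect_equal(back$p, sig$p)
  expect_equal(back$ct, sig$ct)
  expect_equal(back$ctau, sig$ctau)
  expect_equal(back$detection$z_D, -2)
})

test_that("CLI subcommands reproduce library results and validate input", {
  out <- withr::local_tempfile(fileext = ".csv")
  cfg <- withr::local_tempfile(fileext = ".json")
  # simulate on a config with a desk-scale grid
  sc <- oa_preset("fig3a")
  sc$grid <- small_cyl_grid(N_rho = 300)
  write_scenario(sc, cfg)
  expect_equal(suppressMessages(
    oa_cli(c("simulate", "--config", cfg, "--detection", "2",
             "--out", out))), 0L)
  got <- read_signal_csv(out)
  want <- simulate_scenario(sc, detection = 2)
  expect_equal(got$p, want$p)
  # causality-consistent leading zeros in the written record
  expect_true(all(got$p[got$ct < 4 - 5e-3] == 0))

  feat_out <- withr::local_tempfile(fileext = ".csv")
  expect_equal(suppressMessages(
    oa_cli(c("features", "--signal", out, "--out", feat_out))), 0L)
  expect_equal(utils::read.csv(feat_out)$ctau,
               extract_features(want)$ctau)

  sweep_out <- withr::local_tempfile(fileext = ".csv")
  sc3 <- oa_preset("PIII")
  sc3$grid <- oa_grid_cyl(L_rho = 0.3, N_rho = 400, N_phi = 90,
                          L_z = 0.3, N_z = 300)
  write_scenario(sc3, cfg)
  expect_equal(suppressMessages(
    oa_cli(c("sweep-mse", "--config", cfg, "--zd-start", "-0.5",
             "--zd-stop", "-2", "--n", "3", "--out", sweep_out))), 0L)
  tab <- utils::read.csv(sweep_out)
  lib <- mse_sweep(sc3$stack, sc3$beam, seq(-0.5, -2, length.out = 3),
                   grid = sc3$grid)
  expect_equal(tab$mse, lib$mse)

  # usage errors: missing --out, unknown subcommand
  expect_equal(suppressMessages(oa_cli(c("simulate", "--preset", "fig3a"))),
               2L)
  expect_equal(suppressMessages(oa_cli("frobnicate")), 2L)
})
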