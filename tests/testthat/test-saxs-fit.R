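make_chain_curve <- function(relative_sd = 0, seed = 1) {
  pre <- saxs_preset("dilute_0.1wt")
  make_saxs_curve(pre$model, pre$form_params, q = pre$q,
                  relative_sd = relative_sd, seed = seed,
                  concentration = pre$concentration)
}

test_that("noise-free self-fit recovers the generating chain parameters", {
  cur0 <- make_chain_curve(0)
  cur <- saxs_curve(cur0$q, cur0$intensity, sigma = 0.01 * cur0$intensity)
  f <- fit_saxs(cur, saxs_model("gaussian_chain"),
                gaussian_chain_params(rg = 2.5, i0 = 0.004), n_starts = 4)
  expect_true(f$converged)
  expect_lt(abs(coef(f)[["rg"]] - 1.6) / 1.6, 1e-3)
  expect_lt(abs(coef(f)[["i0"]] - 0.0025) / 0.0025, 1e-3)
  expect_lt(f$chi2_reduced, 1e-6)
})

test_that("fitting is deterministic for a fixed seed", {
  cur <- make_chain_curve(0.02, seed = 3)
  f1 <- fit_saxs(cur, saxs_model("gaussian_chain"),
                 gaussian_chain_params(2.5, 0.004), n_starts = 6, seed = 77)
  f2 <- fit_saxs(cur, saxs_model("gaussian_chain"),
                 gaussian_chain_params(2.5, 0.004), n_starts = 6, seed = 77)
  expect_identical(coef(f1), coef(f2))
})

test_that("charged-micelle curve fit recovers the generating effective charge", {
  pre <- saxs_preset("aged_1wt")
  pre$structure_params$z_eff <- 9.81   # the 0.5 wt% charge state
  cur <- make_saxs_curve(pre$model, pre$form_params, pre$structure_params,
                         q = pre$q, relative_sd = 0.02, seed = 21,
                         concentration = 0.005)
  fp0 <- core_shell_params(1.5 * 1.05, 2.45 * 1.05, rho_core = 0.291,
                           rho_shell = 0.40)
  sp0 <- hayter_penfold_params(2.45 * 1.05, 0.0117 * 1.1, 9.81 * 0.9)
  m0 <- saxs_model("core_shell", "hayter_penfold", scale = 0.39 * 1.1)
  f <- fit_saxs(cur, m0, fp0, sp0, n_starts = 1, tie_hs_radius = TRUE,
                lower = c(volume_fraction = 0.005, z_eff = 4,
                          core_radius = 1, shell_thickness = 0.5,
                          scale = 0.1),
                upper = c(volume_fraction = 0.05, z_eff = 20,
                          core_radius = 2, shell_thickness = 1.5,
                          scale = 1))
  expect_lt(abs(coef(f)[["z_eff"]] - 9.81) / 9.81, 0.10)
})

test_that("fit object methods are coherent", {
  cur <- make_chain_curve(0.02, seed = 5)
  f <- fit_saxs(cur, saxs_model("gaussian_chain"),
                gaussian_chain_params(2.5, 0.004), n_starts = 2)
  expect_s3_class(f, "saxs_fit")
  expect_named(coef(f), c("rg", "i0"))
  expect_equal(length(fitted(f)), nrow(cur))
  expect_equal(fitted(f), predict(f, cur$q))
  expect_equal(residuals(f, "raw"), cur$intensity - fitted(f))
  expect_equal(dim(vcov(f)), c(2L, 2L))
  expect_true(all(f$se >= 0))
  sims <- simulate(f, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "saxs_curve")
  s1 <- simulate(f, nsim = 1, seed = 9)[[1]]
  expect_identical(s1$intensity, sims[[1]]$intensity)
  out <- capture.output({print(f); print(summary(f))})
  expect_true(any(grepl("chi2", out)))
})

test_that("structure-factor comparison favours the generating charged model", {
  pre <- saxs_preset("aged_1wt")
  cur <- make_saxs_curve(pre$model, pre$form_params, pre$structure_params,
                         q = micellar:::default_qgrid(100, 0.05, 3),
                         relative_sd = 0.02, seed = 31)
  cmp <- compare_structure_factors(
    cur, core_shell_params(1.55, 2.5, rho_core = 0.291, rho_shell = 0.40),
    hayter_penfold_params(2.5, 0.013, 9.5), n_starts = 2,
    tie_hs_radius = TRUE,
    lower = c(volume_fraction = 0.005, z_eff = 4, core_radius = 1,
              shell_thickness = 0.5, scale = 0.1),
    upper = c(volume_fraction = 0.05, z_eff = 20, core_radius = 2,
              shell_thickness = 1.5, scale = 1))
  expect_false(cmp$peakless)
  expect_lte(cmp$fit_hp$chi2_reduced, cmp$fit_py$chi2_reduced)
})

test_that("a flat featureless curve is flagged peakless", {
  q <- micellar:::default_qgrid(60, 0.05, 3)
  flat <- saxs_curve(q, rep(0.1, 60), sigma = rep(0.002, 60))
  cmp <- tryCatch(suppressWarnings(compare_structure_factors(
    flat, core_shell_params(1.5, 2.45), hayter_penfold_params(2.45, 0.01, 10),
    n_starts = 1)), error = function(e) e)
  if (!inherits(cmp, "error")) expect_true(cmp$peakless)
})

test_that("input validation: short curves and NaN intensities are rejected", {
  expect_error(fit_saxs(saxs_curve(1:5 / 10, rep(1, 5)),
                        saxs_model("gaussian_chain"),
                        gaussian_chain_params(1, 1)), "10")
  expect_error(saxs_curve(1:20 / 10, c(NaN, rep(1, 19))), "finite")
})
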