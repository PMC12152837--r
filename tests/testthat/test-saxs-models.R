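test_that("sphere form factor: normalization, first zero, closed form", {
  q <- c(1e-6, 0.5, 2, 4.4934094579, 10)
  P <- sphere_form_factor(q, sphere_params(radius = 1))
  expect_equal(P[1], 1, tolerance = 1e-10)
  ## closed-form value at qR = 2, frozen from direct high-precision
  ## evaluation of (3 (sin x - x cos x)/x^3)^2 at x = 2
  expect_equal(P[3], (3 * (sin(2) - 2 * cos(2)) / 8)^2, tolerance = 1e-12)
  ## first zero of the amplitude: root of 3(sin x - x cos x)/x^3
  x0 <- uniroot(function(x) 3 * (sin(x) - x * cos(x)) / x^3,
                c(4, 5), tol = 1e-12)$root
  expect_equal(x0, 4.4934094579, tolerance = 1e-8)
  expect_lt(P[4], 1e-15)
  expect_true(all(P >= 0 & P <= 1))
  expect_error(sphere_form_factor(q, sphere_params(-1)), "positive")
})

test_that("core-shell amplitude reduces to homogeneous spheres in the degenerate limits", {
  q <- exp(seq(log(0.05), log(10), length.out = 80))
  ## rho_core = rho_shell: homogeneous sphere of the outer radius
  p1 <- core_shell_params(1.5, 2.45, rho_core = 0.4, rho_shell = 0.4,
                          rho_solvent = 0.333)
  expect_lt(max(abs(core_shell_form_factor(q, p1) -
                    sphere_form_factor(q, sphere_params(2.45)))), 1e-12)
  ## rho_shell = rho_solvent: invisible shell, sphere of the core radius
  p2 <- core_shell_params(1.5, 2.45, rho_core = 0.291, rho_shell = 0.333,
                          rho_solvent = 0.333)
  expect_lt(max(abs(core_shell_form_factor(q, p2) -
                    sphere_form_factor(q, sphere_params(1.5)))), 1e-12)
  expect_error(core_shell_params(2.5, 1.5), "smaller")
})

test_that("core-shell amplitude matches radial quadrature of the density profile", {
  q <- exp(seq(log(0.05), log(8), length.out = 40))
  p <- core_shell_params(1.5, 2.45, rho_core = 0.291, rho_shell = 0.40,
                         rho_solvent = 0.333)
  F_impl <- core_shell_amplitude(q, p)
  F_quad <- core_shell_quadrature(q, p)
  expect_lt(max(abs(F_impl - F_quad) / max(abs(F_quad))), 1e-8)
})

test_that("Gaussian-chain intensity follows the Debye function", {
  p <- gaussian_chain_params(rg = 1.6, i0 = 0.0025)
  ## q -> 0 limit
  expect_equal(gaussian_chain_intensity(1e-8, p), 0.0025, tolerance = 1e-10)
  ## x = (q Rg)^2 = 1: D(1) = 2/e
  q1 <- 1 / 1.6
  expect_equal(gaussian_chain_intensity(q1, p), 0.0025 * 2 * exp(-1),
               tolerance = 1e-10)
  ## large-x asymptote D ~ 2/x
  q2 <- 10 / 1.6
  expect_equal(gaussian_chain_intensity(q2, p), 0.0025 * 2 / 100,
               tolerance = 0.025)
})

test_that("power law: exact slope, homogeneity, constant limit", {
  q <- exp(seq(log(0.02), log(2), length.out = 60))
  I <- power_law_intensity(q, power_law_params(1e-3, 2.6))
  slope <- coef(lm(log(I) ~ log(q)))[[2]]
  expect_equal(slope, -2.6, tolerance = 1e-10)
  expect_equal(power_law_intensity(c(0.1, 1), power_law_params(2, 0)),
               c(2, 2))
  I1 <- power_law_intensity(c(0.2, 0.4), power_law_params(1, 1))
  expect_equal(I1[1] / I1[2], 2, tolerance = 1e-12)
})

test_that("Percus-Yevick structure factor limits", {
  q <- exp(seq(log(0.01), log(10), length.out = 100))
  ## ideal gas
  expect_lt(max(abs(hard_sphere_py_sf(q, 2.45, 1e-9) - 1)), 1e-6)
  ## compressibility limit (1-phi)^4/(1+2phi)^2, evaluated in-test
  S <- hard_sphere_py_sf(1e-6, 2.45, 0.2)
  expect_equal(S, 0.8^4 / 1.4^2, tolerance = 1e-6)
  ## S > 0 and -> 1 at large q
  S2 <- hard_sphere_py_sf(q, 2.45, 0.3)
  expect_true(all(S2 > 0))
  expect_equal(hard_sphere_py_sf(200, 2.45, 0.3), 1, tolerance = 1e-3)
  expect_error(hard_sphere_py_sf(q, 2.45, 0.8), "0.74")
})

test_that("form factors are nonnegative and even in q", {
  q <- exp(seq(log(0.01), log(20), length.out = 120))
  forms <- list(
    sphere_form_factor(q, sphere_params(2)),
    core_shell_form_factor(q, core_shell_params(1.5, 2.45)),
    gaussian_chain_intensity(q, gaussian_chain_params(1.6, 1)),
    power_law_intensity(q, power_law_params(1, 2.6)))
  for (P in forms) expect_true(all(P >= 0))
  ## evenness: evaluate the sphere kernel at +-x symmetric arguments
  k2 <- micellar:::sphere_kernel(c(-2, 2))^2
  expect_equal(k2[1], k2[2])
})

test_that("combined intensity: composition rules and interference peak placement", {
  q <- micellar:::default_qgrid(150, 0.05, 5)
  fp <- core_shell_params(1.5, 2.45)
  ## no structure factor: scale * P + background
  m0 <- saxs_model("core_shell", scale = 2, background = 0.01)
  expect_equal(combined_intensity(q, m0, fp),
               2 * core_shell_form_factor(q, fp) + 0.01, tolerance = 1e-12)
  ## monodisperse: product and decoupling modes coincide
  sp <- hayter_penfold_params(2.45, 0.0117, 10.8)
  mp <- saxs_model("core_shell", "hayter_penfold", scale = 0.39)
  md <- saxs_model("core_shell", "hayter_penfold", scale = 0.39,
                   combination_mode = "decoupling")
  expect_lt(max(abs(combined_intensity(q, mp, fp, sp) -
                    combined_intensity(q, md, fp, sp))), 1e-12)
  ## the 1 wt% parameter set shows its interference maximum at 0.4-0.5 nm^-1
  S <- hayter_penfold_sf(q, sp)
  q_peak <- q[which.max(S)]
  expect_gt(q_peak, 0.4)
  expect_lt(q_peak, 0.5)
  ## structure factors reject chain-like forms
  expect_error(saxs_model("gaussian_chain", "hayter_penfold"),
               "cannot be combined")
  ## I -> background at high q for compact particles (qR_o = 50)
  mb <- saxs_model("core_shell", scale = 1, background = 0.005)
  I_hi <- combined_intensity(50 / 2.45, mb, fp)
  expect_equal(I_hi, 0.005, tolerance = 0.01 * 0.005)
})
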