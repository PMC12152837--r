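test_that("Tanford chain volume is the exact linear formula", {
  expect_equal(tanford_volume(0), 27.4)
  expect_equal(tanford_volume(1), 54.3)
  expect_equal(tanford_volume(17), 27.4 + 26.9 * 17)  # = 484.7
  expect_error(tanford_volume(-1), ">= 0")
  ## exact linearity
  n <- 0:20
  expect_equal(diff(tanford_volume(n)), rep(26.9, 20))
})

test_that("tail electron density is the exact ratio", {
  expect_equal(round(tail_electron_density(142, 487.4), 3), 0.291)
  expect_equal(tail_electron_density(1, 1), 1)
  expect_equal(round(tail_electron_density(142, 484.7), 3), 0.293)
  expect_error(tail_electron_density(142, 0), "> 0")
})

test_that("molar mass from forward scattering matches a from-scratch evaluation", {
  ci <- contrast_inputs(i0 = 0.0025, c_mic = 0.001, v_p = 1.17,
                        rho_l = 0.291, rho_0 = 0.333)
  m <- micelle_molar_mass(ci)
  ## independent hand evaluation of M = I0 NA / (c [r0 vp drho]^2)
  oracle <- 0.0025 * 6.02214076e23 /
    (0.001 * (0.28179e-12 * 1.17 * (0.291 - 0.333) * 1e24)^2)
  expect_equal(m$m_mic, oracle, tolerance = 1e-12)
  ## linearity in I0 and inverse-square contrast
  ci2 <- contrast_inputs(0.005, 0.001, 1.17, 0.291, 0.333)
  expect_equal(micelle_molar_mass(ci2)$m_mic, 2 * m$m_mic,
               tolerance = 1e-12)
  ci3 <- contrast_inputs(0.0025, 0.001, 1.17, 0.312, 0.333)  # half contrast
  expect_equal(micelle_molar_mass(ci3)$m_mic, 4 * m$m_mic,
               tolerance = 1e-12)
  expect_error(micelle_molar_mass(contrast_inputs(1, 1, 1, 0.333, 0.333)),
               "contrast")
})

test_that("association number is the plain mass ratio", {
  expect_equal(association_number(9111, 4113.6), 9111 / 4113.6) # ~2.215
  expect_equal(round(association_number(9111, 4113.6), 1), 2.2)
  expect_equal(association_number(4113.6, 4113.6), 1)
  expect_equal(association_number(123432, 4113.6), 30.00584,
               tolerance = 1e-6)
  expect_error(association_number(100, 0), "> 0")
})

test_that("low-q intensity-ratio estimate scales the reference association number", {
  q <- micellar:::default_qgrid(100, 0.01, 2)
  lo <- make_saxs_curve(saxs_model("gaussian_chain"),
                        gaussian_chain_params(1.6, 0.0025), q = q,
                        relative_sd = 0, concentration = 0.001)
  ## identical curves at equal concentration return p_ref
  expect_equal(ratio_association_estimate(lo, lo, q_probe = 0.01,
                                          p_ref = 2.2)$p_estimate, 2.2)
  ## normalized ratio of 6 gives 6 * 2.2 = 13.2 (inside the 12-15 band)
  hi6 <- saxs_curve(q, 6 * 10 * lo$intensity, concentration = 0.01)
  r6 <- ratio_association_estimate(hi6, lo, q_probe = 0.01, p_ref = 2.2)
  expect_equal(r6$p_estimate, 13.2, tolerance = 1e-10)
  ## synthetic pair generated with a true mass ratio of 5 (no structure
  ## factor): forward intensity per concentration scales with p
  hi <- make_saxs_curve(saxs_model("gaussian_chain"),
                        gaussian_chain_params(2.2, 0.0025 * 5 * 10),
                        q = q, relative_sd = 0.02, seed = 6,
                        concentration = 0.01)
  r <- ratio_association_estimate(hi, lo, q_probe = 0.01, p_ref = 2.2)
  expect_lt(abs(r$p_estimate - 11) / 11, 0.10)
  expect_error(ratio_association_estimate(saxs_curve(q, lo$intensity), lo),
               "concentration")
})

test_that("structure-factor peak in the concentrated curve raises the caveat flag", {
  pre <- saxs_preset("aged_1wt")
  hi <- make_saxs_curve(pre$model, pre$form_params, pre$structure_params,
                        q = pre$q, relative_sd = 0.01, seed = 2,
                        concentration = 0.01)
  lo <- make_saxs_curve(saxs_model("gaussian_chain"),
                        gaussian_chain_params(1.6, 0.0025), q = pre$q,
                        relative_sd = 0.01, seed = 3,
                        concentration = 0.001)
  r <- ratio_association_estimate(hi, lo, q_probe = 0.06)
  expect_true(r$structure_factor_warning)
  expect_false(ratio_association_estimate(lo, lo,
                                          q_probe = 0.06)$structure_factor_warning)
})

test_that("full dilute pipeline recovers the generating association number", {
  ## Eq-1 scaling: generate a dilute curve whose I(0) corresponds to a
  ## known association number, then run I(0) -> molar mass -> p
  p_true <- 3
  m_mol <- 4113.6
  drho <- (0.291 - 0.333) * 1e24
  i0_true <- 0.001 * (p_true * m_mol) *
    (0.28179e-12 * 1.17 * drho)^2 / 6.02214076e23
  cur <- make_saxs_curve(saxs_model("gaussian_chain"),
                         gaussian_chain_params(1.9, i0_true),
                         q = micellar:::default_qgrid(120, 0.05, 3),
                         relative_sd = 0.02, seed = 14,
                         concentration = 0.001)
  i0_est <- forward_intensity(cur, "guinier")$i0
  m_est <- micelle_molar_mass(contrast_inputs(i0_est, 0.001, 1.17,
                                              0.291, 0.333))
  p_est <- association_number(m_est$m_mic, m_mol)
  expect_lt(abs(p_est - p_true) / p_true, 0.15)
})
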