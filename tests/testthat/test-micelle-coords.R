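test_that("uniform sphere gives a flat, electron-conserving radial profile", {
  set.seed(101)
  n <- 1e6
  R <- 2
  u <- runif(n)
  r <- R * u^(1 / 3)
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  pos <- cbind(r * sqrt(1 - z^2) * cos(phi), r * sqrt(1 - z^2) * sin(phi),
               r * z)
  cs <- coordinate_set(pos, rep("C", n))
  prof <- radial_electron_density(cs, center = "geometric", bin_width = 0.2)
  rho_true <- 6 * n / ((4 / 3) * pi * R^3 * 1000)   # e/A^3
  inner <- prof$bin_center < 0.8 * R & prof$bin_center > 0.4
  expect_lt(max(abs(prof$electron_density[inner] / rho_true - 1)), 0.02)
  ## zero beyond the sphere radius
  expect_true(all(prof$electron_density[prof$bin_center > R + 0.2] == 0))
  ## exact electron conservation
  vols <- (4 / 3) * pi * diff((0:nrow(prof) * 0.2)^3) * 1000
  expect_lt(abs(sum(prof$electron_density * vols) - 6 * n) / (6 * n), 1e-9)
})

test_that("single atom at the centre puts all electrons in the first bin", {
  cs <- coordinate_set(rbind(c(0, 0, 0), c(0, 0, 0.001)), c("S", "H"))
  prof <- suppressWarnings(radial_electron_density(cs, bin_width = 0.5))
  expect_equal(sum(prof$electron_density > 0), 1L)
  vol1 <- (4 / 3) * pi * 0.5^3 * 1000
  expect_equal(prof$electron_density[1] * vol1, 17)
})

test_that("synthetic micelle core sits at alkane-like electron density", {
  mic <- make_micelle_coordinates(30, seed = 5)
  prof <- radial_electron_density(mic)
  core <- prof$bin_center > 0.4 & prof$bin_center < 1.3
  plateau <- mean(prof$electron_density[core])
  expect_gt(plateau, 0.25)
  expect_lt(plateau, 0.30)
})

test_that("SASA: analytic sphere, additivity, and overlap against the MC oracle", {
  one <- coordinate_set(rbind(c(0, 0, 0)), "C")   # r = 0.17 nm
  a1 <- as.numeric(sasa(one, probe_radius = 0.14, n_points = 960))
  expect_equal(a1, 4 * pi * 0.31^2, tolerance = 0.01 * 4 * pi * 0.31^2)
  two_far <- coordinate_set(rbind(c(0, 0, 0), c(5, 0, 0)), c("C", "C"))
  expect_equal(as.numeric(sasa(two_far)), 2 * a1, tolerance = 1e-10)
  ## overlapping pair vs high-density random-sampling oracle
  two <- coordinate_set(rbind(c(0, 0, 0), c(0.25, 0, 0)), c("C", "C"))
  a2 <- as.numeric(sasa(two))
  expect_lt(abs(a2 - sasa_mc_oracle(two, n = 50000L)) / a2, 0.02)
  expect_error(sasa(one, n_points = 16), ">= 32")
})

test_that("SASA decreases monotonically as two atoms approach", {
  d <- c(1, 0.6, 0.45, 0.3, 0.15, 0.05)
  areas <- vapply(d, function(dd) {
    as.numeric(sasa(coordinate_set(rbind(c(0, 0, 0), c(dd, 0, 0)),
                                   c("C", "C"))))
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("rigid-motion behaviour: exact translation, sampling-level rotation stability", {
  mic <- make_micelle_coordinates(10, seed = 3)
  s0 <- as.numeric(sasa(mic))
  prof0 <- radial_electron_density(mic)
  shifted <- mic; shifted$positions <- sweep(mic$positions, 2, c(3, -2, 7), `+`)
  expect_equal(as.numeric(sasa(shifted)), s0, tolerance = 1e-12)
  Rm <- random_rotation(7)
  rot <- mic; rot$positions <- mic$positions %*% t(Rm)
  expect_equal(radial_electron_density(rot)$electron_density,
               prof0$electron_density, tolerance = 1e-9)
  expect_equal(as.numeric(sasa(rot)), s0, tolerance = 5e-3 * s0)
})

test_that("aggregation propensity: identity, scaling invariance, constructed compaction", {
  mic <- make_micelle_coordinates(30, seed = 5)
  expect_equal(aggregation_propensity(mic, mic), 1)
  ## uniform scaling of lengths (positions, radii, probe) cancels in the ratio
  loose <- make_micelle_coordinates(30, core_radius = 1.9,
                                    shell_thickness = 1.2, seed = 6)
  ap <- aggregation_propensity(loose, mic)
  half_l <- loose; half_l$positions <- loose$positions / 2
  half_l$radii <- loose$radii / 2
  half_m <- mic; half_m$positions <- mic$positions / 2
  half_m$radii <- mic$radii / 2
  expect_equal(aggregation_propensity(half_l, half_m, probe_radius = 0.07),
               ap, tolerance = 1e-10)
  ## the frozen loose-vs-compact construction sits at AP = 1.36 and agrees
  ## with the independent sampling oracle
  expect_equal(ap, 1.36, tolerance = 0.03 / 1.36)
  ap_oracle <- sasa_mc_oracle(loose, n = 4000L) / sasa_mc_oracle(mic, n = 4000L)
  expect_lt(abs(ap - ap_oracle), 0.03)
})

test_that("element normalization handles united atoms and PDB-style names", {
  expect_equal(elements_from_names(c("ch2", "CA", "OD1", "1HB", "na", "Cl")),
               c("CH2", "C", "O", "H", "NA", "CL"))
  expect_error(elements_from_names("Xx"), "unrecognized")
  cs <- coordinate_set(matrix(0, 2, 3) + runif(6), c("CH3", "N"))
  expect_equal(cs$electrons, c(9, 7))
})
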