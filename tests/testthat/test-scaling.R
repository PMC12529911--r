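# Scaling model: presets, coefficients, assembled energies, error surfaces.

test_that("the preset registry reproduces every published coefficient set", {
  expect_equal(unlist(preset_params("mp2")[c("a", "ap", "b", "bp")]),
               c(a = 0, ap = 0, b = 1, bp = 1))
  expect_equal(unlist(preset_params("scs")[c("a", "ap", "b", "bp")]),
               c(a = 0, ap = 0, b = 0.33, bp = 1.2))
  expect_equal(unlist(preset_params("scs-star")[c("a", "ap", "b", "bp")]),
               c(a = 0, ap = 0, b = 0.44, bp = 1.13))
  expect_equal(unlist(preset_params("s2opt")[c("a", "ap", "b", "bp")]),
               c(a = 0, ap = 0, b = 0.623, bp = 1.055))
  expect_equal(unlist(preset_params("cd2")[c("a", "ap", "b", "bp")]),
               c(a = 2.89, ap = 1.38, b = 0, bp = 0))
  expect_equal(unlist(preset_params("cd4")[c("a", "ap", "b", "bp")]),
               c(a = 0, ap = 0.42, b = 0.47, bp = 0.79))
  expect_error(preset_params("nope"), "unknown preset")
})

test_that("coefficients follow the published functional forms", {
  cd4 <- preset_params("cd4")
  expect_equal(scaling_coefficients(cd4, list(r_D = 1, r_ND = 0)),
               c(c_OS = 1.21, c_SS = 0.47))
  expect_equal(scaling_coefficients(cd4, list(r_D = 0, r_ND = 1)),
               c(c_OS = 0.79, c_SS = 0.47))
  cd2 <- preset_params("cd2")
  expect_equal(scaling_coefficients(cd2, list(r_D = 1, r_ND = 0)),
               c(c_OS = 1.38, c_SS = 0))
  expect_equal(scaling_coefficients(cd2, list(r_D = 0, r_ND = 1)),
               c(c_OS = 0, c_SS = 2.89))
  # indices are mandatory for correlation-driven presets
  expect_error(scaling_coefficients(cd2), "configuration error")
  # fixed-coefficient presets need no indices
  expect_equal(scaling_coefficients(preset_params("scs")),
               c(c_OS = 1.2, c_SS = 0.33))
})

test_that("assembled energies reproduce canonical and scaled totals", {
  sp <- species_energies(E_HF = -1.0, E_OS = -0.051, E_SS = -0.004)
  expect_equal(assemble_energy(sp, preset_params("mp2")), -1.055)
  expect_equal(assemble_energy(sp, preset_params("scs")),
               -1.0 + 1.2 * -0.051 + 0.33 * -0.004)
  # 1.2-scaled opposite-spin contribution of -0.051 au is -0.0612 au
  sp2 <- species_energies(E_HF = 0, E_OS = -0.051, E_SS = 0)
  expect_equal(assemble_energy(sp2, preset_params("scs")), -0.0612)
  expect_error(species_energies(0, 0.1, 0), "non-positive")
})

test_that("assembled energy is affine in the four parameters", {
  s <- occupancy_spectrum(c(0.98, 0.3), c(0.98, 0.3))
  sp <- species_energies(-2, -0.3, -0.1, indices = correlation_indices(s))
  th0 <- c(0.1, 0.2, 0.3, 0.4); th1 <- c(1.1, 0.9, 0.2, 1.3)
  e <- function(th) assemble_energy(sp, scaling_params(th[1], th[2], th[3],
                                                       th[4]))
  lam <- 0.37
  expect_equal(e(lam * th0 + (1 - lam) * th1),
               lam * e(th0) + (1 - lam) * e(th1), tolerance = 1e-12)
})

test_that("error surfaces have the analytic affine structure", {
  species <- list(
    A = species_energies(-1.0, -0.10, -0.020),
    B = species_energies(-0.5, -0.04, -0.008),
    C = species_energies(-1.6, -0.13, -0.030))
  rx <- reaction("r1", c(A = -1, B = -1, C = 1), reference_energy = 0)
  surf <- error_surface(rx, species)
  # zero-error line slope equals -(sum nu E_OS)/(sum nu E_SS)
  os <- (-1) * -0.10 + (-1) * -0.04 + 1 * -0.13
  ss <- (-1) * -0.020 + (-1) * -0.008 + 1 * -0.030
  expect_equal(surf$slope, -os / ss, tolerance = 1e-8)
  # a reaction with vanishing same-spin sum is independent of c_SS
  species$C2 <- species_energies(-1.6, -0.13, -0.028)
  rx2 <- reaction("r2", c(A = -1, B = -1, C2 = 1), 0)
  surf2 <- error_surface(rx2, species)
  expect_lt(max(apply(surf2$errors, 1, function(z) diff(range(z)))), 1e-10)
  # a reaction built to be exact at (1.2, 0.33) has its minimum there
  ref <- (surf$hf_kcal + 1.2 * surf$os_kcal + 0.33 * surf$ss_kcal)
  rx3 <- rx; rx3$reference_energy <- ref
  surf3 <- error_surface(rx3, species,
                         c_os_grid = seq(0, 2.5, 0.1),
                         c_ss_grid = seq(0.03, 2.53, 0.1))
  idx <- which(surf3$errors == min(surf3$errors), arr.ind = TRUE)[1, ]
  expect_equal(surf3$c_os[idx[1]], 1.2, tolerance = 1e-9)
  expect_equal(surf3$c_ss[idx[2]], 0.33, tolerance = 1e-9)
  expect_error(error_surface(reaction("x", c(Zed = -1, A = 1), 0), species),
               "lookup error")
})

test_that("fixed-coefficient degeneration matches direct evaluation", {
  set.seed(3)
  sp <- gen_species(10, seed = 5)
  p_fixed <- scaling_params(0, 0, 0.44, 1.13)
  p_named <- preset_params("scs-star")
  for (s in sp)
    expect_equal(assemble_energy(s, p_fixed), assemble_energy(s, p_named),
                 tolerance = 1e-14)
})
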