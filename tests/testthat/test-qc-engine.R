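# Hartree-Fock and the integral layer: closed-form s-Gaussian oracles,
# reference energies, and SCF behaviour.

test_that("s-type integrals match the closed-form Gaussian formulas", {
  # independent oracle: textbook formulas for primitive s Gaussians
  boys0 <- function(t) ifelse(t < 1e-12, 1 - t / 3,
                              0.5 * sqrt(pi / t) *
                                (2 * pnorm(sqrt(2 * t)) - 1))
  s_overlap <- function(a, b, RA, RB) {
    p <- a + b
    (pi / p)^1.5 * exp(-a * b / p * sum((RA - RB)^2))
  }
  s_kinetic <- function(a, b, RA, RB) {
    mu <- a * b / (a + b); r2 <- sum((RA - RB)^2)
    mu * (3 - 2 * mu * r2) * s_overlap(a, b, RA, RB)
  }
  s_nuclear <- function(a, b, RA, RB, RC) {
    p <- a + b
    P <- (a * RA + b * RB) / p
    -2 * pi / p * exp(-a * b / p * sum((RA - RB)^2)) *
      boys0(p * sum((P - RC)^2))
  }
  s_eri <- function(a, b, c, d, RA, RB, RC, RD) {
    p <- a + b; q <- c + d
    P <- (a * RA + b * RB) / p; Q <- (c * RC + d * RD) / q
    2 * pi^2.5 / (p * q * sqrt(p + q)) *
      exp(-a * b / p * sum((RA - RB)^2) - c * d / q * sum((RC - RD)^2)) *
      boys0(p * q / (p + q) * sum((P - Q)^2))
  }
  # one-primitive unnormalized s shells on a skew geometry
  mol <- molecule(c("H", "He"), rbind(c(0.1, -0.2, 0.3), c(0.5, 0.7, -0.4)))
  RA <- mol$coordinates[1, ] / 0.529177210903
  RB <- mol$coordinates[2, ] / 0.529177210903
  a <- 0.8; b <- 1.3
  shells <- list(list(l = 0L, atom = 1L, exponents = a, coefficients = 1),
                 list(l = 0L, atom = 2L, exponents = b, coefficients = 1))
  coords <- rbind(RA, RB)
  one <- cdscs:::md_one_electron(shells, coords, c(1, 2))
  expect_equal(one$S[1, 2], s_overlap(a, b, RA, RB), tolerance = 1e-12)
  expect_equal(one$T[1, 2], s_kinetic(a, b, RA, RB), tolerance = 1e-12)
  expect_equal(one$V[1, 2],
               1 * s_nuclear(a, b, RA, RB, RA) +
                 2 * s_nuclear(a, b, RA, RB, RB), tolerance = 1e-10)
  eri <- cdscs:::md_eri(shells, coords)
  expect_equal(eri[1, 2, 1, 2], s_eri(a, b, a, b, RA, RB, RA, RB),
               tolerance = 1e-10)
  expect_equal(eri[1, 1, 2, 2], s_eri(a, a, b, b, RA, RA, RB, RB),
               tolerance = 1e-10)
})

test_that("RHF reproduces reference energies and electron counts", {
  # H2 at 1.4 bohr / STO-3G: reference restricted HF energy -1.116714 Eh
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0),
                                    c(0, 0, 1.4 * 0.529177210903)))
  scf <- run_rhf(h2, "sto-3g")
  expect_equal(scf$E_HF, -1.116714, tolerance = 2e-6)
  # He atom / STO-3G: reference -2.807784 Eh
  he <- run_rhf(molecule_fixture("He"), "sto-3g")
  expect_equal(he$E_HF, -2.807784, tolerance = 2e-6)
  expect_equal(he$n_occupied, 1)
  # basis dimension: cc-pVTZ on H2 has 28 spherical functions
  expect_equal(n_basis_functions(molecule_fixture("H2"), "cc-pvtz"), 28)
  expect_equal(scf_h2_tz()$n_basis, 28)
})

test_that("SCF solutions are converged, orthonormal and idempotent", {
  scf <- scf_h2o_sto()
  S <- scf$ints$S
  C <- scf$orbital_coefficients
  expect_lt(max(abs(crossprod(C, S %*% C) - diag(scf$n_basis))), 1e-8)
  expect_false(is.unsorted(scf$orbital_energies))
  P <- scf$density
  expect_lt(max(abs(P %*% S %*% P - P)), 1e-7)
})

test_that("open-shell and degenerate inputs are rejected", {
  expect_error(run_rhf(molecule_fixture("H"), "sto-3g"), "unsupported")
  hplus <- molecule("He", matrix(0, 1, 3), charge = 1L, multiplicity = 2L)
  expect_error(run_rhf(hplus, "sto-3g"), "unsupported")
  # He/STO-3G has no virtual orbitals: MP2 must refuse
  he <- run_rhf(molecule_fixture("He"), "sto-3g")
  expect_error(mp2_components(he), "degenerate")
})
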