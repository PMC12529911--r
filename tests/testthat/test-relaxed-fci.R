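# Relaxed (response) MP2 densities and the determinant FCI engine.

test_that("relaxed one-particle density is the exact energy response", {
  set.seed(42)
  for (fix in list(scf_h2_sto(), scf_lih_sto())) {
    scf <- fix
    mp2 <- mp2_components(scf)
    rel <- relaxed_densities(scf, mp2)
    expect_equal(sum(diag(rel$one_rdm$matrix)), 2 * scf$n_occupied,
                 tolerance = 1e-9)
    n <- scf$n_basis
    O_ao <- matrix(rnorm(n * n), n); O_ao <- (O_ao + t(O_ao)) / 20
    ints0 <- scf$ints
    mol <- scf$molecule
    e_tot <- function(lam) {
      ints <- ints0; ints$Hcore <- ints0$Hcore + lam * O_ao
      s <- run_rhf(mol, scf$basis_label, ints = ints,
                   conv_energy = 1e-12, conv_density = 1e-10)
      s$E_HF + mp2_components(s)$E_corr
    }
    h <- 2e-4
    dE <- (e_tot(h) - e_tot(-h)) / (2 * h)
    C <- scf$orbital_coefficients
    O_mo <- crossprod(C, O_ao %*% C)
    expect_equal(sum(rel$one_rdm$matrix * O_mo), dE, tolerance = 1e-6)
  }
})

test_that("relaxed two-particle density reproduces the interaction
           response", {
  scf <- scf_lih_sto()
  mp2 <- mp2_components(scf)
  rel <- relaxed_densities(scf, mp2)
  ints0 <- scf$ints
  e_mu <- function(mu) {
    ints <- ints0; ints$ERI <- ints0$ERI * (1 + mu)
    s <- run_rhf(scf$molecule, scf$basis_label, ints = ints,
                 conv_energy = 1e-12, conv_density = 1e-10)
    s$E_HF + mp2_components(s)$E_corr
  }
  h <- 2e-4
  dE <- (e_mu(h) - e_mu(-h)) / (2 * h)
  expect_equal(vee_from_two_rdm(rel$two_rdm, mp2$moeri)$total, dE,
               tolerance = 1e-6)
})

test_that("zero-correlation limit collapses relaxed densities to HF", {
  # switching off the two-electron interaction forces all amplitudes to
  # zero, so every MP2-derived quantity must collapse to its HF value
  scf0 <- scf_h2_dz()
  ints <- scf0$ints
  ints$ERI[] <- 0
  scf <- run_rhf(scf0$molecule, scf0$basis_label, ints = ints)
  mp2 <- mp2_components(scf)
  expect_equal(mp2$E_corr, 0, tolerance = 1e-14)
  rel <- relaxed_densities(scf, mp2)
  n <- scf$n_basis
  Dhf <- diag(c(rep(2, scf$n_occupied), rep(0, n - scf$n_occupied)))
  expect_equal(rel$one_rdm$matrix, Dhf, tolerance = 1e-10)
  hf <- hf_two_rdm(scf)
  expect_equal(max(abs(rel$two_rdm$aa - hf$aa)), 0, tolerance = 1e-10)
  expect_equal(max(abs(rel$two_rdm$ab - hf$ab)), 0, tolerance = 1e-10)
  spec <- unrelaxed_occupancies(scf, mp2)
  expect_equal(sort(unique(round(spec$alpha, 12))), c(0, 1))
})

test_that("HF and FCI two-particle densities satisfy exact sum rules", {
  scf <- scf_h2_dz()
  n <- scf$n_basis
  Dhf_spin <- diag(c(rep(1, scf$n_occupied), rep(0, n - scf$n_occupied)))
  chk <- two_rdm_check(hf_two_rdm(scf), Dhf_spin, Dhf_spin)
  expect_lt(chk$contraction_defect, 1e-10)
  expect_lt(chk$pair_defect, 1e-10)
  fci <- fci_h2_dz()
  chk2 <- two_rdm_check(fci$two_rdm, fci$one_rdm$alpha, fci$one_rdm$beta)
  expect_lt(chk2$contraction_defect, 1e-8)
  expect_lt(chk2$pair_defect, 1e-8)
})

test_that("FCI matches the 2x2 CI closed form for minimal-basis H2", {
  scf <- scf_h2_sto()
  fci <- fci_solve(scf)
  gm <- mo_eri(scf)
  C <- scf$orbital_coefficients
  h <- crossprod(C, scf$ints$Hcore %*% C)
  H11 <- 2 * h[1, 1] + gm[1, 1, 1, 1]
  H22 <- 2 * h[2, 2] + gm[2, 2, 2, 2]
  H12 <- gm[1, 2, 1, 2]
  e_closed <- min(eigen(matrix(c(H11, H12, H12, H22), 2))$values) +
    scf$ints$enuc
  expect_equal(fci$energy, e_closed, tolerance = 1e-10)
})

test_that("FCI is variational and size-consistent", {
  expect_lt(fci_h2_tz()$energy, scf_h2_tz()$E_HF)
  expect_lt(fci_he2_dz()$energy, scf_he2_dz()$E_HF)
  # He2 at very large separation dissociates into two He atoms
  far <- molecule(c("He", "He"),
                  rbind(c(0, 0, 0), c(0, 0, 100 * 0.529177210903)))
  f2 <- fci_solve(run_rhf(far, "cc-pvdz"), rdm = FALSE)
  f1 <- fci_solve(run_rhf(molecule_fixture("He"), "cc-pvdz"), rdm = FALSE)
  expect_equal(f2$energy, 2 * f1$energy, tolerance = 1e-6)
})

test_that("FCI energy is reproduced by its own densities", {
  fci <- fci_he2_dz()
  scf <- scf_he2_dz()
  C <- scf$orbital_coefficients
  h <- crossprod(C, scf$ints$Hcore %*% C)
  vee <- vee_from_two_rdm(fci$two_rdm, fci$moeri)$total
  e <- sum(fci$one_rdm$matrix * h) + vee + scf$ints$enuc
  expect_equal(e, fci$energy, tolerance = 1e-9)
})

test_that("the electron-count guard rejects larger systems", {
  expect_error(fci_solve(scf_h2o_sto()), "unsupported")
})
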