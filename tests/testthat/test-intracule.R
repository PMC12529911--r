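# Radial intracules, Coulomb holes and their sum rules.  Tests use a
# reduced per-atom grid (see helper) to keep the suite fast; the package
# default grid is finer.

test_that("HF intracule of He integrates to one pair and matches Vee", {
  scf <- scf_he_dz()
  ipd <- intracule(hf_two_rdm(scf), scf, test_grid)
  expect_lt(ipd$pair_defect, 1e-2)
  expect_equal(sum(ipd$values[, "total"] * ipd$weights), 1,
               tolerance = 1e-3)
  # OS channel carries the single pair of the two-electron singlet
  expect_equal(sum(ipd$values[, "OS"] * ipd$weights), 1, tolerance = 1e-3)
  expect_lt(max(abs(ipd$values[, "SS"])), 1e-12)
  vee_alg <- vee_from_two_rdm(hf_two_rdm(scf), mo_eri(scf))$total
  expect_equal(hole_integral(ipd, "total", "inv_r12"), vee_alg,
               tolerance = 2e-3)
})

test_that("two-electron singlets have no same-spin channel at any level", {
  scf <- scf_h2_dz()
  fci <- fci_h2_dz()
  i_hf <- intracule(hf_two_rdm(scf), scf, test_grid)
  i_fci <- intracule(fci$two_rdm, scf, test_grid)
  expect_lt(max(abs(i_hf$values[, "SS"])), 1e-12)
  expect_lt(max(abs(i_fci$values[, "SS"])), 1e-12)
})

test_that("Coulomb holes integrate to zero and are negative at short
           range", {
  scf <- scf_h2_dz()
  fci <- fci_h2_dz()
  i_hf <- intracule(hf_two_rdm(scf), scf, test_grid)
  i_fci <- intracule(fci$two_rdm, scf, test_grid)
  h <- coulomb_hole(i_fci, i_hf)
  expect_lt(abs(hole_integral(h)), 1e-4)
  # depth near the origin: the correlated pair density is depleted at
  # electron coalescence
  short <- hole_integral(h, range = c(0, 1))
  expect_lt(short, 0)
  expect_true(all(h$values[1:10, "total"] <= 1e-6))
  # identical inputs give the zero hole
  h0 <- coulomb_hole(i_hf, i_hf)
  expect_equal(max(abs(h0$values)), 0)
  # grid mismatch is refused
  i_small <- intracule(hf_two_rdm(scf), scf,
                       c(test_grid, list(r_max = 10)))
  expect_error(coulomb_hole(i_fci, i_small), "grids do not match")
})

test_that("the hole energy matches the algebraic Delta Vee", {
  # the 1e-3 au agreement is certified at the package default grid
  scf <- scf_h2_dz()
  fci <- fci_h2_dz()
  i_hf <- intracule(hf_two_rdm(scf), scf)
  i_fci <- intracule(fci$two_rdm, scf)
  h <- coulomb_hole(i_fci, i_hf)
  dv <- delta_vee(fci$two_rdm, hf_two_rdm(scf), fci$moeri)
  expect_lt(abs(hole_energy(h) - dv$total), 1e-3)
  expect_error(delta_vee(fci$two_rdm, hf_two_rdm(scf_h2_sto()), fci$moeri),
               "different bases")
})

test_that("grid refinement reduces the pair-count defect", {
  scf <- scf_he_dz()
  coarse <- intracule(hf_two_rdm(scf), scf,
                      list(n_radial = 14, n_theta = 6, n_phi = 10))
  fine <- intracule(hf_two_rdm(scf), scf,
                    list(n_radial = 30, n_theta = 10, n_phi = 20))
  expect_lt(fine$pair_defect, coarse$pair_defect)
  # an unreasonably coarse grid fails the certification
  expect_error(
    intracule(hf_two_rdm(scf), scf,
              list(n_radial = 4, n_theta = 2, n_phi = 3)),
    "grid too coarse")
})

test_that("He2 opposite-spin hole dominates the same-spin one at short
           range", {
  scf <- scf_he2_dz()
  fci <- fci_he2_dz()
  i_hf <- intracule(hf_two_rdm(scf), scf, test_grid)
  i_fci <- intracule(fci$two_rdm, scf, test_grid)
  h <- coulomb_hole(i_fci, i_hf)
  os_short <- sum(abs(h$values[h$r <= 2, "OS"]) * h$weights[h$r <= 2])
  ss_short <- sum(abs(h$values[h$r <= 2, "SS"]) * h$weights[h$r <= 2])
  expect_gt(os_short, ss_short)
})

test_that("CSV export round-trips the tabulated channels", {
  scf <- scf_he_dz()
  ipd <- intracule(hf_two_rdm(scf), scf, test_grid)
  f <- tempfile(fileext = ".csv")
  write_intracule_csv(ipd, f)
  df <- read.csv(f)
  expect_equal(df$r12_bohr, ipd$r)
  expect_equal(df$OS, unname(ipd$values[, "OS"]))
})
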