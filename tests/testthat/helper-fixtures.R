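# cached engine fixtures shared across test files (computed once per run)
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, fn(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

scf_h2_sto <- function() fixture("scf_h2_sto", function()
  run_rhf(molecule_fixture("H2"), "sto-3g"))
scf_h2_dz <- function() fixture("scf_h2_dz", function()
  run_rhf(molecule_fixture("H2"), "cc-pvdz"))
scf_h2_tz <- function() fixture("scf_h2_tz", function()
  run_rhf(molecule_fixture("H2"), "cc-pvtz"))
scf_he_dz <- function() fixture("scf_he_dz", function()
  run_rhf(molecule_fixture("He"), "cc-pvdz"))
scf_he2_dz <- function() fixture("scf_he2_dz", function()
  run_rhf(molecule_fixture("He2"), "cc-pvdz"))
scf_lih_sto <- function() fixture("scf_lih_sto", function()
  run_rhf(molecule_fixture("LiH"), "sto-3g"))
scf_h2o_sto <- function() fixture("scf_h2o_sto", function()
  run_rhf(molecule_fixture("H2O"), "sto-3g"))

mp2_h2_tz <- function() fixture("mp2_h2_tz", function()
  mp2_components(scf_h2_tz()))
mp2_h2_dz <- function() fixture("mp2_h2_dz", function()
  mp2_components(scf_h2_dz()))
fci_h2_tz <- function() fixture("fci_h2_tz", function()
  fci_solve(scf_h2_tz()))
fci_h2_dz <- function() fixture("fci_h2_dz", function()
  fci_solve(scf_h2_dz()))
fci_he2_dz <- function() fixture("fci_he2_dz", function()
  fci_solve(scf_he2_dz()))
rel_h2_tz <- function() fixture("rel_h2_tz", function()
  relaxed_densities(scf_h2_tz(), mp2_h2_tz()))

# reduced-size grid used in tests (documented problem size; the package
# default is finer)
test_grid <- list(n_radial = 24, n_theta = 8, n_phi = 16)

# independent brute-force WTMAD2: explicit loop over data points
wtmad2_brute <- function(errors, subsets, dEavg, wt = 56.84) {
  labs <- unique(subsets)
  total <- 0; ntot <- 0
  for (lab in labs) {
    sel <- subsets == lab
    n_i <- sum(sel)
    mad_i <- mean(abs(errors[sel]))
    total <- total + n_i * (wt / dEavg[[lab]]) * mad_i
    ntot <- ntot + n_i
  }
  total / ntot
}

# independent spin-orbital MP2 by explicit loops (no vectorization shared
# with the implementation)
mp2_so_loops <- function(scf) {
  C <- scf$orbital_coefficients
  g <- mo_eri(scf)
  eps <- scf$orbital_energies
  n <- scf$n_basis
  nocc <- scf$n_occupied
  so_spin <- rep(c(1, 2), each = n)
  so_sp <- rep(seq_len(n), 2)
  occ_so <- c(seq_len(nocc), n + seq_len(nocc))
  vir_so <- setdiff(seq_len(2 * n), c(seq_len(nocc), n + seq_len(nocc)))
  anti <- function(p, q, r, s) {
    v <- 0
    if (so_spin[p] == so_spin[r] && so_spin[q] == so_spin[s])
      v <- v + g[so_sp[p], so_sp[r], so_sp[q], so_sp[s]]
    if (so_spin[p] == so_spin[s] && so_spin[q] == so_spin[r])
      v <- v - g[so_sp[p], so_sp[s], so_sp[q], so_sp[r]]
    v
  }
  e2 <- 0; e_os <- 0; e_ss <- 0
  for (i in occ_so) for (j in occ_so) for (a in vir_so) for (b in vir_so) {
    num <- anti(i, j, a, b)^2
    den <- eps[so_sp[i]] + eps[so_sp[j]] - eps[so_sp[a]] - eps[so_sp[b]]
    contrib <- 0.25 * num / den
    e2 <- e2 + contrib
    if (so_spin[i] == so_spin[j]) e_ss <- e_ss + contrib
    else e_os <- e_os + contrib
  }
  list(E_corr = e2, E_OS = e_os, E_SS = e_ss)
}
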