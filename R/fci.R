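# Full configuration interaction for few-electron closed-shell systems, in
# the MO basis of a converged RHF solution.  Determinants are enumerated as
# alpha/beta occupation strings and the Hamiltonian is built densely via
# Slater-Condon rules in compiled code.

det_masks <- function(n_orb, n_alpha, n_beta) {
  strings <- function(k) {
    if (k == 0) return(list(integer(0)))
    cmb <- combn(n_orb, k)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j] - 1L)
  }
  sa <- strings(n_alpha)
  sb <- strings(n_beta)
  amask <- numeric(length(sa) * length(sb))
  bmask <- numeric(length(sa) * length(sb))
  idx <- 1
  for (a in sa) {
    abits <- sum(2^a)
    for (b in sb) {
      amask[idx] <- abits
      bmask[idx] <- sum(2^b)
      idx <- idx + 1
    }
  }
  list(alpha = amask, beta = bmask)
}

#' Full CI for few-electron systems
#'
#' Dense determinant FCI (all singlet-projection `M_s = 0` determinants) in
#' the molecular-orbital basis of an RHF solution.  Intended for systems with
#' at most `max_electrons` electrons; the two-particle density of the ground
#' state is returned in spin-blocked Mulliken form.
#'
#' @param scf an `scf_solution`.
#' @param max_electrons safety limit on the electron count (default 4).
#' @param rdm logical; also compute the ground-state one- and two-particle
#'   densities.
#' @return An `fci_solution` with the total `energy` (hartree, including
#'   nuclear repulsion), the CI vector, and optionally `two_rdm`/`one_rdm`.
#' @export
fci_solve <- function(scf, max_electrons = 4L, rdm = TRUE) {
  nel <- 2L * scf$n_occupied
  if (nel > max_electrons)
    stop("unsupported system: ", nel, " electrons exceeds the FCI limit of ",
         max_electrons)
  n <- scf$n_basis
  if (2L * n > 62L) stop("orbital space too large for the determinant engine")
  C <- scf$orbital_coefficients
  h_mo <- crossprod(C, scf$ints$Hcore %*% C)
  g_mo <- mo_eri(scf)
  masks <- det_masks(n, nel %/% 2L, nel %/% 2L)
  H <- fci_hamiltonian(masks$alpha, masks$beta, h_mo, as.numeric(g_mo), n)
  ev <- eigen(H, symmetric = TRUE)
  nd <- length(masks$alpha)
  ground <- ev$vectors[, nd]   # eigen() returns descending values
  e_elec <- ev$values[nd]
  out <- list(energy = e_elec + scf$ints$enuc, e_electronic = e_elec,
              civec = ground, masks = masks, n_determinants = nd,
              scf = scf, moeri = g_mo)
  if (rdm) {
    r <- fci_rdm(masks$alpha, masks$beta, ground, n, nel)
    out$two_rdm <- structure(
      list(aa = r$aa, bb = r$bb, ab = r$ab, ba = r$ba, kind = "FCI",
           n_electrons = nel, basis_label = scf$basis_label),
      class = "two_rdm")
    out$one_rdm <- structure(
      list(matrix = r$Da + r$Db, alpha = r$Da, beta = r$Db, kind = "FCI",
           n_electrons = nel), class = "one_rdm")
  }
  structure(out, class = "fci_solution")
}

#' @export
print.fci_solution <- function(x, ...) {
  cat(sprintf("FCI: E = %.9f hartree (%d determinants)\n", x$energy,
              x$n_determinants))
  invisible(x)
}
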