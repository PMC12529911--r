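# MP2 in the spatial-orbital closed-shell formulation: spin-resolved
# correlation components and the unrelaxed one-particle density.

frozen_core_count <- function(mol) {
  z <- ELEMENT_Z[mol$atoms]
  sum(ifelse(z <= 2, 0L, 1L))  # one frozen 1s shell per Li..Ne atom
}

#' Spin-resolved MP2 correlation components
#'
#' Computes the opposite-spin and same-spin parts of the MP2 correlation
#' energy from a converged RHF solution, together with the doubles
#' amplitudes `t[i,j,a,b] = (ia|jb)/(e_i + e_j - e_a - e_b)`.
#'
#' @param scf an `scf_solution`.
#' @param frozen_core logical; exclude one 1s core orbital per atom beyond He
#'   from the correlation treatment.  Default is all-electron.
#' @param moeri optionally, precomputed [mo_eri()] output.
#' @return An `mp2_components` object with `E_OS`, `E_SS` (hartree, both
#'   non-positive), the amplitude tensor, and index bookkeeping.
#' @export
mp2_components <- function(scf, frozen_core = FALSE, moeri = NULL) {
  n <- scf$n_basis
  nocc_tot <- scf$n_occupied
  ncore <- if (frozen_core) frozen_core_count(scf$molecule) else 0L
  occ <- setdiff(seq_len(nocc_tot), seq_len(ncore))
  vir <- seq(nocc_tot + 1, length.out = n - nocc_tot)
  if (length(vir) == 0)
    stop("degenerate input: no virtual orbitals in basis '",
         scf$basis_label, "'")
  if (length(occ) == 0)
    stop("degenerate input: no correlated occupied orbitals")
  if (is.null(moeri)) moeri <- mo_eri(scf)
  eps <- scf$orbital_energies
  no <- length(occ); nv <- length(vir)

  ovov <- moeri[occ, vir, occ, vir, drop = FALSE]   # (ia|jb)
  g <- aperm(ovov, c(1, 3, 2, 4))                   # [i,j,a,b]
  denom <- outer(outer(eps[occ], eps[occ], "+"),
                 outer(eps[vir], eps[vir], "+"), "-")  # [i,j,a,b]
  t2 <- g / denom
  gx <- aperm(g, c(1, 2, 4, 3))                     # (ib|ja) as [i,j,a,b]
  E_OS <- sum(t2 * g)
  E_SS <- sum(t2 * (g - gx))

  structure(
    list(E_OS = E_OS, E_SS = E_SS, E_corr = E_OS + E_SS,
         amplitudes = t2, frozen_core = frozen_core, n_core = ncore,
         occ = occ, vir = vir, moeri = moeri, scf = scf),
    class = "mp2_components")
}

#' @export
print.mp2_components <- function(x, ...) {
  cat(sprintf(
    "MP2 components: E_OS = %.9f  E_SS = %.9f  (E_corr = %.9f hartree)%s\n",
    x$E_OS, x$E_SS, x$E_corr,
    if (x$frozen_core) sprintf("  [frozen core: %d]", x$n_core) else ""))
  invisible(x)
}

# spin-summed correction blocks of the unrelaxed MP2 one-particle density
mp2_density_correction <- function(mp2) {
  t2 <- mp2$amplitudes
  d <- dim(t2); no <- d[1]; nv <- d[3]
  tbar <- 2 * t2 - aperm(t2, c(1, 2, 4, 3))
  Mt <- matrix(t2, no, no * nv * nv)
  Mb <- matrix(tbar, no, no * nv * nv)
  Poo <- -2 * Mt %*% t(Mb)
  Ta <- matrix(aperm(t2, c(3, 1, 2, 4)), nv, no * no * nv)
  Tb <- matrix(aperm(tbar, c(3, 1, 2, 4)), nv, no * no * nv)
  Pvv <- 2 * Ta %*% t(Tb)
  list(Poo = (Poo + t(Poo)) / 2, Pvv = (Pvv + t(Pvv)) / 2)
}

#' Unrelaxed MP2 natural-orbital occupancies
#'
#' Builds the MP2 first-order unrelaxed one-particle density (Hartree-Fock
#' density plus the amplitude-quadratic occupied-occupied and virtual-virtual
#' corrections), diagonalizes it per spin channel and returns the natural
#' occupancies, which lie strictly within `[0, 1]`.
#'
#' @param scf an `scf_solution`.
#' @param mp2 an `mp2_components` object for the same SCF solution.
#' @param clamp_tol occupancies within this distance outside `[0, 1]` are
#'   clamped; harder violations raise an error.
#' @return An [occupancy_spectrum()] with identical alpha and beta channels.
#' @export
unrelaxed_occupancies <- function(scf, mp2, clamp_tol = 1e-8) {
  D <- unrelaxed_density(scf, mp2)
  occ_spin <- eigen((D + t(D)) / 2 / 2, symmetric = TRUE)$values
  if (any(occ_spin < -clamp_tol) || any(occ_spin > 1 + clamp_tol))
    stop(sprintf(
      "density construction error: occupancy outside [0,1] by %.3e",
      max(c(-occ_spin, occ_spin - 1), 0)))
  occ_spin <- pmin(pmax(occ_spin, 0), 1)
  occupancy_spectrum(alpha = occ_spin, beta = occ_spin,
                     N = 2 * scf$n_occupied)
}

#' Unrelaxed MP2 one-particle density matrix (spin-summed, MO basis)
#' @param scf an `scf_solution`.
#' @param mp2 an `mp2_components` for the same SCF solution.
#' @return n x n matrix with trace equal to the electron count.
#' @export
unrelaxed_density <- function(scf, mp2) {
  n <- scf$n_basis
  D <- diag(c(rep(2, scf$n_occupied), rep(0, n - scf$n_occupied)))
  corr <- mp2_density_correction(mp2)
  D[mp2$occ, mp2$occ] <- D[mp2$occ, mp2$occ] + corr$Poo
  D[mp2$vir, mp2$vir] <- D[mp2$vir, mp2$vir] + corr$Pvv
  D
}
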