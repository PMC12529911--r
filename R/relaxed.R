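# Relaxed (orbital-response) MP2 densities: the amplitude one-particle
# correction plus the Z-vector occupied-virtual response, and the response
# two-particle density assembled from its separable and cumulant parts.

#' Relaxed MP2 one- and two-particle densities
#'
#' Builds the MP2 response densities: the one-particle density includes the
#' amplitude (unrelaxed) occupied-occupied and virtual-virtual blocks plus
#' the occupied-virtual block obtained from the Z-vector (coupled-perturbed
#' Hartree-Fock) equations; the two-particle density is assembled from the
#' separable part (linear in the one-particle correction) and the amplitude
#' cumulant.  These densities reproduce first-order MP2 response properties:
#' `Tr(D O)` equals the derivative of the total MP2 energy with respect to a
#' one-electron perturbation `O`, and the contraction of the two-particle
#' density with the repulsion integrals equals the corresponding derivative
#' with respect to a uniform scaling of the two-electron interaction.
#'
#' @param scf an `scf_solution`.
#' @param mp2 an all-electron `mp2_components` for the same SCF solution.
#' @return list with `one_rdm` (spin-summed MO matrix, class `one_rdm`) and
#'   `two_rdm` (spin-blocked MO arrays, class `two_rdm`, kind
#'   `"MP2-relaxed"`).
#' @export
relaxed_densities <- function(scf, mp2) {
  if (mp2$frozen_core)
    stop("relaxed densities are implemented for all-electron MP2 only")
  ctx <- so_context(scf, mp2)
  o <- ctx$occ; v <- ctx$vir
  no <- length(o); nv <- length(v)
  t2 <- so_amplitudes(ctx)           # [i,j,a,b] spin-orbital
  anti <- ctx$anti

  # amplitude (unrelaxed) blocks, per spin-orbital pair
  Mt <- matrix(t2, no, no * nv * nv)
  Poo <- -0.5 * (Mt %*% t(Mt))
  Ta <- matrix(aperm(t2, c(3, 1, 2, 4)), nv, no * no * nv)
  Pvv <- 0.5 * (Ta %*% t(Ta))

  # Lagrangian (coefficient of the occupied-virtual rotations in dE2)
  A_ovv <- matrix(aperm(anti[v, o, v, v, drop = FALSE], c(1, 2, 3, 4)),
                  nv, no * nv * nv)
  Tm <- matrix(aperm(t2, c(1, 2, 3, 4)), no, no * nv * nv)  # [i, (j,b,c)]
  L1 <- A_ovv %*% t(Tm)                                     # [a, i]
  Tjka <- matrix(aperm(t2, c(3, 1, 2, 4)), nv, no * no * nv)  # [a,(j,k,b)]
  A_ooi <- matrix(aperm(anti[o, o, o, v, drop = FALSE], c(3, 1, 2, 4)),
                  no, no * no * nv)                           # [i,(j,k,b)]
  L2 <- Tjka %*% t(A_ooi)                                     # [a, i]
  # density-weighted Fock response: sum_pq P_pq <p i||q a>
  P_so <- matrix(0, 2 * ctx$n, 2 * ctx$n)
  P_so[o, o] <- Poo
  P_so[v, v] <- Pvv
  m <- 2 * ctx$n
  Apq <- matrix(aperm(anti, c(2, 4, 1, 3)), m * m, m * m)  # [(i,a),(p,q)]
  LP <- matrix(Apq %*% as.vector(P_so), m, m)[o, v]        # [i, a]
  L <- L1 - L2 + 2 * t(LP)                                 # [a, i]

  # orbital Hessian and Z-vector
  eps <- ctx$eps
  dia <- outer(eps[v], eps[o], "-")                        # [a, i]
  Amat <- diag(as.vector(dia)) +
    matrix(aperm(anti[v, o, o, v, drop = FALSE], c(1, 3, 4, 2)),
           nv * no, nv * no) +
    matrix(aperm(anti[v, v, o, o, drop = FALSE], c(1, 3, 2, 4)),
           nv * no, nv * no)
  z <- solve(Amat, -as.vector(L))                          # [a, i] order
  Z <- matrix(z, nv, no)

  # spin-summed spatial one-particle density (alpha and beta identical)
  n <- ctx$n
  occ_sp <- mp2$occ; vir_sp <- mp2$vir
  D <- diag(c(rep(2, scf$n_occupied), rep(0, n - scf$n_occupied)))
  D[occ_sp, occ_sp] <- D[occ_sp, occ_sp] + 2 * Poo[seq_len(length(occ_sp)),
                                                   seq_len(length(occ_sp))]
  D[vir_sp, vir_sp] <- D[vir_sp, vir_sp] + 2 * Pvv[seq_len(length(vir_sp)),
                                                   seq_len(length(vir_sp))]
  Zsp <- Z[seq_len(length(vir_sp)), seq_len(length(occ_sp)), drop = FALSE]
  D[vir_sp, occ_sp] <- D[vir_sp, occ_sp] + Zsp
  D[occ_sp, vir_sp] <- D[occ_sp, vir_sp] + t(Zsp)

  one <- structure(list(matrix = D, kind = "MP2-relaxed", n_electrons =
                          2 * scf$n_occupied), class = "one_rdm")
  two <- mp2_two_rdm_from_parts(scf, mp2, D)
  list(one_rdm = one, two_rdm = two)
}

# response two-particle density: separable part linear in the one-particle
# correction plus the amplitude cumulant (spatial spin blocks, Mulliken
# pairing as in fci_rdm)
mp2_two_rdm_from_parts <- function(scf, mp2, D_relaxed) {
  n <- scf$n_basis
  nocc <- scf$n_occupied
  Dhf <- diag(c(rep(1, nocc), rep(0, n - nocc)))   # per spin
  Dc <- (D_relaxed - 2 * Dhf) / 2                  # per-spin correction
  sep_block <- function(DA, DB, exchange) {
    G <- outer(DA, DB)
    if (exchange) {
      # subtract same-spin exchange: D_PS D_RQ in Mulliken [P,Q,R,S]
      G <- G - aperm(outer(DA, DB), c(1, 4, 3, 2))
    }
    G
  }
  # linear-response separable part: HF x HF + HF x corr + corr x HF
  lin <- function(exchange) {
    sep_block(Dhf, Dhf, exchange) + sep_block(Dhf, Dc, exchange) +
      sep_block(Dc, Dhf, exchange)
  }
  Gaa <- lin(TRUE)
  Gab <- lin(FALSE)

  # amplitude cumulant
  occ <- mp2$occ; vir <- mp2$vir
  t2 <- mp2$amplitudes                     # [i,j,a,b] = (ia|jb)/denom
  t_same <- t2 - aperm(t2, c(1, 2, 4, 3))
  add_cum <- function(G, tt) {
    cum <- aperm(tt, c(1, 3, 2, 4))        # [i,a,j,b]
    G[occ, vir, occ, vir] <- G[occ, vir, occ, vir, drop = FALSE] + cum
    G[vir, occ, vir, occ] <- G[vir, occ, vir, occ, drop = FALSE] +
      aperm(cum, c(2, 1, 4, 3))
    G
  }
  Gaa <- add_cum(Gaa, t_same)
  Gab <- add_cum(Gab, t2)

  structure(list(aa = Gaa, bb = Gaa, ab = Gab, ba = aperm(Gab, c(3, 4, 1, 2)),
                 kind = "MP2-relaxed", n_electrons = 2 * nocc,
                 basis_label = scf$basis_label),
            class = "two_rdm")
}

#' Hartree-Fock two-particle density
#'
#' The single-determinant two-particle density in the MO basis, spin-blocked
#' with Mulliken pairing.
#'
#' @param scf an `scf_solution`.
#' @return A `two_rdm` of kind `"HF"`.
#' @export
hf_two_rdm <- function(scf) {
  n <- scf$n_basis
  nocc <- scf$n_occupied
  Dhf <- diag(c(rep(1, nocc), rep(0, n - nocc)))
  Gaa <- outer(Dhf, Dhf) - aperm(outer(Dhf, Dhf), c(1, 4, 3, 2))
  Gab <- outer(Dhf, Dhf)
  structure(list(aa = Gaa, bb = Gaa, ab = Gab, ba = Gab, kind = "HF",
                 n_electrons = 2 * nocc, basis_label = scf$basis_label),
            class = "two_rdm")
}

#' Unrelaxed MP2 two-particle density
#'
#' As [relaxed_densities()] but without the orbital-response (Z-vector)
#' occupied-virtual block in the separable part.
#'
#' @param scf an `scf_solution`.
#' @param mp2 an `mp2_components` object.
#' @return A `two_rdm` of kind `"MP2-unrelaxed"`.
#' @export
unrelaxed_two_rdm <- function(scf, mp2) {
  D <- unrelaxed_density(scf, mp2)
  out <- mp2_two_rdm_from_parts(scf, mp2, D)
  out$kind <- "MP2-unrelaxed"
  out
}
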