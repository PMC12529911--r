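# Electron-repulsion expectation values from spin-blocked two-particle
# densities, channel decomposition, and density sum-rule checks.

#' Electron-electron repulsion from a two-particle density
#'
#' `Vee = 1/2 sum_blocks sum_PQRS Gamma_PQRS (PQ|RS)` with MO integrals in
#' chemist order; returns the total and its opposite-/same-spin channels.
#'
#' @param two_rdm a `two_rdm`.
#' @param moeri MO two-electron integrals from [mo_eri()].
#' @return list with `total`, `OS`, `SS` (hartree).
#' @export
vee_from_two_rdm <- function(two_rdm, moeri) {
  ss <- 0.5 * (sum(two_rdm$aa * moeri) + sum(two_rdm$bb * moeri))
  os <- 0.5 * (sum(two_rdm$ab * moeri) + sum(two_rdm$ba * moeri))
  list(total = ss + os, OS = os, SS = ss)
}

#' Correlation contribution to the electron repulsion
#'
#' Computes `Delta Vee = Vee(target) - Vee(reference)` algebraically from two
#' two-particle densities expressed in the same MO basis, with the
#' opposite-/same-spin channel decomposition.
#'
#' @param two_rdm_target,two_rdm_ref `two_rdm` objects in the same MO basis.
#' @param moeri MO two-electron integrals.
#' @return list with `total`, `OS`, `SS` differences (hartree) and the two
#'   `Vee` values.
#' @export
delta_vee <- function(two_rdm_target, two_rdm_ref, moeri) {
  if (!identical(two_rdm_target$basis_label, two_rdm_ref$basis_label))
    stop("two-particle densities come from different bases: ",
         two_rdm_target$basis_label, " vs ", two_rdm_ref$basis_label)
  vt <- vee_from_two_rdm(two_rdm_target, moeri)
  vr <- vee_from_two_rdm(two_rdm_ref, moeri)
  list(total = vt$total - vr$total, OS = vt$OS - vr$OS, SS = vt$SS - vr$SS,
       vee_target = vt, vee_ref = vr)
}

#' Sum-rule checks for a two-particle density
#'
#' Contracts each spin block over one index pair and compares with the
#' matching one-particle density scaled by `(N_sigma - 1)` (same spin) or
#' `N_sigma'` (opposite spin), and checks the total pair count
#' `N(N-1)/2`.  Exact for single-determinant and FCI densities; truncated
#' MP2 response densities satisfy them through second order only.
#'
#' @param two_rdm a `two_rdm`.
#' @param one_alpha,one_beta per-spin one-particle densities (MO).
#' @return list with the maximum contraction defect and the pair-count
#'   defect.
#' @export
two_rdm_check <- function(two_rdm, one_alpha, one_beta) {
  n <- dim(two_rdm$aa)[1]
  na <- sum(diag(one_alpha)); nb <- sum(diag(one_beta))
  contract <- function(G) {
    # sum over R = S of G[P,Q,R,S]
    M <- matrix(0, n, n)
    for (r in seq_len(n)) M <- M + G[, , r, r]
    M
  }
  d_aa <- max(abs(contract(two_rdm$aa) - one_alpha * (na - 1)))
  d_bb <- max(abs(contract(two_rdm$bb) - one_beta * (nb - 1)))
  d_ab <- max(abs(contract(two_rdm$ab) - one_alpha * nb))
  d_ba <- max(abs(contract(two_rdm$ba) - one_beta * na))
  pair_trace <- function(G) {
    s <- 0
    for (p in seq_len(n)) for (r in seq_len(n)) s <- s + G[p, p, r, r]
    s
  }
  pairs <- 0.5 * (pair_trace(two_rdm$aa) + pair_trace(two_rdm$bb) +
                    pair_trace(two_rdm$ab) + pair_trace(two_rdm$ba))
  nel <- na + nb
  list(contraction_defect = max(d_aa, d_bb, d_ab, d_ba),
       pair_count = pairs, pair_defect = abs(pairs - nel * (nel - 1) / 2))
}
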