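# AO integral assembly: calls the compiled McMurchie-Davidson engine over
# contracted Cartesian shells, then maps to normalized real-spherical AOs.

# transform one tensor mode of a 4-index array by U (ncart x nsph)
mode_transform4 <- function(G, U) {
  nc <- dim(G)[1]
  ns <- ncol(U)
  for (k in 1:4) {
    d <- dim(G)
    M <- crossprod(U, matrix(G, d[1], prod(d[-1])))  # ns x rest
    G <- aperm(array(M, c(ns, d[-1])), c(2, 3, 4, 1))
  }
  G
}

#' Atomic-orbital integrals
#'
#' Computes overlap, kinetic, nuclear-attraction and two-electron repulsion
#' integrals over contracted spherical-harmonic Gaussian AOs, plus the nuclear
#' repulsion energy.  Coordinates are converted to bohr internally; all
#' integrals are in hartree atomic units.
#'
#' @param mol a `molecule`.
#' @param basis basis-set name (see [load_basis()]) or a loaded basis.
#' @return list with `S`, `T`, `V`, `Hcore`, `ERI` (4-index array, chemist
#'   `(pq|rs)` ordering), `nbf`, `enuc`, `basis_label` and the shell data.
#' @export
ao_integrals <- function(mol, basis) {
  basis_label <- if (is.character(basis)) basis else attr(basis, "name")
  if (is.character(basis)) basis <- load_basis(basis)
  bs <- build_shells(mol, basis)
  coords <- mol$coordinates * BOHR_PER_ANGSTROM
  Z <- as.numeric(ELEMENT_Z[mol$atoms])

  one <- md_one_electron(bs$shells, coords, Z)
  eri_cart <- md_eri(bs$shells, coords)

  # normalize the spherical AOs to unit self-overlap
  U <- bs$U
  Ssph <- crossprod(U, one$S %*% U)
  U <- U %*% diag(1 / sqrt(diag(Ssph)), ncol(U))

  S <- crossprod(U, one$S %*% U)
  T <- crossprod(U, one$T %*% U)
  V <- crossprod(U, one$V %*% U)
  ERI <- mode_transform4(eri_cart, U)

  enuc <- 0
  n <- nrow(coords)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      enuc <- enuc + Z[i] * Z[j] / sqrt(sum((coords[i, ] - coords[j, ])^2))
  }
  list(S = S, T = T, V = V, Hcore = T + V, ERI = ERI, nbf = bs$nsph,
       enuc = enuc, basis_label = basis_label, shells = bs$shells,
       U = U, coords_bohr = coords, Z = Z)
}
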