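# Restricted Hartree-Fock with DIIS acceleration.

#' Restricted Hartree-Fock
#'
#' Solves the closed-shell SCF equations with DIIS.  Convergence thresholds
#' default to 1e-9 hartree on the energy and 1e-7 on the density RMS change.
#'
#' @param mol a `molecule`; must be closed shell (even electron count,
#'   multiplicity 1).
#' @param basis basis-set name or loaded basis.
#' @param max_cycles maximum SCF iterations.
#' @param conv_energy energy convergence threshold, hartree.
#' @param conv_density RMS density-change threshold.
#' @param diis logical; use DIIS extrapolation.
#' @param ints optionally, precomputed [ao_integrals()] output.
#' @return An `scf_solution`: orbital coefficients (AO x MO), ascending
#'   orbital energies, occupied count per spin, the converged `E_HF`
#'   (including nuclear repulsion), the basis label and the AO integrals.
#' @export
run_rhf <- function(mol, basis, max_cycles = 128L, conv_energy = 1e-9,
                    conv_density = 1e-7, diis = TRUE, ints = NULL) {
  nel <- n_electrons(mol)
  if (mol$multiplicity != 1L || nel %% 2 != 0)
    stop("unsupported system: restricted engine requires a closed-shell ",
         "singlet (got ", nel, " electrons, multiplicity ", mol$multiplicity,
         ")")
  if (is.null(ints)) ints <- ao_integrals(mol, basis)
  n <- ints$nbf
  nocc <- nel %/% 2
  if (nocc > n) stop("basis too small for electron count")

  # symmetric orthogonalizer
  se <- eigen(ints$S, symmetric = TRUE)
  if (min(se$values) < 1e-10)
    stop("AO overlap is numerically singular")
  X <- se$vectors %*% diag(1 / sqrt(se$values), n) %*% t(se$vectors)

  ERImat <- matrix(ints$ERI, n * n, n * n)           # (pq|rs) as (pq) x (rs)
  Kperm <- matrix(aperm(ints$ERI, c(1, 3, 2, 4)), n * n, n * n)

  fock <- function(P) {
    J <- matrix(ERImat %*% as.vector(P), n, n)
    K <- matrix(Kperm %*% as.vector(P), n, n)
    ints$Hcore + 2 * J - K
  }
  solve_fock <- function(F) {
    Fp <- crossprod(X, F %*% X)
    fe <- eigen(Fp, symmetric = TRUE)
    ord <- order(fe$values)
    list(C = X %*% fe$vectors[, ord, drop = FALSE], eps = fe$values[ord])
  }

  # core-Hamiltonian guess
  sol <- solve_fock(ints$Hcore)
  C <- sol$C
  Cocc <- C[, seq_len(nocc), drop = FALSE]
  P <- tcrossprod(Cocc)
  e_old <- 0
  err_list <- list(); fock_list <- list()
  converged <- FALSE

  for (cycle in seq_len(max_cycles)) {
    F <- fock(P)
    e_elec <- sum(P * (ints$Hcore + F))
    energy <- e_elec + ints$enuc

    if (diis) {
      err <- F %*% P %*% ints$S - ints$S %*% P %*% F
      err <- crossprod(X, err %*% X)
      err_list[[length(err_list) + 1]] <- err
      fock_list[[length(fock_list) + 1]] <- F
      if (length(err_list) > 8) {
        err_list <- err_list[-1]; fock_list <- fock_list[-1]
      }
      m <- length(err_list)
      if (m >= 2) {
        B <- matrix(0, m + 1, m + 1)
        for (i in 1:m) for (j in 1:m)
          B[i, j] <- sum(err_list[[i]] * err_list[[j]])
        B[m + 1, 1:m] <- -1; B[1:m, m + 1] <- -1
        rhs <- c(rep(0, m), -1)
        cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
        if (!is.null(cf)) {
          F <- Reduce(`+`, Map(`*`, fock_list, cf))
        }
      }
    }

    sol <- solve_fock(F)
    C <- sol$C
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    P_new <- tcrossprod(Cocc)
    dP <- sqrt(mean((P_new - P)^2))
    dE <- abs(energy - e_old)
    P <- P_new
    e_old <- energy
    if (cycle > 1 && dE < conv_energy && dP < conv_density) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("SCF failed to converge in ", max_cycles, " cycles for molecule [",
         paste(mol$atoms, collapse = ""), "]")

  # final energy with the converged density
  F <- fock(P)
  e_elec <- sum(P * (ints$Hcore + F))
  structure(
    list(orbital_coefficients = C, orbital_energies = sol$eps,
         n_occupied = nocc, E_HF = e_elec + ints$enuc,
         basis_label = ints$basis_label, molecule = mol, ints = ints,
         density = P, fock = F, n_basis = n, cycles = cycle),
    class = "scf_solution")
}

#' @export
print.scf_solution <- function(x, ...) {
  cat(sprintf("RHF/%s: E_HF = %.9f hartree (%d basis functions, %d cycles)\n",
              x$basis_label, x$E_HF, x$n_basis, x$cycles))
  invisible(x)
}

#' Molecular-orbital two-electron integrals
#'
#' Transforms the AO repulsion integrals to the MO basis of a converged SCF
#' solution, chemist `(pq|rs)` ordering.
#'
#' @param scf an `scf_solution`.
#' @return 4-index array of MO integrals.
#' @export
mo_eri <- function(scf) {
  C <- scf$orbital_coefficients
  G <- scf$ints$ERI
  n <- dim(G)[1]
  for (k in 1:4) {
    d <- dim(G)
    M <- crossprod(C, matrix(G, d[1], prod(d[-1])))
    G <- aperm(array(M, c(ncol(C), d[-1])), c(2, 3, 4, 1))
  }
  G
}
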