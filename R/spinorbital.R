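# Spin-orbital machinery used by the relaxed-density (orbital-response)
# construction.  Spin orbitals are ordered 1..n (alpha) then n+1..2n (beta).
# Sizes here are desk scale, so full antisymmetrized tensors are affordable.

so_antisymmetrized <- function(moeri) {
  n <- dim(moeri)[1]
  m <- 2L * n
  a <- seq_len(n); b <- n + a
  chem <- array(0, c(m, m, m, m))
  chem[a, a, a, a] <- moeri
  chem[a, a, b, b] <- moeri
  chem[b, b, a, a] <- moeri
  chem[b, b, b, b] <- moeri
  # physicist <pq||rs> = (pr|qs) - (ps|qr)
  aperm(chem, c(1, 3, 2, 4)) - aperm(chem, c(1, 3, 4, 2))
}

so_context <- function(scf, mp2) {
  n <- scf$n_basis
  occ_sp <- mp2$occ; vir_sp <- mp2$vir
  core_sp <- seq_len(mp2$n_core)
  eps <- scf$orbital_energies
  list(
    n = n,
    anti = so_antisymmetrized(mp2$moeri),
    occ = c(occ_sp, n + occ_sp),
    vir = c(vir_sp, n + vir_sp),
    core = if (mp2$n_core > 0) c(core_sp, n + core_sp) else integer(0),
    eps = c(eps, eps))
}

# spin-orbital doubles amplitudes t[i,j,a,b] = <ij||ab>/(ei+ej-ea-eb)
so_amplitudes <- function(ctx) {
  o <- ctx$occ; v <- ctx$vir
  g <- ctx$anti[o, o, v, v, drop = FALSE]
  denom <- outer(outer(ctx$eps[o], ctx$eps[o], "+"),
                 outer(ctx$eps[v], ctx$eps[v], "+"), "-")
  g / denom
}
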