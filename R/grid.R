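# Atom-centered molecular quadrature grid: Becke fuzzy-cell partitioning,
# Gauss-Legendre radial quadrature under the [0, Inf) rational map, and a
# Gauss-Legendre (cos theta) x uniform (phi) angular product grid.

gauss_legendre <- function(n) {
  # Golub-Welsch: eigen decomposition of the Jacobi matrix
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
}

becke_step <- function(mu, k = 3) {
  for (i in seq_len(k)) mu <- 1.5 * mu - 0.5 * mu^3
  mu
}

#' Atom-centered quadrature grid
#'
#' Builds a molecular integration grid: per-atom spherical product grids
#' (Gauss-Legendre radial shells mapped by `r = R (1+x)/(1-x)`,
#' Gauss-Legendre in `cos(theta)`, uniform in `phi`) combined with Becke
#' fuzzy-cell weights.
#'
#' @param mol a `molecule`.
#' @param n_radial radial points per atom.
#' @param n_theta,n_phi angular points.
#' @param radial_scale map parameter `R` in bohr.
#' @return list with `points` (M x 3, bohr) and `weights` (length M).
#' @export
molecular_grid <- function(mol, n_radial = 30, n_theta = 10, n_phi = 20,
                           radial_scale = 1.0) {
  coords <- mol$coordinates * BOHR_PER_ANGSTROM
  natom <- nrow(coords)
  gl_r <- gauss_legendre(n_radial)
  r <- radial_scale * (1 + gl_r$nodes) / (1 - gl_r$nodes)
  jac <- 2 * radial_scale / (1 - gl_r$nodes)^2
  w_r <- gl_r$weights * jac * r^2
  gl_t <- gauss_legendre(n_theta)
  ct <- gl_t$nodes; st <- sqrt(pmax(0, 1 - ct^2))
  w_t <- gl_t$weights
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  w_p <- rep(2 * pi / n_phi, n_phi)

  # unit sphere directions and angular weights
  dirs <- cbind(
    as.vector(outer(st, cos(phi))),
    as.vector(outer(st, sin(phi))),
    as.vector(outer(ct, rep(1, n_phi))))
  w_ang <- as.vector(outer(w_t, w_p))

  pts_list <- vector("list", natom)
  w_list <- vector("list", natom)
  for (a in seq_len(natom)) {
    p <- dirs[rep(seq_len(nrow(dirs)), times = n_radial), , drop = FALSE] *
      rep(r, each = nrow(dirs))
    p <- sweep(p, 2, coords[a, ], "+")
    w <- rep(w_ang, times = n_radial) * rep(w_r, each = nrow(dirs))
    pts_list[[a]] <- p
    w_list[[a]] <- w
  }
  pts <- do.call(rbind, pts_list)
  w <- unlist(w_list)
  atom_of <- rep(seq_len(natom), vapply(w_list, length, numeric(1)))

  if (natom > 1) {
    # Becke partition weights
    dist_at <- as.matrix(dist(coords))
    M <- nrow(pts)
    ra <- matrix(0, M, natom)
    for (a in seq_len(natom))
      ra[, a] <- sqrt(rowSums(sweep(pts, 2, coords[a, ])^2))
    P <- matrix(1, M, natom)
    for (a in seq_len(natom)) for (b in seq_len(natom)) {
      if (a == b) next
      mu <- (ra[, a] - ra[, b]) / dist_at[a, b]
      P[, a] <- P[, a] * 0.5 * (1 - becke_step(mu))
    }
    wb <- P[cbind(seq_len(M), atom_of)] / rowSums(P)
    w <- w * wb
  }
  list(points = pts, weights = w)
}

# values of the contracted spherical AOs at the given points (bohr)
ao_values <- function(ints, points) {
  shells <- ints$shells
  coords <- ints$coords_bohr
  M <- nrow(points)
  ncart <- nrow(ints$U)
  vals <- matrix(0, M, ncart)
  icol <- 0
  for (s in shells) {
    dx <- points[, 1] - coords[s$atom, 1]
    dy <- points[, 2] - coords[s$atom, 2]
    dz <- points[, 3] - coords[s$atom, 3]
    r2 <- dx^2 + dy^2 + dz^2
    radial <- numeric(M)
    for (k in seq_along(s$exponents))
      radial <- radial + s$coefficients[k] * exp(-s$exponents[k] * r2)
    comps <- list()
    for (lx in s$l:0) for (ly in (s$l - lx):0) {
      lz <- s$l - lx - ly
      comps[[length(comps) + 1]] <- dx^lx * dy^ly * dz^lz
    }
    for (c in comps) {
      icol <- icol + 1
      vals[, icol] <- radial * c
    }
  }
  vals %*% ints$U
}
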