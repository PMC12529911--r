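# Gaussian basis sets: plain-text data files under inst/extdata/basis,
# shell construction, and the Cartesian -> real-spherical transformation.

double_factorial <- function(n) {
  if (n <= 0) return(1)
  prod(seq(n, 1, by = -2))
}

# norm of a primitive Cartesian Gaussian of the (l,0,0) type; contraction
# coefficients in the data files refer to primitives normalized this way
primitive_norm <- function(alpha, l) {
  (2 * alpha / pi)^0.75 * (4 * alpha)^(l / 2) / sqrt(double_factorial(2 * l - 1))
}

#' Read a basis-set data file
#'
#' Parses the plain-text shell format shipped under `inst/extdata/basis`:
#' `ELEMENT <symbol>` opens a block, each shell is `<L> <nprim>` followed by
#' `exponent coefficient` rows, `END` closes the block.
#'
#' @param path path to a basis data file.
#' @return named list: element symbol -> list of shells (`l`, `exponents`,
#'   `coefficients`).
#' @export
read_basis_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  i <- 1
  lmap <- c(S = 0L, P = 1L, D = 2L, F = 3L)
  while (i <= length(lines)) {
    tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (toupper(tok[1]) != "ELEMENT")
      stop("malformed basis file near: ", lines[i])
    elem <- tok[2]
    i <- i + 1
    shells <- list()
    while (toupper(lines[i]) != "END") {
      tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
      l <- lmap[[toupper(tok[1])]]
      np <- as.integer(tok[2])
      rows <- lines[(i + 1):(i + np)]
      vals <- t(vapply(strsplit(rows, "[[:space:]]+"),
                       function(r) as.numeric(r[1:2]), numeric(2)))
      shells[[length(shells) + 1]] <-
        list(l = l, exponents = vals[, 1], coefficients = vals[, 2])
      i <- i + np + 1
    }
    out[[elem]] <- shells
    i <- i + 1
  }
  out
}

#' Load a shipped basis set by name
#' @param name `"sto-3g"`, `"cc-pvdz"` or `"cc-pvtz"` (case-insensitive).
#' @return basis definition as from [read_basis_file()], with a `name`
#'   attribute.
#' @export
load_basis <- function(name) {
  key <- tolower(name)
  path <- system.file("extdata", "basis", paste0(key, ".dat"),
                      package = "cdscs")
  if (!nzchar(path))
    stop("basis set not available: ", name)
  b <- read_basis_file(path)
  attr(b, "name") <- name
  b
}

n_cart <- function(l) (l + 1) * (l + 2) / 2
n_sph <- function(l) 2 * l + 1

# real-spherical combination coefficients on raw Cartesian monomials, ordered
# lx descending then ly descending (the engine's component order); overall
# scale is fixed afterwards by renormalizing each contracted AO
sph_coefs <- function(l) {
  if (l == 0) return(matrix(1, 1, 1))
  if (l == 1) return(diag(3))
  if (l == 2) {
    # cart order: xx, xy, xz, yy, yz, zz ; sph order m = -2,-1,0,+1,+2
    m <- matrix(0, 6, 5)
    m[2, 1] <- 1                       # xy
    m[5, 2] <- 1                       # yz
    m[1, 3] <- -1; m[4, 3] <- -1; m[6, 3] <- 2   # 2zz - xx - yy
    m[3, 4] <- 1                       # xz
    m[1, 5] <- 1; m[4, 5] <- -1        # xx - yy
    return(m)
  }
  stop("angular momentum above d not supported")
}

# Build the shell list for a molecule (coordinates converted to bohr) plus the
# Cartesian -> spherical AO map.  Primitive norms are folded into the
# contraction coefficients here.
build_shells <- function(mol, basis) {
  shells <- list()
  for (ia in seq_along(mol$atoms)) {
    elem <- mol$atoms[ia]
    if (is.null(basis[[elem]]))
      stop("basis '", attr(basis, "name"), "' has no entry for element ", elem)
    for (sh in basis[[elem]]) {
      coef <- sh$coefficients * primitive_norm(sh$exponents, sh$l)
      shells[[length(shells) + 1]] <-
        list(l = sh$l, atom = ia, exponents = sh$exponents,
             coefficients = coef)
    }
  }
  ncart_tot <- sum(vapply(shells, function(s) n_cart(s$l), numeric(1)))
  nsph_tot <- sum(vapply(shells, function(s) n_sph(s$l), numeric(1)))
  U <- matrix(0, ncart_tot, nsph_tot)
  ic <- 0; is <- 0
  for (s in shells) {
    cs <- sph_coefs(s$l)
    U[ic + seq_len(nrow(cs)), is + seq_len(ncol(cs))] <- cs
    ic <- ic + nrow(cs); is <- is + ncol(cs)
  }
  list(shells = shells, U = U, ncart = ncart_tot, nsph = nsph_tot)
}

#' Number of (spherical) basis functions for a molecule in a basis
#' @param mol a `molecule`.
#' @param basis basis name or a loaded basis definition.
#' @return integer count of contracted spherical-harmonic AOs.
#' @export
n_basis_functions <- function(mol, basis) {
  if (is.character(basis)) basis <- load_basis(basis)
  build_shells(mol, basis)$nsph
}
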