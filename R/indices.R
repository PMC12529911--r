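# Dynamic/nondynamic correlation indices from natural-orbital occupancies.

#' Natural-occupancy spectrum
#'
#' Container for per-spin natural orbital occupancies (each in `[0, 1]`) and
#' the electron count `N` used as normalization by the correlation indices.
#' Values within `clamp_tol` outside `[0, 1]` are clamped; harder violations
#' raise an error.
#'
#' @param alpha,beta numeric vectors of occupancies per spin channel.
#' @param N electron count; defaults to `sum(alpha) + sum(beta)`.
#' @param clamp_tol clamping tolerance.
#' @return An `occupancy_spectrum`.
#' @export
occupancy_spectrum <- function(alpha, beta = numeric(0), N = NULL,
                               clamp_tol = 1e-8) {
  check <- function(x, lab) {
    if (any(x < -clamp_tol) || any(x > 1 + clamp_tol))
      stop(sprintf("validation error: %s occupancy outside [0,1] by %.3e",
                   lab, max(c(-x, x - 1))))
    pmin(pmax(x, 0), 1)
  }
  alpha <- check(as.numeric(alpha), "alpha")
  beta <- check(as.numeric(beta), "beta")
  if (is.null(N)) N <- sum(alpha) + sum(beta)
  if (N <= 0) stop("validation error: electron count must be positive")
  structure(list(alpha = alpha, beta = beta, N = N),
            class = "occupancy_spectrum")
}

#' @export
print.occupancy_spectrum <- function(x, ...) {
  cat(sprintf("occupancy spectrum: %d alpha + %d beta orbitals, N = %g\n",
              length(x$alpha), length(x$beta), x$N))
  invisible(x)
}

#' Nondynamic correlation index
#'
#' `I_ND = (1/N) sum_{i,sigma} n (1 - n)`: each fractionally occupied
#' natural orbital contributes in proportion to its distance from integer
#' occupancy, peaking at n = 1/2.
#'
#' @param spectrum an [occupancy_spectrum()].
#' @return nonnegative index value.
#' @export
index_nd <- function(spectrum) {
  n <- c(spectrum$alpha, spectrum$beta)
  sum(n * (1 - n)) / spectrum$N
}

#' Dynamic correlation index
#'
#' `I_D = (1/2N) sum sqrt(n(1-n)) - (1/N) sum n(1-n)`: small occupancy
#' deviations (sqrt-dominated) register as dynamic correlation.  Provably
#' nonnegative since `sqrt(x)/2 >= x` for `x <= 1/4`.
#'
#' @param spectrum an [occupancy_spectrum()].
#' @return nonnegative index value.
#' @export
index_d <- function(spectrum) {
  n <- c(spectrum$alpha, spectrum$beta)
  x <- n * (1 - n)
  sum(sqrt(x)) / (2 * spectrum$N) - sum(x) / spectrum$N
}

#' Correlation indices and dynamic/nondynamic ratios
#'
#' Bundles `I_ND`, `I_D`, `I_T = I_ND + I_D`, the ratios
#' `r_D = I_D/I_T` and `r_ND = I_ND/I_T`, and the single-orbital
#' multireference diagnostic `I_ND_max = max n(1-n)`.  For a near-idempotent
#' spectrum (`I_T < tiny`) the dynamic-dominated convention `r_D = 1,
#' r_ND = 0` applies.
#'
#' @param spectrum an [occupancy_spectrum()].
#' @param tiny threshold on `I_T` below which the idempotent convention is
#'   used.
#' @return A `correlation_indices` object.
#' @export
correlation_indices <- function(spectrum, tiny = 1e-12) {
  i_nd <- index_nd(spectrum)
  i_d <- index_d(spectrum)
  i_t <- i_nd + i_d
  if (i_t < tiny) {
    r_d <- 1; r_nd <- 0
  } else {
    r_d <- i_d / i_t; r_nd <- i_nd / i_t
  }
  n <- c(spectrum$alpha, spectrum$beta)
  structure(
    list(I_ND = i_nd, I_D = i_d, I_T = i_t, r_D = r_d, r_ND = r_nd,
         I_ND_max = if (length(n)) max(n * (1 - n)) else 0),
    class = "correlation_indices")
}

#' @export
print.correlation_indices <- function(x, ...) {
  cat(sprintf(
    "I_ND = %.6f  I_D = %.6f  I_T = %.6f\nr_D = %.4f  r_ND = %.4f  I_ND_max = %.6f\n",
    x$I_ND, x$I_D, x$I_T, x$r_D, x$r_ND, x$I_ND_max))
  invisible(x)
}

#' Read a bare occupancy list from CSV
#'
#' One value per line; an optional blank-line- or `spin`-column-separated
#' two-section layout gives alpha then beta.  A single section is taken as
#' identical alpha and beta channels.
#'
#' @param path CSV/plain-text file with occupancies.
#' @return An [occupancy_spectrum()].
#' @export
read_occupancies <- function(path) {
  lines <- trimws(readLines(path))
  secs <- split(lines, cumsum(lines == ""))
  secs <- lapply(secs, function(s) as.numeric(s[nzchar(s)]))
  secs <- Filter(length, secs)
  if (length(secs) == 1)
    occupancy_spectrum(secs[[1]], secs[[1]])
  else
    occupancy_spectrum(secs[[1]], secs[[2]])
}
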