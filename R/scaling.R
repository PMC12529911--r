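# The correlation-driven scaling model: spin-component coefficients from
# correlation indices, scaled total energies, and error surfaces over fixed
# coefficient grids.

#' Scaling-model parameters
#'
#' The four constants of the correlation-driven model
#' `c_SS = a * r_ND + b`, `c_OS = a' * r_D + b'`.  Fixed-coefficient
#' spin-component scaling corresponds to `a = a' = 0`.
#'
#' @param a coefficient on `r_ND` in `c_SS`.
#' @param ap coefficient on `r_D` in `c_OS`.
#' @param b constant term of `c_SS`.
#' @param bp constant term of `c_OS`.
#' @param name optional label.
#' @return A `scaling_params` object.
#' @export
scaling_params <- function(a = 0, ap = 0, b = 1, bp = 1, name = "custom") {
  vals <- c(a = as.numeric(a)[1], ap = as.numeric(ap)[1],
            b = as.numeric(b)[1], bp = as.numeric(bp)[1])
  if (!all(is.finite(vals))) stop("scaling parameters must be finite")
  structure(c(as.list(vals), list(name = name)), class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf(
    "%s: c_SS = %g * r_ND + %g ; c_OS = %g * r_D + %g\n",
    x$name, x$a, x$b, x$ap, x$bp))
  invisible(x)
}

# preset registry: canonical MP2, the fixed-coefficient literature scalings,
# and the two correlation-driven models
SCALING_PRESETS <- list(
  mp2        = list(a = 0, ap = 0, b = 1, bp = 1),
  scs        = list(a = 0, ap = 0, b = 0.33, bp = 1.2),
  `scs-star` = list(a = 0, ap = 0, b = 0.44, bp = 1.13),
  s2opt      = list(a = 0, ap = 0, b = 0.623, bp = 1.055),
  cd2        = list(a = 2.89, ap = 1.38, b = 0, bp = 0),
  cd4        = list(a = 0, ap = 0.42, b = 0.47, bp = 0.79)
)

#' Named scaling presets
#'
#' Registry of published coefficient sets: `"mp2"` (1, 1), `"scs"`
#' (c_OS = 1.2, c_SS = 0.33), `"scs-star"` (1.13, 0.44), `"s2opt"`
#' (1.055, 0.623), and the correlation-driven `"cd2"`
#' (c_OS = 1.38 r_D, c_SS = 2.89 r_ND) and `"cd4"`
#' (c_OS = 0.42 r_D + 0.79, c_SS = 0.47).
#'
#' @param name preset name.
#' @return A `scaling_params`.
#' @export
preset_params <- function(name) {
  key <- tolower(name)
  if (!key %in% names(SCALING_PRESETS))
    stop("unknown preset: ", name, " (available: ",
         paste(names(SCALING_PRESETS), collapse = ", "), ")")
  p <- SCALING_PRESETS[[key]]
  scaling_params(p$a, p$ap, p$b, p$bp, name = key)
}

#' Spin-component coefficients for a species
#'
#' Evaluates `c_OS = a' * r_D + b'` and `c_SS = a * r_ND + b`.  Indices are
#' required whenever `a` or `a'` is nonzero; coefficients are not clipped,
#' so ranges such as `[0.79, 1.21]` for the four-parameter model emerge from
#' `r_D` in `[0, 1]`.
#'
#' @param params a `scaling_params`.
#' @param indices a `correlation_indices`, or `NULL` for fixed-coefficient
#'   presets.
#' @return named vector `c(c_OS = ..., c_SS = ...)`.
#' @export
scaling_coefficients <- function(params, indices = NULL) {
  if ((params$a != 0 || params$ap != 0) && is.null(indices))
    stop("configuration error: correlation indices required when a or a' ",
         "is nonzero")
  r_d <- if (is.null(indices)) 0 else indices$r_D
  r_nd <- if (is.null(indices)) 0 else indices$r_ND
  c(c_OS = params$ap * r_d + params$bp, c_SS = params$a * r_nd + params$b)
}

#' Species energies record
#'
#' Energy components of one species: the Hartree-Fock energy and the
#' opposite-/same-spin MP2 correlation components (all hartree), optionally
#' with its correlation indices.
#'
#' @param E_HF,E_OS,E_SS energies in hartree; `E_OS` and `E_SS` must be
#'   non-positive.
#' @param indices optional `correlation_indices`.
#' @param label optional species label.
#' @return A `species_energies` object.
#' @export
species_energies <- function(E_HF, E_OS, E_SS, indices = NULL, label = "") {
  if (E_OS > 1e-12 || E_SS > 1e-12)
    stop("validation error: correlation components must be non-positive")
  structure(list(E_HF = E_HF, E_OS = E_OS, E_SS = E_SS, indices = indices,
                 label = label), class = "species_energies")
}

#' Scaled total energy of a species
#'
#' `E = E_HF + c_OS E_OS + c_SS E_SS` with the species' own coefficients.
#'
#' @param species a `species_energies`.
#' @param params a `scaling_params`.
#' @return total energy, hartree.
#' @export
assemble_energy <- function(species, params) {
  cf <- scaling_coefficients(params, species$indices)
  unname(species$E_HF + cf["c_OS"] * species$E_OS + cf["c_SS"] * species$E_SS)
}

#' Absolute-error surface of a reaction over a coefficient grid
#'
#' Applies fixed `(c_OS, c_SS)` uniformly to all species of a reaction and
#' tabulates `|Delta E(c_OS, c_SS) - Delta E_ref|` in kcal/mol.  The
#' reaction energy is affine in the two coefficients, so the zero-error
#' locus is a straight line with slope
#' `-(sum nu E_OS)/(sum nu E_SS)`.
#'
#' @param reaction a [reaction()].
#' @param species named list of `species_energies`.
#' @param c_os_grid,c_ss_grid coefficient grids (default `seq(0, 2.5,
#'   by = 0.05)`).
#' @return An `error_surface`: the `|error|` matrix (rows c_OS, columns
#'   c_SS), the grids, and the affine structure (`hf_kcal`, `os_kcal`,
#'   `ss_kcal`, `slope`).
#' @export
error_surface <- function(reaction, species,
                          c_os_grid = seq(0, 2.5, by = 0.05),
                          c_ss_grid = seq(0, 2.5, by = 0.05)) {
  nu <- reaction$stoichiometry
  missing <- setdiff(names(nu), names(species))
  if (length(missing))
    stop("lookup error: unknown species ", paste(missing, collapse = ", "))
  hf <- sum(nu * vapply(species[names(nu)], `[[`, 0, "E_HF"))
  os <- sum(nu * vapply(species[names(nu)], `[[`, 0, "E_OS"))
  ss <- sum(nu * vapply(species[names(nu)], `[[`, 0, "E_SS"))
  hf_k <- hf * HARTREE_TO_KCAL; os_k <- os * HARTREE_TO_KCAL
  ss_k <- ss * HARTREE_TO_KCAL
  err <- outer(c_os_grid, c_ss_grid,
               function(x, y) abs(hf_k + x * os_k + y * ss_k -
                                    reaction$reference_energy))
  dimnames(err) <- list(format(c_os_grid), format(c_ss_grid))
  structure(list(errors = err, c_os = c_os_grid, c_ss = c_ss_grid,
                 hf_kcal = hf_k, os_kcal = os_k, ss_kcal = ss_k,
                 slope = if (abs(ss_k) > 0) -os_k / ss_k else NA_real_,
                 reaction = reaction$id),
            class = "error_surface")
}

#' @export
print.error_surface <- function(x, ...) {
  idx <- which(x$errors == min(x$errors), arr.ind = TRUE)[1, ]
  cat(sprintf(
    "error surface %s: min |error| %.4f kcal/mol at c_OS = %.2f, c_SS = %.2f\n",
    x$reaction, min(x$errors), x$c_os[idx[1]], x$c_ss[idx[2]]))
  invisible(x)
}

#' Export an error surface as CSV
#' @param surface an `error_surface`.
#' @param path output path.
#' @export
write_surface_csv <- function(surface, path) {
  write.csv(data.frame(c_OS = rep(surface$c_os, times = length(surface$c_ss)),
                       c_SS = rep(surface$c_ss, each = length(surface$c_os)),
                       abs_error_kcal = as.vector(surface$errors)),
            path, row.names = FALSE)
  invisible(path)
}
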