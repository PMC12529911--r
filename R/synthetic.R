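# Synthetic species records and reaction sets.  The generator emulates the
# benchmark currency: per-species energy components with natural-occupancy
# spectra whose dynamic fraction r_D hits a sampled target, and reactions
# whose references are model energies plus Gaussian noise.

# r_D of a spectrum made of one weak pair (1-u, u) and one strong pair
# (1-v, v) per spin channel (either may be absent)
pair_r_d <- function(u, v) {
  x <- c(u * (1 - u), v * (1 - v))
  x <- x[x > 0]
  if (!length(x)) return(1)
  1 - 2 * sum(x) / sum(sqrt(x))
}

# occupancy pair layout hitting a target dynamic fraction: a weakly split
# pair carries dynamic character, a strongly split (near 0.5) pair carries
# nondynamic character
solve_pairs_for_rd <- function(r_d, u_weak = 0.02) {
  if (r_d < 0 || r_d > 1) stop("generation error: r_D target outside [0,1]")
  if (r_d >= 1 - 1e-12) return(c(u = 0, v = 0))        # idempotent limit
  if (abs(r_d) < 1e-12) return(c(u = 0, v = 0.5))      # pure diradical pair
  r_hi <- pair_r_d(u_weak, u_weak)
  r_lo <- pair_r_d(u_weak, 0.5)
  if (r_d > r_hi) {
    # very dynamic: two equal weak pairs, closed form 1 - 2 sqrt(u(1-u))
    x <- (1 - r_d)^2 / 4
    u <- (1 - sqrt(1 - 4 * x)) / 2
    return(c(u = u, v = u))
  }
  if (r_d < r_lo) {
    # very nondynamic: fixed 0.5 pair, shrink the weak pair
    u <- uniroot(function(u) pair_r_d(u, 0.5) - r_d,
                 c(1e-12, u_weak), tol = 1e-14)$root
    return(c(u = u, v = 0.5))
  }
  v <- uniroot(function(v) pair_r_d(u_weak, v) - r_d,
               c(u_weak, 0.5), tol = 1e-14)$root
  c(u = u_weak, v = v)
}

#' Generate synthetic species records
#'
#' For each species, constructs an occupancy spectrum whose dynamic fraction
#' `r_D` matches a target sampled from `r_d_range` (round-trip exact to the
#' root-finder tolerance), plus energy components sampled within the given
#' ranges (`E_OS`, `E_SS` non-positive).
#'
#' @param n_species number of species.
#' @param seed mandatory random seed.
#' @param r_d_range range of dynamic-fraction targets within `[0, 1]`.
#' @param e_hf_range,e_os_range,e_ss_range sampling ranges (hartree); the
#'   correlation ranges must be non-positive.
#' @param n_core_range range of doubly occupied core orbitals per species.
#' @return named list of `species_energies` with attached spectra and
#'   indices; labels `S001`, `S002`, ...
#' @export
gen_species <- function(n_species, seed, r_d_range = c(0.3, 0.95),
                        e_hf_range = c(-80, -1),
                        e_os_range = c(-0.6, -0.05),
                        e_ss_range = c(-0.25, -0.01),
                        n_core_range = c(1L, 6L)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(r_d_range[1] >= 0, r_d_range[2] <= 1,
            e_os_range[2] <= 0, e_ss_range[2] <= 0)
  set.seed(seed)
  out <- list()
  for (k in seq_len(n_species)) {
    target <- runif(1, r_d_range[1], r_d_range[2])
    pr <- solve_pairs_for_rd(target)
    ncore <- sample(seq(n_core_range[1], n_core_range[2]), 1)
    occ <- c(rep(1, ncore),
             if (pr["u"] > 0) c(1 - pr["u"], pr["u"]),
             if (pr["v"] > 0) c(1 - pr["v"], pr["v"]))
    spec <- occupancy_spectrum(occ, occ)
    idx <- correlation_indices(spec)
    if (abs(idx$r_D - target) > 1e-6 && target < 1 - 1e-9)
      stop(sprintf("generation error: r_D target %.8f unreachable (got %.8f)",
                   target, idx$r_D))
    sp <- species_energies(
      E_HF = runif(1, e_hf_range[1], e_hf_range[2]),
      E_OS = runif(1, e_os_range[1], e_os_range[2]),
      E_SS = runif(1, e_ss_range[1], e_ss_range[2]),
      indices = idx, label = sprintf("S%03d", k))
    sp$spectrum <- spec
    out[[sp$label]] <- sp
  }
  out
}

#' Generate a synthetic reaction set
#'
#' Builds random reactions over the given species (2 to 4 participants,
#' signed small-integer stoichiometries) whose reference energies are the
#' scaling-model energies under `params` plus Gaussian noise of standard
#' deviation `sigma` (kcal/mol).
#'
#' @param species named list from [gen_species()].
#' @param params a `scaling_params` used as the generating model.
#' @param n_reactions number of reactions.
#' @param sigma reference-noise standard deviation, kcal/mol.
#' @param seed mandatory random seed.
#' @param n_subsets number of subset labels to spread reactions over.
#' @return list with `species` and `reactions` (a `reaction_set`).
#' @export
gen_reactions <- function(species, params, n_reactions, sigma = 0, seed,
                          n_subsets = 3L) {
  if (missing(seed)) stop("seed is mandatory")
  if (sigma < 0) stop("sigma must be nonnegative")
  set.seed(seed)
  energies <- vapply(species, assemble_energy, 0, params = params)
  labs <- names(species)
  reactions <- vector("list", n_reactions)
  for (k in seq_len(n_reactions)) {
    m <- sample(2:4, 1)
    who <- sample(labs, m)
    nu <- sample(c(1, 2), m, replace = TRUE)
    nsign <- max(1, m %/% 2)
    nu[seq_len(nsign)] <- -nu[seq_len(nsign)]
    nu <- setNames(nu, who)
    rx <- reaction(sprintf("R%04d", k), nu, 0,
                   subset = sprintf("set%d", 1 + (k - 1) %% n_subsets))
    ref <- reaction_energy(rx, energies) + rnorm(1, 0, sigma)
    rx$reference_energy <- ref
    reactions[[k]] <- rx
  }
  structure(list(species = species, reactions = reactions),
            class = "reaction_set")
}
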