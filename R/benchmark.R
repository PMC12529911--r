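# Reaction-energy evaluation and benchmark error statistics: MAD, MAX, RMSD,
# WTMAD2, subset bookkeeping, and the multireference exclusion screen.

#' Reaction definition
#'
#' A signed stoichiometry over species labels, a reference energy in
#' kcal/mol, and a subset label.
#'
#' @param id reaction identifier.
#' @param stoichiometry named numeric vector, species label -> signed
#'   coefficient (products positive, reactants negative); single-species
#'   entries are allowed for atomization-style data points.
#' @param reference_energy reference value, kcal/mol.
#' @param subset subset label used by the weighted statistics.
#' @return A `reaction`.
#' @export
reaction <- function(id, stoichiometry, reference_energy, subset = "default") {
  stoichiometry <- unlist(stoichiometry)
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("stoichiometry must be a named vector")
  if (length(stoichiometry) > 1 &&
      !(any(stoichiometry > 0) && any(stoichiometry < 0)))
    stop("a multi-species reaction needs both positive and negative ",
         "coefficients")
  structure(list(id = id, stoichiometry = stoichiometry,
                 reference_energy = reference_energy, subset = subset),
            class = "reaction")
}

#' Reaction energy in kcal/mol
#'
#' `sum nu_s E_s` converted from hartree with 627.509474 kcal/mol.
#'
#' @param reaction a [reaction()].
#' @param energies named numeric vector or list, species label -> total
#'   energy in hartree.
#' @return energy in kcal/mol.
#' @export
reaction_energy <- function(reaction, energies) {
  nu <- reaction$stoichiometry
  missing <- setdiff(names(nu), names(energies))
  if (length(missing))
    stop("lookup error: no energy for species ",
         paste(missing, collapse = ", "))
  e <- unlist(energies)[names(nu)]
  sum(nu * e) * HARTREE_TO_KCAL
}

#' Benchmark error statistics
#'
#' Computes MAD (mean absolute deviation), MAX (largest absolute error),
#' RMSD, and WTMAD2, the weighted total MAD in which each subset's MAD is
#' weighted by its size and by `wt_constant / |dE|avg_i` where `|dE|avg_i`
#' is the mean absolute reference energy of the subset:
#' `WTMAD2 = (1/sum N_i) sum_i N_i (wt_constant/|dE|avg_i) MAD_i`.
#'
#' @param errors signed errors (computed - reference), kcal/mol.
#' @param subsets subset label per error (single label recycles).
#' @param reference_energies reference energies per data point, kcal/mol;
#'   needed to compute `|dE|avg_i` unless `dEavg` is supplied.
#' @param dEavg optional named vector of published subset averages
#'   `|dE|avg_i` overriding the computed ones.
#' @param wt_constant the weighting constant in kcal/mol (default 56.84, the
#'   all-subset average of `|dE|avg_i` in the reference benchmark).
#' @return An `error_report` with `MAD`, `MAX`, `RMSD`, `WTMAD2` and a
#'   per-subset table.
#' @export
error_stats <- function(errors, subsets = "default",
                        reference_energies = NULL, dEavg = NULL,
                        wt_constant = WTMAD2_REFERENCE_KCAL) {
  if (!length(errors)) stop("empty error set")
  subsets <- rep_len(as.character(subsets), length(errors))
  mad <- mean(abs(errors))
  mx <- max(abs(errors))
  rmsd <- sqrt(mean(errors^2))

  tab <- NULL
  wtmad2 <- NA_real_
  labs <- unique(subsets)
  avg <- setNames(rep(NA_real_, length(labs)), labs)
  if (!is.null(dEavg)) avg[names(dEavg)] <- dEavg
  if (!is.null(reference_energies)) {
    comp <- tapply(abs(reference_energies), subsets, mean)
    miss <- names(avg)[is.na(avg)]
    avg[miss] <- as.numeric(comp[miss])
  }
  avg <- avg[labs]
  if (!anyNA(avg)) {
    if (any(avg <= 0)) stop("subset |dE|avg must be positive")
    n_i <- tapply(errors, subsets, length)[labs]
    mad_i <- tapply(abs(errors), subsets, mean)[labs]
    wtmad2 <- sum(n_i * (wt_constant / avg) * mad_i) / sum(n_i)
    tab <- data.frame(subset = labs, N = as.integer(n_i),
                      MAD = as.numeric(mad_i), dEavg = as.numeric(avg),
                      row.names = NULL)
  }
  structure(list(MAD = mad, MAX = mx, RMSD = rmsd, WTMAD2 = wtmad2,
                 subset_table = tab, n = length(errors)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error report over %d data points (kcal/mol):\n", x$n))
  cat(sprintf("  MAD  %8.3f\n  MAX  %8.3f\n  RMSD %8.3f\n", x$MAD, x$MAX,
              x$RMSD))
  if (!is.na(x$WTMAD2)) cat(sprintf("  WTMAD2 %6.3f\n", x$WTMAD2))
  invisible(x)
}

#' Export an error report as CSV
#' @param report an `error_report`.
#' @param path output path.
#' @export
write_report_csv <- function(report, path) {
  top <- data.frame(subset = "(all)", N = report$n, MAD = report$MAD,
                    MAX = report$MAX, RMSD = report$RMSD,
                    WTMAD2 = report$WTMAD2)
  if (!is.null(report$subset_table)) {
    st <- report$subset_table
    st$MAX <- NA; st$RMSD <- NA; st$WTMAD2 <- NA
    top <- rbind(top, st[, c("subset", "N", "MAD", "MAX", "RMSD", "WTMAD2")])
  }
  write.csv(top, path, row.names = FALSE)
  invisible(path)
}

#' Multireference exclusion screen
#'
#' Drops every reaction containing a species whose single-orbital
#' nondynamic diagnostic `I_ND_max` exceeds the threshold (default 0.030),
#' and reports which species triggered each exclusion.
#'
#' @param indices named list, species label -> `correlation_indices`.
#' @param reactions list of [reaction()] objects.
#' @param threshold diagnostic threshold.
#' @return list with `kept` (surviving reactions), `dropped`, and
#'   `exclusion_log` (data frame of reaction, species, diagnostic value).
#' @export
multiref_filter <- function(indices, reactions, threshold = 0.030) {
  log <- list()
  keep <- logical(length(reactions))
  for (k in seq_along(reactions)) {
    rx <- reactions[[k]]
    labs <- names(rx$stoichiometry)
    missing <- setdiff(labs, names(indices))
    if (length(missing))
      stop("validation error: no indices for species ",
           paste(missing, collapse = ", "))
    vals <- vapply(indices[labs], `[[`, 0, "I_ND_max")
    bad <- vals > threshold
    keep[k] <- !any(bad)
    if (any(bad))
      log[[length(log) + 1]] <- data.frame(
        reaction = rx$id, species = labs[bad], I_ND_max = vals[bad],
        row.names = NULL)
  }
  list(kept = reactions[keep], dropped = reactions[!keep],
       exclusion_log = if (length(log)) do.call(rbind, log) else
         data.frame(reaction = character(0), species = character(0),
                    I_ND_max = numeric(0)))
}

#' Evaluate a scaling model over a reaction set
#'
#' Computes per-reaction signed errors (computed - reference, kcal/mol) of a
#' scaling model and the resulting statistics.
#'
#' @param rset a `reaction_set` (see [read_reaction_set()]) or list with
#'   `species` (named list of `species_energies`) and `reactions`.
#' @param params a `scaling_params`.
#' @param filter_multiref optional `I_ND_max` threshold; reactions with a
#'   flagged species are excluded before the statistics.
#' @param exclude_subsets optional character vector of subset labels to
#'   drop.
#' @param dEavg,wt_constant passed to [error_stats()].
#' @return list with the `error_report`, the per-reaction error vector, and
#'   the exclusion log if filtering was requested.
#' @export
evaluate_model <- function(rset, params, filter_multiref = NULL,
                           exclude_subsets = NULL, dEavg = NULL,
                           wt_constant = WTMAD2_REFERENCE_KCAL) {
  reactions <- rset$reactions
  if (!is.null(exclude_subsets))
    reactions <- Filter(function(r) !(r$subset %in% exclude_subsets),
                        reactions)
  excl <- NULL
  if (!is.null(filter_multiref)) {
    idx <- lapply(rset$species, `[[`, "indices")
    flt <- multiref_filter(idx, reactions, threshold = filter_multiref)
    reactions <- flt$kept
    excl <- flt$exclusion_log
  }
  if (!length(reactions)) stop("no reactions left to evaluate")
  energies <- vapply(rset$species, assemble_energy, 0, params = params)
  errs <- vapply(reactions, function(rx)
    reaction_energy(rx, energies) - rx$reference_energy, 0)
  subsets <- vapply(reactions, `[[`, "", "subset")
  refs <- vapply(reactions, `[[`, 0, "reference_energy")
  rep <- error_stats(errs, subsets, reference_energies = refs, dEavg = dEavg,
                     wt_constant = wt_constant)
  list(report = rep, errors = setNames(errs, vapply(reactions, `[[`, "",
                                                    "id")),
       exclusion_log = excl, n_evaluated = length(reactions))
}
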