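# JSON interchange: per-species records (energy components + occupancies)
# and reaction-set files.

#' Compute a species record for a molecule
#'
#' Runs the full engine pipeline (RHF, MP2 components, unrelaxed natural
#' occupancies, correlation indices) and returns the portable record.
#'
#' @param mol a `molecule`.
#' @param basis basis-set name.
#' @param frozen_core logical.
#' @param label species label (defaults to the element string).
#' @return list with class `species_record`.
#' @export
compute_species_record <- function(mol, basis, frozen_core = FALSE,
                                   label = NULL) {
  scf <- run_rhf(mol, basis)
  mp2 <- mp2_components(scf, frozen_core = frozen_core)
  spec <- unrelaxed_occupancies(scf, mp2)
  if (is.null(label)) label <- paste(mol$atoms, collapse = "")
  structure(list(label = label, E_HF_hartree = scf$E_HF,
                 E_OS_hartree = mp2$E_OS, E_SS_hartree = mp2$E_SS,
                 occupancies = list(alpha = spec$alpha, beta = spec$beta),
                 basis = scf$basis_label, frozen_core = frozen_core),
            class = "species_record")
}

#' Write a species record as JSON
#' @param record a `species_record` (or compatible list).
#' @param path output path.
#' @export
write_species_record <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a species record from JSON
#' @param path JSON file written by [write_species_record()].
#' @return A `species_record`.
#' @export
read_species_record <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(r, class = "species_record")
}

# promote a record to the in-memory species representation
record_to_species <- function(record) {
  spec <- NULL
  if (!is.null(record$occupancies) &&
      length(record$occupancies$alpha))
    spec <- occupancy_spectrum(record$occupancies$alpha,
                               record$occupancies$beta)
  sp <- species_energies(record$E_HF_hartree, record$E_OS_hartree,
                         record$E_SS_hartree,
                         indices = if (is.null(spec)) NULL else
                           correlation_indices(spec),
                         label = record$label)
  sp$spectrum <- spec
  sp
}

#' Write a reaction set as JSON
#'
#' Schema: `subsets` (name and optional published `dEavg`), `species`
#' (inline records), `reactions` (id, subset, named stoichiometry,
#' `reference_kcal`).
#'
#' @param rset a `reaction_set` (list with `species`, `reactions`, optional
#'   `subsets`).
#' @param path output path.
#' @export
write_reaction_set <- function(rset, path) {
  species <- lapply(rset$species, function(s) {
    rec <- list(label = s$label, E_HF_hartree = s$E_HF,
                E_OS_hartree = s$E_OS, E_SS_hartree = s$E_SS)
    if (!is.null(s$spectrum))
      rec$occupancies <- list(alpha = s$spectrum$alpha,
                              beta = s$spectrum$beta)
    rec
  })
  reactions <- lapply(rset$reactions, function(r)
    list(id = r$id, subset = r$subset,
         stoichiometry = as.list(r$stoichiometry),
         reference_kcal = r$reference_energy))
  out <- list(subsets = rset$subsets, species = unname(species),
              reactions = reactions)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a reaction set from JSON
#' @param path JSON file in the [write_reaction_set()] schema.
#' @return A `reaction_set` with `species` (as `species_energies` with
#'   indices) and `reactions`.
#' @export
read_reaction_set <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  species <- list()
  for (rec in raw$species) {
    if (!is.null(rec$occupancies))
      rec$occupancies <- lapply(rec$occupancies, function(x)
        as.numeric(unlist(x)))
    sp <- record_to_species(rec)
    species[[sp$label]] <- sp
  }
  reactions <- lapply(raw$reactions, function(r)
    reaction(r$id, unlist(r$stoichiometry), r$reference_kcal,
             subset = if (is.null(r$subset)) "default" else r$subset))
  subsets <- raw$subsets
  structure(list(species = species, reactions = reactions,
                 subsets = subsets), class = "reaction_set")
}
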