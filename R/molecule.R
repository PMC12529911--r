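ELEMENT_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10)

#' Molecular geometry
#'
#' Constructs a molecule from element symbols and Cartesian coordinates in
#' angstrom.  The electronic-structure engine supports closed-shell species
#' only (singlet multiplicity, even electron count).
#'
#' @param atoms character vector of element symbols (H through Ne).
#' @param coordinates numeric matrix, one row per atom, columns x/y/z in
#'   angstrom.
#' @param charge integer total charge.
#' @param multiplicity integer spin multiplicity; the restricted engine
#'   requires 1.
#' @return An object of class `molecule`.
#' @export
molecule <- function(atoms, coordinates, charge = 0L, multiplicity = 1L) {
  atoms <- as.character(atoms)
  if (!all(atoms %in% names(ELEMENT_Z)))
    stop("unknown element symbol(s): ",
         paste(setdiff(atoms, names(ELEMENT_Z)), collapse = ", "))
  coordinates <- matrix(as.numeric(coordinates), ncol = 3)
  if (nrow(coordinates) != length(atoms))
    stop("coordinates must have one row per atom")
  if (!all(is.finite(coordinates)))
    stop("coordinates must be finite")
  structure(
    list(atoms = atoms, coordinates = coordinates,
         charge = as.integer(charge), multiplicity = as.integer(multiplicity)),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms, charge %d, multiplicity %d\n",
              length(x$atoms), x$charge, x$multiplicity))
  for (i in seq_along(x$atoms))
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$atoms[i],
                x$coordinates[i, 1], x$coordinates[i, 2], x$coordinates[i, 3]))
  invisible(x)
}

#' Number of electrons of a molecule
#' @param mol a `molecule`.
#' @return integer electron count.
#' @export
n_electrons <- function(mol) {
  sum(ELEMENT_Z[mol$atoms]) - mol$charge
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: atom count, comment line, then `element x y z` rows in
#' angstrom.  Charge and multiplicity may be embedded in the comment line as
#' `charge=<int> multiplicity=<int>`; they default to 0 and 1.
#'
#' @param path file path.
#' @return A `molecule`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  comment <- if (length(lines) >= 2) lines[2] else ""
  charge <- 0L; mult <- 1L
  m <- regmatches(comment, regexec("charge=(-?[0-9]+)", comment))[[1]]
  if (length(m) == 2) charge <- as.integer(m[2])
  m <- regmatches(comment, regexec("multiplicity=([0-9]+)", comment))[[1]]
  if (length(m) == 2) mult <- as.integer(m[2])
  rows <- strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+")
  atoms <- vapply(rows, `[[`, "", 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  molecule(atoms, xyz, charge = charge, multiplicity = mult)
}

#' Write a molecule to an XYZ file
#' @param mol a `molecule`.
#' @param path output file path.
#' @param comment optional comment line; charge/multiplicity are appended.
#' @export
write_xyz <- function(mol, path, comment = "") {
  n <- length(mol$atoms)
  comment <- sprintf("%s charge=%d multiplicity=%d", comment, mol$charge,
                     mol$multiplicity)
  lines <- c(as.character(n), trimws(comment),
             sprintf("%-2s %14.8f %14.8f %14.8f", mol$atoms,
                     mol$coordinates[, 1], mol$coordinates[, 2],
                     mol$coordinates[, 3]))
  writeLines(lines, path)
  invisible(path)
}

# named fixture geometries (angstrom); experimental equilibrium bond lengths
# for the diatomics, a standard gas-phase water geometry, and the helium-dimer
# van der Waals separation.
FIXTURE_GEOMETRIES <- list(
  H = list(atoms = "H", xyz = matrix(0, 1, 3), mult = 2L),
  H2 = list(atoms = c("H", "H"),
            xyz = rbind(c(0, 0, 0), c(0, 0, 0.7414))),
  He = list(atoms = "He", xyz = matrix(0, 1, 3)),
  He2 = list(atoms = c("He", "He"),
             xyz = rbind(c(0, 0, 0), c(0, 0, 2.97))),
  LiH = list(atoms = c("Li", "H"),
             xyz = rbind(c(0, 0, 0), c(0, 0, 1.5957))),
  LiH_stretched = list(atoms = c("Li", "H"),
                       xyz = rbind(c(0, 0, 0), c(0, 0, 2 * 1.5957))),
  H2O = list(atoms = c("O", "H", "H"),
             xyz = rbind(c(0, 0, 0.1173),
                         c(0, 0.7572, -0.4692),
                         c(0, -0.7572, -0.4692)))
)

#' Named molecular fixtures
#'
#' Equilibrium geometries used throughout the package: H2 at 0.7414 A, LiH at
#' 1.5957 A (and twice that for the stretched case), He2 at 2.97 A, the He
#' atom, and water.  A bond-length override is accepted for the diatomics.
#'
#' @param name one of `"H2"`, `"He"`, `"He2"`, `"LiH"`, `"LiH_stretched"`,
#'   `"H2O"`, `"H"`.
#' @param bond_length optional bond length in angstrom overriding the default
#'   (diatomics only).
#' @return A `molecule`.
#' @export
molecule_fixture <- function(name, bond_length = NULL) {
  if (!name %in% names(FIXTURE_GEOMETRIES))
    stop("unknown fixture: ", name)
  g <- FIXTURE_GEOMETRIES[[name]]
  xyz <- g$xyz
  if (!is.null(bond_length)) {
    if (nrow(xyz) != 2) stop("bond_length override requires a diatomic")
    xyz[2, 3] <- bond_length
  }
  molecule(g$atoms, xyz, multiplicity = if (is.null(g$mult)) 1L else g$mult)
}
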