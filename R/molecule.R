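# Molecule container and XYZ input/output.
#
# Coordinates are stored as one flat numeric vector of length 3N in Bohr,
# atom-major (atom 1 x,y,z; atom 2 x,y,z; ...). Every 3N-indexed object in the
# package (Hessians, dipole gradients, mode vectors) uses this one ordering.

#' Create a molecule
#'
#' @param symbols character vector of element symbols, length N.
#' @param coords Cartesian coordinates in Bohr: either a flat numeric vector of
#'   length 3N (atom-major) or an N x 3 matrix.
#' @param masses per-atom masses in amu; defaults to [atomic_mass()] of the
#'   symbols.
#' @param charge total molecular charge (integer, metadata only).
#' @return Object of class `"molecule"`: list with `symbols`, `masses`,
#'   `coords` (flat 3N, Bohr) and `charge`.
#' @examples
#' molecule(c("O", "H", "H"),
#'          rbind(c(0, 0, 0), c(1.8, 0, 0), c(-0.45, 1.75, 0)))
#' @export
molecule <- function(symbols, coords, masses = NULL, charge = 0L) {
  stopifnot(is.character(symbols), length(symbols) >= 1)
  n <- length(symbols)
  if (is.matrix(coords)) {
    stopifnot(ncol(coords) == 3, nrow(coords) == n)
    coords <- as.numeric(t(coords))
  }
  coords <- as.numeric(coords)
  if (length(coords) != 3 * n) {
    stop("coords must have length 3*N (or be an N x 3 matrix)", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  if (is.null(masses)) masses <- atomic_mass(symbols)
  masses <- as.numeric(masses)
  if (length(masses) != n) stop("length(masses) != length(symbols)", call. = FALSE)
  if (!all(is.finite(masses) & masses > 0)) stop("masses must be positive", call. = FALSE)
  structure(list(symbols = symbols, masses = masses, coords = coords,
                 charge = as.integer(charge)),
            class = "molecule")
}

#' Number of atoms in a molecule
#' @param mol a [molecule()].
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) length(mol$symbols)

#' Coordinates as an N x 3 matrix
#' @param mol a [molecule()].
#' @param unit `"bohr"` (internal) or `"angstrom"`.
#' @return N x 3 numeric matrix.
#' @export
coords_matrix <- function(mol, unit = c("bohr", "angstrom")) {
  unit <- match.arg(unit)
  m <- matrix(mol$coords, ncol = 3, byrow = TRUE)
  if (unit == "angstrom") m <- convert_units(m, "bohr", "angstrom")
  dimnames(m) <- list(mol$symbols, c("x", "y", "z"))
  m
}

#' Replace the coordinates of a molecule
#' @param mol a [molecule()].
#' @param coords flat 3N vector or N x 3 matrix, Bohr.
#' @return New molecule with identical symbols/masses/charge.
#' @export
set_coords <- function(mol, coords) {
  molecule(mol$symbols, coords, masses = mol$masses, charge = mol$charge)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atoms, charge %d\n", n_atoms(x), x$charge))
  print(round(coords_matrix(x, "angstrom"), 6))
  invisible(x)
}

#' Read a molecule from a standard XYZ file
#'
#' Standard XYZ layout: atom count line, comment line, then `symbol x y z`
#' rows with coordinates in Angstrom. Blank trailing lines are tolerated, as
#' are integer-formatted coordinates. Coordinates are converted to Bohr on
#' read.
#'
#' @param path file path.
#' @return A [molecule()]; the comment line is kept as attribute `"comment"`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("malformed XYZ (", path, "): fewer than 2 lines", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop("malformed XYZ (", path, "), line 1: expected atom count", call. = FALSE)
  }
  if (length(lines) < 2 + n) {
    stop("malformed XYZ (", path, "): expected ", n, " atom lines", call. = FALSE)
  }
  symbols <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- 2 + i
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4) {
      stop("malformed XYZ (", path, "), line ", ln, ": expected 'symbol x y z'",
           call. = FALSE)
    }
    symbols[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v)) {
      stop("malformed XYZ (", path, "), line ", ln, ": non-numeric coordinate",
           call. = FALSE)
    }
    xyz[i, ] <- v
  }
  extra <- lines[-seq_len(2 + n)]
  if (any(nzchar(trimws(extra)))) {
    stop("malformed XYZ (", path, "), line ", 2 + n + which(nzchar(trimws(extra)))[1],
         ": unexpected content after atom block", call. = FALSE)
  }
  mol <- molecule(symbols, convert_units(xyz, "angstrom", "bohr"))
  attr(mol, "comment") <- lines[2]
  mol
}

#' Write a molecule to a standard XYZ file
#'
#' Coordinates are written in Angstrom with fixed-width 10-decimal floats.
#'
#' @param mol a [molecule()].
#' @param path output path.
#' @param comment comment line content.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, comment = "") {
  xyz <- coords_matrix(mol, "angstrom")
  rows <- sprintf("%-3s %16.10f %16.10f %16.10f",
                  mol$symbols, xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(as.character(n_atoms(mol)), comment, rows), path)
  invisible(path)
}

# Center of mass, Bohr (flat 3-vector).
.center_of_mass <- function(mol) {
  x <- coords_matrix(mol)
  colSums(x * mol$masses) / sum(mol$masses)
}

#' Test whether a molecule is linear
#'
#' Uses the principal moments of inertia: the molecule is linear when the
#' smallest moment is below `tol` times the largest (and for diatomics
#' trivially).
#'
#' @param mol a [molecule()].
#' @param tol relative moment-of-inertia threshold (default 1e-8).
#' @return Logical.
#' @export
is_linear <- function(mol, tol = 1e-8) {
  n <- n_atoms(mol)
  if (n <= 2) return(TRUE)
  x <- sweep(coords_matrix(mol), 2, .center_of_mass(mol))
  m <- mol$masses
  I <- matrix(0, 3, 3)
  r2 <- rowSums(x^2)
  for (a in 1:3) for (b in 1:3) {
    I[a, b] <- sum(m * ((a == b) * r2 - x[, a] * x[, b]))
  }
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  min(ev) < tol * max(ev)
}
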