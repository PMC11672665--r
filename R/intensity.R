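# Dipole-moment derivatives and double-harmonic IR intensities.
#
# The Cartesian dipole gradient D (3N x 3, atomic units) is assembled by
# central differences of the molecular dipole, then contracted with the
# mass-back-transformed normal-mode vectors to per-mode derivatives dmu/dQ_p;
# the integral absorption coefficient is proportional to |dmu/dQ_p|^2.

#' Seminumerical dipole gradient from a dipole-capable calculator
#'
#' Central differences of the dipole per Cartesian coordinate:
#' row i is `(mu(x + step e_i) - mu(x - step e_i)) / (2 step)`. Costs exactly
#' 6N dipole evaluations — the same count as the seminumerical Hessian.
#'
#' @param calc a dipole-capable [new_calculator()].
#' @param mol a [molecule()].
#' @param step displacement in Bohr (default 1e-3; may differ from the
#'   Hessian step).
#' @return 3N x 3 matrix `D` with `D[i, alpha] = dmu_alpha/dx_i` in atomic
#'   units; attributes `provenance = "seminumerical"` and `step`.
#' @export
seminumerical_dipole_gradient <- function(calc, mol, step = 1e-3) {
  if (!("dipole" %in% calc_capabilities(calc))) {
    stop("calculator '", calc$name, "' does not provide dipoles", call. = FALSE)
  }
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  x0 <- mol$coords
  n3 <- length(x0)
  D <- matrix(0, n3, 3)
  for (i in seq_len(n3)) {
    xp <- x0; xp[i] <- xp[i] + step
    xm <- x0; xm[i] <- xm[i] - step
    mp <- calc_dipole(calc, set_coords(mol, xp))
    mm <- calc_dipole(calc, set_coords(mol, xm))
    if (!all(is.finite(mp)) || !all(is.finite(mm))) {
      stop("non-finite dipole at displacement of coordinate ", i,
           " (atom ", ceiling(i / 3), ", ", c("x", "y", "z")[(i - 1) %% 3 + 1],
           ")", call. = FALSE)
    }
    D[i, ] <- (mp - mm) / (2 * step)
  }
  attr(D, "provenance") <- "seminumerical"
  attr(D, "step") <- step
  D
}

#' Project a Cartesian dipole gradient onto normal modes
#'
#' `dmu_alpha/dQ_p = sum_i D[i, alpha] Q[i, p] / sqrt(m_i)`: the Cartesian
#' dipole gradient contracted with the mass-back-transformed mode vector
#' (mode columns of the mass-weighted FCM scaled by `m^{-1/2}`). With the
#' internal units used here (e for D, amu for m), the result is in
#' e/sqrt(amu), the unit the km/mol conversion of [intensities()] expects.
#'
#' @param D 3N x 3 Cartesian dipole gradient (atomic units).
#' @param modes a [normal_modes()] result for the same molecule.
#' @param mol the [molecule()] supplying the masses.
#' @return `n_modes` x 3 matrix of per-mode dipole derivatives (rows follow
#'   the mode ordering of `modes`).
#' @export
project_dipole_gradient <- function(D, modes, mol) {
  n3 <- 3 * n_atoms(mol)
  if (!is.matrix(D) || nrow(D) != n3 || ncol(D) != 3) {
    stop("D must be a 3N x 3 matrix matching the molecule", call. = FALSE)
  }
  if (nrow(modes$modes) != n3) {
    stop("normal modes do not match the molecule dimension", call. = FALSE)
  }
  s <- 1 / sqrt(rep(mol$masses, each = 3))
  t(crossprod(D, modes$modes * s))      # n_modes x 3
}

#' Double-harmonic IR intensities
#'
#' Integral absorption coefficient per mode,
#' `A_p = N_A/(12 eps0 c^2) |dmu/dQ_p|^2`, expressed in km/mol (the numeric
#' conversion for derivatives in e/sqrt(amu) is about 974.9 km/mol, derived
#' from CODATA constants; see [spectroscopy_constants()]).
#'
#' @param mode_derivs `n_modes` x 3 matrix from [project_dipole_gradient()].
#' @return Named list with `intensities` (km/mol, non-negative) and
#'   `dmudq2` (raw squared derivatives, (e/sqrt(amu))^2), both per mode.
#' @export
intensities <- function(mode_derivs) {
  if (!is.matrix(mode_derivs) || ncol(mode_derivs) != 3) {
    stop("mode_derivs must be an n_modes x 3 matrix", call. = FALSE)
  }
  d2 <- rowSums(mode_derivs^2)
  list(intensities = d2 * .const$dmudq2_to_kmmol, dmudq2 = d2)
}

# ---------------------------------------------------------------------------
# Dipole-derivative file I/O: '#' comments, 'N <atoms>' header, 3N rows of
# 3 floats (dmu_x dmu_y dmu_z per Cartesian coordinate, atom-major, a.u.).

#' Read a dipole-derivative matrix from a text file
#' @param path file path.
#' @return 3N x 3 matrix (atomic units) with `# key value` comment lines in
#'   attribute `"metadata"`.
#' @export
read_dipole_gradient <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- .parse_hash_metadata(lines)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hd) != 2 || hd[1] != "N") {
    stop("malformed dipole-derivative file (", path, "), line 1: expected 'N <atoms>'",
         call. = FALSE)
  }
  n3 <- 3 * as.integer(hd[2])
  if (length(lines) - 1 != n3) {
    stop("malformed dipole-derivative file (", path, "): expected ", n3, " rows",
         call. = FALSE)
  }
  D <- matrix(NA_real_, n3, 3)
  for (r in seq_len(n3)) {
    v <- as.numeric(strsplit(trimws(lines[1 + r]), "\\s+")[[1]])
    if (length(v) != 3 || anyNA(v)) {
      stop("malformed dipole-derivative file (", path, "), row ", r, call. = FALSE)
    }
    D[r, ] <- v
  }
  attr(D, "metadata") <- meta
  D
}

#' Write a dipole-derivative matrix to a text file
#' @param D 3N x 3 matrix (atomic units).
#' @param path output path.
#' @param metadata optional named vector written as `# key value` lines.
#' @return `path`, invisibly.
#' @export
write_dipole_gradient <- function(D, path, metadata = NULL) {
  if (!is.matrix(D) || ncol(D) != 3 || nrow(D) %% 3 != 0) {
    stop("D must be a 3N x 3 matrix", call. = FALSE)
  }
  hdr <- c(.format_hash_metadata(metadata), sprintf("N %d", nrow(D) %/% 3))
  rows <- apply(D, 1, function(r) paste(sprintf("%22.14e", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
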