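# Seminumerical Hessian, mass weighting, rigid-motion projection and normal
# modes.
#
# The Hessian H (second derivatives of the energy w.r.t. Cartesian nuclear
# coordinates, Eh/a0^2) is assembled column-wise by two-sided finite
# differences of analytic gradients. Mass weighting with M^{-1/2} H M^{-1/2}
# gives the force-constant matrix (FCM) whose eigenvectors are the normal
# modes and whose eigenvalues convert to wavenumbers.

#' Seminumerical Hessian from a gradient-capable calculator
#'
#' Two-sided (central) finite differences of the gradient: column i is
#' `(g(x + step e_i) - g(x - step e_i)) / (2 step)`. The result is
#' symmetrized as `(H + H^T)/2` (finite-difference asymmetry is numerical
#' noise). Costs exactly 6N gradient evaluations for N atoms.
#'
#' @param calc a gradient-capable [new_calculator()].
#' @param mol a [molecule()].
#' @param step displacement in Bohr (default 1e-3).
#' @return 3N x 3N symmetric matrix in Hartree/Bohr^2, attributes
#'   `provenance = "seminumerical"` and `step`.
#' @export
seminumerical_hessian <- function(calc, mol, step = 1e-3) {
  if (!("gradient" %in% calc_capabilities(calc))) {
    stop("calculator '", calc$name, "' does not provide gradients", call. = FALSE)
  }
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  x0 <- mol$coords
  n3 <- length(x0)
  H <- matrix(0, n3, n3)
  for (i in seq_len(n3)) {
    xp <- x0; xp[i] <- xp[i] + step
    xm <- x0; xm[i] <- xm[i] - step
    gp <- calc_gradient(calc, set_coords(mol, xp))
    gm <- calc_gradient(calc, set_coords(mol, xm))
    if (!all(is.finite(gp)) || !all(is.finite(gm))) {
      stop("non-finite gradient at displacement of coordinate ", i,
           " (atom ", ceiling(i / 3), ", ", c("x", "y", "z")[(i - 1) %% 3 + 1],
           ")", call. = FALSE)
    }
    H[, i] <- (gp - gm) / (2 * step)
  }
  H <- (H + t(H)) / 2
  attr(H, "provenance") <- "seminumerical"
  attr(H, "step") <- step
  H
}

#' Mass-weight a Hessian into the force-constant matrix
#'
#' `F_ij = H_ij / sqrt(m_i m_j)` with each atom's mass repeated for its three
#' Cartesian coordinates. Units: Eh / (a0^2 amu).
#'
#' @param H symmetric 3N x 3N Hessian (Eh/a0^2).
#' @param mol a [molecule()] supplying the masses.
#' @return 3N x 3N symmetric mass-weighted FCM.
#' @export
mass_weight <- function(H, mol) {
  m3 <- rep(mol$masses, each = 3)
  if (nrow(H) != length(m3)) stop("Hessian dimension does not match molecule", call. = FALSE)
  s <- 1 / sqrt(m3)
  F <- H * outer(s, s)
  attributes(F)[c("provenance", "step")] <- attributes(H)[c("provenance", "step")]
  F
}

# Orthonormal basis of mass-weighted rigid-body (translation + rotation)
# directions. Rotations about principal axes with near-zero norm (linear
# molecules) are dropped.
.rigid_basis <- function(mol) {
  n <- n_atoms(mol)
  m <- mol$masses
  x <- sweep(coords_matrix(mol), 2, .center_of_mass(mol))
  sm <- sqrt(m)
  vecs <- list()
  for (a in 1:3) {                      # translations
    v <- matrix(0, n, 3); v[, a] <- sm
    vecs[[length(vecs) + 1]] <- as.numeric(t(v))
  }
  for (a in 1:3) {                      # rotations: e_a x (r - com), mass-weighted
    e <- numeric(3); e[a] <- 1
    v <- t(vapply(seq_len(n), function(j) {
      c(e[2] * x[j, 3] - e[3] * x[j, 2],
        e[3] * x[j, 1] - e[1] * x[j, 3],
        e[1] * x[j, 2] - e[2] * x[j, 1]) * sm[j]
    }, numeric(3)))
    vecs[[length(vecs) + 1]] <- as.numeric(t(v))
  }
  B <- do.call(cbind, vecs)
  # Gram-Schmidt with rank filtering (linear molecules lose one rotation).
  keep <- NULL
  scale0 <- sqrt(sum(B[, 1]^2))
  for (j in seq_len(ncol(B))) {
    v <- B[, j]
    if (!is.null(keep)) v <- v - keep %*% crossprod(keep, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8 * scale0) keep <- cbind(keep, v / nv)
  }
  keep
}

#' Project rigid-body motions out of a force-constant matrix
#'
#' Builds an Eckart-style projector from the mass-weighted translation and
#' rotation vectors and applies `P F P`. The 3 translational and 3 (2 for
#' linear molecules) rotational directions then span the null space of the
#' projected matrix; the corresponding near-zero modes are excluded from
#' spectra and ZPVE downstream.
#'
#' @param F symmetric mass-weighted FCM.
#' @param mol a [molecule()].
#' @return Projected FCM with attribute `n_rigid` (number of projected
#'   directions: 6, or 5 for linear molecules).
#' @export
project_rigid_motions <- function(F, mol) {
  B <- .rigid_basis(mol)
  P <- diag(nrow(F)) - tcrossprod(B)
  Fp <- P %*% F %*% P
  Fp <- (Fp + t(Fp)) / 2
  attributes(Fp)[c("provenance", "step")] <- attributes(F)[c("provenance", "step")]
  attr(Fp, "n_rigid") <- ncol(B)
  Fp
}

#' Diagonalize a force-constant matrix into normal modes
#'
#' Eigendecomposition of the (symmetric) mass-weighted FCM. Eigenvalues are
#' returned ascending with orthonormal mode columns; each eigenvalue is
#' converted to a signed wavenumber (imaginary modes appear as negative
#' numbers).
#'
#' @param F symmetric 3N x 3N mass-weighted FCM (Eh/(a0^2 amu)).
#' @param rigid_threshold modes with `|wavenumber|` below this (1/cm) are
#'   counted as rigid/near-zero (default 1).
#' @return Object of class `"normal_mode_set"`: list with `eigenvalues`,
#'   `wavenumbers` (signed, ascending in eigenvalue), `modes` (orthonormal
#'   columns), `n_rigid` (count below the threshold), `rigid_threshold` and
#'   `internal` (indices of internal modes, i.e. above threshold).
#' @export
normal_modes <- function(F, rigid_threshold = 1) {
  if (!is.matrix(F) || nrow(F) != ncol(F)) stop("F must be square", call. = FALSE)
  if (max(abs(F - t(F))) > 1e-10 * max(1, max(abs(F)))) {
    stop("F must be symmetric", call. = FALSE)
  }
  eig <- eigen((F + t(F)) / 2, symmetric = TRUE)
  ord <- order(eig$values)
  vals <- eig$values[ord]
  Q <- eig$vectors[, ord, drop = FALSE]
  wn <- eigenvalue_to_wavenumber(vals)
  rigid <- abs(wn) < rigid_threshold
  nm <- structure(list(
    eigenvalues = vals,
    wavenumbers = wn,
    modes = Q,
    n_rigid = sum(rigid),
    rigid_threshold = rigid_threshold,
    internal = which(!rigid)
  ), class = "normal_mode_set")
  if (any(wn[nm$internal] < 0)) {
    warning("imaginary frequencies present (reported as negative wavenumbers); ",
            "the structure must correspond to a minimum for a meaningful spectrum",
            call. = FALSE)
  }
  nm
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat(sprintf("<normal_mode_set> %d modes (%d rigid below %g 1/cm)\n",
              length(x$wavenumbers), x$n_rigid, x$rigid_threshold))
  cat("wavenumbers (1/cm):\n")
  print(round(x$wavenumbers, 2))
  invisible(x)
}

#' Convert FCM eigenvalues to signed wavenumbers
#'
#' `nu = sign(eps) sqrt(|eps|) C` with `C` the CODATA-derived conversion from
#' sqrt(Eh/(a0^2 amu)) to 1/cm. Negative eigenvalues (imaginary modes) map to
#' negative wavenumbers by convention.
#'
#' @param eps numeric vector of FCM eigenvalues in Eh/(a0^2 amu).
#' @return Signed wavenumbers in 1/cm.
#' @export
eigenvalue_to_wavenumber <- function(eps) {
  sign(eps) * sqrt(abs(eps)) * .const$sqrt_eig_to_rcm
}

#' Full vibrational analysis for one molecule
#'
#' Convenience pipeline: obtain the Hessian (from a calculator — analytic if
#' available and `prefer_analytic`, else seminumerical — or use a supplied
#' matrix), mass-weight, optionally project rigid motions, and diagonalize.
#'
#' @param mol a [molecule()].
#' @param calc calculator used when `hessian` is `NULL`.
#' @param hessian optional precomputed 3N x 3N Hessian (Eh/a0^2).
#' @param step finite-difference displacement in Bohr.
#' @param project project out rigid-body motions (default `TRUE`).
#' @param prefer_analytic use the calculator's analytic Hessian capability
#'   when present (default `FALSE`: seminumerical route).
#' @return A [normal_modes()] result with attribute `provenance`.
#' @export
vibrational_analysis <- function(mol, calc = NULL, hessian = NULL, step = 1e-3,
                                 project = TRUE, prefer_analytic = FALSE) {
  if (is.null(hessian)) {
    if (is.null(calc)) stop("either 'calc' or 'hessian' is required", call. = FALSE)
    hessian <- if (prefer_analytic && "hessian" %in% calc_capabilities(calc)) {
      calc_hessian(calc, mol)
    } else {
      seminumerical_hessian(calc, mol, step = step)
    }
  }
  F <- mass_weight(hessian, mol)
  if (project) F <- project_rigid_motions(F, mol)
  nm <- normal_modes(F)
  attr(nm, "provenance") <- attr(hessian, "provenance")
  nm
}

# ---------------------------------------------------------------------------
# Hessian file I/O
#
# Plain format: '#' comments, header line 'N <atom count>', then 3N rows of
# 3N whitespace-separated floats (Eh/a0^2, atom-major). The "dialect" format
# is a $hessian block (numbers wrapped freely until '$end' or EOF).

#' Read a Hessian matrix from a text file
#'
#' @param path file path.
#' @param format `"plain"` (default, `N`-header format) or `"dialect"`
#'   (`$hessian` block with free-wrapped numbers).
#' @return 3N x 3N matrix (Eh/a0^2); comment metadata lines of the form
#'   `# key value` are kept in attribute `"metadata"`.
#' @export
read_hessian <- function(path, format = c("plain", "dialect")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "dialect") {
    start <- grep("^\\s*\\$hessian", lines)
    if (!length(start)) stop("no $hessian block in ", path, call. = FALSE)
    body <- lines[(start[1] + 1):length(lines)]
    end <- grep("^\\s*\\$", body)
    if (length(end)) body <- body[seq_len(end[1] - 1)]
    vals <- as.numeric(unlist(strsplit(trimws(paste(body, collapse = " ")), "\\s+")))
    n3 <- sqrt(length(vals))
    if (n3 != round(n3)) {
      stop("$hessian block in ", path, " is not a square matrix", call. = FALSE)
    }
    return(matrix(vals, n3, n3, byrow = TRUE))
  }
  meta <- .parse_hash_metadata(lines)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hd) != 2 || hd[1] != "N") {
    stop("malformed Hessian file (", path, "), line 1: expected 'N <atoms>'",
         call. = FALSE)
  }
  n <- as.integer(hd[2]); n3 <- 3 * n
  if (length(lines) - 1 != n3) {
    stop("malformed Hessian file (", path, "): expected ", n3, " matrix rows",
         call. = FALSE)
  }
  H <- matrix(NA_real_, n3, n3)
  for (r in seq_len(n3)) {
    v <- as.numeric(strsplit(trimws(lines[1 + r]), "\\s+")[[1]])
    if (length(v) != n3 || anyNA(v)) {
      stop("malformed Hessian file (", path, "), matrix row ", r, call. = FALSE)
    }
    H[r, ] <- v
  }
  attr(H, "metadata") <- meta
  H
}

#' Write a Hessian matrix to a text file
#'
#' @param H 3N x 3N matrix (Eh/a0^2).
#' @param path output path.
#' @param metadata optional named character/numeric vector written as
#'   `# key value` comment lines.
#' @return `path`, invisibly.
#' @export
write_hessian <- function(H, path, metadata = NULL) {
  n3 <- nrow(H)
  if (n3 %% 3 != 0 || ncol(H) != n3) stop("H must be 3N x 3N", call. = FALSE)
  hdr <- c(.format_hash_metadata(metadata), sprintf("N %d", n3 %/% 3))
  rows <- apply(H, 1, function(r) paste(sprintf("%22.14e", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

.parse_hash_metadata <- function(lines) {
  cm <- lines[grepl("^\\s*#", lines)]
  cm <- sub("^\\s*#\\s*", "", cm)
  kv <- regmatches(cm, regexec("^(\\S+)\\s+(.*)$", cm))
  kv <- kv[vapply(kv, length, integer(1)) == 3]
  stats::setNames(vapply(kv, `[`, character(1), 3),
                  vapply(kv, `[`, character(1), 2))
}

.format_hash_metadata <- function(metadata) {
  if (is.null(metadata) || !length(metadata)) return(character(0))
  sprintf("# %s %s", names(metadata), vapply(metadata, as.character, character(1)))
}
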