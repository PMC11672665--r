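# Spectral similarity metrics and method-combination score matrices.
#
# All metrics operate on two broadened spectra evaluated on the identical
# grid. The matchscore r_msc is the Cauchy-Schwarz cosine-squared overlap,
# scale-invariant and bounded in [0, 1]; alternatives are a normalized
# Euclidean similarity and the Pearson/Spearman correlations of the grid
# intensities.

# Extract the grid intensity vector, checking grids match when both are
# spectra. Numeric vectors are accepted directly (assumed on a shared grid).
.grid_pair <- function(a, b) {
  gv <- function(s) {
    if (inherits(s, "ir_spectrum")) {
      if (is.null(s$grid)) stop("spectrum has no broadened grid; call broaden() first",
                                call. = FALSE)
      s$grid
    } else {
      list(wavenumber = NULL, absorbance = as.numeric(s))
    }
  }
  ga <- gv(a); gb <- gv(b)
  if (length(ga$absorbance) != length(gb$absorbance)) {
    stop("spectra are on different grids", call. = FALSE)
  }
  if (!is.null(ga$wavenumber) && !is.null(gb$wavenumber) &&
      !isTRUE(all.equal(ga$wavenumber, gb$wavenumber, tolerance = 1e-12))) {
    stop("spectra are on different grids", call. = FALSE)
  }
  list(a = ga$absorbance, b = gb$absorbance)
}

#' Cauchy-Schwarz spectral matchscore
#'
#' `r_msc = (sum a_i b_i)^2 / ((sum a_i^2)(sum b_i^2))`, the squared cosine
#' of the angle between the two intensity vectors. Bounded in [0, 1] by the
#' Cauchy-Schwarz inequality, equal to 1 iff the spectra are proportional,
#' and invariant under positive rescaling of either spectrum.
#'
#' @param a,b broadened [ir_spectrum()] objects on the identical grid (or
#'   plain numeric intensity vectors of equal length).
#' @return Scalar matchscore in [0, 1].
#' @examples
#' s <- broaden(ir_spectrum(1500, 1))
#' matchscore(s, s)
#' @export
matchscore <- function(a, b) {
  g <- .grid_pair(a, b)
  sa2 <- sum(g$a^2); sb2 <- sum(g$b^2)
  if (sa2 == 0 || sb2 == 0) {
    stop("matchscore undefined for an all-zero spectrum", call. = FALSE)
  }
  sum(g$a * g$b)^2 / (sa2 * sb2)
}

#' Alternative spectral similarity scores
#'
#' \describe{
#'   \item{euclidean}{`r_euc = 1 - ||a/||a|| - b/||b|||| / sqrt(2)`: the
#'     Euclidean distance between unit-normalized spectra mapped to [0, 1]
#'     (1 for identical spectra up to scale; the sqrt(2) bound holds for
#'     non-negative spectra).}
#'   \item{pearson}{Pearson correlation of grid intensities.}
#'   \item{spearman}{Spearman rank correlation with average-rank tie
#'     handling (grids contain many near-zero ties).}
#' }
#'
#' @param a,b broadened [ir_spectrum()] objects on the identical grid (or
#'   numeric vectors).
#' @param metric one of `"euclidean"`, `"pearson"`, `"spearman"`.
#' @return Scalar score (`euclidean` in [0, 1]; correlations in [-1, 1]).
#' @export
alt_scores <- function(a, b, metric = c("euclidean", "pearson", "spearman")) {
  metric <- match.arg(metric)
  g <- .grid_pair(a, b)
  if (metric == "euclidean") {
    na <- sqrt(sum(g$a^2)); nb <- sqrt(sum(g$b^2))
    if (na == 0 || nb == 0) {
      stop("euclidean similarity undefined for an all-zero spectrum", call. = FALSE)
    }
    return(1 - sqrt(sum((g$a / na - g$b / nb)^2)) / sqrt(2))
  }
  if (stats::sd(g$a) == 0 || stats::sd(g$b) == 0) {
    stop(metric, " correlation undefined for a constant spectrum", call. = FALSE)
  }
  stats::cor(g$a, g$b, method = metric)
}

#' Score all four similarity metrics at once
#' @inheritParams alt_scores
#' @return Named numeric vector `r_msc`, `r_euc`, `r_pcc`, `r_scc`.
#' @export
all_scores <- function(a, b) {
  c(r_msc = matchscore(a, b),
    r_euc = alt_scores(a, b, "euclidean"),
    r_pcc = alt_scores(a, b, "pearson"),
    r_scc = alt_scores(a, b, "spearman"))
}

#' Frequency-method x dipole-method combination score matrix
#'
#' For every pairing of a frequency source `f` (normal modes per molecule)
#' with a dipole source `d` (Cartesian dipole gradients per molecule, taken
#' at the same geometry), assembles the composite double-harmonic spectrum of
#' each molecule, broadens it, and scores it against the reference spectrum;
#' the cell holds the mean matchscore over the molecule set.
#'
#' @param freq_sources named list; each element is a list (one entry per
#'   molecule) of [normal_modes()] results.
#' @param dipole_sources named list; each element is a list of 3N x 3 dipole
#'   gradients.
#' @param reference list of reference [ir_spectrum()] objects (sticks; one
#'   per molecule).
#' @param molecules list of [molecule()] objects the modes/gradients refer
#'   to.
#' @param fwhm Lorentzian width for broadening (1/cm).
#' @param grid `c(from, to, by)` in 1/cm, shared by every comparison.
#' @param scale_factors optional named numeric vector of linear frequency
#'   scaling factors per frequency source (default 1).
#' @return List with `scores` (matrix, rows = frequency sources, columns =
#'   dipole sources), `per_molecule` (3-d array), and `best` (name pair of
#'   the arg-max cell).
#' @export
combination_matrix <- function(freq_sources, dipole_sources, reference,
                               molecules, fwhm = 30, grid = c(0, 4000, 1),
                               scale_factors = NULL) {
  n_mol <- length(molecules)
  bad <- c(
    names(freq_sources)[vapply(freq_sources, length, integer(1)) != n_mol],
    names(dipole_sources)[vapply(dipole_sources, length, integer(1)) != n_mol]
  )
  if (length(reference) != n_mol) bad <- c(bad, "reference")
  if (length(bad)) {
    stop("molecule-list mismatch for source(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fn <- names(freq_sources); dn <- names(dipole_sources)
  ref_grid <- lapply(reference, function(s) {
    broaden(s, fwhm = fwhm, from = grid[1], to = grid[2], by = grid[3])
  })
  per <- array(NA_real_, dim = c(length(fn), length(dn), n_mol),
               dimnames = list(fn, dn, NULL))
  for (f in fn) {
    sf <- if (!is.null(scale_factors) && f %in% names(scale_factors)) {
      scale_factors[[f]]
    } else 1
    for (d in dn) {
      for (m in seq_len(n_mol)) {
        spec <- mode_spectrum(freq_sources[[f]][[m]], dipole_sources[[d]][[m]],
                              molecules[[m]])
        spec <- scale_frequencies(spec, sf)
        spec <- broaden(spec, fwhm = fwhm, from = grid[1], to = grid[2],
                        by = grid[3])
        per[f, d, m] <- matchscore(spec, ref_grid[[m]])
      }
    }
  }
  scores <- apply(per, c(1, 2), mean)
  best_idx <- which(scores == max(scores), arr.ind = TRUE)[1, ]
  list(scores = scores, per_molecule = per,
       best = c(freq = fn[best_idx[1]], dipole = dn[best_idx[2]]))
}
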