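# Benchmark metrics: regularized dipole errors, dipole alignment, Kabsch
# RMSD, and the shared error-statistics engine (MD/MAE/RMSE/SD, threshold
# fractions, log-normal fits).

#' Regularized dipole-magnitude error
#'
#' `dmu = (|mu_test| - |mu_ref|) / max(|mu_ref|, 1 D)`: the signed difference
#' of dipole magnitudes, regularized by clamping the denominator at 1 Debye
#' so that tiny reference dipoles do not blow up the relative error. Signed
#' (magnitudes are differenced, not vectors), so batch mean deviations can be
#' negative.
#'
#' @param mu_test,mu_ref dipole 3-vectors in Debye.
#' @return Signed dimensionless error.
#' @examples
#' regularized_dipole_error(c(3, 0, 0), c(2, 0, 0))  # +0.5
#' @export
regularized_dipole_error <- function(mu_test, mu_ref) {
  nt <- sqrt(sum(mu_test^2)); nr <- sqrt(sum(mu_ref^2))
  (nt - nr) / max(nr, 1)
}

#' Dipole-orientation alignment
#'
#' Dot product of the normalized dipole vectors: 1 for perfect alignment,
#' negative values for opposite orientation.
#'
#' @param mu_test,mu_ref dipole 3-vectors (any common unit); both must be
#'   nonzero.
#' @return Cosine in [-1, 1].
#' @export
dipole_alignment <- function(mu_test, mu_ref) {
  nt <- sqrt(sum(mu_test^2)); nr <- sqrt(sum(mu_ref^2))
  if (nt == 0 || nr == 0) {
    stop("alignment undefined for a zero dipole vector", call. = FALSE)
  }
  sum(mu_test * mu_ref) / (nt * nr)
}

#' Compare two dipole vectors
#' @inheritParams regularized_dipole_error
#' @return List with `error` ([regularized_dipole_error()]) and `alignment`
#'   ([dipole_alignment()]).
#' @export
dipole_comparison <- function(mu_test, mu_ref) {
  list(error = regularized_dipole_error(mu_test, mu_ref),
       alignment = dipole_alignment(mu_test, mu_ref))
}

#' Minimum RMSD over rigid superpositions (Kabsch)
#'
#' Centers both structures on their centroids, finds the optimal rotation by
#' SVD of the cross-covariance (with the determinant correction against
#' improper rotations), and returns the root-mean-square deviation of matched
#' atoms. Assumes input atom correspondence: no graph matching or permutation
#' correction.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices in Angstrom, matching
#'   atom order.
#' @param symbols optional element symbols (length N), required for
#'   `exclude_h`.
#' @param exclude_h drop hydrogen atoms before superposition (default
#'   `FALSE`).
#' @return RMSD in Angstrom (>= 0).
#' @export
kabsch_rmsd <- function(coords_a, coords_b, symbols = NULL, exclude_h = FALSE) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3) {
    stop("coordinate sets must both be N x 3 with equal atom counts", call. = FALSE)
  }
  if (exclude_h) {
    if (is.null(symbols) || length(symbols) != nrow(coords_a)) {
      stop("exclude_h requires matching 'symbols'", call. = FALSE)
    }
    keep <- symbols != "H"
    if (!any(keep)) stop("no atoms left after excluding hydrogens", call. = FALSE)
    coords_a <- coords_a[keep, , drop = FALSE]
    coords_b <- coords_b[keep, , drop = FALSE]
  }
  A <- sweep(coords_a, 2, colMeans(coords_a))
  B <- sweep(coords_b, 2, colMeans(coords_b))
  s <- svd(crossprod(B, A))             # covariance of b against a
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((A - B %*% R)^2)))
}

#' Summary error statistics
#'
#' The table machinery shared by every benchmark: mean deviation (MD), mean
#' absolute error (MAE, a.k.a. MAD), root-mean-square error (RMSE), standard
#' deviation (SD, sample definition with n-1 denominator), plus mean and
#' median, over a vector of signed errors.
#'
#' @param values nonempty numeric vector of signed errors.
#' @return Object of class `"stat_summary"`: named list `MD`, `MAE`, `RMSE`,
#'   `SD`, `mean`, `median`, `n`.
#' @export
error_stats <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty value list", call. = FALSE)
  structure(list(
    MD = mean(values),
    MAE = mean(abs(values)),
    RMSE = sqrt(mean(values^2)),
    SD = if (length(values) > 1) stats::sd(values) else 0,
    mean = mean(values),
    median = stats::median(values),
    n = length(values)
  ), class = "stat_summary")
}

#' @export
print.stat_summary <- function(x, ...) {
  cat(sprintf("n=%d  MD=%.6g  MAE=%.6g  RMSE=%.6g  SD=%.6g  median=%.6g\n",
              x$n, x$MD, x$MAE, x$RMSE, x$SD, x$median))
  invisible(x)
}

#' Fraction of values passing inclusive thresholds
#'
#' Threshold conventions follow benchmark-table style: `"<=0.2"` counts
#' entries at or below 0.2, `">=0.5"` at or above 0.5 (both inclusive).
#'
#' @param values nonempty numeric vector (e.g. RMSDs in Angstrom).
#' @param thresholds character vector like `c("<=0.2", ">=0.5", ">=1.0")`.
#' @return Named numeric vector of percentages (0..100).
#' @examples
#' threshold_fractions(c(0.1, 0.6), c("<=0.2", ">=0.5"))
#' @export
threshold_fractions <- function(values, thresholds = c("<=0.2", ">=0.5", ">=1.0")) {
  if (!length(values)) stop("empty value list", call. = FALSE)
  out <- vapply(thresholds, function(th) {
    m <- regmatches(th, regexec("^(<=|>=)\\s*([0-9.eE+-]+)$", th))[[1]]
    if (length(m) != 3) stop("unparseable threshold: ", th, call. = FALSE)
    cut <- as.numeric(m[3])
    ok <- if (m[2] == "<=") values <= cut else values >= cut
    100 * sum(ok) / length(values)
  }, numeric(1))
  stats::setNames(out, thresholds)
}

#' Maximum-likelihood log-normal fit
#'
#' The MLE of a log-normal distribution: `location` is the mean and `scale`
#' the (population, n-denominator) standard deviation of the log-values.
#'
#' @param values positive numeric vector.
#' @return List with `location` and `scale`.
#' @export
fit_lognormal <- function(values) {
  if (!length(values) || any(values <= 0)) {
    stop("log-normal fit requires positive values", call. = FALSE)
  }
  lv <- log(values)
  mu <- mean(lv)
  list(location = mu, scale = sqrt(mean((lv - mu)^2)))
}
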