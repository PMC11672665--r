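# Seminumerical Hessian, mass weighting, projection, normal modes.

test_that("seminumerical Hessian matches the analytic toy Hessian and counts 6N calls", {
  for (t in list(toy_diatomic(), toy_bent(), toy_linear())) {
    reset_counts(t$calc)
    H <- seminumerical_hessian(t$calc, t$mol, step = 1e-3)
    expect_lt(max(abs(H - ff_hessian(t$model, t$mol))), 1e-7)
    expect_identical(max(abs(H - t(H))), 0)   # exactly symmetric post-symmetrization
    expect_identical(eval_counts(t$calc)[["gradient"]], 6L * n_atoms(t$mol))
  }
  # five atoms -> 30 gradient calls
  t5 <- toy_chain5()
  reset_counts(t5$calc)
  seminumerical_hessian(t5$calc, t5$mol)
  expect_identical(eval_counts(t5$calc)[["gradient"]], 30L)
})

test_that("seminumerical Hessian errors are informative", {
  t <- toy_diatomic()
  expect_error(seminumerical_hessian(t$calc, t$mol, step = 0), "step")
  expect_error(seminumerical_hessian(point_charge_calculator(c(1, -1)), t$mol),
               "gradient")
  bad <- new_calculator("nanny", gradient = function(mol) rep(NaN, 3 * n_atoms(mol)))
  expect_error(seminumerical_hessian(bad, t$mol), "coordinate 1")
})

test_that("zero-interaction calculator gives a zero Hessian", {
  zero <- new_calculator("null", gradient = function(mol) numeric(3 * n_atoms(mol)))
  t <- toy_bent()
  expect_equal(seminumerical_hessian(zero, t$mol), matrix(0, 9, 9),
               ignore_attr = TRUE)
})

test_that("mass weighting divides by sqrt(m_i m_j) per coordinate", {
  t <- toy_bent()
  H <- ff_hessian(t$model, t$mol)
  # equal masses: F = H / m
  molm <- molecule(t$mol$symbols, t$mol$coords, masses = rep(7, 3))
  expect_equal(mass_weight(H, molm), H / 7, ignore_attr = TRUE)
  expect_equal(mass_weight(matrix(0, 9, 9), t$mol), matrix(0, 9, 9),
               ignore_attr = TRUE)
  # general case stays symmetric
  Fm <- mass_weight(H, t$mol)
  expect_equal(Fm, t(Fm), tolerance = 1e-14)
})

test_that("heteronuclear diatomic reduces to the 1-D oscillator k/mu_red", {
  t <- toy_diatomic()
  Fm <- mass_weight(ff_hessian(t$model, t$mol), t$mol)
  Fp <- project_rigid_motions(Fm, t$mol)
  ev <- eigen(Fp, symmetric = TRUE, only.values = TRUE)$values
  mu_red <- prod(t$mol$masses) / sum(t$mol$masses)
  expect_equal(max(ev), 0.3 / mu_red, tolerance = 1e-10)
})

test_that("rigid-motion projection annihilates translations and yields 6/5 null modes", {
  for (t in list(toy_bent(), toy_linear(), toy_chain5())) {
    Fm <- mass_weight(ff_hessian(t$model, t$mol), t$mol)
    Fp <- project_rigid_motions(Fm, t$mol)
    # uniform translation (mass-weighted direction) is in the null space
    sm <- sqrt(rep(t$mol$masses, each = 3))
    for (a in 1:3) {
      v <- numeric(3 * n_atoms(t$mol))
      v[seq(a, length(v), by = 3)] <- sm[seq(a, length(v), by = 3)]
      expect_lt(max(abs(Fp %*% v)), 1e-10)
    }
  }
  nm_bent <- vibrational_analysis(toy_bent()$mol, calc = toy_bent()$calc)
  expect_identical(nm_bent$n_rigid, 6L)
  expect_length(nm_bent$internal, 3)
  nm_lin <- vibrational_analysis(toy_linear()$mol, calc = toy_linear()$calc)
  expect_identical(nm_lin$n_rigid, 5L)
  expect_length(nm_lin$internal, 4)
  # the linear toy's two bends are degenerate
  wl <- nm_lin$wavenumbers[nm_lin$internal]
  expect_equal(wl[1], wl[2], tolerance = 1e-6)
})

test_that("normal_modes returns ascending orthonormal eigenpairs and reconstructs F", {
  # diagonal input: eigenvalues are the diagonal, modes the coordinate axes
  d <- c(-0.2, 0.1, 0.5)
  nm <- suppressWarnings(normal_modes(diag(d)))
  expect_equal(nm$eigenvalues, sort(d))
  expect_equal(abs(nm$modes), diag(3)[, order(d)], tolerance = 1e-12)

  # hand-solved characteristic polynomial: rows/cols (2,1;1,2) + isolated 3
  Fh <- rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 3))
  expect_equal(normal_modes(Fh)$eigenvalues, c(1, 3, 3), tolerance = 1e-10)

  set.seed(1)
  A <- matrix(stats::rnorm(64), 8, 8); Fs <- (A + t(A)) / 2
  nm <- suppressWarnings(normal_modes(Fs))
  expect_equal(crossprod(nm$modes), diag(8), tolerance = 1e-10)
  expect_equal(nm$modes %*% diag(nm$eigenvalues) %*% t(nm$modes), Fs,
               tolerance = 1e-10)
  expect_false(is.unsorted(nm$eigenvalues))
  expect_error(normal_modes(matrix(stats::rnorm(16), 4, 4)), "symmetric")
})

test_that("eigenvalue-to-wavenumber conversion is signed and zero-safe", {
  expect_identical(eigenvalue_to_wavenumber(0), 0)
  eps <- 0.012
  wp <- eigenvalue_to_wavenumber(eps)
  wm <- eigenvalue_to_wavenumber(-eps)
  expect_equal(wm, -wp)
  expect_equal(wp, sqrt(eps) * spectroscopy_constants()$sqrt_eig_to_rcm)
})

test_that("diatomic wavenumber matches the independent closed-form oracle", {
  # oracle scripted from raw CODATA SI values: nu = (1/2 pi c) sqrt(k/mu)
  c0 <- 299792458; a0 <- 5.29177210903e-11
  Eh <- 4.3597447222071e-18; amu <- 1.66053906660e-27
  t <- toy_diatomic()
  mu_red <- prod(t$mol$masses) / sum(t$mol$masses) * amu
  k_si <- 0.3 * Eh / a0^2
  nu_oracle <- sqrt(k_si / mu_red) / (2 * pi * c0) / 100
  nm <- vibrational_analysis(t$mol, calc = t$calc)
  expect_equal(max(nm$wavenumbers), nu_oracle, tolerance = 1e-6)
  expect_lt(abs(max(nm$wavenumbers) - nu_oracle), 0.01)
})

test_that("wavenumbers are invariant under rigid rotation", {
  t <- toy_bent()
  R <- rotation_matrix(c(1, 2, 3), 0.83)
  molr <- rotate_molecule(t$mol, R, shift = c(0.5, -1, 2))
  # exact-Hessian route: invariance to >= 8 digits
  nm0 <- vibrational_analysis(t$mol, calc = t$calc, prefer_analytic = TRUE)
  nmr <- vibrational_analysis(molr, calc = ff_calculator(t$model),
                              prefer_analytic = TRUE)
  w0 <- nm0$wavenumbers[nm0$internal]; wr <- nmr$wavenumbers[nmr$internal]
  expect_equal(wr, w0, tolerance = 1e-9)
  # seminumerical route: displacement directions are not rotation-covariant,
  # so invariance holds only to the O(step^2) truncation level
  sn0 <- vibrational_analysis(t$mol, calc = t$calc)
  snr <- vibrational_analysis(molr, calc = ff_calculator(t$model))
  expect_equal(snr$wavenumbers[snr$internal], sn0$wavenumbers[sn0$internal],
               tolerance = 1e-5)
  expect_equal(sn0$wavenumbers[sn0$internal], w0, tolerance = 1e-5)
})

test_that("ZPVE is invariant under atom permutation of the input", {
  t <- toy_bent()
  nm <- vibrational_analysis(t$mol, calc = t$calc)
  z0 <- zpve(nm$wavenumbers[nm$internal])
  # permute atoms (H, O, H) and remap the model indices accordingly
  perm <- c(2, 1, 3)   # new order: H1, O, H2 ; old index -> position
  x <- coords_matrix(t$mol)[perm, ]
  molp <- molecule(t$mol$symbols[perm], x)
  inv <- order(perm)
  modelp <- harmonic_ff(
    bonds = data.frame(i = inv[c(2, 3)], j = inv[c(1, 1)], k = 0.30, r0 = 2.1),
    angles = data.frame(i = inv[2], j = inv[1], k_atom = inv[3], k = 0.10,
                        theta0 = 104.5 * pi / 180))
  nmp <- vibrational_analysis(molp, calc = ff_calculator(modelp))
  expect_equal(zpve(nmp$wavenumbers[nmp$internal]), z0, tolerance = 1e-9)
})

test_that("imaginary modes warn and are reported as negative wavenumbers", {
  # a saddle: negate the bend force constant
  model <- harmonic_ff(
    bonds = data.frame(i = c(2, 3), j = c(1, 1), k = 0.30, r0 = 2.1),
    angles = data.frame(i = 2, j = 1, k_atom = 3, k = -0.05,
                        theta0 = 104.5 * pi / 180))
  mol <- toy_bent()$mol
  expect_warning(
    nm <- vibrational_analysis(mol, calc = ff_calculator(model)),
    "minimum")
  expect_true(any(nm$wavenumbers[nm$internal] < 0))
})

test_that("Hessian file round trip is exact; dialect reader parses $hessian blocks", {
  t <- toy_bent()
  H <- ff_hessian(t$model, t$mol)
  f <- withr::local_tempfile(fileext = ".hess")
  write_hessian(H, f, metadata = c(provenance = "analytic"))
  H2 <- read_hessian(f)
  expect_equal(H2, H, tolerance = 1e-13, ignore_attr = TRUE)
  expect_identical(attr(H2, "metadata")[["provenance"]], "analytic")

  fd <- withr::local_tempfile(fileext = ".txt")
  vals <- as.numeric(t(H))
  writeLines(c("$hessian",
               vapply(split(vals, ceiling(seq_along(vals) / 5)),
                      function(v) paste(sprintf("%.10e", v), collapse = "  "),
                      character(1)),
               "$end"), fd)
  expect_equal(read_hessian(fd, format = "dialect"), H, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(read_hessian(f, format = "dialect"), "hessian block")
})
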