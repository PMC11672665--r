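# Dipole benchmarking, Kabsch RMSD, error-statistics engine.

test_that("regularized dipole error: sign, clamp branch, rotation invariance", {
  expect_identical(regularized_dipole_error(c(2, 0, 0), c(2, 0, 0)), 0)
  expect_equal(regularized_dipole_error(c(3, 0, 0), c(0, 2, 0)), 0.5)
  # clamp: |ref| = 0.5 D < 1 D -> denominator 1 D
  expect_equal(regularized_dipole_error(c(1, 0, 0), c(0.5, 0, 0)), 0.5)
  # signed: smaller test magnitude gives a negative error
  expect_equal(regularized_dipole_error(c(1, 0, 0), c(2, 0, 0)), -0.5)
  # invariant under simultaneous rigid rotation of both vectors
  R <- rotation_matrix(c(1, 1, 0), 0.7)
  mt <- c(0.3, -1.2, 2.0); mr <- c(1.1, 0.4, -0.5)
  expect_equal(regularized_dipole_error(as.numeric(R %*% mt), as.numeric(R %*% mr)),
               regularized_dipole_error(mt, mr), tolerance = 1e-12)
})

test_that("dipole alignment is the cosine, scale-invariant, and errors on zero", {
  expect_equal(dipole_alignment(c(2, 0, 0), c(5, 0, 0)), 1)
  expect_equal(dipole_alignment(c(1, 1, 0), c(-2, -2, 0)), -1, tolerance = 1e-14)
  expect_equal(dipole_alignment(c(1, 0, 0), c(0, 3, 0)), 0)
  mt <- c(0.2, 0.5, -1); mr <- c(1, -2, 0.3)
  expect_equal(dipole_alignment(17 * mt, mr), dipole_alignment(mt, mr),
               tolerance = 1e-14)
  expect_error(dipole_alignment(c(0, 0, 0), mr), "zero")
  dc <- dipole_comparison(mt, mr)
  expect_named(dc, c("error", "alignment"))
})

test_that("kabsch_rmsd: zero on rigid motions, symmetric, correspondence enforced", {
  set.seed(21)
  A <- matrix(stats::rnorm(15, sd = 2), 5, 3)
  expect_equal(kabsch_rmsd(A, A), 0, tolerance = 1e-12)
  R <- rotation_matrix(c(0.3, -1, 0.5), 1.9)
  B <- A %*% t(R) + matrix(rep(c(3, -1, 7), each = 5), 5, 3)
  expect_lt(kabsch_rmsd(A, B), 1e-10)
  # symmetry to >= 10 digits
  B2 <- B + matrix(stats::rnorm(15, sd = 0.1), 5, 3)
  expect_equal(kabsch_rmsd(A, B2), kabsch_rmsd(B2, A), tolerance = 1e-11)
  expect_error(kabsch_rmsd(A, B2[1:4, ]), "equal atom counts")
  # hydrogen exclusion changes the answer only via the H rows
  sym <- c("C", "H", "O", "H", "N")
  Bh <- B2; Bh[c(2, 4), ] <- Bh[c(2, 4), ] + 5
  expect_equal(kabsch_rmsd(A, Bh, symbols = sym, exclude_h = TRUE),
               kabsch_rmsd(A[-c(2, 4), ], B2[-c(2, 4), ]), tolerance = 1e-12)
})

test_that("kabsch_rmsd attains the minimum found by a coarse rotation-grid search", {
  # 4-atom toy, one atom displaced
  A <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0), c(0, 0, 1.5))
  B <- A; B[4, ] <- B[4, ] + c(0.3, -0.2, 0.4)
  R0 <- rotation_matrix(c(1, 2, -1), 0.9)
  B <- B %*% t(R0) + matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  r_kabsch <- kabsch_rmsd(A, B)
  # brute force over an Euler-angle grid
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  euler_rmsd <- function(p) {
    R <- rotation_matrix(c(0, 0, 1), p[1]) %*%
      rotation_matrix(c(0, 1, 0), p[2]) %*%
      rotation_matrix(c(0, 0, 1), p[3])
    sqrt(mean(rowSums((Ac - Bc %*% R)^2)))
  }
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  half <- seq(0, pi, length.out = 13)
  best <- Inf; best_p <- c(0, 0, 0)
  for (a in ang) for (b in half) for (g in ang) {
    v <- euler_rmsd(c(a, b, g))
    if (v < best) { best <- v; best_p <- c(a, b, g) }
  }
  expect_lte(r_kabsch, best + 1e-12)      # true optimum cannot exceed grid search
  # polish the grid optimum locally; the closed-form result must match it
  best_ref <- stats::optim(best_p, euler_rmsd,
                           control = list(reltol = 1e-14))$value
  expect_equal(r_kabsch, best_ref, tolerance = 1e-7)
})

test_that("error_stats matches independently scripted textbook formulas to 12 digits", {
  st <- error_stats(rep(0.3, 6))
  expect_equal(st$MD, 0.3); expect_equal(st$MAE, 0.3)
  expect_equal(st$RMSE, 0.3, tolerance = 1e-14); expect_equal(st$SD, 0)
  st2 <- error_stats(c(0.4, -0.4))
  expect_equal(st2$MD, 0); expect_equal(st2$MAE, 0.4)

  set.seed(77)
  v <- stats::rnorm(101, mean = 0.2, sd = 1.4)
  st3 <- error_stats(v)
  n <- length(v)
  expect_equal(st3$MD, sum(v) / n, tolerance = 1e-13)
  expect_equal(st3$MAE, sum(abs(v)) / n, tolerance = 1e-13)
  expect_equal(st3$RMSE, sqrt(sum(v^2) / n), tolerance = 1e-13)
  expect_equal(st3$SD, sqrt(sum((v - sum(v) / n)^2) / (n - 1)), tolerance = 1e-13)
  expect_equal(st3$median, sort(v)[(n + 1) / 2], tolerance = 1e-13)
  expect_error(error_stats(numeric(0)), "empty")
})

test_that("MAE <= RMSE for arbitrary inputs (Jensen)", {
  set.seed(13)
  for (i in 1:25) {
    v <- stats::rnorm(sample(2:50, 1), sd = stats::runif(1, 0.1, 5))
    st <- error_stats(v)
    expect_lte(st$MAE, st$RMSE + 1e-14)
  }
})

test_that("threshold fractions use inclusive comparisons and match direct counting", {
  expect_equal(unname(threshold_fractions(rep(0.1, 4), "<=0.2")), 100)
  expect_equal(unname(threshold_fractions(c(0.1, 0.6), ">=0.5")), 50)
  # inclusivity at the boundary
  expect_equal(unname(threshold_fractions(c(0.2, 0.5), c("<=0.2", ">=0.5"))),
               c(50, 50))
  set.seed(99)
  u <- stats::runif(1000)
  tf <- threshold_fractions(u, c("<=0.2", ">=0.5", ">=1.0"))
  expect_identical(unname(tf),
                   c(100 * sum(u <= 0.2) / 1000, 100 * sum(u >= 0.5) / 1000,
                     100 * sum(u >= 1.0) / 1000))
  expect_error(threshold_fractions(u, "~0.3"), "unparseable")
})

test_that("log-normal fit is the MLE of log values", {
  fit <- fit_lognormal(rep(2.5, 10))
  expect_equal(fit$location, log(2.5), tolerance = 1e-13)
  expect_equal(fit$scale, 0)
  set.seed(4)
  v <- exp(stats::rnorm(1e4))
  fit2 <- fit_lognormal(v)
  se_loc <- 1 / sqrt(1e4); se_scale <- 1 / sqrt(2e4)
  expect_lt(abs(fit2$location - 0), 3 * se_loc)
  expect_lt(abs(fit2$scale - 1), 3 * se_scale)
  # scaling equivariance: location shifts by log(c), scale unchanged
  fit3 <- fit_lognormal(7 * v)
  expect_equal(fit3$location, fit2$location + log(7), tolerance = 1e-12)
  expect_equal(fit3$scale, fit2$scale, tolerance = 1e-12)
  expect_error(fit_lognormal(c(1, -2)), "positive")
})
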