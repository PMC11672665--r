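# Pluggable calculator contract plus analytic toy models.
#
# A calculator bundles capability functions (energy, gradient, dipole, and
# optionally analytic hessian / dipole gradient) behind one interface so the
# finite-difference machinery downstream is agnostic of the provider. Toy
# models (harmonic force field, fixed point charges) have closed-form
# derivatives and act as exact oracles for every stage of the pipeline.

#' Create a calculator
#'
#' The calculator contract: each capability function takes a [molecule()] and
#' returns finite values; each evaluation increments that capability's
#' counter exactly once. Counters make displacement-count contracts (6N
#' gradient calls for a two-sided Hessian) testable.
#'
#' @param name identifier used in logs and provenance metadata.
#' @param energy,gradient,dipole,hessian,dipole_gradient functions of a
#'   molecule returning, respectively, a scalar (Hartree), a flat 3N vector
#'   (Hartree/Bohr), a 3-vector (atomic units), a 3N x 3N matrix and a 3N x 3
#'   matrix. Pass `NULL` for missing capabilities.
#' @return Object of class `"ir_calculator"`.
#' @export
new_calculator <- function(name, energy = NULL, gradient = NULL, dipole = NULL,
                           hessian = NULL, dipole_gradient = NULL) {
  fns <- list(energy = energy, gradient = gradient, dipole = dipole,
              hessian = hessian, dipole_gradient = dipole_gradient)
  fns <- fns[!vapply(fns, is.null, logical(1))]
  counts <- new.env(parent = emptyenv())
  for (cap in names(fns)) assign(cap, 0L, envir = counts)
  structure(list(name = name, fns = fns, counts = counts),
            class = "ir_calculator")
}

#' Capabilities advertised by a calculator
#' @param calc an [new_calculator()] object.
#' @return Character vector, subset of `c("energy", "gradient", "dipole",
#'   "hessian", "dipole_gradient")`.
#' @export
calc_capabilities <- function(calc) names(calc$fns)

#' Evaluation counts per capability
#' @param calc an [new_calculator()] object.
#' @return Named integer vector of evaluation counts.
#' @export
eval_counts <- function(calc) {
  vapply(calc_capabilities(calc), function(cap) get(cap, envir = calc$counts),
         integer(1))
}

#' Reset all evaluation counters to zero
#' @param calc an [new_calculator()] object.
#' @return The calculator, invisibly.
#' @export
reset_counts <- function(calc) {
  for (cap in calc_capabilities(calc)) assign(cap, 0L, envir = calc$counts)
  invisible(calc)
}

.calc_eval <- function(calc, cap, mol, expected_len = NULL) {
  fn <- calc$fns[[cap]]
  if (is.null(fn)) {
    stop(sprintf("calculator '%s' does not provide capability '%s'",
                 calc$name, cap), call. = FALSE)
  }
  out <- fn(mol)
  assign(cap, get(cap, envir = calc$counts) + 1L, envir = calc$counts)
  out
}

#' Evaluate calculator capabilities
#'
#' Thin dispatchers that check the capability exists, call it once (bumping
#' the counter) and validate the result shape.
#'
#' @param calc an [new_calculator()] object.
#' @param mol a [molecule()].
#' @return `calc_energy`: scalar Hartree. `calc_gradient`: flat 3N vector in
#'   Hartree/Bohr. `calc_dipole`: dipole 3-vector in atomic units.
#'   `calc_hessian`: 3N x 3N matrix in Hartree/Bohr^2. `calc_dipole_gradient`:
#'   3N x 3 matrix in atomic units.
#' @export
calc_energy <- function(calc, mol) {
  e <- as.numeric(.calc_eval(calc, "energy", mol))
  stopifnot(length(e) == 1)
  e
}

#' @rdname calc_energy
#' @export
calc_gradient <- function(calc, mol) {
  g <- as.numeric(.calc_eval(calc, "gradient", mol))
  stopifnot(length(g) == 3 * n_atoms(mol))
  g
}

#' @rdname calc_energy
#' @export
calc_dipole <- function(calc, mol) {
  d <- as.numeric(.calc_eval(calc, "dipole", mol))
  stopifnot(length(d) == 3)
  d
}

#' @rdname calc_energy
#' @export
calc_hessian <- function(calc, mol) {
  h <- .calc_eval(calc, "hessian", mol)
  stopifnot(is.matrix(h), all(dim(h) == 3 * n_atoms(mol)))
  h
}

#' @rdname calc_energy
#' @export
calc_dipole_gradient <- function(calc, mol) {
  d <- .calc_eval(calc, "dipole_gradient", mol)
  stopifnot(is.matrix(d), nrow(d) == 3 * n_atoms(mol), ncol(d) == 3)
  d
}

# ---------------------------------------------------------------------------
# Harmonic force field toy model

#' Define a harmonic force field
#'
#' Toy intramolecular potential with three term types, all functions of
#' internal coordinates only (hence exactly invariant under rigid rotation and
#' translation):
#' \itemize{
#'   \item bonds: `E = k/2 (r - r0)^2` with `k` in Eh/a0^2 and `r0` in Bohr;
#'   \item angles: `E = k/2 (theta - theta0)^2` with `k` in Eh/rad^2 (atom `j`
#'     is the vertex);
#'   \item linear bends: `E = k (1 + cos theta)`, a form regular at
#'     `theta = pi` that reduces to a harmonic bend of force constant `k`
#'     around linearity (the plain angle form has a singular gradient there).
#' }
#'
#' @param bonds data frame with columns `i`, `j` (1-based atom indices), `k`,
#'   `r0`, or `NULL`.
#' @param angles data frame with columns `i`, `j`, `k_atom`, `k`, `theta0`
#'   (radians), or `NULL`.
#' @param linear_bends data frame with columns `i`, `j`, `k_atom`, `k`, or
#'   `NULL`.
#' @return Object of class `"harmonic_ff"`.
#' @examples
#' harmonic_ff(bonds = data.frame(i = 1, j = 2, k = 0.3, r0 = 2.4))
#' @export
harmonic_ff <- function(bonds = NULL, angles = NULL, linear_bends = NULL) {
  chk <- function(df, cols, what) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    if (!all(cols %in% names(df))) {
      stop(what, " terms need columns: ", paste(cols, collapse = ", "),
           call. = FALSE)
    }
    df
  }
  structure(list(
    bonds = chk(bonds, c("i", "j", "k", "r0"), "bond"),
    angles = chk(angles, c("i", "j", "k_atom", "k", "theta0"), "angle"),
    linear_bends = chk(linear_bends, c("i", "j", "k_atom", "k"), "linear bend")
  ), class = "harmonic_ff")
}

.ff_check_indices <- function(model, n) {
  idx <- c(model$bonds$i, model$bonds$j,
           model$angles$i, model$angles$j, model$angles$k_atom,
           model$linear_bends$i, model$linear_bends$j, model$linear_bends$k_atom)
  if (length(idx) && (any(idx < 1) || any(idx > n))) {
    stop("force-field term references atom outside 1..", n, call. = FALSE)
  }
}

# Energy and gradient over a flat coordinate vector. Written to be valid for
# complex coordinates so that complex-step differentiation of the gradient
# yields second derivatives exact to machine precision (the "analytic"
# Hessian oracle).
.ff_eval <- function(model, x, grad = TRUE) {
  e <- 0 + 0i * x[1]
  g <- if (grad) rep(0 + 0i * x[1], length(x)) else NULL
  at <- function(a) x[(3 * a - 2):(3 * a)]
  add <- function(a, v) if (grad) g[(3 * a - 2):(3 * a)] <<- g[(3 * a - 2):(3 * a)] + v

  if (!is.null(model$bonds)) for (t in seq_len(nrow(model$bonds))) {
    b <- model$bonds[t, ]
    d <- at(b$i) - at(b$j)
    r <- sqrt(sum(d * d))
    e <- e + 0.5 * b$k * (r - b$r0)^2
    if (grad) {
      u <- d / r
      f <- b$k * (r - b$r0)
      add(b$i, f * u); add(b$j, -f * u)
    }
  }

  angle_geom <- function(a) {
    u <- at(a$i) - at(a$j); v <- at(a$k_atom) - at(a$j)
    cu <- sqrt(sum(u * u)); cv <- sqrt(sum(v * v))
    ct <- sum(u * v) / (cu * cv)
    list(u = u, v = v, cu = cu, cv = cv, ct = ct,
         # gradient of cos(theta) w.r.t. r_i and r_k (r_j = -sum)
         dci = (v / cv - ct * u / cu) / cu,
         dck = (u / cu - ct * v / cv) / cv)
  }

  if (!is.null(model$angles)) for (t in seq_len(nrow(model$angles))) {
    a <- model$angles[t, ]
    gm <- angle_geom(a)
    th <- acos(gm$ct)
    e <- e + 0.5 * a$k * (th - a$theta0)^2
    if (grad) {
      st <- sqrt(1 - gm$ct^2)          # sin(theta); model unusable at 0 or pi
      f <- -a$k * (th - a$theta0) / st # dE/dtheta * dtheta/dcos
      add(a$i, f * gm$dci); add(a$k_atom, f * gm$dck)
      add(a$j, -f * (gm$dci + gm$dck))
    }
  }

  if (!is.null(model$linear_bends)) for (t in seq_len(nrow(model$linear_bends))) {
    a <- model$linear_bends[t, ]
    gm <- angle_geom(a)
    e <- e + a$k * (1 + gm$ct)
    if (grad) {
      add(a$i, a$k * gm$dci); add(a$k_atom, a$k * gm$dck)
      add(a$j, -a$k * (gm$dci + gm$dck))
    }
  }
  list(energy = e, gradient = g)
}

#' Harmonic force-field energy and analytic gradient
#'
#' The gradient is the exact analytic derivative of the energy.
#'
#' @param model a [harmonic_ff()].
#' @param mol a [molecule()].
#' @return List with `energy` (Hartree) and `gradient` (flat 3N,
#'   Hartree/Bohr).
#' @export
ff_energy_gradient <- function(model, mol) {
  .ff_check_indices(model, n_atoms(mol))
  out <- .ff_eval(model, mol$coords + 0i, grad = TRUE)
  list(energy = Re(out$energy), gradient = Re(out$gradient))
}

#' Analytic Hessian of a harmonic force field
#'
#' Second derivatives obtained by complex-step differentiation of the analytic
#' gradient (step 1e-100), which is exact to machine precision and free of
#' subtractive cancellation — a true analytic oracle for the seminumerical
#' route.
#'
#' @param model a [harmonic_ff()].
#' @param mol a [molecule()].
#' @return 3N x 3N symmetric matrix in Hartree/Bohr^2 with attribute
#'   `provenance = "analytic"`.
#' @export
ff_hessian <- function(model, mol) {
  .ff_check_indices(model, n_atoms(mol))
  x <- mol$coords
  n3 <- length(x)
  h <- 1e-100
  H <- matrix(0, n3, n3)
  for (i in seq_len(n3)) {
    xi <- x + 0i
    xi[i] <- xi[i] + complex(imaginary = h)
    H[, i] <- Im(.ff_eval(model, xi, grad = TRUE)$gradient) / h
  }
  H <- (H + t(H)) / 2
  attr(H, "provenance") <- "analytic"
  H
}

#' Wrap a harmonic force field (plus optional point charges) as a calculator
#'
#' @param model a [harmonic_ff()].
#' @param charges optional per-atom fixed partial charges (elementary charge
#'   units); enables the dipole and analytic dipole-gradient capabilities.
#' @param name calculator name.
#' @return An [new_calculator()] with capabilities energy, gradient, hessian
#'   and (with charges) dipole, dipole_gradient.
#' @export
ff_calculator <- function(model, charges = NULL, name = "harmonic_ff") {
  fns <- list(
    energy = function(mol) ff_energy_gradient(model, mol)$energy,
    gradient = function(mol) ff_energy_gradient(model, mol)$gradient,
    hessian = function(mol) ff_hessian(model, mol)
  )
  if (!is.null(charges)) {
    fns$dipole <- function(mol) point_charge_dipole(charges, mol)
    fns$dipole_gradient <- function(mol) point_charge_dipole_gradient(charges, mol)
  }
  do.call(new_calculator, c(list(name = name), fns))
}

# ---------------------------------------------------------------------------
# Point-charge dipole toy model

#' Dipole moment of fixed point charges
#'
#' `mu_alpha = sum_j q_j x_{j,alpha}` in atomic units. For a neutral charge
#' set (`sum(q) == 0`) the dipole is origin- and translation-invariant.
#'
#' @param charges per-atom charges in elementary charge units, length N.
#' @param mol a [molecule()].
#' @return Dipole 3-vector in atomic units (e a0).
#' @export
point_charge_dipole <- function(charges, mol) {
  if (length(charges) != n_atoms(mol)) {
    stop("length(charges) != number of atoms", call. = FALSE)
  }
  as.numeric(colSums(coords_matrix(mol) * charges))
}

#' Analytic dipole gradient of fixed point charges
#'
#' Exact derivative of `sum_j q_j r_j`: the 3 x 3 block of atom j is
#' `q_j * I`.
#'
#' @inheritParams point_charge_dipole
#' @return 3N x 3 matrix, attribute `provenance = "analytic"`.
#' @export
point_charge_dipole_gradient <- function(charges, mol) {
  n <- n_atoms(mol)
  if (length(charges) != n) stop("length(charges) != number of atoms", call. = FALSE)
  D <- matrix(0, 3 * n, 3)
  for (j in seq_len(n)) {
    D[(3 * j - 2):(3 * j), ] <- diag(3) * charges[j]
  }
  attr(D, "provenance") <- "analytic"
  D
}

#' Wrap fixed point charges as a dipole-capable calculator
#' @inheritParams point_charge_dipole
#' @param name calculator name.
#' @return An [new_calculator()] with dipole and dipole_gradient capabilities.
#' @export
point_charge_calculator <- function(charges, name = "point_charges") {
  new_calculator(
    name,
    dipole = function(mol) point_charge_dipole(charges, mol),
    dipole_gradient = function(mol) point_charge_dipole_gradient(charges, mol)
  )
}

# ---------------------------------------------------------------------------
# Fixture generator

#' Generate paired reference/test spectra fixtures
#'
#' Emulates a "reference method" and a "test method" over a batch of
#' molecules: per molecule a random number of modes with frequencies drawn
#' uniformly over the mid-IR and log-normal intensities; the test method's
#' frequencies are globally offset so that `reference = factor * test` (plus
#' zero-mean Gaussian noise on the test side), and intensities are perturbed
#' multiplicatively by a log-normal factor. `factor` is thus the linear
#' frequency scaling factor the test method *needs*, the quantity
#' [derive_scaling_factor()] recovers downstream from the ZPVE ratios.
#' Generation is fully reproducible from `seed`.
#'
#' @param n_molecules number of molecules (> 0).
#' @param seed mandatory RNG seed.
#' @param factor the global scaling factor relating the methods
#'   (`reference = factor * test` before noise).
#' @param freq_noise standard deviation of the additive frequency noise
#'   (1/cm).
#' @param intensity_noise standard deviation of log intensity perturbation.
#' @param n_modes_range integer range of mode counts per molecule.
#' @param freq_range frequency window (1/cm) the reference draws from.
#' @return Object of class `"fixture_set"`: list with `reference` and `test`
#'   (each a list of `list(frequencies, intensities)`) plus the generating
#'   parameters.
#' @examples
#' fx <- make_fixture_set(5, seed = 1, factor = 0.96, freq_noise = 5)
#' @export
make_fixture_set <- function(n_molecules, seed, factor = 1, freq_noise = 0,
                             intensity_noise = 0, n_modes_range = c(6L, 30L),
                             freq_range = c(200, 3800)) {
  if (n_molecules < 1) stop("n_molecules must be positive", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ref <- test <- vector("list", n_molecules)
  for (m in seq_len(n_molecules)) {
    k <- sample(n_modes_range[1]:n_modes_range[2], 1)
    f <- sort(stats::runif(k, freq_range[1], freq_range[2]))
    a <- stats::rlnorm(k, meanlog = 2, sdlog = 1)
    ref[[m]] <- list(frequencies = f, intensities = a)
    ft <- f / factor + stats::rnorm(k, 0, freq_noise)
    at <- a * exp(stats::rnorm(k, 0, intensity_noise))
    ord <- order(ft)
    test[[m]] <- list(frequencies = ft[ord], intensities = at[ord])
  }
  structure(list(reference = ref, test = test, n_molecules = n_molecules,
                 seed = seed, factor = factor, freq_noise = freq_noise,
                 intensity_noise = intensity_noise),
            class = "fixture_set")
}
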