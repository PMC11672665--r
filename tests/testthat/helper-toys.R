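# Toy molecules with analytic force fields and point charges, built in code.
# All force constants in Eh/a0^2 (Eh/rad^2 for bends), lengths in Bohr.

# HCl-like diatomic.
toy_diatomic <- function() {
  model <- harmonic_ff(bonds = data.frame(i = 1, j = 2, k = 0.3, r0 = 2.4))
  mol <- molecule(c("H", "Cl"), c(0, 0, 0, 2.4, 0, 0))
  charges <- c(0.2, -0.2)
  list(mol = mol, model = model, charges = charges,
       calc = ff_calculator(model, charges))
}

# Water-like bent triatomic (O vertex), at its exact minimum. Force constants
# kept moderate so the documented finite-difference accuracy contract
# (deviation < 1e-7 Eh/a0^2 at step 1e-3 a0) holds with margin; frequencies
# stay in the mid-IR.
toy_bent <- function() {
  r0 <- 2.1
  th0 <- 104.5 * pi / 180
  model <- harmonic_ff(
    bonds = data.frame(i = c(2, 3), j = c(1, 1), k = 0.30, r0 = r0),
    angles = data.frame(i = 2, j = 1, k_atom = 3, k = 0.10, theta0 = th0))
  # place O at origin, H's in the xy-plane at the equilibrium angle
  h1 <- r0 * c(cos(th0 / 2), sin(th0 / 2), 0)
  h2 <- r0 * c(cos(th0 / 2), -sin(th0 / 2), 0)
  mol <- molecule(c("O", "H", "H"), rbind(c(0, 0, 0), h1, h2))
  charges <- c(-0.66, 0.33, 0.33)
  list(mol = mol, model = model, charges = charges,
       calc = ff_calculator(model, charges))
}

# CO2-like linear symmetric triatomic (C central); the bend is the
# cosine-form term, regular at linearity.
toy_linear <- function() {
  r0 <- 2.2
  model <- harmonic_ff(
    bonds = data.frame(i = c(1, 3), j = c(2, 2), k = 0.5, r0 = r0),
    linear_bends = data.frame(i = 1, j = 2, k_atom = 3, k = 0.15))
  mol <- molecule(c("O", "C", "O"),
                  rbind(c(-r0, 0, 0), c(0, 0, 0), c(r0, 0, 0)))
  charges <- c(-0.3, 0.6, -0.3)
  list(mol = mol, model = model, charges = charges,
       calc = ff_calculator(model, charges))
}

# 5-atom chain with bonds only (for displacement-count contracts).
toy_chain5 <- function() {
  model <- harmonic_ff(
    bonds = data.frame(i = 1:4, j = 2:5, k = c(0.3, 0.4, 0.5, 0.35),
                       r0 = c(2.0, 2.1, 2.2, 2.05)))
  x <- rbind(c(0, 0, 0), c(2.0, 0, 0), c(2.0, 2.1, 0),
             c(2.0, 2.1, 2.2), c(4.05, 2.1, 2.2))
  mol <- molecule(c("C", "C", "O", "N", "H"), x)
  list(mol = mol, model = model,
       calc = ff_calculator(model, charges = c(-0.1, 0.2, -0.3, 0.1, 0.1)))
}

# Rotation matrix about a unit axis.
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rotate_molecule <- function(mol, R, shift = c(0, 0, 0)) {
  x <- coords_matrix(mol) %*% t(R)
  x <- sweep(x, 2, -shift)
  set_coords(mol, x)
}
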