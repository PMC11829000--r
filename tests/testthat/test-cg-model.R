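test_that("topologies resolve beads, bonds and charges", {
  topo <- build_topology("GS", conditions())
  expect_length(topo$sigma, 2)
  expect_equal(nchar(topo$sequence) - 1, 1)  # one bond
  # poly-E at pH 7: side chains fully ionized; termini add +1/-1
  topo <- build_topology(strrep("E", 5), conditions())
  expect_equal(topo$charge, c(0, -1, -1, -1, -2))
  topo <- build_topology(strrep("E", 5), conditions(), termini_charges = FALSE)
  expect_equal(topo$charge, rep(-1, 5))
  # His at pH = pKa carries half a charge (Henderson-Hasselbalch)
  pka <- residue_params()["H", "pka"]
  topo <- build_topology("GHG", conditions(pH = pka), termini_charges = FALSE)
  expect_equal(topo$charge[2], 0.5)
  expect_error(build_topology("GXZ", conditions()), "unknown residue")
})

test_that("Debye screening follows the closed form", {
  dp <- debye_parameters(conditions(298, 7, 0.15))
  expect_equal(dp$debye_length, 0.79, tolerance = 0.02 / 0.79)
  # kappa ~ sqrt(I): quadrupling the ionic strength halves the length
  dp4 <- debye_parameters(conditions(298, 7, 0.6))
  expect_equal(dp4$debye_length, dp$debye_length / 2, tolerance = 1e-10)
  expect_error(debye_parameters(conditions(298, 7, 0)), "no-electrostatics|disable")
  # screening limit: the electrostatic energy of two like charges at 1 nm
  # (beads 1 and 3 of a K-G-K chain; only that pair is nonbonded-charged)
  # decays monotonically to zero as the ionic strength grows
  x <- rbind(c(0, 0, 0), c(0.5, 0.35, 0), c(1, 0, 0))
  e_dh <- vapply(c(0.1, 0.5, 1, 2), function(I) {
    cond <- conditions(ionic_strength = I)
    on <- build_topology("KGK", cond, termini_charges = FALSE)
    off <- build_topology("KGK", cond, termini_charges = FALSE,
                          use_dh = FALSE)
    energy_forces(x, on)$energy - energy_forces(x, off)$energy
  }, numeric(1))
  expect_true(all(diff(e_dh) < 0))
  expect_gt(e_dh[1], 0)
})

test_that("analytic forces match central differences on a random coil", {
  topo <- build_topology("MKVLAWGRES", conditions())
  x <- random_walk_coords(10, seed = 3)
  f <- energy_forces(x, topo)$forces
  h <- 1e-6
  num <- matrix(0, 10, 3)
  for (i in 1:10) for (k in 1:3) {
    xp <- x; xm <- x
    xp[i, k] <- xp[i, k] + h; xm[i, k] <- xm[i, k] - h
    num[i, k] <- -(afmi:::cpp_energy_forces(xp, unclass(topo))$energy -
                   afmi:::cpp_energy_forces(xm, unclass(topo))$energy) / (2 * h)
  }
  expect_lt(max(abs(num - f)), 1e-4)
})

test_that("energy is invariant under rigid motions and forces conserve", {
  topo <- build_topology("MKVLAWGRES", conditions())
  x <- random_walk_coords(10, seed = 5)
  ef <- energy_forces(x, topo)
  expect_lt(max(abs(colSums(ef$forces))), 1e-8)          # net force
  torque <- colSums(cbind(
    x[, 2] * ef$forces[, 3] - x[, 3] * ef$forces[, 2],
    x[, 3] * ef$forces[, 1] - x[, 1] * ef$forces[, 3],
    x[, 1] * ef$forces[, 2] - x[, 2] * ef$forces[, 1]))
  expect_lt(max(abs(torque)), 1e-8)                      # net torque
  th <- 0.3
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  x2 <- x %*% R + matrix(c(1, -2, 0.5), 10, 3, byrow = TRUE)
  expect_equal(energy_forces(x2, topo)$energy, ef$energy, tolerance = 1e-10)
})

test_that("pair potentials vanish continuously at their cutoffs", {
  topo <- build_topology("KGE", conditions(), termini_charges = FALSE)
  # bead 3 orbits bead 2 at fixed bond length, so only the nonbonded 1-3
  # distance r13 changes; all bond energies stay constant
  place <- function(d, r13) {
    ct <- (r13^2 - d^2 - 0.38^2) / (2 * 0.38 * d)
    rbind(c(0, 0, 0), c(d, 0, 0),
          c(d + 0.38 * ct, 0.38 * sqrt(1 - ct^2), 0))
  }
  for (rc in c(topo$ah_rc, topo$dh_rc)) {
    d <- rc - 0.1
    e_in <- afmi:::cpp_energy_forces(place(d, rc - 1e-7), unclass(topo))$energy
    e_out <- afmi:::cpp_energy_forces(place(d, rc + 1e-7), unclass(topo))$energy
    expect_equal(e_in, e_out, tolerance = 1e-10)
  }
  # beyond both cutoffs the 1-3 interaction is exactly zero
  d <- topo$dh_rc
  base <- afmi:::cpp_energy_forces(place(d, d + 0.05), unclass(topo))$energy
  far <- afmi:::cpp_energy_forces(place(d, d + 0.3), unclass(topo))$energy
  expect_equal(base, far)
})

test_that("bonded pair at rest length with no nonbonded terms has zero energy", {
  topo <- build_topology("GS", conditions(), use_dh = FALSE, lambda_scale = 0)
  # lambda = 0 still leaves the repulsive part below r_min; place at rest
  # length 0.38 nm which is below 2^(1/6) sigma -- use the bond term check
  x <- rbind(c(0, 0, 0), c(topo$bond_r0, 0, 0))
  ef <- energy_forces(x, topo)
  bond_only <- 0.5 * topo$bond_k * 0^2
  # residual is the Ashbaugh-Hatch repulsion shift-free value at r0: bonded
  # pairs are excluded from nonbonded terms, so the energy is the bond term
  expect_equal(ef$energy, bond_only)
})

test_that("overlapping beads are rejected with advice to minimize", {
  topo <- tiny_topology()
  x <- random_walk_coords(10, seed = 1)
  x[5, ] <- x[2, ] + 1e-3
  expect_error(energy_forces(x, topo), "minimize")
})
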