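test_that("minimization descends and survives overlaps", {
  topo <- tiny_topology()
  # stretched bond relaxes
  x <- random_walk_coords(10, seed = 2)
  x[2, ] <- x[1, ] + c(2 * topo$bond_r0, 0, 0)
  e0 <- afmi:::cpp_energy_forces(x, unclass(topo))$energy
  xm <- minimize(x, topo)
  e1 <- afmi:::cpp_energy_forces(xm, unclass(topo))$energy
  expect_lt(e1, e0)
  # already near a minimum: stays put
  xm2 <- minimize(xm, topo, max_steps = 5)
  expect_lt(max(abs(xm2 - xm)), 0.05)
  # overlapping beads end up finite
  x[5, ] <- x[4, ] + 1e-4
  xo <- minimize(x, topo, max_steps = 200)
  expect_true(all(is.finite(xo)))
  expect_true(is.finite(afmi:::cpp_energy_forces(xo, unclass(topo))$energy))
})

test_that("Langevin friction limit follows the closed form at T = 0", {
  ff <- function(x) list(energy = 0, forces = 0 * x)
  st <- replica_state(matrix(0, 2, 3), velocities = matrix(1, 2, 3))
  gam <- 0.8; dt <- 0.01
  st2 <- langevin_step(st, ff, masses = c(1, 1), dt = dt, friction = gam,
                       temperature = 0)
  expect_equal(st2$velocities, matrix(exp(-gam * dt), 2, 3))
})

test_that("single bead in a harmonic well equipartitions", {
  k <- 100
  ff <- function(x) list(energy = 0.5 * k * sum(x^2), forces = -k * x)
  st <- replica_state(matrix(0, 1, 3), rng_seed = 42)
  n <- 6000
  xs <- numeric(n)
  for (i in seq_len(n)) {
    st <- langevin_step(st, ff, masses = 1, dt = 0.02, friction = 5,
                        temperature = 300)
    xs[i] <- st$coords[1, 1]
  }
  xs <- xs[-(1:1000)]
  v <- var(xs)
  target <- kB * 300 / k
  # 3-standard-error band with a conservative autocorrelation allowance
  neff <- length(xs) / 10
  se <- target * sqrt(2 / neff)
  expect_lt(abs(v - target), 3 * se)
})

test_that("trajectories are deterministic per seed and decorrelated across replicas", {
  topo <- tiny_topology()
  st <- replica_state(random_walk_coords(10, seed = 1))
  r1 <- run_replicas(st, topo, 500, save_every = 50, seed = 9)
  r2 <- run_replicas(st, topo, 500, save_every = 50, seed = 9)
  expect_identical(r1$trajectories, r2$trajectories)
  # two replicas in one run see different noise
  reps <- list(replica_state(random_walk_coords(10, seed = 1), replica_id = 1),
               replica_state(random_walk_coords(10, seed = 1), replica_id = 2))
  r3 <- run_replicas(reps, topo, 500, save_every = 50, seed = 9)
  expect_false(identical(r3$trajectories[[1]], r3$trajectories[[2]]))
  # R-level stepper folds the replica id into the noise stream
  ff <- function(x) list(energy = 0, forces = 0 * x)
  a <- langevin_step(replica_state(matrix(0, 1, 3), replica_id = 1L,
                                   rng_seed = 5L), ff, 1)
  b <- langevin_step(replica_state(matrix(0, 1, 3), replica_id = 2L,
                                   rng_seed = 5L), ff, 1)
  expect_false(identical(a$velocities, b$velocities))
})

test_that("plain dynamics thermostats to the target temperature", {
  topo <- tiny_topology()
  st <- replica_state(random_walk_coords(10, seed = 1))
  run <- run_replicas(st, topo, 1e5, friction = 2, save_every = 20, seed = 4)
  temps <- run$frame_temperature[-(1:500), 1]
  expect_lt(abs(mean(temps) - 298) / 298, 0.02)
})

test_that("zero steps leaves only the initial frame", {
  topo <- tiny_topology()
  st <- replica_state(random_walk_coords(10, seed = 1))
  run <- run_replicas(st, topo, 0, save_every = 10, seed = 1)
  expect_equal(run$n_frames, 1)
  expect_equal(matrix(run$trajectories[[1]][1, , ], ncol = 3), st$coords)
})

test_that("frictionless dynamics conserves energy", {
  topo <- tiny_topology()
  st0 <- minimize(replica_state(random_walk_coords(10, seed = 6)), topo)
  # draw velocities at 298 K through a short thermostatted segment first
  warm <- run_replicas(st0, topo, 100, friction = 2, save_every = 100, seed = 2)
  st <- replica_state(matrix(warm$trajectories[[1]][2, , ], ncol = 3),
                      warm$final_velocities[[1]])
  run <- run_replicas(st, topo, 1e4, dt = 0.001, friction = 0,
                      save_every = 100, seed = 3)
  n <- 10
  etot <- run$frame_epot[, 1] +
    1.5 * n * kB * run$frame_temperature[, 1]
  drift <- abs(etot[length(etot)] - etot[1])
  expect_lt(drift, 0.001 * abs(mean(run$frame_epot[, 1])))
})

test_that("unhooked replicas are statistically independent", {
  topo <- tiny_topology()
  reps <- lapply(1:2, function(r)
    replica_state(random_walk_coords(10, seed = r), replica_id = r))
  run <- run_replicas(reps, topo, 4e4, friction = 1, save_every = 40, seed = 8)
  rg <- function(tr) apply(tr, 1, function(m) {
    x <- matrix(m, ncol = 3); cm <- colMeans(x)
    sqrt(mean(rowSums(sweep(x, 2, cm)^2)))
  })
  cc <- cor(rg(run$trajectories[[1]])[-(1:200)],
            rg(run$trajectories[[2]])[-(1:200)])
  expect_lt(abs(cc), 0.3)
})

test_that("custom hooks feed energies and abort with context", {
  topo <- build_topology("GS", conditions())
  st <- replica_state(rbind(c(0, 0, 0), c(0.38, 0, 0)))
  # constant downward pull on bead 1 of each replica
  pull <- function(coords_list, step) {
    list(energy = rep(0, length(coords_list)),
         forces = lapply(coords_list, function(x) {
           f <- 0 * x; f[1, 3] <- -50; f
         }))
  }
  run <- run_replicas(st, topo, 200, hooks = list(hook_function(pull)),
                      friction = 0, temperature = 0, save_every = 200, seed = 1)
  expect_lt(run$trajectories[[1]][2, 1, 3], 0)  # bead 1 moved down
  boom <- function(coords_list, step)
    if (step >= 3) stop("boom") else pull(coords_list, step)
  expect_error(
    run_replicas(st, topo, 100, hooks = list(hook_function(boom)), seed = 1),
    "step 3")
})
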