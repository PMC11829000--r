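make_rs <- function(i, j, target, sd = 1) {
  structure(list(restraints = data.frame(i = i, j = j, target = target,
                                         sd = sd)),
            class = "afmi_restraints")
}

test_that("the data term evaluates the Gaussian restraint energy", {
  kt <- kB * 300
  # one replica, one restraint, forward model equals the target
  rs <- make_rs(0L, 1L, 10)
  err <- error_state(1, 1, sigma_init = 1)
  coords <- list(rbind(c(0, 0, 0), c(1.0, 0, 0)))  # 10 A
  out <- restraint_energy_forces(coords, rs, err, 300)
  expect_equal(sum(out$energy), 0)
  expect_equal(max(abs(out$forces[[1]])), 0)
  # 1 A deviation at sigma_B = 1, sigma_SEM = 0: E = kBT / 2
  coords <- list(rbind(c(0, 0, 0), c(1.1, 0, 0)))  # 11 A, dev = -1 A
  out <- restraint_energy_forces(coords, rs, err, 300)
  expect_equal(sum(out$energy), 0.5 * kt)
})

test_that("data-term forces match central differences in both forward modes", {
  rs <- make_rs(c(0L, 1L, 0L), c(2L, 3L, 3L), c(8, 11, 14), sd = c(1, 2, 3))
  err <- error_state(2, 3, sigma_init = c(0.5, 1, 2))
  err$sigma_SEM <- c(0.3, 0.1, 0.6)
  set.seed(1)
  coords <- lapply(1:2, function(r) random_walk_coords(4, seed = r))
  for (mode in c("replica_average", "per_replica")) {
    out <- restraint_energy_forces(coords, rs, err, 300, mode)
    h <- 1e-6
    for (r in 1:2) for (i in 1:4) for (k in 1:3) {
      cp <- coords; cm <- coords
      cp[[r]][i, k] <- cp[[r]][i, k] + h
      cm[[r]][i, k] <- cm[[r]][i, k] - h
      num <- -(sum(restraint_energy_forces(cp, rs, err, 300, mode)$energy) -
               sum(restraint_energy_forces(cm, rs, err, 300, mode)$energy)) /
        (2 * h)
      expect_lt(abs(num - out$forces[[r]][i, k]), 1e-4)
    }
  }
})

test_that("the error energy behaves as written, with the prior switch", {
  kt <- kB * 298
  err <- error_state(1, 1, sigma_init = 1)
  expect_equal(error_energy(err, 298), 0)  # -log 1 + 0.5 log 1
  # sigma_SEM = 0: the two log terms cancel for any sigma_B (as printed)
  for (s in c(0.01, 0.5, 3, 9)) {
    err$sigma_B[1, 1] <- s
    expect_equal(error_energy(err, 298), 0, tolerance = 1e-12)
  }
  # under the Jeffreys switch they add instead
  err$sigma_B[1, 1] <- 2
  expect_equal(error_energy(err, 298, "jeffreys"), kt * 2 * log(2))
  # increasing sigma_SEM strictly increases the energy
  err$sigma_B[1, 1] <- 1
  err$sigma_SEM <- 0.5
  e1 <- error_energy(err, 298)
  err$sigma_SEM <- 1.0
  expect_gt(error_energy(err, 298), e1)
})

test_that("Gibbs moves respect bounds and widths", {
  err <- error_state(2, 3, sigma_init = 5, bounds = c(4.9, 5.1),
                     move_width = 1)
  dev <- matrix(1, 2, 3)
  for (s in 1:20) {
    err <- gibbs_update_errors(err, dev, 300, seed = s)
    expect_true(all(err$sigma_B >= 4.9 & err$sigma_B <= 5.1))
  }
  # zero move width: the chain never moves
  err <- error_state(2, 3, sigma_init = 2, move_width = 0)
  err2 <- gibbs_update_errors(err, dev, 300, seed = 1)
  expect_equal(err2$sigma_B, err$sigma_B)
  # single-sweep moves are bounded by the trial width
  err <- error_state(2, 3, sigma_init = 2, move_width = 0.1)
  err3 <- gibbs_update_errors(err, dev, 300, seed = 3)
  expect_lte(max(abs(err3$sigma_B - 2)), 0.1)
})

test_that("the sigma_B marginal matches quadrature of the full conditional", {
  # pooled chains at fixed deviation vs the normalized density on the grid
  dev <- 2
  ch <- unlist(lapply(1:40, function(s)
    gibbs_chain(dev, 4e4, sigma0 = sqrt(2), seed = s)[seq(8000, 4e4, 40)]))
  gr <- seq(1e-4, 10, length.out = 20001)
  dens <- gr^(-2) * exp(-0.5 * dev^2 / gr^2)  # Jeffreys conditional, SEM 0
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  ks <- max(abs(ecdf(ch)(gr) - cdf))
  expect_lt(ks, 0.05)
})

test_that("sigma_SEM estimates the replica-mean standard error", {
  # identical replicas give zero
  w <- array(5, dim = c(10, 4, 3))
  expect_equal(update_sigma_sem(w), rep(0, 3))
  # iid replicas with known variance v: sem^2 ~ v / n_replicas
  set.seed(2)
  v <- 2.5; nr <- 6
  w <- array(rnorm(4000 * nr * 2, sd = sqrt(v)), dim = c(4000, nr, 2))
  sem <- update_sigma_sem(w)
  se_band <- 3 * sqrt(v / nr) * sqrt(1 / (2 * 4000)) * 3  # generous
  expect_equal(sem^2, rep(v / nr, 2), tolerance = 0.05)
  expect_warning(s1 <- update_sigma_sem(array(1, c(5, 1, 2))), "single replica")
  expect_equal(s1, c(0, 0))
})

test_that("superposition RMSD matches an independent implementation", {
  set.seed(3)
  A <- matrix(rnorm(36), 12, 3)
  B <- A + matrix(rnorm(36, sd = 0.3), 12, 3)
  ours <- afmi:::cpp_kabsch_rmsd(B, A)$rmsd
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(A)), mobile = as.vector(t(B))))
  ref <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - A)^2)))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("the RMSD wall activates only beyond the threshold", {
  set.seed(4)
  refc <- matrix(rnorm(30), 10, 3)
  wall <- hook_rmsd_wall(list(0:9), list(refc), kappa = 100, threshold = 0.1)
  # identical coordinates: zero
  out <- rmsd_wall_energy_forces(refc, wall)
  expect_equal(out$energy, 0)
  expect_equal(out$rmsd[1], 0, tolerance = 1e-7)
  # rigid rotation + translation: still zero (superposition invariance)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  out2 <- rmsd_wall_energy_forces(refc %*% R + 2, wall)
  expect_equal(out2$energy, 0)
  # distorted coordinates: energy positive, forces match central differences
  x <- refc + matrix(rnorm(30, sd = 0.2), 10, 3)
  out3 <- rmsd_wall_energy_forces(x, wall)
  expect_gt(out3$energy, 0)
  h <- 1e-6
  for (i in c(1, 5, 10)) for (k in 1:3) {
    xp <- x; xm <- x
    xp[i, k] <- xp[i, k] + h; xm[i, k] <- xm[i, k] - h
    num <- -(rmsd_wall_energy_forces(xp, wall)$energy -
             rmsd_wall_energy_forces(xm, wall)$energy) / (2 * h)
    expect_lt(abs(num - out3$forces[i, k]), 1e-4)
  }
  expect_error(hook_rmsd_wall(list(0:1), list(refc[1:2, ])), "under-determined")
})

test_that("restraints self-deactivate as sigma_B grows", {
  rs <- make_rs(0L, 1L, 10)
  coords <- list(rbind(c(0, 0, 0), c(1.5, 0, 0)))  # 5 A deviation
  f_at <- vapply(c(0.5, 2, 9.9), function(s) {
    err <- error_state(1, 1, sigma_init = s)
    max(abs(restraint_energy_forces(coords, rs, err, 300)$forces[[1]]))
  }, numeric(1))
  expect_true(all(diff(f_at) < 0))
  expect_lt(f_at[3] / f_at[1], 0.01)
})

test_that("restrained sampling balances the restraint against the prior", {
  # a soft two-bead bond restrained to a stretched target with fixed small
  # sigma: the ensemble mean distance settles at the spring-balance point
  kb_soft <- 500
  topo <- build_topology("GS", conditions(), use_dh = FALSE,
                         bond_k = kb_soft)
  rs <- make_rs(0L, 1L, 4.5, sd = 0.2)  # 0.45 nm vs rest length 0.38
  reps <- lapply(1:2, function(r)
    replica_state(rbind(c(0, 0, 0), c(0.38, 0, 0)), replica_id = r))
  run <- run_replicas(reps, topo, 4e4,
                      hooks = list(hook_metainference(
                        rs, gibbs = FALSE, sigma_init = 0.2,
                        sem_floor = 0.05)),
                      friction = 2, save_every = 20, seed = 11)
  d <- vapply(1:2, function(r) {
    tr <- run$trajectories[[r]]
    mean(sqrt(rowSums((tr[-(1:500), 1, ] - tr[-(1:500), 2, ])^2))) * 10
  }, numeric(1))
  # restraint spring on the replica mean (2 replicas, sigma_B = 0.2 A,
  # sigma_SEM >= 0.05 A) vs the bond spring, in Angstrom units
  k_r <- 2 * kB * 298 * 100 / (0.2^2 + 0.05^2) / 100  # kJ/mol/A^2
  k_b <- kb_soft / 100
  d_eq <- (k_b * 3.8 + k_r * 4.5) / (k_b + k_r)
  # thermal stretching of a 3D spring shifts <r> upward by ~2kBT/(k r)
  expect_gt(mean(d), 3.9)
  expect_equal(mean(d), d_eq, tolerance = 0.05)
})
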