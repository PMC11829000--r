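## Multi-replica NVT Langevin engine.
##
## The production path is the compiled driver (cpp_run_replicas), which
## integrates all replicas with a BAOAB splitting and evaluates the optional
## restraint / bias / wall terms every step with a consistent snapshot of all
## replicas.  A pure-R single step (langevin_step) with an arbitrary force
## callback is kept for unit-level work.

#' Replica state
#'
#' @param coords N x 3 bead positions, nm.
#' @param velocities N x 3 bead velocities, nm/ps (defaults to zero).
#' @param replica_id Integer id folded into the noise stream.
#' @param rng_seed Integer seed.
#' @return List of class `"afmi_replica"`.
#' @export
replica_state <- function(coords, velocities = NULL, replica_id = 1L,
                          rng_seed = 1L) {
  coords <- as.matrix(coords)
  if (is.null(velocities)) velocities <- matrix(0, nrow(coords), 3)
  stopifnot(all(is.finite(coords)), all(is.finite(velocities)),
            all(dim(coords) == dim(velocities)))
  structure(list(coords = coords, velocities = as.matrix(velocities),
                 replica_id = as.integer(replica_id),
                 rng_seed = as.integer(rng_seed), step = 0L),
            class = "afmi_replica")
}

#' Self-avoiding random-walk starting coordinates
#'
#' Bead chain grown at the bond rest length with uniformly random directions,
#' re-drawing any step that lands within `min_dist` of an existing bead.
#' Used when no predicted structure is supplied.
#'
#' @param n Number of beads.
#' @param bond Bond length, nm.
#' @param min_dist Self-avoidance distance, nm.
#' @param seed Integer seed.
#' @return N x 3 matrix, nm.
#' @export
random_walk_coords <- function(n, bond = 0.38, min_dist = 0.35, seed = 1) {
  set.seed(seed)
  x <- matrix(0, n, 3)
  for (i in 2:n) {
    for (try in 1:200) {
      v <- rnorm(3); v <- v / sqrt(sum(v^2))
      cand <- x[i - 1, ] + bond * v
      d2 <- rowSums((x[1:(i - 1), , drop = FALSE] -
                     matrix(cand, i - 1, 3, byrow = TRUE))^2)
      if (i == 2 || min(d2[1:(i - 2)]) > min_dist^2) break
    }
    x[i, ] <- cand
  }
  x
}

#' Energy minimization
#'
#' Steepest descent with adaptive step size and displacement capping;
#' energy is non-increasing over accepted steps.
#'
#' @param state An `afmi_replica` (or bare coordinate matrix).
#' @param topology An `afmi_topology`.
#' @param max_steps Maximum descent steps (default 100).
#' @return The state with minimized coordinates (velocities untouched).
#' @export
minimize <- function(state, topology, max_steps = 100) {
  bare <- !inherits(state, "afmi_replica")
  coords <- if (bare) as.matrix(state) else state$coords
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  res <- cpp_minimize(coords, unclass(topology), as.integer(max_steps))
  if (!is.finite(res$energy)) stop("non-finite energy after minimization")
  if (bare) return(res$coords)
  state$coords <- res$coords
  state
}

#' One BAOAB Langevin step (R reference path)
#'
#' Deterministic given `rng_seed`, `replica_id` and the internal step
#' counter; the noise stream is derived from all three so replicas with the
#' same seed but different ids decorrelate.
#'
#' @param state An `afmi_replica`.
#' @param force_fn Callback `function(coords) -> list(energy, forces)`.
#' @param masses Per-bead masses, amu.
#' @param dt Time step, ps (default 0.005 = 5 fs).
#' @param friction Friction coefficient, 1/ps (default 0.01).
#' @param temperature Kelvin.
#' @return Updated `afmi_replica`.
#' @export
langevin_step <- function(state, force_fn, masses, dt = 0.005,
                          friction = 0.01, temperature = 298) {
  stopifnot(dt > 0)
  x <- state$coords; v <- state$velocities
  n <- nrow(x)
  f <- force_fn(x)$forces
  if (!all(is.finite(f))) stop("non-finite forces")
  invm <- 1 / masses
  v <- v + 0.5 * dt * f * invm
  x <- x + 0.5 * dt * v
  c1 <- exp(-friction * dt)
  c2 <- sqrt(max(0, 1 - c1^2))
  set.seed(state$rng_seed + 1000003L * state$replica_id + state$step)
  xi <- matrix(rnorm(3 * n), n, 3)
  v <- c1 * v + c2 * sqrt(kBT(temperature) * invm) * xi
  x <- x + 0.5 * dt * v
  f <- force_fn(x)$forces
  v <- v + 0.5 * dt * f * invm
  state$coords <- x; state$velocities <- v
  state$step <- state$step + 1L
  state
}

#' Relax a starting structure against the distance restraints
#'
#' Random-walk (or otherwise arbitrary) starting coordinates can sit tens of
#' Angstrom away from the restraint targets, which makes the early
#' restraint forces integrator-breaking.  This quasi-Newton relaxation of
#' E_MD plus a fixed-sigma harmonic version of the data term produces a
#' start that is close to the data, playing the role of the predicted
#' structure the production protocol starts from.
#'
#' @param coords N x 3 starting coordinates, nm.
#' @param topology An `afmi_topology`.
#' @param restraints An `afmi_restraints` (or NULL for plain relaxation).
#' @param temperature Kelvin (sets the restraint prefactor).
#' @param maxit L-BFGS iterations (default 300).
#' @return Relaxed N x 3 coordinate matrix, nm.
#' @export
relax_to_restraints <- function(coords, topology, restraints = NULL,
                                temperature = 298, maxit = 300) {
  n <- nrow(coords)
  kt <- kBT(temperature)
  df <- if (!is.null(restraints)) restraints$restraints else NULL
  sig2 <- if (!is.null(df)) pmax(df$sd, 1)^2 else NULL
  eg <- function(par) {
    x <- matrix(par, n, 3)
    cg <- cpp_energy_forces(x, unclass(topology))
    e <- cg$energy; g <- -cg$forces
    if (!is.null(df) && nrow(df) > 0) {
      a <- x[df$i + 1, , drop = FALSE]; b <- x[df$j + 1, , drop = FALSE]
      dvec <- a - b
      r <- sqrt(rowSums(dvec^2))
      dev <- df$target - 10 * r
      e <- e + 0.5 * kt * sum(dev^2 / sig2)
      pref <- -kt * dev / sig2 * 10 / r
      for (d in seq_len(nrow(df))) {
        g[df$i[d] + 1, ] <- g[df$i[d] + 1, ] + pref[d] * dvec[d, ]
        g[df$j[d] + 1, ] <- g[df$j[d] + 1, ] - pref[d] * dvec[d, ]
      }
    }
    list(e = e, g = g)
  }
  res <- stats::optim(as.vector(coords), fn = function(p) eg(p)$e,
                      gr = function(p) as.vector(eg(p)$g),
                      method = "L-BFGS-B", control = list(maxit = maxit))
  matrix(res$par, n, 3)
}

#' Hook constructors for the replica driver
#'
#' Built-in energy/force contributors evaluated by the compiled driver every
#' step: the Bayesian distance-restraint term, the parallel-bias metadynamics
#' bias, and the structured-segment RMSD wall.  `hook_function` wraps an
#' arbitrary R callback `function(coords_list, step) ->
#' list(energy = numeric(n_replicas), forces = list of N x 3 matrices)`
#' (slow; intended for tests).
#'
#' @param restraints An `afmi_restraints` object.
#' @param sigma_bounds Error-parameter sampling range, Angstrom.
#' @param move_width Gibbs trial-move half-width, Angstrom.
#' @param sem_window Window (steps) for the replica-standard-error refresh.
#' @param forward_model `"replica_average"` (default) or `"per_replica"`.
#' @param sigma_prior `"jeffreys"` (default for simulation) or
#'   `"as_printed"`; see [error_energy()].
#' @param gibbs Sample the error parameters (default TRUE).
#' @param sigma_init Optional per-datapoint initial sigma_B, Angstrom
#'   (defaults to the distogram per-pair spread, clamped to the bounds).
#' @param sem_floor Lower bound on sigma_SEM, Angstrom.  The default is half
#'   the distogram bin width (0.1538 A): the data are quantized at one bin,
#'   so a combined error claiming sub-bin precision is unphysical and makes
#'   the restraint springs stiffer than the integrator can resolve.
#' @param sem_alpha Exponential-moving-average weight of each window's
#'   sigma_SEM estimate (default 0.1).  The raw 200-step window estimate has
#'   ~40% sampling noise; feeding it in unsmoothed modulates every restraint
#'   spring constant once per window, which parametrically pumps heat into
#'   the weakly coupled Langevin bath.
#' @return A hook specification consumed by [run_replicas()].
#' @export
hook_metainference <- function(restraints, sigma_bounds = c(1e-4, 10),
                               move_width = 0.1, sem_window = 200,
                               forward_model = c("replica_average",
                                                 "per_replica"),
                               sigma_prior = c("jeffreys", "as_printed"),
                               gibbs = TRUE, sigma_init = NULL,
                               sem_floor = 0.15380859375, sem_alpha = 0.1) {
  forward_model <- match.arg(forward_model)
  sigma_prior <- match.arg(sigma_prior)
  df <- restraints$restraints
  if (is.null(sigma_init)) sigma_init <- pmax(df$sd, sigma_bounds[1])
  structure(list(
    type = "metainference",
    restraints = list(i = as.integer(df$i), j = as.integer(df$j),
                      target = df$target),
    meta = list(sigma_lower = sigma_bounds[1], sigma_upper = sigma_bounds[2],
                move_width = move_width, sem_window = as.integer(sem_window),
                forward_mode = if (forward_model == "replica_average") 0L else 1L,
                sigma_prior = if (sigma_prior == "as_printed") 1L else -1L,
                gibbs = gibbs, sigma_init = sigma_init,
                sem_floor = sem_floor, sem_alpha = sem_alpha)),
    class = "afmi_hook")
}

#' @rdname hook_metainference
#' @param cvs List of CV specifications from [cv_spec()].
#' @param height Hill height, kJ/mol.
#' @param bias_factor Well-tempering factor (> 1).
#' @param pace Steps between hill depositions.
#' @export
hook_metadynamics <- function(cvs, height = 0.5, bias_factor = 10,
                              pace = 500) {
  stopifnot(bias_factor > 1, pace >= 1)
  structure(list(type = "metadynamics",
                 metad = list(cvs = lapply(cvs, unclass), height = height,
                              bias_factor = bias_factor,
                              pace = as.integer(pace))),
            class = "afmi_hook")
}

#' @rdname hook_metainference
#' @param segments List of 0-based residue index vectors (one per structured
#'   segment).
#' @param references List of reference coordinate matrices (nm), one per
#'   segment, in segment order.
#' @param kappa Wall force constant, kJ/mol/nm^2.
#' @param threshold RMSD threshold, nm.
#' @export
hook_rmsd_wall <- function(segments, references, kappa = 1e4,
                           threshold = 0.1) {
  stopifnot(length(segments) == length(references), threshold > 0)
  for (k in seq_along(segments))
    if (length(segments[[k]]) < 3)
      stop("segment ", k, " has fewer than 3 beads: superposition is ",
           "under-determined")
  structure(list(type = "rmsd_wall",
                 wall = list(segments = lapply(segments, as.integer),
                             references = references,
                             kappa = kappa, threshold = threshold)),
            class = "afmi_hook")
}

#' @rdname hook_metainference
#' @param fn R callback (see Description).
#' @export
hook_function <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(type = "custom", fn = fn), class = "afmi_hook")
}

#' Run multi-replica Langevin dynamics
#'
#' Integrates `n_replicas` copies of the system with the compiled BAOAB
#' driver.  Hooks are evaluated synchronously once per step with a
#' consistent snapshot of all replicas (the metainference term needs
#' cross-replica access).  Fully reproducible per seed.
#'
#' @param replicas List of `afmi_replica` states (or a single state).
#' @param topology An `afmi_topology`.
#' @param n_steps Number of MD steps.
#' @param hooks List of hook objects (see [hook_metainference()]); may be
#'   empty for plain CG dynamics.
#' @param dt Time step, ps (default 0.005 = 5 fs).
#' @param friction 1/ps (default 0.01).
#' @param temperature Kelvin (defaults to the topology conditions).
#' @param save_every Frame-saving stride (default 100).
#' @param seed Integer seed for the single engine noise stream.
#' @return List of class `"afmi_run"` with per-replica trajectories (frames
#'   x beads x 3, nm), per-frame energies / bias / CV values / kinetic
#'   temperatures, hill log and bias grids (when biased), and final error
#'   parameters (when restrained).
#' @export
run_replicas <- function(replicas, topology, n_steps, hooks = list(),
                         dt = 0.005, friction = 0.01, temperature = NULL,
                         save_every = 100, seed = 1) {
  if (inherits(replicas, "afmi_replica")) replicas <- list(replicas)
  stopifnot(length(replicas) >= 1, n_steps >= 0)
  if (is.null(temperature)) temperature <- topology$conditions$temperature
  restr <- meta <- metad <- wall <- NULL
  custom <- NULL
  for (h in hooks) {
    stopifnot(inherits(h, "afmi_hook"))
    switch(h$type,
           metainference = { restr <- h$restraints; meta <- h$meta },
           metadynamics = { metad <- h$metad },
           rmsd_wall = { wall <- h$wall },
           custom = { custom <- h$fn })
  }
  if (!is.null(restr) && length(restr$i) == 0) { restr <- NULL; meta <- NULL }
  if (!is.null(custom)) {
    fn <- custom
    custom <- function(coords_list, step) {
      tryCatch(fn(coords_list, step), error = function(e)
        stop("hook failed at step ", step, ": ", conditionMessage(e),
             call. = FALSE))
    }
  }
  coords <- lapply(replicas, `[[`, "coords")
  vels <- lapply(replicas, `[[`, "velocities")
  all_zero <- all(vapply(vels, function(v) all(v == 0), logical(1)))
  res <- cpp_run_replicas(
    coords, if (all_zero) NULL else vels, unclass(topology),
    dt, friction, temperature, as.integer(n_steps), as.integer(save_every),
    as.integer(seed), restr, meta, metad, wall, custom)
  res$n_replicas <- length(replicas)
  res$save_every <- save_every
  res$dt <- dt
  res$temperature <- temperature
  res$topology <- topology
  class(res) <- "afmi_run"
  res
}

#' @export
print.afmi_run <- function(x, ...) {
  cat("Multi-replica Langevin run:", x$n_replicas, "replica(s),",
      x$n_frames, "saved frames each (stride", x$save_every, ")\n")
  if (!is.null(x$hills))
    cat("  metadynamics hills deposited:", nrow(x$hills), "\n")
  if (!is.null(x$sigma_B))
    cat("  restrained datapoints:", ncol(x$sigma_B), "\n")
  invisible(x)
}

#' Extract an ensemble from a run
#'
#' Concatenates the per-replica trajectories (after discarding an
#' equilibration fraction per replica) into a uniform-weight ensemble.
#'
#' @param run An `afmi_run`.
#' @param equilibration_fraction Fraction of initial frames discarded per
#'   replica (default 0).
#' @return An `afmi_ensemble`.
#' @export
run_ensemble <- function(run, equilibration_fraction = 0) {
  frames <- list(); src_rep <- integer(); src_frm <- integer()
  for (r in seq_len(run$n_replicas)) {
    tr <- run$trajectories[[r]]
    nf <- dim(tr)[1]
    first <- floor(equilibration_fraction * nf) + 1
    for (f in first:nf) {
      frames[[length(frames) + 1]] <- matrix(tr[f, , ], ncol = 3)
      src_rep <- c(src_rep, r); src_frm <- c(src_frm, f)
    }
  }
  new_ensemble(frames, sequence = run$topology$sequence,
               source = data.frame(replica = src_rep, frame = src_frm))
}

#' Construct a bead ensemble
#'
#' @param frames List of N x 3 coordinate matrices, nm.
#' @param weights Frame weights (default uniform; normalized).
#' @param sequence Optional amino-acid string.
#' @param source Optional provenance data frame.
#' @return List of class `"afmi_ensemble"`.
#' @export
bead_ensemble <- function(frames, weights = NULL, sequence = NULL,
                          source = NULL) {
  new_ensemble(frames, weights, sequence, source)
}

new_ensemble <- function(frames, weights = NULL, sequence = NULL,
                         source = NULL) {
  if (is.null(weights)) weights <- rep(1 / length(frames), length(frames))
  stopifnot(length(weights) == length(frames), all(weights >= 0))
  weights <- weights / sum(weights)
  structure(list(frames = frames, weights = weights, sequence = sequence,
                 source = source), class = "afmi_ensemble")
}

#' @export
print.afmi_ensemble <- function(x, ...) {
  cat("Bead ensemble:", length(x$frames), "frames,",
      nrow(x$frames[[1]]), "beads",
      if (!is.null(x$sequence)) paste0("(", x$sequence, ")") else "", "\n")
  invisible(x)
}
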