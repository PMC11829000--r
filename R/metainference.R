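## Bayesian distance-restraint energy (metainference).
##
## The restrained ensemble samples E = E_MD + E_data + E_sigma where, for
## datapoint i (an AlphaFold-predicted distance d_i) and replica r,
##
##   E_data  = (kB T / 2) sum_{r,i} [d_i - f_i]^2 / (sigma_B[r,i]^2 + sigma_SEM[i]^2)
##   E_sigma = kB T sum_{r,i} [ s * (-log sigma_B[r,i])
##                              + 1/2 log(sigma_B[r,i]^2 + sigma_SEM[i]^2) ]
##
## f_i is the forward model: the bead-bead distance, either per replica or
## (default) averaged over replicas, which is the maximum-entropy reading of
## ensemble-averaged data.  The sign s of the prior term is +1 "as printed"
## and -1 for the Jeffreys convention (sigma_prior switch): as printed the
## sigma marginal at fixed deviation is monotone toward the upper bound and
## the restraints self-deactivate, so the simulation default is Jeffreys.
## sigma_B is Gibbs-sampled each step within the bounds; sigma_SEM is the
## standard error of the replica-mean forward model, refreshed on a window.
## All sigma and deviations are in Angstrom (the ratio is dimensionless).

#' Error-parameter state for the metainference energy
#'
#' @param n_replicas,n_data Dimensions.
#' @param sigma_init Initial sigma_B per datapoint (recycled across
#'   replicas), Angstrom; clamped to bounds.
#' @param bounds Sampling range, Angstrom (default `c(1e-4, 10)`).
#' @param move_width Gibbs trial-move half-width, Angstrom (default 0.1).
#' @return List of class `"afmi_errors"` with `sigma_B` (n_replicas x
#'   n_data), `sigma_SEM` (n_data), `bounds`, `move_width`.
#' @export
error_state <- function(n_replicas, n_data, sigma_init = 1,
                        bounds = c(1e-4, 10), move_width = 0.1) {
  stopifnot(bounds[1] > 0, bounds[2] > bounds[1], n_replicas >= 1, n_data >= 1)
  sB <- matrix(pmin(bounds[2], pmax(bounds[1], sigma_init)),
               n_replicas, n_data, byrow = TRUE)
  structure(list(sigma_B = sB, sigma_SEM = rep(0, n_data), bounds = bounds,
                 move_width = move_width), class = "afmi_errors")
}

#' Metainference data-term energy and forces
#'
#' @param coords_list List of N x 3 coordinate matrices (nm), one per
#'   replica.
#' @param restraints An `afmi_restraints`.
#' @param errors An `afmi_errors` dimensioned (n_replicas, n_data).
#' @param temperature Kelvin.
#' @param forward_model `"replica_average"` (default) or `"per_replica"`.
#' @return List with `energy` (per-replica vector, kJ/mol; the total is the
#'   sum), `forces` (list of N x 3 matrices, kJ/mol/nm), `forward`
#'   (n_replicas x n_data distances, Angstrom), `deviations`.
#' @export
restraint_energy_forces <- function(coords_list, restraints, errors,
                                    temperature,
                                    forward_model = c("replica_average",
                                                      "per_replica")) {
  forward_model <- match.arg(forward_model)
  df <- restraints$restraints
  nr <- length(coords_list); nd <- nrow(df)
  stopifnot(nrow(errors$sigma_B) == nr, ncol(errors$sigma_B) == nd)
  kt <- kBT(temperature)
  fwd <- matrix(0, nr, nd)
  for (r in seq_len(nr)) {
    a <- coords_list[[r]][df$i + 1, , drop = FALSE]
    b <- coords_list[[r]][df$j + 1, , drop = FALSE]
    fwd[r, ] <- 10 * sqrt(rowSums((a - b)^2))  # nm -> Angstrom
  }
  denom <- sweep(errors$sigma_B^2, 2, errors$sigma_SEM^2, "+")
  energy <- numeric(nr)
  forces <- lapply(coords_list, function(x) matrix(0, nrow(x), 3))
  if (forward_model == "replica_average") {
    fbar <- colMeans(fwd)
    dev <- df$target - fbar
    wsum <- colSums(1 / denom)
    etot <- 0.5 * kt * sum(dev^2 * wsum)
    energy <- rep(etot / nr, nr)
    forces <- lapply(seq_len(nr), function(r) {
      fo <- matrix(0, nrow(coords_list[[r]]), 3)
      a <- coords_list[[r]][df$i + 1, , drop = FALSE]
      b <- coords_list[[r]][df$j + 1, , drop = FALSE]
      dvec <- a - b
      rnm <- sqrt(rowSums(dvec^2))
      pref <- kt * dev * wsum / nr * 10 / rnm
      for (d in seq_len(nd)) {
        fo[df$i[d] + 1, ] <- fo[df$i[d] + 1, ] + pref[d] * dvec[d, ]
        fo[df$j[d] + 1, ] <- fo[df$j[d] + 1, ] - pref[d] * dvec[d, ]
      }
      fo
    })
    devs <- matrix(dev, nr, nd, byrow = TRUE)
  } else {
    devs <- sweep(-fwd, 2, df$target, "+")
    for (r in seq_len(nr)) {
      w <- 1 / denom[r, ]
      energy[r] <- 0.5 * kt * sum(devs[r, ]^2 * w)
      a <- coords_list[[r]][df$i + 1, , drop = FALSE]
      b <- coords_list[[r]][df$j + 1, , drop = FALSE]
      dvec <- a - b
      rnm <- sqrt(rowSums(dvec^2))
      pref <- kt * devs[r, ] * w * 10 / rnm
      for (d in seq_len(nd)) {
        forces[[r]][df$i[d] + 1, ] <- forces[[r]][df$i[d] + 1, ] +
          pref[d] * dvec[d, ]
        forces[[r]][df$j[d] + 1, ] <- forces[[r]][df$j[d] + 1, ] -
          pref[d] * dvec[d, ]
      }
    }
  }
  list(energy = energy, forces = forces, forward = fwd, deviations = devs)
}

#' Error-term energy
#'
#' Evaluates the sigma-dependent part of the metainference energy.  The
#' default `sigma_prior = "as_printed"` uses the -log(sigma_B) form; the
#' `"jeffreys"` switch flips the sign of that term (+log sigma_B), which is
#' the convention under which the sigma marginal tracks the magnitude of the
#' deviations.
#'
#' @param errors An `afmi_errors`.
#' @param temperature Kelvin.
#' @param sigma_prior `"as_printed"` or `"jeffreys"`.
#' @return Energy in kJ/mol.
#' @export
error_energy <- function(errors, temperature,
                         sigma_prior = c("as_printed", "jeffreys")) {
  sigma_prior <- match.arg(sigma_prior)
  s <- if (sigma_prior == "as_printed") 1 else -1
  sB <- errors$sigma_B
  sem2 <- matrix(errors$sigma_SEM^2, nrow(sB), ncol(sB), byrow = TRUE)
  kBT(temperature) * sum(s * (-log(sB)) + 0.5 * log(sB^2 + sem2))
}

#' One Gibbs sweep over the error parameters
#'
#' Per (replica, datapoint): uniform trial move `sigma' = sigma + U(-w, w)`,
#' rejected outside the bounds, accepted by Metropolis with the full
#' conditional built from the data term plus the error term.  sigma_SEM is
#' held fixed during the sweep.  Deterministic per `seed`.
#'
#' @param errors An `afmi_errors`.
#' @param deviations n_replicas x n_data matrix of `d_i - f_i`, Angstrom.
#' @param temperature Kelvin (cancels in the acceptance; kept for the
#'   interface contract).
#' @param seed Integer seed.
#' @param sigma_prior See [error_energy()]; default `"jeffreys"`.
#' @return Updated `afmi_errors`.
#' @export
gibbs_update_errors <- function(errors, deviations, temperature, seed = 1,
                                sigma_prior = c("jeffreys", "as_printed")) {
  sigma_prior <- match.arg(sigma_prior)
  s <- if (sigma_prior == "as_printed") 1 else -1
  sB <- errors$sigma_B
  stopifnot(all(dim(deviations) == dim(sB)))
  lo <- errors$bounds[1]; hi <- errors$bounds[2]
  w <- errors$move_width
  set.seed(seed)
  e_kT <- function(dev, sig, sem) {
    s2 <- sig^2 + sem^2
    0.5 * dev^2 / s2 + s * (-log(sig)) + 0.5 * log(s2)
  }
  for (r in seq_len(nrow(sB))) {
    for (i in seq_len(ncol(sB))) {
      prop <- sB[r, i] + runif(1, -w, w)
      if (prop < lo || prop > hi) next
      de <- e_kT(deviations[r, i], prop, errors$sigma_SEM[i]) -
            e_kT(deviations[r, i], sB[r, i], errors$sigma_SEM[i])
      if (de <= 0 || runif(1) < exp(-de)) sB[r, i] <- prop
    }
  }
  errors$sigma_B <- sB
  errors
}

#' Long Gibbs chain at fixed deviation (diagnostic)
#'
#' Runs the compiled sampler for one (replica, datapoint) error parameter at
#' a fixed deviation, returning the sigma_B chain.  Used to check the
#' sampler against direct quadrature of the full conditional.
#'
#' @param deviation Fixed deviation, Angstrom.
#' @param n_sweeps Chain length.
#' @param sigma0 Starting value.
#' @param sigma_sem Fixed sigma_SEM.
#' @param bounds,move_width As in [error_state()].
#' @param sigma_prior See [error_energy()].
#' @param seed Integer seed.
#' @return Numeric vector of sampled sigma_B values.
#' @export
gibbs_chain <- function(deviation, n_sweeps, sigma0 = 1, sigma_sem = 0,
                        bounds = c(1e-4, 10), move_width = 0.1,
                        sigma_prior = c("jeffreys", "as_printed"), seed = 1) {
  sigma_prior <- match.arg(sigma_prior)
  s <- if (sigma_prior == "as_printed") 1L else -1L
  cpp_gibbs_chain(deviation, sigma0, sigma_sem, bounds[1], bounds[2],
                  move_width, as.integer(n_sweeps), s, as.integer(seed))
}

#' Update sigma_SEM from a window of forward-model values
#'
#' Estimates, per datapoint, the standard error of the replica-mean forward
#' model: the across-replica variance of f (unbiased) divided by the number
#' of replicas, averaged over the window steps, square-rooted.
#'
#' @param window 3-d array (steps x n_replicas x n_data) or a list of
#'   n_replicas x n_data matrices of forward-model values, Angstrom.
#' @return Numeric vector sigma_SEM (n_data), Angstrom.
#' @export
update_sigma_sem <- function(window) {
  if (is.list(window))
    window <- aperm(simplify2array(window), c(3, 1, 2))
  stopifnot(length(dim(window)) == 3)
  nr <- dim(window)[2]
  if (nr < 2) {
    warning("single replica: sigma_SEM = 0")
    return(rep(0, dim(window)[3]))
  }
  v <- apply(window, c(1, 3), var)      # steps x n_data across-replica var
  sqrt(colMeans(v / nr))
}

#' RMSD upper-wall energy and forces
#'
#' Per structured segment, the optimal-superposition (Kabsch) RMSD of the
#' segment beads to the reference is computed; when it exceeds the threshold
#' a one-sided harmonic penalty `kappa/2 (RMSD - threshold)^2` applies, with
#' forces through the superposition by the envelope theorem.
#'
#' @param coords N x 3 bead coordinates, nm.
#' @param wall A wall specification from [hook_rmsd_wall()].
#' @return List with `energy` (kJ/mol), `forces` (N x 3), `rmsd` (per
#'   segment, nm).
#' @export
rmsd_wall_energy_forces <- function(coords, wall) {
  w <- wall$wall
  if (length(w$segments) == 0) stop("empty wall segment list")
  energy <- 0
  forces <- matrix(0, nrow(coords), 3)
  rmsds <- numeric(length(w$segments))
  for (k in seq_along(w$segments)) {
    idx <- w$segments[[k]] + 1
    res <- cpp_kabsch_rmsd(coords[idx, , drop = FALSE], w$references[[k]],
                           gradient = TRUE)
    rmsds[k] <- res$rmsd
    if (res$rmsd > w$threshold) {
      over <- res$rmsd - w$threshold
      energy <- energy + 0.5 * w$kappa * over^2
      forces[idx, ] <- forces[idx, ] - w$kappa * over * res$gradient
    }
  }
  list(energy = energy, forces = forces, rmsd = rmsds)
}
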