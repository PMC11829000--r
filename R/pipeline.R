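## Pipeline driver: configuration, the top-level afmi() run, and its
## S3 methods.

#' Pipeline configuration
#'
#' All protocol constants in one nested list.  The `"production"` profile
#' carries the published-protocol defaults (6 replicas, 1e6 steps, 5 fs time
#' step, friction 0.01/ps, error-sampling range [1e-4, 10] A with trial
#' moves of 0.1 A refreshed-window 200); the `"test"` profile shrinks the
#' sampling to 2 replicas x 2e5 steps for desk-scale runs.  Any entry can be
#' overridden via `...` (named nested lists are merged).
#'
#' @param profile `"production"` or `"test"`.
#' @param ... Named overrides, e.g. `engine = list(seed = 7)`.
#' @return Nested list of class `"afmi_config"`.
#' @export
afmi_config <- function(profile = c("production", "test"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    selection = list(
      tail_threshold = 0.02,
      kd_threshold = -1.4,
      stretch_len = 5, stretch_cutoff = 75,
      segment_min_len = 2, segment_cutoff = 75,
      pae_cutoffs = c(10, 5),
      min_separation = 3),
    engine = list(
      n_replicas = 6, n_steps = 1e6,
      dt = 0.005, friction = 0.01,
      temperature = 298, pH = 7, ionic_strength = 0.15,
      save_every = 100, seed = 1),
    metainference = list(
      sigma_bounds = c(1e-4, 10), move_width = 0.1, sem_window = 200,
      forward_model = "replica_average", sigma_prior = "jeffreys",
      sem_floor = 0.15380859375, sem_alpha = 0.1),
    metad = list(height = 0.5, bias_factor = 10, pace = 500),
    wall = list(kappa = 1e4, threshold = 0.1),
    output = list(equilibration_fraction = 0.1, n_blocks = 5,
                  n_resample = 2000))
  if (profile == "test") {
    cfg$engine$n_replicas <- 2
    cfg$engine$n_steps <- 2e5
  }
  cfg$profile <- profile
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  structure(cfg, class = "afmi_config")
}

#' Write / read a config as YAML
#'
#' @param config An `afmi_config`.
#' @param path File path.
#' @return The config (read) or `path` (write), invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "afmi_config")
}

#' Run the full restrained-ensemble pipeline
#'
#' Selects distance restraints from the distogram and annotations, builds
#' the coarse-grained model, minimizes, runs the multi-replica restrained +
#' biased simulation, reweights the concatenated trajectory with
#' Torrie-Valleau weights, resamples the final ensemble and computes the
#' analysis block (P(r), Rg, scaling exponent, and D_KL against a reference
#' distribution when one is supplied).
#'
#' Inputs may be given as in-memory objects or file paths (FASTA, distogram
#' exchange JSON, PAE JSON, pLDDT table, multi-model PDB).
#'
#' @param sequence Amino-acid string or FASTA path (optional if the
#'   distogram carries it).
#' @param distogram An `afmi_distogram` or path to exchange JSON.
#' @param annotations List with `plddt` and `pae`, or
#'   `list(plddt = <path>, pae = <path>)`.
#' @param start Optional starting structure: N x 3 matrix (nm) or PDB path
#'   (used for replica starts and as the RMSD-wall reference for structured
#'   segments).
#' @param reference Optional reference `afmi_ensemble` (or `afmi_pr`) for
#'   the D_KL validation entry.
#' @param config An [afmi_config()].
#' @param restrained Set `FALSE` for the unrestrained control run (same
#'   sampling, no distance restraints).
#' @return Object of class `"afmi"`: the restraint set, run metadata, the
#'   final resampled ensemble, per-frame weights, convergence profiles and
#'   the analysis block.
#' @export
afmi <- function(sequence = NULL, distogram, annotations, start = NULL,
                 reference = NULL, config = afmi_config("production"),
                 restrained = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # --- input resolution (fail fast, before any simulation) ---------------
  if (is.character(distogram)) distogram <- stage("inputs",
                                                  read_distogram(distogram))
  if (is.character(sequence) && file.exists(sequence))
    sequence <- read_fasta_sequence(sequence)
  if (is.null(sequence)) sequence <- distogram$sequence
  if (is.character(annotations$pae))
    annotations$pae <- stage("inputs", read_pae(annotations$pae))
  if (is.character(annotations$plddt))
    annotations$plddt <- stage("inputs", read_plddt(annotations$plddt))
  if (is.character(start)) start <- read_ensemble_pdb(start)$frames[[1]]
  cfg <- config

  # --- restraint selection ----------------------------------------------
  sel <- cfg$selection
  rs <- stage("restraints", select_restraints(
    distogram, annotations,
    tail_threshold = sel$tail_threshold,
    min_separation = sel$min_separation,
    kd_threshold = sel$kd_threshold,
    stretch_len = sel$stretch_len, stretch_cutoff = sel$stretch_cutoff,
    segment_cutoff = sel$segment_cutoff,
    segment_min_len = sel$segment_min_len))

  # --- model and starting states ----------------------------------------
  cond <- conditions(cfg$engine$temperature, cfg$engine$pH,
                     cfg$engine$ionic_strength)
  topo <- stage("topology", build_topology(sequence, cond))
  n <- nchar(sequence)
  seed <- cfg$engine$seed
  replicas <- lapply(seq_len(cfg$engine$n_replicas), function(r) {
    x0 <- if (!is.null(start)) start else
      relax_to_restraints(random_walk_coords(n, seed = seed + 7919 * r),
                          topo, if (restrained) rs else NULL,
                          temperature = cfg$engine$temperature)
    minimize(replica_state(x0, replica_id = r, rng_seed = seed + r), topo,
             max_steps = 100)
  })

  # --- hooks -------------------------------------------------------------
  hooks <- list()
  if (restrained && nrow(rs$restraints) > 0)
    hooks <- c(hooks, list(hook_metainference(
      rs, sigma_bounds = cfg$metainference$sigma_bounds,
      move_width = cfg$metainference$move_width,
      sem_window = cfg$metainference$sem_window,
      forward_model = cfg$metainference$forward_model,
      sigma_prior = cfg$metainference$sigma_prior,
      sem_floor = cfg$metainference$sem_floor,
      sem_alpha = cfg$metainference$sem_alpha)))
  cvs <- default_cvs(n)
  hooks <- c(hooks, list(hook_metadynamics(
    cvs, height = cfg$metad$height, bias_factor = cfg$metad$bias_factor,
    pace = cfg$metad$pace)))
  segs <- rs$structured_segments
  if (!is.null(start) && nrow(segs) > 0) {
    seg_idx <- lapply(seq_len(nrow(segs)), function(k)
      segs[k, 1]:(segs[k, 2] - 1))
    seg_idx <- Filter(function(s) length(s) >= 3, seg_idx)
    if (length(seg_idx) > 0)
      hooks <- c(hooks, list(hook_rmsd_wall(
        seg_idx, lapply(seg_idx, function(s) start[s + 1, , drop = FALSE]),
        kappa = cfg$wall$kappa, threshold = cfg$wall$threshold)))
  }

  # --- sampling ----------------------------------------------------------
  run <- stage("sampling", run_replicas(
    replicas, topo, n_steps = cfg$engine$n_steps, hooks = hooks,
    dt = cfg$engine$dt, friction = cfg$engine$friction,
    save_every = cfg$engine$save_every, seed = seed))

  # --- reweighting -------------------------------------------------------
  eq <- cfg$output$equilibration_fraction
  temp <- cfg$engine$temperature
  ens <- run_ensemble(run, equilibration_fraction = eq)
  nf <- dim(run$trajectories[[1]])[1]
  # per-frame CVs for all replicas, replica-major (matches run_ensemble)
  cv_all <- do.call(cbind, lapply(run$frame_cv, as.vector))
  bias_all <- stage("reweighting", recompute_final_bias(
    cv_all, hills = run$hills, cvs = cvs, temperature = temp))
  w_all <- torrie_valleau_weights(bias_all, temp)
  keep <- rep(seq_len(nf) > floor(eq * nf), times = run$n_replicas)
  w <- w_all[keep] / sum(w_all[keep])
  ess <- suppressWarnings(effective_sample_size(w))
  final <- resample_ensemble(ens, weights = w,
                             n_out = cfg$output$n_resample, seed = seed)
  conv <- convergence_profiles(
    run$frame_cv[[1]], matrix(w_all, nf, run$n_replicas), temp,
    n_blocks = cfg$output$n_blocks, equilibration_fraction = eq)

  # --- analysis ----------------------------------------------------------
  pr_out <- pair_distance_distribution(final)
  rg <- radius_of_gyration(final)
  nu <- if (n >= 10) scaling_exponent(final) else NULL
  dkl <- NULL
  if (!is.null(reference)) {
    pr_ref <- if (inherits(reference, "afmi_pr")) reference else
      pair_distance_distribution(reference)
    dkl <- kl_divergence(pr_ref, pr_out)
  }
  structure(list(
    sequence = sequence, restraints = rs, config = cfg, run = run,
    weights = w, ess = ess, ensemble = final,
    convergence = conv,
    analysis = list(pr = pr_out, rg = rg, scaling = nu, dkl = dkl),
    elapsed = proc.time()[["elapsed"]] - t0), class = "afmi")
}

#' @rdname afmi
#' @export
run_pipeline <- afmi

#' @export
print.afmi <- function(x, ...) {
  cat("AlphaFold-Metainference run (", nchar(x$sequence), " residues, ",
      x$config$engine$n_replicas, " replicas x ",
      format(x$config$engine$n_steps, scientific = FALSE), " steps)\n",
      sep = "")
  cat("  restraints kept:  ", nrow(x$restraints$restraints), "\n")
  cat("  final ensemble:   ", length(x$ensemble$frames), "frames (ESS",
      round(x$ess), "of", length(x$weights), ")\n")
  cat(sprintf("  Rg = %.2f +- %.2f A", x$analysis$rg$mean, x$analysis$rg$se))
  if (!is.null(x$analysis$scaling))
    cat(sprintf(", nu = %.3f", x$analysis$scaling$nu))
  if (!is.null(x$analysis$dkl))
    cat(sprintf(", D_KL vs reference = %.4f", x$analysis$dkl))
  cat("\n")
  invisible(x)
}

#' @export
summary.afmi <- function(object, ...) {
  x <- object
  print(x)
  cat("\nRestraint filter provenance:\n")
  print(x$restraints$provenance)
  if (!is.null(x$run$sigma_B)) {
    cat("\nFinal error parameters sigma_B (A): median",
        round(stats::median(x$run$sigma_B), 3), ", range",
        paste(round(range(x$run$sigma_B), 3), collapse = " - "), "\n")
  }
  invisible(x)
}

#' @export
plot.afmi <- function(x, which = c("pr", "convergence"), ...) {
  which <- match.arg(which)
  if (which == "pr") {
    plot(x$analysis$pr, main = "Pairwise distance distribution")
  } else {
    cp <- x$convergence
    graphics::matplot(cp$s, cp$profiles, type = "l", lty = 1,
                      xlab = "CV (nm)", ylab = "F (kJ/mol)",
                      main = "Block convergence")
  }
  invisible(x)
}
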