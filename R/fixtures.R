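## Synthetic inputs.
##
## Everything the pipeline consumes -- sequences, reference ensembles,
## distograms, PAE/pLDDT annotations -- can be generated here, so the whole
## machinery is testable end-to-end with no downloads.  The pLDDT and PAE
## distributions are invented test scaffolding (high confidence inside
## designated ordered segments, low outside; PAE a noisy monotone function
## of the per-pair distance spread, mimicking the observed correlation
## between PAE maps and distance-fluctuation matrices).  No claim of
## AlphaFold realism is made.

DISORDER_AA <- c("G", "S", "T", "N", "Q", "E", "K", "D", "R", "P", "A")
ORDER_AA <- c("F", "Y", "W", "L", "I", "V", "M", "A")

#' Generate a synthetic protein
#'
#' Reproducible sequence with hydrophilic, disorder-prone composition;
#' designated ordered segments are biased toward sticky/hydrophobic
#' residues.  The polyampholyte pattern alternates E and K on the disordered
#' part for a net charge of 0 +- 1.
#'
#' @param length Sequence length (>= 10).
#' @param ordered_segments Integer matrix of half-open 0-based ranges
#'   (columns start, end), or NULL.
#' @param charge_pattern `"neutral"` or `"polyampholyte"`.
#' @param seed Integer seed.
#' @return List of class `"afmi_protein"` with `sequence`,
#'   `ordered_segments`, `seed`.
#' @export
make_synthetic_protein <- function(length, ordered_segments = NULL,
                                   charge_pattern = c("neutral",
                                                      "polyampholyte"),
                                   seed = 1) {
  charge_pattern <- match.arg(charge_pattern)
  stopifnot(length >= 10)
  if (is.null(ordered_segments))
    ordered_segments <- matrix(integer(), 0, 2,
                               dimnames = list(NULL, c("start", "end")))
  ordered_segments <- as.matrix(ordered_segments)
  if (nrow(ordered_segments) > 0) {
    if (any(ordered_segments < 0) || any(ordered_segments > length))
      stop("ordered segments outside sequence bounds")
    o <- order(ordered_segments[, 1])
    os <- ordered_segments[o, , drop = FALSE]
    if (nrow(os) > 1 && any(os[-1, 1] < os[-nrow(os), 2]))
      stop("overlapping ordered segments")
  }
  set.seed(seed)
  aa <- if (charge_pattern == "neutral")
    sample(DISORDER_AA, length, replace = TRUE,
           prob = c(3, 3, 2, 2, 2, 1, 1, 1, 1, 2, 2))
  else {
    base <- sample(c("G", "S", "T", "P", "A", "N", "Q"), length,
                   replace = TRUE)
    charged <- sort(sample.int(length, floor(length / 2)))
    base[charged] <- rep(c("E", "K"), length.out = length(charged))
    base
  }
  ord_idx <- unlist(apply(ordered_segments, 1,
                          function(r) seq(r[[1]] + 1, r[[2]])))
  if (length(ord_idx) > 0)
    aa[ord_idx] <- sample(ORDER_AA, length(ord_idx), replace = TRUE)
  structure(list(sequence = paste(aa, collapse = ""),
                 ordered_segments = ordered_segments, seed = seed),
            class = "afmi_protein")
}

#' Generate a reference ensemble by unrestrained CG dynamics
#'
#' Runs plain Langevin dynamics of the coarse-grained chain (no restraints,
#' no bias), discards the first 10% as equilibration and returns `n_frames`
#' uniform-weight frames.  With `ideal_chain = TRUE` all stickiness and
#' charges are zeroed, reducing the model to a freely jointed harmonic chain.
#'
#' @param protein An `afmi_protein` (or bare sequence string).
#' @param cond A [conditions()] object.
#' @param n_frames Frames to return.
#' @param seed Integer seed.
#' @param ideal_chain Zero all nonbonded interactions.
#' @param n_steps Total MD steps (default sized from `n_frames`).
#' @param friction 1/ps; the default 0.5 decorrelates faster than the
#'   production 0.01 and is only a sampling choice.
#' @param lambda_scale Stickiness scaling of the generating model (default
#'   1.5: the synthetic "truth" is more compact than the plain model --
#'   about 15% in Rg for a 40-residue hydrophilic chain -- emulating the
#'   force-field error that the distance restraints are there to correct).
#' @param save_every Frame stride in MD steps (default 400, comparable to
#'   the chain's Rg decorrelation at this friction).
#' @param contacts Optional data frame (`i`, `j`, `target`, `sd`; 0-based
#'   indices, Angstrom) of specific long-range contacts imposed on the
#'   generating model as fixed-sigma harmonic distance restraints.  This
#'   gives the synthetic "truth" residual structure that the plain
#'   coarse-grained prior cannot form -- the situation the AlphaFold-derived
#'   restraints are designed to correct.
#' @return An `afmi_ensemble`.
#' @export
make_reference_ensemble <- function(protein, cond = conditions(),
                                    n_frames = 1000, seed = 1,
                                    ideal_chain = FALSE, n_steps = NULL,
                                    friction = 0.5, lambda_scale = 1.2,
                                    save_every = 400, contacts = NULL) {
  seqc <- if (inherits(protein, "afmi_protein")) protein$sequence else protein
  topo <- build_topology(seqc, cond,
                         use_dh = !ideal_chain,
                         ah_eps = if (ideal_chain) 0 else 0.8368,
                         lambda_scale = if (ideal_chain) 0 else lambda_scale)
  if (ideal_chain) topo$charge[] <- 0
  n <- nchar(seqc)
  x0 <- random_walk_coords(n, seed = seed)
  hooks <- list()
  if (!is.null(contacts) && nrow(contacts) > 0) {
    crs <- structure(list(restraints = contacts), class = "afmi_restraints")
    x0 <- relax_to_restraints(x0, topo, crs, cond$temperature)
    hooks <- list(hook_metainference(
      crs, forward_model = "per_replica", gibbs = FALSE,
      sigma_init = contacts$sd, sem_floor = 0))
  }
  st <- minimize(replica_state(x0, rng_seed = seed), topo)
  if (is.null(n_steps))
    n_steps <- ceiling(n_frames / 0.9) * save_every + save_every
  run <- run_replicas(st, topo, n_steps, dt = 0.005, friction = friction,
                      hooks = hooks, save_every = save_every, seed = seed)
  ens <- run_ensemble(run, equilibration_fraction = 0.1)
  keep <- seq_len(min(n_frames, length(ens$frames)))
  new_ensemble(ens$frames[keep], sequence = seqc)
}

#' Synthetic specific-contact set for a reference ensemble
#'
#' Picks `n_contacts` long-range residue pairs, spread along the chain with
#' sequence separation of at least `min_sep`, to act as the residual
#' structure of the synthetic truth (see [make_reference_ensemble()]).
#'
#' @param protein An `afmi_protein` (or sequence length).
#' @param n_contacts Number of contacts (default 3).
#' @param target Contact distance, Angstrom (default 6).
#' @param sd Contact spread, Angstrom (default 0.5).
#' @param min_sep Minimum |i-j| (default one third of the chain).
#' @param seed Integer seed.
#' @return Data frame with `i`, `j` (0-based), `target`, `sd`.
#' @export
make_synthetic_contacts <- function(protein, n_contacts = 3, target = 6,
                                    sd = 0.5, min_sep = NULL, seed = 1) {
  n <- if (inherits(protein, "afmi_protein")) nchar(protein$sequence)
       else as.integer(protein)
  if (is.null(min_sep)) min_sep <- max(10, floor(n / 3))
  set.seed(seed)
  picked <- data.frame()
  anchors <- round(seq(2, n - 2 - min_sep, length.out = n_contacts))
  for (a in anchors) {
    i <- a + sample(-1:1, 1)
    j <- min(n - 1, i + min_sep + sample(0:max(1, n - 2 - i - min_sep), 1))
    picked <- rbind(picked, data.frame(i = i, j = j))
  }
  data.frame(i = as.integer(picked$i), j = as.integer(picked$j),
             target = target, sd = sd)
}

#' Freely jointed chain ensemble (analytic sampler)
#'
#' Direct draws of chains with fixed bond length and independent uniformly
#' random bond directions: the textbook ideal chain with nu = 0.5.
#'
#' @param n_res Number of beads.
#' @param n_frames Frames to draw.
#' @param bond Bond length, nm.
#' @param seed Integer seed.
#' @return An `afmi_ensemble`.
#' @export
make_ideal_chain_ensemble <- function(n_res, n_frames, bond = 0.38,
                                      seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    v <- matrix(rnorm(3 * (n_res - 1)), n_res - 1, 3)
    v <- v / sqrt(rowSums(v^2)) * bond
    rbind(0, apply(v, 2, cumsum))
  })
  new_ensemble(frames, sequence = strrep("G", n_res))
}

#' Synthetic AlphaFold-style annotations from a reference ensemble
#'
#' The distogram is the binned pair-distance histogram of the reference.
#' pLDDT is drawn at 90 +- 5 inside the protein's ordered segments and
#' 40 +- 10 outside (capped at 75 outside segments).  PAE is a noise-scaled
#' increasing function of the per-pair distance spread, floored at 0.25 A.
#'
#' @param protein An `afmi_protein`.
#' @param reference An `afmi_ensemble`.
#' @param noise Slope of PAE versus pair-distance standard deviation
#'   (default 0.5, dimensionless).
#' @param seed Integer seed.
#' @return List with `distogram` (an `afmi_distogram`) and `annotations`
#'   (list with `plddt`, `pae`).
#' @export
make_synthetic_annotations <- function(protein, reference, noise = 0.5,
                                       seed = 1) {
  stopifnot(inherits(protein, "afmi_protein"),
            inherits(reference, "afmi_ensemble"))
  if (length(reference$frames) == 0) stop("empty reference ensemble")
  n <- nchar(protein$sequence)
  d <- distogram_from_ensemble(reference)
  d$sequence <- protein$sequence
  set.seed(seed)
  inside <- in_segment(0:(n - 1), protein$ordered_segments)
  plddt <- ifelse(inside,
                  pmin(100, 90 + rnorm(n, 0, 5)),
                  pmin(75, pmax(5, 40 + rnorm(n, 0, 10))))
  # per-pair distance spread straight from the frames (not the binned
  # distogram, which clips the tail)
  pr <- all_pairs(n)
  dm <- cpp_pair_distances(reference$frames, pr) * 10
  sd_pair <- apply(dm, 2, sd)
  pae <- matrix(0, n, n)
  pae[cbind(pr[, 1] + 1, pr[, 2] + 1)] <- 0.25 + noise * sd_pair
  pae <- pae + t(pae)
  both_in <- matrix(inside, n, n) & matrix(inside, n, n, byrow = TRUE)
  pae[both_in] <- pmin(pae[both_in], 1.0)
  list(distogram = d, annotations = list(plddt = plddt, pae = pae))
}

#' Emit a full synthetic input set to a directory
#'
#' Writes FASTA, distogram JSON, PAE JSON, a pLDDT table and the reference
#' multi-model PDB -- one self-contained fake-AlphaFold input bundle.
#'
#' @param out_dir Output directory (created if missing).
#' @param length Sequence length.
#' @param ordered_segments Passed to [make_synthetic_protein()].
#' @param n_frames Reference ensemble size.
#' @param seed Integer seed.
#' @param cond A [conditions()] object for the reference run.
#' @return Named list of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(out_dir, length = 40,
                                 ordered_segments = NULL, n_frames = 500,
                                 seed = 1, cond = conditions()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prot <- make_synthetic_protein(length, ordered_segments, seed = seed)
  ref <- make_reference_ensemble(prot, cond, n_frames = n_frames, seed = seed)
  ann <- make_synthetic_annotations(prot, ref, seed = seed)
  paths <- list(
    fasta = file.path(out_dir, "sequence.fasta"),
    distogram = file.path(out_dir, "distogram.json"),
    pae = file.path(out_dir, "pae.json"),
    plddt = file.path(out_dir, "plddt.tsv"),
    reference = file.path(out_dir, "reference.pdb"))
  write_fasta_sequence(prot$sequence, paths$fasta)
  write_distogram(ann$distogram, paths$distogram)
  jsonlite::write_json(list(predicted_aligned_error = ann$annotations$pae),
                       paths$pae, digits = NA)
  write.table(data.frame(residue = seq_len(length),
                         plddt = round(ann$annotations$plddt, 2)),
              paths$plddt, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write_ensemble_pdb(ref, paths$reference)
  invisible(paths)
}
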