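## Torrie-Valleau reweighting of biased trajectories.

#' Torrie-Valleau weights from per-frame bias values
#'
#' `w_f` proportional to `exp(+V_f / kBT)`, normalized; a max-shift keeps
#' the exponentials finite.  Weights are invariant under adding a constant
#' to all bias values.
#'
#' @param per_frame_bias Final bias evaluated at each frame, kJ/mol.
#' @param temperature Kelvin.
#' @return Normalized weight vector.
#' @export
torrie_valleau_weights <- function(per_frame_bias, temperature) {
  if (length(per_frame_bias) == 0) stop("empty bias vector")
  if (!all(is.finite(per_frame_bias))) stop("non-finite bias values")
  z <- per_frame_bias / kBT(temperature)
  w <- exp(z - max(z))
  w / sum(w)
}

#' Effective sample size of a weight vector
#'
#' Kish's `(sum w)^2 / sum w^2`; warns when below 5% of the frame count.
#'
#' @param weights Weight vector (need not be normalized).
#' @return Effective sample size (>= 1 for any nonzero weight vector).
#' @export
effective_sample_size <- function(weights) {
  ess <- sum(weights)^2 / sum(weights^2)
  if (ess < 0.05 * length(weights))
    warning(sprintf("effective sample size %.1f is < 5%% of %d frames",
                    ess, length(weights)))
  ess
}

#' Resample a weighted ensemble to uniform weights
#'
#' @param ensemble An `afmi_ensemble` (weights used unless overridden).
#' @param weights Optional weight vector overriding the ensemble's.
#' @param n_out Number of output frames.
#' @param seed Integer seed.
#' @param scheme `"multinomial"` (default) or `"systematic"`.
#' @return An `afmi_ensemble` with uniform weights; `source` records the
#'   picked frame indices.
#' @export
resample_ensemble <- function(ensemble, weights = NULL, n_out = NULL,
                              seed = 1, scheme = c("multinomial",
                                                   "systematic")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ensemble, "afmi_ensemble"))
  w <- weights %||% ensemble$weights
  stopifnot(length(w) == length(ensemble$frames), all(w >= 0))
  w <- w / sum(w)
  if (is.null(n_out)) n_out <- length(ensemble$frames)
  if (n_out <= 0) stop("n_out must be positive")
  set.seed(seed)
  idx <- if (scheme == "multinomial") {
    sample.int(length(w), n_out, replace = TRUE, prob = w)
  } else {
    u <- (runif(1) + seq_len(n_out) - 1) / n_out
    findInterval(u, cumsum(w)) + 1L
  }
  new_ensemble(ensemble$frames[idx], sequence = ensemble$sequence,
               source = data.frame(picked = idx))
}

#' Block-convergence free-energy profiles along a CV
#'
#' Splits each replica's post-equilibration frames into blocks of increasing
#' coverage (first 20%, 40%, ..., 100% for `n_blocks = 5`) and computes the
#' weighted free-energy profile `F(s) = -kBT log(weighted histogram)` per
#' block, aligned by minimum.  Agreement between successive blocks indicates
#' convergence of the biased run.
#'
#' @param cv_series Matrix (frames x n_replicas) of one CV's values.
#' @param weights Per-frame weight matrix of the same shape (or vector
#'   recycled per replica).
#' @param temperature Kelvin.
#' @param n_blocks Number of cumulative blocks (default 5).
#' @param equilibration_fraction Initial fraction of each replica's frames
#'   discarded (default 0.1).
#' @param breaks Histogram breaks for the CV (default 40 bins over the
#'   observed range).
#' @return List of class `"afmi_convergence"`: `s` bin centers, `profiles`
#'   (n_bins x n_blocks, kJ/mol; NA where a block has no samples),
#'   `coverage` fractions.
#' @export
convergence_profiles <- function(cv_series, weights, temperature,
                                 n_blocks = 5, equilibration_fraction = 0.1,
                                 breaks = NULL) {
  cv_series <- as.matrix(cv_series)
  nf <- nrow(cv_series); nr <- ncol(cv_series)
  stopifnot(n_blocks >= 2)
  if (is.vector(weights) && length(weights) == nf)
    weights <- matrix(weights, nf, nr)
  weights <- as.matrix(weights)
  first <- floor(equilibration_fraction * nf) + 1
  if (nf - first + 1 < n_blocks) stop("too few frames per block")
  keep <- first:nf
  if (is.null(breaks))
    breaks <- seq(min(cv_series[keep, ]), max(cv_series[keep, ]),
                  length.out = 41)
  ctr <- (breaks[-1] + breaks[-length(breaks)]) / 2
  kt <- kBT(temperature)
  nkeep <- length(keep)
  profiles <- matrix(NA_real_, length(ctr), n_blocks)
  coverage <- seq_len(n_blocks) / n_blocks
  for (b in seq_len(n_blocks)) {
    upto <- keep[seq_len(ceiling(coverage[b] * nkeep))]
    s <- as.vector(cv_series[upto, ])
    w <- as.vector(weights[upto, ])
    bin <- findInterval(s, breaks, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= length(ctr)
    h <- rep(0, length(ctr))
    tb <- rowsum(w[ok], bin[ok])
    h[as.integer(rownames(tb))] <- tb
    f <- -kt * log(h / sum(h))
    f[!is.finite(f)] <- NA
    profiles[, b] <- f - min(f, na.rm = TRUE)
  }
  structure(list(s = ctr, profiles = profiles, coverage = coverage,
                 temperature = temperature), class = "afmi_convergence")
}
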