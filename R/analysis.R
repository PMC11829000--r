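## Ensemble observables and validation statistics: P(r), Rg, the polymer
## scaling exponent, and the Kullback-Leibler divergence between distance
## distributions.

#' Pairwise distance distribution P(r)
#'
#' For an ensemble: weighted normalized histogram of all inter-residue
#' bead-bead distances with `|i-j| >= min_separation` over all frames.  For
#' a distogram: histogram of the per-pair mean distances (the
#' single-structure-prediction style curve, truncated at the grid end).
#'
#' @param source An `afmi_ensemble` or `afmi_distogram`.
#' @param bin_width Angstrom (default 1).
#' @param min_separation Minimum |i-j| included (default 1).
#' @param r_max Histogram upper edge, Angstrom (default: data maximum).
#' @return List of class `"afmi_pr"` with `r` (bin centers, A) and
#'   `density` (sums to 1).
#' @export
pair_distance_distribution <- function(source, bin_width = 1,
                                       min_separation = 1, r_max = NULL) {
  if (inherits(source, "afmi_distogram")) {
    st <- pair_stats_all(source)
    d <- st$mean
    w <- rep(1, length(d))
    keep <- (st$j - st$i) >= min_separation
    d <- d[keep]; w <- w[keep]
  } else if (inherits(source, "afmi_ensemble")) {
    if (length(source$frames) == 0) stop("empty ensemble")
    n <- nrow(source$frames[[1]])
    pr <- all_pairs(n)
    keep <- (pr[, 2] - pr[, 1]) >= min_separation
    pr <- pr[keep, , drop = FALSE]
    dm <- cpp_pair_distances(source$frames, pr) * 10  # nm -> A
    d <- as.vector(dm)
    w <- rep(source$weights, ncol(dm))
  } else stop("source must be an ensemble or a distogram")
  if (is.null(r_max)) r_max <- max(d) + bin_width
  breaks <- seq(0, r_max + bin_width, by = bin_width)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  bin[bin > length(breaks) - 1] <- length(breaks) - 1
  h <- rep(0, length(breaks) - 1)
  tb <- rowsum(w, bin)
  h[as.integer(rownames(tb))] <- tb
  structure(list(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 density = h / sum(h), bin_width = bin_width),
            class = "afmi_pr")
}

#' @export
print.afmi_pr <- function(x, ...) {
  cat(sprintf("P(r): %d bins of %.3g A, mean r = %.2f A\n",
              length(x$r), x$bin_width, sum(x$r * x$density)))
  invisible(x)
}

#' @export
plot.afmi_pr <- function(x, ..., add = FALSE, col = 1, type = "l") {
  if (add) graphics::lines(x$r, x$density, col = col, ...)
  else plot(x$r, x$density, type = type, col = col,
            xlab = "r (Angstrom)", ylab = "P(r)", ...)
  invisible(x)
}

# Re-bin a distribution onto target breaks by proportional mass assignment
# of each source bin (assumes source bins are contiguous of equal width).
rebin_pr <- function(p, breaks) {
  hw <- p$bin_width / 2
  lo <- p$r - hw; hi <- p$r + hw
  out <- numeric(length(breaks) - 1)
  for (k in seq_along(p$r)) {
    if (p$density[k] == 0) next
    a <- pmin(pmax(breaks[-length(breaks)], lo[k]), hi[k])
    b <- pmin(pmax(breaks[-1], lo[k]), hi[k])
    out <- out + p$density[k] * (b - a) / (hi[k] - lo[k])
  }
  out
}

#' Kullback-Leibler divergence between two distance distributions
#'
#' `D_KL(P || Q) = sum_i P_i log(P_i / Q_i)` with the natural logarithm
#' (nats).  Bins where `P_i = 0` contribute zero; Q is regularized by
#' redistributing a pseudo-mass `epsilon` so the ratio stays finite when the
#' simulation misses a populated bin.  Distributions on different grids are
#' re-binned onto the coarser grid first.
#'
#' @param P,Q `afmi_pr` objects (or bare probability vectors on a shared
#'   grid).
#' @param epsilon Regularization pseudo-mass for Q (default 1e-8).
#' @return Divergence in nats (non-negative up to regularization).
#' @export
kl_divergence <- function(P, Q, epsilon = 1e-8) {
  if (inherits(P, "afmi_pr") && inherits(Q, "afmi_pr")) {
    wide <- max(P$bin_width, Q$bin_width)
    rmax <- max(P$r + P$bin_width / 2, Q$r + Q$bin_width / 2)
    breaks <- seq(0, rmax + wide, by = wide)
    p <- rebin_pr(P, breaks)
    q <- rebin_pr(Q, breaks)
  } else {
    p <- as.numeric(P); q <- as.numeric(Q)
    if (length(p) != length(q)) stop("incompatible grids")
  }
  p <- p / sum(p)
  q <- (q + epsilon) / sum(q + epsilon)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Radius of gyration
#'
#' Mass-uniform Rg per frame plus the weighted mean and its standard error.
#'
#' @param ensemble An `afmi_ensemble` (coords in nm).
#' @return List with `mean` (A), `se` (A), `per_frame` (A).
#' @export
radius_of_gyration <- function(ensemble) {
  stopifnot(inherits(ensemble, "afmi_ensemble"), length(ensemble$frames) >= 1)
  rg <- vapply(ensemble$frames, function(x) {
    cm <- colMeans(x)
    sqrt(mean(rowSums(sweep(x, 2, cm)^2)))
  }, numeric(1)) * 10  # nm -> A
  w <- ensemble$weights
  m <- sum(w * rg)
  ess <- sum(w)^2 / sum(w^2)
  se <- sqrt(sum(w * (rg - m)^2) / max(ess - 1, 1))
  list(mean = m, se = se, per_frame = rg)
}

#' Fit a power law to internal-distance scaling
#'
#' Least-squares fit of `log(rms distance) = log(prefactor) + nu * log(s)`
#' over sequence separations `s`.
#'
#' @param separations Sequence separations |i-j|.
#' @param rms_distances Root-mean-square distances at those separations, A.
#' @return List with `nu`, `prefactor` (A), `residual` (RMS of log-space
#'   residuals).
#' @export
fit_scaling <- function(separations, rms_distances) {
  ok <- separations > 0 & rms_distances > 0
  fit <- lm(log(rms_distances[ok]) ~ log(separations[ok]))
  list(nu = unname(coef(fit)[2]), prefactor = exp(unname(coef(fit)[1])),
       residual = sqrt(mean(fit$residuals^2)))
}

#' Polymer scaling exponent of an ensemble
#'
#' Computes `sqrt(<R_ij^2>)` (weighted over frames, averaged over all pairs
#' at each sequence separation) and fits `<R_ij^2>^(1/2) = b |i-j|^nu` over
#' the configured separation range.  `nu = 0.5` is the Flory random-coil
#' value; extended chains approach 1.
#'
#' @param ensemble An `afmi_ensemble`.
#' @param min_sep,max_sep Fit range of separations (defaults 5 to N/2).
#' @return List of class `"afmi_scaling"` with `nu`, `prefactor` (A),
#'   `fit_range`, `residual`, and the per-separation `rms` series.
#' @export
scaling_exponent <- function(ensemble, min_sep = 5, max_sep = NULL) {
  stopifnot(inherits(ensemble, "afmi_ensemble"))
  n <- nrow(ensemble$frames[[1]])
  if (n < 10) stop("chain too short for a scaling fit (need >= 10 beads)")
  if (is.null(max_sep)) max_sep <- floor(n / 2)
  pr <- all_pairs(n)
  sep <- pr[, 2] - pr[, 1]
  keep <- sep >= 1
  dm <- cpp_pair_distances(ensemble$frames, pr[keep, , drop = FALSE]) * 10
  w <- ensemble$weights / sum(ensemble$weights)
  msd_pair <- as.vector(t(dm^2) %*% w)      # weighted <R_ij^2> per pair
  sepk <- sep[keep]
  seps <- sort(unique(sepk))
  rms <- vapply(seps, function(s) sqrt(mean(msd_pair[sepk == s])), numeric(1))
  use <- seps >= min_sep & seps <= max_sep
  fit <- fit_scaling(seps[use], rms[use])
  structure(list(nu = fit$nu, prefactor = fit$prefactor,
                 fit_range = c(min_sep, max_sep), residual = fit$residual,
                 separations = seps, rms = rms), class = "afmi_scaling")
}

#' @export
print.afmi_scaling <- function(x, ...) {
  cat(sprintf("scaling exponent nu = %.3f (prefactor %.2f A, fit %d..%d)\n",
              x$nu, x$prefactor, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}
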