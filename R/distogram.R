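## Distogram container and per-pair statistics.
##
## AlphaFold's distogram head reports, for every residue pair, a discrete
## probability distribution over 64 equal-width distance bins spanning
## 2.15625 - 21.84375 Angstrom, with the last bin absorbing all longer
## distances.  Distances are between C-beta positions (C-alpha for glycine).
## This file owns the container, its exchange format, the per-pair mean and
## standard deviation, and the generation of distograms from bead ensembles.

#' Default AlphaFold distogram bin edges
#'
#' 65 edges delimiting 64 equal-width bins from 2.15625 to 21.84375 Angstrom
#' (bin width 0.3076171875 Angstrom).  The last bin is interpreted as "at or
#' beyond the last finite edge".
#'
#' @return Numeric vector of 65 strictly increasing distances in Angstrom.
#' @export
default_bin_edges <- function() {
  seq(2.15625, 21.84375, length.out = 65)
}

bin_centers <- function(edges) (edges[-length(edges)] + edges[-1]) / 2

#' Construct a distogram
#'
#' @param sequence Amino-acid sequence (1-letter string).
#' @param probs Numeric matrix with one row per stored pair (i < j) and one
#'   column per bin; rows must sum to 1 within `1e-3` (renormalized to 1e-6).
#' @param pairs Integer matrix (n_pairs x 2) of 0-based residue indices with
#'   `i < j`; defaults to all pairs in row-major order.
#' @param bin_edges Bin edges in Angstrom; defaults to [default_bin_edges()].
#' @return An object of class `"afmi_distogram"`.
#' @export
distogram <- function(sequence, probs, pairs = NULL, bin_edges = default_bin_edges()) {
  n <- nchar(sequence)
  stopifnot(n >= 2, is.numeric(bin_edges), length(bin_edges) >= 3)
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (is.null(pairs)) pairs <- all_pairs(n)
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  probs <- as.matrix(probs)
  if (nrow(probs) != nrow(pairs))
    stop("pair count inconsistent: ", nrow(probs), " probability rows for ",
         nrow(pairs), " pairs")
  if (ncol(probs) != length(bin_edges) - 1L)
    stop("probability rows must have one entry per bin")
  if (any(probs < 0)) stop("negative bin probabilities")
  if (any(pairs[, 1] >= pairs[, 2]) || any(pairs < 0) || any(pairs >= n))
    stop("pairs must be 0-based with i < j inside the sequence")
  s <- rowSums(probs)
  if (any(abs(s - 1) > 1e-3)) stop("unnormalized distogram (row sums deviate from 1)")
  if (any(abs(s - 1) > 1e-12)) probs <- probs / s  # keep exact rows bit-identical
  structure(
    list(sequence = sequence, bin_edges = as.numeric(bin_edges), probs = probs,
         pairs = pairs),
    class = "afmi_distogram")
}

all_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # row-major (i ascending, then j)
  ord <- order(idx[, 1], idx[, 2])
  cbind(i = idx[ord, 1] - 1L, j = idx[ord, 2] - 1L)
}

#' @export
print.afmi_distogram <- function(x, ...) {
  cat("AlphaFold-style distogram\n")
  cat("  sequence length:", nchar(x$sequence), "\n")
  cat("  pairs stored:   ", nrow(x$pairs), "\n")
  cat("  bins:           ", ncol(x$probs), " [",
      x$bin_edges[1], ", ", x$bin_edges[length(x$bin_edges)], "] A\n", sep = "")
  invisible(x)
}

pair_row <- function(d, i, j) {
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  k <- which(d$pairs[, 1] == i & d$pairs[, 2] == j)
  if (length(k) != 1L) stop("pair (", i, ",", j, ") not stored in distogram")
  k
}

#' Per-pair distance statistics from a distogram
#'
#' Computes the expected distance (probability-weighted mean over bin
#' centers), its standard deviation, and the probability mass in the last bin
#' (distances at or beyond the last finite edge).
#'
#' @param d An `afmi_distogram`.
#' @param i,j 0-based residue indices, `i != j`.
#' @return List with `i`, `j`, `mean` (A), `sd` (A), `tail_mass`.
#' @export
pair_stats <- function(d, i, j) {
  stopifnot(inherits(d, "afmi_distogram"))
  n <- nchar(d$sequence)
  if (i == j) stop("i == j: no self-distance in a distogram")
  if (min(i, j) < 0 || max(i, j) >= n) stop("residue index out of range")
  p <- d$probs[pair_row(d, i, j), ]
  ctr <- bin_centers(d$bin_edges)
  m <- sum(ctr * p)
  v <- sum((ctr - m)^2 * p)
  list(i = min(i, j), j = max(i, j), mean = m, sd = sqrt(max(v, 0)),
       tail_mass = p[length(p)])
}

#' All per-pair distance statistics
#'
#' Vectorized [pair_stats()] over every stored pair.
#'
#' @param d An `afmi_distogram`.
#' @return Data frame with columns `i`, `j`, `mean`, `sd`, `tail_mass`.
#' @export
pair_stats_all <- function(d) {
  ctr <- bin_centers(d$bin_edges)
  m <- as.vector(d$probs %*% ctr)
  # centered second moment (not E[x^2] - m^2, which loses the exact zero
  # for single-bin rows)
  cc <- matrix(ctr, nrow(d$probs), length(ctr), byrow = TRUE)
  v <- rowSums(d$probs * (cc - m)^2)
  data.frame(i = d$pairs[, 1], j = d$pairs[, 2], mean = m,
             sd = sqrt(pmax(v, 0)), tail_mass = d$probs[, ncol(d$probs)])
}

#' Read a distogram from the JSON exchange format
#'
#' The exchange format is a JSON object
#' `{"sequence", "bin_edges_angstrom", "pairs": [{"i","j","p"}, ...]}` with
#' 0-based indices and only `i < j` stored.
#'
#' @param path File path.
#' @return An `afmi_distogram`.
#' @export
read_distogram <- function(path) {
  if (!file.exists(path)) stop("distogram file not found: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (f in c("sequence", "bin_edges_angstrom", "pairs"))
    if (is.null(x[[f]])) stop("distogram file missing field '", f, "'")
  pr <- x$pairs
  probs <- do.call(rbind, pr$p)
  distogram(x$sequence, probs, pairs = cbind(pr$i, pr$j),
            bin_edges = x$bin_edges_angstrom)
}

#' Write a distogram to the JSON exchange format
#'
#' @param d An `afmi_distogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distogram <- function(d, path) {
  stopifnot(inherits(d, "afmi_distogram"))
  pairs <- lapply(seq_len(nrow(d$pairs)), function(k) {
    list(i = d$pairs[k, 1], j = d$pairs[k, 2], p = as.numeric(d$probs[k, ]))
  })
  obj <- list(sequence = d$sequence,
              bin_edges_angstrom = as.numeric(d$bin_edges),
              pairs = pairs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Build a distogram from a weighted bead ensemble
#'
#' For every residue pair, forms the weighted histogram of bead-bead
#' distances on the bin grid; distances at or beyond the last finite edge
#' accumulate in the last bin.  This is the fixture generator emulating an
#' AlphaFold distogram from a known ensemble.
#'
#' @param ensemble An `afmi_ensemble` (frames in nm).
#' @param bin_edges Bin edges in Angstrom.
#' @return An `afmi_distogram`.
#' @export
distogram_from_ensemble <- function(ensemble, bin_edges = default_bin_edges()) {
  stopifnot(inherits(ensemble, "afmi_ensemble"))
  nf <- length(ensemble$frames)
  if (nf < 1) stop("empty ensemble")
  w <- ensemble$weights
  if (any(w < 0)) stop("negative weights")
  w <- w / sum(w)
  n <- nrow(ensemble$frames[[1]])
  pr <- all_pairs(n)
  dmat <- cpp_pair_distances(ensemble$frames, pr) * 10  # nm -> Angstrom
  nb <- length(bin_edges) - 1L
  # clamp beyond-grid distances into the last bin; below-grid into the first
  brk <- bin_edges
  brk[1] <- -Inf
  brk[length(brk)] <- Inf
  probs <- matrix(0, nrow(pr), nb)
  for (p in seq_len(nrow(pr))) {
    b <- findInterval(dmat[, p], brk, rightmost.closed = TRUE)
    b[b < 1] <- 1L; b[b > nb] <- nb
    tb <- rowsum(w, b)
    probs[p, as.integer(rownames(tb))] <- tb
  }
  probs <- probs / rowSums(probs)  # exact normalization (single-bin rows = 1)
  distogram(ensemble$sequence %||% strrep("G", n), probs, pairs = pr,
            bin_edges = bin_edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
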