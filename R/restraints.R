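## Restraint selection.
##
## Distogram pairs become distance restraints only when AlphaFold is likely
## to be right about them.  Four filters apply, in a fixed bookkeeping order:
##   1. tail: mass at/beyond the last finite bin edge must be <= 0.02 (the
##      distogram head is not trained beyond ~21.84 A);
##   2. PAE: symmetrized predicted aligned error below a protein-level cutoff
##      (10 A for hydrophilic sequences with a confident >= 5-residue
##      stretch, otherwise 5 A);
##   3. structured segments: pairs touching confidently folded regions are
##      excluded (the CG model cannot hold secondary structure; those regions
##      are instead restrained by an RMSD wall);
##   4. sequence separation: |i-j| >= min_separation (local geometry belongs
##      to the force field).

#' Detect structured segments from pLDDT scores
#'
#' Maximal runs of at least `min_len` consecutive residues with
#' `plddt > cutoff` are considered structured (confidently folded) regions.
#'
#' @param plddt Per-residue confidence scores on the 0-100 scale.
#' @param cutoff Score threshold (default 75).
#' @param min_len Minimum run length (default 2).
#' @return Integer matrix with columns `start`, `end`: half-open 0-based
#'   ranges `[start, end)`.
#' @export
detect_structured_segments <- function(plddt, cutoff = 75, min_len = 2) {
  if (length(plddt) == 0) stop("empty pLDDT score list")
  stopifnot(min_len >= 1)
  above <- plddt > cutoff
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- cbind(start = starts[keep] - 1L, end = ends[keep])
  storage.mode(out) <- "integer"
  out
}

in_segment <- function(idx0, segments) {
  if (is.null(segments) || nrow(segments) == 0) return(rep(FALSE, length(idx0)))
  out <- rep(FALSE, length(idx0))
  for (s in seq_len(nrow(segments)))
    out <- out | (idx0 >= segments[s, 1] & idx0 < segments[s, 2])
  out
}

#' Choose the protein-level PAE cutoff
#'
#' Hydrophilic proteins (mean Kyte-Doolittle score below `kd_threshold`,
#' i.e. negative/hydrophilic) that still contain at least one confident
#' stretch of `stretch_len` residues with pLDDT above `stretch_cutoff` get
#' the permissive 10 A cutoff; everything else gets 5 A.
#'
#' @param sequence Amino-acid sequence.
#' @param plddt Per-residue pLDDT (0-100).
#' @param kd_threshold Mean-hydropathy threshold (default -1.4; negative
#'   means hydrophilic).
#' @param stretch_len,stretch_cutoff Confident-stretch criterion
#'   (defaults 5 residues with pLDDT > 75).
#' @return PAE cutoff in Angstrom: 10 or 5.
#' @export
choose_pae_cutoff <- function(sequence, plddt, kd_threshold = -1.4,
                              stretch_len = 5, stretch_cutoff = 75) {
  if (nchar(sequence) != length(plddt))
    stop("pLDDT length does not match sequence")
  kd <- setNames(residue_params()$kd, residue_params()$code)
  aa <- strsplit(sequence, "")[[1]]
  mean_kd <- mean(kd[aa])
  segs <- detect_structured_segments(plddt, cutoff = stretch_cutoff,
                                     min_len = stretch_len)
  if (mean_kd < kd_threshold && nrow(segs) > 0) 10 else 5
}

#' Select distance restraints from a distogram and AlphaFold annotations
#'
#' @param d An `afmi_distogram`.
#' @param annotations List with `plddt` (0-100 per residue) and `pae`
#'   (square matrix, Angstrom); see [make_synthetic_annotations()] or
#'   [read_pae()] / [read_plddt()].
#' @param tail_threshold Maximum allowed last-bin mass (default 0.02).
#' @param min_separation Minimum |i-j| (default 3).
#' @param kd_threshold,stretch_len,stretch_cutoff Passed to
#'   [choose_pae_cutoff()].
#' @param segment_cutoff,segment_min_len Passed to
#'   [detect_structured_segments()].
#' @return An object of class `"afmi_restraints"`: data frame `restraints`
#'   (`i`, `j`, `target` A, `sd` A), `structured_segments`, `pae_cutoff`, and
#'   `provenance` counts of pairs removed by each filter (each excluded pair
#'   counted once, in order tail, pae, segment, separation).
#' @export
select_restraints <- function(d, annotations, tail_threshold = 0.02,
                              min_separation = 3, kd_threshold = -1.4,
                              stretch_len = 5, stretch_cutoff = 75,
                              segment_cutoff = 75, segment_min_len = 2) {
  stopifnot(inherits(d, "afmi_distogram"))
  n <- nchar(d$sequence)
  plddt <- annotations$plddt
  pae <- annotations$pae
  if (length(plddt) != n) stop("pLDDT length does not match distogram sequence")
  if (!all(dim(pae) == c(n, n))) stop("PAE matrix does not match sequence length")
  if (any(pae < 0)) stop("negative PAE")
  if (any(plddt < 0 | plddt > 100)) stop("pLDDT outside [0, 100]")

  cutoff <- choose_pae_cutoff(d$sequence, plddt, kd_threshold, stretch_len,
                              stretch_cutoff)
  segs <- detect_structured_segments(plddt, segment_cutoff, segment_min_len)

  st <- pair_stats_all(d)
  pae_sym <- pmax(pae, t(pae))  # conservative symmetrization
  pae_pair <- pae_sym[cbind(st$i + 1L, st$j + 1L)]
  seg_hit <- in_segment(st$i, segs) | in_segment(st$j, segs)
  sep <- st$j - st$i

  fail_tail <- st$tail_mass > tail_threshold
  fail_pae <- !fail_tail & !(pae_pair < cutoff)
  fail_seg <- !fail_tail & !fail_pae & seg_hit
  fail_sep <- !fail_tail & !fail_pae & !fail_seg & sep < min_separation
  keep <- !(fail_tail | fail_pae | fail_seg | fail_sep)

  out <- structure(
    list(
      restraints = data.frame(i = st$i[keep], j = st$j[keep],
                              target = st$mean[keep], sd = st$sd[keep]),
      structured_segments = segs,
      pae_cutoff = cutoff,
      provenance = c(tail = sum(fail_tail), pae = sum(fail_pae),
                     segment = sum(fail_seg), separation = sum(fail_sep),
                     kept = sum(keep))),
    class = "afmi_restraints")
  if (nrow(out$restraints) == 0)
    warning("restraint set is empty after filtering")
  out
}

#' @export
print.afmi_restraints <- function(x, ...) {
  cat("AlphaFold-derived distance restraints\n")
  cat("  kept pairs:        ", nrow(x$restraints), "\n")
  cat("  PAE cutoff:        ", x$pae_cutoff, "A\n")
  cat("  structured segments:", nrow(x$structured_segments), "\n")
  cat("  removed (tail/pae/segment/separation):",
      paste(x$provenance[c("tail", "pae", "segment", "separation")],
            collapse = "/"), "\n")
  invisible(x)
}

#' Read a PAE matrix from AlphaFold-DB-style JSON
#'
#' Accepts `{"predicted_aligned_error": [[...]]}` or a bare top-level list
#' containing that field (as served by the AlphaFold database).
#'
#' @param path File path.
#' @return Square numeric matrix in Angstrom.
#' @export
read_pae <- function(path) {
  if (!file.exists(path)) stop("PAE file not found: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(x$predicted_aligned_error) && is.list(x) && length(x) >= 1 &&
      !is.null(x[[1]]$predicted_aligned_error))
    x <- x[[1]]
  m <- x$predicted_aligned_error
  if (is.null(m)) stop("no 'predicted_aligned_error' field in ", path)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("PAE matrix is not square")
  m
}

#' Read per-residue pLDDT scores
#'
#' Plain two-column table (residue index, score).  Scores on a 0-1 scale are
#' rescaled to 0-100.
#'
#' @param path File path.
#' @return Numeric vector of per-residue scores on the 0-100 scale.
#' @export
read_plddt <- function(path) {
  if (!file.exists(path)) stop("pLDDT file not found: ", path)
  tb <- read.table(path, header = FALSE, comment.char = "#")
  v <- tb[[ncol(tb)]]
  if (max(v) <= 1) v <- v * 100
  as.numeric(v)
}

#' Write a restraint set as TSV plus a JSON sidecar
#'
#' @param rs An `afmi_restraints`.
#' @param path Output TSV path (`i`, `j`, `target_A`, `sd_A`); the sidecar
#'   with segments, PAE cutoff and provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(rs, path) {
  stopifnot(inherits(rs, "afmi_restraints"))
  df <- rs$restraints
  names(df) <- c("i", "j", "target_A", "sd_A")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    structured_segments = apply(rs$structured_segments, 1,
                                function(r) list(start = r[[1]], end = r[[2]])),
    pae_cutoff = rs$pae_cutoff,
    provenance = as.list(rs$provenance))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
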