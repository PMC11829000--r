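## Structure and sequence file plumbing.
##
## Ensembles travel as multi-model PDB with one C-alpha bead per residue
## (coordinates written in Angstrom, stored internally in nm); pLDDT scores
## may ride along in the B-factor column.  Sequences travel as FASTA via
## seqinr.

#' Write a bead ensemble as a multi-model PDB
#'
#' @param ensemble An `afmi_ensemble` (coords in nm; written in Angstrom).
#' @param path Output path.
#' @param bfactor Optional per-residue B-factor column (e.g. pLDDT).
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path, bfactor = NULL) {
  stopifnot(inherits(ensemble, "afmi_ensemble"))
  aa3 <- residue_params()$three
  names(aa3) <- residue_params()$code
  n <- nrow(ensemble$frames[[1]])
  res <- if (!is.null(ensemble$sequence))
    aa3[strsplit(ensemble$sequence, "")[[1]]] else rep("GLY", n)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ensemble$frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    x <- ensemble$frames[[m]] * 10  # nm -> Angstrom
    lines <- sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(n), res, seq_len(n), x[, 1], x[, 2], x[, 3], 1, bfactor)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model C-alpha PDB into an ensemble
#'
#' Reads CA atom records of every MODEL (Angstrom on disk, nm in memory).
#'
#' @param path PDB file path.
#' @param sequence Optional sequence attached to the ensemble (inferred
#'   from residue names when possible).
#' @return An `afmi_ensemble` with uniform weights.
#' @export
read_ensemble_pdb <- function(path, sequence = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path)
  atom <- startsWith(lines, "ATOM") &
    substr(lines, 13, 16) == " CA "
  model_break <- cumsum(startsWith(lines, "MODEL"))
  if (max(model_break) == 0) model_break <- rep(1, length(lines))
  frames <- list()
  res_names <- NULL
  for (m in unique(model_break[atom])) {
    sel <- lines[atom & model_break == m]
    xyz <- cbind(as.numeric(substr(sel, 31, 38)),
                 as.numeric(substr(sel, 39, 46)),
                 as.numeric(substr(sel, 47, 54))) / 10
    frames[[length(frames) + 1]] <- xyz
    if (is.null(res_names)) res_names <- trimws(substr(sel, 18, 20))
  }
  if (length(frames) == 0) stop("no CA atoms found in ", path)
  if (is.null(sequence)) {
    tb <- residue_params()
    code <- tb$code
    names(code) <- tb$three
    if (all(res_names %in% tb$three))
      sequence <- paste(code[res_names], collapse = "")
  }
  new_ensemble(frames, sequence = sequence)
}

#' Read per-residue B-factors (e.g. pLDDT) from a single-model PDB
#'
#' @param path PDB file path.
#' @return Numeric vector (one value per CA record of the first model),
#'   rescaled to 0-100 if on a 0-1 scale.
#' @export
read_plddt_pdb <- function(path) {
  lines <- readLines(path)
  atom <- startsWith(lines, "ATOM") & substr(lines, 13, 16) == " CA "
  model_break <- cumsum(startsWith(lines, "MODEL"))
  if (max(model_break) > 0) atom <- atom & model_break == model_break[atom][1]
  v <- as.numeric(substr(lines[atom], 61, 66))
  if (max(v) <= 1) v <- v * 100
  v
}

#' Read the first sequence of a FASTA file
#'
#' @param path FASTA path.
#' @return Upper-case amino-acid string.
#' @export
read_fasta_sequence <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  toupper(as.character(x[[1]]))
}

#' Write a sequence as FASTA
#'
#' @param sequence Amino-acid string.
#' @param path Output path.
#' @param name Record name.
#' @return `path`, invisibly.
#' @export
write_fasta_sequence <- function(sequence, path, name = "afmi") {
  seqinr::write.fasta(strsplit(sequence, "")[[1]], names = name,
                      file.out = path)
  invisible(path)
}
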