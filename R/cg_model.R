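## One-bead-per-residue force field (CALVADOS-2 functional forms).
##
## E_MD = harmonic bonds + stickiness-scaled Ashbaugh-Hatch short-range term
## + Debye-Hueckel screened electrostatics, all truncated and shifted so the
## energy is continuous in the coordinates (required for stable Langevin
## dynamics).  Parameters are shipped as a plain-text table
## (inst/extdata/calvados2_residues.tsv) re-typed from the force-field
## publication.

.afmi_env <- new.env(parent = emptyenv())

#' Per-residue force-field parameter table
#'
#' @return Data frame keyed by 1-letter code with mass (amu), sigma (nm),
#'   stickiness lambda, charge (e, at neutral pH), His pKa and
#'   Kyte-Doolittle hydropathy.
#' @export
residue_params <- function() {
  if (is.null(.afmi_env$params)) {
    path <- system.file("extdata", "calvados2_residues.tsv", package = "afmi")
    tb <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                     stringsAsFactors = FALSE)
    rownames(tb) <- tb$code
    .afmi_env$params <- tb
  }
  .afmi_env$params
}

#' Simulation conditions
#'
#' @param temperature Kelvin.
#' @param pH Dimensionless.
#' @param ionic_strength mol/L.
#' @return List of class `"afmi_conditions"`.
#' @export
conditions <- function(temperature = 298, pH = 7, ionic_strength = 0.15) {
  stopifnot(temperature > 0, ionic_strength >= 0)
  structure(list(temperature = temperature, pH = pH,
                 ionic_strength = ionic_strength),
            class = "afmi_conditions")
}

# Temperature-dependent relative permittivity of water (empirical fit).
water_permittivity <- function(temperature) {
  T <- temperature
  5321 / T + 233.76 - 0.9297 * T + 1.417e-3 * T^2 - 8.292e-7 * T^3
}

#' Debye-Hueckel screening parameters
#'
#' Debye length from the standard closed form with temperature-dependent
#' water permittivity, plus the Coulomb prefactor e^2/(4 pi eps0 epsr) in
#' kJ mol^-1 nm e^-2.
#'
#' @param cond An [conditions()] object with `ionic_strength > 0`.
#' @return List with `debye_length` (nm), `kappa` (1/nm), `prefactor`
#'   (kJ/mol nm), `epsilon_r`.
#' @export
debye_parameters <- function(cond) {
  stopifnot(inherits(cond, "afmi_conditions"))
  if (cond$ionic_strength <= 0)
    stop("ionic_strength = 0: screening length diverges; ",
         "disable electrostatics instead (use_dh = FALSE in build_topology)")
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12
  kb <- 1.380649e-23; na <- 6.02214076e23
  epsr <- water_permittivity(cond$temperature)
  conc <- cond$ionic_strength * 1000  # mol/m^3
  kappa2 <- 2 * na * e^2 * conc / (eps0 * epsr * kb * cond$temperature)
  lambda_d <- 1 / sqrt(kappa2) * 1e9  # nm
  list(debye_length = lambda_d, kappa = 1 / lambda_d,
       prefactor = 138.935458 / epsr, epsilon_r = epsr)
}

#' Build a coarse-grained topology for a sequence
#'
#' One bead per residue; N-1 consecutive harmonic bonds.  Side-chain charges
#' are resolved at the given pH (His by Henderson-Hasselbalch); terminal
#' beads optionally carry the +1/-1 backbone charges.
#'
#' @param sequence Amino-acid sequence (canonical 1-letter codes).
#' @param cond An [conditions()] object.
#' @param termini_charges Add +1 to the first and -1 to the last bead
#'   (default TRUE).
#' @param use_dh Include Debye-Hueckel electrostatics (default TRUE; requires
#'   `ionic_strength > 0`).
#' @param bond_k Bond force constant, kJ/mol/nm^2.
#' @param bond_r0 Bond rest length, nm.
#' @param ah_eps Ashbaugh-Hatch well depth, kJ/mol.
#' @param ah_cutoff,dh_cutoff Nonbonded cutoffs, nm.
#' @param lambda_scale Multiplies all stickiness values (model-perturbation
#'   handle for synthetic experiments).
#' @return List of class `"afmi_topology"` consumed by the engine.
#' @export
build_topology <- function(sequence, cond = conditions(),
                           termini_charges = TRUE, use_dh = TRUE,
                           bond_k = 8033, bond_r0 = 0.38,
                           ah_eps = 0.8368, ah_cutoff = 2.4, dh_cutoff = 4.0,
                           lambda_scale = 1.0) {
  stopifnot(inherits(cond, "afmi_conditions"))
  aa <- strsplit(sequence, "")[[1]]
  tb <- residue_params()
  unknown <- setdiff(aa, rownames(tb))
  if (length(unknown) > 0)
    stop("unknown residue code(s): ", paste(unique(unknown), collapse = ", "))
  n <- length(aa)
  if (n < 2) stop("sequence must have at least 2 residues")
  charge <- tb[aa, "charge"]
  his <- which(aa == "H")
  if (length(his) > 0) {
    pka <- tb["H", "pka"]
    charge[his] <- 1 / (1 + 10^(cond$pH - pka))  # Henderson-Hasselbalch
  }
  if (termini_charges) {
    charge[1] <- charge[1] + 1
    charge[n] <- charge[n] - 1
  }
  dh <- if (use_dh && cond$ionic_strength > 0) debye_parameters(cond) else
    list(kappa = 0, prefactor = 0)
  structure(list(
    sequence = sequence,
    sigma = tb[aa, "sigma"], lambda = tb[aa, "lambda"] * lambda_scale,
    charge = charge, mass = tb[aa, "mass"],
    bond_k = bond_k, bond_r0 = bond_r0,
    ah_eps = ah_eps, ah_rc = ah_cutoff, dh_rc = dh_cutoff,
    dh_pref = dh$prefactor, kappa = dh$kappa,
    use_dh = use_dh && cond$ionic_strength > 0,
    conditions = cond), class = "afmi_topology")
}

#' @export
print.afmi_topology <- function(x, ...) {
  cat("CG topology:", nchar(x$sequence), "beads,",
      nchar(x$sequence) - 1, "bonds; net charge",
      round(sum(x$charge), 2), "e;",
      if (x$use_dh) sprintf("Debye length %.3f nm", 1 / x$kappa)
      else "no electrostatics", "\n")
  invisible(x)
}

#' Coarse-grained energy and forces
#'
#' @param coords N x 3 matrix of bead positions in nm.
#' @param topology An `afmi_topology`.
#' @param hard_floor Minimum allowed bead-bead distance in nm; closer
#'   overlaps raise an error advising minimization (default 0.02).
#' @return List with `energy` (kJ/mol) and `forces` (N x 3, kJ/mol/nm).
#' @export
energy_forces <- function(coords, topology, hard_floor = 0.02) {
  stopifnot(inherits(topology, "afmi_topology"))
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (nrow(coords) != nchar(topology$sequence))
    stop("coordinate rows do not match topology")
  dmin <- min(dist(coords))
  if (dmin < hard_floor)
    stop(sprintf(paste0("beads overlap (min distance %.4f nm < floor %.3f ",
                        "nm); run minimize() first"), dmin, hard_floor))
  cpp_energy_forces(coords, unclass(topology))
}
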