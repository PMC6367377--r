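# Average residue masses (Da, 2 dp) and monoisotopic residue masses of
# the 20 standard amino acids; one water is added per chain.
AA_AVERAGE_MASS <- c(
  A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14, E = 129.12,
  Q = 128.13, G = 57.05, H = 137.14, I = 113.16, L = 113.16, K = 128.17,
  M = 131.20, F = 147.18, P = 97.12, S = 87.08, T = 101.10, W = 186.21,
  Y = 163.18, V = 99.13
)
AA_MONO_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)
WATER_AVERAGE <- 18.02
WATER_MONO <- 18.010565
HYDROGEN_AVERAGE <- 1.00794

# Ionizable-group pKa values (EMBOSS set); termini plus side chains.
PKA_TABLE <- c(
  Nterm = 8.6, Cterm = 3.6,
  K = 10.8, R = 12.5, H = 6.5,      # positive side chains
  D = 3.9, E = 4.1, C = 8.5, Y = 10.1  # negative side chains
)

#' Mature-protein length after signal-peptide removal
#'
#' @param full Full protein length(s) in residues.
#' @param signal Signal-peptide length(s) in residues
#'   (\code{0 <= signal < full}).
#' @return \code{full - signal}.
#' @export
mature_length <- function(full, signal) {
  if (any(signal < 0) || any(signal >= full)) {
    stop("signal length must satisfy 0 <= signal < full")
  }
  full - signal
}

#' Average (or monoisotopic) molecular mass of a peptide
#'
#' Sum of residue masses plus one water. Average residue masses are
#' carried to two decimal places, matching the resolution of deconvoluted
#' ESI-TOF comparisons; monoisotopic masses are available behind a flag.
#'
#' @param sequence Amino-acid string (standard 20 letters only).
#' @param monoisotopic Use monoisotopic instead of average masses.
#' @return Mass in Da.
#' @export
average_mass <- function(sequence, monoisotopic = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty amino-acid string")
  }
  res <- strsplit(toupper(sequence), "")[[1L]]
  tab <- if (monoisotopic) AA_MONO_MASS else AA_AVERAGE_MASS
  bad <- setdiff(unique(res), names(tab))
  if (length(bad)) {
    stop("nonstandard residue(s): ", paste(bad, collapse = ", "))
  }
  water <- if (monoisotopic) WATER_MONO else WATER_AVERAGE
  sum(tab[res]) + water
}

#' Oxidized mass after disulfide-bond formation
#'
#' Each disulfide bond removes two hydrogens from the reduced chain:
#' \code{reduced_mass - n_bonds * 2 * 1.00794}.
#'
#' @param reduced_mass Mass of the fully reduced polypeptide (Da).
#' @param n_bonds Number of intramolecular disulfide bonds.
#' @return Oxidized mass in Da.
#' @export
disulfide_adjusted_mass <- function(reduced_mass, n_bonds) {
  if (any(reduced_mass <= 0)) stop("reduced_mass must be positive")
  if (any(n_bonds < 0)) stop("n_bonds must be non-negative")
  reduced_mass - n_bonds * 2 * HYDROGEN_AVERAGE
}

#' Mass after loss of the initial methionine
#'
#' Subtracts the average Met residue mass (131.20 Da); equals the mass of
#' the Met-truncated sequence when the chain starts with M.
#'
#' @param mass Mass of the Met-bearing chain (Da).
#' @return Mass in Da.
#' @export
met_loss_mass <- function(mass) {
  if (any(mass <= AA_AVERAGE_MASS[["M"]])) {
    stop("mass must exceed the Met residue mass (131.20 Da)")
  }
  mass - AA_AVERAGE_MASS[["M"]]
}

.net_charge <- function(counts, n_term, c_term, pH) {
  pos <- sum(c(Nterm = n_term, counts[c("K", "R", "H")]) /
               (1 + 10^(pH - PKA_TABLE[c("Nterm", "K", "R", "H")])))
  neg <- sum(c(Cterm = c_term, counts[c("D", "E", "C", "Y")]) /
               (1 + 10^(PKA_TABLE[c("Cterm", "D", "E", "C", "Y")] - pH)))
  pos - neg
}

#' Isoelectric point by Henderson--Hasselbalch bisection
#'
#' Net charge is modelled from the EMBOSS pKa set (termini plus K, R, H,
#' D, E, C, Y side chains) and its root located by bisection on pH 0--14.
#' No per-residue environment corrections are applied.
#'
#' @param sequence Amino-acid string (standard 20 letters).
#' @param tol Charge tolerance at the returned pH.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, tol = 1e-3) {
  res <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(unique(res), names(AA_AVERAGE_MASS))
  if (length(bad)) {
    stop("nonstandard residue(s): ", paste(bad, collapse = ", "))
  }
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(res == a), numeric(1L))
  lo <- 0; hi <- 14
  # net charge is monotone decreasing in pH
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (.net_charge(counts, 1, 1, mid) > 0) lo <- mid else hi <- mid
  }
  pI <- (lo + hi) / 2
  if (abs(.net_charge(counts, 1, 1, pI)) > tol) {
    # extremely basic/acidic chains can pin the root at a boundary
    warning("net charge at returned pI exceeds tolerance")
  }
  pI
}

#' Summary statistics for family protein lengths
#'
#' @param lengths Numeric vector of lengths (residues), non-empty.
#' @return List with \code{mean}, \code{sd} (sample standard deviation;
#'   \code{NA} for a single record), \code{min} and \code{max}.
#' @export
family_length_stats <- function(lengths) {
  if (length(lengths) == 0L || anyNA(lengths)) {
    stop("lengths must be a non-empty numeric vector without NAs")
  }
  list(mean = mean(lengths), sd = if (length(lengths) > 1L) sd(lengths) else NA_real_,
       min = min(lengths), max = max(lengths))
}
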