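# Residue-level lookup tables used across the package.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_ALPHABET <- c(AA_STANDARD, "X")

#' Bulky hydrophobic residues used by the consecutive-run criterion
#'
#' Leucine, valine, phenylalanine, isoleucine, tryptophan, methionine and
#' tyrosine: the residue set whose presence as a consecutive run on the
#' hydrophobic face is required for an amphipathicity call.
#' @export
BULKY_HYDROPHOBIC <- c("L", "V", "F", "I", "W", "M", "Y")

CHARGED_RESIDUES <- c("D", "E", "K", "R")

# Fauchere-Pliska octanol/water transfer free energies (dimensionless, the
# HeliQuest convention). X contributes nothing to the moment.
FAUCHERE_PLISKA <- c(
  A =  0.31, R = -1.01, N = -0.60, D = -0.77, C =  1.54,
  Q = -0.22, E = -0.64, G =  0.00, H =  0.13, I =  1.80,
  L =  1.70, K = -0.99, M =  1.23, F =  1.79, P =  0.72,
  S = -0.04, T =  0.26, W =  2.25, Y =  0.96, V =  1.22
)

# Per-residue isoelectric points of the free amino acids (Lehninger values),
# used as the local-average pI profile table.
AA_PI_LEHNINGER <- c(
  A = 6.00, R = 10.76, N = 5.41, D = 2.77, C = 5.07,
  Q = 5.65, E =  3.22, G = 5.97, H = 7.59, I = 6.02,
  L = 5.98, K =  9.74, M = 5.74, F = 5.48, P = 6.30,
  S = 5.68, T =  5.60, W = 5.89, Y = 5.66, V = 5.96
)

#' Hydrophobicity scale
#'
#' Returns a per-residue hydrophobicity lookup covering the 20 standard
#' amino acids plus `X`. The default is the Fauchere-Pliska octanol scale,
#' the scale HeliQuest uses for helical-wheel moments. Unknown residues
#' (`X`) are assigned `x_value` so that they contribute neither to the
#' hydrophobic moment nor to face composition decisions.
#'
#' @param name scale name; currently `"fauchere_pliska"`.
#' @param x_value hydrophobicity assigned to `X` (default 0).
#' @return named list with elements `name` and `values`
#'   (named numeric vector over the 21-letter alphabet).
#' @examples
#' hydrophobicity_scale()$values[["W"]]
#' @export
hydrophobicity_scale <- function(name = "fauchere_pliska", x_value = 0) {
  name <- match.arg(name, "fauchere_pliska")
  values <- c(FAUCHERE_PLISKA, X = x_value)
  stopifnot(all(AA_STANDARD %in% names(values)))
  list(name = name, values = values)
}

#' Per-residue isoelectric-point table
#'
#' Free-amino-acid pI values (pH units) used by [isoelectric_profile()].
#' `X` is assigned a configurable neutral value since unknown residues carry
#' no charge information.
#'
#' @param x_value pI assigned to `X` (default 6.0, near neutral).
#' @return named numeric vector over the 21-letter alphabet.
#' @export
aa_pi_table <- function(x_value = 6.0) {
  c(AA_PI_LEHNINGER, X = x_value)
}

# split a sequence string into a character vector of residues
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

validate_residues <- function(sequence, id = "<sequence>") {
  chars <- seq_chars(sequence)
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("record '%s': illegal residue '%s' at position %d",
                 id, chars[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}
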