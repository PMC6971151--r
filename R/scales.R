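#' @importFrom stats setNames
NULL

# The 20 standard amino acids, alphabetical one-letter order used throughout.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte & Doolittle (1982) hydropathy.
.kd_hydropathy <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

# Grantham (1974) polarity.
.grantham_polarity <- c(
  A =  8.1, C =  5.5, D = 13.0, E = 12.3, F =  5.2,
  G =  9.0, H = 10.4, I =  5.2, K = 11.3, L =  4.9,
  M =  5.7, N = 11.6, P =  8.0, Q = 10.5, R = 10.5,
  S =  9.2, T =  8.6, V =  5.9, W =  5.4, Y =  6.2)

# Zimmerman, Eliezer & Simha (1968) bulkiness.
.zimmerman_bulkiness <- c(
  A = 11.50, C = 13.46, D = 11.68, E = 13.57, F = 19.80,
  G =  3.40, H = 13.69, I = 21.40, K = 15.71, L = 21.40,
  M = 16.25, N = 12.82, P = 17.43, Q = 14.45, R = 14.28,
  S =  9.47, T = 15.77, V = 21.57, W = 21.67, Y = 18.03)

# Per-residue transfer free energies (kcal/mol) behind the Boman (2003)
# protein-binding index; hydrophobic residues negative. The index is the
# negated mean, so hydrophilic peptides score high. Proline was not measured
# in the source set and is conventionally set to 0.
.boman_energy <- c(
  A = -1.81, C = -1.28, D =  8.72, E =  6.81, F = -2.98,
  G = -0.94, H =  4.66, I = -4.92, K =  5.55, L = -4.92,
  M = -2.35, N =  6.64, P =  0.00, Q =  5.54, R = 14.92,
  S =  3.40, T =  2.57, V = -4.04, W = -2.33, Y = -0.14)

# Kidera et al. (1985): ten orthogonal factors summarizing 188 physical
# properties; rows = amino acids, columns = factors 1..10.
.kidera <- matrix(c(
  # KF1    KF2    KF3    KF4    KF5    KF6    KF7    KF8    KF9    KF10
  -1.56, -1.67, -0.97, -0.27, -0.93, -0.78, -0.20, -0.08,  0.21, -0.48, # A
   0.12, -0.89,  0.45, -1.05, -0.71,  2.41,  1.52, -0.69,  1.13,  1.10, # C
   0.58, -0.22, -1.58,  0.81, -0.92,  0.15, -1.52,  0.47,  0.76,  0.70, # D
  -1.45,  0.19, -1.61,  1.17, -1.31,  0.40,  0.04,  0.38, -0.35, -0.12, # E
  -0.21,  0.98, -0.36, -1.43,  0.22, -0.81,  0.67,  1.10,  1.71, -0.44, # F
   1.46, -1.96, -0.23, -0.16,  0.10, -0.11,  1.32,  2.36, -1.66,  0.46, # G
  -0.41,  0.52, -0.28,  0.28,  1.61,  1.01, -1.85,  0.47,  1.13,  1.63, # H
  -0.73, -0.16,  1.79, -0.77, -0.54,  0.03, -0.83,  0.51,  0.66, -1.78, # I
  -0.34,  0.82, -0.23,  1.70,  1.54, -1.62,  1.15, -0.08, -0.48,  0.60, # K
  -1.04,  0.00, -0.24, -1.10, -0.55, -2.05,  0.96, -0.76,  0.45,  0.93, # L
  -1.40,  0.18, -0.42, -0.73,  2.00,  1.52,  0.26,  0.11, -1.27,  0.27, # M
   1.14, -0.07, -0.12,  0.81,  0.18,  0.37, -0.09,  1.23,  1.10, -1.73, # N
   2.06, -0.33, -1.15, -0.75,  0.88, -0.45,  0.30, -2.30,  0.74, -0.28, # P
  -0.47,  0.24,  0.07,  1.10,  1.10,  0.59,  0.84, -0.71, -0.03, -2.33, # Q
   0.22,  1.27,  1.37,  1.87, -1.70,  0.46,  0.92, -0.39,  0.23,  0.93, # R
   0.81, -1.08,  0.16,  0.42, -0.21, -0.43, -1.89, -1.15, -0.97, -0.23, # S
   0.26, -0.70,  1.21,  0.63, -0.10,  0.21,  0.24, -1.15, -0.56,  0.19, # T
  -0.74, -0.71,  2.04, -0.40,  0.50, -0.81, -1.07,  0.06, -0.46,  0.65, # V
   0.30,  2.10, -0.72, -1.57, -1.16,  0.57, -0.48, -0.40, -2.30, -0.60, # W
   1.38,  1.48,  0.80, -0.56,  0.00, -0.68, -0.31,  1.03, -0.05,  0.53  # Y
), nrow = 20, byrow = TRUE,
   dimnames = list(AA20, paste0("kidera_", 1:10)))

#' Bundled amino-acid scale tables
#'
#' Returns the per-residue scale tables used by [compute_features()]:
#' Kyte-Doolittle hydropathy, Grantham polarity, Zimmerman bulkiness, the
#' transfer free energies behind the Boman index, and the ten Kidera factors.
#' Exposed so that independent re-computation (e.g. brute-force checks)
#' uses exactly the tables the package ships.
#'
#' @return A list with elements `hydropathy`, `polarity`, `bulkiness`,
#'   `boman_energy` (named numeric vectors over the 20 standard residues)
#'   and `kidera` (a 20 x 10 matrix, rows named by residue).
#' @export
aa_scales <- function() {
  list(hydropathy   = .kd_hydropathy,
       polarity     = .grantham_polarity,
       bulkiness    = .zimmerman_bulkiness,
       boman_energy = .boman_energy,
       kidera       = .kidera)
}

#' Hydropathy classes of the 20 standard amino acids
#'
#' Three disjoint groups covering all residues, following the Kyte-Doolittle
#' scale: hydrophobic (A, C, F, I, L, M, W, V), neutral (G, H, P, S, T, Y)
#' and hydrophilic (E, D, K, N, Q, R).
#'
#' @return Named list of three character vectors.
#' @export
hydropathy_classes <- function() {
  list(hydrophobic = c("A", "C", "F", "I", "L", "M", "W", "V"),
       neutral     = c("G", "H", "P", "S", "T", "Y"),
       hydrophilic = c("E", "D", "K", "N", "Q", "R"))
}

#' Classify residues by hydropathy
#'
#' @param residue Character vector of single-letter amino-acid codes.
#' @return Character vector with values `"hydrophobic"`, `"neutral"` or
#'   `"hydrophilic"`.
#' @examples
#' classify_hydropathy(c("G", "E", "L"))
#' @export
classify_hydropathy <- function(residue) {
  cls <- hydropathy_classes()
  bad <- !residue %in% unlist(cls)
  if (any(bad)) {
    stop("non-standard residue(s): ", paste(unique(residue[bad]), collapse = ", "))
  }
  out <- character(length(residue))
  for (nm in names(cls)) out[residue %in% cls[[nm]]] <- nm
  out
}
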