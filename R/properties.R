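# Physicochemical protein properties in the style of the ExPASy ProtParam
# report: length, average molecular weight, isoelectric point (Bjellqvist
# pKa set, bisection on the net-charge curve), GRAVY (Kyte-Doolittle),
# aliphatic index, and the Guruprasad instability index.

# Kyte & Doolittle (1982) hydropathy values
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# average residue masses (monomer minus water); water added once per chain
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Bjellqvist pKa values (ExPASy-compatible): side chains, C-terminus, and
# residue-specific N-terminal pKa
PKA_SIDE_POS <- c(K = 10.0, R = 12.0, H = 5.98)
PKA_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PKA_CTERM <- 3.55
PKA_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.7)
PKA_NTERM_DEFAULT <- 7.5

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values
# (rows: first residue, columns: second residue)
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE,
  dimnames = list(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))

# Net charge of a peptide at a given pH under the Bjellqvist model.
protein_net_charge <- function(seq, ph) {
  res <- chars(seq)
  nt_pka <- PKA_NTERM[res[1]]
  if (is.na(nt_pka)) nt_pka <- PKA_NTERM_DEFAULT
  pos_pka <- c(nt_pka, unname(PKA_SIDE_POS[res[res %in% names(PKA_SIDE_POS)]]))
  neg_pka <- c(PKA_CTERM, unname(PKA_SIDE_NEG[res[res %in% names(PKA_SIDE_NEG)]]))
  sum(1 / (1 + 10^(ph - pos_pka))) - sum(1 / (1 + 10^(neg_pka - ph)))
}

#' Physicochemical properties of a protein sequence
#'
#' @param seq Amino-acid string; only the 20 standard residues are accepted.
#' @return One-row tibble: `length_aa`, `molecular_weight` (Da, average
#'   masses), `pI` (bisection on the net-charge curve, Bjellqvist pKa set),
#'   `gravy` (mean Kyte-Doolittle hydropathy), `aliphatic_index`
#'   (`X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` in mole percent), and
#'   `instability_index` (Guruprasad dipeptide weights; `NA` for a single
#'   residue).
#' @export
protein_properties <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    abort("`seq` must be a non-empty amino-acid string")
  }
  res <- chars(seq)
  bad <- setdiff(unique(res), AA20)
  if (length(bad)) {
    abort(sprintf("non-standard residue(s): %s", paste(bad, collapse = ", ")))
  }
  n <- length(res)
  mw <- sum(RESIDUE_MASS[res]) + WATER_MASS
  gravy <- mean(KD_HYDROPATHY[res])

  molpct <- 100 * table(factor(res, levels = AA20)) / n
  aliphatic <- unname(molpct["A"] + 2.9 * molpct["V"] +
                        3.9 * (molpct["I"] + molpct["L"]))

  lo <- 0; hi <- 14
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(seq, mid) > 0) lo <- mid else hi <- mid
  }
  pi <- (lo + hi) / 2

  instability <- if (n >= 2) {
    (10 / n) * sum(DIWV[cbind(res[-n], res[-1])])
  } else NA_real_

  tibble(
    length_aa = n, molecular_weight = mw, pI = pi, gravy = gravy,
    aliphatic_index = aliphatic, instability_index = instability
  )
}
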