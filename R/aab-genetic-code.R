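# Standard genetic code lookups shared by the selection and codon-usage
# modules.  Built once at package build time from Biostrings::GENETIC_CODE.

GENETIC_CODE_TAB <- Biostrings::GENETIC_CODE

ALL_CODONS <- names(GENETIC_CODE_TAB)
STOP_CODONS <- ALL_CODONS[GENETIC_CODE_TAB == "*"]
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

# amino acid -> synonymous codon family (sense codons only)
SYN_FAMILIES <- split(SENSE_CODONS, GENETIC_CODE_TAB[SENSE_CODONS])

# family size per codon
FAMILY_SIZE <- setNames(
  lengths(SYN_FAMILIES)[GENETIC_CODE_TAB[SENSE_CODONS]],
  SENSE_CODONS
)

# Codons with any synonymous alternative (excludes Met ATG and Trp TGG).
VARIABLE_CODONS <- SENSE_CODONS[FAMILY_SIZE > 1L]

NUCS <- c("A", "C", "G", "T")

# Per-codon count of synonymous single-nucleotide changes out of the 9
# possible; changes creating a stop codon count as nonsynonymous, so
# synonymous + nonsynonymous site fractions always sum to 3 per codon
# (Nei-Gojobori site convention).
.count_syn_changes <- function(codon) {
  aa <- GENETIC_CODE_TAB[[codon]]
  s <- 0L
  cs <- chars(codon)
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, cs[pos])) {
      alt <- cs
      alt[pos] <- nt
      alt_codon <- paste(alt, collapse = "")
      if (GENETIC_CODE_TAB[[alt_codon]] == aa) s <- s + 1L
    }
  }
  s
}

# synonymous site count per codon (0..3): fraction of the 9 changes * 3
SYN_SITES <- setNames(
  vapply(SENSE_CODONS, .count_syn_changes, integer(1)) / 3,
  SENSE_CODONS
)

# For each sense codon: synonymous alternatives (same aa, excluding self) and
# nonsynonymous sense alternatives (different aa, never a stop).  Used by the
# synthetic generator to plant controlled Ka/Ks signal.
SYN_ALTS <- lapply(setNames(SENSE_CODONS, SENSE_CODONS), function(cd) {
  fam <- SYN_FAMILIES[[GENETIC_CODE_TAB[[cd]]]]
  setdiff(fam, cd)
})
NONSYN_ALTS <- lapply(setNames(SENSE_CODONS, SENSE_CODONS), function(cd) {
  SENSE_CODONS[GENETIC_CODE_TAB[SENSE_CODONS] != GENETIC_CODE_TAB[[cd]]]
})

translate_codons <- function(codons) {
  paste(GENETIC_CODE_TAB[codons], collapse = "")
}
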