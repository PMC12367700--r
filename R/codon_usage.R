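# Codon usage bias suite: codon counting, RSCU, Wright's ENC, CAI, GC/GC3s,
# third-position composition with PR2 coordinates, the ENC-expected curve,
# and optimal-codon identification from ENC-stratified gene sets.

#' Count sense codons in a CDS
#'
#' The terminal stop codon is excluded; an internal stop is an error; codons
#' containing characters outside ACGT are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param cds Nucleotide string with length divisible by 3.
#' @return Named integer vector over the 61 sense codons, with attributes
#'   `n_codons` (sum of counts) and `n_skipped`.
#' @export
count_codons <- function(cds) {
  codons <- codon_split(toupper(cds))
  if (codons[length(codons)] %in% STOP_CODONS) codons <- codons[-length(codons)]
  if (any(codons %in% STOP_CODONS)) abort("internal stop codon")
  valid <- codons %in% SENSE_CODONS
  counts <- table(factor(codons[valid], levels = SENSE_CODONS))
  out <- setNames(as.integer(counts), SENSE_CODONS)
  attr(out, "n_codons") <- sum(out)
  attr(out, "n_skipped") <- sum(!valid)
  out
}

#' Relative synonymous codon usage
#'
#' `RSCU = count / (mean count of the synonymous family)`, so values within
#' an observed family sum to the family size.  Families with zero total and
#' the single-codon families (Met, Trp) are absent from the result.
#'
#' @param counts A [count_codons()] vector (or any named count vector over
#'   sense codons).
#' @return Named numeric vector of RSCU values.
#' @export
rscu <- function(counts) {
  out <- numeric(0)
  for (fam in SYN_FAMILIES) {
    if (length(fam) < 2) next
    cts <- counts[fam]
    tot <- sum(cts)
    if (tot == 0) next
    out <- c(out, cts / (tot / length(fam)))
  }
  out
}

#' Wright's effective number of codons (ENC)
#'
#' Per-family codon homozygosity `F = (n * sum(p^2) - 1) / (n - 1)` for
#' families with `n > 1` observations, averaged within degeneracy classes;
#' `ENC = 2 + n2/F2 + n3/F3 + n4/F4 + n6/F6` with the class-family counts as
#' numerators.  A missing 3-fold mean is imputed as the average of the 2- and
#' 4-fold means.  Results are clamped to [20, 61]; `NA` when no class mean
#' can be formed.
#'
#' @param counts A [count_codons()] vector.
#' @param sixfold_split Treat Leu/Ser/Arg as 2-fold + 4-fold sub-families
#'   instead of single 6-fold families (default FALSE, the codonW
#'   convention).
#' @return ENC value in [20, 61], or `NA`.
#' @export
enc <- function(counts, sixfold_split = FALSE) {
  fams <- if (sixfold_split) {
    unlist(lapply(SYN_FAMILIES, function(fam) {
      if (length(fam) != 6) return(list(fam))
      pre <- substr(fam, 1, 2)
      split(fam, pre == names(sort(table(pre), decreasing = TRUE))[1])
    }), recursive = FALSE)
  } else {
    SYN_FAMILIES
  }
  fams <- fams[lengths(fams) > 1]
  f_by_class <- list()
  for (fam in fams) {
    n <- sum(counts[fam])
    if (n <= 1) next
    p <- counts[fam] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) next  # uninformative family (codonW convention)
    s <- as.character(length(fam))
    f_by_class[[s]] <- c(f_by_class[[s]], f)
  }
  class_sizes <- table(lengths(fams))
  fbar <- vapply(names(class_sizes),
                 function(s) mean(f_by_class[[s]] %||% NA_real_),
                 numeric(1))
  if (is.na(fbar["3"]) && "3" %in% names(fbar) &&
      !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar["3"] <- mean(c(fbar["2"], fbar["4"]))
  }
  if (all(is.na(fbar))) return(NA_real_)
  if (anyNA(fbar)) return(NA_real_)
  val <- 2 + sum(as.numeric(class_sizes) / fbar)
  min(61, max(20, val))
}

#' Expected ENC under mutation pressure alone
#'
#' Wright's reference curve `ENC = 2 + s + 29 / (s^2 + (1 - s)^2)` as a
#' function of GC3s, drawn as the no-selection line on ENC-GC3s plots.
#'
#' @param gc3s GC3s fraction(s) in [0, 1].
#' @return Expected ENC value(s).
#' @export
enc_expected <- function(gc3s) {
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Codon adaptation index
#'
#' Relative adaptiveness `w = count / max family count` on the pooled
#' reference (zero pooled counts replaced by 0.5); CAI is the geometric mean
#' of `w` over the gene's codons, excluding Met, Trp and stops.
#'
#' @param counts A [count_codons()] vector for the gene.
#' @param reference A list of count vectors (pooled by summation) or a
#'   single pooled count vector for the reference gene set.
#' @return CAI in (0, 1], or `NA` when the gene has no scorable codons.
#' @export
cai <- function(counts, reference) {
  pooled <- if (is.list(reference)) Reduce(`+`, reference) else reference
  if (is.null(pooled) || sum(pooled) == 0) abort("empty CAI reference")
  pooled <- pmax(pooled, 0.5)
  w <- pooled
  for (fam in SYN_FAMILIES) w[fam] <- pooled[fam] / max(pooled[fam])
  scorable <- intersect(VARIABLE_CODONS, names(counts)[counts > 0])
  if (length(scorable) == 0) return(NA_real_)
  exp(sum(counts[scorable] * log(w[scorable])) / sum(counts[scorable]))
}

#' Third-position composition and PR2 coordinates
#'
#' Nucleotide tallies at the third position of synonymously variable codons
#' only (Met and Trp excluded): `T3s`, `C3s`, `A3s`, `G3s`, `GC3s`, and the
#' PR2 plot coordinates `pr2_x = G3/(G3+C3)`, `pr2_y = A3/(A3+T3)`.
#'
#' @param counts A [count_codons()] vector.
#' @return One-row tibble with the seven statistics (`NA` components on
#'   zero denominators).
#' @export
third_position_composition <- function(counts) {
  third <- substr(VARIABLE_CODONS, 3, 3)
  tal <- vapply(NUCS, function(nt) sum(counts[VARIABLE_CODONS][third == nt]),
                numeric(1))
  tot <- sum(tal)
  frac <- if (tot > 0) tal / tot else rep(NA_real_, 4)
  names(frac) <- NUCS
  gc3s <- if (tot > 0) (tal["G"] + tal["C"]) / tot else NA_real_
  pr2_x <- if ((tal["G"] + tal["C"]) > 0) tal["G"] / (tal["G"] + tal["C"]) else NA_real_
  pr2_y <- if ((tal["A"] + tal["T"]) > 0) tal["A"] / (tal["A"] + tal["T"]) else NA_real_
  tibble(T3s = unname(frac["T"]), C3s = unname(frac["C"]),
         A3s = unname(frac["A"]), G3s = unname(frac["G"]),
         GC3s = unname(gc3s), pr2_x = unname(pr2_x), pr2_y = unname(pr2_y))
}

#' Per-gene codon usage profiles
#'
#' Runs the whole suite over a CDS catalog: ENC, third-position composition,
#' overall GC, and CAI.  The CAI reference defaults to the pooled counts of
#' the lowest-10%-ENC genes (the high-expression proxy used for
#' optimal-codon calling); pass `reference` to override.
#'
#' @param cds_catalog Tibble with `gene_id`, `sequence`.
#' @param reference Optional CAI reference (list of count vectors or pooled
#'   vector).
#' @param tail Fraction of genes forming the default reference set
#'   (default 0.10).
#' @return Tibble, one row per gene: `gene_id`, `n_codons`, `GC`, `ENC`,
#'   `CAI`, `GC3s`, `T3s`, `C3s`, `A3s`, `G3s`, `pr2_x`, `pr2_y`.
#' @export
codon_usage_profile <- function(cds_catalog, reference = NULL, tail = 0.10) {
  counts_list <- lapply(cds_catalog$sequence, count_codons)
  names(counts_list) <- cds_catalog$gene_id
  enc_vals <- vapply(counts_list, enc, numeric(1))
  if (is.null(reference)) {
    ok <- which(!is.na(enc_vals))
    n_tail <- max(1L, floor(tail * length(ok)))
    ref_idx <- ok[order(enc_vals[ok], cds_catalog$gene_id[ok])][seq_len(n_tail)]
    reference <- counts_list[ref_idx]
  }
  gc_all <- vapply(cds_catalog$sequence, function(s) {
    b <- chars(toupper(s))
    mean(b %in% c("G", "C"))
  }, numeric(1))
  third <- purrr::map_dfr(counts_list, third_position_composition)
  tibble(
    gene_id = cds_catalog$gene_id,
    n_codons = vapply(counts_list, function(x) attr(x, "n_codons"), integer(1)),
    GC = unname(gc_all),
    ENC = unname(enc_vals),
    CAI = vapply(counts_list, cai, numeric(1), reference = reference)
  ) |> bind_cols(third)
}

#' Identify optimal codons from ENC-stratified gene sets
#'
#' The lowest-`tail` ENC genes form the high-expression set and the
#' highest-`tail` ENC genes the low-expression set; RSCU is computed on each
#' set's pooled counts and a codon is optimal when `RSCU_high > 1`,
#' `RSCU_low < 1` and `delta_rscu >= delta_min`.
#'
#' @param profiles Output of [codon_usage_profile()] (uses `gene_id`, `ENC`).
#' @param cds_catalog Tibble with `gene_id`, `sequence`.
#' @param tail Tail fraction (default 0.10).
#' @param delta_min RSCU difference threshold (default 0.3).
#' @return Tibble per synonymous codon: `codon`, `amino_acid`, `rscu_high`,
#'   `rscu_low`, `delta_rscu`, `is_optimal`.
#' @export
optimal_codons <- function(profiles, cds_catalog, tail = 0.10,
                           delta_min = 0.3) {
  ok <- filter(profiles, !is.na(.data$ENC))
  if (nrow(ok) < 10) abort("need at least 10 genes with defined ENC")
  n_tail <- floor(tail * nrow(ok))
  if (n_tail < 1) abort("tail fraction leaves an empty gene set")
  ordered <- arrange(ok, .data$ENC, .data$gene_id)
  high_ids <- head(ordered$gene_id, n_tail)   # lowest ENC = strongest bias
  low_ids <- tail(ordered$gene_id, n_tail)
  pool <- function(ids) {
    seqs <- cds_catalog$sequence[match(ids, cds_catalog$gene_id)]
    Reduce(`+`, lapply(seqs, count_codons))
  }
  rh <- rscu(pool(high_ids))
  rl <- rscu(pool(low_ids))
  codons <- VARIABLE_CODONS
  rscu_high <- unname(rh[codons])
  rscu_low <- unname(rl[codons])
  delta <- rscu_high - rscu_low
  tibble(
    codon = codons,
    amino_acid = unname(GENETIC_CODE_TAB[codons]),
    rscu_high = rscu_high,
    rscu_low = rscu_low,
    delta_rscu = delta,
    is_optimal = !is.na(rscu_high) & !is.na(rscu_low) &
      rscu_high > 1 & rscu_low < 1 & delta >= delta_min
  )
}
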