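# Structural variation around gene loci: TE positional classification and
# three-letter-code tallies, PAV-gene overlap, and simplified duplication
# typing.  All interval arithmetic is 0-based half-open.

overlaps <- function(s1, e1, s2, e2) pmax(s1, s2) < pmin(e1, e2)

# Vectorized positional label for TE interval(s) against gene locus(es).
te_position_vec <- function(te_start, te_end, g_start, g_end, g_strand,
                            window_bp = 2000, strand_aware = TRUE) {
  genic <- overlaps(te_start, te_end, g_start, g_end)
  left <- overlaps(te_start, te_end, g_start - window_bp, g_start)
  right <- overlaps(te_start, te_end, g_end, g_end + window_bp)
  minus <- strand_aware & g_strand == "-"
  ifelse(genic, "genic",
    ifelse(left, ifelse(minus, "downstream", "upstream"),
      ifelse(right, ifelse(minus, "upstream", "downstream"), "none")))
}

#' Classify a TE's position relative to a gene
#'
#' Genic (any overlap with the gene body) takes priority; otherwise the TE
#' is upstream if it overlaps the `window_bp` flank on the gene's 5' side
#' (strand-aware) and downstream for the 3' side.  With
#' `strand_aware = FALSE` the left flank is always called upstream.
#'
#' @param te One-row tibble (or list) with `chrom`, `start`, `end`.
#' @param gene One-row tibble (or list) with `chrom`, `start`, `end`,
#'   `strand`.
#' @param window_bp Flank window width (default 2000).
#' @param strand_aware Mirror flank labels on minus-strand genes
#'   (default TRUE).
#' @return One of `"genic"`, `"upstream"`, `"downstream"`, `"none"`.
#' @export
classify_te_position <- function(te, gene, window_bp = 2000,
                                 strand_aware = TRUE) {
  if (window_bp < 0) abort("window_bp must be nonnegative")
  if (!is.null(te$chrom) && !is.null(gene$chrom) && te$chrom != gene$chrom) {
    return("none")
  }
  te_position_vec(te$start, te$end, gene$start, gene$end,
                  gene$strand %||% "+", window_bp, strand_aware)
}

#' Assign every TE to its best gene and positional label
#'
#' Pairs TEs with same-chromosome genes, labels each pair with
#' [classify_te_position()] semantics and keeps, per TE, the best
#' assignment (genic beats flank; nearer gene beats farther).  TEs with no
#' gene in reach are labelled `none`.
#'
#' @param te TE tibble (`chrom`, `start`, `end`, `strand`, `code`).
#' @param genes Gene loci tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param window_bp Flank window (default 2000).
#' @param strand_aware See [classify_te_position()].
#' @return `te` plus `gene_id` (NA when unassigned) and `position`.
#' @export
te_gene_assignments <- function(te, genes, window_bp = 2000,
                                strand_aware = TRUE) {
  te_idx <- mutate(te, .te = row_number())
  pairs <- inner_join(
    select(te_idx, ".te", "chrom", te_start = "start", te_end = "end"),
    select(genes, "gene_id", "chrom", g_start = "start", g_end = "end",
           g_strand = "strand"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    mutate(position = te_position_vec(.data$te_start, .data$te_end,
                                      .data$g_start, .data$g_end,
                                      .data$g_strand, window_bp,
                                      strand_aware)) |>
    filter(.data$position != "none") |>
    mutate(
      rank = ifelse(.data$position == "genic", 0L, 1L),
      dist = pmax(.data$g_start - .data$te_end, .data$te_start - .data$g_end, 0L)
    ) |>
    group_by(.data$.te) |>
    arrange(.data$rank, .data$dist, .data$gene_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(".te", "gene_id", "position")
  te_idx |>
    left_join(pairs, by = ".te") |>
    mutate(position = dplyr::coalesce(.data$position, "none")) |>
    select(-".te")
}

#' Tally TE positional assignments and three-letter codes
#'
#' @param assignments Tibble with `position` (upstream/genic/downstream/none)
#'   and `code` (three-letter TE classification).
#' @return List with `by_position` (counts and fractions over assigned,
#'   i.e. non-`none`, TE-gene pairs) and `by_code` (counts per code with
#'   derived `order` — retrotransposon / DNA transposon / unknown — and
#'   `superfamily`).
#' @export
tally_te_classes <- function(assignments) {
  assigned <- filter(assignments, .data$position != "none")
  by_position <- assigned |>
    count(position = factor(.data$position,
                            levels = c("upstream", "genic", "downstream")),
          name = "n", .drop = FALSE) |>
    mutate(fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0)
  by_code <- assignments |>
    mutate(code = ifelse(nchar(.data$code) == 3, .data$code, "unknown")) |>
    count(.data$code, name = "n") |>
    mutate(
      order = dplyr::case_when(
        startsWith(.data$code, "R") ~ "retrotransposon",
        startsWith(.data$code, "D") ~ "DNA transposon",
        TRUE ~ "unknown"
      ),
      superfamily = ifelse(.data$code == "unknown", NA_character_,
                           substr(.data$code, 2, 3))
    )
  list(by_position = by_position, by_code = by_code)
}

#' Overlap PAV events with gene loci
#'
#' Half-open interval arithmetic on the shared (reference) coordinate
#' system; touching intervals do not overlap.
#'
#' @param pavs Tibble: `accession_id`, `chrom`, `start`, `end`, `state`.
#' @param genes Tibble: `gene_id`, `chrom`, `start`, `end`.
#' @return Tibble, one row per overlapping pair: `gene_id`, `accession_id`,
#'   `state`, `overlap_bp` (> 0).
#' @export
pav_gene_overlap <- function(pavs, genes) {
  inner_join(
    select(pavs, "accession_id", "chrom", pav_start = "start",
           pav_end = "end", "state"),
    select(genes, "gene_id", "chrom", gene_start = "start", gene_end = "end"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    mutate(overlap_bp = pmin(.data$pav_end, .data$gene_end) -
             pmax(.data$pav_start, .data$gene_start)) |>
    filter(.data$overlap_bp > 0) |>
    select("gene_id", "accession_id", "state", "overlap_bp")
}

#' Classify gene duplication modes from cluster homology
#'
#' Genes are ranked along each chromosome by position; a gene with no
#' homolog is a singleton, one with a homolog at an adjacent rank on the
#' same chromosome is tandem, within `proximal_max_intervening` intervening
#' genes proximal, and otherwise dispersed (tandem > proximal > dispersed
#' when several homologs qualify).  Whole-genome/segmental duplicates are
#' not separated out here; without collinearity blocks they fall into the
#' dispersed category.
#'
#' @param genes Tibble: `gene_id`, `chrom`, `start` (one accession).
#' @param homolog_pairs Tibble with `gene_a`, `gene_b` (e.g. same-cluster
#'   pairs from [greedy_cluster()]).
#' @param proximal_max_intervening Maximum intervening genes for the
#'   proximal call (default 10).
#' @return Tibble: `gene_id`, `label` in
#'   singleton/tandem/proximal/dispersed.
#' @export
classify_duplication <- function(genes, homolog_pairs,
                                 proximal_max_intervening = 10) {
  unknown <- setdiff(c(homolog_pairs$gene_a, homolog_pairs$gene_b),
                     genes$gene_id)
  if (length(unknown)) {
    abort(sprintf("homolog pair references unknown gene(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  ranked <- genes |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select("gene_id", "chrom", "rank")
  pairs <- bind_rows(
    homolog_pairs,
    rename(homolog_pairs, gene_a = "gene_b", gene_b = "gene_a")
  ) |>
    filter(.data$gene_a != .data$gene_b) |>
    distinct() |>
    left_join(rename(ranked, gene_a = "gene_id", chrom_a = "chrom",
                     rank_a = "rank"), by = "gene_a") |>
    left_join(rename(ranked, gene_b = "gene_id", chrom_b = "chrom",
                     rank_b = "rank"), by = "gene_b") |>
    mutate(label = dplyr::case_when(
      .data$chrom_a != .data$chrom_b ~ "dispersed",
      abs(.data$rank_a - .data$rank_b) == 1L ~ "tandem",
      abs(.data$rank_a - .data$rank_b) - 1L <= proximal_max_intervening ~ "proximal",
      TRUE ~ "dispersed"
    ))
  pref <- c(tandem = 1L, proximal = 2L, dispersed = 3L)
  best <- pairs |>
    group_by(gene_id = .data$gene_a) |>
    summarise(label = names(pref)[min(pref[.data$label])], .groups = "drop")
  genes |>
    select("gene_id") |>
    left_join(best, by = "gene_id") |>
    mutate(label = factor(
      dplyr::coalesce(.data$label, "singleton"),
      levels = c("singleton", "dispersed", "proximal", "tandem")
    ))
}
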