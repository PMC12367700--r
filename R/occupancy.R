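# Orthogroup-by-accession occupancy and copy-number matrices and the
# core / soft-core / shell / cloud conservation classification.

# Occupancy bands per class for n accessions.  For n = 20 this reproduces
# core = 20, soft-core = 18-19, shell = 3-17, cloud = 1-2; general n follows
# the percentage phrasing (> 90% soft-core, <= 10% cloud, remainder shell).
occupancy_bands <- function(n_accessions) {
  n <- assert_count(n_accessions, "n_accessions", min = 1)
  cloud_hi <- max(1L, floor(0.1 * n))
  soft_lo <- ceiling(0.9 * n)
  softcore <- if (soft_lo <= n - 1L) soft_lo:(n - 1L) else integer(0)
  shell_lo <- cloud_hi + 1L
  shell_hi <- if (length(softcore)) soft_lo - 1L else n - 1L
  list(
    core = n,
    softcore = softcore,
    shell = if (shell_lo <= shell_hi) shell_lo:shell_hi else integer(0),
    cloud = 1:cloud_hi
  )
}

#' Build occupancy and copy-number matrices from a clustering
#'
#' @param clusters Output of [greedy_cluster()] (one row per member).
#' @param accessions Character vector of all accession identifiers; every
#'   member's accession must be listed.
#' @return List with `occupancy` and `cnv`: wide tibbles, one row per
#'   orthogroup (`ogg_id` column) and one column per accession, holding 0/1
#'   presence and member counts respectively.
#' @export
build_matrices <- function(clusters, accessions) {
  unknown <- setdiff(unique(clusters$accession_id), accessions)
  if (length(unknown)) {
    abort(sprintf("members from unlisted accession(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  counts <- clusters |>
    count(ogg_id = .data$cluster_id, .data$accession_id) |>
    tidyr::pivot_wider(names_from = "accession_id", values_from = "n",
                       values_fill = 0L)
  for (acc in setdiff(accessions, names(counts))) counts[[acc]] <- 0L
  cnv <- select(counts, "ogg_id", all_of(accessions)) |> arrange(.data$ogg_id)
  occupancy <- mutate(cnv, across(all_of(accessions), ~ as.integer(.x > 0)))
  list(occupancy = occupancy, cnv = cnv)
}

#' Classify orthogroups into core / soft-core / shell / cloud
#'
#' For 20 accessions: occupancy 20 is core, 18-19 soft-core, 3-17 shell and
#' 1-2 cloud.  General n uses the percentage bands (core = n; soft-core =
#' ceiling(0.9 n) .. n-1; cloud = 1 .. max(1, floor(0.1 n)); shell = the
#' remainder).  `strict_cloud = TRUE` restricts cloud to occupancy 1 and
#' widens shell downward so the partition stays total.
#'
#' @param occupancy The `occupancy` tibble from [build_matrices()].
#' @param n_accessions Total number of accessions surveyed (>= 3).
#' @param strict_cloud Use the single-accession cloud definition
#'   (default FALSE).
#' @return Tibble: `ogg_id`, `occupancy`, `label`.
#' @export
classify_occupancy <- function(occupancy, n_accessions,
                               strict_cloud = FALSE) {
  n <- assert_count(n_accessions, "n_accessions", min = 3)
  acc_cols <- setdiff(names(occupancy), "ogg_id")
  occ <- rowSums(occupancy[, acc_cols, drop = FALSE] > 0)
  if (any(occ == 0)) abort("orthogroup with zero occupancy")
  if (any(occ > n)) abort("occupancy exceeds n_accessions")
  bands <- occupancy_bands(n)
  cloud_band <- if (strict_cloud) 1L else bands$cloud
  label <- dplyr::case_when(
    occ == n ~ "core",
    occ %in% bands$softcore ~ "softcore",
    occ %in% cloud_band ~ "cloud",
    TRUE ~ "shell"
  )
  tibble(ogg_id = occupancy$ogg_id, occupancy = as.integer(occ),
         label = factor(label, levels = c("core", "softcore", "shell", "cloud")))
}

#' Summarise conservation categories
#'
#' Counts orthogroups per label and, when a copy-number matrix is supplied,
#' the fraction of gene entries falling in each label.
#'
#' @param classes Output of [classify_occupancy()].
#' @param cnv Optional `cnv` tibble from [build_matrices()].
#' @return Tibble: `label`, `n_orthogroups`, `fraction_orthogroups` and,
#'   with `cnv`, `n_genes`, `fraction_genes`.
#' @export
category_summary <- function(classes, cnv = NULL) {
  out <- classes |>
    count(.data$label, name = "n_orthogroups", .drop = FALSE) |>
    mutate(fraction_orthogroups = .data$n_orthogroups / sum(.data$n_orthogroups))
  if (!is.null(cnv)) {
    acc_cols <- setdiff(names(cnv), "ogg_id")
    totals <- tibble(ogg_id = cnv$ogg_id,
                     n_genes = rowSums(cnv[, acc_cols, drop = FALSE]))
    by_label <- classes |>
      left_join(totals, by = "ogg_id") |>
      group_by(.data$label) |>
      summarise(n_genes = sum(.data$n_genes), .groups = "drop")
    out <- out |>
      left_join(by_label, by = "label") |>
      mutate(n_genes = dplyr::coalesce(.data$n_genes, 0),
             fraction_genes = .data$n_genes / sum(.data$n_genes))
  }
  out
}
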