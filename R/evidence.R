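# Domain-search and homology evidence: parsers for the HMMER per-domain
# table and the 12-column tabular homology format, and the identification
# filter combining both evidence tracks.

#' Parse a HMMER per-domain table (domtblout dialect)
#'
#' Whitespace-separated, one row per domain hit; `#` lines are skipped.
#' The query (protein) is taken from the standard query-name column, the
#' domain from the target-name column, the E-value from the per-domain
#' independent E-value and the score from the per-domain bit score.
#'
#' @param path File path.
#' @return Tibble: `query_id`, `domain_name`, `evalue`, `score`,
#'   `ali_from`, `ali_to` (1-based inclusive).
#' @export
parse_domtblout <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(query_id = character(), domain_name = character(),
                  evalue = numeric(), score = numeric(),
                  ali_from = integer(), ali_to = integer()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  purrr::imap_dfr(fields, function(f, i) {
    if (length(f) < 22) {
      abort(sprintf("domtblout line %d: expected >= 22 columns, got %d",
                    i, length(f)))
    }
    num <- suppressWarnings(as.numeric(f[c(13, 14, 18, 19)]))
    if (anyNA(num)) {
      abort(sprintf("domtblout line %d: non-numeric E-value/score/coordinates", i))
    }
    tibble(query_id = f[4], domain_name = f[1],
           evalue = num[1], score = num[2],
           ali_from = as.integer(num[3]), ali_to = as.integer(num[4]))
  })
}

#' Parse a 12-column tabular homology hit table
#'
#' Standard columns: qseqid, sseqid, pident, length, mismatch, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore.  Query coordinates are
#' normalized so `q_start <= q_end`, and query coverage is computed from the
#' supplied query-length table.
#'
#' @param path File path.
#' @param query_lengths Tibble with `gene_id` (or `query_id`) and `length`.
#' @return Tibble: `query_id`, `subject_id`, `percent_identity`,
#'   `align_len`, `evalue`, `bitscore`, `q_start`, `q_end`, `query_len`,
#'   `coverage`.
#' @export
parse_homology_tab <- function(path, query_lengths) {
  if ("gene_id" %in% names(query_lengths)) {
    query_lengths <- rename(query_lengths, query_id = "gene_id")
  }
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    hits <- tibble(query_id = character(), subject_id = character(),
                   percent_identity = numeric(), align_len = integer(),
                   evalue = numeric(), bitscore = numeric(),
                   q_start = integer(), q_end = integer())
  } else {
    fields <- strsplit(trimws(lines), "\\s+")
    hits <- purrr::imap_dfr(fields, function(f, i) {
      if (length(f) != 12) {
        abort(sprintf("homology line %d: expected 12 columns, got %d",
                      i, length(f)))
      }
      num <- suppressWarnings(as.numeric(f[3:12]))
      if (anyNA(num)) abort(sprintf("homology line %d: non-numeric field", i))
      tibble(query_id = f[1], subject_id = f[2],
             percent_identity = num[1], align_len = as.integer(num[2]),
             evalue = num[9], bitscore = num[10],
             q_start = as.integer(min(num[5], num[6])),
             q_end = as.integer(max(num[5], num[6])))
    })
  }
  missing <- setdiff(hits$query_id, query_lengths$query_id)
  if (length(missing)) {
    abort(sprintf("no query length for: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  hits |>
    left_join(select(query_lengths, "query_id", query_len = "length"),
              by = "query_id") |>
    mutate(coverage = (.data$q_end - .data$q_start + 1) / .data$query_len)
}

#' Filter candidate family members on domain and homology evidence
#'
#' A protein is accepted when it has at least one domain hit passing the
#' domain thresholds and (by default) at least one homology hit passing the
#' homology thresholds.  `mode = "or"` accepts either evidence track alone.
#'
#' @param domain_hits Output of [parse_domtblout()].
#' @param homology_hits Output of [parse_homology_tab()].
#' @param evalue_dom Domain E-value ceiling (default 1e-5).
#' @param min_score Domain bit-score floor (default 20).
#' @param evalue_hom Homology E-value ceiling (default 1e-10).
#' @param min_qcov Query-coverage floor (default 0.70).
#' @param mode `"and"` (default) or `"or"` combination of the two tracks.
#' @return Sorted character vector of accepted protein identifiers.
#' @export
filter_candidates <- function(domain_hits, homology_hits,
                              evalue_dom = 1e-5, min_score = 20,
                              evalue_hom = 1e-10, min_qcov = 0.70,
                              mode = c("and", "or")) {
  mode <- match.arg(mode)
  dom_ok <- domain_hits |>
    filter(.data$evalue <= evalue_dom, .data$score >= min_score) |>
    pull("query_id") |> unique()
  hom_ok <- homology_hits |>
    filter(.data$evalue <= evalue_hom, .data$coverage >= min_qcov) |>
    pull("query_id") |> unique()
  out <- if (mode == "and") intersect(dom_ok, hom_ok) else union(dom_ok, hom_ok)
  sort(out)
}
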