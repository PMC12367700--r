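# Greedy incremental protein clustering in the CD-HIT style: records sorted
# longest-first, each compared against existing cluster representatives
# under identity / longer-sequence-coverage / alignment-length thresholds.

# +1 match, -1 mismatch over the 20 standard residues
SUBMAT_AA <- {
  m <- matrix(-1, 20, 20, dimnames = list(AA20, AA20))
  diag(m) <- 1
  m
}

# Align a set of patterns against one subject (semiglobal, free end gaps;
# match +1, mismatch -1, gap open -5, gap extend -1) and return per-pair
# identity / longer-coverage / alignment-length statistics.
align_stats <- function(patterns, subject) {
  subj_len <- nchar(subject)
  pat_len <- nchar(patterns)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    type = "overlap", substitutionMatrix = SUBMAT_AA,
    gapOpening = 5, gapExtension = 1
  )
  aligned_len <- nchar(as.character(Biostrings::pattern(al)))
  span_pat <- Biostrings::end(Biostrings::pattern(al)) -
    Biostrings::start(Biostrings::pattern(al)) + 1L
  span_sub <- Biostrings::end(Biostrings::subject(al)) -
    Biostrings::start(Biostrings::subject(al)) + 1L
  longer_is_pat <- pat_len >= subj_len
  tibble(
    identity = Biostrings::nmatch(al) / pmin(pat_len, subj_len),
    longer_coverage = ifelse(longer_is_pat, span_pat, span_sub) /
      pmax(pat_len, subj_len),
    aligned_len = as.integer(aligned_len)
  )
}

# Elementwise variant: aligns patterns[i] against subjects[i].
align_stats_pairs <- function(patterns, subjects) {
  pat_len <- nchar(patterns)
  sub_len <- nchar(subjects)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAStringSet(subjects),
    type = "overlap", substitutionMatrix = SUBMAT_AA,
    gapOpening = 5, gapExtension = 1
  )
  span_pat <- Biostrings::end(Biostrings::pattern(al)) -
    Biostrings::start(Biostrings::pattern(al)) + 1L
  span_sub <- Biostrings::end(Biostrings::subject(al)) -
    Biostrings::start(Biostrings::subject(al)) + 1L
  longer_is_pat <- pat_len >= sub_len
  tibble(
    identity = Biostrings::nmatch(al) / pmin(pat_len, sub_len),
    longer_coverage = ifelse(longer_is_pat, span_pat, span_sub) /
      pmax(pat_len, sub_len),
    aligned_len = nchar(as.character(Biostrings::pattern(al)))
  )
}

#' Pairwise identity between two protein sequences
#'
#' Semiglobal alignment with free end gaps (match +1, mismatch -1, gap open
#' -5, gap extend -1).  Identity is the count of identical aligned residues
#' divided by the shorter sequence length (the CD-HIT global-identity
#' convention); coverage is the aligned span on the longer sequence divided
#' by its length; `aligned_len` counts alignment columns excluding the
#' terminal free gaps.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return One-row tibble: `identity`, `longer_coverage`, `aligned_len`.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  align_stats(a, b)
}

kmer_set <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Greedy incremental clustering of a protein catalog
#'
#' Records are sorted by length descending (ties broken by `gene_id`
#' ascending) and processed in order: each joins the first existing cluster
#' whose representative passes all three thresholds, otherwise it founds a
#' new cluster.  The representative of every cluster is therefore a longest
#' member (lexicographically smallest on ties), and the partition does not
#' depend on input order.
#'
#' @param records Tibble with `gene_id`, `accession_id`, `sequence`.
#' @param min_identity Identity floor (default 0.95).
#' @param min_longer_cov Floor on aligned coverage of the longer sequence
#'   (default 0.90).
#' @param min_aln_len Minimum alignment length in residues (default 100).
#' @param prefilter Use the 5-mer containment prefilter (skip representative
#'   candidates sharing < `prefilter_min` of 5-mers); a speed device only —
#'   at these thresholds it cannot change the partition (default TRUE).
#' @param prefilter_min Minimum shared 5-mer fraction (default 0.2).
#' @return Tibble, one row per record: `cluster_id`, `representative`,
#'   `gene_id`, `accession_id`, `length_aa`.
#' @export
greedy_cluster <- function(records, min_identity = 0.95,
                           min_longer_cov = 0.90, min_aln_len = 100,
                           prefilter = TRUE, prefilter_min = 0.2) {
  if (nrow(records) == 0) abort("`records` is empty")
  if (anyDuplicated(records$gene_id)) abort("gene_id must be unique")
  recs <- records |>
    mutate(length_aa = nchar(.data$sequence)) |>
    arrange(dplyr::desc(.data$length_aa), .data$gene_id)
  n <- nrow(recs)
  passes <- function(st) {
    st$identity >= min_identity & st$longer_coverage >= min_longer_cov &
      st$aligned_len >= min_aln_len
  }

  if (!prefilter) {
    # plain sequential reference path
    rep_idx <- integer(0)
    assignment <- integer(n)
    for (i in seq_len(n)) {
      joined <- 0L
      if (length(rep_idx) > 0) {
        st <- align_stats(recs$sequence[rep_idx], recs$sequence[i])
        ok <- passes(st)
        if (any(ok)) joined <- rep_idx[which(ok)[1]]
      }
      if (joined == 0L) {
        rep_idx <- c(rep_idx, i)
        joined <- i
      }
      assignment[i] <- joined
    }
  } else {
    # Exact batched evaluation of the same greedy rules: records whose
    # 5-mer prefilter matches no unresolved earlier record are decided per
    # round, with all candidate alignments done in one vectorized call.
    # A record is deferred while an earlier prefilter-matching record is
    # still undecided, so the partition equals the sequential one.
    kmers <- lapply(recs$sequence, kmer_set)
    klen <- lengths(kmers)
    # Phase 1: one pass building an inverted 5-mer index over all earlier
    # records that could act as a representative (confirmed or pending).
    idx_env <- new.env(hash = TRUE, parent = emptyenv())
    index_add <- function(i) {
      for (km in kmers[[i]]) idx_env[[km]] <- c(idx_env[[km]], i)
    }
    index_matches <- function(i) {
      hits <- unlist(mget(kmers[[i]], envir = idx_env,
                          ifnotfound = list(integer(0))),
                     use.names = FALSE)
      if (length(hits) == 0) return(integer(0))
      cnt <- tabulate(hits, nbins = n)
      js <- which(cnt > 0)
      sort(js[cnt[js] / pmin(klen[i], klen[js]) >= prefilter_min])
    }
    assignment <- rep(NA_integer_, n)
    is_rep <- logical(n)
    cand_of <- vector("list", n)
    pending <- logical(n)
    for (i in seq_len(n)) {
      cand <- index_matches(i)
      if (length(cand) == 0) {
        assignment[i] <- i
        is_rep[i] <- TRUE
      } else {
        cand_of[[i]] <- cand  # candidates in record (= founding) order
        pending[i] <- TRUE
      }
      index_add(i)
    }
    # Phase 2: resolve pending records in waves; a record is ready once all
    # its prefilter candidates are themselves resolved, so its effective
    # candidate list (those that ended up representatives) is final.  Each
    # wave's alignments run in one vectorized call.
    while (any(pending)) {
      todo <- which(pending)
      ready <- todo[vapply(todo, function(i) !any(pending[cand_of[[i]]]),
                           logical(1))]
      eff_cand <- lapply(ready, function(i) {
        cand_of[[i]][is_rep[cand_of[[i]]]]
      })
      lens <- lengths(eff_cand)
      st <- if (sum(lens) > 0) {
        align_stats_pairs(recs$sequence[rep(ready, lens)],
                          recs$sequence[unlist(eff_cand)])
      } else NULL
      ok <- if (!is.null(st)) passes(st) else logical(0)
      pos <- 0L
      for (q in seq_along(ready)) {
        i <- ready[q]
        cand <- eff_cand[[q]]
        ok_q <- ok[pos + seq_along(cand)]
        pos <- pos + length(cand)
        if (length(cand) > 0 && any(ok_q)) {
          assignment[i] <- cand[which(ok_q)[1]]
        } else {
          assignment[i] <- i
          is_rep[i] <- TRUE
        }
        pending[i] <- FALSE
      }
    }
  }

  founders <- sort(unique(assignment))
  cluster_no <- match(assignment, founders)
  recs |>
    mutate(
      cluster_id = sprintf("C%05d", cluster_no),
      representative = recs$gene_id[assignment]
    ) |>
    select("cluster_id", "representative", "gene_id", "accession_id",
           "length_aa", "sequence")
}

#' Compare two gene catalogs by joint clustering
#'
#' Runs [greedy_cluster()] on the union of two catalogs with disjoint
#' identifier namespaces and tabulates clusters by composition: singletons,
#' 1:1 cross-catalog pairs, and larger clusters.
#'
#' @param records_a,records_b Tibbles as for [greedy_cluster()].
#' @param ... Passed to [greedy_cluster()].
#' @return List with `clusters` (the joint clustering, plus a `catalog`
#'   column) and `histogram` (tibble `composition`, `n_clusters`).
#' @export
compare_catalogs <- function(records_a, records_b, ...) {
  if (length(intersect(records_a$gene_id, records_b$gene_id)) > 0) {
    abort("catalogs must have disjoint gene_id namespaces")
  }
  combined <- bind_rows(
    mutate(records_a, catalog = "A"),
    mutate(records_b, catalog = "B")
  )
  cl <- greedy_cluster(combined, ...) |>
    left_join(select(combined, "gene_id", "catalog"), by = "gene_id")
  hist <- cl |>
    group_by(.data$cluster_id) |>
    summarise(size = n(), n_a = sum(.data$catalog == "A"),
              n_b = sum(.data$catalog == "B"), .groups = "drop") |>
    mutate(composition = dplyr::case_when(
      .data$size == 1 ~ "singleton",
      .data$size == 2 & .data$n_a == 1 & .data$n_b == 1 ~ "pair_1to1",
      TRUE ~ "larger"
    )) |>
    count(.data$composition, name = "n_clusters")
  list(clusters = cl, histogram = hist)
}
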