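# Co-expression edges, PWM promoter scanning with exact DP p-values, and
# hypergeometric GO enrichment.

#' Pearson co-expression edges from focal genes
#'
#' For every focal gene x non-focal gene pair, the Pearson correlation
#' across conditions and its two-sided p-value from the t transform
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.  An edge is kept
#' iff `r > r_min` and `p < p_max` (strict, matching the published
#' thresholds "greater than 0.9" / "less than 0.01").
#'
#' @param expr Expression tibble (`gene_id` + >= 3 condition columns).
#' @param focal_genes Character vector of focal (source) gene identifiers.
#' @param r_min Correlation floor (default 0.9).
#' @param p_max P-value ceiling (default 0.01).
#' @return Tibble: `source`, `target`, `r`, `p`, `n` (conditions used).
#' @export
pearson_edges <- function(expr, focal_genes, r_min = 0.9, p_max = 0.01) {
  m <- expr_matrix(expr)
  if (ncol(m) < 3) abort("need at least 3 conditions")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("%d zero-variance gene(s) skipped", sum(sds == 0)))
    m <- m[sds > 0, , drop = FALSE]
  }
  focal <- intersect(focal_genes, rownames(m))
  targets <- setdiff(rownames(m), focal_genes)
  if (length(focal) == 0 || length(targets) == 0) {
    return(tibble(source = character(), target = character(),
                  r = numeric(), p = numeric(), n = integer()))
  }
  nc <- ncol(m)
  r <- cor(t(m[focal, , drop = FALSE]), t(m[targets, , drop = FALSE]))
  r[] <- pmin(1, pmax(-1, as.numeric(r)))
  tstat <- r * sqrt((nc - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = nc - 2)
  p[abs(r) == 1] <- 0
  idx <- which(r > r_min & p < p_max, arr.ind = TRUE)
  tibble(
    source = focal[idx[, 1]], target = targets[idx[, 2]],
    r = r[idx], p = p[idx], n = nc
  ) |> arrange(.data$source, .data$target)
}

# Integer log-odds score matrix (granularity in bits) and the exact score
# distribution under the background, by column-wise convolution.
pwm_score_scheme <- function(pwm, background = NULL, granularity = 1e-3) {
  bg <- background %||% pwm$background
  bg <- setNames(as.numeric(bg), NUCS)
  q <- pwm$counts + pwm$pseudocount
  q <- sweep(q, 2, colSums(q), "/")
  bits <- log2(sweep(q, 1, bg, "/"))
  s_int <- round(bits / granularity)
  storage.mode(s_int) <- "integer"
  list(s_int = s_int, granularity = granularity, background = bg)
}

pwm_score_distribution <- function(scheme) {
  s_int <- scheme$s_int
  bg <- scheme$background
  lo <- 0L; hi <- 0L
  v <- 1  # v[i] = P(score == lo + i - 1)
  for (j in seq_len(ncol(s_int))) {
    nlo <- lo + min(s_int[, j]); nhi <- hi + max(s_int[, j])
    nv <- numeric(nhi - nlo + 1L)
    for (b in seq_len(4)) {
      sh <- s_int[b, j]
      pos <- (lo + sh - nlo + 1L):(hi + sh - nlo + 1L)
      nv[pos] <- nv[pos] + v * bg[[b]]
    }
    v <- nv; lo <- nlo; hi <- nhi
  }
  # tail probability P(score >= s) on the integer grid lo..hi
  list(lo = lo, hi = hi, probs = v, tail_p = rev(cumsum(rev(v))))
}

# P(score >= s_int) under the background, from the DP distribution.
pwm_tail_p <- function(dist, s_int) {
  idx <- pmax(s_int, dist$lo) - dist$lo + 1L
  out <- numeric(length(s_int))
  inside <- s_int <= dist$hi
  out[inside] <- dist$tail_p[idx[inside]]
  out
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s) paste(rev(chars(s)), collapse = ""), ""))
}

#' Scan promoters with a position weight matrix
#'
#' Log-odds scoring (pseudocount-regularized frequencies over the
#' background) at every offset on both strands; p-values are exact tail
#' probabilities of the score distribution under the background, computed by
#' dynamic programming over scores discretized at `granularity` bits.
#'
#' @param promoters Named character vector of promoter sequences.
#' @param pwm A [read_pwm()] object.
#' @param p_max Report hits with `p <= p_max` (default 1e-4).
#' @param background Optional length-4 A/C/G/T background; defaults to the
#'   base composition of the scanned promoter set.
#' @param granularity Score discretization in bits (default 1e-3).
#' @return Tibble: `promoter_id`, `offset` (0-based, plus strand
#'   coordinates), `strand`, `score` (bits), `p`.
#' @export
pwm_scan <- function(promoters, pwm, p_max = 1e-4, background = NULL,
                     granularity = 1e-3) {
  w <- pwm$width
  short <- nchar(promoters) < w
  if (any(short)) {
    warn(sprintf("%d promoter(s) shorter than the motif skipped", sum(short)))
    promoters <- promoters[!short]
  }
  if (length(promoters) == 0) {
    return(tibble(promoter_id = character(), offset = integer(),
                  strand = character(), score = numeric(), p = numeric()))
  }
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(promoters, "")), levels = NUCS))
    background <- as.numeric(tab) / sum(tab)
  }
  scheme <- pwm_score_scheme(pwm, background, granularity)
  dist <- pwm_score_distribution(scheme)

  window_scores <- function(seq) {
    codes <- match(chars(seq), NUCS)
    n <- length(codes)
    n_off <- n - w + 1L
    total <- rep(0L, n_off)
    valid <- rep(TRUE, n_off)
    for (j in seq_len(w)) {
      cj <- codes[j:(j + n_off - 1L)]
      valid <- valid & !is.na(cj)
      sj <- scheme$s_int[cbind(cj, j)]
      sj[is.na(sj)] <- 0L
      total <- total + sj
    }
    list(s = total, valid = valid)
  }

  hits <- purrr::imap_dfr(promoters, function(seq, id) {
    n <- nchar(seq)
    fwd <- window_scores(seq)
    rev_ <- window_scores(revcomp(seq))
    per_strand <- function(ws, strand) {
      if (!any(ws$valid)) return(NULL)
      off <- which(ws$valid) - 1L
      s_int <- ws$s[ws$valid]
      p <- pwm_tail_p(dist, s_int)
      keep <- p <= p_max
      if (!any(keep)) return(NULL)
      off <- off[keep]
      if (strand == "-") off <- n - w - off
      tibble(promoter_id = id, offset = off, strand = strand,
             score = s_int[keep] * scheme$granularity, p = p[keep])
    }
    bind_rows(per_strand(fwd, "+"), per_strand(rev_, "-"))
  })
  arrange(hits, .data$promoter_id, .data$offset, .data$strand)
}

#' Hypergeometric term enrichment with BH correction
#'
#' Upper-tail hypergeometric p per term (probability of at least the
#' observed foreground hits) and Benjamini-Hochberg adjustment across the
#' tested terms.
#'
#' @param foreground Character vector of genes (subset of `background`).
#' @param background Character vector of universe genes.
#' @param term_map Tibble `gene_id`, `term`.
#' @return Tibble sorted by `p`: `term`, `k` (foreground hits), `K`
#'   (background hits), `n` (foreground size), `N` (background size), `p`,
#'   `fdr`.
#' @export
enrich <- function(foreground, background, term_map) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(foreground) == 0) abort("empty foreground")
  if (length(setdiff(foreground, background)) > 0) {
    abort("foreground must be a subset of background")
  }
  tm <- term_map |>
    filter(.data$gene_id %in% background) |>
    distinct(.data$gene_id, .data$term)
  N <- length(background)
  n <- length(foreground)
  out <- tm |>
    group_by(.data$term) |>
    summarise(K = n(), k = sum(.data$gene_id %in% foreground),
              .groups = "drop") |>
    mutate(
      n = n, N = N,
      p = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE),
      fdr = p.adjust(.data$p, method = "BH")
    ) |>
    select("term", "k", "K", "n", "N", "p", "fdr") |>
    arrange(.data$p, .data$term)
  out
}

#' Assemble the regulatory network node and edge tables
#'
#' Retains only targets that both pass the correlation filter and carry at
#' least one promoter motif hit, and reports per-cluster counts of retained
#' targets.
#'
#' @param edges Output of [pearson_edges()].
#' @param hits Output of [pwm_scan()] on the target promoters.
#' @param cluster_labels Optional tibble `gene_id`, `cluster` (e.g.
#'   [tidy.fuzzy_cmeans()]) used to annotate nodes and count per cluster.
#' @return List with `edges` (filtered), `nodes` (`gene_id`, `role`,
#'   `cluster`), and `per_cluster` (retained-target counts).
#' @export
assemble_network <- function(edges, hits, cluster_labels = NULL) {
  motif_pos <- unique(hits$promoter_id)
  kept <- filter(edges, .data$target %in% motif_pos)
  nodes <- bind_rows(
    tibble(gene_id = unique(kept$source), role = "focal"),
    tibble(gene_id = unique(kept$target), role = "target")
  )
  per_cluster <- NULL
  if (!is.null(cluster_labels)) {
    nodes <- left_join(nodes, select(cluster_labels, "gene_id", "cluster"),
                       by = "gene_id")
    per_cluster <- nodes |>
      filter(.data$role == "target") |>
      count(.data$cluster, name = "n_targets")
  }
  list(edges = kept, nodes = nodes, per_cluster = per_cluster)
}
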