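# Nei-Gojobori (1986) approximate Ka/Ks for ortholog pairs, with the
# nonparametric core-versus-dispensable contrast.

#' Codon-wise alignment of two coding sequences
#'
#' Aligns the translated proteins (same semiglobal scoring as
#' [pairwise_identity()]), back-translates the alignment to codons and drops
#' every column containing a gap, yielding a gapless equal-length codon
#' pair.  Terminal stop codons are removed before alignment; internal stops
#' are an error.
#'
#' @param cds_a,cds_b Nucleotide strings, lengths divisible by 3.
#' @return A `codon_alignment`: list with `codons_a`, `codons_b` (equal
#'   length character vectors) and `n_codons`.
#' @export
codon_align <- function(cds_a, cds_b) {
  prep <- function(cds) {
    codons <- codon_split(cds)
    if (codons[length(codons)] %in% STOP_CODONS) {
      codons <- codons[-length(codons)]
    }
    if (any(codons %in% STOP_CODONS)) abort("internal stop codon")
    codons
  }
  ca <- prep(cds_a); cb <- prep(cds_b)
  pa <- translate_codons(ca); pb <- translate_codons(cb)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    type = "overlap", substitutionMatrix = SUBMAT_AA,
    gapOpening = 5, gapExtension = 1
  )
  sa <- chars(as.character(Biostrings::pattern(al)))
  sb <- chars(as.character(Biostrings::subject(al)))
  ia <- Biostrings::start(Biostrings::pattern(al)) - 1L
  ib <- Biostrings::start(Biostrings::subject(al)) - 1L
  keep_a <- integer(0); keep_b <- integer(0)
  for (k in seq_along(sa)) {
    ga <- sa[k] == "-"; gb <- sb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
    }
  }
  structure(
    list(codons_a = ca[keep_a], codons_b = cb[keep_b],
         n_codons = length(keep_a)),
    class = "codon_alignment"
  )
}

# Average synonymous/nonsynonymous step counts over all shortest substitution
# pathways between two codons, excluding pathways through stop codons (all
# pathways are used if every one is blocked).  Cached: the codon-pair space
# is small and reused heavily.
.ng86_path_cache <- new.env(parent = emptyenv())

codon_path_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng86_path_cache[[key]]
  if (!is.null(hit)) return(hit)
  pos <- which(chars(c1) != chars(c2))
  d <- length(pos)
  res <- if (d == 0) {
    c(sd = 0, nd = 0)
  } else {
    perms <- if (d == 1) list(pos) else {
      idx <- if (d == 2) list(1:2, 2:1) else {
        list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
             c(3, 1, 2), c(3, 2, 1))
      }
      lapply(idx, function(o) pos[o])
    }
    walk <- function(order) {
      cur <- chars(c1)
      syn <- 0; nsyn <- 0
      for (p in order) {
        nxt <- cur
        nxt[p] <- chars(c2)[p]
        from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
        if (to %in% STOP_CODONS && to != c2) return(NULL)  # blocked pathway
        if (GENETIC_CODE_TAB[[from]] == GENETIC_CODE_TAB[[to]]) {
          syn <- syn + 1
        } else nsyn <- nsyn + 1
        cur <- nxt
      }
      c(sd = syn, nd = nsyn)
    }
    counts <- purrr::compact(lapply(perms, walk))
    if (length(counts) == 0) {
      # every pathway passes through a stop; fall back to all pathways with
      # stop-creating steps counted as nonsynonymous
      counts <- lapply(perms, function(order) {
        cur <- chars(c1); syn <- 0; nsyn <- 0
        for (p in order) {
          nxt <- cur; nxt[p] <- chars(c2)[p]
          from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
          if (!(to %in% STOP_CODONS) && !(from %in% STOP_CODONS) &&
              GENETIC_CODE_TAB[[from]] == GENETIC_CODE_TAB[[to]]) {
            syn <- syn + 1
          } else nsyn <- nsyn + 1
          cur <- nxt
        }
        c(sd = syn, nd = nsyn)
      })
    }
    Reduce(`+`, counts) / length(counts)
  }
  assign(key, res, envir = .ng86_path_cache)
  res
}

jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori (NG86) Ka/Ks for a codon alignment
#'
#' Synonymous site fractions are averaged over the two sequences (changes
#' creating a stop codon count as nonsynonymous, so S + N = 3 x codons);
#' multi-position codon differences are averaged over all shortest
#' substitution pathways that avoid stop codons; the Jukes-Cantor correction
#' is applied to both proportions.  `Ka`, `Ks` or `ratio` are `NA` when the
#' correction is undefined (p >= 3/4) or `Ks = 0`.
#'
#' @param aln A [codon_align()] result, or a length-2 character vector of
#'   equal-length gapless CDS strings.
#' @return One-row tibble: `n_codons`, `S`, `N`, `Sd`, `Nd`, `ps`, `pn`,
#'   `Ka`, `Ks`, `ratio`.
#' @export
ng86 <- function(aln) {
  if (is.character(aln) && length(aln) == 2) {
    ca <- codon_split(aln[1]); cb <- codon_split(aln[2])
    if (length(ca) != length(cb)) abort("sequences differ in codon count")
    drop_stop <- ca %in% STOP_CODONS & cb %in% STOP_CODONS &
      seq_along(ca) == length(ca)
    ca <- ca[!drop_stop]; cb <- cb[!drop_stop]
    aln <- list(codons_a = ca, codons_b = cb, n_codons = length(ca))
  }
  ca <- aln$codons_a; cb <- aln$codons_b
  if (any(ca %in% STOP_CODONS) || any(cb %in% STOP_CODONS)) {
    abort("stop codon inside the alignment")
  }
  n_codons <- length(ca)
  if (n_codons == 0) abort("empty codon alignment")
  S <- (sum(SYN_SITES[ca]) + sum(SYN_SITES[cb])) / 2
  N <- 3 * n_codons - S
  diffs <- vapply(seq_len(n_codons),
                  function(i) codon_path_counts(ca[i], cb[i]),
                  c(sd = 0, nd = 0))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jukes_cantor(ps)
  Ka <- jukes_cantor(pn)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  tibble(n_codons = n_codons, S = S, N = N, Sd = Sd, Nd = Nd,
         ps = ps, pn = pn, Ka = Ka, Ks = Ks, ratio = ratio)
}

#' Ka/Ks per orthogroup
#'
#' Pairs each cluster representative with every other member, estimates
#' NG86 rates per pair, and aggregates to one value per orthogroup.
#'
#' @param clusters Output of [greedy_cluster()].
#' @param cds_catalog Tibble with `gene_id`, `sequence` (CDS).
#' @param aggregate `"mean"` (default), `"median"`, or `"none"` for the
#'   per-pair table.
#' @return Tibble per orthogroup (`ogg_id`, `n_pairs`, `n_na`, `Ka`, `Ks`,
#'   `ratio`) or, with `aggregate = "none"`, one row per pair.
#' @export
orthogroup_kaks <- function(clusters, cds_catalog,
                            aggregate = c("mean", "median", "none")) {
  aggregate <- match.arg(aggregate)
  cds <- setNames(cds_catalog$sequence, cds_catalog$gene_id)
  missing <- setdiff(clusters$gene_id, names(cds))
  if (length(missing)) {
    abort(sprintf("no CDS for gene(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  multi <- clusters |>
    group_by(.data$cluster_id) |>
    filter(n() > 1) |>
    ungroup()
  pairs <- multi |>
    filter(.data$gene_id != .data$representative) |>
    select(ogg_id = "cluster_id", "representative", member = "gene_id")
  if (nrow(pairs) == 0) {
    empty <- tibble(ogg_id = character(), n_pairs = integer(),
                    n_na = integer(), Ka = numeric(), Ks = numeric(),
                    ratio = numeric())
    return(empty)
  }
  per_pair <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    res <- ng86(codon_align(cds[[pairs$representative[i]]],
                            cds[[pairs$member[i]]]))
    bind_cols(pairs[i, ], res)
  })
  if (aggregate == "none") return(per_pair)
  agg <- if (aggregate == "mean") {
    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
  }
  per_pair |>
    group_by(.data$ogg_id) |>
    summarise(
      n_pairs = n(),
      n_na = sum(is.na(.data$ratio)),
      Ka = agg(.data$Ka), Ks = agg(.data$Ks), ratio = agg(.data$ratio),
      .groups = "drop"
    )
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by full enumeration of group assignments when both
#' groups have at most `exact_max` observations; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param exact_max Size ceiling for the exact branch (default 8).
#' @return One-row tibble: `U` (for `x`), `p`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n <= exact_max && m <= exact_max) {
    # enumerate every assignment of n pooled ranks to group x
    r2 <- as.integer(round(2 * r))  # half-ranks -> integers
    u2 <- colSums(matrix(r2[combn(N, n)], nrow = n)) - n * (n + 1L)
    u2_obs <- as.integer(round(2 * U))
    p <- min(1, 2 * min(mean(u2 <= u2_obs), mean(u2 >= u2_obs)))
    return(tibble(U = U, p = p, method = "exact"))
  }
  mu <- n * m / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(tibble(U = U, p = 1, method = "normal"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  tibble(U = U, p = min(1, 2 * pnorm(-max(0, z))), method = "normal")
}

#' Compare Ka, Ks and Ka/Ks between core and dispensable orthogroups
#'
#' Dispensable pools the soft-core, shell and cloud classes.  NA-flagged
#' values (undefined correction or Ks = 0) are excluded per metric, with
#' the exclusion count reported.
#'
#' @param kaks Per-orthogroup table from [orthogroup_kaks()].
#' @param classes Output of [classify_occupancy()].
#' @return Tibble, one row per metric: group sizes, medians, `U`, `p`.
#' @export
kaks_group_compare <- function(kaks, classes) {
  joined <- inner_join(kaks, select(classes, "ogg_id", "label"), by = "ogg_id") |>
    mutate(group = ifelse(.data$label == "core", "core", "dispensable"))
  purrr::map_dfr(c("Ka", "Ks", "ratio"), function(metric) {
    vals <- joined[[metric]]
    ok <- !is.na(vals)
    a <- vals[ok & joined$group == "core"]
    b <- vals[ok & joined$group == "dispensable"]
    if (length(a) == 0 || length(b) == 0) {
      abort(sprintf("%s: a group is empty after NA exclusion", metric))
    }
    mw <- mann_whitney(a, b)
    tibble(metric = metric, n_core = length(a), n_dispensable = length(b),
           n_excluded = sum(!ok),
           median_core = stats::median(a),
           median_dispensable = stats::median(b),
           U = mw$U, p = mw$p)
  })
}
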