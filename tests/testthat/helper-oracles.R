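# Independent reference implementations used as oracles.  Each is written
# as plainly as possible and stays independent of the code path it checks.

# Sequential greedy clustering over precomputed pairwise statistics, coded
# directly from the rules: sort longest-first (gene_id tie-break), join the
# first representative (in founding order) passing all three thresholds.
oracle_greedy_partition <- function(records, min_identity = 0.95,
                                    min_longer_cov = 0.90,
                                    min_aln_len = 100) {
  recs <- records[order(-nchar(records$sequence), records$gene_id), ]
  reps <- integer(0)
  member_of <- integer(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    joined <- 0
    for (r in reps) {
      st <- pairwise_identity(recs$sequence[i], recs$sequence[r])
      if (st$identity >= min_identity &&
          st$longer_coverage >= min_longer_cov &&
          st$aligned_len >= min_aln_len) {
        joined <- r
        break
      }
    }
    if (joined == 0) {
      reps <- c(reps, i)
      joined <- i
    }
    member_of[i] <- joined
  }
  split(recs$gene_id, recs$gene_id[member_of])
}

# canonical form of a partition for comparison
partition_sets <- function(cluster_tbl) {
  unname(lapply(
    split(cluster_tbl$gene_id, cluster_tbl$cluster_id),
    sort
  )) |> (\(x) x[order(vapply(x, `[`, "", 1))])()
}

partition_sets_oracle <- function(lst) {
  unname(lapply(lst, sort)) |> (\(x) x[order(vapply(x, `[`, "", 1))])()
}

# --- NG86 oracle ------------------------------------------------------------

GC_TAB <- Biostrings::GENETIC_CODE
STOPS <- names(GC_TAB)[GC_TAB == "*"]

# synonymous site count of one codon by direct enumeration
oracle_syn_sites <- function(codon) {
  aa <- GC_TAB[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (GC_TAB[[alt]] == aa) s <- s + 1
    }
  }
  s / 3
}

# recursive enumeration of substitution pathways between two codons
oracle_pathways <- function(c1, c2, allow_stops = FALSE) {
  recurse <- function(cur) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(pos) == 0) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stops && nxt %in% STOPS && nxt != c2) next
      step_syn <- !(nxt %in% STOPS) && !(cur %in% STOPS) &&
        GC_TAB[[cur]] == GC_TAB[[nxt]]
      for (rest in recurse(nxt)) {
        out[[length(out) + 1]] <- rest +
          if (step_syn) c(sd = 1, nd = 0) else c(sd = 0, nd = 1)
      }
    }
    out
  }
  recurse(c1)
}

oracle_ng86_counts <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, 0)) +
          sum(vapply(codons_b, oracle_syn_sites, 0))) / 2
  N <- 3 * length(codons_a) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(codons_a)) {
    paths <- oracle_pathways(codons_a[i], codons_b[i])
    if (length(paths) == 0) {
      paths <- oracle_pathways(codons_a[i], codons_b[i], allow_stops = TRUE)
    }
    avg <- Reduce(`+`, paths) / length(paths)
    Sd <- Sd + avg[["sd"]]; Nd <- Nd + avg[["nd"]]
  }
  c(S = S, N = N, Sd = Sd, Nd = Nd)
}

# --- Mann-Whitney oracle ----------------------------------------------------

# Full enumeration over which pooled observations form group A; U computed
# from pairwise comparisons, not ranks.
oracle_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  combos <- combn(length(pooled), n)
  u_all <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# --- PWM p-value oracle -----------------------------------------------------

# Enumerate all 4^w words; integer scores recomputed here with the same
# published discretization rule.
oracle_pwm_tail_p <- function(pwm, background, granularity = 1e-3) {
  nucs <- c("A", "C", "G", "T")
  q <- pwm$counts + pwm$pseudocount
  q <- sweep(q, 2, colSums(q), "/")
  s_int <- round(log2(sweep(q, 1, background, "/")) / granularity)
  words <- do.call(expand.grid, rep(list(1:4), pwm$width))
  word_scores <- as.matrix(words)
  scores <- vapply(seq_len(nrow(words)), function(r) {
    sum(s_int[cbind(word_scores[r, ], seq_len(pwm$width))])
  }, 0)
  probs <- apply(words, 1, function(w) prod(background[w]))
  function(s) sum(probs[scores >= s])
}

# --- misc -------------------------------------------------------------------

oracle_enc <- function(counts) {
  fams <- split(names(GC_TAB)[GC_TAB != "*"], GC_TAB[GC_TAB != "*"])
  fams <- fams[lengths(fams) > 1]
  fbar <- list()
  for (fam in fams) {
    nn <- sum(counts[fam])
    if (nn <= 1) next
    f <- (nn * sum((counts[fam] / nn)^2) - 1) / (nn - 1)
    if (f <= 0) next
    key <- as.character(length(fam))
    fbar[[key]] <- c(fbar[[key]], f)
  }
  m <- vapply(c("2", "3", "4", "6"), function(k) mean(fbar[[k]]), 0)
  if (is.nan(m["3"])) m["3"] <- mean(c(m["2"], m["4"]))
  if (any(is.nan(m))) return(NA_real_)
  min(61, max(20, 2 + 9 / m["2"] + 1 / m["3"] + 5 / m["4"] + 3 / m["6"]))
}

oracle_hypergeom_upper <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
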