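toy_pwm <- function(consensus = c("T", "G", "C", "A", "C")) {
  counts <- matrix(1, 4, length(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 17
  structure(list(motif_id = "toy", width = length(consensus),
                 counts = counts,
                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                 pseudocount = 0.1),
            class = "pwm")
}

test_that("pearson_edges applies both strict thresholds", {
  set.seed(50)
  base <- rnorm(10)
  m <- rbind(
    f1 = base,
    t1 = base + rnorm(10, 0, 1e-3),   # near-perfect correlate
    t2 = rnorm(10),                   # unrelated
    t3 = -base                        # strong negative: excluded (r < 0.9)
  )
  e <- expr_tbl(m, ids = rownames(m))
  edges <- pearson_edges(e, "f1")
  expect_identical(edges$target, "t1")
  expect_gt(edges$r, 0.9)
  expect_lt(edges$p, 0.01)
  # r below threshold is excluded no matter how small p is
  expect_false("t3" %in% edges$target)
  # focal genes are not targets of themselves
  expect_false("f1" %in% edges$target)
  e$gene_id[3] <- "flat"
  e[e$gene_id == "flat", -1] <- as.list(rep(1, 10))
  expect_warning(pearson_edges(e, "f1"), "zero-variance")
})

test_that("edge p-values agree with a permutation estimate", {
  set.seed(51)
  n <- 30
  x <- rnorm(n); y <- 0.6 * x + rnorm(n, 0, 0.8)
  e <- expr_tbl(rbind(f = x, t = y), ids = c("f", "t"))
  edges <- pearson_edges(e, "f", r_min = -1, p_max = 1)
  p_t <- edges$p[edges$target == "t"]
  r_obs <- abs(cor(x, y))
  perm <- replicate(4000, abs(cor(x, sample(y))))
  p_perm <- mean(perm >= r_obs)
  expect_lt(abs(p_t - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.005)
})

test_that("pwm_scan finds planted words on both strands", {
  set.seed(52)
  pwm <- toy_pwm()
  prom <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  substr(prom, 38, 42) <- "TGCAC"   # offset 37, 0-based
  hits <- pwm_scan(setNames(prom, "p1"), pwm, p_max = 1e-2,
                   background = rep(0.25, 4))
  fwd <- hits[hits$strand == "+", ]
  expect_true(37 %in% fwd$offset)
  expect_equal(max(hits$score), fwd$score[fwd$offset == 37])

  # reverse complement planted on the minus strand reports the same score
  prom2 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
  substr(prom2, 101, 105) <- "GTGCA"  # revcomp of TGCAC
  hits2 <- pwm_scan(setNames(prom2, "p2"), pwm, p_max = 1e-2,
                    background = rep(0.25, 4))
  minus <- hits2[hits2$strand == "-", ]
  expect_true(100 %in% minus$offset)
  expect_equal(minus$score[minus$offset == 100], fwd$score[fwd$offset == 37])
})

test_that("scan p-values equal brute-force word enumeration", {
  set.seed(53)
  for (w in 4:6) {
    consensus <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
    pwm <- toy_pwm(consensus)
    bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    oracle_p <- oracle_pwm_tail_p(pwm, bg)
    scheme <- pannac:::pwm_score_scheme(pwm, bg)
    dist <- pannac:::pwm_score_distribution(scheme)
    expect_equal(sum(dist$probs), 1, tolerance = 1e-9)
    # every achievable integer score: DP tail equals enumeration
    some_scores <- unique(round(seq(dist$lo, dist$hi, length.out = 25)))
    for (s in some_scores) {
      expect_equal(pannac:::pwm_tail_p(dist, s), oracle_p(s),
                   tolerance = 1e-9)
    }
    # monotone: higher scores never have larger p
    ps <- pannac:::pwm_tail_p(dist, some_scores)
    expect_true(all(diff(ps[order(some_scores)]) <= 1e-12))
  }
})

test_that("hypergeometric enrichment matches exact computation", {
  term_map <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    term = rep(c("GO:A", "GO:B", "GO:C", "GO:D"), each = 5)
  )
  fg <- sprintf("g%02d", 1:5)  # exactly the GO:A genes
  res <- enrich(fg, sprintf("g%02d", 1:20), term_map)
  expect_equal(res$p[res$term == "GO:A"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(all(res$p >= 0 & res$p <= 1))
  # BH preserves the p ordering
  expect_true(all(diff(res$fdr) >= -1e-12))
  set.seed(54)
  for (i in 1:10) {
    N <- 20; n <- sample(3:8, 1)
    bg <- sprintf("g%02d", 1:N)
    fg2 <- sample(bg, n)
    tm <- tibble::tibble(gene_id = sample(bg, 12), term = "GO:X")
    got <- enrich(fg2, bg, tm)
    k <- sum(fg2 %in% tm$gene_id)
    if (nrow(got) > 0) {
      expect_equal(got$p, oracle_hypergeom_upper(N, 12, n, k),
                   tolerance = 1e-12)
    }
  }
  # identical p-values get identical BH values
  tm2 <- tibble::tibble(gene_id = rep(sprintf("g%02d", 1:4), 2),
                        term = rep(c("GO:E", "GO:F"), each = 4))
  res2 <- enrich(sprintf("g%02d", 1:4), sprintf("g%02d", 1:20), tm2)
  expect_equal(res2$fdr[1], res2$fdr[2])
  expect_error(enrich(character(), sprintf("g%02d", 1:20), term_map),
               "empty foreground")
  expect_error(enrich("zz", sprintf("g%02d", 1:20), term_map), "subset")
})

test_that("assemble_network requires both edge and motif support", {
  edges <- tibble::tibble(
    source = c("f1", "f1", "f2"),
    target = c("t1", "t2", "t3"),
    r = c(0.95, 0.99, 0.97), p = c(1e-3, 1e-4, 1e-3), n = 4L
  )
  hits <- tibble::tibble(promoter_id = c("t1", "t3", "t9"), offset = 0L,
                         strand = "+", score = 5, p = 1e-5)
  labels <- tibble::tibble(gene_id = c("t1", "t2", "t3"),
                           cluster = c(1L, 1L, 2L))
  net <- assemble_network(edges, hits, labels)
  expect_setequal(net$edges$target, c("t1", "t3"))  # t2 lacks a motif hit
  expect_setequal(net$nodes$gene_id[net$nodes$role == "target"],
                  c("t1", "t3"))
  expect_identical(net$per_cluster$n_targets[net$per_cluster$cluster == 1L],
                   1L)
})
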