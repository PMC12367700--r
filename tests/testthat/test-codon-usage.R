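SENSE <- pannac:::SENSE_CODONS
FAMS <- pannac:::SYN_FAMILIES

# counts with one fixed codon per synonymous family, n observations each
one_codon_per_family <- function(n = 50) {
  counts <- setNames(rep(0L, length(SENSE)), SENSE)
  for (fam in FAMS) counts[fam[1]] <- n
  counts
}

uniform_counts <- function(n = 600) {
  counts <- setNames(rep(0L, length(SENSE)), SENSE)
  for (fam in FAMS) counts[fam] <- n / length(fam)
  counts
}

test_that("count_codons applies the stop and ambiguity rules", {
  c1 <- count_codons("ATGAAATAG")
  expect_identical(unname(c1["ATG"]), 1L)
  expect_identical(unname(c1["AAA"]), 1L)
  expect_identical(sum(c1), 2L)
  c2 <- count_codons("ATGNNNAAA")
  expect_identical(sum(c2), 2L)
  expect_identical(attr(c2, "n_skipped"), 1L)
  expect_error(count_codons("ATGTAGAAA"), "internal stop")
  expect_error(count_codons("ATGA"), "multiple of 3")
})

test_that("rscu normalizes within synonymous families", {
  counts <- setNames(rep(0L, length(SENSE)), SENSE)
  counts["GAA"] <- 2L; counts["GAG"] <- 2L
  r <- rscu(counts)
  expect_equal(unname(r["GAA"]), 1)
  expect_equal(unname(r["GAG"]), 1)
  counts["GAA"] <- 3L; counts["GAG"] <- 1L
  r2 <- rscu(counts)
  expect_equal(unname(r2["GAA"]), 1.5)
  expect_equal(unname(r2["GAG"]), 0.5)
  # family sums equal family sizes on random genes
  set.seed(30)
  for (i in 1:10) {
    cds <- random_cds(300, runif(1, 0.2, 0.8))
    r <- rscu(count_codons(cds))
    for (fam in FAMS) {
      if (length(fam) < 2 || !all(fam %in% names(r))) next
      expect_equal(sum(r[fam]), length(fam))
    }
  }
})

test_that("enc spans its theoretical range and matches the formula oracle", {
  expect_equal(enc(one_codon_per_family()), 20)
  expect_equal(enc(uniform_counts(6000)), 61)  # capped at the no-bias limit
  set.seed(31)
  for (i in 1:20) {
    counts <- setNames(rpois(length(SENSE), 6), SENSE)
    expect_equal(enc(counts), oracle_enc(counts), tolerance = 1e-9)
  }
  # concentrating usage lowers ENC
  skewed <- uniform_counts(600)
  for (fam in FAMS) {
    if (length(fam) < 2) next
    tot <- sum(skewed[fam])
    skewed[fam] <- 0L
    skewed[fam[1]] <- tot
  }
  expect_lt(enc(skewed), enc(uniform_counts(600)))
})

test_that("enc_expected reproduces Wright's closed forms", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
})

test_that("cai rewards reference-preferred codons and is scale invariant", {
  ref <- setNames(rep(0L, length(SENSE)), SENSE)
  for (fam in FAMS) {
    ref[fam[1]] <- 90L
    if (length(fam) > 1) ref[fam[-1]] <- 10L
  }
  gene_pref <- one_codon_per_family(10)  # only preferred codons
  expect_equal(cai(gene_pref, ref), 1.0)
  set.seed(32)
  g <- count_codons(random_cds(200, 0.5))
  v <- cai(g, ref)
  expect_gt(v, 0); expect_lte(v, 1)
  expect_equal(cai(g, ref * 7L), v)  # scale invariance
  # hand computation on a two-family toy
  ref2 <- setNames(rep(0L, length(SENSE)), SENSE)
  ref2["GAA"] <- 9L; ref2["GAG"] <- 1L    # Glu: w(GAG) = 1/9
  ref2["AAA"] <- 5L; ref2["AAG"] <- 5L    # Lys: w both 1
  gene <- setNames(rep(0L, length(SENSE)), SENSE)
  gene["GAA"] <- 2L; gene["GAG"] <- 1L; gene["AAA"] <- 3L
  expect_equal(cai(gene, ref2), exp(log(1 / 9) / 6), tolerance = 1e-9)
})

test_that("third-position composition and PR2 coordinates tally by hand", {
  counts <- setNames(rep(0L, length(SENSE)), SENSE)
  counts["GGA"] <- 2L  # A3
  counts["GGT"] <- 2L  # T3
  counts["GGG"] <- 1L  # G3
  counts["GGC"] <- 3L  # C3
  counts["ATG"] <- 5L  # excluded (Met)
  comp <- third_position_composition(counts)
  expect_equal(comp$A3s, 2 / 8); expect_equal(comp$T3s, 2 / 8)
  expect_equal(comp$G3s, 1 / 8); expect_equal(comp$C3s, 3 / 8)
  expect_equal(comp$GC3s, 4 / 8)
  expect_equal(comp$pr2_y, 0.5)          # A3 = T3
  expect_equal(comp$pr2_x, 1 / 4)
  all_gc <- setNames(rep(0L, length(SENSE)), SENSE)
  all_gc["GGG"] <- 2L; all_gc["GGC"] <- 2L
  expect_equal(third_position_composition(all_gc)$GC3s, 1)
})

test_that("optimal codons are exactly the planted preferred set", {
  set.seed(33)
  preferred <- vapply(FAMS[lengths(FAMS) > 1], `[`, "", 1)
  # p_pref: probability of drawing the planted preferred codon, as a
  # function of family size
  # 1000-codon genes: long enough that realized per-gene usage sits close
  # to its expectation, so the ENC tails separate the two planted tiers
  biased_gene <- function(p_pref) {
    codons <- unlist(lapply(sample(names(FAMS), 1000, replace = TRUE),
                            function(aa) {
      fam <- FAMS[[aa]]
      if (length(fam) == 1) return(fam)
      if (runif(1) < p_pref(length(fam))) fam[1] else sample(fam[-1], 1)
    }))
    paste(c("ATG", codons, "TAA"), collapse = "")
  }
  strong <- function(k) 0.9         # RSCU_high = 0.9 k > 1
  weak <- function(k) 0.4 / k       # RSCU_low approx 0.4, stays below 1
  catalog <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:60),
    sequence = c(vapply(1:30, function(i) biased_gene(strong), ""),
                 vapply(1:30, function(i) biased_gene(weak), ""))
  )
  profiles <- codon_usage_profile(catalog)
  opt <- optimal_codons(profiles, catalog, tail = 0.10)
  flagged <- opt$codon[opt$is_optimal]
  expect_setequal(flagged, unname(preferred))
  # published decision rule on explicit RSCU values
  expect_true(all(opt$rscu_high[opt$is_optimal] > 1))
  expect_true(all(opt$rscu_low[opt$is_optimal] < 1))
  expect_true(all(opt$delta_rscu[opt$is_optimal] >= 0.3))
  expect_error(optimal_codons(profiles[1:5, ], catalog), "at least 10")
})

test_that("profile table is invariant to gene order", {
  set.seed(34)
  catalog <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:12),
    sequence = vapply(1:12, function(i) random_cds(250, runif(1, 0.3, 0.7)), "")
  )
  p1 <- codon_usage_profile(catalog)
  p2 <- codon_usage_profile(catalog[sample(12), ])
  expect_equal(dplyr::arrange(p1, gene_id), dplyr::arrange(p2, gene_id))
})
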