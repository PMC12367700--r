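random_codons <- function(n) {
  sense <- pannac:::SENSE_CODONS
  sample(sense, n, replace = TRUE)
}

test_that("ng86 handles degenerate pairs as defined", {
  set.seed(20)
  cds <- paste(c("ATG", random_codons(50), "TAA"), collapse = "")
  res <- ng86(codon_align(cds, cds))
  expect_equal(res$Ka, 0)
  expect_equal(res$Ks, 0)
  expect_true(is.na(res$ratio))
  expect_equal(res$S + res$N, 3 * res$n_codons)

  # a pair differing only nonsynonymously: Ks = 0, Ka > 0, ratio undefined
  a <- c("ATG", "AAA", "GGG", "TTT", "TAA")  # K G F
  b <- c("ATG", "AGA", "GGG", "TTT", "TAA")  # K->R nonsynonymous
  res2 <- ng86(c(paste(a, collapse = ""), paste(b, collapse = "")))
  expect_equal(res2$Sd, 0)
  expect_equal(res2$Ks, 0)
  expect_gt(res2$Ka, 0)
  expect_true(is.na(res2$ratio))
})

test_that("synonymous site counts match canonical codons", {
  expect_equal(unname(pannac:::SYN_SITES["ATG"]), 0)      # Met: none
  expect_equal(unname(pannac:::SYN_SITES["TGG"]), 0)      # Trp: none
  expect_equal(unname(pannac:::SYN_SITES["GGG"]), 1)      # 4-fold third position
  # poly-GGG pair: total S = one synonymous site per codon
  cds <- paste(c("ATG", rep("GGG", 30), "TAA"), collapse = "")
  res <- ng86(codon_align(cds, cds))
  expect_equal(res$S, 30 + pannac:::SYN_SITES[["ATG"]])
})

test_that("ng86 is symmetric and zero under synonymous-only divergence", {
  set.seed(21)
  for (i in 1:5) {
    ca <- random_codons(40)
    cb <- random_codons(40)
    r1 <- ng86(list(codons_a = ca, codons_b = cb, n_codons = 40))
    r2 <- ng86(list(codons_a = cb, codons_b = ca, n_codons = 40))
    expect_equal(r1$S, r2$S); expect_equal(r1$Sd, r2$Sd)
    expect_equal(r1$N, r2$N); expect_equal(r1$Nd, r2$Nd)
  }
  # synonymous-only mutation: Ka exactly 0
  one_step_syn <- function(cd) {
    alts <- pannac:::SYN_ALTS[[cd]]
    if (length(alts) > 0) {
      alts <- alts[vapply(alts, function(a) {
        sum(strsplit(a, "")[[1]] != strsplit(cd, "")[[1]]) == 1
      }, logical(1))]
    }
    if (length(alts) == 0 || runif(1) < 0.5) cd else sample(alts, 1)
  }
  ca <- random_codons(60)
  cb <- vapply(ca, one_step_syn, "")
  res <- ng86(list(codons_a = ca, codons_b = unname(cb), n_codons = 60))
  expect_equal(res$Nd, 0)
  expect_equal(res$Ka, 0)
})

test_that("ng86 site and difference counts equal the pathway oracle", {
  set.seed(22)
  for (i in 1:20) {
    ca <- random_codons(30)
    cb <- random_codons(30)
    res <- ng86(list(codons_a = ca, codons_b = cb, n_codons = 30))
    want <- oracle_ng86_counts(ca, cb)
    expect_equal(res$S, unname(want["S"]), tolerance = 1e-12)
    expect_equal(res$N, unname(want["N"]), tolerance = 1e-12)
    expect_equal(res$Sd, unname(want["Sd"]), tolerance = 1e-12)
    expect_equal(res$Nd, unname(want["Nd"]), tolerance = 1e-12)
  }
})

test_that("codon_align drops gap columns and terminal stops", {
  set.seed(23)
  codons <- random_codons(60)
  cds_a <- paste(c("ATG", codons, "TAA"), collapse = "")
  cds_b <- paste(c("ATG", codons[1:55], "TGA"), collapse = "")  # truncated
  aln <- codon_align(cds_a, cds_b)
  expect_identical(aln$n_codons, 56L)
  expect_identical(aln$codons_a, aln$codons_b)
  expect_error(codon_align(paste(c("ATG", "TAA", "AAA"), collapse = ""),
                           cds_a), "internal stop")
})

test_that("mann_whitney exact branch equals enumeration", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_equal(mann_whitney(c(2, 2, 3), c(2, 2, 3))$p, 1)
  set.seed(24)
  for (i in 1:20) {
    x <- sample(1:8, sample(2:6, 1), replace = TRUE)
    y <- sample(1:8, sample(2:6, 1), replace = TRUE)
    expect_equal(mann_whitney(x, y)$p, oracle_mann_whitney_p(x, y))
  }
  # tie-free exact p agrees with the standard exact test
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(mann_whitney(x, y)$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("normal approximation is close to exact at the branch point", {
  set.seed(25)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    p_exact <- mann_whitney(x, y)$p
    p_approx <- mann_whitney(x, y, exact_max = 4)$p
    expect_identical(mann_whitney(x, y, exact_max = 4)$method, "normal")
    # continuity-corrected normal tail; worst observed deviation at n = 8
    # is just above 0.01, so bound at 0.02
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("core-versus-dispensable contrast detects planted differences", {
  set.seed(26)
  classes <- tibble::tibble(
    ogg_id = sprintf("C%03d", 1:40),
    occupancy = c(rep(20L, 20), rep(10L, 20)),
    label = factor(rep(c("core", "shell"), each = 20),
                   levels = c("core", "softcore", "shell", "cloud"))
  )
  kaks <- tibble::tibble(
    ogg_id = classes$ogg_id,
    Ka = c(rnorm(20, 0.01, 0.002), rnorm(20, 0.05, 0.01)),
    Ks = c(rnorm(20, 0.05, 0.01), rnorm(20, 0.15, 0.02)),
    ratio = c(rnorm(20, 0.2, 0.05), rnorm(20, 0.4, 0.05))
  )
  out <- kaks_group_compare(kaks, classes)
  expect_identical(out$metric, c("Ka", "Ks", "ratio"))
  expect_true(all(out$p < 0.05))
  expect_true(all(out$median_core < out$median_dispensable))

  # NA-flagged ratios are excluded and reported
  kaks$ratio[1:3] <- NA
  out2 <- kaks_group_compare(kaks, classes)
  expect_identical(out2$n_excluded[out2$metric == "ratio"], 3L)
  expect_identical(out2$n_core[out2$metric == "ratio"], 17L)

  # a group with no defined values errors
  kaks$ratio[classes$label == "core"] <- NA
  expect_error(kaks_group_compare(kaks, classes), "empty")
})

test_that("type-I error is controlled under the null", {
  set.seed(27)
  classes <- tibble::tibble(
    ogg_id = sprintf("C%03d", 1:30),
    label = factor(rep(c("core", "shell"), each = 15),
                   levels = c("core", "softcore", "shell", "cloud"))
  )
  ps <- replicate(200, {
    kaks <- tibble::tibble(ogg_id = classes$ogg_id, Ka = rnorm(30),
                           Ks = rnorm(30), ratio = rnorm(30))
    kaks_group_compare(kaks, classes)$p[1]
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("orthogroup_kaks pairs representatives with members", {
  b <- small_bundle()
  cl <- greedy_cluster(b$proteins)
  kk <- orthogroup_kaks(cl, b$cds)
  expect_true(all(kk$n_pairs >= 1))
  expect_true(all(kk$Ka >= 0, na.rm = TRUE))
  expect_true(all(kk$Ks >= 0, na.rm = TRUE))
  per_pair <- orthogroup_kaks(cl, b$cds, aggregate = "none")
  expect_identical(sum(kk$n_pairs), nrow(per_pair))
})
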