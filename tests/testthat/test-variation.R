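gene <- function(start, end, strand = "+", chrom = "chr1H",
                 gene_id = "g1") {
  tibble::tibble(gene_id = gene_id, chrom = chrom, start = start, end = end,
                 strand = strand)
}
te <- function(start, end, chrom = "chr1H", code = "DTC") {
  tibble::tibble(chrom = chrom, start = start, end = end, strand = "+",
                 code = code)
}

test_that("TE position labels are strand-aware with genic priority", {
  g <- gene(1000, 2000, "+")
  expect_identical(classify_te_position(te(500, 800), g), "upstream")
  expect_identical(classify_te_position(te(500, 800), gene(1000, 2000, "-")),
                   "downstream")
  expect_identical(classify_te_position(te(900, 1100), g), "genic")
  expect_identical(classify_te_position(te(2100, 2300), g), "downstream")
  expect_identical(classify_te_position(te(5000, 5100), g), "none")
  # strand-naive mode keeps the left flank upstream
  expect_identical(
    classify_te_position(te(500, 800), gene(1000, 2000, "-"),
                         strand_aware = FALSE), "upstream")
  # half-open: touching the gene start from the left is not genic
  expect_identical(classify_te_position(te(800, 1000), g), "upstream")
  expect_error(classify_te_position(te(1, 2), g, window_bp = -1),
               "nonnegative")
})

test_that("labels are exhaustive and mirror under strand flip", {
  set.seed(10)
  for (i in 1:200) {
    s <- sample(0:6000, 1)
    t1 <- te(s, s + sample(50:500, 1))
    gp <- gene(2000, 3000, "+")
    gm <- gene(2000, 3000, "-")
    lp <- classify_te_position(t1, gp)
    lm <- classify_te_position(t1, gm)
    expect_true(lp %in% c("upstream", "genic", "downstream", "none"))
    mirrored <- c(upstream = "downstream", downstream = "upstream",
                  genic = "genic", none = "none")
    expect_identical(lm, unname(mirrored[lp]))
  }
})

test_that("tally_te_classes maps codes to orders and superfamilies", {
  asg <- tibble::tibble(
    position = c("upstream", "genic", "downstream", "none"),
    code = c("DTC", "DTC", "RLC", "XX")
  )
  tl <- tally_te_classes(asg)
  expect_identical(sum(tl$by_position$n), 3L)  # the 'none' row is unassigned
  expect_equal(sum(tl$by_position$fraction), 1)
  codes <- tl$by_code
  expect_identical(codes$order[codes$code == "RLC"], "retrotransposon")
  expect_identical(codes$superfamily[codes$code == "RLC"], "LC")
  expect_identical(codes$order[codes$code == "DTC"], "DNA transposon")
  expect_identical(codes$order[codes$code == "unknown"], "unknown")
  expect_identical(sum(codes$n), 4L)
})

test_that("pav_gene_overlap uses half-open arithmetic", {
  genes <- gene(1000, 2000)
  pavs <- tibble::tibble(
    accession_id = c("B", "B", "C"), chrom = "chr1H",
    start = c(0L, 2000L, 1500L), end = c(5000L, 3000L, 1600L),
    state = c("deletion", "deletion", "insertion")
  )
  ov <- pav_gene_overlap(pavs, genes)
  expect_identical(nrow(ov), 2L)  # the touching interval makes no row
  expect_equal(ov$overlap_bp[ov$accession_id == "B"], 1000)
  expect_equal(ov$overlap_bp[ov$accession_id == "C"], 100)
})

test_that("duplication typing follows rank distance with label priority", {
  genes <- dplyr::bind_rows(lapply(1:12, function(i) {
    gene(i * 10000, i * 10000 + 1000, gene_id = sprintf("g%02d", i))
  }))
  genes$chrom[11:12] <- "chr2H"
  pairs <- tibble::tibble(
    gene_a = c("g01", "g03", "g05"),
    gene_b = c("g02", "g09", "g11")
  )
  labs <- classify_duplication(genes, pairs)
  lab_of <- function(g) as.character(labs$label[labs$gene_id == g])
  expect_identical(lab_of("g01"), "tandem")     # adjacent ranks
  expect_identical(lab_of("g02"), "tandem")
  expect_identical(lab_of("g03"), "proximal")   # 5 intervening genes
  expect_identical(lab_of("g05"), "dispersed")  # cross-chromosome
  expect_identical(lab_of("g11"), "dispersed")
  expect_identical(lab_of("g04"), "singleton")
  expect_error(
    classify_duplication(genes, tibble::tibble(gene_a = "zz", gene_b = "g01")),
    "unknown gene")
  # invariance under order-preserving renumbering of coordinates
  genes2 <- genes
  genes2$start <- rank(genes2$start) * 7L
  genes2$end <- genes2$start + 1L
  expect_identical(classify_duplication(genes2, pairs), labs)
})

test_that("a gene with both tandem and distant homologs is tandem", {
  genes <- dplyr::bind_rows(lapply(1:10, function(i) {
    gene(i * 1000, i * 1000 + 100, gene_id = sprintf("g%02d", i))
  }))
  pairs <- tibble::tibble(gene_a = c("g05", "g05"), gene_b = c("g06", "g10"))
  labs <- classify_duplication(genes, pairs)
  expect_identical(as.character(labs$label[labs$gene_id == "g05"]), "tandem")
})
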