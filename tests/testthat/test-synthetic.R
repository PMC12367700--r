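test_that("identical config and seed give byte-identical bundles", {
  cfg <- synthetic_config(
    n_accessions = 4, n_core = 4, n_softcore = 0, n_shell = 2, n_cloud = 2,
    mean_cds_len_codons = 120, n_te_per_accession = 8,
    n_background_genes = 10, n_regulated_targets = 3, seed = 99
  )
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_pangenome(cfg, d1)
  generate_pangenome(cfg, d2)
  m1 <- dir_md5(d1); m2 <- dir_md5(d2)
  expect_identical(names(m1), names(m2))
  expect_identical(unname(m1), unname(m2))

  cfg2 <- synthetic_config(
    n_accessions = 4, n_core = 4, n_softcore = 0, n_shell = 2, n_cloud = 2,
    mean_cds_len_codons = 120, n_te_per_accession = 8,
    n_background_genes = 10, n_regulated_targets = 3, seed = 100
  )
  d3 <- withr::local_tempdir()
  generate_pangenome(cfg2, d3)
  expect_false(identical(unname(dir_md5(d3)), unname(m1)))
})

test_that("configuration validation rejects impossible class requests", {
  expect_error(synthetic_config(n_accessions = 5, n_softcore = 2),
               "soft-core")
  expect_error(synthetic_config(within_group_identity = 0.9), "within")
  expect_error(synthetic_config(between_group_identity = 0.6), "between")
  expect_error(synthetic_config(gc3_range = c(0.9, 0.2)), "gc3_range")
})

test_that("mutate_protein realizes its identity target", {
  set.seed(1)
  seq <- random_protein(200)
  expect_identical(mutate_protein(seq, 1.0, 5), seq)
  mut <- mutate_protein(seq, 0.97, 5)
  n_same <- sum(strsplit(seq, "")[[1]] == strsplit(mut, "")[[1]])
  expect_true(abs(n_same - 194) <= 4)
  scrambled <- mutate_protein(seq, 0.0, 5)
  id0 <- mean(strsplit(seq, "")[[1]] == strsplit(scrambled, "")[[1]])
  expect_lte(id0, 0.1)
  expect_error(mutate_protein("", 0.5, 1), "non-empty")
  # realized identity within 0.02 of target across targets and lengths
  for (target in c(0.5, 0.8, 0.97)) {
    s <- random_protein(150)
    m <- mutate_protein(s, target, 7)
    realized <- mean(strsplit(s, "")[[1]] == strsplit(m, "")[[1]])
    expect_lte(abs(realized - target), 0.02)
  }
})

test_that("generate_cds_with_bias controls structure and GC3", {
  cds <- generate_cds_with_bias(200, 1.0, 3)
  expect_identical(nchar(cds) %% 3L, 0L)
  expect_identical(substr(cds, 1, 3), "ATG")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
  counts <- count_codons(cds)
  expect_identical(sum(counts) + 1L, 200L)  # stop excluded from the counts
  comp <- third_position_composition(counts)
  expect_equal(comp$GC3s, 1.0)

  cds2 <- generate_cds_with_bias(1000, 0.5, 11)
  gc3 <- third_position_composition(count_codons(cds2))$GC3s
  expect_gte(gc3, 0.47); expect_lte(gc3, 0.53)
  expect_error(generate_cds_with_bias(1, 0.5, 1), "n_codons")
})

test_that("generate_timecourse_expression plants recoverable structure", {
  tc <- generate_timecourse_expression(40, 4, noise_sd = 0, seed = 5)
  expect_identical(nrow(tc$expr), 40L)
  m <- as.matrix(tc$expr[, -1])
  for (cl in 1:4) {
    rows <- m[tc$labels$cluster == cl, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(x) diff(range(x)) == 0)))
  }
  expect_error(generate_timecourse_expression(3, 4, 0.1, 1), "at least")
})

test_that("plant_motifs places recoverable consensus sites", {
  set.seed(2)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("A", c(1, 17, 1, 1, 1)), collapse = "\t"),
               paste(c("C", c(1, 1, 17, 1, 1)), collapse = "\t"),
               paste(c("G", c(17, 1, 1, 17, 1)), collapse = "\t"),
               paste(c("T", c(1, 1, 1, 1, 17)), collapse = "\t")), tf)
  pwm <- read_pwm(tf)
  proms <- setNames(replicate(6, paste(sample(c("A", "C", "G", "T"), 300,
                                              replace = TRUE),
                                       collapse = "")),
                    paste0("P", 1:6))
  unchanged <- plant_motifs(proms, pwm, 0, seed = 1)
  expect_identical(unchanged$promoters, proms)
  planted <- plant_motifs(proms, pwm, 6, seed = 1)
  expect_identical(nrow(planted$sites), 6L)
  hits <- pwm_scan(planted$promoters, pwm, p_max = 1e-2,
                   background = rep(0.25, 4))
  found <- dplyr::inner_join(planted$sites, hits,
                             by = c("promoter_id", "offset"))
  expect_identical(nrow(found), 6L)
  expect_error(plant_motifs(proms, pwm, 1e6, seed = 1), "capacity")
})

test_that("bundle truth is internally consistent", {
  b <- small_bundle()
  tr <- b$truth
  # every gene appears in exactly one orthogroup record
  expect_identical(anyDuplicated(tr$genes$gene_id), 0L)
  expect_setequal(tr$genes$gene_id, b$proteins$gene_id)
  # planted occupancy equals the presence pattern of the generated members
  occ_from_genes <- tr$genes |>
    dplyr::distinct(ogg_id, accession_id) |>
    dplyr::count(ogg_id)
  joined <- dplyr::inner_join(tr$orthogroups, occ_from_genes, by = "ogg_id")
  expect_identical(joined$occupancy, joined$n)
  # cloud orthogroups are carried by at most 10% of the accessions
  cloud <- dplyr::filter(tr$orthogroups, class == "cloud")
  expect_identical(nrow(cloud), 5L)
  expect_true(all(cloud$occupancy <= 1))
  # generated files round-trip through the package readers
  reread <- read_fasta_catalog(
    file.path(b$dir, sprintf("proteins_%s.fa", b$accessions)), "AA")
  expect_identical(
    dplyr::arrange(reread, gene_id)$sequence,
    dplyr::arrange(b$proteins, gene_id)$sequence
  )
  te1 <- read_te_table(file.path(b$dir, sprintf("te_%s.tsv", b$accessions[1])))
  expect_identical(nrow(te1), 25L)
})
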