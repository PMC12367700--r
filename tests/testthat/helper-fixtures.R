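# Shared fixture builders: everything generated in code, seeded per test.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

random_cds <- function(n_codons, gc3 = 0.5, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  generate_cds_with_bias(n_codons, gc3, seed)
}

# A clustering instance with planted groups: each group is a founder protein
# plus copies mutated to varying identities (some above, some below the
# clustering threshold) and slightly truncated.
random_cluster_instance <- function(n_groups, copies_per_group,
                                    len_range = c(90, 200)) {
  recs <- list()
  gid <- 0
  for (g in seq_len(n_groups)) {
    len <- sample(len_range[1]:len_range[2], 1)
    founder <- random_protein(len)
    k <- sample(copies_per_group, 1)
    for (c in seq_len(k)) {
      gid <- gid + 1
      seq <- if (c == 1) founder else {
        target <- sample(c(0.92, 0.95, 0.97, 0.99), 1)
        mut <- mutate_protein(founder, target, seed = sample.int(1e6, 1))
        substr(mut, 1, nchar(mut) - sample(0:3, 1))
      }
      recs[[gid]] <- tibble::tibble(
        gene_id = sprintf("G%03d", gid),
        accession_id = sprintf("ACC%d", sample(1:4, 1)),
        sequence = seq
      )
    }
  }
  dplyr::bind_rows(recs)
}

# Small synthetic bundle shared by several test files (cached per session).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(
        n_accessions = 5, n_core = 10, n_softcore = 0, n_shell = 5,
        n_cloud = 5, mean_cds_len_codons = 130, n_te_per_accession = 25,
        n_background_genes = 40, n_regulated_targets = 8, seed = 424242
      )
      cache <<- generate_pangenome(cfg)
    }
    cache
  }
})

dir_md5 <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  md5 <- tools::md5sum(files)
  names(md5) <- sub(paste0("^", dir), "", files)
  md5
}

expr_tbl <- function(m, ids = sprintf("g%02d", seq_len(nrow(m)))) {
  colnames(m) <- sprintf("c%d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = ids),
                   tibble::as_tibble(as.data.frame(m)))
}
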