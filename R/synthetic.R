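# Synthetic pan-genome generator.  Every downstream stage of the pipeline is
# exercised against bundles produced here, with the planted ground truth
# recorded so recovery can be asserted exactly.

#' Configuration for the synthetic pan-genome generator
#'
#' Defaults emulate the study conditions of a 20-accession barley-like
#' pan-genome survey of a transcription-factor family: ~60 orthogroups split
#' across the four occupancy classes, proteins of a few hundred residues,
#' high within-orthogroup identity, a GC3 gradient across genes, TEs placed
#' around gene loci, and a 4-point salt-stress-like expression time course
#' with planted temporal clusters.
#'
#' @param n_accessions Number of accessions (default 20).
#' @param n_core,n_softcore,n_shell,n_cloud Planted orthogroup counts per
#'   occupancy class (defaults 30/10/10/10).
#' @param mean_cds_len_codons Mean CDS length in codons including start and
#'   stop (default 300; generated proteins are >= 110 aa so every
#'   within-orthogroup alignment clears the 100-aa clustering floor).
#' @param within_group_identity Protein identity of a derived member to its
#'   orthogroup founder, in (0.95, 1] (default 0.97).
#' @param between_group_identity Planted identity between orthogroup
#'   ancestors, in [0, 0.5] (default 0.25).
#' @param gc3_range Range the per-orthogroup GC3 target is drawn from
#'   (default c(0.35, 0.85)).
#' @param n_te_per_accession TEs planted per accession (default 60).
#' @param te_window_bp Flank window used when planting upstream/downstream
#'   TEs (default 2000).
#' @param n_timepoints Time points in the stress time course (default 4).
#' @param n_planted_expression_clusters Temporal clusters planted in the
#'   time course (default 10).
#' @param n_background_genes Non-family genes added to the time course and
#'   promoter set (default 150).
#' @param n_regulated_targets Background genes planted as regulatory targets:
#'   tightly correlated with a family gene and carrying a promoter motif site
#'   (default 30).
#' @param promoter_len_bp Promoter length (default 1000).
#' @param cnv_dup_prob Probability that a carrier accession holds a second
#'   copy of an orthogroup (default 0.08).
#' @param expression_noise_sd SD of log2-scale noise around planted cluster
#'   prototypes (default 0.25).
#' @param seed Integer seed; same config and seed give a byte-identical
#'   bundle.
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_accessions = 20,
                             n_core = 30, n_softcore = 10,
                             n_shell = 10, n_cloud = 10,
                             mean_cds_len_codons = 300,
                             within_group_identity = 0.97,
                             between_group_identity = 0.25,
                             gc3_range = c(0.35, 0.85),
                             n_te_per_accession = 60,
                             te_window_bp = 2000,
                             n_timepoints = 4,
                             n_planted_expression_clusters = 10,
                             n_background_genes = 150,
                             n_regulated_targets = 30,
                             promoter_len_bp = 1000,
                             cnv_dup_prob = 0.08,
                             expression_noise_sd = 0.25,
                             seed = 1) {
  assert_count(n_accessions, "n_accessions", min = 1)
  for (nm in c("n_core", "n_softcore", "n_shell", "n_cloud",
               "n_te_per_accession", "n_timepoints",
               "n_planted_expression_clusters", "n_background_genes",
               "n_regulated_targets")) {
    assert_count(get(nm), nm)
  }
  assert_count(mean_cds_len_codons, "mean_cds_len_codons", min = 115)
  assert_fraction(within_group_identity, "within_group_identity", 0.95, 1)
  assert_fraction(between_group_identity, "between_group_identity", 0, 0.5)
  if (between_group_identity >= within_group_identity) {
    abort("between_group_identity must be below within_group_identity")
  }
  if (length(gc3_range) != 2 || any(gc3_range < 0) || any(gc3_range > 1) ||
      gc3_range[1] > gc3_range[2]) {
    abort("gc3_range must be an ascending pair within [0, 1]")
  }
  bands <- occupancy_bands(n_accessions)
  if (n_softcore > 0 && length(bands$softcore) == 0) {
    abort(sprintf(
      "soft-core orthogroups are impossible with n_accessions = %d", n_accessions))
  }
  if (n_shell > 0 && length(bands$shell) == 0) {
    abort(sprintf(
      "shell orthogroups are impossible with n_accessions = %d", n_accessions))
  }
  if (n_core + n_softcore + n_shell + n_cloud == 0) {
    abort("at least one orthogroup must be requested")
  }
  structure(as.list(environment())[c(
    "n_accessions", "n_core", "n_softcore", "n_shell", "n_cloud",
    "mean_cds_len_codons", "within_group_identity", "between_group_identity",
    "gc3_range", "n_te_per_accession", "te_window_bp", "n_timepoints",
    "n_planted_expression_clusters", "n_background_genes",
    "n_regulated_targets", "promoter_len_bp", "cnv_dup_prob",
    "expression_noise_sd", "seed"
  )], class = "synthetic_config")
}

#' Mutate a protein sequence to a target identity
#'
#' Substitutes an exact count `round((1 - target_identity) * nchar(seq))` of
#' positions (chosen uniformly without replacement) with a uniformly drawn
#' different residue, so the realized identity equals the target up to
#' rounding.
#'
#' @param seq Amino-acid string (standard 20 residues).
#' @param target_identity Fraction in [0, 1].
#' @param seed Integer seed.
#' @return The mutated amino-acid string.
#' @export
mutate_protein <- function(seq, target_identity, seed) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    abort("`seq` must be a non-empty amino-acid string")
  }
  assert_fraction(target_identity, "target_identity")
  n <- nchar(seq)
  k <- round((1 - target_identity) * n)
  if (k == 0) return(seq)
  with_seed(seed, {
    pos <- sample.int(n, k)
    res <- chars(seq)
    res[pos] <- vapply(res[pos], function(a) sample(setdiff(AA20, a), 1), "")
    paste(res, collapse = "")
  })
}

#' Generate a CDS with a controlled GC3 bias
#'
#' Builds `n_codons` codons (ATG start, random stop, no internal stop).
#' Among the synonymously variable internal codons, an exact count
#' `round(gc3 * m)` receives a G/C-ending codon, so the realized GC3s equals
#' the request up to rounding.
#'
#' @param n_codons Total codons including start and stop (>= 2).
#' @param gc3 Target GC3s fraction in [0, 1].
#' @param seed Integer seed.
#' @return A nucleotide string of length `3 * n_codons`.
#' @export
generate_cds_with_bias <- function(n_codons, gc3, seed) {
  assert_count(n_codons, "n_codons", min = 2)
  assert_fraction(gc3, "gc3")
  with_seed(seed, {
    n_internal <- n_codons - 2L
    aas <- if (n_internal > 0) sample(names(SYN_FAMILIES), n_internal, replace = TRUE)
           else character()
    variable <- which(lengths(SYN_FAMILIES[aas]) > 1L)
    m <- length(variable)
    gc_pos <- if (m > 0) variable[sample.int(m, round(gc3 * m))] else integer()
    is_gc <- logical(n_internal)
    is_gc[gc_pos] <- TRUE
    codons <- character(n_internal)
    # sample codons group-wise: one draw batch per (amino acid, GC flag)
    for (grp in split(seq_len(n_internal), paste0(aas, is_gc))) {
      fam <- SYN_FAMILIES[[aas[grp[1]]]]
      if (length(fam) == 1L) {
        codons[grp] <- fam
        next
      }
      third <- substr(fam, 3, 3)
      opts <- fam[if (is_gc[grp[1]]) third %in% c("G", "C")
                  else third %in% c("A", "T")]
      codons[grp] <- opts[sample.int(length(opts), length(grp), replace = TRUE)]
    }
    paste(c("ATG", codons, sample(STOP_CODONS, 1)), collapse = "")
  })
}

#' Generate a planted-cluster expression time course
#'
#' Each cluster has a distinct sinusoidal prototype on the log2 scale; genes
#' get their cluster prototype plus iid Gaussian noise and are mapped to
#' FPKM as `base_fpkm * 2^z`, rounded to 3 decimals.
#'
#' @param n_genes Number of genes (>= `n_clusters`).
#' @param n_clusters Number of planted clusters (>= 1).
#' @param noise_sd Log2-scale noise SD (>= 0).
#' @param seed Integer seed.
#' @param n_timepoints Number of time points (default 4).
#' @param base_fpkm Median expression level (default 40, comfortably above
#'   the FPKM >= 10 clustering filter).
#' @param gene_ids Optional gene identifiers (default `SYN0001`, ...).
#' @param labels Optional cluster assignment per gene (integers in
#'   `1:n_clusters`); default cycles through the clusters.
#' @return List with `expr` (tibble `gene_id` + `tp1..tpT`) and `labels`
#'   (tibble `gene_id`, `cluster`).
#' @export
generate_timecourse_expression <- function(n_genes, n_clusters, noise_sd, seed,
                                           n_timepoints = 4, base_fpkm = 40,
                                           gene_ids = NULL, labels = NULL) {
  assert_count(n_clusters, "n_clusters", min = 1)
  assert_count(n_genes, "n_genes", min = 1)
  if (n_genes < n_clusters) abort("n_genes must be at least n_clusters")
  if (noise_sd < 0) abort("noise_sd must be nonnegative")
  if (is.null(gene_ids)) gene_ids <- sprintf("SYN%04d", seq_len(n_genes))
  tp <- seq_len(n_timepoints)
  prototypes <- t(vapply(seq_len(n_clusters), function(c) {
    sqrt(2) * cos(pi * (tp - 1) / max(1, n_timepoints - 1) +
                    2 * pi * (c - 1) / n_clusters)
  }, numeric(n_timepoints)))
  if (is.null(labels)) labels <- rep_len(seq_len(n_clusters), n_genes)
  if (length(labels) != n_genes || !all(labels %in% seq_len(n_clusters))) {
    abort("labels must assign each gene a cluster in 1:n_clusters")
  }
  z <- with_seed(seed, {
    prototypes[labels, , drop = FALSE] +
      matrix(rnorm(n_genes * n_timepoints, 0, noise_sd), n_genes)
  })
  fpkm <- round(base_fpkm * 2^z, 3)
  expr <- as_tibble(as.data.frame(fpkm))
  names(expr) <- sprintf("tp%d", tp)
  expr <- bind_cols(tibble(gene_id = gene_ids), expr)
  list(expr = expr, labels = tibble(gene_id = gene_ids, cluster = labels))
}

#' Plant motif consensus sites into promoter sequences
#'
#' Writes the PWM consensus word at randomly chosen non-overlapping offsets
#' (on a motif-width grid) across the promoters, round-robin, and records
#' the planted positions.
#'
#' @param promoters Named character vector of promoter sequences.
#' @param pwm A [read_pwm()] object.
#' @param n_sites Total number of sites to plant.
#' @param seed Integer seed.
#' @return List with `promoters` (modified) and `sites` (tibble
#'   `promoter_id`, `offset` 0-based, `strand`).
#' @export
plant_motifs <- function(promoters, pwm, n_sites, seed) {
  assert_count(n_sites, "n_sites")
  w <- pwm$width
  if (any(nchar(promoters) < w)) abort("motif wider than a promoter")
  slots_per <- nchar(promoters) %/% w
  if (n_sites > sum(slots_per)) abort("n_sites exceeds promoter capacity")
  consensus <- paste(NUCS[apply(pwm$counts, 2, which.max)], collapse = "")
  if (n_sites == 0) {
    return(list(promoters = promoters,
                sites = tibble(promoter_id = character(),
                               offset = integer(), strand = character())))
  }
  with_seed(seed, {
    # round-robin over promoters until n_sites are placed
    ord <- rep(seq_along(promoters), times = slots_per)
    take <- ord[order(stats::ave(ord, ord, FUN = seq_along), ord)][seq_len(n_sites)]
    sites <- purrr::map_dfr(unique(take), function(i) {
      k <- sum(take == i)
      slots <- sample.int(slots_per[i], k) - 1L
      tibble(promoter_id = names(promoters)[i],
             offset = slots * w, strand = "+")
    })
    for (j in seq_len(nrow(sites))) {
      i <- sites$promoter_id[j]
      off <- sites$offset[j]
      substr(promoters[[i]], off + 1L, off + w) <- consensus
    }
    list(promoters = promoters, sites = arrange(sites, .data$promoter_id,
                                                .data$offset))
  })
}

# ---- full bundle -----------------------------------------------------------

random_dna <- function(n, gc = 0.45) {
  paste(sample(NUCS, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Apply exact counts of nonsynonymous and synonymous codon substitutions to
# internal codons (start and stop are never touched).
mutate_codons <- function(codons, k_nonsyn, k_syn) {
  internal <- 2:(length(codons) - 1L)
  k_nonsyn <- min(k_nonsyn, length(internal))
  pos_ns <- sample(internal, k_nonsyn)
  for (p in pos_ns) {
    alts <- NONSYN_ALTS[[codons[p]]]
    codons[p] <- alts[sample.int(length(alts), 1)]
  }
  remaining <- setdiff(internal, pos_ns)
  syn_ok <- remaining[lengths(SYN_ALTS[codons[remaining]]) > 0]
  k_syn <- min(k_syn, length(syn_ok))
  if (k_syn > 0) {
    pos_s <- if (length(syn_ok) == 1) syn_ok else sample(syn_ok, k_syn)
    for (p in pos_s) {
      alts <- SYN_ALTS[[codons[p]]]
      codons[p] <- alts[sample.int(length(alts), 1)]
    }
  }
  codons
}

TE_CODES_DNA <- c("DTC", "DTM", "DTH", "DTA", "DTT", "DHH")
TE_CODES_RETRO <- c("RLC", "RLG", "RLX", "RIX", "RSX")
TISSUES <- c("caryopsis", "coleoptile", "inflorescence", "root", "shoot")

#' Generate a complete synthetic pan-genome bundle
#'
#' Produces per-accession protein/CDS FASTA and GFF3, TE and PAV tables, a
#' tissue expression matrix, a stress time course with planted temporal
#' clusters, promoters with planted binding sites, a PWM, a gene-to-GO map,
#' and the full ground truth.  All randomness derives from `config$seed`
#' through per-stream child seeds, so the same config yields a byte-identical
#' bundle.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @param write Write the bundle files (default TRUE); `FALSE` returns the
#'   in-memory bundle only, for repeated simulation studies.
#' @return A `pangenome_bundle` list: `dir`, `config`, `accessions`, `files`
#'   (named paths), in-memory tables (`proteins`, `cds`, `loci`, `te`, `pav`,
#'   `expr_tissue`, `expr_timecourse`, `promoters`, `pwm`, `go_map`) and
#'   `truth` (list of tibbles: `orthogroups`, `genes`, `te`, `pav`,
#'   `expression_clusters`, `regulated_targets`, `motif_sites`).
#' @export
generate_pangenome <- function(config, dir = tempfile("pangenome"),
                               write = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  if (write) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  }
  cfg <- config
  accs <- sprintf("ACC%02d", seq_len(cfg$n_accessions))
  ref_acc <- accs[1]
  bands <- occupancy_bands(cfg$n_accessions)

  n_ogg <- cfg$n_core + cfg$n_softcore + cfg$n_shell + cfg$n_cloud
  classes <- rep(c("core", "softcore", "shell", "cloud"),
                 c(cfg$n_core, cfg$n_softcore, cfg$n_shell, cfg$n_cloud))
  ogg_ids <- sprintf("OGG%04d", seq_len(n_ogg))

  # ---- orthogroup ancestors ------------------------------------------------
  anc <- with_seed(derive_seed(cfg$seed, "ancestors"), {
    lens <- pmax(115L, round(rnorm(n_ogg, cfg$mean_cds_len_codons,
                                   0.15 * cfg$mean_cds_len_codons)))
    gc3 <- runif(n_ogg, cfg$gc3_range[1], cfg$gc3_range[2])
    root_len <- max(lens)
    root <- codon_split(generate_cds_with_bias(
      root_len, mean(cfg$gc3_range), derive_seed(cfg$seed, "root")))
    cds <- lapply(seq_len(n_ogg), function(i) {
      own <- codon_split(generate_cds_with_bias(
        lens[i], gc3[i], derive_seed(cfg$seed, "anc", i)))
      # overwrite a planted fraction of internal codons with root codons so
      # ancestors share `between_group_identity` with each other
      internal <- 2:(lens[i] - 1L)
      reusable <- internal[internal < root_len &
                             !(root[internal] %in% STOP_CODONS)]
      k <- round(cfg$between_group_identity * length(reusable))
      if (k > 0) {
        pos <- sample(reusable, k)
        own[pos] <- root[pos]
      }
      own
    })
    list(lens = lens, gc3 = gc3, cds = cds)
  })

  # ---- carriers and copy numbers ------------------------------------------
  occupancy_truth <- with_seed(derive_seed(cfg$seed, "carriers"), {
    lapply(seq_len(n_ogg), function(i) {
      occ <- switch(classes[i],
        core = cfg$n_accessions,
        softcore = bands$softcore[sample.int(length(bands$softcore), 1)],
        shell = bands$shell[sample.int(length(bands$shell), 1)],
        cloud = bands$cloud[sample.int(length(bands$cloud), 1)]
      )
      carriers <- if (occ == cfg$n_accessions) accs else sort(sample(accs, occ))
      copies <- setNames(1L + rbinom(occ, 1L, cfg$cnv_dup_prob), carriers)
      list(occ = occ, carriers = carriers, copies = copies)
    })
  })

  # ---- member genes --------------------------------------------------------
  chrom_of <- sprintf("chr%dH", (seq_len(n_ogg) - 1L) %% 7L + 1L)
  slot_of <- (seq_len(n_ogg) - 1L) %/% 7L
  strand_of <- with_seed(derive_seed(cfg$seed, "strand"),
                         sample(c("+", "-"), n_ogg, replace = TRUE))

  genes <- with_seed(derive_seed(cfg$seed, "members"), {
    rows <- vector("list", n_ogg)
    base_ns <- 1 - cfg$within_group_identity
    for (i in seq_len(n_ogg)) {
      ot <- occupancy_truth[[i]]
      len <- anc$lens[i]
      # planted purifying-selection contrast: core orthogroups get fewer
      # substitutions, with nonsynonymous suppressed more strongly than
      # synonymous so Ka, Ks and Ka/Ks are all lower for core
      ns_mult <- if (classes[i] == "core") 0.4 else 1.2
      s_mult <- if (classes[i] == "core") 0.7 else 1.1
      k_ns <- round(ns_mult * base_ns * len)
      k_s <- round(s_mult * 0.04 * len)
      base_start <- 100000L + slot_of[i] * 60000L
      acc_v <- rep(ot$carriers, ot$copies)
      cp_v <- unlist(lapply(ot$copies, seq_len), use.names = FALSE)
      founder_v <- seq_along(acc_v) == 1L
      m <- length(acc_v)
      cds_v <- character(m)
      for (j in seq_len(m)) {
        codons <- anc$cds[[i]]
        codons <- if (founder_v[j]) {
          mutate_codons(codons, 0L, k_s)  # synonymous drift only
        } else {
          trim <- sample(1:3, 1)
          mutated <- mutate_codons(codons, k_ns, k_s)
          # trim a few C-terminal codons so the founder is strictly longest
          c(mutated[seq_len(length(mutated) - 1L - trim)],
            mutated[length(mutated)])
        }
        cds_v[j] <- paste(codons, collapse = "")
      }
      tandem_v <- cp_v == 1L | runif(m) < 0.7
      next_chrom <- sprintf(
        "chr%dH", (as.integer(sub("chr(\\d)H", "\\1", chrom_of[i])) %% 7L) + 1L)
      chrom_v <- ifelse(tandem_v, chrom_of[i], next_chrom)
      start_v <- ifelse(cp_v == 1L, base_start,
                        ifelse(tandem_v, base_start + 3L * len + 2000L,
                               base_start + 31000L))
      rows[[i]] <- tibble(
        ogg_id = ogg_ids[i], class = classes[i], accession_id = acc_v,
        copy = cp_v, is_founder = founder_v,
        chrom = chrom_v, start = as.integer(start_v),
        end = as.integer(start_v) + nchar(cds_v),
        strand = strand_of[i],
        cds = cds_v
      )
    }
    bind_rows(rows)
  })
  genes <- genes |>
    group_by(.data$accession_id) |>
    arrange(.data$chrom, .data$start, .by_group = TRUE) |>
    mutate(gene_id = sprintf("%s_G%04d", .data$accession_id, row_number())) |>
    ungroup() |>
    arrange(.data$accession_id, .data$chrom, .data$start)
  genes$protein <- vapply(genes$cds, function(s) {
    cd <- codon_split(s)
    translate_codons(cd[-length(cd)])
  }, "", USE.NAMES = FALSE)

  # ---- TE placements -------------------------------------------------------
  te <- with_seed(derive_seed(cfg$seed, "te"), {
    purrr::map_dfr(accs, function(acc) {
      g <- filter(genes, .data$accession_id == acc)
      k <- cfg$n_te_per_accession
      w <- cfg$te_window_bp
      idx <- sample.int(nrow(g), k, replace = TRUE)
      lab <- sample(c("upstream", "downstream", "genic", "none"),
                    k, replace = TRUE, prob = c(0.35, 0.33, 0.22, 0.10))
      te_len <- sample(100:min(1000, w - 2L), k, replace = TRUE)
      gi <- g[idx, ]
      gene_len <- gi$end - gi$start
      te_len <- ifelse(lab == "genic", pmin(te_len, gene_len - 1L), te_len)
      # window on the 5' side is upstream for + genes, downstream for -
      side <- dplyr::case_when(
        lab == "genic" ~ "genic",
        lab == "none" ~ "far",
        (lab == "upstream") == (gi$strand == "+") ~ "left",
        TRUE ~ "right"
      )
      u <- runif(k)
      start <- dplyr::case_when(
        side == "left" ~ gi$start - w + floor(u * (w - te_len)),
        side == "right" ~ gi$end + floor(u * (w - te_len)),
        side == "genic" ~ gi$start + floor(u * pmax(1, gene_len - te_len)),
        TRUE ~ gi$end + w + 10000L + floor(u * 5000)
      )
      tibble(accession_id = acc, chrom = gi$chrom,
             start = as.integer(start), end = as.integer(start + te_len),
             strand = sample(c("+", "-"), k, replace = TRUE),
             code = ifelse(runif(k) < 0.85,
                           sample(TE_CODES_DNA, k, replace = TRUE),
                           sample(TE_CODES_RETRO, k, replace = TRUE)),
             gene_id = gi$gene_id, position = lab)
    })
  })

  # ---- PAV events (relative to the reference accession) --------------------
  ref_genes <- filter(genes, .data$accession_id == ref_acc, .data$copy == 1L)
  pav <- with_seed(derive_seed(cfg$seed, "pav"), {
    planted <- purrr::map_dfr(seq_len(n_ogg), function(i) {
      ot <- occupancy_truth[[i]]
      if (!(ref_acc %in% ot$carriers)) return(NULL)
      absent <- setdiff(accs, ot$carriers)
      if (length(absent) == 0) return(NULL)
      gi <- filter(ref_genes, .data$ogg_id == ogg_ids[i])[1, ]
      tibble(accession_id = absent, chrom = gi$chrom,
             start = as.integer(gi$start - sample(100:500, length(absent),
                                                  replace = TRUE)),
             end = as.integer(gi$end + sample(100:500, length(absent),
                                              replace = TRUE)),
             state = "deletion", gene_id = gi$gene_id)
    })
    extra <- purrr::map_dfr(setdiff(accs, ref_acc), function(acc) {
      k <- 5L
      tibble(accession_id = acc, chrom = sample(sprintf("chr%dH", 1:7), k, replace = TRUE),
             start = as.integer(5e6 + sample.int(1e6, k)),
             end = NA_integer_, state = "insertion", gene_id = NA_character_) |>
        mutate(end = .data$start + sample(c(50:200, 1000:10000), k, replace = TRUE))
    })
    bind_rows(planted, extra)
  })

  # ---- expression ----------------------------------------------------------
  expr_tissue <- with_seed(derive_seed(cfg$seed, "tissue"), {
    g <- ref_genes$gene_id
    vals <- matrix(round(exp(rnorm(length(g) * length(TISSUES), log(15), 1.2)), 3),
                   nrow = length(g))
    out <- as_tibble(as.data.frame(vals))
    names(out) <- TISSUES
    bind_cols(tibble(gene_id = g), out)
  })

  bg_ids <- sprintf("BG%04d", seq_len(cfg$n_background_genes))
  tc_ids <- c(ref_genes$gene_id, bg_ids)
  # family genes and background genes are planted into disjoint temporal
  # clusters, so co-expression with a family gene singles out the planted
  # regulatory targets rather than cluster-mates
  k_tc <- cfg$n_planted_expression_clusters
  k_fam <- max(1L, k_tc %/% 2L)
  tc_labels <- c(
    rep_len(seq_len(k_fam), nrow(ref_genes)),
    rep_len(if (k_tc > k_fam) (k_fam + 1L):k_tc else seq_len(k_tc),
            length(bg_ids))
  )
  tc <- generate_timecourse_expression(
    n_genes = length(tc_ids),
    n_clusters = k_tc,
    noise_sd = cfg$expression_noise_sd,
    seed = derive_seed(cfg$seed, "timecourse"),
    n_timepoints = cfg$n_timepoints,
    gene_ids = tc_ids,
    labels = tc_labels
  )
  expr_tc <- tc$expr

  # regulated targets: background genes re-profiled as near-copies of a focal
  # family gene, so the coexpression + motif route recovers exactly them
  n_reg <- min(cfg$n_regulated_targets, cfg$n_background_genes)
  regulated <- with_seed(derive_seed(cfg$seed, "targets"), {
    if (n_reg == 0 || nrow(ref_genes) == 0) {
      tibble(target_id = character(), focal_id = character())
    } else {
      targets <- sample(bg_ids, n_reg)
      focals <- sample(ref_genes$gene_id, n_reg, replace = TRUE)
      tp_cols <- sprintf("tp%d", seq_len(cfg$n_timepoints))
      for (j in seq_len(n_reg)) {
        focal_row <- as.numeric(expr_tc[expr_tc$gene_id == focals[j], tp_cols])
        expr_tc[expr_tc$gene_id == targets[j], tp_cols] <-
          as.list(round(focal_row * 2^rnorm(cfg$n_timepoints, 0, 0.02), 3))
        # the target now follows its focal gene's temporal profile
        tc$labels$cluster[tc$labels$gene_id == targets[j]] <-
          tc$labels$cluster[tc$labels$gene_id == focals[j]]
      }
      tibble(target_id = targets, focal_id = focals)
    }
  })

  # ---- promoters, PWM, planted motif sites ---------------------------------
  pwm <- nac_like_pwm()
  promoters <- with_seed(derive_seed(cfg$seed, "promoters"), {
    setNames(vapply(tc_ids, function(x) random_dna(cfg$promoter_len_bp), ""),
             tc_ids)
  })
  consensus <- paste(NUCS[apply(pwm$counts, 2, which.max)], collapse = "")
  motif_sites <- with_seed(derive_seed(cfg$seed, "motifs"), {
    if (nrow(regulated) == 0) {
      tibble(promoter_id = character(), offset = integer(), strand = character())
    } else {
      purrr::map_dfr(regulated$target_id, function(tid) {
        off <- sample.int(cfg$promoter_len_bp - pwm$width + 1L, 1) - 1L
        substr(promoters[[tid]], off + 1L, off + pwm$width) <<- consensus
        tibble(promoter_id = tid, offset = off, strand = "+")
      })
    }
  })

  # ---- GO map --------------------------------------------------------------
  go_map <- with_seed(derive_seed(cfg$seed, "go"), {
    pool <- sprintf("GO:%07d", seq_len(20) * 5000)
    n_terms <- sample(1:3, length(tc_ids), replace = TRUE)
    base <- tibble(
      gene_id = rep(tc_ids, n_terms),
      term = unlist(lapply(n_terms, function(k) sample(pool, k)))
    )
    planted <- tibble(gene_id = regulated$target_id, term = "GO:0009651")
    distinct(bind_rows(base, planted))
  })

  # ---- write files ---------------------------------------------------------
  files <- list()
  if (write) for (acc in accs) {
    g <- filter(genes, .data$accession_id == acc)
    files[[paste0("protein_", acc)]] <- write_fasta_catalog(
      tibble(gene_id = g$gene_id, accession_id = acc, sequence = g$protein),
      file.path(dir, sprintf("proteins_%s.fa", acc)), type = "AA")
    files[[paste0("cds_", acc)]] <- write_fasta_catalog(
      tibble(gene_id = g$gene_id, accession_id = acc, sequence = g$cds),
      file.path(dir, sprintf("cds_%s.fa", acc)), type = "DNA")
    files[[paste0("gff_", acc)]] <- write_gff3_genes(
      g, file.path(dir, sprintf("genes_%s.gff3", acc)))
    files[[paste0("te_", acc)]] <- {
      p <- file.path(dir, sprintf("te_%s.tsv", acc))
      readr::write_tsv(select(filter(te, .data$accession_id == acc),
                              "chrom", "start", "end", "strand", "code"), p)
      p
    }
  }
  if (write) {
  files$pav <- {
    p <- file.path(dir, "pav.tsv")
    readr::write_tsv(select(pav, "accession_id", "chrom", "start", "end", "state"), p)
    p
  }
  files$expr_tissue <- {
    p <- file.path(dir, "expression_tissue.tsv"); readr::write_tsv(expr_tissue, p); p
  }
  files$expr_timecourse <- {
    p <- file.path(dir, "expression_timecourse.tsv"); readr::write_tsv(expr_tc, p); p
  }
  files$promoters <- write_fasta_catalog(
    tibble(gene_id = names(promoters), accession_id = NA_character_,
           sequence = unname(promoters)),
    file.path(dir, "promoters.fa"), type = "DNA")
  files$pwm <- write_pwm_meme(pwm, file.path(dir, "motif.meme"))
  files$go_map <- {
    p <- file.path(dir, "go_map.tsv")
    readr::write_lines(sprintf("%s\t%s", go_map$gene_id, go_map$term), p)
    p
  }
  }

  truth <- list(
    orthogroups = tibble(
      ogg_id = ogg_ids, class = classes,
      occupancy = as.integer(vapply(occupancy_truth, function(x) x$occ,
                                    numeric(1)))
    ),
    genes = select(genes, "gene_id", "accession_id", "ogg_id", "class",
                   "copy", "is_founder"),
    te = select(te, "accession_id", "chrom", "start", "end", "strand",
                "code", "gene_id", "position"),
    pav = filter(pav, .data$state == "deletion"),
    expression_clusters = tc$labels,
    regulated_targets = regulated,
    motif_sites = motif_sites
  )
  if (write) for (nm in names(truth)) {
    p <- file.path(dir, "truth", sprintf("truth_%s.tsv", nm))
    readr::write_tsv(truth[[nm]], p)
    files[[paste0("truth_", nm)]] <- p
  }

  structure(list(
    dir = dir, config = cfg, accessions = accs, reference = ref_acc,
    files = files,
    proteins = select(genes, "gene_id", "accession_id", "sequence" = "protein") |>
      mutate(length = nchar(.data$sequence)),
    cds = select(genes, "gene_id", "accession_id", "sequence" = "cds"),
    loci = select(genes, "gene_id", "accession_id", "chrom", "start", "end", "strand"),
    te = te, pav = pav,
    expr_tissue = expr_tissue, expr_timecourse = expr_tc,
    promoters = promoters, pwm = pwm, go_map = go_map,
    truth = truth
  ), class = "pangenome_bundle")
}

# A strongly informative NAC-like binding motif (CACG core), 97 of 100
# observations on the consensus base per column; sharp enough that at the
# default scan threshold essentially only near-consensus words qualify.
nac_like_pwm <- function() {
  consensus <- chars("TTGCACGTGTCA")
  counts <- matrix(1, nrow = 4, ncol = length(consensus),
                   dimnames = list(NUCS, NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 97
  structure(
    list(motif_id = "NACBS", width = length(consensus), counts = counts,
         background = setNames(rep(0.25, 4), NUCS), pseudocount = 0.1),
    class = "pwm"
  )
}

#' @export
print.pangenome_bundle <- function(x, ...) {
  cat(sprintf(
    "<pangenome_bundle> %d accessions, %d orthogroups, %d genes\n  dir: %s\n",
    length(x$accessions), nrow(x$truth$orthogroups), nrow(x$proteins), x$dir))
  invisible(x)
}
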