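# End-to-end driver: reads a (typically synthetic) pan-genome bundle from
# disk through the package's own readers and chains every analysis stage,
# writing a deterministic TSV report.

#' Pipeline configuration
#'
#' @param bundle_dir Directory holding a pan-genome bundle laid out as
#'   written by [generate_pangenome()].
#' @param out_dir Report directory (created on run).
#' @param seed Integer seed for the stochastic stages.
#' @param stages Stages to run, in dependency order; `cluster` is required
#'   by `occupancy`, `variation` and `selection`; `expression` is required
#'   by `network`.
#' @param min_identity,min_longer_cov,min_aln_len Clustering thresholds
#'   (defaults 0.95 / 0.90 / 100).
#' @param te_window_bp TE flank window (default 2000).
#' @param fuzzy_k,fuzzy_m Fuzzy c-means cluster count and fuzzifier
#'   (defaults 10 and 1.25).
#' @param min_mean_fpkm Expression filter floor (default 10).
#' @param r_min,p_max_edge Co-expression edge thresholds (defaults 0.9,
#'   0.01).
#' @param p_max_motif Motif hit p ceiling (default 1e-4).
#' @param make_plots Also write diagnostic plots (default FALSE; plot files
#'   are excluded from byte-level reproducibility comparisons).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(bundle_dir, out_dir,
                            seed = 1,
                            stages = c("cluster", "occupancy", "variation",
                                       "selection", "codon_usage",
                                       "expression", "network"),
                            min_identity = 0.95, min_longer_cov = 0.90,
                            min_aln_len = 100,
                            te_window_bp = 2000,
                            fuzzy_k = 10, fuzzy_m = 1.25,
                            min_mean_fpkm = 10,
                            r_min = 0.9, p_max_edge = 0.01,
                            p_max_motif = 1e-4,
                            make_plots = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(bundle_dir)) abort("bundle_dir does not exist")
  needs <- list(occupancy = "cluster", variation = "cluster",
                selection = c("cluster", "occupancy"),
                network = "expression")
  for (st in stages) {
    missing <- setdiff(needs[[st]], stages)
    if (length(missing)) {
      abort(sprintf("stage '%s' requires stage(s): %s",
                    st, paste(missing, collapse = ", ")))
    }
  }
  structure(as.list(environment())[c(
    "bundle_dir", "out_dir", "seed", "stages", "min_identity",
    "min_longer_cov", "min_aln_len", "te_window_bp", "fuzzy_k", "fuzzy_m",
    "min_mean_fpkm", "r_min", "p_max_edge", "p_max_motif", "make_plots"
  )], class = "pipeline_config")
}

read_bundle_dir <- function(dir) {
  prot_files <- sort(list.files(dir, "^proteins_.*\\.fa$", full.names = TRUE))
  if (length(prot_files) == 0) abort("no proteins_*.fa in bundle_dir")
  accs <- sub("^proteins_(.*)\\.fa$", "\\1", basename(prot_files))
  list(
    accessions = accs,
    reference = accs[1],
    proteins = read_fasta_catalog(prot_files, "AA"),
    cds = read_fasta_catalog(
      file.path(dir, sprintf("cds_%s.fa", accs)), "DNA"),
    loci = purrr::map_dfr(accs, function(a) {
      mutate(read_gff3_genes(file.path(dir, sprintf("genes_%s.gff3", a))),
             accession_id = a)
    }),
    te = purrr::map_dfr(accs, function(a) {
      mutate(read_te_table(file.path(dir, sprintf("te_%s.tsv", a))),
             accession_id = a)
    }),
    pav = read_pav_table(file.path(dir, "pav.tsv")),
    expr_tissue = read_expression_tsv(file.path(dir, "expression_tissue.tsv")),
    expr_timecourse = read_expression_tsv(
      file.path(dir, "expression_timecourse.tsv")),
    promoters = {
      x <- read_fasta_catalog(file.path(dir, "promoters.fa"), "DNA")
      setNames(x$sequence, x$gene_id)
    },
    pwm = read_pwm(file.path(dir, "motif.meme")),
    go_map = read_go_map(file.path(dir, "go_map.tsv"))
  )
}

#' Run the full pan-genome analysis pipeline
#'
#' Reads the bundle through the package readers, runs the configured stages
#' in dependency order, writes one TSV per result table plus a stage-count
#' summary and a (timestamp-free) run log, and returns all tables.
#'
#' @param config A [pipeline_config()].
#' @return A `pannac_report` list of result tables, invisibly writable and
#'   fully reproducible for a fixed config and seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  out <- list(config = config)
  emit <- function(tbl, name) {
    readr::write_tsv(tbl, file.path(config$out_dir, paste0(name, ".tsv")))
    out[[name]] <<- tbl
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  b <- read_bundle_dir(config$bundle_dir)
  say("bundle: %d accessions, %d proteins", length(b$accessions),
      nrow(b$proteins))
  family_ref <- filter(b$loci, .data$accession_id == b$reference)$gene_id

  if ("cluster" %in% config$stages) run_stage("cluster", {
    clusters <- greedy_cluster(b$proteins,
                               min_identity = config$min_identity,
                               min_longer_cov = config$min_longer_cov,
                               min_aln_len = config$min_aln_len)
    emit(select(clusters, -"sequence"), "clusters")
    say("cluster: %d genes -> %d orthogroups", nrow(clusters),
        dplyr::n_distinct(clusters$cluster_id))
  })

  if ("occupancy" %in% config$stages) run_stage("occupancy", {
    mats <- build_matrices(out$clusters, b$accessions)
    classes <- classify_occupancy(mats$occupancy, length(b$accessions))
    emit(mats$occupancy, "occupancy_matrix")
    emit(mats$cnv, "cnv_matrix")
    emit(classes, "occupancy_classes")
    emit(category_summary(classes, mats$cnv), "category_summary")
    say("occupancy: %s", paste(sprintf(
      "%s=%d", levels(classes$label), tabulate(classes$label, 4)),
      collapse = " "))
  })

  if ("variation" %in% config$stages) run_stage("variation", {
    te_assign <- purrr::map_dfr(b$accessions, function(a) {
      te_gene_assignments(
        filter(b$te, .data$accession_id == a),
        filter(b$loci, .data$accession_id == a),
        window_bp = config$te_window_bp
      )
    })
    tallies <- tally_te_classes(te_assign)
    emit(te_assign, "te_assignments")
    emit(tallies$by_position, "te_by_position")
    emit(tallies$by_code, "te_by_code")
    ref_loci <- filter(b$loci, .data$accession_id == b$reference)
    emit(pav_gene_overlap(b$pav, ref_loci), "pav_overlaps")
    homologs <- out$clusters |>
      filter(.data$accession_id == b$reference) |>
      group_by(.data$cluster_id) |>
      filter(n() > 1) |>
      summarise(pairs = list(combn(.data$gene_id, 2)), .groups = "drop")
    homolog_pairs <- if (nrow(homologs) == 0) {
      tibble(gene_a = character(), gene_b = character())
    } else {
      purrr::map_dfr(homologs$pairs, function(p) {
        tibble(gene_a = p[1, ], gene_b = p[2, ])
      })
    }
    emit(classify_duplication(ref_loci, homolog_pairs), "duplication_types")
    say("variation: %d TE assignments, %d PAV overlaps",
        nrow(te_assign), nrow(out$pav_overlaps))
  })

  if ("selection" %in% config$stages) run_stage("selection", {
    kaks <- orthogroup_kaks(out$clusters, b$cds)
    emit(kaks, "kaks_by_orthogroup")
    contrast <- kaks_group_compare(kaks, out$occupancy_classes)
    emit(contrast, "kaks_contrast")
    say("selection: %d orthogroups with pairs; Ka p=%.3g Ks p=%.3g ratio p=%.3g",
        nrow(kaks), contrast$p[1], contrast$p[2], contrast$p[3])
  })

  if ("codon_usage" %in% config$stages) run_stage("codon_usage", {
    profiles <- codon_usage_profile(b$cds)
    emit(profiles, "codon_usage_profiles")
    opt <- optimal_codons(profiles, b$cds)
    emit(opt, "optimal_codons")
    say("codon_usage: mean ENC %.2f, %d optimal codons",
        mean(profiles$ENC, na.rm = TRUE), sum(opt$is_optimal))
    if (config$make_plots) {
      ggplot2::ggsave(file.path(config$out_dir, "enc_gc3s.png"),
                      plot_enc_gc3s(profiles), width = 5, height = 4)
      ggplot2::ggsave(file.path(config$out_dir, "pr2.png"),
                      plot_pr2(profiles), width = 5, height = 4)
    }
  })

  if ("expression" %in% config$stages) run_stage("expression", {
    group_map <- if (!is.null(out$clusters) && !is.null(out$occupancy_classes)) {
      out$clusters |>
        select("gene_id", ogg_id = "cluster_id") |>
        left_join(select(out$occupancy_classes, "ogg_id", "label"),
                  by = "ogg_id") |>
        select("gene_id", group = "label")
    } else NULL
    ts <- tissue_summary(b$expr_tissue, group_map)
    emit(ts$normalized, "tissue_normalized")
    if (!is.null(ts$group_means)) emit(ts$group_means, "tissue_group_means")
    std <- filter_and_standardize(b$expr_timecourse,
                                  min_mean = config$min_mean_fpkm)
    fit <- fuzzy_cmeans(std, k = config$fuzzy_k, m = config$fuzzy_m,
                        seed = derive_seed(config$seed, "fcm"))
    out$fuzzy_fit <- fit
    emit(tidy(fit), "expression_clusters")
    emit(bind_cols(tibble(cluster = rownames(fit$centers)),
                   as_tibble(as.data.frame(fit$centers))),
         "cluster_centers")
    emit(cluster_membership_table(fit, family_ref), "family_cluster_counts")
    say("expression: %d genes clustered into %d clusters (%d family genes)",
        nrow(std), config$fuzzy_k,
        sum(std$gene_id %in% family_ref))
  })

  if ("network" %in% config$stages) run_stage("network", {
    focal <- intersect(family_ref, b$expr_timecourse$gene_id)
    edges <- pearson_edges(b$expr_timecourse, focal,
                           r_min = config$r_min, p_max = config$p_max_edge)
    target_promoters <- b$promoters[names(b$promoters) %in% edges$target]
    hits <- if (length(target_promoters)) {
      pwm_scan(target_promoters, b$pwm, p_max = config$p_max_motif)
    } else {
      tibble(promoter_id = character(), offset = integer(),
             strand = character(), score = numeric(), p = numeric())
    }
    net <- assemble_network(edges, hits, out$expression_clusters)
    emit(edges, "coexpression_edges")
    emit(hits, "motif_hits")
    emit(net$edges, "network_edges")
    emit(net$nodes, "network_nodes")
    if (!is.null(net$per_cluster)) emit(net$per_cluster, "network_per_cluster")
    targets <- unique(net$edges$target)
    if (length(targets) > 0) {
      emit(enrich(targets, b$expr_timecourse$gene_id, b$go_map),
           "go_enrichment")
    }
    say("network: %d edges, %d motif-supported targets",
        nrow(edges), length(targets))
  })

  summary_tbl <- tibble(
    table = setdiff(names(out), c("config", "fuzzy_fit")),
    n_rows = vapply(out[setdiff(names(out), c("config", "fuzzy_fit"))],
                    nrow, integer(1))
  )
  readr::write_tsv(summary_tbl, file.path(config$out_dir, "summary.tsv"))
  readr::write_lines(log_lines, file.path(config$out_dir, "run_log.txt"))
  out$summary <- summary_tbl
  structure(out, class = "pannac_report")
}

#' @export
print.pannac_report <- function(x, ...) {
  cat("<pannac_report>\n")
  print(x$summary)
  invisible(x)
}
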