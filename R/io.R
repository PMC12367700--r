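#' Read per-accession protein or CDS FASTA files
#'
#' Record identifiers are expected in the `accession|gene_id` form written by
#' [generate_pangenome()]; records without a `|` keep their full identifier as
#' `gene_id` and get `accession_id = NA`.
#'
#' @param paths Character vector of FASTA file paths.
#' @param type `"AA"` for protein, `"DNA"` for CDS.
#' @return A tibble with columns `gene_id`, `accession_id`, `sequence`,
#'   `length` (residues or nucleotides).
#' @export
read_fasta_catalog <- function(paths, type = c("AA", "DNA")) {
  type <- match.arg(type)
  reader <- if (type == "AA") Biostrings::readAAStringSet else Biostrings::readDNAStringSet
  recs <- purrr::map(paths, function(p) {
    ss <- reader(p)
    ids <- sub("\\s.*$", "", names(ss))
    has_acc <- grepl("|", ids, fixed = TRUE)
    seqs <- unname(as.character(ss))
    tibble(
      gene_id = ifelse(has_acc, sub("^[^|]*\\|", "", ids), ids),
      accession_id = ifelse(has_acc, sub("\\|.*$", "", ids), NA_character_),
      sequence = seqs,
      length = nchar(seqs)
    )
  })
  out <- bind_rows(recs)
  if (anyDuplicated(out$gene_id)) abort("duplicate gene_id across FASTA inputs")
  out
}

#' Write a sequence catalog to FASTA
#'
#' @param catalog Tibble with `gene_id`, `accession_id`, `sequence`.
#' @param path Output file.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta_catalog <- function(catalog, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  ctor <- if (type == "AA") Biostrings::AAStringSet else Biostrings::DNAStringSet
  ss <- ctor(setNames(
    catalog$sequence,
    ifelse(
      is.na(catalog$accession_id),
      catalog$gene_id,
      paste0(catalog$accession_id, "|", catalog$gene_id)
    )
  ))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene loci from a GFF3 file
#'
#' Keeps `gene`-type features and converts the 1-based inclusive GFF3
#' coordinates to the package's internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
read_gff3_genes <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) abort(sprintf("GFF3 line %d does not have 9 columns", bad[1]))
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  ids <- sub("^.*ID=([^;]+).*$", "\\1", m[, 9])
  tibble(
    gene_id = ids,
    chrom = m[, 1],
    start = as.integer(m[, 4]) - 1L,  # to 0-based half-open
    end = as.integer(m[, 5]),
    strand = m[, 7]
  )
}

write_gff3_genes <- function(genes, path, source = "pannac") {
  lines <- sprintf(
    "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
    genes$chrom, source, genes$start + 1L, genes$end, genes$strand, genes$gene_id
  )
  readr::write_lines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a transposable-element table
#'
#' Tab-separated with header `chrom  start  end  strand  code`; coordinates
#' 0-based half-open; `code` is the three-letter TE classification string.
#'
#' @param path File path.
#' @return Tibble with those columns.
#' @export
read_te_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), strand = readr::col_character(),
    code = readr::col_character()
  ))
}

#' Read a presence/absence-variation table
#'
#' Tab-separated with header `accession_id  chrom  start  end  state`;
#' `state` is `insertion` or `deletion` relative to the reference accession.
#'
#' @param path File path.
#' @return Tibble with those columns plus `length_bp`.
#' @export
read_pav_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    accession_id = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    state = readr::col_character()
  ))
  if (!all(x$state %in% c("insertion", "deletion"))) {
    abort("PAV state must be 'insertion' or 'deletion'")
  }
  mutate(x, length_bp = .data$end - .data$start)
}

#' Read an expression matrix (genes x conditions, TSV)
#'
#' First column `gene_id`, remaining columns one per tissue/time point, FPKM.
#'
#' @param path File path.
#' @return Tibble, `gene_id` plus numeric condition columns.
#' @export
read_expression_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
  vals <- as.matrix(x[, -1])
  if (any(vals < 0)) abort("expression values must be nonnegative")
  if (anyDuplicated(names(x))) abort("condition labels must be unique")
  x
}

#' Read a gene-to-GO-term map (two-column TSV, no header)
#'
#' @param path File path.
#' @return Tibble `gene_id`, `term`.
#' @export
read_go_map <- function(path) {
  readr::read_tsv(path, col_names = c("gene_id", "term"),
                  col_types = "cc")
}

#' Read a position weight matrix
#'
#' Accepts either MEME-minimal format (`MEME version` header with a
#' `letter-probability matrix` block; probabilities are scaled by `nsites`
#' to counts) or a plain 4 x w tab-separated count table whose first column
#' holds the row labels A, C, G, T.
#'
#' @param path File path.
#' @param pseudocount Added to every cell before frequencies are formed when
#'   the matrix is scored (default 0.1).
#' @param background Length-4 background nucleotide distribution (A,C,G,T);
#'   default uniform.
#' @return A `pwm` object: list with `motif_id`, `width`, `counts` (4 x w
#'   matrix, rows A/C/G/T), `background`, `pseudocount`.
#' @export
read_pwm <- function(path, pseudocount = 0.1, background = rep(0.25, 4)) {
  lines <- readr::read_lines(path)
  if (any(grepl("^MEME version", lines))) {
    motif_line <- grep("^MOTIF", lines)[1]
    if (is.na(motif_line)) abort("MEME file has no MOTIF block")
    motif_id <- strsplit(trimws(lines[motif_line]), "\\s+")[[1]][2]
    lp <- grep("^letter-probability matrix", lines)[1]
    hdr <- lines[lp]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr))
    } else 20
    rows <- lines[(lp + 1):(lp + w)]
    probs <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    counts <- t(probs) * nsites  # 4 x w, rows A C G T
  } else {
    fields <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
    lab <- vapply(fields, `[[`, character(1), 1)
    if (!setequal(lab, NUCS)) abort("count-table PWM must have rows A, C, G, T")
    counts <- do.call(rbind, lapply(fields, function(f) as.numeric(f[-1])))
    rownames(counts) <- lab
    counts <- counts[NUCS, , drop = FALSE]
    motif_id <- sub("\\.[^.]*$", "", basename(path))
    w <- ncol(counts)
  }
  if (any(counts < 0)) abort("PWM counts must be nonnegative")
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  rownames(counts) <- NUCS
  structure(
    list(motif_id = motif_id, width = w, counts = counts,
         background = setNames(as.numeric(background), NUCS),
         pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d\n", x$motif_id, x$width))
  print(round(x$counts, 2))
  invisible(x)
}

write_pwm_meme <- function(pwm, path) {
  counts <- pwm$counts
  nsites <- max(colSums(counts))
  probs <- t(counts) / colSums(counts)
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    sprintf("MOTIF %s", pwm$motif_id),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            pwm$width, as.integer(nsites)),
    apply(probs, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  )
  readr::write_lines(lines, path)
  invisible(path)
}
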