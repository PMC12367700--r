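# Expression summarization and fuzzy c-means time-course clustering.

expr_matrix <- function(expr) {
  m <- as.matrix(expr[, setdiff(names(expr), "gene_id"), drop = FALSE])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}

#' Tissue expression summary
#'
#' Per-gene min-max normalization across conditions (constant rows map to
#' all zeros) and per-group per-condition means on the raw FPKM scale.
#'
#' @param expr Expression tibble (`gene_id` + condition columns, FPKM).
#' @param group_map Optional tibble `gene_id`, `group`; group means are
#'   computed over the genes present in the matrix.
#' @return List with `normalized` (tibble, same shape as `expr`) and
#'   `group_means` (tibble `group` x condition, or NULL).
#' @export
tissue_summary <- function(expr, group_map = NULL) {
  m <- expr_matrix(expr)
  rng <- apply(m, 1, function(x) diff(range(x)))
  norm <- (m - apply(m, 1, min)) / ifelse(rng == 0, 1, rng)
  norm[rng == 0, ] <- 0
  normalized <- bind_cols(tibble(gene_id = rownames(m)),
                          as_tibble(as.data.frame(norm)))
  group_means <- NULL
  if (!is.null(group_map)) {
    group_means <- expr |>
      inner_join(group_map, by = "gene_id") |>
      group_by(.data$group) |>
      summarise(across(-"gene_id", mean), .groups = "drop")
  }
  list(normalized = normalized, group_means = group_means)
}

#' Filter low-expression genes and standardize rows
#'
#' Rows with mean FPKM below `min_mean` are removed; surviving rows are
#' z-scored across conditions.  Zero-variance survivors cannot be
#' standardized and are dropped with a warning.
#'
#' @param expr Expression tibble (`gene_id` + >= 2 condition columns).
#' @param min_mean Mean-FPKM floor; rows with mean strictly below are
#'   dropped (default 10).
#' @return Tibble of standardized rows (mean 0, sd 1 per gene).
#' @export
filter_and_standardize <- function(expr, min_mean = 10) {
  m <- expr_matrix(expr)
  if (ncol(m) < 2) abort("need at least 2 conditions")
  m <- m[rowMeans(m) >= min_mean, , drop = FALSE]
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("%d zero-variance gene(s) removed before standardization",
                 sum(sds == 0)))
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (m - rowMeans(m)) / sds
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(as.data.frame(z)))
}

#' Fuzzy c-means clustering of expression profiles
#'
#' Standard fuzzy c-means with Euclidean distance: memberships
#' `u_ij = 1 / sum_k (d_ij / d_kj)^(2/(m-1))`, centers as the
#' membership^m-weighted means.  Initial centers are chosen by maximin
#' (farthest-point) seeding: the first center is a seeded random gene and
#' each subsequent center is the gene farthest from all chosen centers,
#' which avoids the degenerate local optima of purely random starts.
#' Iteration stops when the largest center shift falls below `tol` or
#' after `max_iter` rounds.
#'
#' @param std Standardized expression tibble from [filter_and_standardize()].
#' @param k Number of clusters (default 10).
#' @param m Fuzzifier, > 1 (default 1.25).
#' @param seed Integer seed for the center initialization.
#' @param max_iter Iteration ceiling (default 200).
#' @param tol Center-shift convergence threshold (default 1e-6).
#' @return A `fuzzy_cmeans` object: `memberships` (gene x cluster matrix,
#'   rows sum to 1), `centers` (cluster x condition), `hard_labels` (named
#'   integer vector, argmax membership), `m`, `k`, `n_iterations`,
#'   `objective` (per-iteration trace of `sum u^m d^2`).
#' @export
fuzzy_cmeans <- function(std, k = 10, m = 1.25, seed = 1,
                         max_iter = 200, tol = 1e-6) {
  x <- expr_matrix(std)
  n <- nrow(x)
  assert_count(k, "k", min = 1)
  if (k > n) abort("k exceeds the number of genes")
  if (m <= 1) abort("fuzzifier m must be > 1")
  # maximin initialization over the sorted identifier list, so the fit does
  # not depend on input row order; ties break toward the first sorted id
  ids_sorted <- sort(rownames(x))
  xs <- x[ids_sorted, , drop = FALSE]
  first <- with_seed(seed, sample.int(n, 1))
  chosen <- first
  if (k > 1) {
    d2min <- rowSums((xs - matrix(xs[first, ], n, ncol(xs), byrow = TRUE))^2)
    for (j in 2:k) {
      nxt <- which.max(d2min)
      chosen <- c(chosen, nxt)
      d2min <- pmin(d2min, rowSums(
        (xs - matrix(xs[nxt, ], n, ncol(xs), byrow = TRUE))^2))
    }
  }
  centers <- xs[chosen, , drop = FALSE]
  rownames(centers) <- NULL

  memberships_for <- function(centers) {
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2[d2 < 0] <- 0
    expo <- 1 / (m - 1)
    u <- matrix(0, n, k)
    zero <- d2 <= .Machine$double.eps
    any_zero <- rowSums(zero) > 0
    inv <- (1 / d2[!any_zero, , drop = FALSE])^expo
    u[!any_zero, ] <- inv / rowSums(inv)
    u[any_zero, ] <- zero[any_zero, , drop = FALSE] /
      rowSums(zero[any_zero, , drop = FALSE])
    list(u = u, d2 = d2)
  }

  objective <- numeric(0)
  for (iter in seq_len(max_iter)) {
    mu <- memberships_for(centers)
    um <- mu$u^m
    objective <- c(objective, sum(um * mu$d2))
    new_centers <- (t(um) %*% x) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  mu <- memberships_for(centers)
  hard <- apply(mu$u, 1, which.max)
  dimnames(mu$u) <- list(rownames(x), paste0("cluster", seq_len(k)))
  dimnames(centers) <- list(paste0("cluster", seq_len(k)), colnames(x))
  structure(
    list(memberships = mu$u, centers = centers,
         hard_labels = setNames(as.integer(hard), rownames(x)),
         m = m, k = k, n_iterations = iter, objective = objective),
    class = "fuzzy_cmeans"
  )
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat(sprintf("<fuzzy_cmeans> %d genes, k = %d, m = %.3g, %d iterations\n",
              nrow(x$memberships), x$k, x$m, x$n_iterations))
  print(table(cluster = x$hard_labels))
  invisible(x)
}

#' @describeIn fuzzy_cmeans Tidy per-gene memberships: `gene_id`, `cluster`
#'   (hard label), `membership` of the hard cluster.
#' @param x A `fuzzy_cmeans` object.
#' @param ... Unused.
#' @method tidy fuzzy_cmeans
#' @export
tidy.fuzzy_cmeans <- function(x, ...) {
  tibble(
    gene_id = names(x$hard_labels),
    cluster = unname(x$hard_labels),
    membership = x$memberships[cbind(seq_along(x$hard_labels),
                                     x$hard_labels)]
  )
}

#' @describeIn fuzzy_cmeans One-row fit summary.
#' @method glance fuzzy_cmeans
#' @export
glance.fuzzy_cmeans <- function(x, ...) {
  tibble(n_genes = nrow(x$memberships), k = x$k, m = x$m,
         n_iterations = x$n_iterations,
         objective = tail(x$objective, 1))
}

#' Count cluster membership of a gene subset
#'
#' @param fit A [fuzzy_cmeans()] result.
#' @param gene_subset Character vector of gene identifiers (genes absent
#'   from the fit contribute nothing).
#' @return Tibble `cluster`, `n` (counts sum to the number of subset genes
#'   present in the fit).
#' @export
cluster_membership_table <- function(fit, gene_subset) {
  labels <- fit$hard_labels[names(fit$hard_labels) %in% gene_subset]
  tibble(cluster = seq_len(fit$k)) |>
    left_join(count(tibble(cluster = unname(labels)), .data$cluster),
              by = "cluster") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
}
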