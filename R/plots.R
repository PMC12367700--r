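# Basic diagnostic plots for the suite's result tables.

#' ENC versus GC3s with Wright's expected curve
#'
#' @param profiles Output of [codon_usage_profile()].
#' @return A ggplot.
#' @export
plot_enc_gc3s <- function(profiles) {
  s <- seq(0.01, 0.99, by = 0.01)
  curve <- tibble(GC3s = s, ENC = enc_expected(s))
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$GC3s, y = .data$ENC)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::coord_cartesian(ylim = c(20, 61)) +
    ggplot2::labs(x = "GC3s", y = "ENC",
                  title = "Codon usage bias: ENC plot") +
    ggplot2::theme_minimal()
}

#' PR2 plot (third-position parity)
#'
#' @param profiles Output of [codon_usage_profile()].
#' @return A ggplot.
#' @export
plot_pr2 <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$pr2_x, y = .data$pr2_y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "G3/(G3+C3)", y = "A3/(A3+T3)", title = "PR2 plot") +
    ggplot2::theme_minimal()
}

#' Occupancy class counts
#'
#' @param classes Output of [classify_occupancy()].
#' @return A ggplot.
#' @export
plot_occupancy <- function(classes) {
  ggplot2::ggplot(classes, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "conservation class", y = "orthogroups") +
    ggplot2::theme_minimal()
}

#' @describeIn fuzzy_cmeans Per-cluster standardized expression profiles
#'   with the cluster centers overlaid.
#' @param object A `fuzzy_cmeans` object.
#' @param std The standardized matrix the fit was computed on (tibble);
#'   omit to plot centers only.
#' @param ... Unused.
#' @method autoplot fuzzy_cmeans
#' @export
autoplot.fuzzy_cmeans <- function(object, std = NULL, ...) {
  centers <- as_tibble(as.data.frame(object$centers)) |>
    mutate(cluster = seq_len(object$k)) |>
    tidyr::pivot_longer(-"cluster", names_to = "condition",
                        values_to = "z") |>
    mutate(condition = factor(.data$condition,
                              levels = colnames(object$centers)))
  p <- ggplot2::ggplot(centers,
                       ggplot2::aes(x = .data$condition, y = .data$z,
                                    group = .data$cluster))
  if (!is.null(std)) {
    genes <- std |>
      tidyr::pivot_longer(-"gene_id", names_to = "condition",
                          values_to = "z") |>
      left_join(tibble(gene_id = names(object$hard_labels),
                       cluster = unname(object$hard_labels)),
                by = "gene_id") |>
      mutate(condition = factor(.data$condition,
                                levels = colnames(object$centers)))
    p <- p + ggplot2::geom_line(
      data = genes,
      ggplot2::aes(group = .data$gene_id), alpha = 0.2, colour = "grey50")
  }
  p + ggplot2::geom_line(colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "standardized expression") +
    ggplot2::theme_minimal()
}
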