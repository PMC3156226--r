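#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an overlap graph into its edge table
#' @param x An `overlap_graph`.
#' @param ... Unused.
#' @return A tibble of edges (one row per alignment).
#' @method tidy overlap_graph
#' @export
tidy.overlap_graph <- function(x, ...) as_tibble(x$edges)

#' @rdname tidy.overlap_graph
#' @method glance overlap_graph
#' @export
glance.overlap_graph <- function(x, ...) {
  tibble(n_reads = nrow(x$vertices),
         n_overlap_edges = sum(x$edges$kind == "overlap"),
         n_containment_edges = sum(x$edges$kind == "containment"),
         n_contained = nrow(x$exemplar_of))
}

#' Tidy a path graph into its inner-edge table
#' @param x A `path_graph`.
#' @param ... Unused.
#' @return A tibble with one row per unique path.
#' @method tidy path_graph
#' @export
tidy.path_graph <- function(x, ...) {
  mutate(select(as_tibble(x$inner), -"reads", -"orients", -"offsets"),
         n_real_edges = nrow(x$real))
}

#' @rdname tidy.path_graph
#' @method glance path_graph
#' @export
glance.path_graph <- function(x, ...) {
  tibble(n_vertices = nrow(x$vertices), n_inner_edges = nrow(x$inner),
         n_real_edges = nrow(x$real),
         total_path_bp = sum(x$inner$length))
}

#' Tidy an assembly into its contig table
#' @param x An `assembly`.
#' @param ... Unused.
#' @return The contigs tibble (without list columns).
#' @method tidy assembly
#' @export
tidy.assembly <- function(x, ...) {
  select(as_tibble(x$contigs), -"read_path", -"support")
}

#' @rdname tidy.assembly
#' @method glance assembly
#' @export
glance.assembly <- function(x, ...) {
  lens <- sort(x$contigs$length, decreasing = TRUE)
  # classical length-weighted N50 of the contig set (not the block variant)
  n50 <- if (length(lens)) lens[which(cumsum(lens) >= sum(lens) / 2)[1]] else 0L
  tibble(n_contigs = nrow(x$contigs), total_bp = sum(x$contigs$length),
         longest = if (length(lens)) lens[1] else 0L, n50 = n50,
         n_repeat_branches = if (!is.null(x$subgraph))
           nrow(x$subgraph$repeat_branches) else 0L,
         n_marked_cycles = if (!is.null(x$subgraph))
           length(x$subgraph$marked_cycles) else 0L)
}

#' Plot contig lengths of an assembly
#' @param object An `assembly`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot assembly
#' @export
autoplot.assembly <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$id, -.data$length),
                                  y = .data$length)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "contig", y = "length (bp)",
                  title = "Assembly contig lengths") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot per-column read support of a contig
#' @param assembly An `assembly`.
#' @param contig_id Contig to plot (default: the longest).
#' @return A ggplot of coverage along the contig.
#' @export
plot_contig_support <- function(assembly, contig_id = NULL) {
  ctg <- assembly$contigs
  if (is.null(contig_id)) contig_id <- ctg$id[which.max(ctg$length)]
  row <- ctg[ctg$id == contig_id, ]
  d <- tibble(position = seq_along(row$support[[1]]),
              support = row$support[[1]])
  ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$support)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(x = "contig position (bp)", y = "read support",
                  title = contig_id) +
    ggplot2::theme_minimal()
}

#' Plot per-block evaluation metrics
#' @param evaluation Result of [evaluate_blocks()].
#' @return A ggplot of per-block N50 and error rate.
#' @export
plot_block_metrics <- function(evaluation) {
  d <- tidyr::pivot_longer(evaluation$per_block,
                           c("n50", "err_rate"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$block), .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "block", y = NULL, title = "Per-block assembly metrics") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
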