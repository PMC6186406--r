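#' Heatmap of a pairwise-identity matrix
#'
#' @param object A `cress_pim` from [build_pi_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cress_pim <- function(object, ...) {
  df <- tidy(object)
  full <- bind_rows(df,
                    tibble(id1 = df$id2, id2 = df$id1, identity = df$identity,
                           mode = df$mode),
                    tibble(id1 = object$ids, id2 = object$ids,
                           identity = 1, mode = object$mode))
  ggplot2::ggplot(full, ggplot2::aes(x = .data$id1, y = .data$id2,
                                     fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "PI") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Pairwise identity (%s)", object$mode)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Per-residue disorder profile plot
#'
#' Shows the smoothed disorder propensity along the protein with the calling
#' threshold and the first-100-residue window highlighted.
#'
#' @param object A `cress_disorder` from [disorder_profile()].
#' @param threshold Calling threshold to draw (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cress_disorder <- function(object, threshold = 0.5, ...) {
  df <- tibble(residue = seq_along(object$scores), score = object$scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$score)) +
    ggplot2::annotate("rect", xmin = 0.5, xmax = min(100, nrow(df)) + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "blue") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Residue", y = "Disorder propensity") +
    ggplot2::theme_minimal()
}

#' Linear map of annotated features on a circular genome
#'
#' Draws the major ORFs (strand-separated) and the called origin along the
#' unrolled circle.
#'
#' @param annotation A `cress_annotation` from [annotate_genomes()].
#' @param genome_id Which genome to draw (default: the first).
#' @return A ggplot object.
#' @export
plot_genome_map <- function(annotation, genome_id = NULL) {
  stopifnot(inherits(annotation, "cress_annotation"))
  genome_id <- genome_id %||% annotation$report$genome_id[1]
  det <- annotation$details[[genome_id]]
  if (is.null(det$orfs)) abort(sprintf("no details for genome '%s'", genome_id))
  L <- annotation$report$genome_size_nt[
    match(genome_id, annotation$report$genome_id)]
  orfs <- mutate(det$orfs,
                 y = ifelse(.data$strand == "+", 1, -1),
                 role = ifelse(.data$orf_id ==
                                 annotation$report$rep_orf[
                                   match(genome_id, annotation$report$genome_id)],
                               "Rep", "other"))
  p <- ggplot2::ggplot(orfs) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = .data$y - 0.35, ymax = .data$y + 0.35,
                                    fill = .data$role)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_y_continuous(breaks = c(-1, 1), labels = c("-", "+"),
                                limits = c(-1.8, 1.8)) +
    ggplot2::labs(x = sprintf("Position (nt, 0..%d; features may extend past L)", L),
                  y = "Strand", title = genome_id) +
    ggplot2::theme_minimal()
  if (!is.null(det$ori)) {
    p <- p + ggplot2::annotate("point", x = det$ori$nonamer$pos, y = 0,
                               shape = 17, size = 3) +
      ggplot2::annotate("text", x = det$ori$nonamer$pos, y = 0.45,
                        label = det$ori$nonamer$seq9, size = 3)
  }
  p
}
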