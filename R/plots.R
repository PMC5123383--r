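#' MA-style plot of a fuzzy differential-expression run
#'
#' Centroid log2 fold change against mean centroid expression, colored by
#' same-expression possibility (low values = reliable DE events), with
#' the fitted significance envelope `+-t(m)` overlaid. Genes with an
#' infinite centroid fold change are dropped from the panel with a
#' message.
#'
#' @param object A `fuzzy_de` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fuzzy_de
#' @export
autoplot.fuzzy_de <- function(object, ...) {
  res <- object$results
  res$mean_expr <- (res$case_centroid + res$control_centroid) / 2
  drop <- !is.finite(res$log2fc_centroid) | res$mean_expr <= 0
  if (any(drop)) {
    message(sum(drop), " gene(s) with infinite fold change or zero mean omitted from the plot")
    res <- res[!drop, ]
  }
  mg <- exp(seq(log(max(min(res$mean_expr), 1e-3)), log(max(res$mean_expr)),
                length.out = 200))
  env <- tibble::tibble(mean_expr = rep(mg, 2),
                        fc = c(threshold(object$model, mg), -threshold(object$model, mg)),
                        side = rep(c("upper", "lower"), each = length(mg)))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$mean_expr, y = .data$log2fc_centroid)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_same), alpha = 0.8) +
    ggplot2::geom_line(data = env,
                       ggplot2::aes(y = .data$fc, group = .data$side),
                       linetype = "dashed", colour = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_viridis_c(direction = -1, limits = c(0, 1)) +
    ggplot2::labs(x = "mean normalized centroid count",
                  y = "centroid log2 fold change",
                  colour = "same-expression\npossibility") +
    ggplot2::theme_minimal()
}

#' Plot the fuzzy read count of one gene in both conditions
#'
#' Draws the two trapezoidal membership functions (case and control) of a
#' gene from a [fuzzy_de()] result, with the centroids marked -- a direct
#' visualization of how much multiread uncertainty the two counts carry
#' and how far apart they are.
#'
#' @param x A `fuzzy_de` object.
#' @param gene Gene identifier.
#' @return A ggplot object.
#' @export
plot_fuzzy_count <- function(x, gene) {
  stopifnot(inherits(x, "fuzzy_de"))
  row <- x$results[x$results$gene == gene, ]
  if (nrow(row) == 0) stop("gene `", gene, "` not in the results", call. = FALSE)
  traps <- tibble::tibble(
    condition = c("case", "control"),
    A = c(row$case_A, row$control_A), B = c(row$case_B, row$control_B),
    C = c(row$case_C, row$control_C), D = c(row$case_D, row$control_D),
    centroid = c(row$case_centroid, row$control_centroid)
  )
  curves <- purrr::pmap(traps, function(condition, A, B, C, D, centroid) {
    xs <- seq(max(A - 1.5, 0), D + 1.5, length.out = 256)
    tibble::tibble(condition = condition, count = xs,
                   membership = trapezoid_membership(xs, A, B, C, D))
  }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$count, y = .data$membership,
                                       colour = .data$condition)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(data = traps,
                        ggplot2::aes(xintercept = .data$centroid,
                                     colour = .data$condition),
                        linetype = "dotted") +
    ggplot2::labs(title = gene, x = "normalized read count", y = "possibility") +
    ggplot2::theme_minimal()
}
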