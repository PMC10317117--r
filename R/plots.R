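#' Plot a guide design
#'
#' Cutting-frequency distribution of the selected guides, coloured by pool,
#' with the per-guide minimum site count marked.
#'
#' @param object a `guide_design`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot guide_design
#' @export
autoplot.guide_design <- function(object, ...) {
  g <- object$guides
  if (nrow(g) == 0) abort("empty design")
  fill <- if (!is.null(g$pool)) factor(g$pool) else factor(1)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$on_target_sites, fill = fill)) +
    ggplot2::geom_histogram(bins = 30, colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$params$min_sites,
                        linetype = "dashed") +
    ggplot2::labs(x = "on-target cleavage sites per guide",
                  y = "guides", fill = "pool",
                  title = "Cutting-frequency distribution of selected guides")
}

#' Plot a depletion report
#'
#' Mean variation of mapped reads by class: negative bars are depleted
#' classes, positive bars enriched ones.
#'
#' @param object a `depletion_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot depletion_report
#' @export
autoplot.depletion_report <- function(object, ...) {
  v <- object$class_variation
  ggplot2::ggplot(v, ggplot2::aes(
    x = stats::reorder(.data$class_label, .data$mean_variation),
    y = .data$mean_variation)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$mean_variation < 0),
                      show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "variation of mapped reads",
                  title = "Read-count variation after depletion")
}

#' gRNA density versus coverage variation
#'
#' Scatter of per-region log2 coverage variation against cleavage-site
#' density, with the density threshold marked.
#'
#' @param report a `depletion_report` built with `sites`.
#' @return A ggplot object.
#' @export
plot_density_depletion <- function(report) {
  if (is.null(report$density)) abort("report was built without cut sites")
  ggplot2::ggplot(report$density$table,
                  ggplot2::aes(x = .data$density, y = .data$log2_variation)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = report$params$density_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "cleavage sites per kbp",
                  y = "log2 coverage variation",
                  title = "Depletion depends on local gRNA density")
}
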