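# ggplot2 views of the main result types. Each autoplot returns a plain
# ggplot object the caller can restyle.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a distance-decay profile
#' @param object A `distance_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_profile <- function(object, ...) {
  d <- object[object$distance_bp > 0 & object$mean_contact > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_bp,
                                  y = .data$mean_contact)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic distance (bp)", y = "mean contact",
                  title = object$chrom[1]) +
    ggplot2::theme_minimal()
}

#' Plot a boundary-centered feature profile
#' @param object A `boundary_profile`.
#' @param ... Unused.
#' @return A ggplot with mean +/- SE ribbon.
#' @export
autoplot.boundary_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset_bp, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "offset from boundary (bp)", y = "mean track value") +
    ggplot2::theme_minimal()
}

#' Plot an observed/expected variant profile
#' @param object An `obs_exp_profile`.
#' @param ... Unused.
#' @return A ggplot of the Obs/Exp ratio against boundary offset.
#' @export
autoplot.obs_exp_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset_bp, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "offset from boundary (bp)", y = "observed / expected") +
    ggplot2::theme_minimal()
}

#' Plot a subcompartment switching table
#' @param object A `switching_table`.
#' @param ... Unused.
#' @return A ggplot bar chart of shift-category proportions.
#' @export
autoplot.switching_table <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     category = factor(.data$category,
                                       levels = object$category))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category,
                                  y = .data$proportion)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "subcompartment rank shift", y = "proportion of bins") +
    ggplot2::theme_minimal()
}

#' Plot a synteny-break enrichment profile
#' @param object A `break_enrichment`.
#' @param ... Unused.
#' @return A ggplot of the alignability-normalized fold per relative cell.
#' @export
autoplot.break_enrichment <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$rel_cell, y = .data$fold)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "relative position in domain (cell)",
                  y = "normalized fold") +
    ggplot2::theme_minimal()
}

#' Heatmap of a contact matrix
#' @param object A `contact_matrix`.
#' @param ... Unused.
#' @param max_quantile Clip the fill scale at this count quantile.
#' @return A ggplot heatmap (log1p fill).
#' @export
autoplot.contact_matrix <- function(object, max_quantile = 0.98, ...) {
  d <- tidy.contact_matrix(object)
  cap <- stats::quantile(d$count, max_quantile, na.rm = TRUE)
  d$count <- pmin(d$count, cap)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start1, y = .data$start2,
                                  fill = log1p(.data$count))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = object$chrom) +
    ggplot2::theme_minimal()
}
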