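#' Plot a hotspot table
#'
#' Bar chart of per-residue interaction frequencies, highlighting residues
#' above the display threshold.
#'
#' @param object A `hotspot_table`.
#' @param threshold Display threshold, percent.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.hotspot_table <- function(object, threshold = 2.5, ...) {
  df <- dplyr::as_tibble(object)
  df$flagged <- df$percent > threshold
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$pooled_key, .data$resid),
    y = .data$percent, fill = .data$flagged
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#B2182B")) +
    ggplot2::labs(
      x = NULL, y = "% of headgroup contacts",
      title = paste0(attr(object, "species") %||% "", " contact hotspots")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Plot a survival curve, optionally with its biexponential fit
#'
#' @param object A `survival_curve`.
#' @param fit Optional `residence_fit` overlay.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.survival_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(dplyr::as_tibble(object),
                       ggplot2::aes(.data$t, .data$sigma)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "lag t (ns)", y = expression(sigma(t)),
                  title = "Survival time-correlation function") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    tt <- seq(0, max(object$t), length.out = 200L)
    pred <- tibble::tibble(
      t = tt,
      sigma = fit$A * exp(-tt / fit$theta1) + fit$B * exp(-tt / fit$theta2)
    )
    p <- p + ggplot2::geom_line(data = pred, colour = "#B2182B",
                                linetype = 2)
  }
  p
}

#' Plot a lateral RDF profile
#'
#' @param object An `rdf_profile`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.rdf_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::as_tibble(object),
                  ggplot2::aes(.data$r_mid, .data$g)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "lateral distance from protein (nm)", y = "g(r)",
      title = paste0(attr(object, "species") %||% "", " (",
                     attr(object, "leaflet") %||% "", " leaflet) lateral RDF")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a site partition as a weighted residue graph summary
#'
#' One bar per detected site showing its total internal edge weight.
#'
#' @param object A `site_partition`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.site_partition <- function(object, ...) {
  df <- dplyr::as_tibble(object)
  df$label <- vapply(df$residues, function(r) paste(r, collapse = "\n"),
                     character(1L))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$site_id),
                                   .data$total_weight)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.1,
                       size = 2.8, lineheight = 0.85) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(c(0, 0.35))) +
    ggplot2::labs(x = "interaction site", y = "internal co-contact weight",
                  title = paste0(attr(object, "species") %||% "",
                                 " interaction sites")) +
    ggplot2::theme_minimal()
}
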