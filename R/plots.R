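# ggplot2 autoplot methods for the main result types.

#' Plot a per-site variance profile
#'
#' Points per covered position, coloured by variance bin, on a square-root
#' scale that keeps the sub-1% floor visible next to genuine variants.
#'
#' @param object A `variance_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variance_profile <- function(object, ...) {
  df <- object[!is.na(object$variance), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$variance,
                                   colour = .data$bin)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_sqrt(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "position (0-based)", y = "per-site variance",
                  colour = "bin") +
    ggplot2::theme_minimal()
}

#' Plot per-locus copy-number ratios
#'
#' @param object A `copy_number_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.copy_number_estimate <- function(object, ...) {
  df <- object$per_locus[object$per_locus$used, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = object$mean_copy_number,
                        linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "nrDNA depth / locus depth",
                  title = sprintf("copy number %.1f (SD %.1f)",
                                  object$mean_copy_number,
                                  object$sd_copy_number)) +
    ggplot2::theme_minimal()
}

#' Plot an intron presence/absence matrix
#'
#' Grey-filled tiles mark intron presence per taxon, mirroring the usual
#' presentation of intron patterns next to a phylogeny.
#'
#' @param object An `intron_presence_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.intron_presence_matrix <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"taxon",
                            names_to = "intron", values_to = "present")
  df$intron <- factor(df$intron, levels = setdiff(names(object), "taxon"))
  df$state <- dplyr::case_when(is.na(df$present) ~ "unknown",
                               df$present ~ "present", TRUE ~ "absent")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$intron, y = .data$taxon,
                                   fill = .data$state)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(present = "grey35",
                                          absent = "grey92",
                                          unknown = "goldenrod")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
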