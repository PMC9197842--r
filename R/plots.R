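#' Saddle plot
#'
#' Visualizes a saddle matrix (O/E reordered by A-B index and aggregated)
#' as a heat map: strong compartmentalization shows as bright same-class
#' corners.
#'
#' @param saddle Matrix from [saddle_matrix()].
#' @return A ggplot object.
#' @export
plot_saddle <- function(saddle) {
  df <- tidyr::expand_grid(row = seq_len(nrow(saddle)),
                           col = seq_len(ncol(saddle)))
  df$value <- saddle[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = log2(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "A-B index quantile (low → high)",
                  y = "A-B index quantile", fill = "log2 O/E") +
    ggplot2::theme_minimal()
}

#' Plot a bin track along the chromosome
#'
#' @param track Tibble with `bin` and a value column (`value`, `ab_index`,
#'   `di` or `is`).
#' @param value_col Which column to plot (default auto-detected).
#' @return A ggplot object.
#' @export
plot_track <- function(track, value_col = NULL) {
  if (is.null(value_col)) {
    value_col <- intersect(c("value", "ab_index", "di", "is", "vne"),
                           names(track))[1]
  }
  ggplot2::ggplot(track, ggplot2::aes(.data$bin, .data[[value_col]])) +
    ggplot2::geom_area(ggplot2::aes(
      fill = .data[[value_col]] > 0), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "#2166ac")) +
    ggplot2::labs(x = "bin", y = value_col) +
    ggplot2::theme_minimal()
}

#' Phase portrait of form vs function
#'
#' Plots each stage of each chromosome in the (Fiedler number, mean TPM)
#' plane after per-chromosome z-normalization, connecting consecutive
#' stages.
#'
#' @param points Tibble with `chrom`, `stage`, `fn`, `expr` (as for
#'   [phase_distance()]).
#' @return A ggplot object.
#' @export
plot_phase_portrait <- function(points) {
  znorm <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  df <- points |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(fn_z = znorm(.data$fn), expr_z = znorm(.data$expr)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$fn_z, .data$expr_z,
                                   group = .data$chrom)) +
    ggplot2::geom_path(alpha = 0.5, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$stage)),
                        size = 2) +
    ggplot2::labs(x = "Fiedler number (z)", y = "mean TPM (z)",
                  colour = "stage") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a VNE result
#'
#' @param x A `vne_result`.
#' @param ... Unused.
#' @return A one-row tibble with `vne`, `n`, `max_vne`.
#' @export
tidy.vne_result <- function(x, ...) {
  tibble::tibble(vne = x$vne, n = x$n, max_vne = log(x$n))
}

#' Tidy a compartmentalization strength result
#'
#' @param x A `strength_result`.
#' @param ... Unused.
#' @return A one-row tibble with `AA`, `BB`, `AB`, `strength`.
#' @export
tidy.strength_result <- function(x, ...) {
  tibble::tibble(AA = x$AA, BB = x$BB, AB = x$AB, strength = x$strength)
}

#' Glance at a contact map
#'
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return A one-row tibble with `chrom`, `n_bins`, `bin_size`,
#'   `n_masked`, `state`, `total`.
#' @export
glance.contact_map <- function(x, ...) {
  tibble::tibble(chrom = x$chrom, n_bins = nrow(x$mat),
                 bin_size = x$binning$bin_size, n_masked = sum(x$mask),
                 state = x$state, total = sum(x$mat) / 2)
}
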