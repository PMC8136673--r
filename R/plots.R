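# ggplot2 views of the result types; numerical tables remain the tested
# surface, figures are a convenience layer.

#' Plot genotypic values and per-background regression lines
#'
#' Genotypic values against A1 dosage, point area proportional to genotype
#' frequency, with the weighted least-squares line for each locus-B
#' background (and optionally the marginal line, dashed). Parallel lines
#' mean no additive-by-additive epistasis between the loci.
#'
#' @param model A `two_locus` model.
#' @param marginal Add the marginal (all-backgrounds) line.
#' @return A ggplot object.
#' @export
plot_background_regressions <- function(model, marginal = TRUE) {
  stopifnot(inherits(model, "two_locus"))
  pts <- tidy(model)
  pts$background <- c("B2B2", "B1B2", "B1B1")[pts$dosage_B + 1]
  fits <- background_regressions(model)
  lines <- dplyr::filter(fits, .data$background != "marginal")
  gg <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$dosage_A,
                                          y = .data$value,
                                          colour = .data$background)) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$background)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$frequency)) +
    ggplot2::scale_colour_manual(
      values = c(B2B2 = "black", B1B2 = "red", B1B1 = "blue")) +
    ggplot2::scale_x_continuous(breaks = 0:2) +
    ggplot2::labs(x = "A1 allele dosage", y = "Genotypic value",
                  colour = "Locus B genotype", size = "Frequency")
  if (marginal) {
    mg <- dplyr::filter(fits, .data$background == "marginal")
    gg <- gg + ggplot2::geom_abline(intercept = mg$intercept,
                                    slope = mg$slope, linetype = "dashed")
  }
  gg
}

#' Plot a single-locus partition table
#'
#' Genotypic values against dosage with the additive regression line whose
#' fitted values are the breeding values (plus population mean); vertical
#' segments show the dominance deviations.
#'
#' @param model A [single_locus()] model.
#' @return A ggplot object.
#' @export
plot_partition <- function(model) {
  tb <- partition_table(model)
  M <- pop_mean(model)
  alpha <- unname(average_effects(model))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$dosage, y = .data$value)) +
    ggplot2::geom_abline(intercept = M - alpha * 2 * model$p,
                         slope = alpha, colour = "grey40") +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$dosage,
                   yend = .data$value - .data$dominance_deviation),
      linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(size = .data$frequency)) +
    ggplot2::scale_x_continuous(breaks = 0:2) +
    ggplot2::labs(x = "A1 allele dosage", y = "Genotypic value",
                  size = "Frequency")
}

#' Plot a frequency surface
#'
#' Line plot over `p` for single-locus (or diagonal) scans, or a `p x q`
#' heat map for full two-locus grids.
#'
#' @param surface A [frequency_surface()] tibble.
#' @param what Column to display (default `"ratio_A"`).
#' @return A ggplot object.
#' @export
plot_surface <- function(surface, what = "ratio_A") {
  stopifnot(what %in% names(surface))
  if (!"q" %in% names(surface) || all(surface$p == surface$q)) {
    return(
      ggplot2::ggplot(surface,
                      ggplot2::aes(x = .data$p, y = .data[[what]])) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "Allele frequency", y = what)
    )
  }
  ggplot2::ggplot(surface, ggplot2::aes(x = .data$p, y = .data$q,
                                        fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "p (A1 frequency)", y = "q (B1 frequency)",
                  fill = what)
}
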