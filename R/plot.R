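#' Plot bubbles over the branch lattice of the R-HDS plane
#'
#' Branches are drawn as curves parametrized by prevalence and labeled
#' by genotype at their full-prevalence tip; bubbles are sized by
#' segment length and colored by chromosome.
#'
#' @param bubbles Bubble table (adjusted column `r_adj` used when
#'   present, else `r_raw`).
#' @param max_total_copy Branch lattice bound on `x + y` (default 5 for
#'   a readable plot).
#' @param tick_step Prevalence tick spacing along the branches (default
#'   0.05).
#' @return A ggplot object.
#' @export
plot_rhds <- function(bubbles = NULL, max_total_copy = 5,
                      tick_step = 0.05) {
  br <- build_branches(max_total_copy,
                       prevalence_ticks = seq(0.01, 1, by = 0.01))
  ticks <- br[abs(br$p / tick_step - round(br$p / tick_step)) < 1e-9, ]
  tips <- br[br$p == 1, ]
  gg <- ggplot2::ggplot() +
    ggplot2::geom_path(data = br,
                       ggplot2::aes(x = .data$r, y = .data$hds,
                                    group = .data$genotype),
                       color = "grey55", linewidth = 0.3) +
    ggplot2::geom_point(data = ticks,
                        ggplot2::aes(x = .data$r, y = .data$hds),
                        color = "grey55", size = 0.4) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$r, y = .data$hds,
                                    label = .data$genotype),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "copy ratio R", y = "HDS = |BAF - 0.5|") +
    ggplot2::theme_minimal()
  if (!is.null(bubbles) && nrow(bubbles) > 0) {
    b <- bubbles
    b$r_plot <- if ("r_adj" %in% names(b) && !all(is.na(b$r_adj)))
      b$r_adj else b$r_raw
    b$chrom <- factor(b$chrom, levels = unique(
      b$chrom[order(chrom_rank(b$chrom))]))
    gg <- gg +
      ggplot2::geom_point(data = b,
                          ggplot2::aes(x = .data$r_plot,
                                       y = .data$hds_median,
                                       size = .data$length_bp,
                                       color = .data$chrom),
                          alpha = 0.65) +
      ggplot2::scale_size_area(max_size = 10, guide = "none") +
      ggplot2::scale_color_viridis_d(name = "chromosome")
  }
  gg
}
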