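# Static figure helpers. Plots are side effects only; no quantitative
# output ever depends on them.

#' Volcano plot of GSEA results
#'
#' NES against -log10 nominal p with threshold lines at +/- `nes_min`;
#' enriched sets red, depleted blue.
#'
#' @param results A [volcano_table()] data frame.
#' @param nes_min,p_max Thresholds to draw, defaults 1 and 0.05.
#' @param file Optional PNG path; plots to the active device when NULL.
#' @return Invisibly, `file`.
#' @export
plot_gsea_volcano <- function(results, nes_min = 1, p_max = 0.05,
                              file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 800, height = 600)
  logp <- -log10(pmax(results$p, 1e-4))
  col <- ifelse(results$nes > nes_min & results$p < p_max, "red3",
                ifelse(results$nes < -nes_min & results$p < p_max,
                       "blue3", "grey60"))
  graphics::plot(results$nes, logp, pch = 19, col = col,
                 xlab = "normalized enrichment score (NES)",
                 ylab = "-log10 nominal p")
  graphics::abline(v = c(-nes_min, nes_min), lty = 2)
  graphics::abline(h = -log10(p_max), lty = 3)
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}

#' Spectrum arrow plot (2D projections of the 3D vectors)
#'
#' Draws the xy, xz and yz projections of the cluster displacement vectors
#' as arrows from the baseline origin.
#'
#' @param vectors A [spectrum_vectors()] table.
#' @param file Optional PNG path.
#' @return Invisibly, `file`.
#' @export
plot_spectrum <- function(vectors, file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 1200, height = 420)
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op), add = TRUE)
  proj <- list(c("x", "y"), c("x", "z"), c("y", "z"))
  for (ax in proj) {
    lim <- range(c(vectors[[ax[1]]], vectors[[ax[2]]], 0)) * 1.2
    graphics::plot(0, 0, type = "n", xlim = lim, ylim = lim,
                   xlab = ax[1], ylab = ax[2], asp = 1)
    graphics::arrows(0, 0, vectors[[ax[1]]], vectors[[ax[2]]],
                     length = 0.08, col = vectors$cluster + 1)
    graphics::text(vectors[[ax[1]]], vectors[[ax[2]]],
                   vectors$cluster, pos = 3, cex = 0.8)
  }
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}

#' Module-eigengene / condition correlation heatmap
#'
#' @param mt A [module_trait_correlation()] result.
#' @param file Optional PNG path.
#' @return Invisibly, `file`.
#' @export
plot_module_trait <- function(mt, file = NULL) {
  if (!is.null(file)) grDevices::png(file, width = 800, height = 600)
  pal <- grDevices::colorRampPalette(c("blue3", "white", "orange2"))(101)
  graphics::image(t(mt$r[rev(seq_len(nrow(mt$r))), , drop = FALSE]),
                  col = pal, zlim = c(-1, 1), axes = FALSE)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(mt$r)),
                 labels = colnames(mt$r), las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(mt$r)),
                 labels = rev(rownames(mt$r)), las = 1, cex.axis = 0.8)
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}
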