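# Chromosome track plots: one horizontal lane per breed, island boxes,
# vertical gene lines.  Tests assert on the returned layout description, not
# on pixels.

#' Plot ROH islands along a chromosome
#'
#' One horizontal lane per breed carrying island boxes; optional gene
#' intervals are drawn as vertical lines at their midpoints with labels, and
#' optional overlap regions as shaded spans. Deterministic layout: lanes in
#' breed order of first appearance, bottom to top.
#'
#' @param islands Island data frame (breed, chrom, start_bp, end_bp).
#' @param overlap_regions Optional regions data frame from
#'   \code{\link{cross_breed_overlaps}}.
#' @param genes Optional annotation data frame (gene, chrom, start_bp,
#'   end_bp).
#' @param chrom Chromosome to draw.
#' @param range_bp Optional length-2 vector restricting the bp range.
#' @param ... Additional arguments passed to \code{plot}.
#' @return Invisibly, a list describing the layout: \code{lanes} (breed ->
#'   lane y), \code{boxes} (one row per drawn island), \code{gene_lines}
#'   (one row per drawn gene), \code{chrom}, \code{range_bp}.
#' @export
plot_tracks <- function(islands, overlap_regions = NULL, genes = NULL,
                        chrom, range_bp = NULL, ...) {
  isl <- islands[islands$chrom == chrom, , drop = FALSE]
  if (!is.null(range_bp))
    isl <- isl[isl$end_bp >= range_bp[1] & isl$start_bp <= range_bp[2], ,
               drop = FALSE]
  gen <- if (!is.null(genes)) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (!is.null(range_bp))
      g <- g[g$end_bp >= range_bp[1] & g$start_bp <= range_bp[2], ,
             drop = FALSE]
    g
  } else NULL
  breeds <- unique(isl$breed)
  lanes <- stats::setNames(seq_along(breeds), breeds)
  xr <- range_bp %||% (if (nrow(isl)) c(min(isl$start_bp), max(isl$end_bp))
                       else c(0, 1))
  graphics::plot(NA, xlim = xr / 1e6, ylim = c(0.5, max(1, length(lanes)) + 0.5),
                 xlab = sprintf("chr%s position (Mb)", chrom), ylab = "",
                 yaxt = "n", ...)
  if (length(lanes))
    graphics::axis(2, at = unname(lanes), labels = names(lanes), las = 2,
                   cex.axis = 0.7)
  if (!is.null(overlap_regions) && nrow(overlap_regions)) {
    reg <- overlap_regions[overlap_regions$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(reg)))
      graphics::rect(reg$start_bp[k] / 1e6, 0.5, reg$end_bp[k] / 1e6,
                     length(lanes) + 0.5,
                     col = grDevices::adjustcolor("gold", 0.2), border = NA)
  }
  boxes <- isl
  if (nrow(isl)) {
    for (k in seq_len(nrow(isl))) {
      y <- lanes[[isl$breed[k]]]
      graphics::rect(isl$start_bp[k] / 1e6, y - 0.3, isl$end_bp[k] / 1e6,
                     y + 0.3, col = "steelblue", border = "black")
    }
  }
  gene_lines <- NULL
  if (!is.null(gen) && nrow(gen)) {
    mids <- (gen$start_bp + gen$end_bp) / 2
    graphics::abline(v = mids / 1e6, col = "firebrick", lty = 2)
    graphics::mtext(gen$gene, side = 3, at = mids / 1e6, cex = 0.6,
                    col = "firebrick", las = 2)
    gene_lines <- data.frame(gene = gen$gene, mid_bp = mids)
  }
  invisible(list(lanes = lanes, boxes = boxes, gene_lines = gene_lines,
                 chrom = chrom, range_bp = xr))
}
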