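## Minimal overlay rendering: contact heatmap with stripe rectangles and
## seed marks for a genomic region.

#' Plot called stripes over the contact heatmap
#'
#' Renders the symmetrized contact matrix of a genomic region (log1p color
#' scale), overlays the horizontal x vertical rectangle of every called
#' stripe intersecting the region, and marks seed sites on the diagonal.
#' The returned metadata carries the rectangle coordinates actually drawn,
#' in bp, which map back exactly to the archive's bin geometry.
#'
#' @param x A `stripe_call` object or archive path.
#' @param band A raw [contact_band()] with the underlying contacts (either
#'   triangle; the map is symmetrized for display).
#' @param start,end Region in bp (0-based half-open, within the chromosome).
#' @param path Optional PNG output path; when `NULL`, draws on the active
#'   device.
#' @param rel_change Optional relative-change filter applied before drawing.
#' @return Invisibly, a list with `path`, `region` and `rectangles` (data
#'   frame with bp coordinates `start1`, `end1`, `start2`, `end2`,
#'   `triangle`, `seed_pos`).
#' @export
plot_stripes <- function(x, band, start, end, path = NULL, rel_change = NULL) {
  if (is.character(x)) x <- read_archive(x)
  stopifnot(inherits(x, "stripe_call"), inherits(band, "contact_band"))
  bins <- x$bins
  res <- bins$resolution
  if (end <= start || start < 0 || start >= bins$length) {
    stop(sprintf("empty or out-of-range region [%s, %s) on %s",
                 format(start), format(end), bins$chrom))
  }
  end <- min(end, bins$length)
  b0 <- as.integer(start %/% res)
  b1 <- as.integer((end - 1) %/% res)
  nb <- b1 - b0 + 1L

  dense <- matrix(0, nb, nb)
  e <- band$entries
  sel <- e$row >= b0 & e$row <= b1 & e$col >= b0 & e$col <= b1
  if (any(sel)) {
    ri <- e$row[sel] - b0 + 1L
    ci <- e$col[sel] - b0 + 1L
    dense[cbind(ri, ci)] <- e$count[sel]
    dense[cbind(ci, ri)] <- e$count[sel]
  }

  st <- stripe_table(x, rel_change = rel_change)
  st <- st[st$right_bin >= b0 & st$left_bin <= b1 &
             st$bottom_bin >= b0 & st$top_bin <= b1, , drop = FALSE]
  rect_df <- data.frame(
    start1 = st$left_bin * res, end1 = (st$right_bin + 1) * res,
    start2 = st$top_bin * res, end2 = (st$bottom_bin + 1) * res,
    triangle = st$triangle, seed_pos = st$seed_bin * res,
    stringsAsFactors = FALSE
  )

  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  xs <- (b0:(b1 + 1L)) * res
  pal <- grDevices::hcl.colors(64, "Reds", rev = TRUE)
  ## image() draws column-major with y up; flip so the diagonal runs as in a
  ## contact map (genomic coordinates on both axes)
  graphics::image(xs, xs, log1p(dense), col = pal, useRaster = TRUE,
                  xlab = sprintf("%s (bp)", bins$chrom),
                  ylab = sprintf("%s (bp)", bins$chrom),
                  main = sprintf("%s:%s-%s", bins$chrom,
                                 format(start, big.mark = ","),
                                 format(end, big.mark = ",")))
  if (nrow(rect_df)) {
    col <- ifelse(rect_df$triangle == "lower", "#2166ac", "#1a9850")
    graphics::rect(rect_df$start1, rect_df$start2, rect_df$end1, rect_df$end2,
                   border = col, lwd = 2)
    graphics::points(rect_df$seed_pos + res / 2, rect_df$seed_pos + res / 2,
                     pch = 4, col = col, cex = 1.2)
  }
  invisible(list(path = path, region = c(start = start, end = end),
                 rectangles = rect_df))
}
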