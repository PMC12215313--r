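## BEDPE export of called stripes.
##
## Column semantics (documented in the output header): interval 1 is the
## stripe's horizontal domain (its width along the diagonal), interval 2 its
## vertical extent (height away from the diagonal); both are 0-based
## half-open bp intervals on the same chromosome. Three extra columns carry
## the triangle, the seed position (bp, interval start) and the relative
## change in percent.

stripes_to_bedpe <- function(stripes, bins) {
  res <- bins$resolution
  clip <- function(bp) pmin(bp, bins$length)
  data.frame(
    chrom1 = rep(bins$chrom, nrow(stripes)),
    start1 = stripes$left_bin * res,
    end1 = clip((stripes$right_bin + 1) * res),
    chrom2 = rep(bins$chrom, nrow(stripes)),
    start2 = stripes$top_bin * res,
    end2 = clip((stripes$bottom_bin + 1) * res),
    triangle = stripes$triangle,
    seed_pos = stripes$seed_bin * res,
    relative_change = stripes$relative_change,
    stringsAsFactors = FALSE
  )
}

#' Export called stripes as BEDPE
#'
#' Writes one BEDPE line per stripe surviving the relative-change filter to
#' `file` (standard output by default). Raising the threshold can only
#' shrink the output; rows keep the archive's order.
#'
#' @param x A `stripe_call` object or the path of an archive written by
#'   [write_archive()].
#' @param rel_change Relative-change threshold in percent (`NULL` = no
#'   filtering). Recommended: 4 for simulated maps, 3 for real maps.
#' @param file A connection or file path; default standard output.
#' @return Invisibly, the exported data frame (possibly zero rows).
#' @export
view_stripes <- function(x, rel_change = NULL, file = stdout()) {
  if (is.character(x)) x <- read_archive(x)
  stopifnot(inherits(x, "stripe_call"))
  st <- stripe_table(x, rel_change = rel_change)
  bed <- stripes_to_bedpe(st, x$bins)
  lines <- c(
    "# BEDPE: interval1 = horizontal domain (width), interval2 = vertical extent (height); 0-based half-open bp",
    "# extra columns: triangle, seed_pos (bp), relative_change (%)",
    sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%.6g",
            bed$chrom1, as.integer(bed$start1), as.integer(bed$end1),
            bed$chrom2, as.integer(bed$start2), as.integer(bed$end2),
            bed$triangle, as.integer(bed$seed_pos), bed$relative_change)
  )
  writeLines(lines, con = file)
  invisible(bed)
}

#' Read stripes from a BEDPE file
#'
#' Understands both the dialect written by [view_stripes()] (9 columns) and
#' bare 6-column BEDPE. For bare files the triangle is inferred from the two
#' intervals (interval 2 extending past interval 1 = lower) and the seed is
#' taken as the midpoint of interval 1.
#'
#' @param path BEDPE file path.
#' @param resolution Bin size in bp used to convert coordinates to bins.
#' @return Data frame with columns `chrom`, `triangle`, `seed_bin`,
#'   `left_bin`, `right_bin`, `top_bin`, `bottom_bin`, `relative_change`
#'   (NA for bare BEDPE).
#' @export
read_bedpe <- function(path, resolution) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), triangle = character(),
                      seed_bin = integer(), left_bin = integer(),
                      right_bin = integer(), top_bin = integer(),
                      bottom_bin = integer(), relative_change = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1L || !ncol %in% c(6L, 9L)) {
    stop(sprintf("unrecognized BEDPE layout in %s (expected 6 or 9 columns)", path))
  }
  m <- do.call(rbind, parts)
  start1 <- as.numeric(m[, 2]); end1 <- as.numeric(m[, 3])
  start2 <- as.numeric(m[, 5]); end2 <- as.numeric(m[, 6])
  if (ncol == 9L) {
    triangle <- m[, 7]
    seed_bin <- as.integer(as.numeric(m[, 8]) %/% resolution)
    rc <- as.numeric(m[, 9])
  } else {
    triangle <- ifelse(end2 > end1, "lower", "upper")
    seed_bin <- as.integer(((start1 + end1) / 2) %/% resolution)
    rc <- rep(NA_real_, nrow(m))
  }
  data.frame(
    chrom = m[, 1],
    triangle = triangle,
    seed_bin = seed_bin,
    left_bin = as.integer(start1 %/% resolution),
    right_bin = as.integer((end1 - 1) %/% resolution),
    top_bin = as.integer(start2 %/% resolution),
    bottom_bin = as.integer((end2 - 1) %/% resolution),
    relative_change = rc,
    stringsAsFactors = FALSE
  )
}
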