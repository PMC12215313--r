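## Banded sparse views of a chromosome's contact matrix.
##
## All bin indices are 0-based; genomic intervals derived from them are
## 0-based half-open, as in BED/BEDPE. The two triangles share the main
## diagonal: the lower band stores cells with row >= col, the upper band
## cells with row <= col, both within |row - col| <= bandwidth_bins.

#' Bin table for one chromosome
#'
#' Describes the fixed-resolution binning of a chromosome: chromosome name,
#' length in bp, bin size in bp, and the implied number of bins
#' (`ceiling(length / resolution)`).
#'
#' @param chrom Chromosome name.
#' @param length Chromosome length in bp (> 0).
#' @param resolution Bin size in bp (> 0).
#' @return An object of class `bin_table`.
#' @examples
#' bin_table("chr1", 2.5e6, 10e3)
#' @export
bin_table <- function(chrom, length, resolution) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  length <- as.numeric(length)
  resolution <- as.numeric(resolution)
  if (!is.finite(length) || length <= 0) stop("chromosome length must be > 0")
  if (!is.finite(resolution) || resolution <= 0) stop("resolution must be > 0")
  structure(
    list(
      chrom = chrom,
      length = length,
      resolution = resolution,
      n_bins = as.integer(ceiling(length / resolution))
    ),
    class = "bin_table"
  )
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf(
    "<bin_table> %s: %s bp at %s bp/bin (%d bins)\n",
    x$chrom, format(x$length, big.mark = ","),
    format(x$resolution, big.mark = ","), x$n_bins
  ))
  invisible(x)
}

#' Construct a banded triangular contact matrix view
#'
#' A `contact_band` holds the nonzero contacts of one triangle of a
#' chromosome's contact matrix, restricted to a band around the main
#' diagonal. Entries outside the band or the stated triangle are rejected;
#' explicit zeros are dropped; duplicate cells are summed.
#'
#' @param bins A [bin_table()].
#' @param bandwidth_bins Band half-width in bins (>= 0): only cells with
#'   `|row - col| <= bandwidth_bins` are kept.
#' @param triangle `"lower"` (row >= col) or `"upper"` (row <= col).
#' @param entries A data frame with integer columns `row`, `col` (0-based bin
#'   indices) and numeric `count` (>= 0).
#' @return An object of class `contact_band`.
#' @export
contact_band <- function(bins, bandwidth_bins, triangle = c("lower", "upper"),
                         entries = data.frame(row = integer(), col = integer(),
                                              count = numeric())) {
  triangle <- match.arg(triangle)
  stopifnot(inherits(bins, "bin_table"))
  bandwidth_bins <- as.integer(bandwidth_bins)
  stopifnot(length(bandwidth_bins) == 1L, bandwidth_bins >= 0L)
  stopifnot(is.data.frame(entries), all(c("row", "col", "count") %in% names(entries)))

  row <- as.integer(entries$row)
  col <- as.integer(entries$col)
  count <- as.numeric(entries$count)
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("contact counts must be finite and nonnegative")
  }
  n <- bins$n_bins
  if (length(row) && (min(row, col) < 0L || max(row, col) >= n)) {
    stop(sprintf("bin indices must lie in [0, %d)", n))
  }
  bad_tri <- if (triangle == "lower") any(row < col) else any(row > col)
  if (bad_tri) stop(sprintf("entries must lie in the %s triangle", triangle))
  if (length(row) && max(abs(row - col)) > bandwidth_bins) {
    stop("entries outside the diagonal band")
  }

  keep <- count > 0
  e <- data.frame(row = row[keep], col = col[keep], count = count[keep])
  if (anyDuplicated(e[c("row", "col")])) {
    key <- paste(e$row, e$col)
    cnt <- rowsum(e$count, key, reorder = FALSE)
    first <- !duplicated(key)
    e <- data.frame(row = e$row[first], col = e$col[first], count = cnt[, 1L])
  }
  e <- e[order(e$col, e$row), , drop = FALSE]
  rownames(e) <- NULL

  structure(
    list(bins = bins, bandwidth_bins = bandwidth_bins, triangle = triangle,
         entries = e),
    class = "contact_band"
  )
}

#' @export
print.contact_band <- function(x, ...) {
  cat(sprintf(
    "<contact_band> %s triangle of %s: %d nonzero cells, band %d bins%s\n",
    x$triangle, x$bins$chrom, nrow(x$entries), x$bandwidth_bins,
    if (isTRUE(attr(x, "preprocessed"))) " (log1p/max-rescaled)" else ""
  ))
  invisible(x)
}

#' Transpose a contact band into the opposite triangle
#'
#' Mirrors every cell `(row, col)` to `(col, row)`; the diagonal is shared by
#' the two triangles.
#'
#' @param band A [contact_band()].
#' @return The mirrored `contact_band`.
#' @export
band_transpose <- function(band) {
  stopifnot(inherits(band, "contact_band"))
  out <- contact_band(
    band$bins, band$bandwidth_bins,
    triangle = if (band$triangle == "lower") "upper" else "lower",
    entries = data.frame(row = band$entries$col, col = band$entries$row,
                         count = band$entries$count)
  )
  attr(out, "preprocessed") <- attr(band, "preprocessed")
  out
}

empty_band_error <- function(chrom, triangle) {
  stop(errorCondition(
    sprintf("contact band is empty (%s triangle of %s): skipping", triangle, chrom),
    class = c("hicstripes_empty_band", "hicstripes_error")
  ))
}

#' Preprocess a raw contact band
#'
#' Applies the caller's first step: each raw count `v` is mapped to
#' `log(1 + v)` and the transformed band is divided by its maximum, so values
#' lie in `[0, 1]` with at least one cell equal to 1. The transform is
#' strictly monotone, hence the ordering of cell values is preserved.
#'
#' `log1p` is used (rather than a plain log) because banded contact matrices
#' are dominated by empty cells; max-rescaling (rather than min-max) keeps the
#' denominator well defined when all stored counts are equal.
#'
#' @param band A raw [contact_band()].
#' @return A `contact_band` whose `count` column holds the rescaled values and
#'   with attribute `preprocessed = TRUE`.
#' @export
preprocess <- function(band) {
  stopifnot(inherits(band, "contact_band"))
  if (nrow(band$entries) == 0L || all(band$entries$count == 0)) {
    empty_band_error(band$bins$chrom, band$triangle)
  }
  v <- log1p(band$entries$count)
  band$entries$count <- v / max(v)
  attr(band, "preprocessed") <- TRUE
  band
}

bp_to_bins <- function(bp, resolution) max(0L, as.integer(bp %/% resolution))

## ---------------------------------------------------------------------------
## Loading

#' Load a chromosome's contact band pair from a file
#'
#' Reads raw (unbalanced) contacts for one chromosome from a cooler file
#' (`.cool` / `.mcool`) or from the plain-text COO fixture dialect (any other
#' extension), restricts them to a diagonal band, and returns both triangular
#' views. Contact maps are symmetric and typically stored upper-triangular;
#' the lower band is reconstructed by mirroring, so `lower` and `upper` are
#' transposes of each other and share the diagonal.
#'
#' The text dialect is tab-separated `bin1 bin2 count` preceded by a header
#' line `#resolution=<bp> chrom=<name> length=<bp>`.
#'
#' @param path Path to a `.cool`, `.mcool` or text COO file.
#' @param resolution Bin size in bp. Mandatory for `.mcool`; for
#'   single-resolution files it is checked against the file when supplied.
#' @param chromosome Chromosome to load. Defaults to the only/first chromosome
#'   in the file; an unknown name is an error.
#' @param band_width Band half-width in bp around the diagonal
#'   (default 5 Mbp, an upper bound on mammalian TAD sizes).
#' @param use_balanced If `TRUE` and the file stores balancing weights, apply
#'   them; raw counts are the default since the detection method works best on
#'   unbalanced maps.
#' @return A list with elements `lower` and `upper` ([contact_band()]s).
#' @export
load_contacts <- function(path, resolution = NULL, chromosome = NULL,
                          band_width = 5e6, use_balanced = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.(cool|mcool)$", path, ignore.case = TRUE)) {
    parsed <- read_cooler(path, resolution, chromosome, use_balanced)
  } else {
    if (use_balanced) stop("balancing weights are not available in text fixtures")
    parsed <- read_coo_fixture(path, resolution, chromosome)
  }
  bins <- parsed$bins
  bw <- min(bins$n_bins - 1L, bp_to_bins(band_width, bins$resolution))
  bw <- max(bw, 0L)

  ## fold everything into the lower triangle, then band-restrict
  r <- pmax(parsed$row, parsed$col)
  c <- pmin(parsed$row, parsed$col)
  keep <- (r - c) <= bw
  lower <- contact_band(bins, bw, "lower",
                        data.frame(row = r[keep], col = c[keep],
                                   count = parsed$count[keep]))
  list(lower = lower, upper = band_transpose(lower))
}

read_coo_fixture <- function(path, resolution, chromosome) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec(
    "^#\\s*resolution=([0-9]+)\\s+chrom=(\\S+)\\s+length=([0-9]+)\\s*$", first))[[1]]
  if (length(m) != 4L) {
    stop(sprintf(
      "not a contact fixture: expected header '#resolution=<bp> chrom=<name> length=<bp>' in %s",
      path))
  }
  file_res <- as.numeric(m[2]); chrom <- m[3]; len <- as.numeric(m[4])
  if (!is.null(resolution) && as.numeric(resolution) != file_res) {
    stop(sprintf("resolution %s not found in %s; available: %s",
                 format(resolution), path, format(file_res)))
  }
  if (!is.null(chromosome) && chromosome != chrom) {
    stop(sprintf("chromosome '%s' not present in %s; available: %s",
                 chromosome, path, chrom))
  }
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("bin1", "bin2", "count"),
                           colClasses = c("integer", "integer", "numeric"))
  list(bins = bin_table(chrom, len, file_res),
       row = tab$bin1, col = tab$bin2, count = tab$count)
}

read_cooler <- function(path, resolution, chromosome, use_balanced) {
  ls <- rhdf5::h5ls(path, recursive = TRUE)
  root <- ""
  if (any(ls$group == "/" & ls$name == "resolutions")) {
    avail <- ls$name[ls$group == "/resolutions"]
    if (is.null(resolution)) {
      stop(sprintf("resolution must be given for %s; available: %s",
                   path, paste(sort(as.numeric(avail)), collapse = ", ")))
    }
    hit <- avail[as.numeric(avail) == as.numeric(resolution)]
    if (length(hit) != 1L) {
      stop(sprintf("resolution %s not found in %s; available: %s",
                   format(resolution), path,
                   paste(sort(as.numeric(avail)), collapse = ", ")))
    }
    root <- paste0("/resolutions/", hit)
  }
  h5 <- function(name) rhdf5::h5read(path, paste0(root, name), bit64conversion = "double")

  chrom_names <- as.character(h5("/chroms/name"))
  chrom_lens <- as.numeric(h5("/chroms/length"))
  bin_chrom <- h5("/bins/chrom")
  bin_start <- as.numeric(h5("/bins/start"))
  ## enum/int chrom column -> chromosome name per bin
  if (is.numeric(bin_chrom)) {
    bin_chrom <- chrom_names[as.integer(bin_chrom) + 1L]
  } else {
    bin_chrom <- as.character(bin_chrom)
  }
  file_res <- if (length(bin_start) > 1L) bin_start[2] - bin_start[1] else chrom_lens[1]
  if (!is.null(resolution) && as.numeric(resolution) != file_res && root == "") {
    stop(sprintf("resolution %s not found in %s; available: %s",
                 format(resolution), path, format(file_res)))
  }
  if (is.null(chromosome)) chromosome <- chrom_names[1]
  if (!chromosome %in% chrom_names) {
    stop(sprintf("chromosome '%s' not present in %s; available: %s",
                 chromosome, path, paste(chrom_names, collapse = ", ")))
  }
  len <- chrom_lens[match(chromosome, chrom_names)]
  bins <- bin_table(chromosome, len, file_res)

  bin_idx <- which(bin_chrom == chromosome)  # 1-based, contiguous
  b0 <- bin_idx[1] - 1L                      # 0-based offset of first bin
  b1 <- bin_idx[length(bin_idx)] - 1L

  offsets <- as.numeric(h5("/indexes/bin1_offset"))  # length n_bins_total + 1
  lo <- offsets[b0 + 1L] + 1L
  hi <- offsets[b1 + 2L]
  if (hi < lo) {
    return(list(bins = bins, row = integer(), col = integer(), count = numeric()))
  }
  idx <- list(lo:hi)
  p1 <- as.numeric(rhdf5::h5read(path, paste0(root, "/pixels/bin1_id"), index = idx,
                                 bit64conversion = "double"))
  p2 <- as.numeric(rhdf5::h5read(path, paste0(root, "/pixels/bin2_id"), index = idx,
                                 bit64conversion = "double"))
  cnt <- as.numeric(rhdf5::h5read(path, paste0(root, "/pixels/count"), index = idx,
                                  bit64conversion = "double"))
  keep <- p2 >= b0 & p2 <= b1
  p1 <- p1[keep] - b0; p2 <- p2[keep] - b0; cnt <- cnt[keep]

  if (use_balanced) {
    w_path <- paste0(root, "/bins/weight")
    has_w <- any(ls$name == "weight" & ls$group == paste0(root, "/bins"))
    if (!has_w) stop(sprintf("no balancing weights stored in %s", path))
    w <- as.numeric(rhdf5::h5read(path, w_path))[bin_idx]
    cnt <- cnt * w[p1 + 1L] * w[p2 + 1L]
    ok <- is.finite(cnt)
    p1 <- p1[ok]; p2 <- p2[ok]; cnt <- cnt[ok]
  }
  list(bins = bins, row = as.integer(p1), col = as.integer(p2), count = cnt)
}

#' List chromosomes stored in a contact file
#'
#' @param path A `.cool`/`.mcool` file or text COO fixture.
#' @param resolution Resolution to inspect (required for `.mcool`).
#' @return Named numeric vector of chromosome lengths (bp).
#' @export
list_chromosomes <- function(path, resolution = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.(cool|mcool)$", path, ignore.case = TRUE)) {
    ls <- rhdf5::h5ls(path)
    root <- ""
    if (any(ls$group == "/" & ls$name == "resolutions")) {
      avail <- ls$name[ls$group == "/resolutions"]
      if (is.null(resolution)) resolution <- as.numeric(avail[1])
      root <- paste0("/resolutions/", avail[as.numeric(avail) == as.numeric(resolution)][1])
    }
    nm <- as.character(rhdf5::h5read(path, paste0(root, "/chroms/name")))
    ln <- as.numeric(rhdf5::h5read(path, paste0(root, "/chroms/length")))
    stats::setNames(ln, nm)
  } else {
    first <- readLines(path, n = 1L)
    m <- regmatches(first, regexec(
      "^#\\s*resolution=([0-9]+)\\s+chrom=(\\S+)\\s+length=([0-9]+)\\s*$", first))[[1]]
    if (length(m) != 4L) stop(sprintf("unrecognized contact file: %s", path))
    stats::setNames(as.numeric(m[4]), m[3])
  }
}
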