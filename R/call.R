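## End-to-end stripe calling: preprocessing, seed detection, domain
## estimation and descriptors, run independently on the lower and upper
## triangles of each chromosome band.

#' Parameters of the stripe-calling pipeline
#'
#' Collects the tunable parameters with their defaults: a 5 Mbp diagonal
#' band (upper bound on mammalian TAD sizes), persistence threshold 0.04
#' (4% of the pseudo-distribution maximum), maximum stripe width 100 kb,
#' threshold-based vertical boundary with cutoff 0.1, moving-average
#' half-width 2 bins, and flanks as wide as the stripe for the descriptors.
#' The parameter set is stored verbatim in the results archive so a call can
#' be rerun deterministically.
#'
#' @param resolution Bin size in bp (may be `NULL` for single-resolution
#'   inputs).
#' @param band_width Diagonal band half-width in bp.
#' @param persistence_threshold Seed persistence threshold in `[0, 1]`.
#' @param max_width Maximum stripe width in bp.
#' @param vertical_criterion `"threshold"` or `"persistence"`.
#' @param min_value Vertical cutoff for the `threshold` criterion.
#' @param vd_persistence Persistence threshold for the vertical
#'   `persistence` criterion.
#' @param wma_half_width Moving-average kernel half-width in bins.
#' @param k_flank Flank width in bins for descriptors, or `"match-width"`
#'   to use the stripe's own width.
#' @param use_balanced Apply stored balancing weights when loading contacts.
#' @return An object of class `call_parameters`.
#' @export
call_parameters <- function(resolution = NULL, band_width = 5e6,
                            persistence_threshold = 0.04, max_width = 1e5,
                            vertical_criterion = c("threshold", "persistence"),
                            min_value = 0.1, vd_persistence = 0.04,
                            wma_half_width = 2L, k_flank = "match-width",
                            use_balanced = FALSE) {
  vertical_criterion <- match.arg(vertical_criterion)
  stopifnot(band_width > 0, persistence_threshold >= 0, max_width > 0,
            min_value >= 0, vd_persistence >= 0, wma_half_width >= 0)
  if (!identical(k_flank, "match-width")) {
    k_flank <- as.integer(k_flank)
    stopifnot(k_flank >= 1L)
  }
  structure(
    list(resolution = if (is.null(resolution)) NULL else as.numeric(resolution),
         band_width = as.numeric(band_width),
         persistence_threshold = as.numeric(persistence_threshold),
         max_width = as.numeric(max_width),
         vertical_criterion = vertical_criterion,
         min_value = as.numeric(min_value),
         vd_persistence = as.numeric(vd_persistence),
         wma_half_width = as.integer(wma_half_width),
         k_flank = k_flank,
         use_balanced = isTRUE(use_balanced)),
    class = "call_parameters"
  )
}

empty_triangle <- function(triangle, n_bins) {
  list(triangle = triangle,
       pseudodistribution = numeric(0),
       raw_marginal = numeric(0),
       seeds = data.frame(bin = integer(), persistence = numeric(),
                          essential = logical()),
       stripes = empty_stripe_frame())
}

empty_stripe_frame <- function() {
  data.frame(
    seed_bin = integer(), seed_persistence = numeric(),
    left_bin = integer(), right_bin = integer(),
    top_bin = integer(), bottom_bin = integer(),
    interior_peaks = character(),
    inner_min = numeric(), inner_q1 = numeric(), inner_median = numeric(),
    inner_q3 = numeric(), inner_max = numeric(), inner_mean = numeric(),
    inner_std = numeric(), outer_mean_left = numeric(),
    outer_mean_right = numeric(), outer_mean = numeric(),
    relative_change = numeric(),
    stringsAsFactors = FALSE
  )
}

## restrict a band to a column window; entries are sorted by column, so the
## window is found by binary search (the per-seed loops stay linear overall)
slice_band_cols <- function(band, c0, c1) {
  col <- band$entries$col
  i0 <- findInterval(c0 - 1L, col) + 1L
  i1 <- findInterval(c1, col)
  band$entries <- band$entries[seq.int(i0, length.out = max(0L, i1 - i0 + 1L)),
                               , drop = FALSE]
  band
}

call_triangle <- function(raw_band, params) {
  pre <- preprocess(raw_band)
  pd <- compute_pseudodistribution(pre, params$wma_half_width)
  seeds <- detect_seeds(pd, params$persistence_threshold)
  resolution <- raw_band$bins$resolution

  rows <- lapply(seq_len(nrow(seeds)), function(i) {
    hd <- estimate_horizontal_domain(pd, seeds$bin[i], params$max_width,
                                     resolution,
                                     tolerance = params$persistence_threshold)
    vd <- estimate_vertical_domain(
      slice_band_cols(pre, hd$left_bin, hd$right_bin), hd,
      params$vertical_criterion, params$vd_persistence, params$min_value)
    stripe <- list(left_bin = hd$left_bin, right_bin = hd$right_bin,
                   top_bin = vd$top_bin, bottom_bin = vd$bottom_bin)
    k <- if (identical(params$k_flank, "match-width")) NULL else params$k_flank
    k_used <- if (is.null(k)) hd$right_bin - hd$left_bin + 1L else k
    st <- compute_statistics(
      slice_band_cols(raw_band, hd$left_bin - k_used, hd$right_bin + k_used),
      stripe, k)
    c(list(seed_bin = seeds$bin[i], seed_persistence = seeds$persistence[i],
           left_bin = hd$left_bin, right_bin = hd$right_bin,
           top_bin = vd$top_bin, bottom_bin = vd$bottom_bin,
           interior_peaks = paste(vd$interior_peaks, collapse = ",")),
      st)
  })
  stripes <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    empty_stripe_frame()
  }
  rownames(stripes) <- NULL
  list(triangle = raw_band$triangle,
       pseudodistribution = pd$values,
       raw_marginal = pd$raw_marginal,
       seeds = seeds,
       stripes = stripes)
}

#' Call architectural stripes on a contact map
#'
#' Runs the full detection pipeline on both triangles of a chromosome's
#' banded contact matrix: log/max preprocessing, marginal
#' pseudo-distribution, persistent-maxima seed detection, horizontal and
#' vertical domain estimation, and raw-count descriptors including the
#' relative change. The result is deterministic given the input and
#' parameters. A triangle whose band is empty is skipped with a message.
#'
#' @param input Either a file path accepted by [load_contacts()] or a list
#'   with elements `lower` and `upper` ([contact_band()]s sharing one
#'   diagonal).
#' @param params A [call_parameters()] object.
#' @param quiet Suppress progress messages.
#' @return An object of class `stripe_call`: list with `chrom`, `bins`,
#'   `parameters` and `triangles` (per-triangle pseudo-distribution, seeds
#'   and stripe table). Use [stripe_table()] for a combined stripe data
#'   frame.
#' @export
call_stripes <- function(input, params = call_parameters(), quiet = FALSE) {
  stopifnot(inherits(params, "call_parameters"))
  if (is.character(input)) {
    bands <- load_contacts(input, resolution = params$resolution,
                           band_width = params$band_width,
                           use_balanced = params$use_balanced)
  } else {
    stopifnot(is.list(input), all(c("lower", "upper") %in% names(input)))
    bands <- input
  }
  bins <- bands$lower$bins
  if (is.null(params$resolution)) params$resolution <- bins$resolution

  triangles <- list()
  for (tri in c("lower", "upper")) {
    res <- tryCatch(
      call_triangle(bands[[tri]], params),
      hicstripes_empty_band = function(e) {
        if (!quiet) message(conditionMessage(e))
        empty_triangle(tri, bins$n_bins)
      }
    )
    if (!quiet) {
      message(sprintf("%s/%s: %d seeds, %d candidate stripes",
                      bins$chrom, tri, nrow(res$seeds), nrow(res$stripes)))
    }
    triangles[[tri]] <- res
  }
  structure(
    list(chrom = bins$chrom, bins = bins, parameters = params,
         triangles = triangles),
    class = "stripe_call"
  )
}

#' Combined stripe table of a call
#'
#' @param x A `stripe_call` object.
#' @param rel_change Optional relative-change threshold in percent; when
#'   given, the table is filtered with [filter_by_relative_change()].
#' @return Data frame with one row per candidate stripe, columns `chrom`,
#'   `triangle`, geometry (0-based inclusive bins) and descriptors.
#' @export
stripe_table <- function(x, rel_change = NULL) {
  stopifnot(inherits(x, "stripe_call"))
  out <- do.call(rbind, lapply(c("lower", "upper"), function(tri) {
    st <- x$triangles[[tri]]$stripes
    if (nrow(st) == 0L) return(cbind(chrom = character(), triangle = character(), st))
    cbind(chrom = x$chrom, triangle = tri, st, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(rel_change)) out <- filter_by_relative_change(out, rel_change)
  out
}

#' @export
print.stripe_call <- function(x, ...) {
  cat(sprintf("<stripe_call> %s (%d bins at %s bp)\n", x$chrom, x$bins$n_bins,
              format(x$bins$resolution, big.mark = ",")))
  for (tri in names(x$triangles)) {
    cat(sprintf("  %s: %d seeds, %d stripes\n", tri,
                nrow(x$triangles[[tri]]$seeds),
                nrow(x$triangles[[tri]]$stripes)))
  }
  invisible(x)
}
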