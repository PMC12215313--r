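## Stripe descriptors: inner summary statistics, flank means, relative change.
## Computed on raw counts, not the log-rescaled band, so relative change
## measures enrichment on the original scale.

#' Summary statistics for a candidate stripe
#'
#' Computes the five-number summary, mean and standard deviation of the raw
#' counts inside the stripe rectangle (cells with no stored contact count as
#' zero), plus the mean signal in the stripe's k-neighbour: the `k` columns
#' immediately left and right of the horizontal domain over the same vertical
#' extent. The two flank means are averaged into `outer_mean` and combined
#' with the inner mean into the relative change,
#' `100 * (inner_mean - outer_mean) / outer_mean`.
#'
#' Flanks are truncated at the chromosome edge; if one flank is entirely
#' outside, the other alone defines `outer_mean`; if both are, `outer_mean`
#' is 0 and the relative change is `Inf` when the inner mean is positive
#' (0 otherwise). Quartiles use linear interpolation; the standard deviation
#' is the population form (n denominator).
#'
#' @param band A raw [contact_band()] (same triangle as the stripe).
#' @param stripe List with `left_bin`, `right_bin`, `top_bin`, `bottom_bin`
#'   (inclusive 0-based bins).
#' @param k Flank width in bins (>= 1). Defaults to the stripe width, making
#'   the comparison region area-matched.
#' @return Named list: `inner_min`, `inner_q1`, `inner_median`, `inner_q3`,
#'   `inner_max`, `inner_mean`, `inner_std`, `outer_mean_left`,
#'   `outer_mean_right`, `outer_mean`, `relative_change` (percent).
#' @export
compute_statistics <- function(band, stripe, k = NULL) {
  stopifnot(inherits(band, "contact_band"))
  l <- stripe$left_bin; r <- stripe$right_bin
  t <- stripe$top_bin; b <- stripe$bottom_bin
  stopifnot(l <= r, t <= b)
  if (is.null(k)) k <- r - l + 1L
  k <- as.integer(k)
  stopifnot(k >= 1L)
  n <- band$bins$n_bins
  nrows <- b - t + 1L
  e <- band$entries
  in_rows <- e$row >= t & e$row <= b

  inner_vals <- e$count[in_rows & e$col >= l & e$col <= r]
  n_inner <- nrows * (r - l + 1L)
  x <- c(inner_vals, numeric(n_inner - length(inner_vals)))
  q <- unname(stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))

  flank_mean <- function(c0, c1) {
    c0 <- max(c0, 0L); c1 <- min(c1, n - 1L)
    if (c0 > c1) return(NaN)
    vals <- e$count[in_rows & e$col >= c0 & e$col <= c1]
    sum(vals) / (nrows * (c1 - c0 + 1L))
  }
  m_left <- flank_mean(l - k, l - 1L)
  m_right <- flank_mean(r + 1L, r + k)
  flanks <- c(m_left, m_right)
  outer <- if (all(is.na(flanks))) 0 else mean(flanks, na.rm = TRUE)

  rc <- if (outer > 0) 100 * (m - outer) / outer else if (m > 0) Inf else 0

  list(inner_min = q[1], inner_q1 = q[2], inner_median = q[3],
       inner_q3 = q[4], inner_max = q[5], inner_mean = m, inner_std = s,
       outer_mean_left = m_left, outer_mean_right = m_right,
       outer_mean = outer, relative_change = rc)
}

#' Filter stripes by relative change
#'
#' Keeps the stripes whose relative change reaches `threshold` percent,
#' preserving their order. Recommended defaults: 4 for simulated maps, 3 for
#' real contact maps; lowering the threshold retains more stripes.
#'
#' @param stripes Data frame with a `relative_change` column (percent).
#' @param threshold Minimum relative change in percent.
#' @return The filtered data frame (stable order).
#' @export
filter_by_relative_change <- function(stripes, threshold = 3) {
  stopifnot(is.data.frame(stripes), "relative_change" %in% names(stripes))
  out <- stripes[stripes$relative_change >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
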