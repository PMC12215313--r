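## Seed detection and stripe-geometry estimation on one triangle.

#' Triangular-weight moving average
#'
#' Symmetric weighted moving average with triangular weights
#' `(1, 2, ..., half_width + 1, ..., 2, 1)` normalized to sum 1. The profile
#' is zero-padded at both ends and the full kernel weight is used everywhere,
#' so edge values are shrunk towards zero rather than renormalized.
#'
#' @param f Numeric profile.
#' @param half_width Kernel half-width in bins (>= 0).
#' @return Smoothed profile of the same length.
#' @export
triangular_wma <- function(f, half_width = 2L) {
  half_width <- as.integer(half_width)
  stopifnot(half_width >= 0L)
  if (half_width == 0L || length(f) == 0L) return(as.numeric(f))
  w <- c(seq_len(half_width + 1L), rev(seq_len(half_width)))
  w <- w / sum(w)
  padded <- c(numeric(half_width), as.numeric(f), numeric(half_width))
  sm <- stats::filter(padded, w, sides = 2)
  as.numeric(sm[(half_width + 1L):(half_width + length(f))])
}

#' Marginal pseudo-distribution of a preprocessed triangle
#'
#' Marginalizes one triangle of the (log-rescaled) band by summing over the
#' rows, giving a scalar function of the columns. To damp uninformative dips
#' caused by sparse columns, the profile is corrected to the pointwise maximum
#' of itself and its triangular-weight moving average, then divided by its
#' maximum so values lie in `[0, 1]`. Persistent maxima of this profile are
#' the stripe seed sites.
#'
#' @param band A preprocessed [contact_band()] (see [preprocess()]).
#' @param wma_half_width Half-width in bins of the moving-average kernel.
#' @return An object of class `pseudodistribution`: list with `triangle`,
#'   `values` (corrected, max-rescaled profile), `raw_marginal` (plain column
#'   sums) and `n_bins`.
#' @export
compute_pseudodistribution <- function(band, wma_half_width = 2L) {
  stopifnot(inherits(band, "contact_band"))
  n <- band$bins$n_bins
  f <- numeric(n)
  if (nrow(band$entries)) {
    agg <- rowsum(band$entries$count, band$entries$col)
    f[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  }
  if (max(f) == 0) empty_band_error(band$bins$chrom, band$triangle)
  g <- pmax(f, triangular_wma(f, wma_half_width))
  structure(
    list(triangle = band$triangle, values = g / max(g), raw_marginal = f,
         n_bins = n),
    class = "pseudodistribution"
  )
}

#' Detect stripe seed sites
#'
#' Applies [persistent_maxima()] to the pseudo-distribution and returns the
#' surviving maxima as candidate stripe anchors.
#'
#' @param pd A [compute_pseudodistribution()] result.
#' @param persistence_threshold Minimum topological persistence, as a fraction
#'   of the profile maximum (default 0.04).
#' @return Data frame sorted by `bin` (0-based) with columns `bin`,
#'   `persistence`, `essential`.
#' @export
detect_seeds <- function(pd, persistence_threshold = 0.04) {
  stopifnot(inherits(pd, "pseudodistribution"))
  pk <- persistent_maxima(pd$values, persistence_threshold)
  data.frame(bin = pk$position - 1L, persistence = pk$persistence,
             essential = pk$essential)
}

#' Estimate a stripe's horizontal domain (width)
#'
#' Starting from a seed, follows the pseudo-distribution through its maximal
#' non-decreasing run to the left (non-increasing to the right) and places the
#' boundary just after the steepest rise (just before the steepest fall). Ties
#' in the differences are broken towards the seed, so an isolated one-bin
#' spike yields a width-1 domain. The domain is then clipped symmetrically
#' around the seed to at most `floor(max_width / resolution)` bins.
#'
#' On sampled contact maps the profile carries shot noise, and a strictly
#' monotone run would be cut short by the first noise dip inside a stripe's
#' plateau. The run therefore bridges counter-movements no larger than
#' `tolerance` -- by default the same 4% of the profile maximum below which
#' the seed filter already treats fluctuations as insignificant. With
#' `tolerance = 0` the rule is strictly monotone.
#'
#' @param pd A [compute_pseudodistribution()] result.
#' @param seed_bin Seed position (0-based bin).
#' @param max_width Maximum stripe width in bp (default 100 kb).
#' @param resolution Bin size in bp.
#' @param tolerance Largest counter-movement (on the `[0, 1]` profile scale)
#'   the monotone run may bridge.
#' @return List with `left_bin`, `right_bin` (inclusive, 0-based) and
#'   `seed_bin`.
#' @export
estimate_horizontal_domain <- function(pd, seed_bin, max_width = 1e5,
                                       resolution, tolerance = 0.04) {
  stopifnot(inherits(pd, "pseudodistribution"), tolerance >= 0)
  v <- pd$values
  n <- length(v)
  s <- as.integer(seed_bin) + 1L
  stopifnot(s >= 1L, s <= n)

  L <- s
  while (L > 1L && v[L - 1L] <= v[L] + tolerance) L <- L - 1L
  d <- if (L < s) diff(v[L:s]) else numeric(0)
  if (length(d) == 0L || max(d) <= 0) {
    left <- s
  } else {
    i <- max(which(d == max(d)))     # tie towards the seed
    left <- L + i                    # bin just after the steepest rise
  }

  R <- s
  while (R < n && v[R + 1L] <= v[R] + tolerance) R <- R + 1L
  drop <- if (R > s) -diff(v[s:R]) else numeric(0)
  if (length(drop) == 0L || max(drop) <= 0) {
    right <- s
  } else {
    i <- min(which(drop == max(drop)))
    right <- s + i - 1L              # bin just before the steepest fall
  }

  max_w <- max(1L, as.integer(max_width %/% resolution))
  if (right - left + 1L > max_w) {
    lh <- min(s - left, (max_w - 1L) %/% 2L)
    rh <- min(right - s, max_w - 1L - lh)
    lh <- min(s - left, max_w - 1L - rh)
    left <- s - lh
    right <- s + rh
  }
  list(left_bin = left - 1L, right_bin = right - 1L,
       seed_bin = as.integer(seed_bin))
}

#' Estimate a stripe's vertical domain (height)
#'
#' Extracts the columns of the horizontal domain from the triangle, sums them
#' per row offset from the seed's diagonal position (the lower triangle grows
#' downward, the upper upward) and rescales the offset profile to `[0, 1]`.
#' Two boundary criteria are available:
#' \describe{
#'   \item{`threshold`}{extend away from the diagonal until the profile first
#'     drops below `min_value` (default 0.1).}
#'   \item{`persistence`}{take the persistent peak farthest from the diagonal
#'     as the boundary; the remaining off-diagonal persistent peaks are
#'     reported as `interior_peaks`, marking sharp signal increases inside
#'     the stripe.}
#' }
#' An empty column set yields a degenerate height-1 domain at the diagonal.
#'
#' @param band A preprocessed [contact_band()].
#' @param horizontal A horizontal domain from [estimate_horizontal_domain()].
#' @param criterion `"threshold"` or `"persistence"`.
#' @param vd_persistence Persistence threshold for the `persistence` criterion.
#' @param min_value Cutoff for the `threshold` criterion.
#' @return List with `top_bin`, `bottom_bin` (inclusive, 0-based) and
#'   `interior_peaks` (0-based bins).
#' @export
estimate_vertical_domain <- function(band, horizontal,
                                     criterion = c("threshold", "persistence"),
                                     vd_persistence = 0.04, min_value = 0.1) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(band, "contact_band"))
  seed <- horizontal$seed_bin
  n <- band$bins$n_bins
  max_off <- min(band$bandwidth_bins - 1L,
                 if (band$triangle == "lower") n - 1L - seed else seed)
  max_off <- max(max_off, 0L)

  e <- band$entries
  sel <- e$col >= horizontal$left_bin & e$col <= horizontal$right_bin
  off <- if (band$triangle == "lower") e$row[sel] - seed else seed - e$row[sel]
  cnt <- e$count[sel]
  keep <- off >= 0L & off <= max_off
  profile <- numeric(max_off + 1L)
  if (any(keep)) {
    agg <- rowsum(cnt[keep], off[keep])
    profile[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  }

  interior <- integer(0)
  if (max(profile) == 0) {
    height <- 1L
  } else {
    p <- profile / max(profile)
    if (criterion == "threshold") {
      below <- which(p < min_value)
      height <- if (length(below) == 0L) max_off + 1L else max(1L, below[1L] - 1L)
    } else {
      pk <- persistent_maxima(p, vd_persistence)
      boundary_off <- max(pk$position) - 1L
      height <- boundary_off + 1L
      interior <- setdiff(pk$position - 1L, c(0L, boundary_off))
    }
  }

  if (band$triangle == "lower") {
    list(top_bin = seed, bottom_bin = seed + height - 1L,
         interior_peaks = seed + interior)
  } else {
    list(top_bin = seed - height + 1L, bottom_bin = seed,
         interior_peaks = seed - interior)
  }
}
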