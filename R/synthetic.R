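## Synthetic banded contact maps with planted directional stripes.
##
## This generator is NOT a loop-extrusion simulator: it reproduces the
## statistical silhouette of extrusion-derived maps -- a distance-decay
## background, directional rectangles of enriched contacts anchored at the
## diagonal, and knobs for contact density, noise and resolution -- which is
## sufficient to exercise the caller and the benchmark metrics under
## controlled conditions.

#' Describe a planted stripe
#'
#' @param anchor_bin Diagonal anchor (0-based bin).
#' @param direction `"lower"` (stripe grows below the diagonal) or `"upper"`.
#' @param occupancy Barrier occupancy in `(0, 1]`; scales stripe intensity.
#' @param width_bins Stripe width in bins (centred on the anchor).
#' @param height_bins Stripe height in bins (away from the diagonal).
#' @return An object of class `planted_stripe`.
#' @export
planted_stripe <- function(anchor_bin, direction = c("lower", "upper"),
                           occupancy = 0.9, width_bins = 3L,
                           height_bins = 30L) {
  direction <- match.arg(direction)
  stopifnot(anchor_bin >= 0, occupancy > 0, occupancy <= 1,
            width_bins >= 1, height_bins >= 1)
  structure(
    list(anchor_bin = as.integer(anchor_bin), direction = direction,
         occupancy = as.numeric(occupancy), width_bins = as.integer(width_bins),
         height_bins = as.integer(height_bins)),
    class = "planted_stripe"
  )
}

#' Configuration of a synthetic contact map
#'
#' The background expected count at diagonal distance `d` bins is
#' `background_scale * (1 + d)^(-decay_exponent)`, rescaled so that the mean
#' expected count over the band equals `contact_density` (the sequencing-depth
#' knob). Inside each planted stripe's rectangle the mean is multiplied by
#' `1 + enrichment * occupancy`. Counts are Poisson draws from these means;
#' with `noise_scale > 0`, each sampled contact is then displaced along both
#' axes by a signed geometric number of bins with mean `noise_scale`,
#' blurring the map (contacts displaced out of the band are lost).
#'
#' @param n_bins Number of bins.
#' @param resolution Bin size in bp.
#' @param bandwidth_bins Diagonal band half-width in bins.
#' @param background_scale Unnormalized expected count at the diagonal.
#' @param decay_exponent Distance-decay exponent (> 0 for decay; 0 = flat).
#' @param contact_density Target mean expected count per band pixel.
#' @param noise_scale Mean bin displacement of the noise kernel (>= 0).
#' @param enrichment Stripe enrichment factor `s` in `1 + s * occupancy`.
#' @param stripes List of [planted_stripe()] objects.
#' @param chrom Chromosome name.
#' @param rng_seed Integer seed; the map is fully reproducible from it.
#' @return An object of class `synthetic_map_config`.
#' @export
synthetic_map_config <- function(n_bins = 500L, resolution = 10e3,
                                 bandwidth_bins = 500L, background_scale = 1,
                                 decay_exponent = 1, contact_density = 1,
                                 noise_scale = 0, enrichment = 5,
                                 stripes = list(), chrom = "chrS",
                                 rng_seed = 1L) {
  stopifnot(n_bins >= 2, resolution > 0, bandwidth_bins >= 1,
            background_scale > 0, decay_exponent >= 0, contact_density > 0,
            noise_scale >= 0, enrichment >= 0)
  stripes <- lapply(stripes, function(s) {
    stopifnot(inherits(s, "planted_stripe"))
    s
  })
  structure(
    list(n_bins = as.integer(n_bins), resolution = as.numeric(resolution),
         bandwidth_bins = as.integer(min(bandwidth_bins, n_bins - 1L)),
         background_scale = background_scale,
         decay_exponent = decay_exponent,
         contact_density = contact_density, noise_scale = noise_scale,
         enrichment = enrichment, stripes = stripes, chrom = chrom,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_map_config"
  )
}

#' Place well-separated random stripes
#'
#' Draws `n` stripes with anchors at least `min_separation` bins apart (and
#' clear of the chromosome ends), alternating directions, widths, heights and
#' occupancies sampled uniformly from the given ranges. Uses the current RNG
#' state; seed it (or rely on [generate_map()]'s seed when placing stripes
#' yourself) for reproducibility.
#'
#' @param n Number of stripes.
#' @param n_bins,bandwidth_bins Map geometry (see [synthetic_map_config()]).
#' @param occupancy Length-2 range for occupancies.
#' @param width_bins Integer vector of candidate widths.
#' @param height_bins Length-2 integer range for heights.
#' @param min_separation Minimum anchor distance in bins.
#' @return List of [planted_stripe()] objects sorted by anchor.
#' @export
random_planted_stripes <- function(n = 10L, n_bins = 500L,
                                   bandwidth_bins = 500L,
                                   occupancy = c(0.9, 1),
                                   width_bins = 2:4,
                                   height_bins = c(20L, 60L),
                                   min_separation = 10L) {
  height_hi <- min(height_bins[2], bandwidth_bins)
  height_lo <- min(height_bins[1], height_hi)
  margin <- max(width_bins) + height_hi + 1L
  lo <- margin
  hi <- n_bins - 1L - margin
  stopifnot(hi - lo >= (n - 1L) * min_separation)
  repeat {
    anchors <- sort(sample(lo:hi, n))
    if (n == 1L || min(diff(anchors)) >= min_separation) break
  }
  dirs <- rep(c("lower", "upper"), length.out = n)
  lapply(seq_len(n), function(i) {
    planted_stripe(
      anchor_bin = anchors[i],
      direction = dirs[i],
      occupancy = stats::runif(1, occupancy[1], occupancy[2]),
      width_bins = sample(width_bins, 1L),
      height_bins = sample(seq(height_lo, height_hi), 1L)
    )
  })
}

stripe_cols <- function(s) {
  left <- s$anchor_bin - (s$width_bins - 1L) %/% 2L
  c(left, left + s$width_bins - 1L)
}

#' Generate a synthetic contact map
#'
#' Samples the lower-triangular band described by `config` (see
#' [synthetic_map_config()] for the model), mirrors it into the upper band,
#' and returns both together with the ground-truth barrier list (one barrier
#' per planted stripe, positioned at the midpoint of its anchor bin).
#'
#' @param config A [synthetic_map_config()].
#' @return An object of class `synthetic_map`: list with `lower`, `upper`
#'   ([contact_band()]s), `barriers` (data frame `chrom`, `position`,
#'   `direction`, `occupancy`) and `config`.
#' @export
generate_map <- function(config) {
  stopifnot(inherits(config, "synthetic_map_config"))
  n <- config$n_bins
  bw <- config$bandwidth_bins
  set.seed(config$rng_seed)

  for (s in config$stripes) {
    cols <- stripe_cols(s)
    a <- s$anchor_bin
    ok <- cols[1] >= 0L && cols[2] <= n - 1L && s$height_bins <= bw &&
      if (s$direction == "lower") a + s$height_bins - 1L <= n - 1L else
        a - s$height_bins + 1L >= 0L
    if (!ok) {
      stop(sprintf("planted stripe at bin %d (%s) exceeds the band", a,
                   s$direction))
    }
  }

  ## enumerate band pixels of the lower triangle: i = j + d
  offs <- 0:bw
  per_off <- n - offs
  d <- rep(offs, per_off)
  j <- unlist(lapply(offs, function(dd) 0:(n - 1L - dd)), use.names = FALSE)
  i <- j + d

  mu <- config$background_scale * (1 + d)^(-config$decay_exponent)
  mu <- mu * config$contact_density / mean(mu)

  for (s in config$stripes) {
    cols <- stripe_cols(s)
    a <- s$anchor_bin
    mask <- if (s$direction == "lower") {
      j >= cols[1] & j <= cols[2] & i >= a & i <= a + s$height_bins - 1L
    } else {
      ## vertical stripe of the upper triangle, mirrored into lower storage
      i >= cols[1] & i <= cols[2] & j >= a - s$height_bins + 1L & j <= a
    }
    mu[mask] <- mu[mask] * (1 + config$enrichment * s$occupancy)
  }

  counts <- stats::rpois(length(mu), mu)

  if (config$noise_scale > 0 && any(counts > 0)) {
    nz <- counts > 0L
    ii <- rep(i[nz], counts[nz])
    jj <- rep(j[nz], counts[nz])
    m <- length(ii)
    p <- 1 / (1 + config$noise_scale)
    di <- stats::rgeom(m, p) * sample(c(-1L, 1L), m, replace = TRUE)
    dj <- stats::rgeom(m, p) * sample(c(-1L, 1L), m, replace = TRUE)
    r2 <- pmax(ii + di, jj + dj)
    c2 <- pmin(ii + di, jj + dj)
    ok <- c2 >= 0L & r2 <= n - 1L & (r2 - c2) <= bw
    key <- r2[ok] * n + c2[ok]
    agg <- rowsum(rep(1, sum(ok)), key)
    kk <- as.numeric(rownames(agg))
    i <- as.integer(kk %/% n)
    j <- as.integer(kk %% n)
    counts <- as.numeric(agg[, 1L])
  }

  bins <- bin_table(config$chrom, n * config$resolution, config$resolution)
  lower <- contact_band(bins, bw, "lower",
                        data.frame(row = i, col = j, count = counts))
  barriers <- if (length(config$stripes)) {
    data.frame(
      chrom = config$chrom,
      position = vapply(config$stripes, function(s)
        s$anchor_bin * config$resolution + config$resolution %/% 2, numeric(1)),
      direction = vapply(config$stripes, `[[`, character(1), "direction"),
      occupancy = vapply(config$stripes, `[[`, numeric(1), "occupancy")
    )
  } else {
    data.frame(chrom = character(), position = numeric(),
               direction = character(), occupancy = numeric())
  }
  structure(list(lower = lower, upper = band_transpose(lower),
                 barriers = barriers, config = config),
            class = "synthetic_map")
}

#' Write a synthetic map as text fixtures
#'
#' Writes the lower band in the COO text dialect understood by
#' [load_contacts()] (`<stem>.coo.tsv`) and the ground-truth barriers as a
#' TSV (`<stem>.barriers.tsv`). The contact fixture round-trips losslessly
#' through [load_contacts()].
#'
#' @param map A [generate_map()] result.
#' @param stem Output path stem.
#' @return Named character vector with elements `contacts` and `barriers`.
#' @export
write_fixture <- function(map, stem) {
  stopifnot(inherits(map, "synthetic_map"))
  contacts <- paste0(stem, ".coo.tsv")
  barriers <- paste0(stem, ".barriers.tsv")
  write_contact_fixture(map$lower, contacts)
  write_barriers(map$barriers, barriers)
  c(contacts = contacts, barriers = barriers)
}

#' Write a contact band in the COO text dialect
#'
#' @param band A [contact_band()] (lower-triangle storage is conventional).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_contact_fixture <- function(band, path) {
  stopifnot(inherits(band, "contact_band"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#resolution=%d chrom=%s length=%d",
                     as.integer(band$bins$resolution), band$bins$chrom,
                     as.integer(band$bins$length)), con)
  e <- band$entries
  if (nrow(e)) {
    writeLines(sprintf("%d\t%d\t%s", e$row, e$col,
                       format(e$count, trim = TRUE, scientific = FALSE)), con)
  }
  invisible(path)
}
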