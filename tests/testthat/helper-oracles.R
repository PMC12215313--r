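# Independent dense-matrix oracles and small fixture builders used across
# the suite. Everything here works on plain dense matrices so it shares no
# code path with the banded sparse implementation it checks.

# dense n x n matrix -> lower-triangle contact_band (0-based sparse entries)
dense_to_band <- function(m, resolution = 1e4, bandwidth = nrow(m) - 1L,
                          triangle = "lower", chrom = "chrT") {
  n <- nrow(m)
  idx <- which(m != 0, arr.ind = TRUE)
  row <- idx[, 1] - 1L
  col <- idx[, 2] - 1L
  keep <- if (triangle == "lower") row >= col else row <= col
  keep <- keep & abs(row - col) <= bandwidth
  contact_band(
    bin_table(chrom, n * resolution, resolution), bandwidth, triangle,
    data.frame(row = row[keep], col = col[keep], count = m[idx][keep])
  )
}

band_to_dense <- function(band) {
  n <- band$bins$n_bins
  m <- matrix(0, n, n)
  e <- band$entries
  m[cbind(e$row + 1L, e$col + 1L)] <- e$count
  m
}

# random lower-triangular banded count matrix (dense), Poisson counts
random_dense_lower <- function(n, bandwidth, lambda = 2) {
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    rows <- j:min(n, j + bandwidth)
    m[rows, j] <- stats::rpois(length(rows), lambda)
  }
  m
}

# dense oracle for the marginal pseudo-distribution of a lower triangle:
# log1p/max preprocessing + column sums + triangular WMA correction
dense_pseudodistribution <- function(m, wma_half_width = 2L) {
  v <- log1p(m)
  v <- v / max(v)
  f <- colSums(v)
  w <- c(seq_len(wma_half_width + 1L), rev(seq_len(wma_half_width)))
  w <- w / sum(w)
  n <- length(f)
  wma <- vapply(seq_len(n), function(i) {
    acc <- 0
    for (k in seq_along(w)) {
      j <- i + k - wma_half_width - 1L
      if (j >= 1L && j <= n) acc <- acc + w[k] * f[j]
    }
    acc
  }, numeric(1))
  g <- pmax(f, wma)
  g / max(g)
}

# dense oracle for stripe descriptors on a lower-triangle raw matrix
dense_statistics <- function(m, l, r, t, b, k) {
  sub <- function(c0, c1) {
    c0 <- max(c0, 0L); c1 <- min(c1, ncol(m) - 1L)
    if (c0 > c1) return(NULL)
    m[(t:b) + 1L, (c0:c1) + 1L, drop = FALSE]
  }
  x <- as.vector(sub(l, r))
  q <- unname(stats::quantile(x, c(0, .25, .5, .75, 1), type = 7))
  fl <- sub(l - k, l - 1L); fr <- sub(r + 1L, r + k)
  ml <- if (is.null(fl)) NaN else mean(fl)
  mr <- if (is.null(fr)) NaN else mean(fr)
  outer <- if (is.nan(ml) && is.nan(mr)) 0 else mean(c(ml, mr), na.rm = TRUE)
  inner <- mean(x)
  list(q = q, mean = inner, sd = sqrt(mean((x - inner)^2)),
       outer = outer,
       rc = if (outer > 0) 100 * (inner - outer) / outer else
         if (inner > 0) Inf else 0)
}

# a small deterministic map with planted stripes, shared by several tests
toy_map <- function(seed = 7, n_stripes = 10, sigma = 0, occupancy = c(0.9, 1),
                    n_bins = 500L) {
  set.seed(seed)
  bw <- min(500L, n_bins - 1L)
  heights <- if (n_bins >= 400L) c(20L, 60L) else c(10L, 25L)
  st <- random_planted_stripes(n_stripes, n_bins = n_bins,
                               bandwidth_bins = bw, occupancy = occupancy,
                               height_bins = heights)
  generate_map(synthetic_map_config(n_bins = n_bins, bandwidth_bins = bw,
                                    stripes = st, rng_seed = seed,
                                    noise_scale = sigma))
}

random_profile <- function(n) {
  base <- stats::runif(n)
  # mix in plateaus and repeated values to exercise tie-breaking
  if (n >= 4 && stats::runif(1) < 0.5) {
    i <- sample(seq_len(n - 2), 1)
    base[i + 1] <- base[i]
  }
  round(base, 2)
}
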