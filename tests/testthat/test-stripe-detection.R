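test_that("pseudo-distribution matches hand arithmetic and the dense oracle", {
  # f = [1, 0, 1] after marginalization, window 1 -> WMA = [.5, .5, .5]
  f <- c(1, 0, 1)
  expect_equal(triangular_wma(f, 1L), c(0.5, 0.5, 0.5))
  g <- pmax(f, triangular_wma(f, 1L))
  expect_equal(g / max(g), c(1, 0.5, 1))

  # 4x4 lower triangle with equal entries: the column marginal reflects the
  # triangle's depth (4, 3, 2, 1 cells), max-rescaled
  m <- matrix(0, 4, 4)
  m[lower.tri(m, diag = TRUE)] <- exp(1) - 1
  pd <- compute_pseudodistribution(preprocess(dense_to_band(m)), 0L)
  expect_equal(pd$values, c(1, 0.75, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(pd$raw_marginal, c(4, 3, 2, 1), tolerance = 1e-12)

  # random band: equals the independent dense computation
  set.seed(5)
  for (rep in 1:10) {
    md <- random_dense_lower(30, 12)
    pd <- compute_pseudodistribution(preprocess(dense_to_band(md)), 2L)
    expect_equal(pd$values, dense_pseudodistribution(md, 2L), tolerance = 1e-12)
    expect_equal(max(pd$values), 1)
  }

  empty <- contact_band(bin_table("chrE", 5e4, 1e4), 2L, "lower")
  expect_error(compute_pseudodistribution(empty),
               class = "hicstripes_empty_band")
})

fake_pd <- function(values, triangle = "lower") {
  structure(list(triangle = triangle, values = values,
                 raw_marginal = values, n_bins = length(values)),
            class = "pseudodistribution")
}

test_that("seed detection follows the persistence filter", {
  pd <- fake_pd(c(0, 1.0, 0.4, 0.8, 0))
  expect_equal(detect_seeds(pd, 0.04)$bin, c(1L, 3L))
  expect_equal(detect_seeds(pd, 0.5)$bin, 1L)
  s <- detect_seeds(fake_pd(rep(1, 5)), 0.04)
  expect_equal(s$bin, 0L)
  expect_true(s$essential)
})

test_that("horizontal domain boundaries sit at the steepest rise and fall", {
  # isolated spike: width 1
  hd <- estimate_horizontal_domain(fake_pd(c(0, 1, 0)), 1L, 1e5, 1e4)
  expect_equal(c(hd$left_bin, hd$right_bin), c(1L, 1L))

  # steepest rise 0->1, steepest fall 3->4
  hd <- estimate_horizontal_domain(fake_pd(c(0.1, 0.9, 1.0, 0.9, 0.1)), 2L,
                                   1e5, 1e4)
  expect_equal(c(hd$left_bin, hd$right_bin), c(1L, 3L))

  # exhaustive check against the rule (strict runs, tolerance 0) on random
  # strictly-unimodal profiles where the boundary placement is enumerable
  set.seed(21)
  for (rep in 1:30) {
    nl <- sample(2:6, 1); nr <- sample(2:6, 1)
    up <- sort(runif(nl)); down <- sort(runif(nr), decreasing = TRUE)
    v <- c(up, 1, down)
    s0 <- nl  # 0-based seed at the peak
    hd <- estimate_horizontal_domain(fake_pd(v), s0, 1e7, 1e4, tolerance = 0)
    dl <- diff(v[1:(nl + 1)])
    expect_equal(hd$left_bin, max(which(dl == max(dl))))
    dr <- -diff(v[(nl + 1):length(v)])
    expect_equal(hd$right_bin, s0 + min(which(dr == max(dr))) - 1L)
  }
})

test_that("a wide plateau is clipped symmetrically to the width cap", {
  v <- c(0.1, rep(1, 40), 0.1)
  hd <- estimate_horizontal_domain(fake_pd(v), 20L, max_width = 1e5,
                                   resolution = 1e4)
  expect_equal(hd$right_bin - hd$left_bin + 1L, 10L)  # 100 kb / 10 kb
  expect_true(hd$left_bin <= 20L && hd$right_bin >= 20L)
})

test_that("the run tolerance bridges sub-threshold dips but not real edges", {
  # a noisy plateau over bins 3..7 with a 0.02 interior dip
  v <- c(0.2, 0.2, 0.2, 0.9, 0.88, 0.9, 0.89, 0.9, 0.2, 0.2)
  hd <- estimate_horizontal_domain(fake_pd(v), 7L, 1e7, 1e4, tolerance = 0.04)
  expect_equal(c(hd$left_bin, hd$right_bin), c(3L, 7L))
  # with a strictly monotone rule the dip truncates the run
  hd0 <- estimate_horizontal_domain(fake_pd(v), 7L, 1e7, 1e4, tolerance = 0)
  expect_equal(hd0$left_bin, 7L)
})

test_that("vertical domain criteria follow the offset profile", {
  # build a lower band whose single-column offset profile is prescribed
  prof <- c(1.0, 0.8, 0.5, 0.3, 0.05, 0.2)
  n <- 10L
  m <- matrix(0, n, n)
  m[2L + seq_along(prof) - 1L, 2L] <- prof  # col 1 (0-based), rows 1..6
  band <- dense_to_band(m)
  attr(band, "preprocessed") <- TRUE
  hd <- list(left_bin = 1L, right_bin = 1L, seed_bin = 1L)
  vd <- estimate_vertical_domain(band, hd, "threshold", min_value = 0.1)
  expect_equal(c(vd$top_bin, vd$bottom_bin), c(1L, 4L))  # height 4

  # persistence criterion: peaks at offsets 0 and 7 -> boundary 7, no interior
  prof2 <- c(1.0, 0.5, 0.45, 0.4, 0.35, 0.3, 0.4, 0.8, 0.1)
  m2 <- matrix(0, 12L, 12L)
  m2[1L + seq_along(prof2) - 1L, 1L] <- prof2
  band2 <- dense_to_band(m2)
  hd2 <- list(left_bin = 0L, right_bin = 0L, seed_bin = 0L)
  vd2 <- estimate_vertical_domain(band2, hd2, "persistence",
                                  vd_persistence = 0.04)
  expect_equal(vd2$bottom_bin, 7L)
  expect_equal(vd2$interior_peaks, integer(0))

  # a third interior peak at offset 3
  prof3 <- c(1.0, 0.5, 0.45, 0.7, 0.35, 0.3, 0.4, 0.8, 0.1)
  m3 <- matrix(0, 12L, 12L)
  m3[1L + seq_along(prof3) - 1L, 1L] <- prof3
  vd3 <- estimate_vertical_domain(dense_to_band(m3), hd2, "persistence",
                                  vd_persistence = 0.04)
  expect_equal(vd3$interior_peaks, 3L)

  # profile everywhere above the cutoff extends to the full band
  m4 <- matrix(0, 8L, 8L)
  m4[, 1L] <- 1
  m4[1, 1] <- 1
  band4 <- dense_to_band(m4, bandwidth = 5L)
  vd4 <- estimate_vertical_domain(band4, hd2, "threshold", min_value = 0.1)
  expect_equal(vd4$bottom_bin - vd4$top_bin, band4$bandwidth_bins - 1L)
})

test_that("the full pipeline recovers planted stripes and is deterministic", {
  map <- toy_map(seed = 5)
  bands <- list(lower = map$lower, upper = map$upper)
  params <- call_parameters(resolution = 1e4)
  r1 <- call_stripes(bands, params, quiet = TRUE)
  tab <- stripe_table(r1, rel_change = 4)
  anchors <- bin_ground_truth(map$barriers, map$lower$bins)
  covered <- vapply(seq_len(nrow(anchors)), function(i) {
    any(tab$triangle == anchors$direction[i] &
          tab$left_bin <= anchors$bin[i] & tab$right_bin >= anchors$bin[i])
  }, logical(1))
  expect_gte(sum(covered), 9L)

  # geometry invariants: rectangles inside band and triangle, width capped
  full <- stripe_table(r1)
  expect_true(all(full$left_bin <= full$seed_bin &
                    full$seed_bin <= full$right_bin))
  expect_true(all((full$right_bin - full$left_bin + 1L) * 1e4 <= params$max_width))
  low <- full[full$triangle == "lower", ]
  expect_true(all(low$top_bin == low$seed_bin & low$bottom_bin >= low$top_bin))
  up <- full[full$triangle == "upper", ]
  expect_true(all(up$bottom_bin == up$seed_bin & up$top_bin <= up$bottom_bin))
  expect_true(all(full$bottom_bin - full$top_bin < map$lower$bandwidth_bins))
  expect_true(all(full$bottom_bin <= map$lower$bins$n_bins - 1L &
                    full$top_bin >= 0L))

  # seeds are local maxima (or plateau representatives) of the profile
  for (tri in c("lower", "upper")) {
    v <- r1$triangles[[tri]]$pseudodistribution
    for (b in r1$triangles[[tri]]$seeds$bin) {
      i <- b + 1L
      lhs <- if (i > 1) v[i - 1] else -Inf
      expect_gte(v[i], lhs)
      # right neighbour may only tie within a plateau represented at i
      if (i < length(v)) expect_gte(v[i], v[i + 1] - 1e-12)
    }
  }

  # determinism: identical inputs give identical outputs
  r2 <- call_stripes(bands, params, quiet = TRUE)
  expect_identical(stripe_table(r1), stripe_table(r2))
})

test_that("an all-zero map yields zero stripes and a clean exit", {
  bins <- bin_table("chrZ", 5e5, 1e4)
  empty <- contact_band(bins, 10L, "lower")
  r <- suppressMessages(
    call_stripes(list(lower = empty, upper = band_transpose(empty)),
                 call_parameters(resolution = 1e4))
  )
  expect_equal(nrow(stripe_table(r)), 0L)
})

test_that("raising the persistence threshold never increases the seed count", {
  map <- toy_map(seed = 9, n_stripes = 6, n_bins = 300L)
  pd <- compute_pseudodistribution(preprocess(map$lower), 2L)
  thresholds <- c(0.01, 0.04, 0.1, 0.3, 0.6)
  counts <- vapply(thresholds,
                   function(t) nrow(detect_seeds(pd, t)), integer(1))
  expect_true(all(diff(counts) <= 0L))
})
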