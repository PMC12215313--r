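## Reproducible evaluation studies on synthetic maps: the planted-stripe
## recovery study and the noise-degradation study. Both drive the full call
## pipeline end to end and score it with the benchmark metrics.

#' Score one stripe call against planted truth
#'
#' Runs the full pipeline on a synthetic map, filters by relative change, and
#' returns recognition metrics plus the width-recovery rate: the fraction of
#' planted stripes, among those whose anchor lies inside at least one called
#' horizontal domain, for which some matching call has a width within
#' `width_slack` bins of the planted width.
#'
#' @param map A [generate_map()] result.
#' @param params [call_parameters()] used for the call.
#' @param rel_change Relative-change filter in percent (4 = simulated-data
#'   default).
#' @param width_slack Allowed width error in bins.
#' @return One-row data frame: `AHR`, `FGC`, `F1r`, `FMr`, `width_match_rate`,
#'   `n_called`, `n_matched`.
#' @export
score_call_against_truth <- function(map, params = call_parameters(),
                                     rel_change = 4, width_slack = 1L) {
  stopifnot(inherits(map, "synthetic_map"))
  result <- call_stripes(list(lower = map$lower, upper = map$upper), params,
                         quiet = TRUE)
  tab <- stripe_table(result, rel_change = rel_change)
  anchors <- bin_ground_truth(map$barriers, map$lower$bins)
  rec <- recognition_metrics(tab, anchors)

  width_ok <- logical(0)
  for (s in map$config$stripes) {
    hits <- tab[tab$triangle == s$direction & tab$left_bin <= s$anchor_bin &
                  tab$right_bin >= s$anchor_bin, , drop = FALSE]
    if (nrow(hits)) {
      widths <- hits$right_bin - hits$left_bin + 1L
      width_ok <- c(width_ok, any(abs(widths - s$width_bins) <= width_slack))
    }
  }
  data.frame(AHR = rec$AHR, FGC = rec$FGC, F1r = rec$F1r, FMr = rec$FMr,
             width_match_rate = if (length(width_ok)) mean(width_ok) else NaN,
             n_called = nrow(tab), n_matched = length(width_ok))
}

#' Planted-stripe recovery study
#'
#' Generates `n_maps` independent synthetic maps (500 bins at 10 kb, ten
#' well-separated stripes with occupancy in `[0.9, 1]`, contact density 1,
#' no displacement noise) and scores the full pipeline on each with the
#' simulated-data relative-change filter of 4%.
#'
#' @param n_maps Number of maps.
#' @param base_seed Integer; map `i` uses seed `base_seed * 1000 + i`.
#' @param n_stripes Planted stripes per map.
#' @param occupancy Length-2 occupancy range.
#' @param noise_scale Displacement-noise scale passed to the generator.
#' @param rel_change Relative-change filter in percent.
#' @return Data frame with one row per map (columns of
#'   [score_call_against_truth()] plus `seed`).
#' @export
planted_recovery_study <- function(n_maps = 20L, base_seed = 1L,
                                   n_stripes = 10L, occupancy = c(0.9, 1),
                                   noise_scale = 0, rel_change = 4) {
  rows <- lapply(seq_len(n_maps), function(i) {
    seed <- base_seed * 1000L + i
    set.seed(seed)
    stripes <- random_planted_stripes(n_stripes, occupancy = occupancy)
    map <- generate_map(synthetic_map_config(stripes = stripes,
                                             rng_seed = seed,
                                             noise_scale = noise_scale))
    cbind(seed = seed,
          score_call_against_truth(map, call_parameters(resolution = 10e3),
                                   rel_change = rel_change))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Noise-degradation study
#'
#' Measures how the anchor hit rate decays as the displacement-noise scale
#' grows, holding everything else fixed. To keep the readout off its ceiling
#' and at a useful granularity, each map plants 20 stripes spanning the full
#' realistic occupancy spectrum (0.2 to 1) with heights of 100 to 500 kb, so
#' that part of the population sits near the detection boundary where noise
#' can move it.
#'
#' @param sigmas Noise scales to compare.
#' @param n_seeds Maps per noise scale (stripe placements are shared across
#'   scales for a given seed).
#' @param base_seed Integer; map `i` uses seed `base_seed * 1000 + i`.
#' @param rel_change Relative-change filter in percent.
#' @return Data frame with columns `sigma`, `seed`, `AHR`.
#' @export
noise_degradation_study <- function(sigmas = c(0, 1, 3), n_seeds = 10L,
                                    base_seed = 1L, rel_change = 4) {
  rows <- list()
  for (sigma in sigmas) {
    for (i in seq_len(n_seeds)) {
      seed <- base_seed * 1000L + i
      set.seed(seed)
      stripes <- random_planted_stripes(20L, occupancy = c(0.2, 1),
                                        height_bins = c(10L, 50L))
      map <- generate_map(synthetic_map_config(stripes = stripes,
                                               rng_seed = seed,
                                               noise_scale = sigma))
      sc <- score_call_against_truth(map, call_parameters(resolution = 10e3),
                                     rel_change = rel_change)
      rows[[length(rows) + 1L]] <- data.frame(sigma = sigma, seed = seed,
                                              AHR = sc$AHR)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
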