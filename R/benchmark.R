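## Benchmarking stripe callers against ground-truth extrusion barriers:
## per-bin classification metrics and stripe-level recognition metrics.
##
## Barriers block loop extrusion in one direction; the blocking direction
## maps to the matrix triangle in which the stripe appears ("lower" or
## "upper"). Undefined ratios (zero denominators) are reported as NaN and
## propagate into derived measures, never silently coerced to 0.

nan_div <- function(a, b) if (is.na(b) || b == 0) NaN else a / b

#' Bin ground-truth barriers and deduplicate per bin
#'
#' Assigns each barrier to bin `floor(position / resolution)`. Barriers that
#' fall in the same bin with the same blocking direction collapse to a single
#' anchor whose occupancy is the mean of theirs; opposite directions stay
#' separate (one anchor per triangle).
#'
#' @param barriers Data frame with columns `position` (bp), `direction`
#'   (`"lower"`/`"upper"`) and `occupancy` (in `[0, 1]`); an optional `chrom`
#'   column is carried through.
#' @param bins A [bin_table()].
#' @return Data frame of anchors sorted by (`direction`, `bin`): columns
#'   `bin`, `direction`, `occupancy` (mean), `n_barriers`.
#' @export
bin_ground_truth <- function(barriers, bins) {
  stopifnot(is.data.frame(barriers),
            all(c("position", "direction", "occupancy") %in% names(barriers)),
            inherits(bins, "bin_table"))
  pos <- as.numeric(barriers$position)
  if (any(pos < 0 | pos >= bins$length)) {
    bad <- pos[pos < 0 | pos >= bins$length][1]
    stop(sprintf("barrier position %s outside chromosome %s [0, %s)",
                 format(bad), bins$chrom, format(bins$length)))
  }
  dir <- as.character(barriers$direction)
  stopifnot(all(dir %in% c("lower", "upper")))
  occ <- as.numeric(barriers$occupancy)
  stopifnot(all(occ >= 0 & occ <= 1))

  bin <- as.integer(pos %/% bins$resolution)
  key <- paste(dir, bin)
  first <- !duplicated(key)
  out <- data.frame(
    bin = bin[first],
    direction = dir[first],
    occupancy = as.numeric(tapply(occ, key, mean)[key[first]]),
    n_barriers = as.integer(table(key)[key[first]])
  )
  out <- out[order(out$direction, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build per-bin classification vectors
#'
#' Encodes truth anchors and predicted anchor bins as 0/1 vectors of length
#' `2 * n_bins` (lower triangle first, then upper), pooling the two triangles
#' micro-style so confusion counts are summed before ratios are taken.
#'
#' @param anchors Data frame from [bin_ground_truth()] (columns `bin`,
#'   `direction`).
#' @param predicted Data frame of predicted anchor bins with columns `bin`
#'   and `triangle`.
#' @param n_bins Number of bins in the chromosome.
#' @return List with binary vectors `truth` and `predicted`.
#' @export
classification_vectors <- function(anchors, predicted, n_bins) {
  enc <- function(df, dir_col) {
    v <- integer(2L * n_bins)
    if (nrow(df)) {
      dirs <- as.character(df[[dir_col]])
      idx <- df$bin + 1L + ifelse(dirs == "upper", n_bins, 0L)
      v[idx] <- 1L
    }
    v
  }
  list(truth = enc(anchors, "direction"),
       predicted = enc(predicted, "triangle"))
}

#' Per-bin classification metrics
#'
#' Confusion counts and the eight classification measures: TPR (sensitivity),
#' TNR (specificity), PPV (precision), balanced accuracy
#' `bACC = (TPR + TNR) / 2`, geometric mean `GM = sqrt(TPR * TNR)`, F1 score
#' `F1c = 2 * PPV * TPR / (PPV + TPR)`, Fowlkes-Mallows index
#' `FMc = sqrt(PPV * TPR)` and Jaccard index `JI = TP / (TP + FP + FN)`.
#'
#' @param truth,predicted Equal-length 0/1 vectors.
#' @return Named list with `TP`, `FP`, `TN`, `FN` and the eight measures
#'   (NaN where undefined).
#' @export
classification_metrics <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted vectors must have equal length")
  }
  stopifnot(all(truth %in% 0:1), all(predicted %in% 0:1))
  TP <- sum(truth == 1L & predicted == 1L)
  FP <- sum(truth == 0L & predicted == 1L)
  TN <- sum(truth == 0L & predicted == 0L)
  FN <- sum(truth == 1L & predicted == 0L)
  TPR <- nan_div(TP, TP + FN)
  TNR <- nan_div(TN, TN + FP)
  PPV <- nan_div(TP, TP + FP)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       TPR = TPR, TNR = TNR, PPV = PPV,
       bACC = (TPR + TNR) / 2,
       GM = sqrt(TPR * TNR),
       F1c = nan_div(2 * PPV * TPR, PPV + TPR),
       FMc = sqrt(PPV * TPR),
       JI = nan_div(TP, TP + FP + FN))
}

#' Stripe-level recognition metrics
#'
#' A predicted stripe recognizes an anchor when the anchor's bin lies inside
#' the stripe's horizontal domain on the matching triangle. The Anchor Hit
#' Rate `AHR` is the fraction of anchors inside at least one stripe (the
#' recognition analogue of TPR); the Fraction of Good Candidates `FGC` is the
#' fraction of stripes containing at least one anchor (analogue of PPV).
#' `F1r` and `FMr` combine them as harmonic and geometric means. For
#' width-1 stripes placed at predicted anchor bins, recognition reduces
#' exactly to classification: AHR == TPR and FGC == PPV.
#'
#' @param stripes Data frame of predicted stripes with columns `triangle`,
#'   `left_bin`, `right_bin` (inclusive 0-based bins).
#' @param anchors Data frame from [bin_ground_truth()].
#' @return Named list: `AHR`, `FGC`, `F1r`, `FMr`, `n_anchors_found`,
#'   `n_stripes_predicted` (NaN ratios when there are no anchors/stripes).
#' @export
recognition_metrics <- function(stripes, anchors) {
  stopifnot(is.data.frame(stripes),
            all(c("triangle", "left_bin", "right_bin") %in% names(stripes)),
            is.data.frame(anchors),
            all(c("bin", "direction") %in% names(anchors)))
  n_anchor <- nrow(anchors)
  n_stripe <- nrow(stripes)

  anchor_hit <- logical(n_anchor)
  stripe_good <- logical(n_stripe)
  if (n_anchor && n_stripe) {
    for (tri in c("lower", "upper")) {
      ai <- which(anchors$direction == tri)
      si <- which(stripes$triangle == tri)
      if (!length(ai) || !length(si)) next
      hit_mat <- outer(anchors$bin[ai], stripes$left_bin[si], `>=`) &
        outer(anchors$bin[ai], stripes$right_bin[si], `<=`)
      anchor_hit[ai] <- rowSums(hit_mat) > 0
      stripe_good[si] <- colSums(hit_mat) > 0
    }
  }
  AHR <- nan_div(sum(anchor_hit), n_anchor)
  FGC <- nan_div(sum(stripe_good), n_stripe)
  list(AHR = AHR, FGC = FGC,
       F1r = nan_div(2 * AHR * FGC, AHR + FGC),
       FMr = sqrt(AHR * FGC),
       n_anchors_found = sum(anchor_hit),
       n_stripes_predicted = n_stripe)
}

#' Full benchmark report for one map
#'
#' Combines classification metrics (on predicted seed bins vs anchor bins)
#' and recognition metrics (on stripe horizontal domains) into one row. With
#' `stratify = TRUE`, two additional rows restrict the truth to anchors with
#' mean barrier occupancy >= 0.70 and < 0.70 respectively (predictions are
#' unchanged; only the truth side is stratified).
#'
#' @param stripes Data frame with `triangle`, `seed_bin`, `left_bin`,
#'   `right_bin`.
#' @param anchors Data frame from [bin_ground_truth()].
#' @param n_bins Number of bins in the chromosome.
#' @param stratify Also report occupancy strata (cutoff 0.70).
#' @return Data frame with one row per stratum (`stratum` column: `"all"`,
#'   `"occ>=0.70"`, `"occ<0.70"`), confusion counts and all twelve measures.
#' @export
benchmark_report <- function(stripes, anchors, n_bins, stratify = FALSE) {
  one <- function(anch, label) {
    cv <- classification_vectors(
      anch,
      data.frame(bin = stripes$seed_bin, triangle = stripes$triangle),
      n_bins
    )
    cm <- classification_metrics(cv$truth, cv$predicted)
    rm_ <- recognition_metrics(stripes, anch)
    as.data.frame(c(list(stratum = label), cm, rm_), stringsAsFactors = FALSE)
  }
  out <- one(anchors, "all")
  if (stratify) {
    out <- rbind(out,
                 one(anchors[anchors$occupancy >= 0.70, , drop = FALSE], "occ>=0.70"),
                 one(anchors[anchors$occupancy < 0.70, , drop = FALSE], "occ<0.70"))
  }
  rownames(out) <- NULL
  out
}

#' Read / write ground-truth barrier tables
#'
#' Tab-separated text with columns `chrom`, `position`, `direction`,
#' `occupancy` and a header line; comment lines start with `#`.
#'
#' @param path File path.
#' @return `read_barriers()` returns the barrier data frame.
#' @export
read_barriers <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "position", "direction", "occupancy") %in% names(tab)))
  tab
}

#' @rdname read_barriers
#' @param barriers Data frame with columns `chrom`, `position`, `direction`,
#'   `occupancy`.
#' @export
write_barriers <- function(barriers, path) {
  utils::write.table(barriers[c("chrom", "position", "direction", "occupancy")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
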