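test_that("barriers are binned and deduplicated per bin and direction", {
  bins <- bin_table("chrA", 1e6, 5e3)
  b <- data.frame(chrom = "chrA", position = c(12000, 14000),
                  direction = "lower", occupancy = c(0.6, 0.9))
  a <- bin_ground_truth(b, bins)
  expect_equal(nrow(a), 1L)
  expect_equal(a$bin, 2L)
  expect_equal(a$occupancy, 0.75)
  expect_equal(a$n_barriers, 2L)
  expect_gte(a$occupancy, 0.70)  # stratified into the high-occupancy class

  # same positions, opposite directions: one anchor per triangle
  b2 <- data.frame(chrom = "chrA", position = c(12000, 14000),
                   direction = c("lower", "upper"), occupancy = c(0.6, 0.9))
  a2 <- bin_ground_truth(b2, bins)
  expect_equal(nrow(a2), 2L)
  expect_setequal(a2$direction, c("lower", "upper"))
  expect_equal(a2$bin, c(2L, 2L))

  expect_error(bin_ground_truth(
    data.frame(position = 2e6, direction = "lower", occupancy = 0.5), bins),
    "outside chromosome")
})

test_that("classification metrics match the closed-form definitions", {
  # perfect prediction: every measure equals 1
  m <- classification_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  for (s in c("TPR", "TNR", "PPV", "bACC", "GM", "F1c", "FMc", "JI")) {
    expect_equal(m[[s]], 1)
  }

  # TP=2 FP=1 FN=3 TN=94
  truth <- c(rep(1, 5), rep(0, 95))
  pred <- c(1, 1, 0, 0, 0, 1, rep(0, 94))
  m <- classification_metrics(truth, pred)
  expect_equal(m$TP, 2); expect_equal(m$FP, 1)
  expect_equal(m$FN, 3); expect_equal(m$TN, 94)
  expect_equal(m$TPR, 0.4)
  expect_equal(m$PPV, 2 / 3)
  expect_equal(m$JI, 1 / 3)
  expect_equal(m$F1c, 0.5)
  expect_equal(m$FMc, sqrt(4 / 15))

  # degenerate: all-zero prediction with positives present
  m0 <- classification_metrics(truth, rep(0, 100))
  expect_equal(m0$TPR, 0)
  expect_true(is.nan(m0$PPV))
  expect_equal(m0$TNR, 1)
  expect_true(is.nan(m0$F1c))  # NaN propagates, never coerced to 0

  expect_error(classification_metrics(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("metric arithmetic matches an independent recomputation", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, runif(1, 0.05, 0.5))
    pred <- rbinom(n, 1, runif(1, 0.05, 0.5))
    m <- classification_metrics(truth, pred)
    tp <- sum(truth & pred); fp <- sum(!truth & pred)
    tn <- sum(!truth & !pred); fn <- sum(truth & !pred)
    d <- function(a, b) if (is.na(b) || b == 0) NaN else a / b
    want <- list(TPR = d(tp, tp + fn), TNR = d(tn, tn + fp),
                 PPV = d(tp, tp + fp))
    want$bACC <- (want$TPR + want$TNR) / 2
    want$GM <- sqrt(want$TPR * want$TNR)
    want$F1c <- d(2 * want$PPV * want$TPR, want$PPV + want$TPR)
    want$FMc <- sqrt(want$PPV * want$TPR)
    want$JI <- d(tp, tp + fp + fn)
    for (s in names(want)) {
      expect_equal(m[[s]], want[[s]], tolerance = 1e-12)
    }
    # AM-GM: FM >= F1 and bACC >= GM wherever defined
    if (!is.nan(m$F1c)) expect_gte(m$FMc, m$F1c - 1e-12)
    if (!is.nan(m$GM)) expect_gte(m$bACC, m$GM - 1e-12)
  }
})

test_that("recognition metrics count anchor containment per triangle", {
  # every anchor covered -> AHR 1
  stripes <- data.frame(triangle = "lower", left_bin = c(0L, 10L),
                        right_bin = c(5L, 15L))
  anchors <- data.frame(bin = c(2L, 12L), direction = "lower",
                        occupancy = 1, n_barriers = 1L)
  r <- recognition_metrics(stripes, anchors)
  expect_equal(r$AHR, 1)

  # 4 anchors, 3 stripes, 2 anchors covered by 2 distinct good stripes
  stripes2 <- data.frame(triangle = "lower",
                         left_bin = c(0L, 10L, 30L),
                         right_bin = c(5L, 15L, 32L))
  anchors2 <- data.frame(bin = c(2L, 12L, 50L, 60L), direction = "lower",
                         occupancy = 1, n_barriers = 1L)
  r2 <- recognition_metrics(stripes2, anchors2)
  expect_equal(r2$AHR, 0.5)
  expect_equal(r2$FGC, 2 / 3)
  expect_equal(r2$F1r, 2 * (0.5 * 2 / 3) / (0.5 + 2 / 3))
  expect_equal(r2$FMr, sqrt(0.5 * 2 / 3))
  expect_equal(r2$n_anchors_found, 2L)
  expect_equal(r2$n_stripes_predicted, 3L)

  # direction must match the stripe's triangle
  anchors3 <- data.frame(bin = 2L, direction = "upper",
                         occupancy = 1, n_barriers = 1L)
  expect_equal(recognition_metrics(stripes, anchors3)$AHR, 0)

  # degenerate denominators are NaN
  none <- data.frame(triangle = character(), left_bin = integer(),
                     right_bin = integer())
  expect_true(is.nan(recognition_metrics(none, anchors)$FGC))
  empty_anchors <- anchors[0, ]
  expect_true(is.nan(recognition_metrics(stripes, empty_anchors)$AHR))
})

test_that("width-1 stripes collapse recognition onto classification exactly", {
  set.seed(23)
  for (rep in 1:25) {
    n_bins <- sample(50:150, 1)
    truth_bins <- sort(sample(0:(n_bins - 1), sample(3:10, 1)))
    pred_bins <- sort(sample(0:(n_bins - 1), sample(3:10, 1)))
    dirs_t <- sample(c("lower", "upper"), length(truth_bins), replace = TRUE)
    dirs_p <- sample(c("lower", "upper"), length(pred_bins), replace = TRUE)
    anchors <- data.frame(bin = truth_bins, direction = dirs_t,
                          occupancy = 1, n_barriers = 1L)
    stripes <- data.frame(triangle = dirs_p, seed_bin = pred_bins,
                          left_bin = pred_bins, right_bin = pred_bins)
    # drop duplicate (bin, triangle) predictions so counts align
    stripes <- stripes[!duplicated(stripes[c("triangle", "left_bin")]), ]
    cv <- classification_vectors(
      anchors, data.frame(bin = stripes$seed_bin, triangle = stripes$triangle),
      n_bins)
    cm <- classification_metrics(cv$truth, cv$predicted)
    rm_ <- recognition_metrics(stripes, anchors)
    expect_identical(rm_$AHR, cm$TPR)
    expect_identical(rm_$FGC, cm$PPV)
    expect_identical(rm_$F1r, cm$F1c)
    expect_identical(rm_$FMr, cm$FMc)
  }
})

test_that("widening a stripe's horizontal domain never decreases AHR", {
  set.seed(29)
  for (rep in 1:20) {
    n_bins <- 100L
    anchors <- data.frame(bin = sort(sample(0:99, 8)),
                          direction = sample(c("lower", "upper"), 8, TRUE),
                          occupancy = 1, n_barriers = 1L)
    left <- sort(sample(0:95, 5))
    stripes <- data.frame(triangle = sample(c("lower", "upper"), 5, TRUE),
                          left_bin = left, right_bin = left + 1L)
    base <- recognition_metrics(stripes, anchors)$AHR
    wider <- stripes
    wider$left_bin <- pmax(0L, wider$left_bin - sample(0:3, 5, TRUE))
    wider$right_bin <- pmin(99L, wider$right_bin + sample(0:3, 5, TRUE))
    expect_gte(recognition_metrics(wider, anchors)$AHR, base)
  }
})

test_that("benchmark_report pools triangles and stratifies by occupancy", {
  anchors <- data.frame(bin = c(5L, 20L, 40L),
                        direction = c("lower", "lower", "upper"),
                        occupancy = c(0.9, 0.5, 0.8), n_barriers = 1L)
  stripes <- data.frame(triangle = c("lower", "upper"),
                        seed_bin = c(5L, 40L),
                        left_bin = c(4L, 39L), right_bin = c(6L, 41L))
  rep_all <- benchmark_report(stripes, anchors, 50L, stratify = TRUE)
  expect_equal(rep_all$stratum, c("all", "occ>=0.70", "occ<0.70"))
  expect_equal(rep_all$TP[1], 2)
  expect_equal(rep_all$FN[1], 1)
  expect_equal(rep_all$AHR[1], 2 / 3)
  expect_equal(rep_all$FGC[1], 1)
  expect_equal(rep_all$AHR[2], 1)    # both high-occupancy anchors found
  expect_equal(rep_all$AHR[3], 0)    # the 0.5-occupancy anchor is missed
})
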