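# Compound loss and overlap metrics: closed forms, oracles, identities.

test_that("binary cross-entropy matches hand evaluations", {
  t <- c(0, 1, 1, 0)
  expect_equal(bce_loss(rep(0.5, 4), t), log(2), tolerance = 1e-9)
  expect_lt(bce_loss(t, t), 1e-3)                        # perfect after clamping
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-9)
  expect_error(bce_loss(c(0.5, 0.5), c(0, 2)), "binary")
})

test_that("dice loss matches direct evaluation of its formula", {
  t <- c(1, 0, 1, 0)
  expect_equal(dice_loss(t, t), 0, tolerance = 1e-5)
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5, tolerance = 1e-5)
  expect_equal(dice_loss(rep(0, 8), rep(0, 8)), 0)       # empty-empty
})

test_that("the compound loss composes its two terms linearly", {
  o <- c(0.9, 0.2); t <- c(1, 0)
  w <- loss_weights()
  expect_equal(combined_loss(o, t, w),
               0.5 * bce_loss(o, t, w$epsilon) + dice_loss(o, t, w$epsilon),
               tolerance = 1e-12)
  expect_equal(combined_loss(o, t, w), 0.2250, tolerance = 1e-3)
  expect_lt(combined_loss(t, t, w), 1e-3)
  w0 <- loss_weights(lambda1 = 0)
  expect_equal(combined_loss(o, t, w0), dice_loss(o, t, w0$epsilon))
})

test_that("confusion counts agree with a pixel-by-pixel loop", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(cc, list(TP = 1L, FP = 1L, FN = 1L))

  t <- matrix(rbinom(64, 1, 0.4), 8)
  expect_equal(confusion_counts(t, t),
               list(TP = as.integer(sum(t)), FP = 0L, FN = 0L))

  set.seed(12)
  p <- matrix(rbinom(256, 1, 0.5), 16)
  q <- matrix(rbinom(256, 1, 0.3), 16)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in 1:16) for (j in 1:16) {
    if (p[i, j] == 1 && q[i, j] == 1) tp <- tp + 1L
    if (p[i, j] == 1 && q[i, j] == 0) fp <- fp + 1L
    if (p[i, j] == 0 && q[i, j] == 1) fn <- fn + 1L
  }
  expect_equal(confusion_counts(p, q), list(TP = tp, FP = fp, FN = fn))
  expect_equal(sum(p), confusion_counts(p, q)$TP + confusion_counts(p, q)$FP)

  expect_error(confusion_counts(c(0.5, 1), c(1, 0)), "binary")
})

test_that("IoU and Dice follow their count formulas and identity", {
  m <- evaluate_counts(list(TP = 6, FP = 2, FN = 2))
  expect_equal(m$iou, 0.6, tolerance = 1e-5)
  expect_equal(m$dice, 0.75, tolerance = 1e-5)
  expect_equal(evaluate_counts(list(TP = 9, FP = 0, FN = 0)),
               list(iou = 1, dice = 1), tolerance = 1e-5)
  z <- evaluate_counts(list(TP = 0, FP = 3, FN = 2))
  expect_lt(z$iou, 1e-4); expect_lt(z$dice, 1e-4)
  expect_equal(evaluate_counts(list(TP = 0, FP = 0, FN = 0)),
               list(iou = 1, dice = 1))

  set.seed(13)   # Dice = 2 IoU / (1 + IoU) across random counts
  for (i in 1:1000) {
    cc <- list(TP = sample(0:50, 1), FP = sample(0:50, 1), FN = sample(0:50, 1))
    if (cc$TP + cc$FP + cc$FN == 0) next
    iou <- cc$TP / (cc$TP + cc$FP + cc$FN)
    dice <- 2 * cc$TP / (cc$FP + 2 * cc$TP + cc$FN)
    expect_equal(dice, 2 * iou / (1 + iou), tolerance = 1e-12)
  }
})

test_that("dataset metrics are the mean of per-image metrics", {
  set.seed(14)
  probs <- lapply(1:5, function(i) matrix(runif(64), 8))
  masks <- lapply(1:5, function(i) matrix(rbinom(64, 1, 0.4), 8))
  agg <- segmentation_metrics(probs, masks)
  serial <- t(vapply(1:5, function(i) {
    m <- segmentation_metrics(probs[[i]], masks[[i]])$per_image
    c(m$iou, m$dice)
  }, numeric(2)))
  expect_equal(agg$summary[["mean_iou"]], mean(serial[, 1]), tolerance = 1e-12)
  expect_equal(agg$summary[["mean_dice"]], mean(serial[, 2]), tolerance = 1e-12)
})

test_that("metrics report round-trips through CSV and JSON", {
  set.seed(15)
  metrics <- segmentation_metrics(lapply(1:3, function(i) matrix(runif(16), 4)),
                                  lapply(1:3, function(i) matrix(rbinom(16, 1, 0.5), 4)))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metrics_report(metrics, csv, js)
  rows <- read.csv(csv)
  expect_equal(nrow(rows), 3L)
  expect_equal(mean(rows$dice), metrics$summary[["mean_dice"]], tolerance = 1e-9)
  expect_equal(jsonlite::read_json(js)$mean_iou, metrics$summary[["mean_iou"]],
               tolerance = 1e-9)
})
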