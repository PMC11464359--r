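box <- function(x1, y1, x2, y2, conf = NULL, cls = 0L) {
  b <- data.frame(x_min = x1, y_min = y1, x_max = x2, y_max = y2,
                  class_id = cls)
  if (!is.null(conf)) b$confidence <- conf
  b
}

test_that("greedy one-to-one matching covers identity, double detection and miss", {
  g <- box(0, 0, 10, 10)
  m <- match_detections(box(0, 0, 10, 10, conf = 0.9), g)
  expect_identical(c(m$TP, m$FP, m$FN), c(1L, 0L, 0L))
  expect_equal(m$pairs$iou, 1)
  # two overlapping predictions on one object: second one is a false positive
  two <- rbind(box(0, 0, 10, 10, conf = 0.9), box(1, 1, 11, 11, conf = 0.8))
  m2 <- match_detections(two, g)
  expect_identical(c(m2$TP, m2$FP, m2$FN), c(1L, 1L, 0L))
  expect_identical(m2$pairs$pred_idx, 1L)
  # disjoint boxes: miss plus false positive
  m3 <- match_detections(box(50, 50, 60, 60, conf = 1), g)
  expect_identical(c(m3$TP, m3$FP, m3$FN), c(0L, 1L, 1L))
  expect_error(match_detections(box(5, 5, 5, 10), g), "extent")
})

test_that("precision, recall and F1 follow their defining ratios with 0/0 -> 0", {
  pm <- detection_metrics(list(TP = 90, FP = 10, FN = 10))
  expect_equal(unname(pm), c(0.9, 0.9, 0.9))
  expect_equal(unname(detection_metrics(list(TP = 0, FP = 0, FN = 5))),
               c(0, 0, 0))
  expect_equal(unname(detection_metrics(list(TP = 1, FP = 0, FN = 0))),
               c(1, 1, 1))
  # F1 is the harmonic mean, not the arithmetic one
  pm2 <- detection_metrics(list(TP = 30, FP = 10, FN = 70))
  expect_equal(unname(pm2["F1"]),
               2 * 0.75 * 0.3 / (0.75 + 0.3))
})

test_that("single matching prediction gives AP 1 and mAP averages classes", {
  g <- box(0, 0, 10, 10)
  expect_equal(average_precision(box(0, 0, 10, 10, conf = 0.7), g), 1)
  # two classes, one perfect and one half-recalled at full precision
  gts <- rbind(box(0, 0, 10, 10, cls = 0L),
               box(20, 20, 30, 30, cls = 1L), box(40, 40, 50, 50, cls = 1L))
  preds <- rbind(box(0, 0, 10, 10, conf = 0.9, cls = 0L),
                 box(20, 20, 30, 30, conf = 0.8, cls = 1L))
  r <- map_over_classes(preds, gts)
  expect_equal(unname(r$AP_per_class), c(1, 0.5))
  expect_equal(r$mAP, 0.75)
  expect_error(map_over_classes(box(0, 0, 1, 1, conf = 1, cls = 7L), gts),
               "universe")
})

test_that("AP equals the brute-force cutoff-enumeration oracle on random instances", {
  set.seed(41)
  for (rep in 1:200) {
    inst <- random_instance(n_pred = sample(1:10, 1), n_gt = sample(1:8, 1))
    got <- average_precision(inst$preds, inst$gts)
    want <- ap_oracle(inst$preds, inst$gts)
    expect_equal(got, want, tolerance = 1e-12, info = rep)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("count metrics reproduce the hand-worked case and its edge cases", {
  cm <- count_metrics(c(10, 20, 30), c(12, 18, 33))
  expect_equal(unname(cm["RMSE"]), sqrt(17 / 3), tolerance = 1e-12)
  expect_equal(unname(cm["R2"]), 1 - 17 / 200, tolerance = 1e-12)
  expect_equal(unname(cm["RRMSE"]), 100 * sqrt(17 / 3) / 20, tolerance = 1e-12)
  perfect <- count_metrics(c(5, 9, 14), c(5, 9, 14))
  expect_equal(unname(perfect), c(1, 0, 0))
  null_model <- count_metrics(c(10, 20, 30), c(20, 20, 20))
  expect_equal(unname(null_model["R2"]), 0)
  expect_error(count_metrics(c(3, 3, 3), c(1, 2, 3)), "equal")
  expect_error(count_metrics(1:3, 1:4), "length")
  expect_error(count_metrics(5, 5), "two")
})

test_that("count metrics are invariant to image order and R2 never exceeds 1", {
  set.seed(42)
  for (rep in 1:20) {
    Y <- sample(5:40, 12)
    X <- pmax(0, Y + sample(-4:4, 12, replace = TRUE))
    p <- sample(12)
    expect_identical(count_metrics(Y, X), count_metrics(Y[p], X[p]))
    expect_lte(count_metrics(Y, X)["R2"], 1)
  }
})

test_that("YOLO prediction files score against label files end to end", {
  dir <- withr::local_tempdir()
  # image 1: two objects, both found (one box slightly jittered);
  # image 2: one object missed, one spurious detection
  gt1 <- data.frame(class_id = 0L, x_center = c(0.25, 0.70),
                    y_center = c(0.25, 0.70), width = 0.2, height = 0.2)
  pr1 <- gt1
  pr1$x_center <- pr1$x_center + c(0.01, 0)
  pr1$confidence <- c(0.9, 0.8)
  gt2 <- data.frame(class_id = 0L, x_center = 0.5, y_center = 0.5,
                    width = 0.3, height = 0.3)
  pr2 <- data.frame(class_id = 0L, x_center = 0.1, y_center = 0.9,
                    width = 0.1, height = 0.1, confidence = 0.7)
  for (nm in c("gt1", "pr1", "gt2", "pr2")) {
    write_yolo_labels(get(nm), file.path(dir, paste0(nm, ".txt")))
  }
  res <- score_yolo_files(file.path(dir, c("pr1.txt", "pr2.txt")),
                          file.path(dir, c("gt1.txt", "gt2.txt")),
                          image_sizes = cbind(c(100, 100), c(100, 100)))
  expect_equal(res$P, 2 / 3)
  expect_equal(res$R, 2 / 3)
  expect_equal(res$Y, c(2L, 1L))
  expect_equal(res$X, c(2L, 1L))
  expect_gt(res$mAP, 0.5)
})
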