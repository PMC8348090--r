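# independent one-vs-rest oracle: recompute metrics from label pairs
oracle_metrics <- function(cm) {
  classes <- rownames(cm)
  out <- t(vapply(seq_along(classes), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }, numeric(3)))
  rownames(out) <- classes
  out
}

test_that("confusion matrix counts exactly and row-normalizes to recall", {
  truth <- rep(c("bite", "chew", "chew_bite"), each = 10)
  cm <- confusion_matrix(truth, truth)
  expect_equal(diag(unclass(cm)), c(bite = 10L, chew = 10L, chew_bite = 10L))
  expect_equal(sum(cm) - sum(diag(unclass(cm))), 0L)

  all_chew <- confusion_matrix(truth, rep("chew", 30))
  expect_equal(unname(colSums(all_chew)), c(0L, 30L, 0L))

  set.seed(11)
  pred <- sample(c("bite", "chew", "chew_bite"), 30, replace = TRUE)
  cm2 <- confusion_matrix(truth, pred)
  rn <- normalize_confusion(cm2)
  rep2 <- suppressWarnings(precision_recall_f1(cm2))
  expect_equal(unname(diag(rn)), rep2$per_class$recall)

  expect_error(confusion_matrix(truth, pred[-1]), "length")
  expect_error(confusion_matrix(c("bite"), c("moo")), "unknown labels")
})

test_that("precision/recall/F1 match the hand-worked example exactly", {
  cm <- matrix(c(8, 1, 1, 2, 6, 2, 0, 2, 8), 3, 3, byrow = TRUE,
               dimnames = list(true = c("bite", "chew", "chew_bite"),
                               predicted = c("bite", "chew", "chew_bite")))
  class(cm) <- c("confusion_matrix", class(cm))
  rep <- precision_recall_f1(cm)
  bite <- rep$per_class[rep$per_class$behavior == "bite", ]
  expect_equal(bite$precision, 0.8)
  expect_equal(bite$recall, 0.8)
  expect_equal(bite$f1, 0.8)
  expect_equal(unname(unlist(rep$per_class[2:4])),
               as.vector(oracle_metrics(cm)), tolerance = 1e-12)
})

test_that("metrics agree with the brute-force oracle on random matrices", {
  set.seed(23)
  for (i in 1:100) {
    cm <- matrix(rpois(9, 5), 3, 3,
                 dimnames = list(true = c("bite", "chew", "chew_bite"),
                                 predicted = c("bite", "chew", "chew_bite")))
    if (sum(cm) == 0) cm[1, 1] <- 1
    class(cm) <- c("confusion_matrix", class(cm))
    rep <- suppressWarnings(precision_recall_f1(cm))
    orc <- oracle_metrics(cm)
    expect_equal(rep$per_class$precision, unname(orc[, "precision"]))
    expect_equal(rep$per_class$recall, unname(orc[, "recall"]))
    expect_equal(rep$per_class$f1, unname(orc[, "f1"]))
    # micro-averaged recall equals overall accuracy
    support <- rowSums(cm)
    micro <- sum(support / sum(support) * orc[, "recall"])
    expect_equal(micro, sum(diag(unclass(cm))) / sum(cm))
    expect_equal(unname(rep$overall["recall"]), micro)
    # F1 lies between precision and recall
    with(rep$per_class, expect_true(all(f1 >= pmin(precision, recall) - 1e-12 &
                                          f1 <= pmax(precision, recall) + 1e-12)))
  }
})

test_that("degenerate predictions yield zero metrics with a warning", {
  cm <- confusion_matrix(rep(c("bite", "chew", "chew_bite"), each = 2),
                         rep("chew", 6))
  expect_warning(rep <- precision_recall_f1(cm), "precision")
  expect_equal(rep$per_class$precision[rep$per_class$behavior == "bite"], 0)
  expect_error(precision_recall_f1(confusion_matrix(character(0), character(0))),
               "empty")
})

test_that("processing speed normalizes time per second of audio", {
  expect_equal(processing_speed(5, 60), 83 + 1 / 3)
  expect_equal(processing_speed(7, 7), 1000)
  expect_error(processing_speed(1, 0), "duration")
})

test_that("segment descriptors recover amplitude and duration", {
  square <- audio_segment(rep(c(32767L, -32768L), 500))
  d <- segment_descriptors(square)
  expect_equal(d$amplitude, 65535 / 65536)
  expect_equal(segment_descriptors(audio_segment(rep(1L, 22050)))$duration, 1)
  expect_error(segment_descriptors(audio_segment(integer(0))), "empty")
})
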