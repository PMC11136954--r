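# Metric suite: accumulation against a per-pixel loop oracle, all seven
# metrics against an independent one-vs-rest computation, formatting, and
# internal consistency of the published benchmark tables.

test_that("accumulation counts pixels, commutes, and respects ignore_index", {
  cm <- confusion_matrix(3)
  pred <- array(1L, dim = c(2, 5))
  targ <- array(1L, dim = c(2, 5))
  cm <- cm_accumulate(cm, pred, targ)
  expect_equal(unclass(cm)[2, 2], 10)
  expect_equal(sum(cm), 10)

  set.seed(1)
  a_p <- sample(0:2, 40, TRUE); a_t <- sample(0:2, 40, TRUE)
  b_p <- sample(0:2, 25, TRUE); b_t <- sample(0:2, 25, TRUE)
  ab <- cm_accumulate(cm_accumulate(confusion_matrix(3), a_p, a_t), b_p, b_t)
  ba <- cm_accumulate(cm_accumulate(confusion_matrix(3), b_p, b_t), a_p, a_t)
  expect_equal(ab, ba)
  # naive double-loop oracle
  ref <- matrix(0, 3, 3)
  for (i in seq_along(a_p)) ref[a_t[i] + 1, a_p[i] + 1] <-
      ref[a_t[i] + 1, a_p[i] + 1] + 1
  for (i in seq_along(b_p)) ref[b_t[i] + 1, b_p[i] + 1] <-
      ref[b_t[i] + 1, b_p[i] + 1] + 1
  expect_equal(unclass(ab), ref, ignore_attr = TRUE)

  skip <- cm_accumulate(confusion_matrix(3), c(0L, 1L), c(9L, 1L),
                        ignore_index = 9L)
  expect_equal(sum(skip), 1)
  expect_error(cm_accumulate(confusion_matrix(3), c(5L), c(0L)),
               "out of range")
})

test_that("the 2x2 worked example reproduces hand arithmetic for all metrics", {
  cm <- confusion_matrix(2, c("a", "b"))
  m <- unclass(cm); m[1, ] <- c(50, 10); m[2, ] <- c(5, 35)
  class(m) <- class(cm); dimnames(m) <- dimnames(cm)
  r <- compute_report(m)
  expect_equal(r$per_class$precision, 100 * c(50 / 55, 35 / 45))
  expect_equal(r$per_class$recall, 100 * c(50 / 60, 35 / 40))
  p0 <- 50 / 55; r0 <- 50 / 60
  expect_equal(r$per_class$f1[1], 100 * 2 * p0 * r0 / (p0 + r0))
  expect_equal(r$per_class$iou, 100 * c(50 / 65, 35 / 50))
  expect_equal(r$overall_accuracy, 85)
  expect_equal(r$miou, 100 * mean(c(50 / 65, 35 / 50)))
  expect_equal(r$fwiou, 100 * (50 / 65 * 60 + 35 / 50 * 40) / 100)
})

test_that("a perfect confusion matrix scores 100 everywhere", {
  cm <- confusion_matrix(3)
  m <- unclass(cm); diag(m) <- c(10, 20, 30); class(m) <- class(cm)
  r <- compute_report(m)
  expect_equal(r$per_class$precision, rep(100, 3))
  expect_equal(r$per_class$iou, rep(100, 3))
  expect_equal(r$overall_accuracy, 100)
  expect_equal(r$miou, 100)
  expect_equal(r$fwiou, 100)
  expect_length(r$undefined, 0)
})

test_that("all seven metrics match an independent per-class computation on random matrices", {
  set.seed(2)
  for (rep in 1:100) {
    K <- sample(2:5, 1)
    m <- matrix(rpois(K * K, 20), K, K)
    if (sum(m) == 0) m[1, 1] <- 1
    cm <- confusion_matrix(K)
    mm <- unclass(cm) * 0 + m
    class(mm) <- class(cm)
    r <- compute_report(mm)
    iou <- numeric(K)
    for (k in 1:K) {        # one-vs-rest binary computation per class
      tp <- m[k, k]; fp <- sum(m[, k]) - tp; fn <- sum(m[k, ]) - tp
      pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
      iou[k] <- if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn)
      expect_equal(r$per_class$precision[k], 100 * pr)
      expect_equal(r$per_class$recall[k], 100 * rc)
      expect_equal(r$per_class$f1[k], 100 * f1)
      expect_equal(r$per_class$iou[k], 100 * iou[k])
    }
    expect_equal(r$overall_accuracy, 100 * sum(diag(m)) / sum(m))
    expect_equal(r$miou, 100 * mean(iou))
    expect_equal(r$fwiou, 100 * sum(iou * rowSums(m)) / sum(m))
    # FWIoU is a convex combination of per-class IoUs
    expect_gte(r$fwiou, 100 * min(iou) - 1e-9)
    expect_lte(r$fwiou, 100 * max(iou) + 1e-9)
  }
})

test_that("0/0 ratios are reported as 0 with a flag", {
  cm <- confusion_matrix(3)
  m <- unclass(cm); m[1, 1] <- 5; m[2, 1] <- 3   # class 3 never occurs
  class(m) <- class(cm); dimnames(m) <- dimnames(cm)
  r <- compute_report(m)
  expect_equal(r$per_class$precision[3], 0)
  expect_true(any(grepl("weed", r$undefined)))
  expect_error(compute_report(confusion_matrix(2)), "empty")
})

test_that("table formatting is lossless at two decimals", {
  cm <- confusion_matrix(3)
  m <- unclass(cm) + matrix(c(97, 1, 2, 3, 88, 2, 1, 4, 90), 3, 3)
  class(m) <- class(cm); dimnames(m) <- dimnames(cm)
  r <- compute_report(m)
  txt <- format_metrics_table(list(modelA = r))
  expect_length(txt, 2)
  cells <- strsplit(trimws(txt[2]), " +")[[1]]
  vals <- as.numeric(cells[-1])
  row <- report_row(r, "modelA")
  expect_equal(vals, floor(as.numeric(row[-1]) * 100 + 0.5) / 100)
  # perfect report prints 100.00 in every numeric cell
  mp <- unclass(confusion_matrix(2, c("x", "y"))); diag(mp) <- 5
  class(mp) <- c("confusion_matrix", "matrix")
  txtp <- format_metrics_table(list(perfect = compute_report(mp)))
  cellsp <- strsplit(trimws(txtp[2]), " +")[[1]]
  expect_true(all(cellsp[-1] == "100.00"))
})

test_that("published benchmark rows are internally consistent", {
  tabs <- reference_tables()
  cons <- table_consistency(tabs)
  # headline rows: exact at the printed 2-decimal precision
  for (key in list(c("ablation", "erfnet-ce"), c("ablation", "epanet"))) {
    row <- cons[cons$table == key[1] & cons$method == key[2], ]
    expect_lte(row$f1_max_abs_err, 0.005)
    expect_lte(row$miou_abs_err, 0.005)
  }
  # all rows: within the rounding-propagation bound of the printed cells
  # (per-class inputs are themselves rounded to 2 dp)
  expect_lte(max(cons$f1_max_abs_err), 0.01 + 1e-9)
  expect_lte(max(cons$miou_abs_err), 0.01 + 1e-9)
  # ERFnet bean-seedling row: F1 = 2PR/(P+R) of the printed P, R
  bean <- tabs[tabs$method == "erfnet-ce" & tabs$class == "bean_seedling", ]
  expect_equal(round(2 * bean$precision * bean$recall /
                       (bean$precision + bean$recall), 2), 87.34)
})
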