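test_that("confusion counts follow the >= threshold convention", {
  cm <- confusion(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(unclass(cm)[c("tp", "tn", "fp", "fn")],
               list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  # score equal to the threshold is called positive
  expect_equal(confusion(0.5, 1, 0.5)$tp, 1L)
  cm <- confusion(rep(1, 5), c(1, 1, 0, 0, 0), 0.5)  # all predicted positive
  expect_equal(cm$fn + cm$tn, 0L)
  expect_error(confusion(1:3, 1:2), "same length")
  expect_error(confusion(numeric(0), integer(0)), "empty")
})

test_that("confusion matches a loop oracle on random data", {
  set.seed(41)
  s <- runif(1000)
  l <- rbinom(1000, 1, 0.4)
  for (thr in c(0.2, 0.5, 0.8)) {
    cm <- confusion(s, l, thr)
    tp <- tn <- fp <- fn <- 0L
    for (i in seq_along(s)) {
      p <- s[i] >= thr
      if (p && l[i] == 1) tp <- tp + 1L
      if (p && l[i] == 0) fp <- fp + 1L
      if (!p && l[i] == 1) fn <- fn + 1L
      if (!p && l[i] == 0) tn <- tn + 1L
    }
    expect_equal(unclass(cm)[c("tp", "tn", "fp", "fn")],
                 list(tp = tp, tn = tn, fp = fp, fn = fn))
  }
  # raising the threshold never increases tp or fp
  thr_grid <- seq(0, 1, by = 0.05)
  tps <- sapply(thr_grid, function(t) confusion(s, l, t)$tp)
  fps <- sapply(thr_grid, function(t) confusion(s, l, t)$fp)
  expect_true(all(diff(tps) <= 0))
  expect_true(all(diff(fps) <= 0))
})

test_that("published-scale confusion counts reproduce the printed metrics", {
  # independent-test confusion reconstructed from Sn/Sp at 2,989 per class
  m <- metrics_from_confusion(list(tp = 2699, tn = 2342, fp = 647, fn = 290))
  expect_equal(round(m$sn, 4), 0.9030)
  expect_equal(round(m$sp, 4), 0.7835)
  expect_equal(round(m$acc, 4), 0.8433)
  expect_equal(round(m$mcc, 4), 0.6915)
})

test_that("metric formulas agree with independent recomputation", {
  perfect <- metrics_from_confusion(list(tp = 7, tn = 13, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(sn = 1, sp = 1, acc = 1, mcc = 1))
  # MCC equals the Pearson correlation of the two binary vectors
  set.seed(42)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- ifelse(runif(n) < 0.7, truth, 1 - truth)
    if (length(unique(truth)) < 2 || length(unique(pred)) < 2) next
    cm <- list(tp = sum(pred & truth), tn = sum(!pred & !truth),
               fp = sum(pred & !truth), fn = sum(!pred & truth))
    m <- metrics_from_confusion(cm)
    expect_equal(m$mcc, cor(pred, truth), tolerance = 1e-12)
    expect_equal(m$acc, mean(pred == truth), tolerance = 1e-12)
    expect_equal(m$sn, mean(pred[truth == 1]), tolerance = 1e-12)
    expect_equal(m$sp, mean(1 - pred[truth == 0]), tolerance = 1e-12)
  }
  # degenerate margin (no predicted positives) -> MCC 0 by convention
  expect_equal(metrics_from_confusion(list(tp = 0, tn = 3, fp = 0, fn = 2))$mcc, 0)
  expect_true(is.na(metrics_from_confusion(list(tp = 0, tn = 3, fp = 1, fn = 0))$sn))
  expect_error(metrics_from_confusion(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "zero")
})

test_that("AUC equals the pairwise Mann-Whitney statistic", {
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5))$auc, 0.5)  # all tied
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)   # separated
  set.seed(43)
  s <- round(runif(500), 1)  # heavy ties stress the midrank convention
  l <- rbinom(500, 1, 0.5)
  got <- roc_auc(s, l)$auc
  pos <- s[l == 1]; neg <- s[l == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(got, mean(cmp), tolerance = 1e-9)
  # label swap mirrors the AUC
  expect_equal(roc_auc(s, 1 - l)$auc, 1 - got, tolerance = 1e-9)
  # swapping labels AND negating scores preserves it
  expect_equal(roc_auc(-s, 1 - l)$auc, got, tolerance = 1e-9)
  expect_error(roc_auc(s, rep(1, 500)), "both classes")
})

test_that("evaluate assembles the individual metrics", {
  set.seed(44)
  s <- runif(200)
  l <- rbinom(200, 1, 0.5)
  rep <- evaluate(s, l, threshold = 0.4)
  cm <- confusion(s, l, 0.4)
  m <- metrics_from_confusion(cm)
  expect_equal(rep$sn, m$sn)
  expect_equal(rep$mcc, m$mcc)
  expect_equal(rep$auc, roc_auc(s, l)$auc)
  expect_equal(rep$n_pos, sum(l))
  # perfect scores give an all-ones report
  perf <- evaluate(l, l)
  expect_equal(c(perf$sn, perf$sp, perf$acc, perf$mcc, perf$auc),
               rep(1, 5))
  # label swap exchanges Sn and Sp
  a <- evaluate(s, l); b <- evaluate(1 - s, 1 - l)
  expect_equal(a$sn, b$sp, tolerance = 1e-12)
  expect_equal(a$sp, b$sn, tolerance = 1e-12)
})

test_that("metric reports serialize to CSV and JSON", {
  set.seed(45)
  rep <- evaluate(runif(50), rbinom(50, 1, 0.5))
  prefix <- file.path(withr::local_tempdir(), "m")
  write_metrics(rep, prefix)
  back <- read.csv(paste0(prefix, ".csv"))
  expect_equal(back$mcc, rep$mcc, tolerance = 1e-12)
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$auc, rep$auc, tolerance = 1e-12)
  roc <- read.csv(paste0(prefix, "_roc.csv"))
  expect_equal(names(roc), c("fpr", "tpr", "threshold"))
})
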