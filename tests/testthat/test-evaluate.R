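test_that("macro metrics evaluate hand-built confusions exactly", {
  # perfect prediction
  r <- macro_metrics(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))

  # binary with per-class TP=8, FP=2, FN=2
  cm <- matrix(c(8L, 2L, 2L, 8L), 2, byrow = TRUE)
  r2 <- metrics_from_confusion(cm)
  expect_equal(r2$precision, 0.8)
  expect_equal(r2$recall, 0.8)
  expect_equal(r2$f1, 0.8)

  # all-one-class prediction: undefined precisions count as 0
  r3 <- macro_metrics(c(1, 1, 2, 2), c(1, 1, 1, 1), n_classes = 2)
  expect_equal(r3$per_class$precision, c(0.5, 0))
  expect_equal(r3$recall, 0.5)

  expect_error(macro_metrics(c(1, 5), c(1, 1), n_classes = 2), "label error")
  expect_error(macro_metrics(1:3, 1:2), "equal length")
})

test_that("confusion-matrix metrics equal label-vector metrics", {
  set.seed(12)
  for (i in 1:20) {
    Q <- sample(2:5, 1); n <- 60
    yt <- sample(Q, n, replace = TRUE)
    yp <- sample(Q, n, replace = TRUE)
    a <- macro_metrics(yt, yp, Q)
    b <- metrics_from_confusion(a$confusion)
    expect_equal(a$precision, b$precision)
    expect_equal(a$recall, b$recall)
    expect_equal(a$f1, b$f1)
    expect_equal(rowSums(a$confusion),
                 as.numeric(tabulate(yt, Q)))
  }
})

test_that("F1 is the harmonic mean and collapses to P when P = R", {
  set.seed(13)
  for (i in 1:100) {
    Q <- sample(2:6, 1)
    m <- matrix(rpois(Q * Q, 5), Q)
    r <- metrics_from_confusion(m)
    if (r$precision + r$recall > 0)
      expect_equal(r$f1, 2 * r$precision * r$recall /
                     (r$precision + r$recall), tolerance = 1e-12)
    # symmetric confusion: FP = FN per class, so P* = R* and F1 = P*
    s <- metrics_from_confusion(m + t(m))
    expect_equal(s$precision, s$recall, tolerance = 1e-12)
    expect_equal(s$f1, s$precision, tolerance = 1e-12)
  }
})

test_that("task-wise splits honour the ratio grammar and partition tasks", {
  man <- data.frame(path = "x", subject = 1L, task = 1:14)
  for (ratio in c("4:10", "7:7", "10:4", "13:1")) {
    ab <- as.integer(strsplit(ratio, ":")[[1]])
    sp <- split_by_tasks(man, ratio, fold = 0)
    expect_length(sp$train_tasks, ab[1])
    expect_length(sp$test_tasks, ab[2])
    expect_length(intersect(sp$train_tasks, sp$test_tasks), 0L)
    expect_setequal(c(sp$train_tasks, sp$test_tasks), 1:14)
    # held-out folds are pairwise disjoint and cover all tasks
    held <- lapply(seq_len(sp$n_folds) - 1L,
                   function(f) split_by_tasks(man, ratio, f)$test_tasks)
    expect_setequal(unlist(held), 1:14)
    expect_equal(sum(lengths(held)), 14L)
  }
  expect_error(split_by_tasks(man, "13:2"), "ratio error")
  expect_error(split_by_tasks(man, "nonsense"), "ratio error")
  expect_error(split_by_tasks(man, "13:1", fold = 14), "fold index")
})

test_that("every baseline reaches the memorization ceiling on a separable toy", {
  set.seed(14)
  n <- 30
  x <- rbind(matrix(rnorm(n * 4, 0), n), matrix(rnorm(n * 4, 4), n))
  fe <- structure(list(
    x = x,
    labels = data.frame(subject = rep(1:2, each = n),
                        task = 1L, class = rep(1:2, each = n))),
    class = "feature_set")
  for (name in c("svm", "lda", "nn", "dts", "bayes", "adaboost", "mlp")) {
    r <- run_baseline(name, fe, split = NULL, target = "subject")
    expect_equal(r$f1, 1, tolerance = 1e-9, label = paste(name, "F1"))
  }
  expect_error(run_baseline("nope", fe, NULL), "registry error")
})

test_that("1-NN returns the class of an exactly matching training point", {
  fe <- structure(list(
    x = matrix(c(0, 0, 10, 10, 0, 0), 3, byrow = TRUE),
    labels = data.frame(subject = c(1L, 2L, 1L), task = c(1L, 1L, 2L),
                        class = 1L)),
    class = "feature_set")
  sp <- list(train_tasks = 1L, test_tasks = 2L)
  r <- run_baseline("nn", fe, sp, target = "subject")
  expect_equal(r$confusion[1, 1], 1L)   # test point equals subject 1's point
})

test_that("baselines sit at chance under permuted labels", {
  set.seed(15)
  n <- 240
  x <- matrix(rnorm(n * 6), n)
  labs <- data.frame(subject = sample(rep(1:2, n / 2)),
                     task = rep(1:6, each = n / 6), class = 1L)
  fe <- structure(list(x = x, labels = labs), class = "feature_set")
  accs <- vapply(0:2, function(f) {
    sp <- split_by_tasks(data.frame(task = 1:6), "4:2", f)
    r <- run_baseline("nn", fe, sp, target = "subject")
    sum(diag(r$confusion)) / sum(r$confusion)
  }, 0)
  se <- sqrt(0.25 / (n / 3))
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("the experiment driver enumerates the requested grid", {
  s <- synth10()
  res <- run_experiment(s$manifest, fs = s$fs, methods = "nn",
                        l_tildes = c(120L, 150L), k_tildes = NA,
                        ratios = c("3:1", "2:2"), folds = 0L,
                        target = "subject", classes = 2L, seed = 3L)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$precision >= 0 & res$precision <= 1))
  expect_true(all(res$f1 >= 0 & res$f1 <= 1))
  res2 <- run_experiment(s$manifest, fs = s$fs, methods = "nn",
                         l_tildes = c(120L, 150L), k_tildes = NA,
                         ratios = c("3:1", "2:2"), folds = 0L,
                         target = "subject", classes = 2L, seed = 3L)
  expect_identical(res, res2)
})

test_that("deep and classical branches both recover subject identity", {
  s <- synth10()
  tl <- trained_lstm()
  pred <- apply(forward_lstm(tl$model, tl$test$segments), 2L, which.max)
  lstm_f1 <- macro_metrics(tl$test$labels$subject, pred, 10L)$f1
  feats <- memo("synth10_features", function()
    extract_features(eeglink:::normalize_batch(s$batch, s$fs), fs = s$fs))
  nn_f1 <- run_baseline("nn", feats, s$split, target = "subject")$f1
  # 10-class chance macro F1 is about 0.1; both branches must clear 3x that
  expect_gte(lstm_f1, 0.3)
  expect_gte(nn_f1, 0.3)
})
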