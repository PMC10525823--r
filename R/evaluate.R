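#' Macro-averaged precision, recall and F1
#'
#' Per class q: precision = TP/(TP+FP), recall = TP/(TP+FN), with 0 where
#' the denominator is 0. The macro averages P* and R* are the unweighted
#' means over classes, and F1 is their harmonic mean
#' `2 P* R* / (P* + R*)` (0 when P* + R* = 0).
#'
#' @param y_true,y_pred equal-length integer label vectors in 1..n_classes.
#' @param n_classes number of classes (default: max observed label).
#' @return A `metrics_report`: list with `confusion` (n x n integer matrix,
#'   rows = true class), `per_class` (data.frame of precision/recall/F1 and
#'   support), and the macro `precision`, `recall`, `f1`.
#' @examples
#' macro_metrics(c(1, 1, 2, 2), c(1, 2, 2, 2))
#' @export
macro_metrics <- function(y_true, y_pred, n_classes = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("label vectors must have equal length")
  if (is.null(n_classes)) n_classes <- max(y_true, y_pred)
  if (any(c(y_true, y_pred) < 1L) || any(c(y_true, y_pred) > n_classes))
    stop("label error: labels outside 1..", n_classes)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  metrics_from_confusion(cm)
}

#' @rdname macro_metrics
#' @param cm a square confusion matrix of counts (rows = true class,
#'   columns = predicted class).
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1c <- safe_div(2 * prec * rec, prec + rec)
  P <- mean(prec); R <- mean(rec)
  structure(list(
    confusion = cm,
    per_class = data.frame(class = seq_len(nrow(cm)), precision = prec,
                           recall = rec, f1 = f1c, support = rowSums(cm)),
    precision = P, recall = R,
    f1 = if (P + R > 0) 2 * P * R / (P + R) else 0),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> macro P=%.4f R=%.4f F1=%.4f (%d classes, %d obs)\n",
              x$precision, x$recall, x$f1, nrow(x$confusion),
              sum(x$confusion)))
  invisible(x)
}

#' Task-wise train/test split
#'
#' Splits every subject's tasks into `a` training and `b` held-out tasks
#' according to a ratio string `"a:b"` with `a + b = M` (the tasks per
#' subject). Splits are always task-wise, never segment-wise, so no
#' temporal context of one recording leaks between train and test. The
#' fold index rotates which block of tasks is held out (consecutive blocks
#' of `b` tasks; when `b` does not divide M the final fold holds out the
#' remaining tasks, so folds always partition the task set).
#'
#' @param manifest an [eeg_manifest] (or anything with a `task` column).
#' @param ratio ratio string, e.g. `"13:1"`, `"7:7"`.
#' @param fold 0-based fold index, `0 <= fold < n_folds(M, b)`.
#' @return A `split_plan`: list with `train_tasks`, `test_tasks`, `ratio`,
#'   `fold`, `n_folds`.
#' @export
split_by_tasks <- function(manifest, ratio, fold = 0L) {
  tasks <- sort(unique(manifest$task))
  M <- length(tasks)
  parts <- suppressWarnings(as.integer(strsplit(ratio, ":", fixed = TRUE)[[1L]]))
  if (length(parts) != 2L || anyNA(parts))
    stop("ratio error: cannot parse ratio '", ratio, "'")
  a <- parts[1L]; b <- parts[2L]
  if (a + b != M)
    stop(sprintf("ratio error: %d:%d does not sum to the %d tasks per subject",
                 a, b, M))
  nf <- as.integer(ceiling(M / b))
  fold <- as.integer(fold)
  if (fold < 0L || fold >= nf)
    stop("fold index must be in 0..", nf - 1L)
  lo <- fold * b + 1L
  hi <- min((fold + 1L) * b, M)
  test <- tasks[lo:hi]
  structure(list(train_tasks = setdiff(tasks, test), test_tasks = test,
                 ratio = ratio, fold = fold, n_folds = nf),
            class = "split_plan")
}

# SAMME AdaBoost over depth-1 rpart stumps (no boosting package installed)
adaboost_fit <- function(x, y, n_rounds = 50L) {
  n <- nrow(x); Kc <- nlevels(y)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  df <- data.frame(y = y, x)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1L,
                                                       cp = -1, minsplit = 2L,
                                                       xval = 0L))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / Kc) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(Kc - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-10) break
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

adaboost_predict <- function(model, x) {
  scores <- matrix(0, nrow(x), length(model$levels))
  df <- data.frame(x)
  for (m in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[m]], df, type = "class")
    scores <- scores + model$alphas[m] *
      outer(as.integer(pred), seq_along(model$levels), "==")
  }
  factor(model$levels[max.col(scores, ties.method = "first")],
         levels = model$levels)
}

#' Run one baseline classifier
#'
#' Fits an off-the-shelf classifier on the training portion of a classical
#' feature set and scores the held-out portion. Available baselines:
#' linear-kernel SVM (`svm`), linear discriminant analysis (`lda`),
#' 1-nearest-neighbour (`nn`), a decision tree (`dts`), naive Bayes
#' (`bayes`), SAMME AdaBoost over decision stumps (`adaboost`) and a
#' single-hidden-layer perceptron (`mlp`). Hyperparameters beyond the SVM's
#' linear kernel are the libraries' defaults.
#'
#' @param name one of `"svm"`, `"lda"`, `"nn"`, `"dts"`, `"bayes"`,
#'   `"adaboost"`, `"mlp"`.
#' @param features a `feature_set` from [extract_features()].
#' @param split a `split_plan` from [split_by_tasks()], or `NULL` to train
#'   and test on everything (memorization ceiling).
#' @param target label column to predict: `"subject"` or `"class"`.
#' @param seed seed for the stochastic learners (mlp).
#' @return A `metrics_report` on the held-out segments.
#' @export
run_baseline <- function(name, features, split = NULL,
                         target = c("subject", "class"), seed = 1L) {
  target <- match.arg(target)
  stopifnot(inherits(features, "feature_set"))
  y_all <- as.integer(features$labels[[target]])
  n_classes <- max(y_all)
  in_test <- if (is.null(split)) rep(TRUE, nrow(features$x))
             else features$labels$task %in% split$test_tasks
  in_train <- if (is.null(split)) rep(TRUE, nrow(features$x)) else !in_test
  xtr <- features$x[in_train, , drop = FALSE]
  xte <- features$x[in_test, , drop = FALSE]
  ytr <- factor(y_all[in_train], levels = seq_len(n_classes))
  yte <- y_all[in_test]
  # drop zero-variance columns (degenerate for lda/bayes) and standardize
  keep <- apply(xtr, 2L, stats::sd) > 0
  xtr <- xtr[, keep, drop = FALSE]; xte <- xte[, keep, drop = FALSE]
  mu <- colMeans(xtr); sdv <- apply(xtr, 2L, stats::sd)
  xtr <- scale(xtr, mu, sdv); xte <- scale(xte, mu, sdv)
  set.seed(seed)
  pred <- switch(name,
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "linear")
      predict(fit, xte)
    },
    lda = {
      fit <- MASS::lda(xtr, grouping = ytr)
      predict(fit, xte)$class
    },
    nn = class::knn(xtr, xte, ytr, k = 1L),
    dts = {
      df <- data.frame(y = ytr, xtr)
      fit <- rpart::rpart(y ~ ., data = df, method = "class")
      predict(fit, data.frame(xte), type = "class")
    },
    bayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      predict(fit, xte)
    },
    adaboost = {
      fit <- adaboost_fit(xtr, ytr)
      adaboost_predict(fit, xte)
    },
    mlp = {
      fit <- nnet::nnet(xtr, class.ind(ytr), size = 16L, maxit = 200L,
                        decay = 1e-4, softmax = TRUE, trace = FALSE,
                        MaxNWts = 100000L)
      factor(levels(ytr)[max.col(predict(fit, xte))], levels = levels(ytr))
    },
    stop("registry error: unknown baseline '", name, "'"))
  macro_metrics(yte, as.integer(as.character(pred)), n_classes = n_classes)
}

# one-hot indicator matrix for nnet's softmax interface
class.ind <- function(y) {
  m <- matrix(0, length(y), nlevels(y))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  colnames(m) <- levels(y)
  m
}

#' Run a grid of evaluation conditions
#'
#' Executes segment -> (features) -> model -> metrics for every combination
#' of segment length, channel count, split ratio and method, and returns
#' (optionally writes) one result row per condition. Deep methods
#' (`"lstm"`) consume horizontal raw segments; `"cnn"` consumes vertical
#' segments; every other name is a [run_baseline()] classifier over
#' classical features.
#'
#' @param manifest an [eeg_manifest].
#' @param fs sampling rate of the CSV recordings.
#' @param methods character vector of method names.
#' @param l_tildes integer vector of horizontal segment lengths.
#' @param k_tildes integer vector of retained channel counts (`NA` = all).
#' @param ratios character vector of `"a:b"` split ratios.
#' @param folds integer vector of fold indices.
#' @param target `"subject"` or `"class"`.
#' @param classes round-robin class count for synthetic labels.
#' @param config a [train_config()] for the deep methods.
#' @param out optional TSV path for the report.
#' @param seed global seed fanned out to every stochastic component.
#' @return data.frame with columns method, l_tilde, k_tilde, ratio, fold,
#'   precision, recall, f1.
#' @export
run_experiment <- function(manifest, fs, methods = "lstm",
                           l_tildes = 150L, k_tildes = NA, ratios = "3:1",
                           folds = 0L, target = "subject", classes = NULL,
                           config = train_config(), out = NULL, seed = 1L) {
  rows <- list()
  for (lt in l_tildes) for (kt in k_tildes) {
    spec_h <- segmentation_spec("horizontal", l_tilde = lt,
                                k_tilde = if (!is.na(kt)) kt)
    batch_h <- segment_dataset(manifest, spec_h, fs = fs, classes = classes)
    feats <- NULL
    for (ratio in ratios) for (fold in folds) {
      split <- split_by_tasks(manifest, ratio, fold)
      for (method in methods) {
        rep <- if (method == "lstm") {
          eval_lstm(batch_h, split, config)
        } else if (method == "cnn") {
          batch_v <- segment_dataset(manifest,
                                     segmentation_spec("vertical"),
                                     fs = fs, classes = classes)
          eval_cnn(batch_v, split, config)
        } else {
          if (is.null(feats))
            feats <- extract_features(normalize_batch(batch_h, fs), fs = fs)
          run_baseline(method, feats, split, target = target,
                       seed = child_seed(seed, fold + 1L))
        }
        rows[[length(rows) + 1L]] <-
          data.frame(method = method, l_tilde = lt, k_tilde = kt,
                     ratio = ratio, fold = fold, precision = rep$precision,
                     recall = rep$recall, f1 = rep$f1)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}

# normalize + band-pass every segment of a batch for the classical branch
normalize_batch <- function(batch, fs) {
  batch$segments <- lapply(batch$segments, function(seg) {
    rec <- eeg_recording(seg, fs = fs)
    bandpass(zero_mean_normalize(rec))$data
  })
  batch
}

eval_lstm <- function(batch, split, config) {
  tr <- batch$labels$task %in% split$train_tasks
  sub <- function(keep) new_segment_batch(batch$segments[keep],
                                          batch$labels[keep, , drop = FALSE],
                                          batch$provenance[keep, , drop = FALSE])
  model <- train_subject_lstm(sub(tr), config)
  te <- sub(!tr)
  pred <- apply(forward_lstm(model, te$segments), 2L, which.max)
  macro_metrics(te$labels$subject, pred, n_classes = model$n_classes)
}

eval_cnn <- function(batch, split, config) {
  tr <- batch$labels$task %in% split$train_tasks
  sub <- function(keep) new_segment_batch(batch$segments[keep],
                                          batch$labels[keep, , drop = FALSE],
                                          batch$provenance[keep, , drop = FALSE])
  model <- train_task_cnn(sub(tr), config)
  te <- sub(!tr)
  pred <- apply(forward_cnn(model, te$segments), 2L, which.max)
  macro_metrics(te$labels$class, pred, n_classes = model$n_classes)
}
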