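#' Five-block 1-D CNN for task classification
#'
#' The task-linking network consumes a single-channel, full-length sequence
#' (one vertical segment, 1 x L) and outputs a probability per task class.
#' Architecture, per block:
#' \itemize{
#'   \item block 1: BN - conv(16, k3, s1, same) - ReLU - BN -
#'     conv(16, k3, s1, same) - ReLU - maxpool(2, stride 2);
#'   \item blocks 2-5: BN - conv(32/64/128/128, k3, s1, same) - ReLU -
#'     [dropout in blocks 4-5 during training] - maxpool(2, stride 2).
#' }
#' Batch normalization sits before each convolution's input; pooling acts
#' on the time axis only (the filter axis is untouched), so each block
#' halves the temporal length (floor). The flattened block-5 map feeds a
#' linear softmax head. For the 9600-sample inputs of a 60 s recording at
#' 160 Hz the per-block post-pool maps are 4800x16, 2400x32, 1200x64,
#' 600x128 and 300x128.
#'
#' @name task_cnn
NULL

cnn_filters <- function() list(c(16L, 16L), 32L, 64L, 128L, 128L)

#' Per-stage output shapes of the CNN
#'
#' Symbolic shape propagation: same-padding stride-1 convolutions keep the
#' temporal length and set the channel count to the filter count; each
#' pool halves the length (floor). Useful as an architecture ledger and to
#' size the softmax head.
#'
#' @param input_length temporal length of the 1-channel input (>= 32 so
#'   that five halvings survive).
#' @return data.frame with columns `block`, `stage` ("conv"/"pool"),
#'   `length`, `channels`, one row per conv and pool stage in order.
#' @export
cnn_output_shapes <- function(input_length) {
  input_length <- as.integer(input_length)
  if (input_length < 32L)
    stop("shape error: input length ", input_length,
         " too short to pool 5 times")
  rows <- list()
  len <- input_length
  for (b in seq_along(cnn_filters())) {
    for (f in cnn_filters()[[b]])
      rows[[length(rows) + 1L]] <- data.frame(block = b, stage = "conv",
                                              length = len, channels = f)
    len <- len %/% 2L
    ch <- utils::tail(cnn_filters()[[b]], 1L)
    rows[[length(rows) + 1L]] <- data.frame(block = b, stage = "pool",
                                            length = len, channels = ch)
  }
  do.call(rbind, rows)
}

#' @rdname task_cnn
#' @param input_length temporal length L of the single-channel input.
#' @param n_classes number of task classes.
#' @param dropout dropout rate in blocks 4-5 during training (default 0.5).
#' @param seed integer seed for weight initialization.
#' @return `task_cnn()`: an untrained model object (class `task_cnn`).
#' @export
task_cnn <- function(input_length, n_classes, dropout = 0.5, seed = 1L) {
  shapes <- cnn_output_shapes(input_length)
  set.seed(seed)
  convs <- list(); bns <- list()
  c_in <- 1L
  for (b in seq_along(cnn_filters())) {
    for (f in cnn_filters()[[b]]) {
      s <- 1 / sqrt(3 * c_in)
      convs[[length(convs) + 1L]] <-
        list(W = matrix(stats::runif(f * 3L * c_in, -s, s), f, 3L * c_in),
             b = numeric(f), block = b)
      bns[[length(bns) + 1L]] <-
        list(gamma = rep(1, c_in), beta = numeric(c_in),
             run_mean = numeric(c_in), run_var = rep(1, c_in))
      c_in <- f
    }
  }
  pool <- shapes[shapes$stage == "pool", ]
  flat_dim <- pool$length[5L] * pool$channels[5L]
  sh <- 1 / sqrt(flat_dim)
  structure(list(
    convs = convs, bns = bns,
    head = list(W = matrix(stats::runif(n_classes * flat_dim, -sh, sh),
                           n_classes, flat_dim),
                b = numeric(n_classes)),
    input_length = as.integer(input_length),
    n_classes = as.integer(n_classes),
    dropout = dropout, bn_eps = 1e-5, bn_momentum = 0.1),
    class = "task_cnn")
}

# ---- array helpers; X is (C, L, B) throughout -----------------------------

conv_stack <- function(X) {
  d <- dim(X); C <- d[1L]; L <- d[2L]; B <- d[3L]
  S <- array(0, c(3L * C, L, B))
  S[seq_len(C), 2:L, ] <- X[, 1:(L - 1L), ]        # kernel tap t-1
  S[C + seq_len(C), , ] <- X                        # tap t
  S[2L * C + seq_len(C), 1:(L - 1L), ] <- X[, 2:L, ] # tap t+1
  dim(S) <- c(3L * C, L * B)
  S
}

conv_unstack_grad <- function(dS, C, L, B) {
  dim(dS) <- c(3L * C, L, B)
  dX <- array(0, c(C, L, B))
  dX[, 1:(L - 1L), ] <- dX[, 1:(L - 1L), , drop = FALSE] +
    dS[seq_len(C), 2:L, , drop = FALSE]
  dX <- dX + dS[C + seq_len(C), , , drop = FALSE]
  dX[, 2:L, ] <- dX[, 2:L, , drop = FALSE] +
    dS[2L * C + seq_len(C), 1:(L - 1L), , drop = FALSE]
  dX
}

maxpool2 <- function(X) {
  d <- dim(X); L <- d[2L]
  Lp <- L %/% 2L
  X1 <- X[, 2L * seq_len(Lp) - 1L, , drop = FALSE]
  X2 <- X[, 2L * seq_len(Lp), , drop = FALSE]
  mask <- X1 >= X2                       # ties keep the earlier sample
  list(out = ifelse(mask, X1, X2), mask = mask, L_in = L)
}

maxpool2_grad <- function(dY, mask, L_in) {
  d <- dim(dY); C <- d[1L]; Lp <- d[2L]; B <- d[3L]
  dX <- array(0, c(C, L_in, B))
  dX[, 2L * seq_len(Lp) - 1L, ] <- dY * mask
  dX[, 2L * seq_len(Lp), ] <- dY * !mask
  dX
}

# forward through all stages; cache everything when training
cnn_forward_full <- function(model, X, train = FALSE, cache = FALSE,
                             drop_masks = NULL) {
  d <- dim(X); B <- d[3L]
  caches <- list()
  ci <- 0L
  for (b in seq_along(cnn_filters())) {
    for (f in cnn_filters()[[b]]) {
      ci <- ci + 1L
      bn <- model$bns[[ci]]
      C <- dim(X)[1L]; L <- dim(X)[2L]
      Xm <- X; dim(Xm) <- c(C, L * B)
      if (train) {
        mu <- rowMeans(Xm)
        v <- rowMeans(Xm^2) - mu^2
      } else {
        mu <- bn$run_mean; v <- bn$run_var
      }
      invstd <- 1 / sqrt(v + model$bn_eps)
      xhat <- (Xm - mu) * invstd
      Y <- bn$gamma * xhat + bn$beta
      dim(Y) <- c(C, L, B)
      S <- conv_stack(Y)
      cv <- model$convs[[ci]]
      Z <- cv$W %*% S + cv$b
      relu_mask <- Z > 0
      A <- Z * relu_mask
      dim(A) <- c(f, L, B)
      dm <- NULL
      if (b >= 4L && model$dropout > 0) {
        if (train) {
          dm <- if (!is.null(drop_masks)) drop_masks[[ci]] else
            array(stats::rbinom(length(A), 1L, 1 - model$dropout),
                  dim(A)) / (1 - model$dropout)
          A <- A * dm
        }
      }
      if (cache)
        caches[[ci]] <- list(xhat = xhat, invstd = invstd, mu = mu, v = v,
                             S = S, relu_mask = relu_mask, drop = dm,
                             C = C, L = L)
      X <- A
    }
    pl <- maxpool2(X)
    if (cache) caches[[ci]]$pool <- pl
    X <- pl$out
  }
  flat <- X; dim(flat) <- c(prod(dim(X)[1:2]), B)
  logits <- model$head$W %*% flat + model$head$b
  list(probs = softmax_cols(logits), flat = flat, caches = caches,
       final_dim = dim(X))
}

#' Forward pass of the task CNN
#'
#' @param model a [task_cnn()].
#' @param segments one `1 x L` matrix/vector or a list of them.
#' @param train logical: training mode (batch statistics and dropout) or
#'   evaluation mode (running statistics, no dropout; deterministic).
#' @return Matrix of class probabilities, `n_classes` x `n_segments`.
#' @export
forward_cnn <- function(model, segments, train = FALSE) {
  if (is.matrix(segments) || is.numeric(segments)) segments <- list(segments)
  segments <- lapply(segments, function(s) as.numeric(s))
  L <- length(segments[[1L]])
  if (L != model$input_length)
    stop("shape error: segment length ", L, " but model expects ",
         model$input_length)
  X <- array(unlist(segments), c(1L, L, length(segments)))
  cnn_forward_full(model, X, train = train)$probs
}

cnn_flatten <- function(model) {
  out <- list()
  for (i in seq_along(model$convs)) {
    out[[paste0("conv", i, ".W")]] <- model$convs[[i]]$W
    out[[paste0("conv", i, ".b")]] <- model$convs[[i]]$b
    out[[paste0("bn", i, ".gamma")]] <- model$bns[[i]]$gamma
    out[[paste0("bn", i, ".beta")]] <- model$bns[[i]]$beta
  }
  out$head.W <- model$head$W
  out$head.b <- model$head$b
  out
}

cnn_unflatten <- function(model, flat) {
  for (i in seq_along(model$convs)) {
    model$convs[[i]]$W <- flat[[paste0("conv", i, ".W")]]
    model$convs[[i]]$b <- flat[[paste0("conv", i, ".b")]]
    model$bns[[i]]$gamma <- flat[[paste0("bn", i, ".gamma")]]
    model$bns[[i]]$beta <- flat[[paste0("bn", i, ".beta")]]
  }
  model$head$W <- flat$head.W
  model$head$b <- flat$head.b
  model
}

# loss + gradients for one minibatch in train mode
cnn_loss_grads <- function(model, X, targets, drop_masks = NULL) {
  B <- dim(X)[3L]
  fw <- cnn_forward_full(model, X, train = TRUE, cache = TRUE,
                         drop_masks = drop_masks)
  ce <- xent(fw$probs, targets)
  grads <- list()
  grads$head.W <- ce$dlogits %*% t(fw$flat)
  grads$head.b <- rowSums(ce$dlogits)
  dflat <- t(model$head$W) %*% ce$dlogits
  dX <- array(dflat, c(fw$final_dim[1:2], B))
  ci <- length(model$convs)
  for (b in rev(seq_along(cnn_filters()))) {
    nconv <- length(cnn_filters()[[b]])
    for (k in seq_len(nconv)) {
      cc <- fw$caches[[ci]]
      if (k == 1L)  # pool follows the block's last conv
        dX <- maxpool2_grad(dX, cc$pool$mask, cc$L)
      if (!is.null(cc$drop)) dX <- dX * cc$drop
      f <- dim(dX)[1L]; L <- dim(dX)[2L]
      dZ <- dX
      dim(dZ) <- c(f, L * B)
      dZ <- dZ * cc$relu_mask
      cv <- model$convs[[ci]]
      grads[[paste0("conv", ci, ".W")]] <- dZ %*% t(cc$S)
      grads[[paste0("conv", ci, ".b")]] <- rowSums(dZ)
      dS <- t(cv$W) %*% dZ
      dY <- conv_unstack_grad(dS, cc$C, cc$L, B)
      dim(dY) <- c(cc$C, cc$L * B)
      bn <- model$bns[[ci]]
      grads[[paste0("bn", ci, ".gamma")]] <- rowSums(dY * cc$xhat)
      grads[[paste0("bn", ci, ".beta")]] <- rowSums(dY)
      N <- cc$L * B
      dxhat <- dY * bn$gamma
      dXm <- (cc$invstd / N) *
        (N * dxhat - rowSums(dxhat) - cc$xhat * rowSums(dxhat * cc$xhat))
      dX <- array(dXm, c(cc$C, cc$L, B))
      ci <- ci - 1L
    }
  }
  list(loss = ce$loss, grads = grads, probs = fw$probs,
       bn_stats = lapply(fw$caches, function(cc) list(mu = cc$mu, v = cc$v)))
}

#' Train the task-classification CNN
#'
#' Minimizes cross-entropy over classes with Adam; batch-norm running
#' statistics are accumulated during training (momentum 0.1) and used at
#' evaluation time; dropout is active in blocks 4-5 only during training.
#'
#' @param batch a vertical `segment_batch`; `batch$labels$class` are the
#'   targets and must cover 1..Q with at least one segment each.
#' @param config a [train_config()].
#' @param n_classes number of classes (default: max label).
#' @param dropout dropout rate for blocks 4-5.
#' @return The trained [task_cnn()] with `loss_trace`, `initial_loss` and
#'   `epochs_run`.
#' @export
train_task_cnn <- function(batch, config = train_config(epochs = 30L),
                           n_classes = NULL, dropout = 0.5) {
  stopifnot(inherits(batch, "segment_batch"))
  y <- as.integer(batch$labels$class)
  if (anyNA(y)) stop("data error: batch has unlabelled (NA class) segments")
  if (is.null(n_classes)) n_classes <- max(y)
  miss <- setdiff(seq_len(n_classes), unique(y))
  if (length(miss))
    stop("data error: no training segments for class(es) ",
         paste(miss, collapse = ", "))
  L <- ncol(batch$segments[[1L]])
  model <- task_cnn(L, n_classes, dropout = dropout, seed = config$seed)
  flat <- cnn_flatten(model)
  opt <- adam_init(flat)
  n <- length(batch$segments)
  X_all <- array(unlist(batch$segments), c(1L, L, n))
  init <- xent(forward_cnn(model, batch$segments), y)
  set.seed(config$seed + 1L)
  trace <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c(); correct <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      X <- X_all[, , idx, drop = FALSE]
      lg <- cnn_loss_grads(model, X, y[idx])
      correct <- correct + sum(apply(lg$probs, 2L, which.max) == y[idx])
      losses <- c(losses, lg$loss)
      up <- adam_step(flat, lg$grads, opt, config)
      flat <- up$params; opt <- up$state
      model <- cnn_unflatten(model, flat)
      mom <- model$bn_momentum
      for (i in seq_along(model$bns)) {
        model$bns[[i]]$run_mean <- (1 - mom) * model$bns[[i]]$run_mean +
          mom * lg$bn_stats[[i]]$mu
        model$bns[[i]]$run_var <- (1 - mom) * model$bns[[i]]$run_var +
          mom * lg$bn_stats[[i]]$v
      }
    }
    trace <- c(trace, mean(losses))
    if (!is.null(config$stop_at_train_acc) &&
        correct / n >= config$stop_at_train_acc) break
  }
  model <- cnn_calibrate_bn(model, X_all)
  model$loss_trace <- trace
  model$initial_loss <- init$loss
  model$epochs_run <- length(trace)
  model
}

# set the batch-norm running statistics to the statistics of the full
# training set (propagated in train mode, averaged over chunks), so
# evaluation-mode behaviour does not depend on how many updates the EMA saw
cnn_calibrate_bn <- function(model, X_all, chunk = 64L) {
  drop_saved <- model$dropout
  model$dropout <- 0          # no dropout while measuring statistics
  n <- dim(X_all)[3L]
  sums <- lapply(model$bns, function(b) b$run_mean * 0)
  sqs <- sums
  wts <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- cnn_forward_full(model, X_all[, , idx, drop = FALSE],
                           train = TRUE, cache = TRUE)
    w <- length(idx)
    for (i in seq_along(model$bns)) {
      sums[[i]] <- sums[[i]] + w * fw$caches[[i]]$mu
      sqs[[i]] <- sqs[[i]] + w * (fw$caches[[i]]$v + fw$caches[[i]]$mu^2)
    }
    wts <- wts + w
  }
  for (i in seq_along(model$bns)) {
    model$bns[[i]]$run_mean <- sums[[i]] / wts
    model$bns[[i]]$run_var <- sqs[[i]] / wts - (sums[[i]] / wts)^2
  }
  model$dropout <- drop_saved
  model
}

#' Predict the task class of a recording
#'
#' Splits the recording vertically, scores every channel with
#' [forward_cnn()] in evaluation mode, and majority-votes over channels;
#' ties are broken by the summed probability of the tied classes.
#'
#' @param model a trained [task_cnn()].
#' @param rec an [eeg_recording] whose length matches the model input.
#' @return The winning class id (integer).
#' @export
predict_task <- function(model, rec) {
  segs <- vertical_split(rec)$segments
  vote_predict(forward_cnn(model, segs, train = FALSE))
}
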