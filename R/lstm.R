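#' Peephole LSTM for subject identification
#'
#' A five-layer stacked LSTM whose gates "peep" at the memory cell: the
#' input and forget gates see the previous cell state and the output gate
#' sees the freshly updated cell state,
#' \deqn{I_t = \sigma(W_I x_t + U_I h_{t-1} + v_I \odot c_{t-1} + b_I)}
#' \deqn{F_t = \sigma(W_F x_t + U_F h_{t-1} + v_F \odot c_{t-1} + b_F)}
#' \deqn{c_t = F_t \odot c_{t-1} + I_t \odot \tanh(W_C x_t + U_C h_{t-1} + b_C)}
#' \deqn{O_t = \sigma(W_O x_t + U_O h_{t-1} + v_O \odot c_t + b_O)}
#' \deqn{h_t = O_t \odot \tanh(c_t)}
#' Peephole weights are elementwise (diagonal). A time step consumes one
#' column of the K x l segment (the K-vector of channel values); the final
#' hidden state of the top layer feeds a linear softmax head with one score
#' per subject. Training minimizes cross-entropy with Adam; the forget-gate
#' bias is initialized to 1 so early training retains memory.
#'
#' @name subject_lstm
NULL

# uniform fan-in-scaled init of one layer; gates stacked in rows as
# [input; forget; output; candidate], each block `hidden` rows
lstm_layer_init <- function(input_size, hidden, forget_bias) {
  s_in <- 1 / sqrt(input_size)
  s_h <- 1 / sqrt(hidden)
  b <- numeric(4L * hidden)
  b[(hidden + 1L):(2L * hidden)] <- forget_bias
  list(W = matrix(stats::runif(4L * hidden * input_size, -s_in, s_in),
                  4L * hidden, input_size),
       U = matrix(stats::runif(4L * hidden * hidden, -s_h, s_h),
                  4L * hidden, hidden),
       b = b,
       vI = stats::runif(hidden, -s_h, s_h),
       vF = stats::runif(hidden, -s_h, s_h),
       vO = stats::runif(hidden, -s_h, s_h))
}

#' @rdname subject_lstm
#' @param input_size number of input channels per time step.
#' @param n_subjects number of output classes (subjects).
#' @param hidden hidden size per layer (default 64).
#' @param n_layers number of stacked layers (default 5).
#' @param seed integer seed for weight initialization.
#' @param forget_bias initial forget-gate bias (default 1.0).
#' @return `subject_lstm()`: an untrained model object (class
#'   `subject_lstm`) with `layers` (list of per-layer parameter lists
#'   `W, U, b, vI, vF, vO`) and a softmax `head` (`W`, `b`).
#' @export
subject_lstm <- function(input_size, n_subjects, hidden = 64L, n_layers = 5L,
                         seed = 1L, forget_bias = 1.0) {
  stopifnot(input_size >= 1L, n_subjects >= 2L, hidden >= 1L, n_layers >= 1L)
  set.seed(seed)
  layers <- vector("list", n_layers)
  for (j in seq_len(n_layers))
    layers[[j]] <- lstm_layer_init(if (j == 1L) input_size else hidden,
                                   hidden, forget_bias)
  sh <- 1 / sqrt(hidden)
  structure(list(
    layers = layers,
    head = list(W = matrix(stats::runif(n_subjects * hidden, -sh, sh),
                           n_subjects, hidden),
                b = numeric(n_subjects)),
    input_size = as.integer(input_size), hidden = as.integer(hidden),
    n_layers = as.integer(n_layers), n_classes = as.integer(n_subjects)),
    class = "subject_lstm")
}

#' One peephole-LSTM cell update
#'
#' Applies the gate equations above for a single time step. Exposed mainly
#' so the cell can be checked in isolation; [forward_lstm()] runs the full
#' stacked rollout.
#'
#' @param params one layer's parameter list (`W, U, b, vI, vF, vO` with
#'   gates stacked in rows as input/forget/output/candidate).
#' @param x input vector for this time step.
#' @param state list with `h` and `c` vectors (the previous state).
#' @return The updated state: list with `h`, `c`, and the gate activations
#'   `I`, `F`, `O` (each in (0,1)).
#' @export
lstm_cell_step <- function(params, x, state) {
  H <- length(state$h)
  if (length(state$c) != H) stop("dimension error: |h| != |c|")
  if (nrow(params$W) != 4L * H || ncol(params$W) != length(x))
    stop("dimension error: W is ", nrow(params$W), "x", ncol(params$W),
         " but expected ", 4L * H, "x", length(x))
  a <- as.numeric(params$W %*% x + params$U %*% state$h) + params$b
  iI <- seq_len(H); iF <- iI + H; iO <- iF + H; iC <- iO + H
  I <- stats::plogis(a[iI] + params$vI * state$c)
  F <- stats::plogis(a[iF] + params$vF * state$c)
  g <- tanh(a[iC])
  c_new <- F * state$c + I * g
  O <- stats::plogis(a[iO] + params$vO * c_new)
  list(h = O * tanh(c_new), c = c_new, I = I, F = F, O = O)
}

#' Forward pass of the stacked model
#'
#' Rolls a `k x l` segment (or several) through the five-layer stack; time
#' steps are the `l` columns, the per-step input is the `k`-vector of
#' channel values. The final hidden state of the top layer is mapped to a
#' probability vector over subjects by the linear softmax head.
#'
#' @param model a [subject_lstm()].
#' @param segments one `k x l` matrix or a list of them (equal shapes).
#' @return Matrix of probabilities, `n_subjects` x `n_segments`; every
#'   column sums to 1.
#' @export
forward_lstm <- function(model, segments) {
  if (is.matrix(segments)) segments <- list(segments)
  k <- nrow(segments[[1L]])
  if (k != model$input_size)
    stop("dimension error: segment has ", k, " channels, model expects ",
         model$input_size)
  if (isTRUE(model$standardize))
    segments <- lapply(segments, standardize_segment)
  X <- array(unlist(segments),
             c(k, ncol(segments[[1L]]), length(segments)))
  .lstm_forward_cpp(model$layers, model$head$W, model$head$b, X)
}

# per-channel zero-mean/unit-variance scaling of one segment (population
# sigma); constant channels are left at zero rather than dividing by zero
standardize_segment <- function(s) {
  mu <- rowMeans(s)
  sd_ <- sqrt(pmax(rowMeans(s^2) - mu^2, 0))
  sd_[sd_ == 0] <- 1
  (s - mu) / sd_
}

# flatten model params to a named flat list (for Adam) and back
lstm_flatten <- function(model) {
  out <- list()
  for (j in seq_along(model$layers))
    for (nm in names(model$layers[[j]]))
      out[[paste0("L", j, ".", nm)]] <- model$layers[[j]][[nm]]
  out$head.W <- model$head$W
  out$head.b <- model$head$b
  out
}

lstm_unflatten <- function(model, flat) {
  for (j in seq_along(model$layers))
    for (nm in names(model$layers[[j]]))
      model$layers[[j]][[nm]] <- flat[[paste0("L", j, ".", nm)]]
  model$head$W <- flat$head.W
  model$head$b <- flat$head.b
  model
}

# loss and flat gradients for one minibatch (used by training and by the
# finite-difference tests); the heavy lifting happens in the compiled
# peephole-BPTT kernel
lstm_loss_grads <- function(model, X, targets) {
  out <- .lstm_loss_grads_cpp(model$layers, model$head$W, model$head$b,
                              X, as.integer(targets))
  # column vectors from the kernel become plain numerics so parameter
  # shapes survive the Adam update
  grads <- out$grads
  vecs <- grepl("\\.(b|vI|vF|vO)$", names(grads))
  grads[vecs] <- lapply(grads[vecs], as.numeric)
  list(loss = out$loss, grads = grads, probs = out$probs)
}

#' Train the subject-identification LSTM
#'
#' Minimizes cross-entropy over subjects with Adam. Reproducible given the
#' config seed (which drives init, shuffling and nothing else).
#'
#' @param batch a horizontal `segment_batch`; `batch$labels$subject` are the
#'   targets and must cover 1..N with at least one segment each.
#' @param config a [train_config()].
#' @param hidden,n_layers model size (defaults 64 and 5).
#' @param n_subjects number of subjects (default: max label).
#' @param standardize per-channel zero-mean/unit-variance scaling of every
#'   segment before the rollout (default `FALSE`: the model consumes raw
#'   signal). The choice is recorded on the model and applied consistently
#'   at prediction time.
#' @return The trained [subject_lstm()] with extra fields `loss_trace`
#'   (mean minibatch loss per epoch), `initial_loss` (pre-update loss on
#'   the whole training set) and `epochs_run`.
#' @export
train_subject_lstm <- function(batch, config = train_config(),
                               hidden = 64L, n_layers = 5L,
                               n_subjects = NULL, standardize = FALSE) {
  stopifnot(inherits(batch, "segment_batch"))
  if (standardize)
    batch$segments <- lapply(batch$segments, standardize_segment)
  y <- as.integer(batch$labels$subject)
  if (is.null(n_subjects)) n_subjects <- max(y)
  if (n_subjects < 2L) stop("need >= 2 subjects")
  miss <- setdiff(seq_len(n_subjects), unique(y))
  if (length(miss))
    stop("data error: no training segments for subject(s) ",
         paste(miss, collapse = ", "))
  k <- nrow(batch$segments[[1L]])
  Tn <- ncol(batch$segments[[1L]])
  model <- subject_lstm(k, n_subjects, hidden = hidden, n_layers = n_layers,
                        seed = config$seed, forget_bias = config$forget_bias)
  model$standardize <- standardize
  flat <- lstm_flatten(model)
  opt <- adam_init(flat)
  n <- length(batch$segments)
  X_all <- array(unlist(batch$segments), c(k, Tn, n))
  init <- xent(forward_lstm(model, batch$segments), y)
  set.seed(config$seed + 1L)
  trace <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c(); correct <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      X <- X_all[, , idx, drop = FALSE]
      lg <- lstm_loss_grads(model, X, y[idx])
      correct <- correct + sum(apply(lg$probs, 2L, which.max) == y[idx])
      losses <- c(losses, lg$loss)
      up <- adam_step(flat, lg$grads, opt, config)
      flat <- up$params; opt <- up$state
      model <- lstm_unflatten(model, flat)
    }
    trace <- c(trace, mean(losses))
    if (!is.null(config$stop_at_train_acc) &&
        correct / n >= config$stop_at_train_acc) break
  }
  model$loss_trace <- trace
  model$initial_loss <- init$loss
  model$epochs_run <- length(trace)
  model
}

#' Predict the subject of a recording from its segments
#'
#' Scores each segment with [forward_lstm()], takes the per-segment argmax
#' and returns the majority vote; ties are broken by the summed probability
#' of the tied subjects.
#'
#' @param model a trained [subject_lstm()].
#' @param segments a list of `k x l` matrices (>= 1) or a `segment_batch`.
#' @return The winning subject id (integer).
#' @export
predict_subject <- function(model, segments) {
  if (inherits(segments, "segment_batch")) segments <- segments$segments
  vote_predict(forward_lstm(model, segments))
}
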