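#' Training configuration
#'
#' Adam hyperparameters and training-loop settings shared by both deep
#' models. Defaults are the standard Adam settings used throughout:
#' stepsize `alpha = 0.001`, decay rates `beta1 = 0.9`, `beta2 = 0.999`,
#' `eps = 1e-8`.
#'
#' @param alpha Adam stepsize.
#' @param beta1,beta2 exponential decay rates for the moment estimates,
#'   both in (0, 1).
#' @param eps small constant avoiding division by zero.
#' @param epochs maximum number of passes over the training set.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling weight init, shuffling and dropout.
#' @param forget_bias initial value of the LSTM forget-gate bias (the
#'   "forgetting rate"; 1.0 keeps early memory intact at init).
#' @param stop_at_train_acc optional early-stopping threshold: training
#'   halts once epoch training accuracy reaches this value (`NULL` = never).
#' @param clip_norm global gradient-norm clip (`Inf` = off).
#' @return A `train_config` list.
#' @export
train_config <- function(alpha = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, epochs = 100L, batch_size = 32L,
                         seed = 1L, forget_bias = 1.0,
                         stop_at_train_acc = NULL, clip_norm = 5) {
  stopifnot(beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, eps > 0,
            alpha > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2, eps = eps,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), forget_bias = forget_bias,
                 stop_at_train_acc = stop_at_train_acc,
                 clip_norm = clip_norm),
            class = "train_config")
}

# ---- internal: Adam over a flat named list of numeric arrays --------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),   # zeros with p's shape
       v = lapply(params, function(p) p * 0))
}

dim_or_len <- function(p) if (is.null(dim(p))) length(p) else dim(p)

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  if (is.finite(cfg$clip_norm)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
    if (gn > cfg$clip_norm)
      grads <- lapply(grads, function(g) g * (cfg$clip_norm / gn))
  }
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- cfg$beta1 * state$m[[k]] + (1 - cfg$beta1) * g
    state$v[[k]] <- cfg$beta2 * state$v[[k]] + (1 - cfg$beta2) * g * g
    params[[k]] <- params[[k]] -
      cfg$alpha * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + cfg$eps)
  }
  list(params = params, state = state)
}

# stable softmax over columns of a logit matrix (classes x batch)
softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# cross-entropy loss and logit gradient for 1-based integer targets
xent <- function(probs, targets) {
  B <- ncol(probs)
  idx <- cbind(targets, seq_len(B))
  loss <- -mean(log(pmax(probs[idx], 1e-300)))
  d <- probs
  d[idx] <- d[idx] - 1
  list(loss = loss, dlogits = d / B)
}

# majority vote over per-segment probability columns; ties broken by the
# summed probability of the tied classes
vote_predict <- function(probs) {
  hard <- apply(probs, 2L, which.max)
  counts <- tabulate(hard, nbins = nrow(probs))
  top <- which(counts == max(counts))
  if (length(top) == 1L) return(top)
  top[which.max(rowSums(probs)[top])]
}
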