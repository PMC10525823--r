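test_that("the peephole cell reduces to closed forms on zero weights", {
  H <- 3
  p0 <- list(W = matrix(0, 4 * H, 2), U = matrix(0, 4 * H, H),
             b = numeric(4 * H), vI = numeric(H), vF = numeric(H),
             vO = numeric(H))
  st <- lstm_cell_step(p0, c(5, -2), list(h = numeric(H), c = numeric(H)))
  expect_equal(st$I, rep(0.5, H))
  expect_equal(st$F, rep(0.5, H))
  expect_equal(st$O, rep(0.5, H))
  expect_equal(st$c, numeric(H))
  expect_equal(st$h, numeric(H))

  # scalar cell with c_prev = 1: c = 0.5*1 + 0.5*tanh(0) = 0.5,
  # h = 0.5 * tanh(0.5)
  p1 <- list(W = matrix(0, 4, 1), U = matrix(0, 4, 1), b = numeric(4),
             vI = 0, vF = 0, vO = 0)
  s1 <- lstm_cell_step(p1, 0, list(h = 0, c = 1))
  expect_equal(s1$c, 0.5)
  expect_equal(s1$h, 0.5 * tanh(0.5), tolerance = 1e-10)
  expect_equal(s1$h, 0.23106, tolerance = 1e-4)

  expect_error(lstm_cell_step(p1, c(1, 2), list(h = 0, c = 0)),
               "dimension error")
})

test_that("vectorized cell matches the explicit scalar-loop oracle", {
  set.seed(123)
  for (i in 1:25) {
    ins <- sample(1:4, 1); H <- sample(1:5, 1)
    p <- random_lstm_params(ins, H)
    st <- list(h = rnorm(H), c = rnorm(H))
    x <- rnorm(ins)
    got <- lstm_cell_step(p, x, st)
    want <- scalar_cell_oracle(p, x, st)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
  }
})

test_that("the batched rollout agrees with repeated single cell steps", {
  set.seed(7)
  model <- subject_lstm(3, 4, hidden = 5, n_layers = 2, seed = 11)
  seg <- matrix(rnorm(3 * 8), 3, 8)
  # manual rollout through the stack with the exported cell
  input <- lapply(seq_len(8), function(t) seg[, t])
  for (j in 1:2) {
    st <- list(h = numeric(5), c = numeric(5))
    outs <- vector("list", 8)
    for (t in 1:8) {
      st <- lstm_cell_step(model$layers[[j]], input[[t]], st)
      outs[[t]] <- st$h
    }
    input <- outs
  }
  logits <- model$head$W %*% input[[8]] + model$head$b
  want <- exp(logits - max(logits)); want <- want / sum(want)
  expect_equal(as.numeric(forward_lstm(model, seg)), as.numeric(want),
               tolerance = 1e-10)
})

test_that("forward output is a probability distribution with known cases", {
  model <- subject_lstm(2, 4, hidden = 6, n_layers = 5, seed = 3)
  segs <- lapply(1:5, function(i) matrix(rnorm(2 * 12), 2))
  pr <- forward_lstm(model, segs)
  expect_equal(colSums(pr), rep(1, 5), tolerance = 1e-8)
  expect_true(all(pr > 0 & pr < 1))

  # zero head: uniform regardless of input
  model$head$W[] <- 0; model$head$b[] <- 0
  expect_equal(forward_lstm(model, segs[[1]])[, 1], rep(0.25, 4),
               tolerance = 1e-12)

  # fixed logits (0, log 2): probabilities (1/3, 2/3)
  m2 <- subject_lstm(2, 2, hidden = 4, n_layers = 1, seed = 3)
  m2$head$W[] <- 0; m2$head$b <- c(0, log(2))
  expect_equal(forward_lstm(m2, segs[[1]])[, 1], c(1, 2) / 3,
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  set.seed(20)
  m <- subject_lstm(2, 3, hidden = 4, n_layers = 3, seed = 5)
  X <- array(rnorm(2 * 6 * 3), c(2, 6, 3)); y <- c(1L, 3L, 2L)
  lg <- eeglink:::lstm_loss_grads(m, X, y)
  flat <- eeglink:::lstm_flatten(m)
  fd <- function(nm, i, eps = 1e-6) {
    f1 <- flat; f1[[nm]][i] <- f1[[nm]][i] + eps
    f2 <- flat; f2[[nm]][i] <- f2[[nm]][i] - eps
    (eeglink:::lstm_loss_grads(eeglink:::lstm_unflatten(m, f1), X, y)$loss -
     eeglink:::lstm_loss_grads(eeglink:::lstm_unflatten(m, f2), X, y)$loss) /
      (2 * eps)
  }
  for (nm in names(flat))
    for (i in sample(length(flat[[nm]]), min(3, length(flat[[nm]])))) {
      g <- lg$grads[[nm]][i]; n <- fd(nm, i)
      expect_equal(g, n, tolerance = 1e-3,
                   label = sprintf("d loss / d %s[%d]", nm, i))
    }
})

test_that("gates stay in (0,1) and states stay bounded on random rollouts", {
  set.seed(9)
  for (i in 1:10) {
    H <- sample(2:6, 1)
    p <- random_lstm_params(3, H)
    st <- list(h = numeric(H), c = numeric(H))
    for (t in 1:20) {
      st <- lstm_cell_step(p, rnorm(3), st)
      expect_true(all(st$I > 0 & st$I < 1))
      expect_true(all(st$F > 0 & st$F < 1))
      expect_true(all(st$O > 0 & st$O < 1))
      expect_true(all(abs(st$h) < 1))
      expect_true(all(abs(st$c) <= t))   # |c_t| grows at most one per step
    }
  }
})

test_that("training separates a linearly separated two-subject toy", {
  set.seed(31)
  mk <- function(level) matrix(level + rnorm(2 * 20, sd = 0.3), 2, 20)
  segs <- c(lapply(1:20, function(i) mk(-1)), lapply(1:20, function(i) mk(1)))
  batch <- eeglink:::new_segment_batch(
    segs, data.frame(subject = rep(1:2, each = 20), task = 1L, class = 1L),
    data.frame(recording = 1L, offset = 0L))
  cfg <- train_config(epochs = 50L, seed = 2L, batch_size = 8L,
                      stop_at_train_acc = 1.0)
  model <- train_subject_lstm(batch, cfg, hidden = 8L)
  expect_lte(model$epochs_run, 50L)
  pred <- apply(forward_lstm(model, segs), 2L, which.max)
  expect_equal(pred, rep(1:2, each = 20))
  # balanced two-class cross-entropy starts near log(2)
  expect_equal(model$initial_loss, log(2), tolerance = 0.1)
})

test_that("training is reproducible given the seed", {
  set.seed(44)
  segs <- lapply(1:12, function(i) matrix(rnorm(2 * 10), 2))
  batch <- eeglink:::new_segment_batch(
    segs, data.frame(subject = rep(1:2, 6), task = 1L, class = 1L),
    data.frame(recording = 1L, offset = 0L))
  cfg <- train_config(epochs = 4L, seed = 9L, batch_size = 4L)
  m1 <- train_subject_lstm(batch, cfg, hidden = 4L)
  m2 <- train_subject_lstm(batch, cfg, hidden = 4L)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$layers, m2$layers)
})

test_that("training refuses a subject with no segments", {
  segs <- lapply(1:4, function(i) matrix(rnorm(2 * 10), 2))
  batch <- eeglink:::new_segment_batch(
    segs, data.frame(subject = c(1L, 1L, 3L, 3L), task = 1L, class = 1L),
    data.frame(recording = 1L, offset = 0L))
  expect_error(train_subject_lstm(batch, train_config(epochs = 1L),
                                  hidden = 4L),
               "data error.*subject\\(s\\) 2")
})

test_that("an untrained model guesses at chance on random balanced data", {
  set.seed(55)
  model <- subject_lstm(3, 4, hidden = 8, n_layers = 5, seed = 100)
  n <- 400
  segs <- lapply(seq_len(n), function(i) matrix(rnorm(3 * 15), 3))
  y <- rep(1:4, n / 4)
  pred <- apply(forward_lstm(model, segs), 2L, which.max)
  acc <- mean(pred == y)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(acc - 0.25), 3 * se + 1e-9)
})

test_that("subject prediction majority-votes with probability tie-breaks", {
  vp <- eeglink:::vote_predict
  expect_equal(vp(matrix(c(0.9, 0.1, 0.8, 0.2, 0.7, 0.3), 2)), 1L)
  # 2-2 vote; summed probability favours subject 2
  probs <- matrix(c(0.6, 0.4, 0.6, 0.4, 0.1, 0.9, 0.2, 0.8), 2)
  expect_equal(vp(probs), 2L)
  expect_equal(vp(matrix(c(0.2, 0.8), 2)), 2L)

  model <- subject_lstm(2, 3, hidden = 4, n_layers = 1, seed = 1)
  seg <- matrix(rnorm(2 * 6), 2)
  expect_equal(predict_subject(model, list(seg)),
               which.max(forward_lstm(model, seg)[, 1]))
})
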