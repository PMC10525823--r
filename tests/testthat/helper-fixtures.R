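# Shared fixtures. Expensive artefacts (synthetic datasets, trained models)
# are built once per test run and memoized here so several test files can
# share them.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = fixture_cache))
    assign(key, builder(), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

# take a subset of a segment batch
batch_subset <- function(batch, keep) subset_batch(batch, keep)

# 10-subject, 4-task, 8-channel synthetic dataset (the subject-linking
# study conditions), segmented horizontally at l = 150
synth10 <- function() memo("synth10", function() {
  dir <- file.path(tempdir(), "eeglink-synth10")
  man <- generate_dataset(n_subjects = 10L, n_tasks = 4L, classes = 2L,
                          K = 8L, L = 4800L, fs = 160, seed = 42L,
                          outdir = dir)
  batch <- segment_dataset(man, segmentation_spec("horizontal", l_tilde = 150L),
                           fs = 160, classes = 2L)
  split <- split_by_tasks(man, "3:1", 0L)
  list(manifest = man, batch = batch, split = split, fs = 160)
})

# the subject LSTM trained on synth10's training tasks (shared by the
# end-to-end recovery and method-comparison tests)
trained_lstm <- function() memo("trained_lstm", function() {
  s <- synth10()
  tr <- s$batch$labels$task %in% s$split$train_tasks
  model <- train_subject_lstm(
    batch_subset(s$batch, tr),
    train_config(epochs = 30L, batch_size = 16L, seed = 7L,
                 stop_at_train_acc = 1.0),
    hidden = 32L)
  list(model = model, test = batch_subset(s$batch, !tr))
})

# 3-class synthetic dataset with alpha-gain ratio 3 (the task-linking
# study conditions), segmented vertically
synth3c <- function() memo("synth3c", function() {
  dir <- file.path(tempdir(), "eeglink-synth3c")
  man <- generate_dataset(n_subjects = 5L, n_tasks = 6L, classes = 3L,
                          K = 8L, L = 640L, fs = 160, seed = 11L,
                          outdir = dir, gain_ratio = 3)
  batch <- segment_dataset(man, segmentation_spec("vertical"),
                           fs = 160, classes = 3L)
  split <- split_by_tasks(man, "4:2", 0L)
  list(manifest = man, batch = batch, split = split, fs = 160)
})

trained_cnn <- function() memo("trained_cnn", function() {
  s <- synth3c()
  tr <- s$batch$labels$task %in% s$split$train_tasks
  model <- train_task_cnn(
    batch_subset(s$batch, tr),
    train_config(epochs = 30L, seed = 7L, stop_at_train_acc = 1.0))
  list(model = model, test = batch_subset(s$batch, !tr))
})

# independent scalar-loop peephole LSTM cell (explicit loops, no matrix
# algebra) used as the oracle for the vectorized cell
scalar_cell_oracle <- function(params, x, state) {
  H <- length(state$h)
  sig <- function(z) 1 / (1 + exp(-z))
  gate_row <- function(block, r) (block - 1L) * H + r
  lin <- function(block, r, peep_c) {
    acc <- params$b[gate_row(block, r)]
    for (j in seq_along(x))
      acc <- acc + params$W[gate_row(block, r), j] * x[j]
    for (j in seq_len(H))
      acc <- acc + params$U[gate_row(block, r), j] * state$h[j]
    acc + peep_c
  }
  h <- numeric(H); cc <- numeric(H)
  for (r in seq_len(H)) {
    I <- sig(lin(1L, r, params$vI[r] * state$c[r]))
    F <- sig(lin(2L, r, params$vF[r] * state$c[r]))
    g <- tanh(lin(4L, r, 0))
    cc[r] <- F * state$c[r] + I * g
    O <- sig(lin(3L, r, params$vO[r] * cc[r]))
    h[r] <- O * tanh(cc[r])
  }
  list(h = h, c = cc)
}

random_lstm_params <- function(input_size, H) {
  list(W = matrix(rnorm(4 * H * input_size), 4 * H, input_size),
       U = matrix(rnorm(4 * H * H), 4 * H, H),
       b = rnorm(4 * H),
       vI = rnorm(H), vF = rnorm(H), vO = rnorm(H))
}
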