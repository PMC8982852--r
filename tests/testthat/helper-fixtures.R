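# Shared fixtures: a tiny architecture for fast tests, a tiny generator
# spec, and a memoized desk-scale trained model shared by the acceptance
# tests (trained once per test run).

tiny_arch <- function(dropout = 0.2) {
  model_config(conv_channels = c(6L, 8L, 10L), kernel_sizes = c(5L, 3L, 3L),
               pool_sizes = c(5L, 5L, 5L), dropout_rate = dropout,
               gru_hidden = 10L, blend_channels = c(8L, 6L, 4L, 1L))
}

tiny_spec <- function(n_pos = 60L, n_neg = 60L, seed = 7L) {
  generator_spec(seq_len = 250L, n_pos = n_pos, n_neg = n_neg,
                 bump_sd = 30, seed = seed)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

.fixture_env <- new.env(parent = emptyenv())

# The end-to-end synthetic model used by the acceptance criteria: packaged
# generator defaults (2000 positives + 2000 negatives, 1000 bp, fixed seed),
# default architecture, default training configuration (<= 30 epochs, early
# stopping). Trained once and reused across acceptance tests.
acceptance_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  spec <- generator_spec(seed = 1L)
  sim <- simulate_dataset(spec)
  split <- split_random(sim$samples, seed = 1L)
  model <- train_model(split, train_config(seed = 1L))
  te <- stack_samples(split$test)
  pred <- bindsignal:::predict_batch(model, te$x)
  .fixture_env$fx <- list(spec = spec, sim = sim, split = split,
                          model = model, test = te, pred = pred)
  .fixture_env$fx
}
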