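test_that("analytic BPTT gradients match finite differences on a tiny stacked GRU", {
  p <- mctsmol:::gru_init_params(3L, 4L, 2L, 3L, seed = 3)
  in_ids <- rbind(c(0L, 1L, 2L), c(0L, 2L, 0L))
  tgt_ids <- rbind(c(1L, 2L, 3L), c(2L, 3L, 0L))
  fwd <- mctsmol:::gru_forward(p, in_ids, tgt_ids, keep_cache = TRUE)
  g <- mctsmol:::gru_backward(p, fwd)
  eps <- 1e-6
  check_leaf <- function(get, set, gval) {
    set.seed(11)
    for (i in sample(length(gval), min(6L, length(gval)))) {
      pp <- p; v <- get(pp); v[i] <- v[i] + eps; pp <- set(pp, v)
      up <- mctsmol:::gru_forward(pp, in_ids, tgt_ids)$loss
      pp <- p; v <- get(pp); v[i] <- v[i] - eps; pp <- set(pp, v)
      dn <- mctsmol:::gru_forward(pp, in_ids, tgt_ids)$loss
      expect_lt(abs((up - dn) / (2 * eps) - gval[i]), 1e-6)
    }
  }
  for (l in 1:2) {
    check_leaf(function(q) q$layers[[l]]$W,
               function(q, v) { q$layers[[l]]$W[] <- v; q }, g$layers[[l]]$W)
    check_leaf(function(q) q$layers[[l]]$U,
               function(q, v) { q$layers[[l]]$U[] <- v; q }, g$layers[[l]]$U)
    check_leaf(function(q) q$layers[[l]]$b,
               function(q, v) { q$layers[[l]]$b[] <- v; q }, g$layers[[l]]$b)
  }
  check_leaf(function(q) q$Wy, function(q, v) { q$Wy[] <- v; q }, g$Wy)
  check_leaf(function(q) q$by, function(q, v) { q$by[] <- v; q }, g$by)
})

test_that("next-symbol distributions are normalized over the full vocabulary", {
  fit <- toy_model()
  for (prefix in list(character(0), "C", c("C", "C"), tokenize("Cc1ccccc1"))) {
    p <- next_distribution(fit, prefix)
    expect_length(p, 64L)
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-6)
  }
  expect_error(next_distribution(fit, c("C", "$")), "terminal")
})

test_that("the training loss equals the chained next-symbol negative log-likelihood", {
  fit <- toy_model()
  s <- "CCO"
  toks <- c(tokenize(s), TERMINAL_TOKEN)
  nll <- 0
  for (t in seq_along(toks)) {
    p <- next_distribution(fit, toks[seq_len(t - 1L)])
    nll <- nll - log(p[[toks[t]]])
  }
  expect_lt(abs(lm_loss(fit, s) - nll / length(toks)), 1e-9)
})

test_that("training is reproducible and rejects degenerate inputs", {
  cfg <- model_config(hidden_per_layer = 8L, epochs = 3L, batch_size = 4L,
                      seed = 5L)
  corpus <- c("CCO", "CCC", "c1ccccc1", "CCCC", "CO")
  f1 <- train_lm(corpus, cfg)
  f2 <- train_lm(corpus, cfg)
  expect_identical(f1$report$epoch_loss, f2$report$epoch_loss)
  expect_identical(f1$params$Wy, f2$params$Wy)
  expect_error(train_lm(character(0), cfg), "empty")
  cfg_short <- model_config(hidden_per_layer = 8L, epochs = 1L,
                            batch_size = 4L, max_sequence_length = 3L)
  expect_warning(train_lm(corpus, cfg_short), "truncated")
})

test_that("a model overfit to one sequence predicts it exactly", {
  cfg <- model_config(hidden_per_layer = 16L, epochs = 250L, batch_size = 1L,
                      learning_rate = 5e-3, seed = 2L)
  fit <- train_lm("CC", cfg)
  # terminal is the modal symbol after the full prefix
  p <- next_distribution(fit, c("C", "C"))
  expect_identical(names(which.max(p)), TERMINAL_TOKEN)
  # greedy decoding reproduces the training sequence
  dec <- greedy_decode(fit)
  expect_identical(dec$smiles, "CC")
  expect_true(dec$complete)
  # and the final training loss is near zero
  expect_lt(fit$report$final_loss, 0.05)
})

test_that("sampled next-symbol frequencies match the model distribution", {
  fit <- toy_model()
  p <- next_distribution(fit, character(0))
  n <- 10000L
  draws <- sample_molecules(fit, n, seed = 99L)
  first <- vapply(draws, function(d) d$tokens[1L], character(1))
  for (s in names(p)[p > 0.02]) {
    se <- sqrt(p[[s]] * (1 - p[[s]]) / n)
    expect_lt(abs(mean(first == s) - p[[s]]), 3 * se + 1e-3)
  }
  expect_identical(sample_next(fit, "C", seed = 7L),
                   sample_next(fit, "C", seed = 7L))
})

test_that("rollout stops at the terminal or at the length cap", {
  fit <- toy_model()
  done <- rollout(fit, c("C", "C", "$"))
  expect_identical(done$tokens, c("C", "C", "$"))
  expect_true(done$complete)
  ro <- rollout(fit, "C", max_length = 81L, seed = 3L)
  if (ro$complete) {
    expect_identical(ro$tokens[length(ro$tokens)], TERMINAL_TOKEN)
    expect_identical(sum(ro$tokens == TERMINAL_TOKEN), 1L)
  }
  # a policy that never emits the terminal is truncated and flagged
  never_end <- fixed_model(c(1, 1, 0), c("A", "B"))
  tr <- rollout(never_end, character(0), max_length = 5L, seed = 1L)
  expect_length(tr$tokens, 5L)
  expect_false(tr$complete)
})

test_that("batched sampling is seed-deterministic and vocabulary-closed", {
  fit <- toy_model()
  a <- sample_molecules(fit, 25L, seed = 4L)
  b <- sample_molecules(fit, 25L, seed = 4L)
  expect_identical(a, b)
  expect_identical(sample_molecules(fit, 0L), list())
  v <- as.character(unclass(smiles_vocabulary()))
  for (m in a) expect_true(all(m$tokens %in% v))
})

test_that("checkpoints round-trip exactly and pin the vocabulary", {
  fit <- toy_model()
  dir <- withr::local_tempdir()
  save_checkpoint(fit, dir)
  fit2 <- load_checkpoint(dir)
  expect_identical(fit2$params$Wy, fit$params$Wy)
  expect_identical(fit2$params$layers[[2L]]$U, fit$params$layers[[2L]]$U)
  p1 <- next_distribution(fit, c("C", "C"))
  p2 <- next_distribution(fit2, c("C", "C"))
  expect_identical(p1, p2)
  # a tampered vocabulary sidecar is rejected
  vpath <- file.path(dir, "vocab.json")
  writeLines(sub("\\[C@@H\\]", "[XX]", readLines(vpath)), vpath)
  expect_error(load_checkpoint(dir), "hash")
})
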