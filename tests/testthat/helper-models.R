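# Shared fixtures: a small trained language model (built once per session)
# and two plug-in toy policies exercising the search through the generic
# stepping interface.

.fixtures <- new.env(parent = emptyenv())

toy_corpus <- function() generate_toy_corpus(200, seed = 17)

# 200-string toy corpus, 10 epochs, modest hidden size: trains in a couple
# of seconds and is reused by every test that needs a real model.
toy_model <- function() {
  if (is.null(.fixtures$model)) {
    cfg <- model_config(hidden_per_layer = 48L, epochs = 10L,
                        batch_size = 32L, seed = 17L)
    .fixtures$model <- train_lm(toy_corpus(), cfg)
  }
  .fixtures$model
}

# Uniform policy over a tiny alphabet (terminal included): every symbol
# equally likely regardless of prefix.
uniform_model <- function(symbols = c("A", "B", "C")) {
  v <- vocabulary(symbols)
  structure(list(vocab = v), class = "uniform_lm")
}

# Fixed next-symbol distribution, prefix-independent.
fixed_model <- function(probs, symbols) {
  v <- vocabulary(symbols)
  stopifnot(length(probs) == length(v))
  structure(list(vocab = v, probs = probs / sum(probs)), class = "fixed_lm")
}

registerS3method("next_distribution", "uniform_lm", function(model, prefix) {
  p <- rep(1 / length(model$vocab), length(model$vocab))
  names(p) <- as.character(unclass(model$vocab))
  p
}, envir = asNamespace("mctsmol"))

registerS3method("next_distribution", "fixed_lm", function(model, prefix) {
  p <- model$probs
  names(p) <- as.character(unclass(model$vocab))
  p
}, envir = asNamespace("mctsmol"))

# Deterministic toy objective over strings of A/B/C: each string maps to a
# distinct integer (digits 1..3 in base 4 by position), spread over [-0.9,
# 0.9] by a fixed nonlinear map. Used with brute-force enumeration as the
# search oracle.
toy_score <- function(s) {
  if (!nzchar(s)) return(-0.95)
  d <- match(strsplit(s, "")[[1]], c("A", "B", "C"))
  val <- sum(d * 4^(seq_along(d) - 1))
  0.9 * sin(val * 2.1)
}

toy_reward_fn <- function(smiles) {
  list(reward = toy_score(smiles), valid = TRUE, scores = NULL,
       canonical = NULL)
}
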