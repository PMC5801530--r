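#' Language-model configuration
#'
#' Architecture and training hyper-parameters for the character-level SMILES
#' model: a stack of `gru_layers` gated recurrent units with
#' `hidden_per_layer` units each (the default 2 x 256 gives a 512-dimensional
#' stacked hidden state), reading one-hot encoded symbols and emitting a
#' softmax distribution over the full vocabulary (terminal included). The
#' training objective is the relative entropy between the one-hot next
#' symbol and the predicted distribution, which for one-hot targets equals
#' categorical cross-entropy and is computed as such.
#'
#' @param vocab_size Encoding dimension; equals the vocabulary size
#'   (64 for [smiles_vocabulary()]).
#' @param gru_layers Number of stacked GRU layers.
#' @param hidden_per_layer Hidden units per GRU layer.
#' @param batch_size Minibatch size for Adam.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param max_sequence_length Training sequences longer than this (terminal
#'   included) are truncated with a warning.
#' @param max_length Generation cap: rollouts stop after this many tokens
#'   (terminal included) and are flagged incomplete.
#' @param clip_norm Global gradient-norm clip; `Inf` disables.
#' @param temperature Sampling temperature (1 = plain ancestral sampling).
#' @param seed Integer seed making initialisation and training reproducible.
#' @return A list of class `"lm_config"`.
#' @export
model_config <- function(vocab_size = 64L, gru_layers = 2L,
                         hidden_per_layer = 256L, batch_size = 256L,
                         learning_rate = 1e-3, epochs = 10L,
                         max_sequence_length = 81L, max_length = 81L,
                         clip_norm = 5, temperature = 1, seed = 0L) {
  stopifnot(vocab_size >= 2L, gru_layers >= 1L, hidden_per_layer >= 1L,
            batch_size >= 1L, learning_rate > 0, epochs >= 1L,
            max_sequence_length >= 2L, max_length >= 2L, temperature > 0)
  structure(list(
    vocab_size = as.integer(vocab_size),
    onehot_dim = as.integer(vocab_size),
    gru_layers = as.integer(gru_layers),
    hidden_per_layer = as.integer(hidden_per_layer),
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    epochs = as.integer(epochs),
    max_sequence_length = as.integer(max_sequence_length),
    max_length = as.integer(max_length),
    clip_norm = clip_norm,
    temperature = temperature,
    seed = as.integer(seed)
  ), class = "lm_config")
}

# ---- corpus preparation ----------------------------------------------------

# Accepts raw SMILES strings or pre-tokenized character vectors; returns a
# list of integer id vectors, each ending with the terminal id.
corpus_to_ids <- function(corpus, vocab, max_sequence_length) {
  if (length(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  term_id <- vocab_index(vocab, TERMINAL_TOKEN)
  n_trunc <- 0L
  seqs <- lapply(corpus, function(x) {
    toks <- if (length(x) == 1L && !x %in% as.character(unclass(vocab)))
      tokenize(x, vocab) else as.character(x)
    if (!is_complete(toks)) toks <- c(toks, TERMINAL_TOKEN)
    ids <- vocab_index(vocab, toks)
    if (length(ids) > max_sequence_length) {
      n_trunc <<- n_trunc + 1L
      ids <- ids[seq_len(max_sequence_length)]
    }
    ids
  })
  if (n_trunc > 0L) {
    warning(sprintf("%d sequence(s) longer than max_sequence_length were truncated",
                    n_trunc), call. = FALSE)
  }
  seqs
}

# Pad a list of id vectors into input/target matrices. Inputs are the ids
# right-shifted by one position (position 1 reads the start marker, encoded
# as id 0 = zero vector); targets are the ids themselves, 0 = masked pad.
pad_batch <- function(seqs) {
  Tt <- max(lengths(seqs))
  n <- length(seqs)
  in_ids <- matrix(0L, n, Tt)
  tgt_ids <- matrix(0L, n, Tt)
  for (i in seq_len(n)) {
    s <- seqs[[i]]
    len <- length(s)
    tgt_ids[i, seq_len(len)] <- s
    if (len > 1L) in_ids[i, 2:len] <- s[seq_len(len - 1L)]
  }
  list(in_ids = in_ids, tgt_ids = tgt_ids)
}

# ---- training --------------------------------------------------------------

#' Train the SMILES language model
#'
#' Fits the stacked-GRU model so that it predicts a right-shifted version of
#' each input sequence: position t reads symbol s_{t-1} (the start marker at
#' t = 1) and is trained towards s_t. The loss is the mean categorical
#' cross-entropy over all unmasked positions, minimised with Adam.
#'
#' @param corpus Character vector of SMILES strings, or a list of token
#'   vectors. Sequences need not carry the terminal symbol; it is appended.
#' @param config A [model_config()].
#' @param vocab A [vocabulary()]; its size must equal `config$vocab_size`.
#' @param verbose Print the per-epoch loss.
#' @return An object of class `"smiles_lm"`: the trained parameters, the
#'   vocabulary, the config, and `$report`, a training report with the
#'   per-epoch loss trajectory, corpus size and final loss.
#' @export
#' @examples
#' \donttest{
#' v <- smiles_vocabulary()
#' cfg <- model_config(hidden_per_layer = 16, epochs = 3, batch_size = 8,
#'                     seed = 1)
#' fit <- train_lm(c("CCO", "CCC", "c1ccccc1"), cfg, v)
#' fit$report$epoch_loss
#' }
train_lm <- function(corpus, config = model_config(), vocab = smiles_vocabulary(),
                     verbose = FALSE) {
  stopifnot(inherits(config, "lm_config"))
  if (length(vocab) != config$vocab_size) {
    stop(sprintf("vocabulary size (%d) does not match config$vocab_size (%d)",
                 length(vocab), config$vocab_size), call. = FALSE)
  }
  seqs <- corpus_to_ids(corpus, vocab, config$max_sequence_length)
  n <- length(seqs)
  params <- gru_init_params(config$vocab_size, config$hidden_per_layer,
                            config$gru_layers, config$vocab_size,
                            seed = config$seed)
  opt <- adam_init(params)
  epoch_loss <- numeric(config$epochs)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      tot <- 0; tot_pos <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        b <- pad_batch(seqs[idx])
        fwd <- gru_forward(params, b$in_ids, b$tgt_ids, keep_cache = TRUE)
        grads <- gru_backward(params, fwd)
        upd <- adam_update(params, grads, opt, lr = config$learning_rate,
                           clip_norm = config$clip_norm)
        params <- upd$params; opt <- upd$opt
        tot <- tot + fwd$loss * fwd$n_pos
        tot_pos <- tot_pos + fwd$n_pos
      }
      epoch_loss[ep] <- tot / tot_pos
      if (verbose) message(sprintf("epoch %d/%d  loss %.4f",
                                   ep, config$epochs, epoch_loss[ep]))
    }
  })
  model <- structure(list(params = params, vocab = vocab, config = config),
                     class = "smiles_lm")
  model$report <- list(epoch_loss = epoch_loss, n_sequences = n,
                       epochs = config$epochs,
                       final_loss = epoch_loss[config$epochs])
  model
}

#' @export
print.smiles_lm <- function(x, ...) {
  cat(sprintf("<smiles_lm: %d-layer GRU, %d hidden/layer, vocab %d%s>\n",
              x$config$gru_layers, x$config$hidden_per_layer,
              length(x$vocab),
              if (!is.null(x$report))
                sprintf(", final loss %.4f", x$report$final_loss) else ""))
  invisible(x)
}

#' Mean cross-entropy of a model on a set of sequences
#'
#' Evaluates (without updating) the same masked objective used in training:
#' the mean over all symbol positions of the negative log predicted
#' probability of the true next symbol.
#'
#' @param model A trained `"smiles_lm"`.
#' @param corpus As in [train_lm()].
#' @return Mean negative log-likelihood per symbol.
#' @export
lm_loss <- function(model, corpus) {
  seqs <- corpus_to_ids(corpus, model$vocab, model$config$max_sequence_length)
  b <- pad_batch(seqs)
  gru_forward(model$params, b$in_ids, b$tgt_ids)$loss
}

# ---- incremental stepping interface (used by the tree search) --------------

#' Step a language model one symbol at a time
#'
#' The tree search consumes models through this two-function interface so
#' that alternative models (for instance uniform toy policies in tests) can
#' be plugged in. `lm_init_state()` returns the state after reading the
#' begin-of-sequence marker together with the distribution of the first
#' symbol; `lm_advance()` feeds one more symbol and returns the updated
#' state and the distribution of the following symbol. Distributions are
#' numeric vectors over the model's vocabulary, in vocabulary order.
#'
#' The default methods rebuild the prefix and delegate to
#' [next_distribution()]; the `"smiles_lm"` methods carry the GRU hidden
#' state so each call costs a single step.
#'
#' @param model A language model.
#' @return A list with elements `state` and `probs`.
#' @export
lm_init_state <- function(model) UseMethod("lm_init_state")

#' @rdname lm_init_state
#' @param state A state returned by `lm_init_state()` or `lm_advance()`.
#' @param token A single vocabulary symbol to feed.
#' @export
lm_advance <- function(model, state, token) UseMethod("lm_advance")

#' @export
lm_init_state.default <- function(model) {
  list(state = list(prefix = character(0)),
       probs = next_distribution(model, character(0)))
}

#' @export
lm_advance.default <- function(model, state, token) {
  prefix <- c(state$prefix, token)
  list(state = list(prefix = prefix),
       probs = next_distribution(model, prefix))
}

#' @export
lm_init_state.smiles_lm <- function(model) {
  st <- gru_zero_state(model$params, 1L)
  X <- matrix(0, 1L, model$params$input_dim)  # start marker = zero vector
  out <- gru_step(model$params, st, X)
  list(state = out$state, probs = drop(out$probs))
}

#' @export
lm_advance.smiles_lm <- function(model, state, token) {
  id <- vocab_index(model$vocab, token)
  X <- matrix(0, 1L, model$params$input_dim)
  X[1L, id] <- 1
  out <- gru_step(model$params, state, X)
  list(state = out$state, probs = drop(out$probs))
}

#' Vocabulary of a language model
#' @param model A language model.
#' @return The model's [vocabulary()].
#' @export
lm_vocab <- function(model) UseMethod("lm_vocab")

#' @export
lm_vocab.default <- function(model) model$vocab

# ---- querying and sampling -------------------------------------------------

#' Next-symbol distribution given a prefix
#'
#' @param model A language model.
#' @param prefix Character vector of tokens already emitted (possibly
#'   empty: the distribution of the first symbol). Must not contain the
#'   terminal symbol anywhere but the end; a terminal-ended prefix is
#'   rejected since nothing follows it.
#' @return Named numeric vector over the vocabulary, summing to 1.
#' @export
next_distribution <- function(model, prefix) UseMethod("next_distribution")

#' @export
next_distribution.smiles_lm <- function(model, prefix) {
  prefix <- as.character(prefix)
  if (TERMINAL_TOKEN %in% prefix) {
    stop("prefix contains the terminal symbol; nothing can follow it",
         call. = FALSE)
  }
  cur <- lm_init_state(model)
  for (tok in prefix) cur <- lm_advance(model, cur$state, tok)
  p <- cur$probs
  names(p) <- as.character(unclass(model$vocab))
  p
}

apply_temperature <- function(p, temperature) {
  if (temperature == 1) return(p)
  q <- p^(1 / temperature)
  q / sum(q)
}

#' Sample the next symbol
#'
#' Draws one symbol from [next_distribution()] (ancestral sampling at the
#' configured temperature). Reproducible under [set.seed()] or `seed`.
#'
#' @inheritParams next_distribution
#' @param seed Optional seed for this single draw.
#' @return A single vocabulary symbol.
#' @export
sample_next <- function(model, prefix, seed = NULL) {
  p <- apply_temperature(next_distribution(model, prefix),
                         model$config$temperature %||% 1)
  with_seed(seed, {
    sym <- as.character(unclass(lm_vocab(model)))
    sym[sample.int(length(p), 1L, prob = p)]
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorised categorical draw: one index per row of the probability matrix.
sample_rows <- function(P) {
  n <- nrow(P); k <- ncol(P)
  cum <- P %*% upper.tri(matrix(0, k, k), diag = TRUE)
  u <- stats::runif(n) * cum[, k]  # guard tiny normalisation drift
  as.integer(rowSums(cum < u) + 1L)
}

#' Complete a prefix by ancestral sampling
#'
#' Repeatedly samples the next symbol from the model until the terminal
#' symbol occurs or `max_length` total tokens are reached. A prefix already
#' ending in the terminal is returned unchanged.
#'
#' @inheritParams next_distribution
#' @param max_length Cap on total tokens (terminal included); defaults to
#'   the model config's `max_length`.
#' @param seed Optional seed.
#' @param state Optional precomputed model state for the prefix (as from
#'   [lm_advance()]); used by the tree search to avoid re-reading the prefix.
#' @return A list: `tokens` (the full sequence) and `complete` (`TRUE` iff
#'   it ends with the terminal symbol; `FALSE` means the cap was hit).
#' @export
rollout <- function(model, prefix = character(0), max_length = NULL,
                    seed = NULL, state = NULL) {
  prefix <- as.character(prefix)
  if (is_complete(prefix)) return(list(tokens = prefix, complete = TRUE))
  max_length <- max_length %||% (model$config$max_length %||% 81L)
  temp <- model$config$temperature %||% 1
  vocab <- lm_vocab(model)
  sym <- as.character(unclass(vocab))
  with_seed(seed, {
    if (is.null(state)) {
      cur <- lm_init_state(model)
      for (tok in prefix) cur <- lm_advance(model, cur$state, tok)
    } else {
      cur <- state
    }
    tokens <- prefix
    complete <- FALSE
    while (length(tokens) < max_length) {
      p <- apply_temperature(cur$probs, temp)
      tok <- sym[sample.int(length(p), 1L, prob = p)]
      tokens <- c(tokens, tok)
      if (tok == TERMINAL_TOKEN) { complete <- TRUE; break }
      cur <- lm_advance(model, cur$state, tok)
    }
    list(tokens = tokens, complete = complete)
  })
}

#' Sample molecules by plain ancestral generation
#'
#' The pure language-model baseline: `n` independent rollouts from the empty
#' prefix, each elongated symbol by symbol until the terminal occurs (or the
#' length cap is hit). Rollouts are run as one batch, so large `n` is cheap.
#'
#' @param model A trained `"smiles_lm"`.
#' @param n Number of molecules (0 returns an empty list).
#' @param max_length Token cap per sequence, terminal included.
#' @param seed Optional seed; the same seed reproduces the same list.
#' @return A list of `n` results, each a list with `tokens`, `complete`,
#'   and `smiles` (the detokenized string).
#' @export
sample_molecules <- function(model, n, max_length = NULL, seed = NULL) {
  stopifnot(n >= 0L)
  if (n == 0L) return(list())
  max_length <- max_length %||% (model$config$max_length %||% 81L)
  temp <- model$config$temperature %||% 1
  V <- model$params$input_dim
  term_id <- vocab_index(model$vocab, TERMINAL_TOKEN)
  sym <- as.character(unclass(model$vocab))
  with_seed(seed, {
    state <- gru_zero_state(model$params, n)
    X <- matrix(0, n, V)  # all rows start at the begin marker
    toks <- matrix(0L, n, max_length)
    active <- rep(TRUE, n)
    lens <- integer(n)
    for (t in seq_len(max_length)) {
      out <- gru_step(model$params, state, X)
      state <- out$state
      P <- out$probs
      if (temp != 1) {
        P <- P^(1 / temp); P <- P / rowSums(P)
      }
      draw <- sample_rows(P)
      draw[!active] <- 0L
      toks[active, t] <- draw[active]
      lens[active] <- t
      done <- active & draw == term_id
      active <- active & !done
      if (!any(active)) break
      X <- matrix(0, n, V)
      X[cbind(which(active), draw[active])] <- 1
    }
    lapply(seq_len(n), function(i) {
      ids <- toks[i, seq_len(lens[i])]
      tokens <- sym[ids]
      list(tokens = tokens, complete = is_complete(tokens),
           smiles = detokenize(tokens))
    })
  })
}

#' Greedy (argmax) decoding from the empty prefix
#'
#' Deterministically follows the modal symbol at every step; used for
#' overfit sanity checks (a model trained to convergence on one sequence
#' reproduces it greedily).
#'
#' @inheritParams sample_molecules
#' @return As one element of [sample_molecules()]'s result.
#' @export
greedy_decode <- function(model, max_length = NULL) {
  max_length <- max_length %||% (model$config$max_length %||% 81L)
  sym <- as.character(unclass(lm_vocab(model)))
  cur <- lm_init_state(model)
  tokens <- character(0)
  complete <- FALSE
  while (length(tokens) < max_length) {
    tok <- sym[which.max(cur$probs)]
    tokens <- c(tokens, tok)
    if (tok == TERMINAL_TOKEN) { complete <- TRUE; break }
    cur <- lm_advance(model, cur$state, tok)
  }
  list(tokens = tokens, complete = complete, smiles = detokenize(tokens))
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory of plain-text JSON: `config.json`,
#' `vocab.json` (the ordered symbol sidecar) and `weights.json` (all
#' parameter matrices at 17 significant digits, an exact double round
#' trip). Loading verifies that the vocabulary file hash recorded at save
#' time matches, so a checkpoint can never silently run against different
#' symbol indexing.
#'
#' @param model A `"smiles_lm"`.
#' @param dir Checkpoint directory (created if needed).
#' @return `save_checkpoint` returns `dir` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vocab_path <- file.path(dir, "vocab.json")
  write_vocabulary(model$vocab, vocab_path)
  cfg <- unclass(model$config)
  cfg$vocab_md5 <- unname(tools::md5sum(vocab_path))
  cfg$format_version <- 1L
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  p <- model$params
  w <- list(hidden = p$hidden, n_layers = p$n_layers,
            input_dim = p$input_dim, output_dim = p$output_dim,
            layers = lapply(p$layers, function(l)
              list(W = l$W, U = l$U, b = l$b)),
            Wy = p$Wy, by = p$by)
  writeLines(jsonlite::toJSON(w, digits = I(17), auto_unbox = TRUE),
             file.path(dir, "weights.json"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  vocab_path <- file.path(dir, "vocab.json")
  md5 <- unname(tools::md5sum(vocab_path))
  if (!identical(md5, cfg$vocab_md5)) {
    stop("checkpoint vocabulary sidecar does not match the hash recorded at save time",
         call. = FALSE)
  }
  vocab <- read_vocabulary(vocab_path)
  w <- jsonlite::read_json(file.path(dir, "weights.json"),
                           simplifyVector = TRUE)
  params <- list(
    layers = lapply(seq_len(w$n_layers), function(l) {
      ll <- if (is.data.frame(w$layers)) {
        list(W = w$layers$W[[l]], U = w$layers$U[[l]], b = w$layers$b[[l]])
      } else w$layers[[l]]
      list(W = as.matrix(ll$W), U = as.matrix(ll$U), b = as.numeric(ll$b))
    }),
    Wy = as.matrix(w$Wy), by = as.numeric(w$by),
    hidden = as.integer(w$hidden), n_layers = as.integer(w$n_layers),
    input_dim = as.integer(w$input_dim), output_dim = as.integer(w$output_dim)
  )
  keep <- intersect(names(formals(model_config)), names(cfg))
  config <- do.call(model_config, cfg[keep])
  structure(list(params = params, vocab = vocab, config = config),
            class = "smiles_lm")
}
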