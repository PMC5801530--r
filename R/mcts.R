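#' Tree-search configuration
#'
#' Settings for the UCT search over symbol sequences. At every iteration the
#' tree is traversed by upper-confidence-bound selection, the reached leaf
#' is expanded by sampling `expansion_samples` candidate next symbols from
#' the language model (distinct draws become children), one rollout is
#' simulated from the chosen child, and the resulting reward is
#' backpropagated along the path.
#'
#' @param exploration_constant UCT exploration weight `c`.
#' @param expansion_samples Number of next-symbol draws per expansion
#'   (default 30); distinct symbols among the draws become children.
#' @param expansion_mode `"sample"` (default) draws from the model
#'   distribution; `"topk"` instead takes the `expansion_samples` most
#'   probable symbols with nonzero probability.
#' @param max_rollout_length Cap on total tokens of a rollout (terminal
#'   included); rollouts that hit the cap score `invalid_reward`.
#' @param budget_iterations Number of search iterations (must be positive).
#' @param budget_seconds Optional wall-clock cap; the loop stops early once
#'   exceeded.
#' @param invalid_reward Reward for invalid or truncated strings.
#' @param seed Integer seed; together with the model it fully determines
#'   the search.
#' @param log_interval Print running-best progress every this many
#'   iterations; `0` disables.
#' @return A list of class `"mcts_config"`.
#' @export
search_config <- function(exploration_constant = 1.0, expansion_samples = 30L,
                          expansion_mode = c("sample", "topk"),
                          max_rollout_length = 81L, budget_iterations = 1000L,
                          budget_seconds = Inf, invalid_reward = -1.0,
                          seed = 0L, log_interval = 0L) {
  expansion_mode <- match.arg(expansion_mode)
  stopifnot(expansion_samples >= 1L, max_rollout_length >= 2L,
            exploration_constant >= 0)
  if (is.null(budget_iterations) || budget_iterations <= 0) {
    stop("budget_iterations must be positive", call. = FALSE)
  }
  structure(list(
    exploration_constant = exploration_constant,
    expansion_samples = as.integer(expansion_samples),
    expansion_mode = expansion_mode,
    max_rollout_length = as.integer(max_rollout_length),
    budget_iterations = as.integer(budget_iterations),
    budget_seconds = budget_seconds,
    invalid_reward = invalid_reward,
    seed = as.integer(seed),
    log_interval = as.integer(log_interval)
  ), class = "mcts_config")
}

#' Upper confidence bound of a tree node
#'
#' The UCT score `W/n + c * sqrt(2 * ln(N) / n)` where `W` is the node's
#' cumulative reward, `n` its visit count and `N` the parent's visit count.
#' Unvisited nodes score `+Inf`, so every child is explored once before any
#' is revisited; with `c = 0` the score reduces to the empirical mean.
#'
#' @param visits Node visit count `n` (>= 0).
#' @param total_reward Cumulative backpropagated reward `W`.
#' @param parent_visits Parent visit count `N` (>= 1).
#' @param c Exploration constant.
#' @return Numeric scalar (possibly `Inf`).
#' @export
#' @examples
#' ucb_score(1, 0.5, 2, 1)  # 0.5 + sqrt(2 * log(2)) = 1.67741...
ucb_score <- function(visits, total_reward, parent_visits, c = 1.0) {
  if (visits < 0 || parent_visits < 1) {
    stop("visits must be >= 0 and parent_visits >= 1", call. = FALSE)
  }
  if (visits == 0) return(Inf)
  total_reward / visits + c * sqrt(2 * log(parent_visits) / visits)
}

# ---- nodes -----------------------------------------------------------------

# Nodes are environments (mutable, shared by reference along the path).
new_node <- function(sym, sym_id, parent) {
  node <- new.env(parent = emptyenv())
  node$sym <- sym
  node$sym_id <- sym_id
  node$parent <- parent
  node$children <- list()
  node$visits <- 0L
  node$total_reward <- 0
  node$expanded <- FALSE
  node$terminal <- identical(sym, TERMINAL_TOKEN)
  node$prefix <- if (is.null(parent)) character(0) else c(parent$prefix, sym)
  node$state <- NULL   # language-model state after consuming `sym`
  node$probs <- NULL   # next-symbol distribution at this node
  node
}

#' Create a search-tree root
#'
#' The root holds the begin-of-sequence marker: its next-symbol
#' distribution is the model's first-symbol prior.
#'
#' @param model A language model (see [lm_init_state()]).
#' @return The root node (an environment).
#' @export
mcts_root <- function(model) {
  root <- new_node(START_TOKEN, 0L, NULL)
  init <- lm_init_state(model)
  root$state <- init$state
  root$probs <- init$probs
  root
}

# Compute (lazily, recursively) the model state and next-symbol distribution
# at a node from its parent's state.
ensure_node_dist <- function(node, model) {
  if (!is.null(node$probs)) return(invisible(node))
  ensure_node_dist(node$parent, model)
  out <- lm_advance(model, node$parent$state, node$sym)
  node$state <- out$state
  node$probs <- out$probs
  invisible(node)
}

#' Selection step
#'
#' Walks from the root towards the leaves, at each level choosing the child
#' with the largest [ucb_score()]; stops at the first unexpanded or
#' terminal node. Ties break deterministically towards the lowest
#' vocabulary index.
#'
#' @param root A node from [mcts_root()].
#' @param c Exploration constant.
#' @return The list of nodes on the selected path, root first.
#' @export
mcts_select <- function(root, c = 1.0) {
  node <- root
  path <- list(node)
  while (node$expanded && !node$terminal && length(node$children) > 0L) {
    pv <- max(node$visits, 1L)
    scores <- vapply(node$children, function(ch)
      ucb_score(ch$visits, ch$total_reward, pv, c), numeric(1))
    node <- node$children[[which.max(scores)]]  # children are in vocab order
    path <- c(path, list(node))
  }
  path
}

#' Expansion step
#'
#' Draws `expansion_samples` symbols from the model's next-symbol
#' distribution at the node; the distinct drawn symbols become children
#' (ordered by vocabulary index), so there are at most `expansion_samples`
#' of them. The node is marked expanded. Terminal nodes cannot be expanded.
#'
#' @param node A non-terminal, unexpanded node.
#' @param model The language model.
#' @param config A [search_config()].
#' @return The list of newly created children.
#' @export
mcts_expand <- function(node, model, config = search_config()) {
  if (node$terminal) stop("cannot expand a terminal node", call. = FALSE)
  if (node$expanded) stop("node is already expanded", call. = FALSE)
  ensure_node_dist(node, model)
  p <- node$probs
  vocab <- lm_vocab(model)
  sym <- as.character(unclass(vocab))
  ids <- if (config$expansion_mode == "sample") {
    sort(unique(sample.int(length(p), config$expansion_samples,
                           replace = TRUE, prob = p)))
  } else {
    nz <- which(p > 0)
    sort(nz[order(p[nz], decreasing = TRUE)][
      seq_len(min(config$expansion_samples, length(nz)))])
  }
  ids <- as.integer(unname(ids))
  node$children <- lapply(ids, function(i) new_node(sym[i], i, node))
  node$expanded <- TRUE
  node$children
}

#' Simulation (rollout) step
#'
#' Completes the node's prefix by ancestral sampling from the model, up to
#' the terminal symbol or `max_rollout_length` total tokens, then scores
#' the string with `reward_fn`. A terminal node's own (complete) prefix is
#' scored directly; a truncated rollout scores `invalid_reward`.
#'
#' @param node A tree node.
#' @param model The language model.
#' @param reward_fn A function of one SMILES string returning a list with
#'   at least `reward` and `valid`; see [penalized_logp_reward()].
#' @param config A [search_config()].
#' @return A list: `record` (one scored generation) and `reward`.
#' @export
mcts_simulate <- function(node, model, reward_fn, config = search_config()) {
  if (node$terminal) {
    if (is.null(node$record)) {
      smiles <- detokenize(node$prefix)
      node$record <- make_record(reward_fn(smiles), smiles, complete = TRUE)
    }
    return(list(record = node$record, reward = node$record$reward))
  }
  ensure_node_dist(node, model)
  ro <- rollout(model, prefix = node$prefix,
                max_length = config$max_rollout_length,
                state = list(state = node$state, probs = node$probs))
  smiles <- detokenize(ro$tokens)
  if (!ro$complete) {
    rec <- list(smiles = smiles, valid = FALSE, complete = FALSE,
                logp = NA_real_, sa = NA_real_, ring_penalty = NA_real_,
                j = NA_real_, reward = config$invalid_reward,
                canonical = NA_character_)
    return(list(record = rec, reward = config$invalid_reward))
  }
  rec <- make_record(reward_fn(smiles), smiles, complete = TRUE)
  list(record = rec, reward = rec$reward)
}

make_record <- function(res, smiles, complete) {
  sc <- res$scores
  list(smiles = smiles,
       valid = isTRUE(res$valid),
       complete = complete,
       logp = if (!is.null(sc)) sc$logp else NA_real_,
       sa = if (!is.null(sc)) sc$sa else NA_real_,
       ring_penalty = if (!is.null(sc)) sc$ring_penalty else NA_real_,
       j = if (!is.null(sc)) sc$j else NA_real_,
       reward = res$reward,
       canonical = res$canonical %||% NA_character_)
}

#' Backpropagation step
#'
#' Adds one visit and the reward to every node on the path (root first);
#' no other node changes.
#'
#' @param path List of nodes as returned by [mcts_select()].
#' @param reward Scalar reward to credit.
#' @return Invisibly, the path.
#' @export
mcts_backpropagate <- function(path, reward) {
  if (length(path) == 0L) stop("cannot backpropagate an empty path", call. = FALSE)
  for (node in path) {
    node$visits <- node$visits + 1L
    node$total_reward <- node$total_reward + reward
  }
  invisible(path)
}

# ---- the outer loop --------------------------------------------------------

#' Monte Carlo tree search over SMILES strings
#'
#' Repeats selection, expansion, simulation and backpropagation until the
#' iteration budget is exhausted (or the wall-clock cap is hit). Every
#' simulated string is recorded in discovery order, duplicates included
#' (flagged via canonical form); the running best objective value is
#' tracked and optionally logged.
#'
#' @param model A trained language model (or any object implementing
#'   [lm_init_state()] / [lm_advance()] / [next_distribution()]).
#' @param reward_fn Scoring function of one SMILES string; defaults to the
#'   bounded penalized-logP reward. See [penalized_logp_reward()].
#' @param config A [search_config()].
#' @return A data.frame with one row per simulated string: `iteration`,
#'   `elapsed_s`, `smiles`, `valid`, `logp`, `sa`, `ring_penalty`, `j`,
#'   `reward`, `tree_prefix_len` (tokens contributed by the tree rather
#'   than the rollout), `is_duplicate`. Attributes: `"best"` (the best
#'   valid record by `j`, falling back to reward for score-free reward
#'   functions) and `"root"` (the search tree, for inspection).
#' @export
#' @examples
#' \donttest{
#' corpus <- generate_toy_corpus(200, seed = 17)
#' cfg <- model_config(hidden_per_layer = 32, epochs = 5, batch_size = 32,
#'                     seed = 1)
#' fit <- train_lm(corpus, cfg)
#' res <- mcts_search(fit, config = search_config(budget_iterations = 50,
#'                                                seed = 1))
#' attr(res, "best")$smiles
#' }
mcts_search <- function(model, reward_fn = penalized_logp_reward(),
                        config = search_config()) {
  stopifnot(inherits(config, "mcts_config"))
  t0 <- proc.time()[["elapsed"]]
  root <- mcts_root(model)
  seen <- new.env(parent = emptyenv())
  rows <- vector("list", config$budget_iterations)
  best <- NULL
  n_done <- 0L
  with_seed(config$seed, {
    for (i in seq_len(config$budget_iterations)) {
      if (proc.time()[["elapsed"]] - t0 > config$budget_seconds) break
      path <- mcts_select(root, config$exploration_constant)
      leaf <- path[[length(path)]]
      if (leaf$terminal) {
        sim <- mcts_simulate(leaf, model, reward_fn, config)
        tip <- leaf
      } else {
        children <- mcts_expand(leaf, model, config)
        pv <- max(leaf$visits, 1L)
        scores <- vapply(children, function(ch)
          ucb_score(ch$visits, ch$total_reward, pv,
                    config$exploration_constant), numeric(1))
        tip <- children[[which.max(scores)]]
        path <- c(path, list(tip))
        sim <- mcts_simulate(tip, model, reward_fn, config)
      }
      mcts_backpropagate(path, sim$reward)
      rec <- sim$record
      key <- paste0("k:", if (!is.na(rec$canonical)) rec$canonical else rec$smiles)
      dup <- !is.null(get0(key, envir = seen, inherits = FALSE))
      if (!dup) assign(key, TRUE, envir = seen)
      rows[[i]] <- data.frame(
        iteration = i,
        elapsed_s = proc.time()[["elapsed"]] - t0,
        smiles = rec$smiles, valid = rec$valid,
        logp = rec$logp, sa = rec$sa, ring_penalty = rec$ring_penalty,
        j = rec$j, reward = rec$reward,
        tree_prefix_len = length(tip$prefix),
        is_duplicate = dup,
        stringsAsFactors = FALSE
      )
      n_done <- i
      score <- if (!is.na(rec$j)) rec$j else rec$reward
      if (rec$valid && (is.null(best) || score > best$score)) {
        best <- c(rec, list(iteration = i, score = score))
      }
      if (config$log_interval > 0L && i %% config$log_interval == 0L) {
        message(sprintf("iter %d  best %s = %.4f  (%.1f strings/min)",
                        i, if (!is.null(best) && !is.na(best$j)) "J" else "reward",
                        if (!is.null(best)) best$score else NA_real_,
                        i / max(proc.time()[["elapsed"]] - t0, 1e-9) * 60))
      }
    }
  })
  out <- do.call(rbind, rows[seq_len(n_done)])
  attr(out, "best") <- best
  attr(out, "root") <- root
  out
}
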