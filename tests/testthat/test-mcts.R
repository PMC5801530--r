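test_that("the UCB score follows the UCT form", {
  expect_identical(ucb_score(0, 0, 5), Inf)                 # forced exploration
  expect_identical(ucb_score(10, 9, 1000, c = 0), 0.9)      # pure exploitation
  expect_equal(ucb_score(1, 0.5, 2, c = 1), 0.5 + sqrt(2 * log(2)),
               tolerance = 1e-12)
  expect_error(ucb_score(-1, 0, 2), "visits")
  expect_error(ucb_score(1, 0, 0), "parent_visits")
})

test_that("selection walks the UCB-maximal path and stops at unexpanded or terminal nodes", {
  m <- uniform_model()
  root <- mcts_root(m)
  expect_identical(mcts_select(root, 1), list(root))  # fresh tree
  # hand-built tree: two visited children, exploitation picks the better mean
  cfg <- search_config(expansion_samples = 50L, budget_iterations = 1L)
  set.seed(1)
  kids <- mcts_expand(root, m, cfg)
  root$visits <- 20L
  kids[[1L]]$visits <- 10L; kids[[1L]]$total_reward <- 9
  kids[[2L]]$visits <- 10L; kids[[2L]]$total_reward <- 1
  for (k in kids[-(1:2)]) { k$visits <- 10L; k$total_reward <- 0 }
  path <- mcts_select(root, c = 0)
  expect_identical(path[[2L]], kids[[1L]])
  # exact ties resolve to the lowest vocabulary index, reproducibly
  kids[[2L]]$total_reward <- 9
  expect_identical(mcts_select(root, c = 0)[[2L]], kids[[1L]])
})

test_that("expansion deduplicates sampled symbols into at most expansion_samples children", {
  cfg <- search_config(expansion_samples = 30L, budget_iterations = 1L)
  # all probability mass on one symbol: exactly one child despite 30 draws
  m1 <- fixed_model(c(1, 0, 0), c("A", "B"))
  r1 <- mcts_root(m1)
  set.seed(2)
  expect_length(mcts_expand(r1, m1, cfg), 1L)
  expect_identical(r1$children[[1L]]$sym, "A")
  expect_error(mcts_expand(r1, m1, cfg), "already expanded")
  # children are distinct, in vocabulary order, within the model's support
  m2 <- uniform_model(c("A", "B", "C"))
  r2 <- mcts_root(m2)
  set.seed(3)
  kids <- mcts_expand(r2, m2, cfg)
  syms <- vapply(kids, function(k) k$sym, character(1))
  expect_false(anyDuplicated(syms) > 0)
  expect_true(all(syms %in% c("A", "B", "C", "$")))
  ids <- vapply(kids, function(k) k$sym_id, integer(1))
  expect_identical(ids, sort(ids))
  # terminal nodes are never expanded
  term <- kids[[which(syms == "$")]]
  expect_error(mcts_expand(term, m2, cfg), "terminal")
})

test_that("top-k expansion takes the most probable symbols", {
  m <- fixed_model(c(0.5, 0.3, 0.05, 0.15), c("A", "B", "C"))
  r <- mcts_root(m)
  cfg <- search_config(expansion_samples = 2L, expansion_mode = "topk",
                       budget_iterations = 1L)
  kids <- mcts_expand(r, m, cfg)
  expect_identical(vapply(kids, function(k) k$sym, character(1)),
                   c("A", "B"))
})

test_that("backpropagation credits exactly the nodes on the path", {
  m <- uniform_model()
  root <- mcts_root(m)
  cfg <- search_config(budget_iterations = 1L)
  set.seed(4)
  kids <- mcts_expand(root, m, cfg)
  child <- kids[[1L]]
  path <- list(root, child)
  mcts_backpropagate(path, 0.5)
  expect_identical(root$visits, 1L)
  expect_identical(child$visits, 1L)
  expect_identical(child$total_reward, 0.5)
  other <- kids[[2L]]
  expect_identical(other$visits, 0L)
  mcts_backpropagate(path, 0)  # zero reward still counts a visit
  expect_identical(root$visits, 2L)
  expect_identical(root$total_reward, 0.5)
  expect_error(mcts_backpropagate(list(), 1), "empty")
})

test_that("simulation scores terminal prefixes directly and truncations as invalid", {
  m <- uniform_model()
  cfg <- search_config(max_rollout_length = 4L, invalid_reward = -1,
                       budget_iterations = 1L)
  root <- mcts_root(m)
  set.seed(5)
  kids <- mcts_expand(root, m, cfg)
  syms <- vapply(kids, function(k) k$sym, character(1))
  term <- kids[[which(syms == "$")]]
  sim <- mcts_simulate(term, m, toy_reward_fn, cfg)
  expect_identical(sim$reward, toy_score(""))  # empty string before "$"
  # a never-terminating policy is truncated at the cap and scored invalid
  m2 <- fixed_model(c(1, 1, 0), c("A", "B"))
  r2 <- mcts_root(m2)
  set.seed(6)
  k2 <- mcts_expand(r2, m2, cfg)[[1L]]
  sim2 <- mcts_simulate(k2, m2, toy_reward_fn, cfg)
  expect_identical(sim2$reward, -1)
  expect_false(sim2$record$valid)
})

test_that("a one-iteration search expands the root and records one result", {
  m <- uniform_model()
  cfg <- search_config(budget_iterations = 1L, max_rollout_length = 4L,
                       seed = 1L)
  res <- mcts_search(m, toy_reward_fn, cfg)
  expect_identical(nrow(res), 1L)
  root <- attr(res, "root")
  expect_true(root$expanded)
  expect_identical(root$visits, 1L)
  expect_error(search_config(budget_iterations = 0L), "positive")
})

test_that("search satisfies visit conservation, bounded means and prior consistency", {
  m <- toy_model()
  cfg <- search_config(budget_iterations = 60L, max_rollout_length = 40L,
                       seed = 11L)
  res <- mcts_search(m, penalized_logp_reward(), cfg)
  root <- attr(res, "root")
  expect_identical(root$visits, nrow(res))
  walk <- function(node) {
    if (node$visits > 0L) {
      mean_r <- node$total_reward / node$visits
      expect_true(mean_r >= -1 && mean_r <= 1)
    }
    if (length(node$children)) {
      expect_gte(node$visits, sum(vapply(node$children, function(ch)
        ch$visits, integer(1))))
      for (ch in node$children) {
        # every tree edge was sampled from the model's support
        expect_gt(node$probs[[ch$sym_id]], 0)
        walk(ch)
      }
    }
  }
  walk(root)
})

test_that("search output is fully determined by seed, config and model", {
  m <- toy_model()
  cfg <- search_config(budget_iterations = 40L, max_rollout_length = 40L,
                       seed = 21L)
  r1 <- mcts_search(m, penalized_logp_reward(), cfg)
  r2 <- mcts_search(m, penalized_logp_reward(), cfg)
  expect_identical(r1$smiles, r2$smiles)
  expect_identical(r1$reward, r2$reward)
  # nested budgets: the longer run extends the shorter one
  cfg80 <- search_config(budget_iterations = 80L, max_rollout_length = 40L,
                         seed = 21L)
  r3 <- mcts_search(m, penalized_logp_reward(), cfg80)
  expect_identical(r3$smiles[seq_len(40L)], r1$smiles)
  # so the running best objective is non-decreasing in budget
  expect_true(max(r3$reward) >= max(r1$reward))
  expect_true(all(diff(cummax(r3$reward)) >= 0))
})

test_that("duplicate molecules are recorded but flagged", {
  m <- fixed_model(c(0.6, 0.4), c("A"))  # only "A" and "$": tiny space
  cfg <- search_config(budget_iterations = 25L, max_rollout_length = 4L,
                       seed = 2L)
  res <- mcts_search(m, toy_reward_fn, cfg)
  expect_identical(nrow(res), 25L)
  expect_true(any(res$is_duplicate))
  expect_false(res$is_duplicate[1L])
  first_seen <- !duplicated(res$smiles)
  expect_identical(res$is_duplicate, !first_seen)
})

test_that("a short search on a tiny space already finds the enumerated optimum", {
  oracle <- brute_force_best(c("A", "B", "C"), 3L, toy_score)
  expect_identical(sum(oracle$scores == oracle$score), 1L)  # unique argmax
  m <- uniform_model()
  cfg <- search_config(budget_iterations = 400L, max_rollout_length = 4L,
                       seed = 31L)
  res <- mcts_search(m, toy_reward_fn, cfg)
  expect_identical(attr(res, "best")$smiles, oracle$best)
  expect_equal(attr(res, "best")$reward, oracle$score, tolerance = 1e-12)
})
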