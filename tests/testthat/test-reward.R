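# Descriptor values asserted below were frozen from the reference RDKit
# implementations (Crippen logP, Ertl-Schuffenhauer SA) run on the same
# structures.

test_that("validity is parse-and-sanitize, with failure as FALSE not an error", {
  expect_identical(check_validity(c("c1ccccc1", "C(", "")),
                   c(TRUE, FALSE, FALSE))
  expect_false(check_validity("CX"))          # no such element symbol
  expect_false(check_validity("c1ccccc2"))    # unclosed ring
  expect_false(check_validity("C)("))
})

test_that("Crippen logP matches the reference and depends only on the graph", {
  expect_equal(compute_logp("C"), 0.6361, tolerance = 1e-4)
  expect_equal(compute_logp("OCC"), compute_logp("CCO"), tolerance = 1e-10)
  expect_gt(compute_logp("CCCCCC"), compute_logp("C"))
  expect_error(compute_logp("C("), "invalid")
})

test_that("SA score behaves like a synthesis-difficulty estimate", {
  sa_ethanol <- compute_sa("CCO")
  sa_bridged <- compute_sa("C1CC2CCC1C2")  # bicyclic, harder to make
  expect_lt(sa_ethanol, sa_bridged)
  expect_equal(compute_sa("OCC"), compute_sa("CCO"), tolerance = 1e-10)
  batch <- compute_sa(generate_toy_corpus(20, seed = 3))
  expect_true(all(is.finite(batch)))
  expect_true(all(batch >= 1 & batch <= 10))
})

test_that("the ring penalty counts atoms beyond the threshold in the largest ring", {
  expect_identical(ring_penalty("c1ccccc1"), 0)   # six-ring: no penalty
  expect_identical(ring_penalty("CCO"), 0)        # acyclic
  expect_identical(ring_penalty("C1CCCCCCC1"), 2) # cyclooctane: 8 - 6
  expect_identical(ring_penalty("C1CCCCCCC1", threshold = 8L), 0)
  expect_identical(ring_penalty("C1CCCCCCC1", slope = 2), 4)
})

test_that("J is exactly the sum of its parts, computed on one molecule", {
  for (s in c("CCO", "c1ccccc1", "C1CCCCCCC1", "CC(C)Cc1ccccc1")) {
    sj <- score_j(s)
    expect_identical(sj$j, sj$logp - sj$sa - sj$ring_penalty)
    expect_true(all(is.finite(c(sj$logp, sj$sa, sj$ring_penalty, sj$j))))
  }
  # composition agrees with independently chained component calls
  sj <- score_j("CCO")
  expect_identical(sj$j,
                   compute_logp("CCO") - compute_sa("CCO") - ring_penalty("CCO"))
  expect_error(score_j("C("), "invalid")
})

test_that("the bounded reward map is odd, monotone and confined to (-1, 1)", {
  expect_identical(reward_from_j(0), 0)
  expect_identical(reward_from_j(3), 0.75)
  expect_identical(reward_from_j(-3), -0.75)
  grid <- seq(-50, 50, by = 0.25)
  r <- reward_from_j(grid)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > -1 & r < 1))
})

test_that("smiles_reward scores invalid strings at exactly -1 and is idempotent", {
  r <- smiles_reward(c("CCO", "C(", "c1ccccc1"))
  expect_identical(r$reward[2L], -1.0)
  expect_false(r$valid[2L])
  expect_true(all(is.na(r$logp[2L])))
  expect_identical(r$reward[1L], reward_from_j(r$j[1L]))
  expect_identical(smiles_reward("c1ccccc1"), smiles_reward("c1ccccc1"))
  # spelling invariance of the full score (descriptor sums can differ in
  # the last bits across atom orderings)
  expect_equal(smiles_reward("OCC")[-1L], smiles_reward("CCO")[-1L],
               tolerance = 1e-10)
})

test_that("optional component standardization shifts J as documented", {
  std <- list(logp_mean = 0, logp_sd = 2, sa_mean = 3, sa_sd = 1,
              ring_mean = 0, ring_sd = 1)
  raw <- score_j("CCO")
  z <- score_j("CCO", standardize = std)
  expect_equal(z$logp, raw$logp / 2, tolerance = 1e-12)
  expect_equal(z$sa, raw$sa - 3, tolerance = 1e-12)
  expect_identical(z$j, z$logp - z$sa - z$ring_penalty)
})
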