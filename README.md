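# mctsmol

De novo molecular generation in R: Monte Carlo tree search (UCT) over the
space of SMILES strings, guided by a character-level recurrent language
model.

## The problem and the approach

Designing organic molecules computationally is a combinatorial search over
a vast chemical space. `mctsmol` explores that space string by string: a
molecule is a SMILES string `S = s1 ... sT` over a closed 64-symbol
alphabet (atoms, bracket atoms such as `[C@@H]`, bonds, ring-closure
digits, branches, and a terminal marker `$`), and the search tree assigns
one symbol per level, so a root-to-terminal path spells a complete
molecule.

Three components cooperate:

- **Language model.** A two-layer stacked GRU (256 hidden units per layer,
  so a 512-dimensional stacked state) reads one-hot encoded symbols
  (`x_t ∈ R^64`) and emits `P(y_t = j) = g_j(h_t)` through a softmax over
  the 64 symbols. It is trained with Adam (batch size 256) to predict the
  right-shifted input, i.e. to minimise the relative entropy between the
  one-hot next symbol and the predicted distribution — categorical
  cross-entropy, since the targets are one-hot. The GRU, backpropagation
  through time and Adam are implemented in plain R matrix algebra and are
  verified against finite-difference gradients in the test suite.
- **Reward.** The benchmark objective is penalized logP,
  `J(S) = logP(S) − SA(S) − RingPenalty(S)`: Crippen logP minus the
  Ertl–Schuffenhauer synthetic-accessibility score minus
  `max(0, largest ring − 6)`. The search reward is bounded:
  `r(S) = J/(1+|J|)` for chemically valid strings and exactly `−1.0`
  otherwise (validity = RDKit parse + sanitize, via a bundled Python
  worker).
- **Search.** UCT: selection by the upper confidence bound
  `W/n + c·sqrt(2·ln N / n)` (unvisited nodes score `+Inf`), expansion by
  drawing 30 next symbols from the model (distinct draws become children),
  simulation by rollout — ancestral sampling from the model until `$` —
  and backpropagation of the reward along the path.

## Worked example

Train on the built-in synthetic toy corpus (200 small alkanes, alcohols,
ethers and benzene derivatives) and search for 300 iterations:

```r
library(mctsmol)
corpus <- generate_toy_corpus(200, seed = 17)
cfg <- model_config(hidden_per_layer = 48, epochs = 10, batch_size = 32,
                    seed = 17)
fit <- train_lm(corpus, cfg)
fit$report$epoch_loss
#>  [1] 4.104 3.947 3.699 3.266 2.742 2.396 2.131 1.973 1.842 1.724

res <- mcts_search(fit, penalized_logp_reward(),
                   search_config(budget_iterations = 300,
                                 max_rollout_length = 40, seed = 1))
best <- attr(res, "best")
sprintf("best J = %.4f (reward %.4f) %s at iteration %d",
        best$j, best$reward, best$smiles, best$iteration)
#> [1] "best J = 0.2007 (reward 0.1671) CCCC at iteration 27"
```

The per-epoch loss is the mean cross-entropy per symbol; it falls from
4.10 (near `ln 64`, the uniform baseline) to 1.72 in ten epochs on this
tiny corpus. Every simulated string is recorded with its property scores:

```r
smiles_reward(c("CCO", "c1ccccc1", "C1CCCCCCC1", "C("))
#>       smiles valid    logp   sa ring_penalty       j  reward
#> 1        CCO  TRUE -0.0014 1.98            0 -1.9817 -0.6646
#> 2   c1ccccc1  TRUE  1.6866 1.00            0  0.6866  0.4071
#> 3 C1CCCCCCC1  TRUE  3.1208 1.00            2  0.1208  0.1078
#> 4         C( FALSE      NA   NA           NA      NA -1.0000
```

Ethanol is easy to make (SA 1.98) but hydrophilic, so its J is negative;
benzene scores positive; cyclooctane pays a ring penalty of 2 (8-ring);
the unbalanced `C(` is invalid and earns exactly −1.

A command-line front end is installed as `exec/mctsmol` with subcommands
`train`, `sample`, `score`, `search` and `make-fixtures`.

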