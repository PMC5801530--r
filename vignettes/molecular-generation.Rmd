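---
title: "Generating molecules by tree search over SMILES strings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating molecules by tree search over SMILES strings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mctsmol` generates candidate molecules by best-first search over SMILES
strings. This vignette explains the model and the procedure, the
parameters that matter, what the synthetic data emulate, and the
numerical and design choices behind the implementation.

## The generation model

A molecule is written as a SMILES string over a closed vocabulary of 64
symbols: 63 SMILES tokens — aliphatic and aromatic atoms, bracket atoms
with charge/chirality/hydrogen annotations (each bracket expression is a
single symbol, e.g. `[NH3+]`), the two-letter halogens `Cl` and `Br`,
bond symbols including the stereo pair `/` and `\`, ring-closure digits
`1`–`9`, and parentheses — plus the terminal marker `$` that ends every
complete string. Generation is sequential: given a prefix
`s1 ... s(t-1)`, a language model supplies the distribution of the next
symbol, and a string is complete when `$` is emitted.

The language model is a two-layer stack of gated recurrent units, 256
hidden units per layer by default (a 512-dimensional stacked state),
reading one-hot vectors in `R^64` and producing a softmax over all 64
symbols. Training minimises the relative entropy between the one-hot
next symbol and the predicted distribution — for one-hot targets this is
exactly categorical cross-entropy, and the implementation computes it as
such. Optimisation is Adam (default step size `1e-3`, batch size 256)
with global-norm gradient clipping at 5; the step size and clip are
conventional defaults, as the sequence-model literature rarely reports
sensitivity to them at this scale, and both are configurable.

Two representation choices deserve note:

- **Begin-of-sequence.** The first symbol's distribution must condition
  on *something*. We use an internal start marker that is encoded as the
  all-zero input vector: this keeps the input dimension exactly equal to
  the vocabulary size (64), keeps the start marker out of the output
  softmax (it can never be emitted), and makes `P(s1)` well defined. The
  alternative — a 65th one-hot index — would change the stated input
  dimension for no behavioural gain.
- **Padding and masking.** Variable-length sequences in a minibatch are
  padded; padded positions contribute zero loss, so the model is not
  biased toward any pad symbol.

## The reward

The benchmark objective is penalized logP,

```
J(S) = logP(S) − SA(S) − RingPenalty(S)
```

with Crippen logP, the Ertl–Schuffenhauer synthetic-accessibility score
(fragment contributions plus complexity terms, typically in [1, 10],
higher = harder), and a large-ring penalty. The search itself optimises
the bounded reward

```
r(S) = J(S) / (1 + |J(S)|)   if S is a valid molecule
r(S) = −1.0                  otherwise
```

which is strictly increasing in J and confined to (−1, 1), so one
freak molecule cannot dominate the tree statistics; invalid strings are
pushed to the boundary.

Choices within the reward:

- **Ring penalty formula.** We use `max(0, largest ring − 6)` over the
  smallest-set-of-smallest-rings perception, the convention of the
  penalized-logP benchmark lineage; both the threshold (6) and the slope
  (1) are arguments. Macrocycle perception varies between toolkits, so
  the perception set used (SSSR) is part of the contract.
- **Validity.** A string counts as valid only if it parses *and*
  sanitizes (realistic valences etc.); grammatical SMILES describing an
  impossible molecule scores −1. Parse failure is an ordinary `FALSE`,
  never an exception, so the search can score anything a rollout emits.
- **No component standardization by default.** J combines raw
  components, following the formula as written. An optional
  standardization mode (user-supplied means/sds) exists because parts of
  the comparison literature z-score components over the training corpus.
- **Toolkit delegation.** Validity and all three descriptors come from
  RDKit behind a narrow interface (a persistent Python worker spoken to
  over a localhost socket, one process per session, results cached per
  SMILES). Nothing else in the package touches the toolkit, so the
  scoring backend is swappable.

## The search

Standard UCT, specialised to strings. Each node holds one symbol; the
path from the root spells a prefix. One iteration is:

1. **Selection.** From the root, repeatedly descend to the child with
   the largest upper confidence bound `W/n + c·sqrt(2·ln N / n)` (`W` =
   cumulative reward, `n` = child visits, `N` = parent visits), stopping
   at the first unexpanded or terminal node. Unvisited children score
   `+Inf`, so every child is tried once; exact ties break to the lowest
   vocabulary index for bit-reproducibility.
2. **Expansion.** Draw 30 symbols (configurable) from the model's
   next-symbol distribution at the node; the *distinct* draws become
   children, so high-probability symbols are almost always present and
   the branching factor adapts to the entropy of the distribution. A
   `topk` mode is available as an alternative.
3. **Simulation.** From the newly chosen child (picked among the fresh
   children by the same UCB rule, which for all-unvisited children is
   the tie-break order), complete the prefix by ancestral sampling from
   the model until `$` or the rollout length cap; score the completed
   string with the reward.
4. **Backpropagation.** Add the reward and one visit to every node on
   the path.

The paper-trail decisions here, each made where the method description
is silent: the UCB constant defaults to `c = 1.0` (the standard UCT
form with the `sqrt(2 ln N / n)` bonus); one rollout is run per
iteration; terminal nodes are never expanded — selecting one re-scores
its (cached) complete string and backpropagates, which keeps visit
accounting uniform; truncated rollouts (no `$` within the cap) and
invalid strings score −1.0 rather than pruning the subtree, so the tree
statistics themselves learn to avoid bad regions; duplicates are
recorded every time they are generated (generation-rate accounting) but
flagged via canonical SMILES so reporting can deduplicate.

Every simulated string becomes one record — SMILES, validity, the three
property scores and J, the reward, the iteration, elapsed time, and how
many tokens came from the tree rather than the rollout — and the search
returns them all in discovery order.

## The synthetic corpus, and what the tests do and do not show

`generate_toy_corpus()` draws from four constructive template families —
linear and branched alkanes, primary alcohols, dialkyl ethers, and
mono-substituted benzenes — each valid by construction and within the
vocabulary. The defaults (200 molecules, at most 9 heavy atoms in a
chain) are sized so that a 10-epoch training run takes seconds on one
CPU while still exposing the model to chains, branches and aromatic
rings. The test suite trains on this corpus with a 48-unit hidden layer,
a deliberate scale-down of the default 256 that leaves every structural
property (normalisation, losslessness, determinism, loss descent)
intact.

What the toy corpus does *not* emulate: the size (hundreds of thousands
of drug-like molecules), chemical diversity, stereochemistry and charge
annotations of a real training set. Consequently a toy-trained model has
a modest valid-SMILES rate and proposes only small molecules; tests
passing on it demonstrate the correctness of the machinery — tokenizer,
model, reward plumbing, search bookkeeping, seed determinism — not the
chemical quality of generations. Reproducing published-scale results
requires training on a large public corpus (e.g. a ZINC extract) for on
the order of 100 epochs and searching for hours; the pipeline supports
this (the CLI accepts any SMILES file and a wall-clock budget) but it is
a manual exercise outside the test suite.

For the same reason the search-correctness guarantee is established on
an enumerable space instead: a uniform three-symbol policy with rollout
cap 4 spans 39 complete strings, a deterministic objective scores them,
and the search must return the same optimum as brute-force enumeration
across seeds (budget 2000). That is the strongest statement one can test
exactly, and it exercises the full select/expand/simulate/backpropagate
loop.

## Numerical choices and degenerate inputs

- Softmax is computed with max-subtraction; log-probabilities are
  clamped at `1e-12` before `log` so a collapsed distribution cannot
  produce `-Inf` loss.
- Checkpoints are plain-text JSON with weights written at 17 significant
  digits, which round-trips IEEE doubles exactly; a checkpoint records
  the MD5 of its vocabulary sidecar and refuses to load against a
  modified one.
- All stochastic operations (initialisation, shuffling, sampling,
  expansion, rollouts) run under locally scoped seeds, so identical
  `(seed, config, corpus)` give bit-identical results and nested budgets
  extend each other's record streams.
- Degenerate inputs: an empty corpus errors; over-long training
  sequences are truncated with a warning; a prefix already ending in
  `$` rolls out to itself; an expansion of a terminal node errors; an
  empty rollout product (immediate `$`) is the empty string, which the
  validity checker rejects and the reward prices at −1.
- The descriptor layer returns identical values for identical strings
  (cached); different SMILES spellings of the same molecule agree to
  descriptor-sum rounding (last-bit differences from atom ordering),
  which is why spelling invariance is asserted to `1e-10` rather than
  bitwise.

## Known limitations

- The vocabulary is closed: corpora containing symbols outside the
  64-symbol set (e.g. `[Si]`, `%10` ring closures, isotopes) have those
  lines skipped at read time with a count.
- The GRU runs on CPU in R; it is fast at the package's scale (seconds
  per toy epoch, hundreds of search iterations per second) but not
  intended for corpus-scale training runs, which remain a batch job.
- One rollout per iteration and no tree parallelism; no progressive
  widening or RAVE.
- The reward is single-objective; multi-objective search is out of
  scope.
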