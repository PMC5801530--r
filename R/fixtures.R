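# Synthetic toy corpus and plain-text I/O. The toy corpus stands in for a
# large public SMILES training set: a few hundred small, unquestionably
# valid molecules (alkanes, alcohols, ethers, benzene derivatives) built
# from parametric templates, enough for the language model to learn the
# local grammar of chains, branches and aromatic rings in seconds.

#' Generate a synthetic toy SMILES corpus
#'
#' Draws molecules from four constructive template families -- linear and
#' branched alkanes, primary alcohols, dialkyl ethers and mono-substituted
#' benzenes -- so every emitted string is valid by construction, tokenizes
#' under the 64-symbol vocabulary, and stays small (default at most 9 heavy
#' atoms in a chain). Duplicates are allowed, mimicking the redundancy of
#' real corpora. Deterministic for a given seed.
#'
#' @param n_molecules Number of strings to emit.
#' @param max_heavy_atoms Cap on chain length used by the templates.
#' @param families Character vector choosing template families, a subset of
#'   `c("alkane", "alcohol", "ether", "aromatic")`.
#' @param seed Integer seed.
#' @return Character vector of `n_molecules` SMILES strings.
#' @export
#' @examples
#' corpus <- generate_toy_corpus(10, seed = 7)
#' all(nchar(corpus) > 0)
generate_toy_corpus <- function(n_molecules, max_heavy_atoms = 9L,
                                families = c("alkane", "alcohol", "ether",
                                             "aromatic"),
                                seed = 0L) {
  stopifnot(n_molecules >= 1L, max_heavy_atoms >= 3L)
  families <- match.arg(families, several.ok = TRUE)
  chain <- function(k) strrep("C", k)
  gen_one <- function(fam) {
    switch(fam,
      alkane = {
        k <- sample(1:max_heavy_atoms, 1L)
        if (k >= 4L && stats::runif(1) < 0.4) {
          # branched: insert a methyl after an interior carbon
          pos <- sample(2:(k - 2L), 1L)
          paste0(chain(pos), "(C)", chain(k - pos - 1L))
        } else {
          chain(k)
        }
      },
      alcohol = paste0(chain(sample(1:(max_heavy_atoms - 1L), 1L)), "O"),
      ether = paste0(chain(sample(1:4, 1L)), "O",
                     chain(sample(1:4, 1L))),
      aromatic = {
        sub <- sample(c("", "C", "CC", "O", "OC", "N", "F", "Cl", "Br"), 1L)
        paste0(sub, "c1ccccc1")
      }
    )
  }
  with_seed(seed, {
    fams <- sample(families, n_molecules, replace = TRUE)
    vapply(fams, gen_one, character(1), USE.NAMES = FALSE)
  })
}

#' Read a SMILES corpus file
#'
#' Plain UTF-8 text, one SMILES per line, no header. Blank lines are
#' skipped silently; lines that fail tokenization are skipped with a
#' message reporting how many were dropped.
#'
#' @param path Path to the file.
#' @param vocab Vocabulary used to screen lines.
#' @return Character vector of tokenizable SMILES strings (possibly empty,
#'   with a warning, for an empty file).
#' @export
read_smiles_file <- function(path, vocab = smiles_vocabulary()) {
  if (!file.exists(path)) {
    stop(sprintf("SMILES file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning(sprintf("no SMILES found in %s", path), call. = FALSE)
    return(character(0))
  }
  ok <- vapply(lines, function(x)
    !inherits(tryCatch(tokenize(x, vocab), error = identity), "error"),
    logical(1), USE.NAMES = FALSE)
  if (any(!ok)) {
    message(sprintf("skipped %d line(s) that failed tokenization", sum(!ok)))
  }
  lines[ok]
}

#' Write / read search results as CSV
#'
#' The schema matches [mcts_search()] output: `iteration`, `elapsed_s`,
#' `smiles`, `valid`, `logp`, `sa`, `ring_penalty`, `j`, `reward`,
#' `tree_prefix_len`, `is_duplicate`.
#'
#' @param records A data.frame of generated records.
#' @param path Output CSV path.
#' @return `write_results_csv` returns `path` invisibly;
#'   `read_results_csv` the data.frame.
#' @export
write_results_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("results file not found: %s", path), call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}
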