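#' SMILES symbol vocabularies
#'
#' A vocabulary is a closed, ordered set of SMILES symbols. Multi-character
#' tokens (bracket atoms such as `"[C@@H]"`, the two-letter halogens `"Cl"`
#' and `"Br"`) count as single symbols. Every vocabulary contains the
#' terminal symbol `"$"` that marks the end of a complete string, and an
#' internal begin-of-sequence marker (see [START_TOKEN]) used only on the
#' input side of the language model -- it is never emitted and does not
#' occupy an index.
#'
#' @param symbols Character vector of unique tokens. The terminal `"$"` is
#'   appended automatically if absent.
#' @return An object of class `"smiles_vocab"`: a character vector of
#'   symbols with an `index` lookup environment attached.
#' @seealso [smiles_vocabulary()] for the canonical 64-symbol set.
#' @export
#' @examples
#' v <- vocabulary(c("A", "B", "C"))
#' length(v)  # 4: three symbols plus the terminal "$"
vocabulary <- function(symbols) {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) {
    stop("vocabulary symbols must be unique", call. = FALSE)
  }
  if (!TERMINAL_TOKEN %in% symbols) symbols <- c(symbols, TERMINAL_TOKEN)
  idx <- new.env(parent = emptyenv(), size = length(symbols))
  for (i in seq_along(symbols)) assign(symbols[i], i, envir = idx)
  structure(symbols, index = idx, class = "smiles_vocab")
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat(sprintf("<smiles_vocab: %d symbols, terminal \"%s\">\n",
              length(x), TERMINAL_TOKEN))
  print(unclass(x)[seq_along(x)])
  invisible(x)
}

#' Terminal and start markers
#'
#' `TERMINAL_TOKEN` (`"$"`) ends every complete sequence and is a first-class
#' vocabulary symbol with its own index in the output softmax.
#' `START_TOKEN` is the internal begin-of-sequence marker: it conditions the
#' distribution of the first symbol but is never emitted, has no vocabulary
#' index, and is encoded as the all-zero input vector so the model input
#' dimension equals the vocabulary size exactly.
#'
#' @format Length-one character strings.
#' @export
TERMINAL_TOKEN <- "$"

#' @rdname TERMINAL_TOKEN
#' @export
START_TOKEN <- "^"

# The SMILES symbol set used for molecular generation: atoms (aromatic and
# aliphatic), bracket atoms with charge/chirality/hydrogen counts, bonds,
# ring-closure digits, branch parentheses and the stereo-bond pair "/", "\".
# 63 symbols; with the terminal "$" the encoding dimension is 64.
.SMILES_SYMBOLS <- c(
  "C", "c", "o", "O", "N", "F", "[C@@H]", "n", "-", "S", "Cl", "[O-]",
  "[C@H]", "[NH+]", "[C@]", "s", "Br", "[nH]", "[NH3+]", "[NH2+]", "[C@@]",
  "[N+]", "[nH+]", "[S@]", "[N-]", "[n+]", "[S@@]", "[S-]", "I", "[n-]",
  "P", "[OH+]", "[NH-]", "[P@@H]", "[P@@]", "[PH2]", "[P@]", "[P+]",
  "[S+]", "[o+]", "[CH2-]", "[CH-]", "[SH+]", "[O+]", "[s+]", "[PH+]",
  "[PH]", "[S@@+]", "/", "=", "#",
  "1", "2", "3", "4", "5", "6", "7", "8", "9",
  "(", ")", "\\"
)

#' The canonical 64-symbol SMILES vocabulary
#'
#' The closed symbol set the generator is defined over: 63 SMILES symbols
#' (atoms, bracket atoms, bonds, ring-closure digits, branches, stereo-bond
#' markers) plus the terminal `"$"`, for an encoding dimension of 64.
#'
#' @return A [vocabulary()] of 64 symbols.
#' @export
#' @examples
#' v <- smiles_vocabulary()
#' stopifnot(length(v) == 64, "[C@@H]" %in% v, "Cl" %in% v)
smiles_vocabulary <- function() {
  vocabulary(.SMILES_SYMBOLS)
}

#' Look up vocabulary indices
#'
#' @param vocab A [vocabulary()].
#' @param tokens Character vector of symbols.
#' @return Integer indices into the vocabulary.
#' @export
vocab_index <- function(vocab, tokens) {
  idx <- attr(vocab, "index")
  out <- integer(length(tokens))
  for (i in seq_along(tokens)) {
    v <- get0(tokens[i], envir = idx, inherits = FALSE)
    if (is.null(v)) {
      stop(sprintf("token \"%s\" is not in the vocabulary", tokens[i]),
           call. = FALSE)
    }
    out[i] <- v
  }
  out
}

#' Tokenize a SMILES string
#'
#' Greedy longest-match tokenization against a closed vocabulary. Bracket
#' atoms are treated atomically: a `"["` consumes through its matching
#' `"]"` and the whole bracket expression must be a vocabulary symbol.
#' Two-character bare atoms (`"Cl"`, `"Br"`) take precedence over their
#' one-character prefixes. Tokenization is lossless:
#' `detokenize(tokenize(x)) == x` for every tokenizable `x`.
#'
#' @param text A single non-empty SMILES string (without the terminal
#'   marker; a trailing `"$"` is accepted and kept as the terminal token).
#' @param vocab A [vocabulary()]; defaults to [smiles_vocabulary()].
#' @return Character vector of tokens.
#' @export
#' @examples
#' tokenize("C[C@@H]Cl")  # "C" "[C@@H]" "Cl"
tokenize <- function(text, vocab = smiles_vocabulary()) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("'text' must be a single string", call. = FALSE)
  }
  if (!nzchar(text)) stop("'text' must be non-empty", call. = FALSE)
  idx <- attr(vocab, "index")
  max_len <- max(nchar(vocab))
  n <- nchar(text)
  tokens <- character(0)
  pos <- 1L
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    tok <- NULL
    if (ch == "[") {
      close <- regexpr("]", substr(text, pos, n), fixed = TRUE)
      if (close == -1L) {
        stop(sprintf("tokenization error at position %d: unclosed bracket atom in \"%s\"",
                     pos, text), call. = FALSE)
      }
      cand <- substr(text, pos, pos + close - 1L)
      if (!is.null(get0(cand, envir = idx, inherits = FALSE))) tok <- cand
    } else {
      # greedy longest match among non-bracket symbols
      for (l in seq(min(max_len, n - pos + 1L), 1L)) {
        cand <- substr(text, pos, pos + l - 1L)
        if (substr(cand, 1, 1) != "[" &&
            !is.null(get0(cand, envir = idx, inherits = FALSE))) {
          tok <- cand
          break
        }
      }
    }
    if (is.null(tok)) {
      stop(sprintf("tokenization error at position %d: no vocabulary symbol matches \"%s\"",
                   pos, substr(text, pos, min(n, pos + 5L))), call. = FALSE)
    }
    tokens <- c(tokens, tok)
    pos <- pos + nchar(tok)
  }
  tokens
}

#' Reassemble a SMILES string from tokens
#'
#' Concatenates tokens, stripping the internal start marker and the terminal
#' `"$"`. Inverse of [tokenize()] on its image.
#'
#' @param tokens Character vector of tokens.
#' @return A single SMILES string (possibly `""` for an empty sequence).
#' @export
detokenize <- function(tokens) {
  tokens <- tokens[tokens != START_TOKEN & tokens != TERMINAL_TOKEN]
  paste(tokens, collapse = "")
}

#' Is a token sequence complete?
#'
#' A sequence is complete iff its last token is the terminal symbol.
#'
#' @param tokens Character vector of tokens.
#' @return Logical scalar.
#' @export
is_complete <- function(tokens) {
  length(tokens) > 0L && tokens[length(tokens)] == TERMINAL_TOKEN
}

#' One-hot encode a token sequence
#'
#' @param tokens Character vector of vocabulary symbols.
#' @param vocab A [vocabulary()].
#' @return A `length(tokens)` x `length(vocab)` matrix; each row has a
#'   single 1 at the token's vocabulary index.
#' @export
encode_onehot <- function(tokens, vocab = smiles_vocabulary()) {
  ids <- vocab_index(vocab, tokens)
  m <- matrix(0, nrow = length(tokens), ncol = length(vocab),
              dimnames = list(NULL, as.character(unclass(vocab))))
  if (length(ids)) m[cbind(seq_along(ids), ids)] <- 1
  m
}

#' Save / load a vocabulary sidecar
#'
#' The ordered symbol list is stored as a small JSON file so that model
#' checkpoints can pin their symbol indexing.
#'
#' @param vocab A [vocabulary()].
#' @param path File path for the JSON sidecar.
#' @return `write_vocabulary` returns `path` invisibly; `read_vocabulary`
#'   returns the vocabulary.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(as.character(unclass(vocab)), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  vocabulary(jsonlite::read_json(path, simplifyVector = TRUE))
}
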