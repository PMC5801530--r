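# Chemical scoring: validity, Crippen logP, synthetic accessibility, ring
# penalty, the combined objective J and the bounded search reward. All
# descriptor work is delegated to RDKit behind this interface, via a
# persistent Python worker (inst/python/mol_scorer.py) spoken to over a
# localhost socket; results are cached per SMILES string within the session.

.scorer <- new.env(parent = emptyenv())

scorer_running <- function() {
  !is.null(.scorer$con) && isOpen(.scorer$con)
}

#' Start / stop the molecular property worker
#'
#' The worker is a Python process hosting RDKit; it is started lazily by the
#' first scoring call, so calling `scorer_start()` yourself is only useful
#' to front-load the startup cost or to point at a non-default Python. The
#' worker is shut down when the package unloads or on `scorer_stop()`.
#'
#' @param python Python executable with RDKit available; defaults to
#'   `getOption("mctsmol.python", "python")`.
#' @return Invisibly `TRUE`.
#' @export
scorer_start <- function(python = getOption("mctsmol.python", "python")) {
  if (scorer_running()) return(invisible(TRUE))
  script <- system.file("python", "mol_scorer.py", package = "mctsmol")
  if (!nzchar(script)) {
    # during development (pkgload), fall back to the source tree
    script <- file.path("inst", "python", "mol_scorer.py")
  }
  port_file <- tempfile("mol_scorer_port_")
  log_file <- tempfile("mol_scorer_log_")
  system2(python, c(shQuote(script), shQuote(port_file)),
          wait = FALSE, stdout = log_file, stderr = log_file)
  port <- NA_integer_
  for (i in seq_len(600L)) {  # rdkit import can take a few seconds
    if (file.exists(port_file)) {
      txt <- tryCatch(readLines(port_file, warn = FALSE), error = function(e) character(0))
      if (length(txt) && nzchar(txt[1L])) { port <- as.integer(txt[1L]); break }
    }
    Sys.sleep(0.05)
  }
  if (is.na(port)) {
    stop("molecular property worker failed to start; log:\n",
         paste(readLines(log_file, warn = FALSE), collapse = "\n"),
         call. = FALSE)
  }
  .scorer$con <- socketConnection("127.0.0.1", port, blocking = TRUE,
                                  open = "r+", timeout = 600)
  .scorer$cache <- new.env(parent = emptyenv())
  invisible(TRUE)
}

#' @rdname scorer_start
#' @export
scorer_stop <- function() {
  if (!is.null(.scorer$con)) {
    try(close(.scorer$con), silent = TRUE)
    .scorer$con <- NULL
    .scorer$cache <- NULL
  }
  invisible(TRUE)
}

scorer_query <- function(smiles) {
  scorer_start()
  req <- jsonlite::toJSON(list(smiles = smiles), auto_unbox = FALSE)
  writeLines(req, .scorer$con)
  resp <- readLines(.scorer$con, n = 1L)
  if (length(resp) == 0L) {
    scorer_stop()
    stop("molecular property worker closed the connection unexpectedly",
         call. = FALSE)
  }
  jsonlite::fromJSON(resp, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

# Batched, cached lookup of raw properties for a character vector of SMILES.
# Returns a data.frame: smiles, valid, logp, sa, largest_ring, canonical.
mol_properties <- function(smiles) {
  smiles <- as.character(smiles)
  scorer_start()
  cache <- .scorer$cache
  key <- function(s) paste0("s:", s)  # avoid "" as an env name
  todo <- unique(smiles[!vapply(smiles, function(s)
    !is.null(get0(key(s), envir = cache, inherits = FALSE)), logical(1))])
  if (length(todo)) {
    res <- scorer_query(todo)
    for (i in seq_along(todo)) {
      assign(key(todo[i]), list(
        valid = isTRUE(res$valid[i]),
        logp = if (isTRUE(res$valid[i])) res$logp[i] else NA_real_,
        sa = if (isTRUE(res$valid[i])) res$sa[i] else NA_real_,
        largest_ring = if (isTRUE(res$valid[i])) as.integer(res$largest_ring[i]) else NA_integer_,
        canonical = if (isTRUE(res$valid[i])) res$canonical[i] else NA_character_
      ), envir = cache)
    }
  }
  rows <- lapply(smiles, function(s) get(key(s), envir = cache))
  data.frame(
    smiles = smiles,
    valid = vapply(rows, `[[`, logical(1), "valid"),
    logp = vapply(rows, `[[`, numeric(1), "logp"),
    sa = vapply(rows, `[[`, numeric(1), "sa"),
    largest_ring = vapply(rows, `[[`, integer(1), "largest_ring"),
    canonical = vapply(rows, `[[`, character(1), "canonical"),
    stringsAsFactors = FALSE
  )
}

#' Chemical validity of SMILES strings
#'
#' A string is valid iff RDKit parses *and* sanitizes it into a molecule;
#' grammatical SMILES that fail sanitization (impossible valences etc.)
#' count as invalid. Parse failure is the `FALSE` branch, never an error.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector.
#' @export
#' @examples
#' \donttest{
#' check_validity(c("c1ccccc1", "C(", ""))  # TRUE FALSE FALSE
#' }
check_validity <- function(smiles) {
  mol_properties(smiles)$valid
}

stop_if_invalid <- function(props, what) {
  bad <- props$smiles[!props$valid]
  if (length(bad)) {
    stop(sprintf("%s requires valid molecules; invalid SMILES: %s",
                 what, paste(sprintf('"%s"', bad), collapse = ", ")),
         call. = FALSE)
  }
}

#' Crippen octanol-water partition coefficient
#'
#' The atomic-contribution (Crippen) logP estimate; a descriptor of the
#' molecular graph, so any SMILES spelling of the same molecule scores
#' identically.
#'
#' @inheritParams check_validity
#' @return Numeric vector. Errors on invalid SMILES; gate with
#'   [check_validity()].
#' @export
compute_logp <- function(smiles) {
  props <- mol_properties(smiles)
  stop_if_invalid(props, "compute_logp")
  props$logp
}

#' Synthetic accessibility score
#'
#' The Ertl-Schuffenhauer fragment-contribution + complexity score,
#' typically in \[1, 10\]; higher means harder to synthesise.
#'
#' @inheritParams check_validity
#' @return Numeric vector. Errors on invalid SMILES.
#' @export
compute_sa <- function(smiles) {
  props <- mol_properties(smiles)
  stop_if_invalid(props, "compute_sa")
  props$sa
}

#' Large-ring penalty
#'
#' Penalises unrealistically large rings:
#' `slope * max(0, largest_ring - threshold)`, where `largest_ring` is the
#' largest ring in RDKit's smallest-set-of-smallest-rings perception.
#' Acyclic molecules score 0. The defaults (threshold 6, slope 1) follow
#' the penalized-logP benchmark convention.
#'
#' @inheritParams check_validity
#' @param threshold Ring size above which the penalty starts.
#' @param slope Penalty per atom beyond the threshold.
#' @return Non-negative numeric vector. Errors on invalid SMILES.
#' @export
ring_penalty <- function(smiles, threshold = 6L, slope = 1) {
  props <- mol_properties(smiles)
  stop_if_invalid(props, "ring_penalty")
  slope * pmax(0, props$largest_ring - threshold)
}

#' The combined objective J = logP - SA - ring penalty
#'
#' All three components are computed on the same parsed molecule; `j` is
#' their combination exactly as written (no component standardization by
#' default -- see `standardize`).
#'
#' @inheritParams ring_penalty
#' @param standardize Optional list with numeric entries
#'   `logp_mean/logp_sd/sa_mean/sa_sd/ring_mean/ring_sd`: if supplied, each
#'   component is z-scored with these constants before combining, as some
#'   benchmark implementations do. Default `NULL` uses raw components.
#' @return A data.frame: `smiles`, `logp`, `sa`, `ring_penalty`, `j`.
#'   Errors on invalid SMILES; gate with [check_validity()].
#' @export
score_j <- function(smiles, threshold = 6L, slope = 1, standardize = NULL) {
  props <- mol_properties(smiles)
  stop_if_invalid(props, "score_j")
  rp <- slope * pmax(0, props$largest_ring - threshold)
  logp <- props$logp; sa <- props$sa
  if (!is.null(standardize)) {
    logp <- (logp - standardize$logp_mean) / standardize$logp_sd
    sa <- (sa - standardize$sa_mean) / standardize$sa_sd
    rp <- (rp - standardize$ring_mean) / standardize$ring_sd
  }
  data.frame(smiles = props$smiles, logp = logp, sa = sa,
             ring_penalty = rp, j = logp - sa - rp,
             stringsAsFactors = FALSE)
}

#' Map an objective value to a bounded reward
#'
#' `j / (1 + |j|)`: strictly increasing, odd, and confined to (-1, 1).
#'
#' @param j Numeric vector of objective values.
#' @return Numeric vector in (-1, 1).
#' @export
reward_from_j <- function(j) j / (1 + abs(j))

#' Search reward of SMILES strings
#'
#' Invalid strings score exactly `invalid_reward` (-1.0 by default); valid
#' molecules score `J/(1+|J|)`, strictly inside (-1, 1).
#'
#' @inheritParams score_j
#' @param invalid_reward Reward assigned to strings that fail
#'   [check_validity()].
#' @return A data.frame: `smiles`, `valid`, `logp`, `sa`, `ring_penalty`,
#'   `j`, `reward` (property columns are `NA` for invalid strings).
#' @export
#' @examples
#' \donttest{
#' smiles_reward(c("CCO", "C("))
#' }
smiles_reward <- function(smiles, threshold = 6L, slope = 1,
                          standardize = NULL, invalid_reward = -1.0) {
  props <- mol_properties(smiles)
  out <- data.frame(smiles = props$smiles, valid = props$valid,
                    logp = NA_real_, sa = NA_real_, ring_penalty = NA_real_,
                    j = NA_real_, reward = invalid_reward,
                    stringsAsFactors = FALSE)
  ok <- which(props$valid)
  if (length(ok)) {
    sj <- score_j(props$smiles[ok], threshold = threshold, slope = slope,
                  standardize = standardize)
    out$logp[ok] <- sj$logp
    out$sa[ok] <- sj$sa
    out$ring_penalty[ok] <- sj$ring_penalty
    out$j[ok] <- sj$j
    out$reward[ok] <- reward_from_j(sj$j)
  }
  out
}

#' Build the reward function used by the tree search
#'
#' Returns a closure mapping one SMILES string to a scored record, in the
#' shape [mcts_search()] expects: a list with `reward`, `valid`, `scores`
#' (logp/sa/ring_penalty/j) and `canonical` (for duplicate detection).
#'
#' @inheritParams smiles_reward
#' @return A function of one SMILES string.
#' @export
penalized_logp_reward <- function(threshold = 6L, slope = 1,
                                  standardize = NULL, invalid_reward = -1.0) {
  force(threshold); force(slope); force(standardize); force(invalid_reward)
  function(smiles) {
    r <- smiles_reward(smiles, threshold = threshold, slope = slope,
                       standardize = standardize,
                       invalid_reward = invalid_reward)
    props <- mol_properties(smiles)
    list(reward = r$reward, valid = r$valid,
         scores = list(logp = r$logp, sa = r$sa,
                       ring_penalty = r$ring_penalty, j = r$j),
         canonical = if (r$valid) props$canonical else NA_character_)
  }
}

.onUnload <- function(libpath) {
  scorer_stop()
}
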