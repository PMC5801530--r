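# Independent brute-force oracle for the search: enumerate every complete
# string of emitting symbols up to a length cap and score each one directly.

enumerate_complete_strings <- function(symbols, max_emit) {
  out <- character(0)
  grow <- function(prefix, depth) {
    for (s in symbols) {
      cur <- paste0(prefix, s)
      out[[length(out) + 1L]] <<- cur
      if (depth < max_emit) grow(cur, depth + 1L)
    }
  }
  grow("", 1L)
  out
}

brute_force_best <- function(symbols, max_emit, score_fn) {
  all_strings <- enumerate_complete_strings(symbols, max_emit)
  scores <- vapply(all_strings, score_fn, numeric(1))
  list(best = all_strings[which.max(scores)], score = max(scores),
       n = length(all_strings), scores = scores, strings = all_strings)
}
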