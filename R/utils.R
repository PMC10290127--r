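# internal helpers

# row-wise log(sum(exp(x))) without overflow
logsumexp_rows <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of 1:k as a list (k <= 7 in practice)
permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
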