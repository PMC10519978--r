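# Shared fixtures, built in code. The small library/pool mirrors the
# experimental layout: 8 addresses x 96 payload 25-mers, combination factor
# 32, one payload position per oligo, same message on every address.

fixture_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_library(8, 96, seed = 1)
    cache
  }
})

fixture_message <- function(lib = fixture_library()) {
  encode_data("HelloWorld", codec_params(96, 32), lib,
              replicate_addresses = TRUE)
}

fixture_pool <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lib <- fixture_library()
      cache <<- expand_pool(fixture_message(lib), lib)
    }
    cache
  }
})

# independent enumeration oracle: all k-subsets of 0..m-1 in colex order
# (sorted by reversed member tuple), as a list of integer vectors
colex_enumerate <- function(m, k) {
  if (k == 0L) return(list(integer(0)))
  combos <- utils::combn(m, k) - 1L  # k x C(m,k), each column ascending
  ord <- do.call(order, lapply(rev(seq_len(k)), function(i) combos[i, ]))
  lapply(ord, function(j) combos[, j])
}

# exact edit distance between two sequences (independent of the decoder)
edit_dist <- function(a, b) as.integer(utils::adist(a, b))

# inject n random edits (sub/ins/del uniformly) into a sequence
mutate_seq <- function(seq, n_edits) {
  for (i in seq_len(n_edits)) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    op <- sample(c("sub", "ins", "del"), 1)
    pos <- sample(length(ch), 1)
    if (op == "sub") {
      ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
    } else if (op == "ins") {
      ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = pos)
    } else if (length(ch) > 1) {
      ch <- ch[-pos]
    }
    seq <- paste(ch, collapse = "")
  }
  seq
}
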