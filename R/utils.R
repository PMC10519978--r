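# shared internal helpers

# Seed the RNG for the calling frame and restore the caller's RNG state on
# exit, so package functions never perturb the user's random stream.
local_seed <- function(seed, envir = parent.frame()) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  restore <- substitute({
    if (!is.null(OLD)) assign(".Random.seed", OLD, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, list(OLD = old))
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  invisible(seed)
}

# Stage-specific sub-seed so pipeline stages are independently reproducible
# from one global seed. Always below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(seq, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), ""))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
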