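# Recovery evaluation: exact set comparison of decoded oligos against the
# synthesized pool, and recovery-versus-coverage curves via seeded read
# subsampling (how the read-side pipeline is benchmarked).

#' TP / FP / FN of a recovered oligo set
#'
#' Exact comparison on the (address, payload tuple) identity. True positives
#' are recovered oligos present in the original pool; false positives are
#' recovered oligos absent from it (when decoding against an expanded
#' reference space, these are the spurious members of that space); false
#' negatives are pool oligos never recovered.
#'
#' @param recovered A `"consensus_result"`, a data frame with an `oligo_id`
#'   column (e.g. [consensus_oligos()]), or an `"inferred_oligos"` frame.
#' @param pool The true `"oligo_pool"`.
#' @return An `"eval_report"` list: tp, fp, fn, plus the id sets.
#' @export
evaluate_recovery <- function(recovered, pool) {
  stopifnot(inherits(pool, "oligo_pool"))
  ids <- if (inherits(recovered, "consensus_result"))
    consensus_oligos(recovered)$oligo_id
  else if (is.data.frame(recovered) && "oligo_id" %in% names(recovered))
    recovered$oligo_id
  else if (is.data.frame(recovered))
    unique(sprintf("oligo_A%d_P%s", recovered$address_index,
                   gsub(",", "-", recovered$payloads, fixed = TRUE)))
  else stop("unsupported recovered object")
  ids <- unique(ids)
  truth <- unique(pool$oligo_id)
  structure(list(
    tp = length(intersect(ids, truth)),
    fp = length(setdiff(ids, truth)),
    fn = length(setdiff(truth, ids)),
    n_truth = length(truth),
    recovered_ids = ids), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<recovery> TP=", x$tp, "/", x$n_truth, "  FP=", x$fp,
      "  FN=", x$fn, "\n", sep = "")
  invisible(x)
}

#' Recovery as a function of sequencing coverage
#'
#' Simulates reads once at the highest requested coverage, then subsamples
#' down the coverage grid with a fixed seed, decoding at each point —
#' recovery curves of the TP/FP-versus-coverage kind. Subsamples are nested
#' (a seeded permutation of the reads, truncated per coverage) and each read
#' is inferred once: per-read inference is independent of the subset, so
#' only the consensus is recomputed per coverage point.
#'
#' @param pool The true `"oligo_pool"`.
#' @param lib Library used for decoding (may be larger than the pool's: an
#'   expanded reference space for FP studies).
#' @param channel A [channel_params()]; its `coverage` is overridden by the
#'   grid maximum.
#' @param coverages Numeric coverage grid (fold coverage).
#' @param sparams A [search_params()] (defaults from `lib`).
#' @param k Combination factor used by the consensus (defaults to the pool's
#'   per-address oligo count).
#' @param seed Subsampling seed.
#' @return Data frame: coverage, reads, tp, fp, fn.
#' @export
recovery_curve <- function(pool, lib, channel, coverages,
                           sparams = NULL, k = NULL, seed = 1L) {
  stopifnot(inherits(pool, "oligo_pool"))
  coverages <- sort(coverages)
  cmax <- max(coverages)
  channel$coverage <- cmax
  reads <- simulate_reads(pool, channel)
  if (is.null(sparams)) sparams <- search_params(lib)
  if (is.null(k)) k <- max(table(pool$address_index))
  inferred <- infer_reads(reads, lib, sparams)
  local_seed(derive_seed(seed, "subsample"))
  perm <- sample(reads$reads$read_id)
  out <- data.frame(coverage = coverages, reads = NA_integer_,
                    tp = NA_integer_, fp = NA_integer_, fn = NA_integer_)
  for (i in seq_along(coverages)) {
    n_keep <- round(coverages[i] / cmax * length(perm))
    kept <- perm[seq_len(n_keep)]
    sub_inf <- inferred[inferred$read_id %in% kept, , drop = FALSE]
    consensus <- call_consensus(sub_inf, k = k,
                                positions = sparams$positions[1L],
                                min_support = sparams$min_support)
    ev <- evaluate_recovery(consensus, pool)
    out$reads[i] <- n_keep
    out$tp[i] <- ev$tp; out$fp[i] <- ev$fp; out$fn[i] <- ev$fn
  }
  out
}
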