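# Motif-Search: structure-aware inference of oligos from raw noisy reads.
# An oligo is address + (spacer + payload)*n with all motifs drawn from a
# finite library, so decoding proceeds by (i) segmentation: locate spacer
# starts by k-mer voting, refine them with a randomized edit->Hamming
# embedding; (ii) mapping: align inter-spacer windows against the candidate
# motifs with affine-gap local alignment; (iii) overlap check: greedy
# selection of non-overlapping chains by score; then top-k frequency
# consensus per address recovers the composite motifs.

#' Spacer k-mer index
#'
#' All k-mers of the spacer (2-bit encoded) with their offsets; the
#' segmentation seed table.
#'
#' @param spacer Spacer motif sequence.
#' @param k K-mer length (default 4).
#' @return A `"spacer_index"`: k, spacer, and the offset table.
#' @export
spacer_index <- function(spacer, k = 4L) {
  stopifnot(k >= 2L, nchar(spacer) >= k)
  kmers <- substring(spacer, seq_len(nchar(spacer) - k + 1L),
                     seq_len(nchar(spacer) - k + 1L) + k - 1L)
  table <- split(seq_along(kmers) - 1L, kmers)
  structure(list(k = as.integer(k), spacer = spacer, table = table),
            class = "spacer_index")
}

#' Decoder parameters
#'
#' All Motif-Search thresholds in one place. Defaults: 4-mer seeding with a
#' ceil(spacer_length/k) vote threshold, +-3 nt candidate merging, +-3 nt
#' refinement shifts with 3 CGK embedding repetitions, +-5 nt chain-gap
#' tolerance, ksw-style scoring (match +2, mismatch -4, gap open 4, extend
#' 2), +-4 nt window widening, calls below 0.6 x the perfect score rejected,
#' and consensus support of at least 2 inferred oligos per motif.
#'
#' @param lib A `"motif_library"`.
#' @param positions Payload positions per oligo (M - 1 spacers for M
#'   motifs); may be a vector of admissible counts when the pool mixes oligo
#'   lengths (e.g. a short final block).
#' @param k K-mer length for spacer seeding.
#' @param merge_window Candidate-merge window (nt).
#' @param shift_window Refinement shift range (nt).
#' @param embed_reps CGK embedding repetitions.
#' @param chain_tolerance Allowed deviation of inter-spacer gaps from
#'   motif_length + spacer_length (nt).
#' @param margin Window widening before alignment (nt).
#' @param match,mismatch,gap_open,gap_ext Integer alignment scores (gap of
#'   length L costs gap_open + L * gap_ext).
#' @param min_score_frac Motif calls below this fraction of the perfect
#'   score reject the chain.
#' @param min_support Minimum inferred-oligo support for a consensus motif.
#' @param seed Seed for the shared embedding random bits.
#' @return A `"search_params"` list.
#' @export
search_params <- function(lib, positions = 1L, k = 4L, merge_window = 3L,
                          shift_window = 3L, embed_reps = 3L,
                          chain_tolerance = 5L, margin = 4L,
                          match = 2L, mismatch = -4L, gap_open = 4L,
                          gap_ext = 2L, min_score_frac = 0.6,
                          min_support = 2L, seed = 42L) {
  stopifnot(inherits(lib, "motif_library"), all(positions >= 1))
  p <- list(positions = sort(unique(as.integer(positions))),
            k = as.integer(k),
            min_votes = as.integer(ceiling(lib$spacer_length / k)),
            merge_window = as.integer(merge_window),
            shift_window = as.integer(shift_window),
            embed_reps = as.integer(embed_reps),
            chain_tolerance = as.integer(chain_tolerance),
            margin = as.integer(margin),
            match = as.integer(match), mismatch = as.integer(mismatch),
            gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
            min_score_frac = min_score_frac,
            min_support = as.integer(min_support),
            seed = as.integer(seed),
            d = lib$motif_length + lib$spacer_length,
            bit_mats = cgk_bits(3L * lib$spacer_length, embed_reps, seed))
  structure(p, class = "search_params")
}

# shared CGK random bits: one (3L x 4) 0/1 matrix per repetition, reused for
# query and reference so the embedding is a proper metric embedding
cgk_bits <- function(n_out, reps, seed) {
  local_seed(seed)
  lapply(seq_len(reps), function(r)
    matrix(stats::rbinom(n_out * 4L, 1L, 0.5), ncol = 4L))
}

#' Candidate spacer positions in a read
#'
#' K-mer voting: each read k-mer found in the spacer index votes for the
#' normalized start position (read position minus spacer offset); positions
#' with fewer than ceil(spacer_length/k) votes are discarded and surviving
#' neighbours within the merge window collapse to a vote-weighted centroid.
#'
#' @param read Read sequence.
#' @param idx A [spacer_index()].
#' @param min_votes Vote threshold (default ceil(spacer_length/k)).
#' @param merge_window Neighbour-merge window in nt.
#' @return Data frame: position (0-based), votes.
#' @export
find_spacer_candidates <- function(read, idx,
                                   min_votes = ceiling(nchar(idx$spacer) / idx$k),
                                   merge_window = 3L) {
  stopifnot(inherits(idx, "spacer_index"))
  C_spacer_candidates(read, idx$spacer, idx$k, as.integer(min_votes),
                      as.integer(merge_window))
}

#' Refine a candidate spacer position by randomized embedding
#'
#' For each shift in -shift_window..+shift_window, the spacer-length window
#' at candidate+shift is embedded with the shared CGK random bits and
#' compared with the embedded spacer by Hamming distance; the shift with the
#' least mean embedded distance wins (ties: smaller |shift|, then the
#' negative one). Cheap surrogate for exact edit distance over shifts.
#'
#' @param read Read sequence.
#' @param position Candidate 0-based start.
#' @param spacer Spacer sequence.
#' @param params A [search_params()] (for shift window and bit matrices).
#' @return List: position (refined 0-based start), shift, clamped flag.
#' @export
refine_position <- function(read, position, spacer, params) {
  L <- nchar(spacer)
  n <- nchar(read)
  shifts <- seq.int(-params$shift_window, params$shift_window)
  clamped <- FALSE
  dist <- rep(Inf, length(shifts))
  for (i in seq_along(shifts)) {
    s0 <- position + shifts[i]
    if (s0 < 0L || s0 >= n) { clamped <- TRUE; next }
    if (s0 + L > n) clamped <- TRUE
    win <- substr(read, s0 + 1L, min(s0 + L, n))
    dist[i] <- C_cgk_dist(win, spacer, params$bit_mats)
  }
  ord <- order(dist, abs(shifts), shifts)
  best <- shifts[ord[1L]]
  list(position = position + best, shift = best, clamped = clamped)
}

#' Chains of spacer positions at the expected period
#'
#' All chains of M-1 candidate positions whose consecutive gaps lie within
#' tolerance of d = motif_length + spacer_length. With a single spacer per
#' oligo (M = 2) every candidate is its own chain.
#'
#' @param candidates Integer vector of candidate positions (0-based).
#' @param M Number of motifs per oligo (address + payloads).
#' @param d Expected inter-spacer distance (nt).
#' @param tolerance Allowed gap deviation (nt).
#' @return List of integer vectors (each of length M-1).
#' @export
build_chains <- function(candidates, M, d, tolerance = 5L) {
  stopifnot(d > 0, M >= 2)
  candidates <- sort(unique(as.integer(candidates)))
  need <- M - 1L
  if (length(candidates) == 0L) return(list())
  if (need == 1L) return(as.list(candidates))
  out <- list()
  extend <- function(chain) {
    if (length(chain) == need) {
      out[[length(out) + 1L]] <<- chain
      return(invisible())
    }
    last <- chain[length(chain)]
    nxt <- candidates[candidates >= last + d - tolerance &
                      candidates <= last + d + tolerance]
    for (p in nxt) extend(c(chain, p))
  }
  for (p in candidates) extend(p)
  out
}

# extract the motif windows implied by a chain of refined spacer starts and
# align them against the library; returns a scored chain call
map_chain <- function(read, spacer_positions, lib, params) {
  n <- nchar(read)
  sp <- sort(as.integer(spacer_positions))
  L <- lib$spacer_length
  mg <- params$margin
  windows <- list()
  # address window sits before the first spacer
  a_start <- max(sp[1L] - lib$address_length - mg, 0L)
  windows[[1L]] <- c(a_start, sp[1L] + mg)
  for (i in seq_along(sp)) {
    w_start <- sp[i] + L - mg
    w_end <- if (i < length(sp)) sp[i + 1L] + mg
             else sp[i] + L + lib$motif_length + mg
    windows[[i + 1L]] <- c(max(w_start, 0L), min(w_end, n))
  }
  roles <- c("address", rep("payload", length(sp)))
  calls <- data.frame(role = roles, index = NA_integer_,
                      score = NA_integer_, stringsAsFactors = FALSE)
  rejected <- FALSE
  reason <- NA_character_
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (w[2L] <= w[1L]) { rejected <- TRUE; reason <- "empty window"; break }
    q <- substr(read, w[1L] + 1L, w[2L])
    refs <- if (roles[i] == "address") lib$address else lib$payload
    scores <- C_align_score_many(q, refs, params$match, params$mismatch,
                                 params$gap_open, params$gap_ext)
    best <- which.max(scores)  # ties resolve to the lowest motif index
    calls$index[i] <- best - 1L
    calls$score[i] <- scores[best]
    perfect <- params$match *
      (if (roles[i] == "address") lib$address_length else lib$motif_length)
    if (scores[best] < params$min_score_frac * perfect) {
      rejected <- TRUE
      reason <- sprintf("%s call below score threshold (%d < %.1f)",
                        roles[i], scores[best],
                        params$min_score_frac * perfect)
      break
    }
  }
  # ownership span excludes the alignment margin: adjacent oligos in a
  # merged read abut without overlapping
  span <- c(max(sp[1L] - lib$address_length, 0L),
            min(sp[length(sp)] + L + lib$motif_length, n))
  structure(list(spacer_positions = sp, calls = calls,
                 total_score = if (rejected) -Inf else sum(calls$score),
                 span = span,
                 rejected = rejected, reason = reason),
            class = "motif_chain")
}

#' Greedy resolution of overlapping chains
#'
#' Each read nucleotide may belong to one oligo only: chains are taken in
#' order of decreasing mapping score (ties: leftmost span, then fewer
#' positions) and kept only if their span overlaps no previously kept chain.
#' Greedy per the decoding contract; not guaranteed to maximize total score.
#'
#' @param chains List of mapped chains (from internal mapping).
#' @return The kept chains, sorted by span start.
#' @export
resolve_overlaps <- function(chains) {
  chains <- Filter(function(ch) !ch$rejected, chains)
  if (length(chains) == 0L) return(list())
  score <- vapply(chains, function(ch) ch$total_score, 0)
  start <- vapply(chains, function(ch) ch$span[1L], 0)
  npos <- vapply(chains, function(ch) length(ch$spacer_positions), 0L)
  ord <- order(-score, start, npos)
  kept <- list()
  for (i in ord) {
    ch <- chains[[i]]
    clash <- any(vapply(kept, function(kc)
      ch$span[1L] < kc$span[2L] && kc$span[1L] < ch$span[2L], TRUE))
    if (!clash) kept[[length(kept) + 1L]] <- ch
  }
  kept[order(vapply(kept, function(ch) ch$span[1L], 0))]
}

#' Infer oligos from a single read
#'
#' Runs segmentation, refinement, chain building, mapping and overlap
#' resolution on the read and its reverse complement, keeping the
#' orientation with the higher summed kept-chain score (ties: forward).
#' Junk reads yield an empty result.
#'
#' @param read Read sequence.
#' @param lib A `"motif_library"`.
#' @param params A [search_params()].
#' @param read_id Identifier carried into the result.
#' @return Data frame of inferred oligos: read_id, strand, address_index,
#'   payloads (comma-separated indices), score.
#' @export
infer_read <- function(read, lib, params, read_id = "read") {
  idx <- spacer_index(lib$spacer, params$k)
  run_one <- function(seq, strand) {
    if (nchar(seq) < params$k) return(list(chains = list(), total = 0))
    cand <- find_spacer_candidates(seq, idx, params$min_votes,
                                   params$merge_window)
    if (nrow(cand) == 0L) return(list(chains = list(), total = 0))
    refined <- unique(vapply(cand$position, function(p)
      refine_position(seq, p, lib$spacer, params)$position, 0))
    chains <- list()
    for (M in params$positions + 1L)
      chains <- c(chains, build_chains(refined, M, params$d,
                                       params$chain_tolerance))
    chains <- unique(chains)
    mapped <- lapply(chains, function(sp) map_chain(seq, sp, lib, params))
    kept <- resolve_overlaps(mapped)
    list(chains = kept,
         total = sum(vapply(kept, function(ch) ch$total_score, 0)))
  }
  fwd <- run_one(read, "+")
  rev <- run_one(revcomp(read), "-")
  use_rev <- rev$total > fwd$total
  res <- if (use_rev) rev else fwd
  strand <- if (use_rev) "-" else "+"
  if (length(res$chains) == 0L)
    return(data.frame(read_id = character(0), strand = character(0),
                      address_index = integer(0), payloads = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  data.frame(
    read_id = read_id, strand = strand,
    address_index = vapply(res$chains, function(ch)
      ch$calls$index[ch$calls$role == "address"], 0L),
    payloads = vapply(res$chains, function(ch)
      paste(ch$calls$index[ch$calls$role == "payload"], collapse = ","), ""),
    score = vapply(res$chains, function(ch) ch$total_score, 0),
    stringsAsFactors = FALSE)
}

#' Infer oligos from a set of reads
#'
#' @param reads A `"sim_reads"` object or data frame (read_id, sequence).
#' @param lib A `"motif_library"`.
#' @param params A [search_params()].
#' @return Data frame of inferred oligos (one row per kept chain), class
#'   `"inferred_oligos"`.
#' @export
infer_reads <- function(reads, lib, params) {
  df <- if (inherits(reads, "sim_reads")) reads$reads else reads
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df)))
    out[[i]] <- infer_read(df$sequence[i], lib, params, df$read_id[i])
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(read_id = character(0), strand = character(0),
                      address_index = integer(0), payloads = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("inferred_oligos", "data.frame")
  res
}

#' @export
print.inferred_oligos <- function(x, ...) {
  cat("<inferred oligos> ", nrow(x), " chains from ",
      length(unique(x$read_id)), " reads, ",
      length(unique(x$address_index)), " distinct addresses\n", sep = "")
  invisible(x)
}

#' Consensus calling over inferred oligos
#'
#' Clusters inferred oligos by address motif and, at each payload position,
#' ranks motifs by support count (ties: higher summed alignment score, then
#' lower motif index). The top k motifs with support of at least min_support
#' form the recovered composite for that position; an address that cannot
#' field k supported motifs at every position is flagged as failed.
#'
#' @param inferred An `"inferred_oligos"` data frame.
#' @param k Combination factor (composite size to recover).
#' @param positions Payload positions per oligo.
#' @param min_support Minimum supporting inferred oligos per motif.
#' @return A `"consensus_result"`: per-address position tables, recovered
#'   composites, and failure flags.
#' @export
call_consensus <- function(inferred, k, positions = 1L, min_support = 2L) {
  stopifnot(k >= 1)
  result <- list()
  for (a in sort(unique(inferred$address_index))) {
    grp <- inferred[inferred$address_index == a, , drop = FALSE]
    pls <- strsplit(grp$payloads, ",", fixed = TRUE)
    ok <- lengths(pls) == positions
    grp <- grp[ok, , drop = FALSE]
    pls <- pls[ok]
    pos_tables <- vector("list", positions)
    comps <- vector("list", positions)
    failed <- FALSE
    for (pidx in seq_len(positions)) {
      motif <- as.integer(vapply(pls, `[`, "", pidx))
      tab <- stats::aggregate(
        list(support = rep(1L, length(motif)), score_sum = grp$score),
        by = list(motif = motif), FUN = sum)
      tab <- tab[order(-tab$support, -tab$score_sum, tab$motif), ,
                 drop = FALSE]
      rownames(tab) <- NULL
      pos_tables[[pidx]] <- tab
      eligible <- tab[tab$support >= min_support, , drop = FALSE]
      if (nrow(eligible) < k) {
        failed <- TRUE
        comps[[pidx]] <- NULL
      } else {
        comps[[pidx]] <- new_composite_motif(sort(eligible$motif[seq_len(k)]),
                                             k)
      }
    }
    result[[as.character(a)]] <- list(address_index = a,
                                      positions = pos_tables,
                                      composites = comps,
                                      n_oligos = nrow(grp),
                                      recovery_failed = failed)
  }
  structure(list(addresses = result, k = as.integer(k),
                 n_positions = as.integer(positions),
                 min_support = as.integer(min_support)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  ok <- vapply(x$addresses, function(a) !a$recovery_failed, TRUE)
  cat("<consensus> ", length(x$addresses), " addresses (", sum(ok),
      " recovered, ", sum(!ok), " failed); k=", x$k, ", ",
      x$n_positions, " position(s), min support ", x$min_support,
      "\n", sep = "")
  invisible(x)
}

#' Recovered logical sequences from a consensus result
#'
#' @param consensus A `"consensus_result"`.
#' @return List of `logical_sequence` objects for addresses that recovered.
#' @export
consensus_sequences <- function(consensus) {
  ok <- Filter(function(a) !a$recovery_failed, consensus$addresses)
  lapply(ok, function(a)
    new_logical_sequence(a$address_index, a$composites))
}

#' The oligo set implied by a consensus result
#'
#' Per address, the cartesian product over positions of the recovered top-k
#' motif sets — the molecule set the consensus asserts was synthesized; the
#' unit compared against the true pool in TP/FP evaluation.
#'
#' @param consensus A `"consensus_result"`.
#' @return Data frame: oligo_id, address_index, payloads.
#' @export
consensus_oligos <- function(consensus) {
  rows <- list()
  for (a in consensus$addresses) {
    if (a$recovery_failed) next
    members <- lapply(a$composites, function(cm) as.integer(cm))
    grid <- as.matrix(expand.grid(members, KEEP.OUT.ATTRS = FALSE))
    for (i in seq_len(nrow(grid))) {
      p <- as.integer(grid[i, ])
      rows[[length(rows) + 1L]] <- data.frame(
        oligo_id = oligo_id(a$address_index, p),
        address_index = a$address_index,
        payloads = paste(p, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(oligo_id = character(0), address_index = integer(0),
                      payloads = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Decode stored bytes from reads
#'
#' Full read-side pipeline: infer oligos from every read, call consensus per
#' address, assemble the recovered logical sequences, and decode them with
#' the encoding manifest.
#'
#' @param reads A `"sim_reads"` object or data frame (read_id, sequence).
#' @param lib A `"motif_library"`.
#' @param manifest Manifest from [encode_data()].
#' @param params A [search_params()]; defaults follow the manifest geometry.
#' @return List: bytes (raw or NULL on failure), consensus, inferred,
#'   recovery_failed flags per address.
#' @export
decode_from_reads <- function(reads, lib, manifest, params = NULL) {
  # per-address expected position counts (the final block may be short)
  ppo <- manifest$positions_per_oligo
  n_blocks <- ceiling(manifest$n_composites / ppo)
  block_pos <- rep(ppo, n_blocks)
  block_pos[n_blocks] <- manifest$n_composites - ppo * (n_blocks - 1L)
  if (manifest$replicate_addresses) block_pos <- rep(block_pos[1L],
                                                     length(lib$address))
  if (is.null(params))
    params <- search_params(lib, positions = unique(block_pos),
                            min_support = 2L)
  inferred <- infer_reads(reads, lib, params)
  merged <- list(addresses = list(), k = manifest$k,
                 n_positions = ppo, min_support = params$min_support)
  for (p in unique(block_pos)) {
    addr_with_p <- which(block_pos == p) - 1L
    sub <- inferred[inferred$address_index %in% addr_with_p, , drop = FALSE]
    cons_p <- call_consensus(sub, k = manifest$k, positions = p,
                             min_support = params$min_support)
    merged$addresses <- c(merged$addresses, cons_p$addresses)
  }
  merged$addresses <- merged$addresses[order(as.integer(
    names(merged$addresses)))]
  consensus <- structure(merged, class = "consensus_result")
  seqs <- consensus_sequences(consensus)
  bytes <- tryCatch(decode_data(seqs, manifest), error = function(e) {
    warning("decoding failed: ", conditionMessage(e))
    NULL
  })
  failed <- vapply(consensus$addresses, function(a) a$recovery_failed, TRUE)
  list(bytes = bytes, consensus = consensus, inferred = inferred,
       recovery_failed = failed)
}
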