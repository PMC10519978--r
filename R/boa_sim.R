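# Bridged oligonucleotide assembly, in silico: expand logical sequences of
# composite motifs into the pool of concrete single-molecule oligos produced
# by template-directed ligation. General layout per molecule:
#   address + spacer + payload_1 + spacer + payload_2 + ...
# (one member motif per composite position; the composite lives across
# molecules, not within one).

oligo_sequence <- function(lib, address_index, payload_indices) {
  paste0(lib$address[[address_index + 1L]],
         paste0(lib$spacer, lib$payload[payload_indices + 1L],
                collapse = ""))
}

oligo_id <- function(address_index, payload_indices) {
  sprintf("oligo_A%d_P%s", address_index,
          paste(payload_indices, collapse = "-"))
}

#' Expand logical sequences into an oligo pool
#'
#' Cartesian mode enumerates, per logical sequence, every per-position choice
#' of one member motif (product over positions of k molecules), which
#' guarantees that every member of every composite is physically represented
#' (lossless synthesis, decodable at sufficient coverage). Sampled mode
#' instead draws `n_samples` molecules per logical sequence with uniform
#' per-position member choices, modeling stochastic ligation.
#'
#' @param message An `"encoded_message"` from [encode_data()], or a bare list
#'   of `logical_sequence` objects.
#' @param lib A `"motif_library"`.
#' @param mode `"cartesian"` (default) or `"sampled"`.
#' @param n_samples Molecules drawn per logical sequence in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @param max_molecules Guard against cartesian explosion (k^positions).
#' @return An `"oligo_pool"`: data.frame with columns oligo_id,
#'   address_index, payloads (comma-separated indices), sequence, copies;
#'   plus provenance attributes.
#' @export
expand_pool <- function(message, lib, mode = c("cartesian", "sampled"),
                        n_samples = 100L, seed = 1L,
                        max_molecules = 1e6) {
  mode <- match.arg(mode)
  seqs <- if (inherits(message, "encoded_message")) message$sequences
          else message
  stopifnot(inherits(lib, "motif_library"))
  rows <- list()
  if (mode == "sampled") local_seed(seed)
  for (s in seqs) {
    a <- s$address_index
    if (a >= length(lib$address))
      stop("address index ", a, " outside library (",
           length(lib$address), " addresses)")
    members <- lapply(s$composites, function(cm) as.integer(cm))
    bad <- unlist(members) >= length(lib$payload)
    if (any(bad)) stop("payload index outside library in address ", a)
    if (mode == "cartesian") {
      n_mol <- prod(vapply(members, length, 0))
      if (n_mol > max_molecules)
        stop("cartesian expansion would produce ", n_mol, " molecules (> ",
             max_molecules, "); use mode = \"sampled\"")
      combos <- as.matrix(expand.grid(members, KEEP.OUT.ATTRS = FALSE))
      combos <- combos[do.call(order, as.data.frame(combos)), , drop = FALSE]
      for (i in seq_len(nrow(combos))) {
        p <- as.integer(combos[i, ])
        rows[[length(rows) + 1L]] <- list(a = a, p = p, copies = 1L)
      }
    } else {
      draws <- vapply(seq_len(n_samples), function(i)
        paste(vapply(members, function(mm)
          as.character(mm[sample.int(length(mm), 1L)]), ""),
          collapse = ","), "")
      tab <- table(draws)
      for (j in seq_along(tab)) {
        p <- as.integer(strsplit(names(tab)[j], ",", fixed = TRUE)[[1L]])
        rows[[length(rows) + 1L]] <- list(a = a, p = p,
                                          copies = as.integer(tab[[j]]))
      }
    }
  }
  pool <- data.frame(
    oligo_id = vapply(rows, function(r) oligo_id(r$a, r$p), ""),
    address_index = vapply(rows, function(r) r$a, 0L),
    payloads = vapply(rows, function(r) paste(r$p, collapse = ","), ""),
    sequence = vapply(rows, function(r) oligo_sequence(lib, r$a, r$p), ""),
    copies = vapply(rows, function(r) r$copies, 0L),
    stringsAsFactors = FALSE)
  if (anyDuplicated(pool$oligo_id)) {
    # same (address, chain) reachable from several logical sequences: merge
    agg <- stats::aggregate(copies ~ oligo_id, pool, sum)
    pool <- pool[!duplicated(pool$oligo_id), ]
    pool$copies <- agg$copies[match(pool$oligo_id, agg$oligo_id)]
  }
  attr(pool, "mode") <- mode
  attr(pool, "library_checksum") <- library_checksum(lib)
  attr(pool, "seed") <- if (mode == "sampled") as.integer(seed) else NA_integer_
  class(pool) <- c("oligo_pool", "data.frame")
  pool
}

#' Size (and lazily, members) of the full reference oligo space
#'
#' The expanded space of every syntactically valid oligo over a library:
#' |address| * |payload|^positions. Used for false-positive studies, where
#' inferred oligos are judged against a space much larger than the set
#' actually synthesized.
#'
#' @param lib A `"motif_library"` (or a list with counts `n_address`,
#'   `n_payload`).
#' @param positions Payload positions per oligo.
#' @param materialize If TRUE, also return the id table (guarded).
#' @param max_materialize Refuse to materialize more ids than this.
#' @return List with `count`, and `ids` when materialized.
#' @examples
#' lib <- generate_library(8, 96, seed = 1)
#' enumerate_reference_space(lib, 1)$count  # 768
#' @export
enumerate_reference_space <- function(lib, positions = 1L,
                                      materialize = FALSE,
                                      max_materialize = 1e6) {
  stopifnot(positions >= 1)
  na <- if (inherits(lib, "motif_library")) length(lib$address)
        else lib$n_address
  np <- if (inherits(lib, "motif_library")) length(lib$payload)
        else lib$n_payload
  count <- na * np^positions
  out <- list(count = count, n_address = na, n_payload = np,
              positions = as.integer(positions))
  if (materialize) {
    if (count > max_materialize)
      stop("refusing to materialize ", count, " oligo ids (> ",
           max_materialize, ")")
    grid <- expand.grid(rep(list(seq_len(np) - 1L), positions),
                        KEEP.OUT.ATTRS = FALSE)
    ids <- character(0)
    for (a in seq_len(na) - 1L)
      ids <- c(ids, apply(grid, 1L, function(p) oligo_id(a, as.integer(p))))
    out$ids <- ids
  }
  out
}

#' Write an oligo pool as FASTA plus a TSV index
#'
#' @param pool An `"oligo_pool"`.
#' @param fasta,tsv Output paths (either may be NULL to skip).
#' @export
write_pool <- function(pool, fasta = NULL, tsv = NULL) {
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(stats::setNames(pool$sequence,
      sprintf("%s copies=%d", pool$oligo_id, pool$copies)))
    Biostrings::writeXStringSet(ss, fasta)
  }
  if (!is.null(tsv))
    utils::write.table(as.data.frame(pool), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(pool)
}

#' @export
print.oligo_pool <- function(x, ...) {
  cat("<oligo pool> ", nrow(x), " distinct oligos (",
      sum(x$copies), " molecules), ", attr(x, "mode"),
      " expansion, library ", attr(x, "library_checksum"), "\n", sep = "")
  invisible(x)
}
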