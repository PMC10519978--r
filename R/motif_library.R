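# Motif libraries: the fixed alphabet of the storage system. Address motifs
# index logical sequences, payload motifs carry data, and a single constant
# spacer motif separates payloads and anchors the decoder's segmentation.

motif_id <- function(role, index) {
  prefix <- c(address = "A", payload = "P", spacer = "S")[[role]]
  sprintf("%s_%03d", prefix, index)
}

new_motif_library <- function(address, payload, spacer, min_edit_distance) {
  structure(list(
    address = address, payload = payload, spacer = spacer,
    motif_length = nchar(payload[[1L]]),
    address_length = nchar(address[[1L]]),
    spacer_length = nchar(spacer),
    min_edit_distance = as.integer(min_edit_distance)),
    class = "motif_library")
}

validate_sequences <- function(seqs, what) {
  bad <- !grepl("^[ACGT]+$", seqs)
  if (any(bad))
    stop(what, " record(s) with empty/lower-case/ambiguous bases: ",
         paste(names(seqs)[bad], collapse = ", "))
  invisible(seqs)
}

check_lengths <- function(seqs, what) {
  len <- nchar(seqs)
  if (length(unique(len)) > 1L) {
    off <- names(seqs)[len != stats::median(len)]
    stop(what, " motifs differ in length (", paste(sort(unique(len)),
         collapse = ", "), " nt); offending record(s): ",
         paste(off, collapse = ", "))
  }
  invisible(len[1L])
}

validate_library <- function(lib) {
  validate_sequences(lib$address, "address")
  validate_sequences(lib$payload, "payload")
  validate_sequences(stats::setNames(lib$spacer, "S_000"), "spacer")
  check_lengths(lib$address, "address")
  check_lengths(lib$payload, "payload")

  all_seq <- c(lib$address, lib$payload, stats::setNames(lib$spacer, "S_000"))
  dup <- duplicated(all_seq) | duplicated(all_seq, fromLast = TRUE)
  if (any(dup))
    stop("duplicate sequences across the library: ",
         paste(names(all_seq)[dup], collapse = ", "))

  thr <- lib$min_edit_distance
  if (length(lib$payload) > 1L) {
    d <- utils::adist(lib$payload)
    diag(d) <- NA
    if (any(d < thr, na.rm = TRUE)) {
      w <- which(d < thr, arr.ind = TRUE)[1L, ]
      stop("payload motifs ", names(lib$payload)[w[1L]], " and ",
           names(lib$payload)[w[2L]], " are at edit distance ",
           d[w[1L], w[2L]], " < ", thr)
    }
  }
  ds <- utils::adist(lib$spacer, c(lib$address, lib$payload))
  if (any(ds < thr)) {
    off <- names(c(lib$address, lib$payload))[ds < thr]
    stop("spacer within edit distance ", thr, " of: ",
         paste(off, collapse = ", "))
  }
  invisible(lib)
}

#' Load a motif library from FASTA files
#'
#' Reads address, payload and spacer motifs (one FASTA record per motif;
#' record order defines the 0-based motif indices) and validates the library
#' invariants: uppercase ACGT sequences, uniform lengths per role, pairwise
#' distinct sequences, minimum pairwise edit distance between payload motifs,
#' and spacer separation from every other motif.
#'
#' @param address_fasta,payload_fasta,spacer_fasta FASTA file paths.
#' @param min_edit_distance Required minimum pairwise edit distance between
#'   payload motifs and from the spacer to everything else (default 9, suited
#'   to 25-mer barcode-style motifs).
#' @return A `"motif_library"`.
#' @export
load_library <- function(address_fasta, payload_fasta, spacer_fasta,
                         min_edit_distance = 9L) {
  read_fa <- function(path, role) {
    if (!file.exists(path)) stop("no such FASTA file: ", path)
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) == 0L) stop("no records in ", path)
    seqs <- as.character(ss)
    names(seqs) <- if (is.null(names(ss)) || any(names(ss) == ""))
      vapply(seq_along(ss) - 1L, function(i) motif_id(role, i), "")
    else sub("\\s.*$", "", names(ss))
    seqs
  }
  address <- read_fa(address_fasta, "address")
  payload <- read_fa(payload_fasta, "payload")
  spacer <- read_fa(spacer_fasta, "spacer")
  if (length(spacer) != 1L)
    stop("spacer FASTA must contain exactly one record, found ",
         length(spacer))
  lib <- new_motif_library(address, payload, unname(spacer),
                           min_edit_distance)
  validate_library(lib)
  lib
}

#' Generate a random motif library
#'
#' Greedy rejection sampling: candidate motifs are drawn uniformly over
#' ACGT strings and accepted only if their edit distance to every previously
#' accepted motif (and eventually the spacer) meets the threshold.
#' Deterministic for a fixed seed. Mirrors barcode-set design; real libraries
#' would additionally screen thermodynamics, which is out of scope here.
#'
#' @param n_address,n_payload Number of address / payload motifs.
#' @param motif_length Payload (and spacer) length in nt, default 25.
#' @param min_edit_distance Pairwise edit-distance threshold, default 9.
#' @param seed RNG seed.
#' @param address_length Address motif length, default `motif_length`.
#' @param max_attempts Candidate draws allowed per motif before giving up.
#' @return A validated `"motif_library"`.
#' @examples
#' lib <- generate_library(8, 96, seed = 1)
#' lib
#' @export
generate_library <- function(n_address, n_payload, motif_length = 25L,
                             min_edit_distance = 9L, seed = 1L,
                             address_length = motif_length,
                             max_attempts = 400L) {
  stopifnot(n_address >= 1, n_payload >= 1, motif_length >= 4,
            min_edit_distance >= 1)
  local_seed(seed)
  accepted <- character(0)
  draw <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                     replace = TRUE), collapse = "")
  need <- n_address + n_payload + 1L
  lens <- c(rep(address_length, n_address), rep(motif_length, n_payload),
            motif_length)
  for (i in seq_len(need)) {
    found <- FALSE
    for (try in seq_len(max_attempts)) {
      cand <- draw(lens[i])
      if (length(accepted) == 0L ||
          min(utils::adist(cand, accepted)) >= min_edit_distance) {
        accepted <- c(accepted, cand)
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("could not generate ", need, " motifs of length ", motif_length,
           " at pairwise edit distance >= ", min_edit_distance, "; found ",
           length(accepted), " before exhausting ", max_attempts,
           " attempts (distance likely infeasible at this length)")
  }
  address <- accepted[seq_len(n_address)]
  payload <- accepted[n_address + seq_len(n_payload)]
  spacer <- accepted[need]
  names(address) <- vapply(seq_len(n_address) - 1L,
                           function(i) motif_id("address", i), "")
  names(payload) <- vapply(seq_len(n_payload) - 1L,
                           function(i) motif_id("payload", i), "")
  lib <- new_motif_library(address, payload, spacer, min_edit_distance)
  validate_library(lib)
  lib
}

#' Extend a library to a larger reference space
#'
#' Appends address/payload motifs (same greedy rejection sampling and
#' distance constraints) while keeping every existing motif at its index, so
#' oligos decoded against the extended library remain comparable with a pool
#' synthesized from the original one — the construction behind expanded-space
#' false-positive studies.
#'
#' @param lib A `"motif_library"`.
#' @param n_address,n_payload Target counts (>= the current ones).
#' @param seed RNG seed for the new draws.
#' @param max_attempts Candidate draws allowed per motif.
#' @return A validated `"motif_library"` with the original as a prefix.
#' @export
extend_library <- function(lib, n_address, n_payload, seed = 1L,
                           max_attempts = 400L) {
  stopifnot(inherits(lib, "motif_library"),
            n_address >= length(lib$address),
            n_payload >= length(lib$payload))
  local_seed(seed)
  accepted <- c(unname(lib$address), unname(lib$payload), lib$spacer)
  draw <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                     replace = TRUE), collapse = "")
  grow <- function(n_new, len) {
    out <- character(0)
    for (i in seq_len(n_new)) {
      found <- FALSE
      for (try in seq_len(max_attempts)) {
        cand <- draw(len)
        if (min(utils::adist(cand, c(accepted, out))) >=
            lib$min_edit_distance) {
          out <- c(out, cand)
          found <- TRUE
          break
        }
      }
      if (!found)
        stop("could not extend library: found ", length(out), " of ",
             n_new, " new motifs within ", max_attempts, " attempts each")
    }
    out
  }
  new_addr <- grow(n_address - length(lib$address), lib$address_length)
  accepted <- c(accepted, new_addr)
  new_pay <- grow(n_payload - length(lib$payload), lib$motif_length)
  address <- c(unname(lib$address), new_addr)
  payload <- c(unname(lib$payload), new_pay)
  names(address) <- vapply(seq_along(address) - 1L,
                           function(i) motif_id("address", i), "")
  names(payload) <- vapply(seq_along(payload) - 1L,
                           function(i) motif_id("payload", i), "")
  out <- new_motif_library(address, payload, lib$spacer,
                           lib$min_edit_distance)
  validate_library(out)
  out
}

#' Spacer-extended synthesis form of a payload motif
#'
#' The form in which a payload motif is physically synthesized for bridged
#' ligation: the last ceil(L/2) nt of the spacer are prepended and the first
#' floor(L/2) nt appended (13 + 25 + 12 = 50 nt for 25-mers), so that
#' concatenating synthesis forms yields payload motifs separated by complete
#' spacers and a single universal bridge oligo suffices.
#'
#' @param lib A `"motif_library"`.
#' @param index 0-based payload motif index.
#' @return The extended DNA string (motif_length + spacer_length nt).
#' @export
synthesis_form <- function(lib, index) {
  stopifnot(inherits(lib, "motif_library"))
  if (index < 0L || index >= length(lib$payload))
    stop("payload index out of range (synthesis forms exist for payload ",
         "motifs only)")
  L <- lib$spacer_length
  head_len <- ceiling(L / 2)
  paste0(substr(lib$spacer, L - head_len + 1L, L),
         lib$payload[[index + 1L]],
         substr(lib$spacer, 1L, L - head_len))
}

#' Measured minimum pairwise edit distance of a library
#'
#' The realized separation of a loaded library (across all address, payload
#' and spacer sequences), reported as a property rather than assumed.
#'
#' @param lib A `"motif_library"`.
#' @return Integer minimum pairwise edit distance.
#' @export
min_pairwise_distance <- function(lib) {
  all_seq <- c(lib$address, lib$payload, lib$spacer)
  d <- utils::adist(all_seq)
  min(d[upper.tri(d)])
}

#' Content checksum of the library sequences
#'
#' Rolling polynomial hash over the concatenated sequences (order-sensitive),
#' used to tie manifests, pools and runs to a specific library.
#'
#' @param lib A `"motif_library"`.
#' @return Hex string identifying the library content.
#' @export
library_checksum <- function(lib) {
  bytes <- utf8ToInt(paste(c(lib$address, lib$payload, lib$spacer),
                           collapse = "|"))
  p <- 67108859  # largest prime below 2^26: 31*h + b stays < 2^53, exact
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% p
  sprintf("%07x", h)
}

#' Write a motif library to FASTA + JSON manifest
#'
#' @param lib A `"motif_library"`.
#' @param dir Output directory (created if needed). Writes address.fasta,
#'   payload.fasta, spacer.fasta and library.json.
#' @return The directory path, invisibly.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(seqs, file) {
    ss <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(ss, file.path(dir, file))
  }
  wr(lib$address, "address.fasta")
  wr(lib$payload, "payload.fasta")
  wr(stats::setNames(lib$spacer, "S_000"), "spacer.fasta")
  jsonlite::write_json(list(
    address_fasta = "address.fasta", payload_fasta = "payload.fasta",
    spacer_fasta = "spacer.fasta",
    n_address = length(lib$address), n_payload = length(lib$payload),
    motif_length = lib$motif_length, address_length = lib$address_length,
    min_edit_distance = lib$min_edit_distance,
    checksum = library_checksum(lib)),
    file.path(dir, "library.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a library written by [write_library()]
#'
#' @param dir Directory containing the FASTA files and library.json.
#' @return A `"motif_library"`.
#' @export
read_library <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "library.json"),
                             simplifyVector = TRUE)
  lib <- load_library(file.path(dir, man$address_fasta),
                      file.path(dir, man$payload_fasta),
                      file.path(dir, man$spacer_fasta),
                      min_edit_distance = man$min_edit_distance)
  if (!identical(library_checksum(lib), man$checksum))
    stop("library checksum mismatch: files edited since manifest was written")
  lib
}

#' @export
print.motif_library <- function(x, ...) {
  cat("<motif library> ", length(x$address), " address (", x$address_length,
      " nt) + ", length(x$payload), " payload (", x$motif_length,
      " nt) motifs + 1 spacer\n", "  min pairwise edit distance >= ",
      x$min_edit_distance, " (declared)\n", sep = "")
  invisible(x)
}
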