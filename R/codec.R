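#' Exact number of k-combinations of m items
#'
#' Computes the binomial coefficient C(m, k) exactly at arbitrary precision
#' (Pascal-triangle additions on big integers, no floating point), since the
#' composite spaces used in motif-based storage, e.g. C(96, 32) of the order
#' of 3e25, exceed exact double range.
#'
#' @param m Library size (non-negative integer).
#' @param k Combination factor, 0 <= k <= m.
#' @return A `"bigint"` object; use [as.character()] for the exact decimal
#'   value or [as.numeric()] for an approximate double.
#' @examples
#' n_combinations(32, 4)   # 35960
#' n_combinations(7, 2)    # 21
#' @export
n_combinations <- function(m, k) {
  stopifnot(length(m) == 1L, length(k) == 1L, m == floor(m), k == floor(k))
  if (m < 0 || k < 0) stop("m and k must be non-negative")
  if (k > m) stop("k must not exceed m (got k=", k, ", m=", m, ")")
  structure(binom_bi(m, k), class = "bigint")
}

#' @export
as.character.bigint <- function(x, ...) bi_to_decimal(unclass(x))

#' @export
as.double.bigint <- function(x, ...) bi_to_num(unclass(x))

#' @export
print.bigint <- function(x, ...) {
  cat(bi_to_decimal(unclass(x)), "\n")
  invisible(x)
}

#' @export
format.bigint <- function(x, ...) bi_to_decimal(unclass(x))

#' Bits stored per composite motif
#'
#' The information content of one composite position: floor(log2 C(m, k)),
#' computed exactly from the integer bit length of the binomial coefficient
#' (never via a floating-point logarithm).
#'
#' @inheritParams n_combinations
#' @return Integer number of bits (>= 1).
#' @examples
#' bits_per_composite(96, 32)  # 84
#' bits_per_composite(32, 4)   # 15
#' bits_per_composite(96, 1)   # 6, motif-by-motif limit
#' @export
bits_per_composite <- function(m, k) {
  cnt <- binom_bi(m, k)
  if (!is.numeric(cnt) || bi_cmp(cnt, bi_from_num(2)) < 0)
    stop("C(m, k) must be at least 2 to store data (m=", m, ", k=", k, ")")
  bi_bitlen(cnt) - 1L
}

#' Unrank a combination: integer value to composite motif
#'
#' Maps the integer r, 0 <= r < C(m, k), to the r-th k-subset of {0, ..., m-1}
#' in colexicographic order — the canonical value-to-combination bijection of
#' the codec (value 0 maps to {0, 1, ..., k-1}).
#'
#' @param r Rank: non-negative integer (double below 2^53, or a `"bigint"`).
#' @inheritParams n_combinations
#' @return A `"composite_motif"`: strictly increasing integer vector of k
#'   payload-motif indices, with attribute `k`.
#' @examples
#' combo_unrank(0, 7, 2)   # {0, 1}
#' combo_unrank(20, 7, 2)  # {5, 6}
#' @export
combo_unrank <- function(r, m, k) {
  r <- if (inherits(r, "bigint")) unclass(r) else bi_from_num(r)
  if (bi_cmp(r, binom_bi(m, k)) >= 0L)
    stop("rank out of range: r >= C(", m, ", ", k, ")")
  members <- integer(k)
  if (k > 0L) {
    cmax <- m - 1L
    for (i in k:1) {
      c <- cmax
      while (c >= i - 1L && bi_cmp(binom_bi(c, i), r) > 0L) c <- c - 1L
      members[i] <- c
      r <- bi_sub(r, binom_bi(c, i))
      cmax <- c - 1L
    }
  }
  stopifnot(bi_is_zero(r))
  new_composite_motif(members, k)
}

#' Rank a combination: composite motif to integer value
#'
#' Inverse of [combo_unrank()]: the colexicographic rank of a k-subset,
#' computed by the closed form sum over members c_1 < ... < c_k of C(c_i, i).
#'
#' @param members A `"composite_motif"` or strictly increasing integer vector
#'   of motif indices in 0..m-1.
#' @inheritParams n_combinations
#' @return A `"bigint"` rank in 0 .. C(m,k)-1.
#' @examples
#' combo_rank(c(0, 1), 7, 2)  # 0
#' combo_rank(c(5, 6), 7, 2)  # 20
#' @export
combo_rank <- function(members, m, k) {
  members <- as.integer(members)
  if (length(members) != k) stop("subset has ", length(members),
                                 " members, expected k=", k)
  if (k > 0L) {
    if (any(diff(members) <= 0L)) stop("members must be strictly increasing")
    if (members[1L] < 0L || members[k] >= m)
      stop("member indices must lie in 0..m-1")
  }
  r <- 0
  for (i in seq_len(k)) r <- bi_add(r, binom_bi(members[i], i))
  structure(r, class = "bigint")
}

new_composite_motif <- function(members, k) {
  structure(as.integer(members), k = as.integer(k), class = "composite_motif")
}

#' @export
print.composite_motif <- function(x, ...) {
  cat("<composite motif> k=", attr(x, "k"), ": {",
      paste(unclass(x), collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Codec parameters
#'
#' Fixes the encoding geometry: payload-library size m, combination factor k,
#' and the number of composite positions per logical sequence (synthesis
#' cycles per oligo). The derived bits_per_composite is the logical density
#' in bits per cycle.
#'
#' @param m Payload-motif library size.
#' @param k Combination factor (motifs mixed per position).
#' @param positions_per_oligo Composite positions per logical sequence.
#' @return A `"codec_params"` list with fields m, k, positions_per_oligo and
#'   bits_per_composite.
#' @examples
#' codec_params(96, 32)  # 84 bits per cycle
#' @export
codec_params <- function(m, k, positions_per_oligo = 1L) {
  stopifnot(m >= 1, k >= 1, k <= m, positions_per_oligo >= 1)
  structure(list(m = as.integer(m), k = as.integer(k),
                 positions_per_oligo = as.integer(positions_per_oligo),
                 bits_per_composite = bits_per_composite(m, k)),
            class = "codec_params")
}

#' @export
print.codec_params <- function(x, ...) {
  cat("<codec> m=", x$m, " k=", x$k, " positions/oligo=",
      x$positions_per_oligo, " (", x$bits_per_composite,
      " bits per composite)\n", sep = "")
  invisible(x)
}

new_logical_sequence <- function(address_index, composites) {
  structure(list(address_index = as.integer(address_index),
                 composites = composites),
            class = "logical_sequence")
}

#' Encode bytes as addressed composite motifs
#'
#' Splits the payload bit stream (MSB-first within each byte) into chunks of
#' bits_per_composite bits; each chunk is unranked into a composite motif;
#' composites are grouped positions_per_oligo at a time into logical
#' sequences carrying sequential address indices. The final chunk is
#' zero-padded at the tail; the true byte length is recorded in the manifest
#' so decoding is exact.
#'
#' @param data Raw vector, or a character scalar (encoded as UTF-8 bytes).
#' @param params A [codec_params()] object.
#' @param lib Optional [motif_library]; when given, the address space and
#'   payload count are validated against it and its checksum is recorded.
#' @param n_address Address-space size when no library is supplied.
#' @param replicate_addresses If TRUE, the encoded block set is replicated on
#'   every address (the read-pipeline stress layout: identical data stored on
#'   all addresses); requires the data to fit in a single address block.
#' @return An `"encoded_message"`: list of `logical_sequence` objects plus a
#'   manifest (m, k, positions_per_oligo, byte length, library checksum).
#' @examples
#' lib <- generate_library(8, 96, seed = 1)
#' enc <- encode_data("HelloWorld", codec_params(96, 32), lib)
#' length(enc$sequences)  # 1: 80 bits fit in one 84-bit composite
#' @export
encode_data <- function(data, params, lib = NULL, n_address = NULL,
                        replicate_addresses = FALSE) {
  stopifnot(inherits(params, "codec_params"))
  if (is.character(data)) data <- charToRaw(paste(data, collapse = ""))
  if (!is.raw(data)) stop("data must be raw bytes or a character scalar")
  if (length(data) == 0L) stop("empty input: nothing to encode")
  if (!is.null(lib)) {
    stopifnot(inherits(lib, "motif_library"))
    if (params$m > length(lib$payload))
      stop("codec m=", params$m, " exceeds library payload count ",
           length(lib$payload))
    n_address <- length(lib$address)
  }
  if (is.null(n_address)) n_address <- .Machine$integer.max

  b <- params$bits_per_composite
  bits <- as.integer(rawToBits(data) == as.raw(1))
  # rawToBits is LSB-first per byte; reorder to MSB-first
  bits <- as.vector(matrix(bits, nrow = 8L)[8:1, ])
  n_chunks <- as.integer(ceiling(length(bits) / b))
  bits <- c(bits, integer(n_chunks * b - length(bits)))

  composites <- vector("list", n_chunks)
  for (i in seq_len(n_chunks)) {
    chunk <- bits[((i - 1L) * b + 1L):(i * b)]
    composites[[i]] <- combo_unrank(structure(bi_from_bits(chunk),
                                              class = "bigint"),
                                    params$m, params$k)
  }

  ppo <- params$positions_per_oligo
  n_blocks <- as.integer(ceiling(n_chunks / ppo))
  if (n_blocks > n_address)
    stop("data needs ", n_blocks, " address blocks but only ", n_address,
         " address motifs are available (single-tier addressing)")
  if (replicate_addresses && n_blocks > 1L)
    stop("replicate_addresses requires the data to fit one address block")

  seqs <- vector("list", n_blocks)
  for (a in seq_len(n_blocks)) {
    idx <- ((a - 1L) * ppo + 1L):min(a * ppo, n_chunks)
    seqs[[a]] <- new_logical_sequence(a - 1L, composites[idx])
  }
  if (replicate_addresses) {
    if (is.infinite(n_address) || n_address == .Machine$integer.max)
      stop("replicate_addresses needs a library or explicit n_address")
    seqs <- lapply(seq_len(n_address) - 1L, function(a)
      new_logical_sequence(a, seqs[[1L]]$composites))
  }

  manifest <- list(
    m = params$m, k = params$k,
    positions_per_oligo = params$positions_per_oligo,
    bits_per_composite = b,
    n_bytes = length(data),
    n_composites = n_chunks,
    replicate_addresses = replicate_addresses,
    library_checksum = if (!is.null(lib)) library_checksum(lib) else NA_character_)
  structure(list(sequences = seqs, manifest = manifest),
            class = "encoded_message")
}

#' @export
print.encoded_message <- function(x, ...) {
  m <- x$manifest
  cat("<encoded message> ", m$n_bytes, " bytes -> ", m$n_composites,
      " composite(s) in ", length(x$sequences), " logical sequence(s) [m=",
      m$m, ", k=", m$k, ", ", m$bits_per_composite, " bits/composite]\n",
      sep = "")
  invisible(x)
}

#' Decode logical sequences back to bytes
#'
#' Exact inverse of [encode_data()]: orders blocks by address index, ranks
#' each composite, concatenates the MSB-first bit chunks, and strips tail
#' padding using the byte length recorded in the manifest.
#'
#' @param sequences List of `logical_sequence` objects (any order; addresses
#'   define the order), or an `"encoded_message"`.
#' @param manifest The manifest from [encode_data()] (taken from the message
#'   when one is passed).
#' @return Raw vector of the stored bytes.
#' @export
decode_data <- function(sequences, manifest = NULL) {
  if (inherits(sequences, "encoded_message")) {
    manifest <- sequences$manifest
    sequences <- sequences$sequences
  }
  stopifnot(!is.null(manifest))
  b <- manifest$bits_per_composite
  ppo <- manifest$positions_per_oligo
  n_chunks <- manifest$n_composites
  n_blocks <- ceiling(n_chunks / ppo)

  addr <- vapply(sequences, function(s) s$address_index, integer(1))
  if (manifest$replicate_addresses) {
    # every address carries the same block; use the lowest one present
    if (length(sequences) == 0L) stop("missing address block(s): 0")
    sequences <- sequences[which.min(addr)]
    addr <- 0L
    n_blocks <- 1L
  }
  need <- seq_len(n_blocks) - 1L
  missing <- setdiff(need, addr)
  if (length(missing) > 0L)
    stop("missing address block(s): ", paste(missing, collapse = ", "))
  sequences <- sequences[match(need, addr)]

  bits <- integer(0)
  got <- 0L
  for (s in sequences) {
    for (cm in s$composites) {
      got <- got + 1L
      if (got > n_chunks) break
      k <- length(cm)
      if (k != manifest$k)
        stop("composite with k=", k, " found; manifest expects k=",
             manifest$k)
      r <- combo_rank(cm, manifest$m, manifest$k)
      bits <- c(bits, bi_to_bits(unclass(r), b))
    }
  }
  if (got < n_chunks)
    stop("expected ", n_chunks, " composites, found ", got)
  bits <- bits[seq_len(manifest$n_bytes * 8L)]
  # repack MSB-first bits into bytes (packBits wants LSB-first per byte)
  mat <- matrix(bits, nrow = 8L)[8:1, , drop = FALSE]
  packBits(as.logical(as.vector(mat)), type = "raw")
}

#' Logical and physical density of a codec configuration
#'
#' Reports the logical density (bits written per synthesis cycle,
#' floor(log2 C(m,k))), the physical density (bits per nucleotide,
#' logical density / motif length), and the oligo capacity N = x * logical
#' density for x cycles.
#'
#' @param params A [codec_params()] object.
#' @param motif_length Payload motif length in nt (taken from `lib` if given).
#' @param lib Optional [motif_library].
#' @param x Number of synthesis cycles for the capacity figure.
#' @return A `"density_report"` list: bits_per_cycle, bits_per_nt,
#'   n_combinations (bigint), capacity_bits.
#' @examples
#' density_report(codec_params(96, 32), motif_length = 25)  # 84; 3.36 bits/nt
#' @export
density_report <- function(params, motif_length = NULL, lib = NULL, x = 1L) {
  stopifnot(inherits(params, "codec_params"))
  if (!is.null(lib)) motif_length <- lib$motif_length
  stopifnot(!is.null(motif_length), motif_length >= 1)
  b <- params$bits_per_composite
  structure(list(
    m = params$m, k = params$k, motif_length = as.integer(motif_length),
    n_combinations = n_combinations(params$m, params$k),
    bits_per_cycle = b,
    bits_per_nt = b / motif_length,
    cycles = as.integer(x),
    capacity_bits = as.integer(x) * b), class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat("<density report> m=", x$m, " k=", x$k, "\n",
      "  combinations per position : ", format(x$n_combinations), "\n",
      "  logical density           : ", x$bits_per_cycle, " bits/cycle\n",
      "  physical density          : ", format(round(x$bits_per_nt, 4)),
      " bits/nt (motif length ", x$motif_length, ")\n",
      "  capacity over ", x$cycles, " cycle(s)   : ", x$capacity_bits,
      " bits\n", sep = "")
  invisible(x)
}

#' Serialize logical sequences to JSON
#'
#' @param message An `"encoded_message"`.
#' @param path Output file path.
#' @export
write_logical_sequences <- function(message, path) {
  stopifnot(inherits(message, "encoded_message"))
  obj <- list(
    manifest = message$manifest,
    sequences = lapply(message$sequences, function(s)
      list(address_index = s$address_index,
           composites = lapply(s$composites, function(cm) as.integer(cm)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read logical sequences from JSON
#'
#' @param path File written by [write_logical_sequences()].
#' @return An `"encoded_message"`.
#' @export
read_logical_sequences <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  man <- obj$manifest
  man$m <- as.integer(man$m); man$k <- as.integer(man$k)
  man$positions_per_oligo <- as.integer(man$positions_per_oligo)
  man$bits_per_composite <- as.integer(man$bits_per_composite)
  man$n_bytes <- as.integer(man$n_bytes)
  man$n_composites <- as.integer(man$n_composites)
  man$replicate_addresses <- isTRUE(man$replicate_addresses)
  seqs <- lapply(obj$sequences, function(s)
    new_logical_sequence(as.integer(s$address_index),
                         lapply(s$composites, function(cm)
                           new_composite_motif(unlist(cm), man$k))))
  structure(list(sequences = seqs, manifest = man),
            class = "encoded_message")
}
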