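# Direct oligonucleotide sequencing, in silico. Nanopore sequencing of short
# oligos without assembly/amplification/end-prep shows a characteristic error
# structure: mixed substitution/insertion/deletion errors with no dominant
# type, heavy truncation ("soft-clip-like") at read ends — worst at the 3'
# end — reads whose signal spans several concatenated molecules, junk reads
# from mis-segmented empty signal, and both strands. The simulator reproduces
# those artifacts on top of an oligo pool and carries exact ground-truth
# provenance for every read.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Sequencing channel parameters
#'
#' Defaults model a high-error short-oligo nanopore channel: ~10% total
#' per-base error split evenly across substitutions, insertions and deletions
#' (3.3% each), heavier 3' than 5' end truncation, half the reads continuing
#' into another molecule, 5% junk reads, and unbiased strand orientation.
#' These magnitudes are calibration choices of the simulator, exposed so the
#' decoder can be stressed across a rate grid.
#'
#' @param p_sub,p_ins,p_del Per-base substitution / insertion / deletion
#'   probabilities.
#' @param p_clip5,p_clip3 Probability a read is truncated at the 5' / 3' end.
#' @param clip5_mean,clip3_mean Mean truncation lengths (nt, geometric).
#' @param p_merge Probability a read continues with another oligo (mean
#'   oligos per read = 1/(1-p_merge)).
#' @param p_junk Fraction of junk reads (random sequence, no provenance).
#' @param p_revcomp Per-molecule strand-flip probability.
#' @param coverage Mean sequencing coverage: expected number of reads
#'   covering each distinct oligo (Poisson per molecule).
#' @param seed RNG seed; identical (pool, params) give byte-identical output.
#' @return A `"channel_params"` list.
#' @export
channel_params <- function(p_sub = 0.033, p_ins = 0.033, p_del = 0.033,
                           p_clip5 = 0.1, clip5_mean = 4,
                           p_clip3 = 0.3, clip3_mean = 8,
                           p_merge = 0.5, p_junk = 0.05, p_revcomp = 0.5,
                           coverage = 20, seed = 1L) {
  p <- list(p_sub = p_sub, p_ins = p_ins, p_del = p_del,
            p_clip5 = p_clip5, clip5_mean = clip5_mean,
            p_clip3 = p_clip3, clip3_mean = clip3_mean,
            p_merge = p_merge, p_junk = p_junk, p_revcomp = p_revcomp,
            coverage = coverage, seed = as.integer(seed))
  probs <- unlist(p[c("p_sub", "p_ins", "p_del", "p_clip5", "p_clip3",
                      "p_merge", "p_junk", "p_revcomp")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p$p_sub + p$p_del >= 1)
    stop("degenerate channel: p_sub + p_del must be < 1")
  if (p$p_merge >= 1) stop("degenerate channel: p_merge must be < 1")
  if (p$coverage <= 0) stop("coverage must be positive")
  structure(p, class = "channel_params")
}

# per-base error channel on one strand-oriented sequence; 0-based op
# positions refer to the input (strand-oriented) coordinates
apply_channel <- function(seq, p_sub, p_ins, p_del) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(bases)
  del <- stats::runif(n) < p_del
  sub <- !del & (stats::runif(n) < p_sub)
  ins <- stats::runif(n) < p_ins
  if (any(sub)) {
    # uniform over the three other bases
    shift <- sample.int(3L, sum(sub), replace = TRUE)
    cur <- match(bases[sub], DNA_ALPHABET)
    bases[sub] <- DNA_ALPHABET[((cur - 1L + shift) %% 4L) + 1L]
  }
  parts <- character(n)
  parts[!del] <- bases[!del]
  insv <- character(n)
  if (any(ins)) insv[ins] <- sample(DNA_ALPHABET, sum(ins), replace = TRUE)
  list(seq = paste0(parts, insv, collapse = ""),
       sub = which(sub) - 1L, ins = which(ins) - 1L, del = which(del) - 1L)
}

#' Simulate nanopore-like reads from an oligo pool
#'
#' Each molecule of the pool is sequenced Poisson(coverage * copies) times.
#' Molecule instances are shuffled and grouped into reads of 1 + Geometric
#' (p_merge) molecules (merged squiggles), each molecule independently
#' strand-flipped and passed through the per-base error channel; read ends
#' are then truncated and junk reads mixed in. Ground-truth provenance
#' intervals (0-based, half-open, post-error coordinates) are attached to
#' every read.
#'
#' @param pool An `"oligo_pool"` from [expand_pool()].
#' @param params A [channel_params()] object.
#' @return A `"sim_reads"` object: `reads` (read_id, sequence), `truth`
#'   (read_id, oligo_id, start, end, strand, clip5, clip3), per-instance
#'   error events, and the parameters.
#' @export
simulate_reads <- function(pool, params) {
  stopifnot(inherits(pool, "oligo_pool"), inherits(params, "channel_params"))
  if (nrow(pool) == 0L) stop("empty oligo pool")
  local_seed(params$seed)

  counts <- stats::rpois(nrow(pool), params$coverage * pool$copies)
  inst <- rep.int(seq_len(nrow(pool)), counts)
  n_inst <- length(inst)
  reads_seq <- character(0)
  truth_rows <- list()
  events <- list()

  if (n_inst > 0L) {
    inst <- inst[sample.int(n_inst)]
    sizes <- 1L + stats::rgeom(n_inst, prob = 1 - params$p_merge)
    read_of <- rep.int(seq_along(sizes), sizes)[seq_len(n_inst)]
    n_reads <- max(read_of)
    reads_seq <- character(n_reads)
    for (r in seq_len(n_reads)) {
      members <- inst[read_of == r]
      offset <- 0L
      segs <- character(length(members))
      for (j in seq_along(members)) {
        row <- members[j]
        flip <- stats::runif(1) < params$p_revcomp
        s <- pool$sequence[row]
        if (flip) s <- revcomp(s)
        ch <- apply_channel(s, params$p_sub, params$p_ins, params$p_del)
        segs[j] <- ch$seq
        len <- nchar(ch$seq)
        truth_rows[[length(truth_rows) + 1L]] <- list(
          read = r, oligo_id = pool$oligo_id[row],
          start = offset, end = offset + len,
          strand = if (flip) "-" else "+")
        events[[length(events) + 1L]] <- list(
          oligo_id = pool$oligo_id[row], strand = if (flip) "-" else "+",
          ref_len = nchar(s), sub = ch$sub, ins = ch$ins, del = ch$del,
          clip5 = 0L, clip3 = 0L)
        offset <- offset + len
      }
      reads_seq[r] <- paste0(segs, collapse = "")
    }

    # end truncation, with truth-coordinate bookkeeping
    truth_read <- vapply(truth_rows, function(t) t$read, 0L)
    for (r in seq_len(n_reads)) {
      L <- nchar(reads_seq[r])
      c5 <- if (stats::runif(1) < params$p_clip5)
        stats::rgeom(1, prob = 1 / (1 + params$clip5_mean)) else 0L
      c3 <- if (stats::runif(1) < params$p_clip3)
        stats::rgeom(1, prob = 1 / (1 + params$clip3_mean)) else 0L
      if (c5 + c3 >= L) { c5 <- min(c5, L); c3 <- L - c5 }
      if (c5 == 0L && c3 == 0L) next
      reads_seq[r] <- substr(reads_seq[r], c5 + 1L, L - c3)
      for (i in which(truth_read == r)) {
        t <- truth_rows[[i]]
        ns <- max(t$start - c5, 0L)
        ne <- min(t$end - c5, L - c5 - c3)
        cut5 <- max(c5 - t$start, 0L)
        cut3 <- max(t$end - (L - c3), 0L)
        truth_rows[[i]]$start <- ns
        truth_rows[[i]]$end <- max(ne, ns)
        events[[i]]$clip5 <- min(cut5, t$end - t$start)
        events[[i]]$clip3 <- min(cut3, t$end - t$start)
      }
    }
  }

  # junk reads: mis-segmented empty signal basecalled as short random reads
  n_reads <- length(reads_seq)
  n_junk <- if (params$p_junk > 0 && n_reads > 0L)
    stats::rpois(1, params$p_junk / (1 - params$p_junk) * n_reads) else 0L
  junk_seq <- vapply(seq_len(n_junk), function(i)
    random_dna(sample(15:80, 1L)), "")

  all_seq <- c(reads_seq, junk_seq)
  ord <- sample.int(length(all_seq))
  ids <- sprintf("read_%06d", seq_along(all_seq))
  new_index <- match(seq_along(all_seq), ord)  # original -> shuffled slot

  truth <- if (length(truth_rows) > 0L) data.frame(
    read_id = ids[new_index[vapply(truth_rows, function(t) t$read, 0L)]],
    oligo_id = vapply(truth_rows, function(t) t$oligo_id, ""),
    start = vapply(truth_rows, function(t) t$start, 0L),
    end = vapply(truth_rows, function(t) t$end, 0L),
    strand = vapply(truth_rows, function(t) t$strand, ""),
    stringsAsFactors = FALSE)
  else data.frame(read_id = character(0), oligo_id = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), stringsAsFactors = FALSE)
  truth <- truth[truth$end > truth$start | nchar(truth$oligo_id) == 0L, ,
                 drop = FALSE]

  reads <- data.frame(read_id = ids, sequence = all_seq[ord],
                      stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth, events = events,
                 params = params,
                 pool_checksum = attr(pool, "library_checksum")),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  lens <- nchar(x$reads$sequence)
  cat("<simulated reads> ", nrow(x$reads), " reads (",
      nrow(x$truth), " truth intervals over ",
      length(unique(x$truth$oligo_id)), " oligos); median length ",
      stats::median(lens), " nt\n", sep = "")
  invisible(x)
}

#' Realized per-position error profile
#'
#' Aggregates the simulator's recorded per-molecule error events into
#' substitution / insertion / deletion / clip rates per reference position
#' (position within the oligo, 5' to 3' on the reference strand), the
#' standard per-position view of a sequencing channel. No aligner is
#' involved: the simulator's ground truth is used directly.
#'
#' @param reads A `"sim_reads"` object.
#' @return Data frame: position, n (instances covering), sub, ins, del, clip
#'   rates.
#' @export
channel_stats <- function(reads) {
  stopifnot(inherits(reads, "sim_reads"))
  if (length(reads$events) == 0L) stop("reads carry no truth provenance")
  L <- max(vapply(reads$events, function(e) e$ref_len, 0L))
  n <- sub <- ins <- del <- clip <- numeric(L)
  for (e in reads$events) {
    pos <- seq_len(e$ref_len)
    n[pos] <- n[pos] + 1
    to_ref <- function(p) if (e$strand == "+") p + 1L else e$ref_len - p
    if (length(e$sub)) { i <- to_ref(e$sub); sub[i] <- sub[i] + 1 }
    if (length(e$ins)) { i <- to_ref(e$ins); ins[i] <- ins[i] + 1 }
    if (length(e$del)) { i <- to_ref(e$del); del[i] <- del[i] + 1 }
    # end truncation maps approximately onto reference ends
    cf <- if (e$strand == "+") e$clip5 else e$clip3
    cb <- if (e$strand == "+") e$clip3 else e$clip5
    if (cf > 0) clip[seq_len(min(cf, e$ref_len))] <-
        clip[seq_len(min(cf, e$ref_len))] + 1
    if (cb > 0) clip[(e$ref_len - min(cb, e$ref_len) + 1L):e$ref_len] <-
        clip[(e$ref_len - min(cb, e$ref_len) + 1L):e$ref_len] + 1
  }
  n[n == 0] <- NA
  data.frame(position = seq_len(L) - 1L, n = n,
             sub = sub / n, ins = ins / n, del = del / n, clip = clip / n)
}

#' Subsample reads to a lower effective coverage
#'
#' Keeps a seeded uniform fraction of the reads (truth follows), the standard
#' way of studying recovery as a function of sequencing coverage.
#'
#' @param reads A `"sim_reads"` object.
#' @param fraction Fraction of reads to keep, in (0, 1].
#' @param seed RNG seed.
#' @return A `"sim_reads"` object with the retained subset.
#' @export
subsample_reads <- function(reads, fraction, seed = 1L) {
  stopifnot(inherits(reads, "sim_reads"), fraction > 0, fraction <= 1)
  if (fraction == 1) return(reads)
  local_seed(seed)
  keep <- sort(sample.int(nrow(reads$reads),
                          round(fraction * nrow(reads$reads))))
  kept_ids <- reads$reads$read_id[keep]
  out <- reads
  out$reads <- reads$reads[keep, , drop = FALSE]
  out$truth <- reads$truth[reads$truth$read_id %in% kept_ids, , drop = FALSE]
  rownames(out$reads) <- rownames(out$truth) <- NULL
  out
}

#' Write simulated reads as FASTQ (constant Q12) and truth as TSV
#'
#' @param reads A `"sim_reads"` object.
#' @param fastq,truth_tsv Output paths (either may be NULL to skip).
#' @export
write_reads <- function(reads, fastq = NULL, truth_tsv = NULL) {
  stopifnot(inherits(reads, "sim_reads"))
  if (!is.null(fastq)) {
    ss <- Biostrings::DNAStringSet(stats::setNames(reads$reads$sequence,
                                                   reads$reads$read_id))
    qual <- Biostrings::PhredQuality(strrep("-", nchar(reads$reads$sequence)))
    qss <- Biostrings::QualityScaledDNAStringSet(ss, qual)
    Biostrings::writeQualityScaledXStringSet(qss, fastq)
  }
  if (!is.null(truth_tsv))
    utils::write.table(reads$truth, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(reads)
}

#' Read basecalled reads from FASTQ or FASTA
#'
#' @param path Input file; format inferred from the extension.
#' @return Data frame (read_id, sequence) usable by [infer_reads()].
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  data.frame(read_id = sub("\\s.*$", "", names(ss)),
             sequence = as.character(ss), stringsAsFactors = FALSE,
             row.names = NULL)
}
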