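# Pipeline workspace: run configuration, derived per-stage seeds, and the
# encode / simulate / decode / evaluate entry points that tie the modules
# together and write their artifacts. A thin command-line wrapper around
# these functions ships as inst/cli/motifstore.R.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "motifstore_run",
    message = "HelloWorld",
    library = list(n_address = 8L, n_payload = 96L, motif_length = 25L,
                   min_edit_distance = 9L),
    codec = list(m = 96L, k = 32L, positions_per_oligo = 1L,
                 replicate_addresses = TRUE),
    channel = list(p_sub = 0.033, p_ins = 0.033, p_del = 0.033,
                   p_clip5 = 0.1, clip5_mean = 4, p_clip3 = 0.3,
                   clip3_mean = 8, p_merge = 0.5, p_junk = 0.05,
                   p_revcomp = 0.5, coverage = 20),
    search = list(),
    evaluate = list(coverages = c(7, 14, 20, 27, 34)))
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration (or takes a list), fills defaults, and
#' validates the schema. Every stochastic stage receives a sub-seed derived
#' from the global seed and the stage name, so stages are independently
#' reproducible.
#'
#' @param config Path to a YAML/JSON file, a list, or NULL for defaults.
#' @return A validated `"run_config"` list.
#' @export
run_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_config(), config)
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  cfg$seed <- as.integer(cfg$seed)
  with(cfg$codec, stopifnot(m >= 1, k >= 1, k <= m))
  if (cfg$codec$m > cfg$library$n_payload)
    stop("codec m exceeds library payload count")
  structure(cfg, class = "run_config")
}

cfg_library <- function(cfg) {
  if (!is.null(cfg$library$dir)) return(read_library(cfg$library$dir))
  generate_library(cfg$library$n_address, cfg$library$n_payload,
                   motif_length = cfg$library$motif_length,
                   min_edit_distance = cfg$library$min_edit_distance,
                   seed = derive_seed(cfg$seed, "library"))
}

cfg_channel <- function(cfg) {
  args <- cfg$channel
  args$seed <- derive_seed(cfg$seed, "simulate")
  do.call(channel_params, args)
}

cfg_search <- function(cfg, lib, positions = cfg$codec$positions_per_oligo) {
  args <- cfg$search
  args$lib <- lib
  args$positions <- positions
  if (is.null(args$seed)) args$seed <- derive_seed(cfg$seed, "embed")
  do.call(search_params, args)
}

#' Encode stage: data to logical sequences on disk
#'
#' Builds (or loads) the motif library, encodes the configured message, and
#' writes the library, the logical sequences and the manifest under the
#' configured output directory.
#'
#' @param config Anything [run_config()] accepts.
#' @return Invisibly, a list with the library, encoded message and paths.
#' @export
cmd_encode <- function(config = NULL) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  lib <- cfg_library(cfg)
  params <- codec_params(cfg$codec$m, cfg$codec$k,
                         cfg$codec$positions_per_oligo)
  enc <- encode_data(cfg$message, params, lib,
                     replicate_addresses = isTRUE(cfg$codec$replicate_addresses))
  write_library(lib, file.path(cfg$out_dir, "library"))
  write_logical_sequences(enc, file.path(cfg$out_dir, "logical_sequences.json"))
  invisible(list(lib = lib, encoded = enc,
                 paths = list(library = file.path(cfg$out_dir, "library"),
                              sequences = file.path(cfg$out_dir,
                                                    "logical_sequences.json"))))
}

#' Simulate stage: oligo pool and noisy reads on disk
#'
#' Expands the encoded logical sequences into the oligo pool (cartesian) and
#' simulates the sequencing channel, writing pool FASTA/TSV, reads FASTQ and
#' ground-truth TSV.
#'
#' @param config Anything [run_config()] accepts.
#' @return Invisibly, a list with the pool, reads and paths.
#' @export
cmd_simulate <- function(config = NULL) {
  cfg <- run_config(config)
  st <- cmd_encode(cfg)
  pool <- expand_pool(st$encoded, st$lib)
  reads <- simulate_reads(pool, cfg_channel(cfg))
  write_pool(pool, fasta = file.path(cfg$out_dir, "pool.fasta"),
             tsv = file.path(cfg$out_dir, "pool.tsv"))
  write_reads(reads, fastq = file.path(cfg$out_dir, "reads.fastq"),
              truth_tsv = file.path(cfg$out_dir, "truth.tsv"))
  invisible(list(lib = st$lib, encoded = st$encoded, pool = pool,
                 reads = reads))
}

#' Decode stage: recovered bytes and reports on disk
#'
#' Runs Motif-Search over the simulated reads, writes the inferred-oligo
#' TSV, the consensus JSON and the recovered bytes.
#'
#' @param config Anything [run_config()] accepts.
#' @return Invisibly, the decode result (bytes, consensus, inferred,
#'   recovery_failed) plus an `exact` flag against the configured message.
#' @export
cmd_decode <- function(config = NULL) {
  cfg <- run_config(config)
  st <- cmd_simulate(cfg)
  man <- st$encoded$manifest
  n_blocks <- ceiling(man$n_composites / man$positions_per_oligo)
  block_pos <- rep(man$positions_per_oligo, n_blocks)
  block_pos[n_blocks] <- man$n_composites -
    man$positions_per_oligo * (n_blocks - 1L)
  res <- decode_from_reads(st$reads, st$lib, man,
                           cfg_search(cfg, st$lib,
                                      positions = unique(block_pos)))
  utils::write.table(res$inferred, file.path(cfg$out_dir, "inferred.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- consensus_sequences(res$consensus)
  jsonlite::write_json(lapply(seqs, function(s)
    list(address_index = s$address_index,
         composites = lapply(s$composites, as.integer))),
    file.path(cfg$out_dir, "consensus.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$bytes))
    writeBin(res$bytes, file.path(cfg$out_dir, "recovered.bin"))
  res$exact <- !is.null(res$bytes) &&
    identical(res$bytes, charToRaw(cfg$message))
  invisible(res)
}

#' Evaluate stage: recovery-versus-coverage table on disk
#'
#' Runs the full write pipeline once, then decodes over the configured
#' coverage grid by subsampling reads, reporting TP/FP/FN per coverage.
#'
#' @param config Anything [run_config()] accepts.
#' @return The recovery table (also written as recovery.tsv).
#' @export
cmd_evaluate <- function(config = NULL) {
  cfg <- run_config(config)
  st <- cmd_encode(cfg)
  pool <- expand_pool(st$encoded, st$lib)
  tab <- recovery_curve(pool, st$lib, cfg_channel(cfg),
                        cfg$evaluate$coverages,
                        sparams = cfg_search(cfg, st$lib),
                        k = cfg$codec$k,
                        seed = derive_seed(cfg$seed, "subsample"))
  utils::write.table(tab, file.path(cfg$out_dir, "recovery.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
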