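# Sequencing-channel simulator: determinism, conservation, realized error
# rates, merged-read length structure, per-position statistics.

test_that("a noiseless channel at unit coverage emits exact oligo copies", {
  pool <- fixture_pool()
  ch <- channel_params(p_sub = 0, p_ins = 0, p_del = 0, p_clip5 = 0,
                       p_clip3 = 0, p_merge = 0, p_junk = 0, p_revcomp = 0,
                       coverage = 2, seed = 3)
  reads <- simulate_reads(pool, ch)
  expect_true(all(reads$reads$sequence %in% pool$sequence))
  expect_identical(nrow(reads$truth), nrow(reads$reads))
  expect_true(all(reads$truth$strand == "+"))
  st <- channel_stats(reads)
  expect_true(all(st$sub == 0 & st$ins == 0 & st$del == 0 & st$clip == 0))
})

test_that("simulation is byte-for-byte reproducible for a fixed seed", {
  pool <- fixture_pool()
  ch <- channel_params(coverage = 3, seed = 11)
  r1 <- simulate_reads(pool, ch)
  r2 <- simulate_reads(pool, ch)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_reads(r1, fastq = f1)
  write_reads(r2, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  r3 <- simulate_reads(pool, channel_params(coverage = 3, seed = 12))
  expect_false(identical(r1$reads, r3$reads))
})

test_that("truth intervals are ordered, in bounds, and reference real oligos", {
  pool <- fixture_pool()
  reads <- simulate_reads(pool, channel_params(coverage = 4, seed = 21))
  expect_true(all(reads$truth$oligo_id %in% pool$oligo_id))
  lens <- nchar(reads$reads$sequence)
  names(lens) <- reads$reads$read_id
  expect_true(all(reads$truth$start >= 0))
  expect_true(all(reads$truth$end <= lens[reads$truth$read_id]))
  expect_true(all(reads$truth$end > reads$truth$start))
  by_read <- split(reads$truth, reads$truth$read_id)
  overlaps <- vapply(by_read, function(tr) {
    tr <- tr[order(tr$start), ]
    nrow(tr) > 1 && any(tr$start[-1] < tr$end[-nrow(tr)])
  }, TRUE)
  expect_false(any(overlaps))
})

test_that("per-oligo read counts are Poisson(coverage) to chi-square sanity", {
  pool <- fixture_pool()
  cov <- 10
  reads <- simulate_reads(pool, channel_params(
    p_clip5 = 0, p_clip3 = 0, coverage = cov, seed = 31))
  counts <- table(factor(reads$truth$oligo_id, levels = pool$oligo_id))
  # mean close to coverage
  expect_lt(abs(mean(counts) - cov), 3 * sqrt(cov / nrow(pool)))
  # dispersion consistent with Poisson
  disp <- stats::var(as.numeric(counts)) / mean(counts)
  expect_gt(disp, 0.7)
  expect_lt(disp, 1.4)
})

test_that("realized per-base error rates match the nominal channel", {
  lib <- fixture_library()
  pool <- fixture_pool()
  p <- 0.03
  reads <- simulate_reads(pool, channel_params(
    p_sub = p, p_ins = p, p_del = p, p_clip5 = 0, p_clip3 = 0,
    p_merge = 0, p_junk = 0, coverage = 6, seed = 41))
  n_bases <- sum(vapply(reads$events, function(e) e$ref_len, 0L))
  expect_gt(n_bases, 1e5)
  tol <- 3 * sqrt(p * (1 - p) / n_bases)
  for (op in c("sub", "ins", "del")) {
    rate <- sum(vapply(reads$events, function(e) length(e[[op]]), 0L)) / n_bases
    expect_lt(abs(rate - p), tol)
  }
  # substitution-only channel: per-position profile shows no indels
  sub_only <- simulate_reads(pool, channel_params(
    p_sub = 0.05, p_ins = 0, p_del = 0, p_clip5 = 0, p_clip3 = 0,
    coverage = 2, seed = 42))
  st <- channel_stats(sub_only)
  expect_true(all(st$ins == 0 & st$del == 0))
  expect_gt(mean(st$sub), 0.02)
})

test_that("merged reads make the length distribution long-tailed", {
  pool <- fixture_pool()
  merged <- simulate_reads(pool, channel_params(
    p_merge = 0.5, p_junk = 0, coverage = 6, seed = 51))
  solo <- simulate_reads(pool, channel_params(
    p_merge = 0, p_junk = 0, coverage = 6, seed = 51))
  oligo_len <- nchar(pool$sequence[1])
  per_read <- table(merged$truth$read_id)
  expect_gt(mean(per_read), 1.6)   # ~2 molecules per read at p_merge = 0.5
  expect_lt(mean(per_read), 2.6)
  # more than half of merged reads exceed the single-oligo length
  expect_gt(mean(nchar(merged$reads$sequence) > oligo_len), 0.4)
  expect_lt(stats::median(nchar(solo$reads$sequence)), oligo_len + 1)
})

test_that("junk reads carry no provenance and appear at the configured rate", {
  pool <- fixture_pool()
  reads <- simulate_reads(pool, channel_params(
    p_junk = 0.2, coverage = 8, seed = 61))
  junk <- setdiff(reads$reads$read_id, reads$truth$read_id)
  frac <- length(junk) / nrow(reads$reads)
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.3)
})

test_that("3' clipping is heavier than 5' under the default end model", {
  pool <- fixture_pool()
  reads <- simulate_reads(pool, channel_params(
    p_merge = 0, p_junk = 0, coverage = 6, seed = 71))
  st <- channel_stats(reads)
  L <- nrow(st)
  expect_gt(mean(st$clip[(L - 4):L]), mean(st$clip[1:5]))
})

test_that("degenerate channels are rejected", {
  expect_error(channel_params(p_sub = 0.7, p_del = 0.5), "degenerate")
  expect_error(channel_params(p_merge = 1), "degenerate")
  expect_error(channel_params(p_sub = 1.2), "probabilities")
  expect_error(channel_params(coverage = 0), "coverage")
})

test_that("FASTQ output round trips through a standard reader", {
  pool <- fixture_pool()
  reads <- simulate_reads(pool, channel_params(coverage = 1, seed = 81))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads(reads, fastq = fq)
  back <- read_reads(fq)
  expect_identical(back$read_id, reads$reads$read_id)
  expect_identical(back$sequence, reads$reads$sequence)
})

test_that("subsampling keeps a seeded fraction with matching truth", {
  pool <- fixture_pool()
  reads <- simulate_reads(pool, channel_params(coverage = 6, seed = 91))
  sub <- subsample_reads(reads, 0.25, seed = 5)
  expect_equal(nrow(sub$reads), round(0.25 * nrow(reads$reads)))
  expect_true(all(sub$truth$read_id %in% sub$reads$read_id))
  sub2 <- subsample_reads(reads, 0.25, seed = 5)
  expect_identical(sub$reads, sub2$reads)
})
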