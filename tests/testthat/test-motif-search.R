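# Motif-Search decoder: segmentation, refinement, chaining, mapping,
# overlap resolution, consensus — each against an independent oracle where
# the contract admits one.

test_that("spacer index holds every k-mer of the spacer", {
  lib <- fixture_library()
  idx <- spacer_index(lib$spacer, 4)
  expect_identical(sum(lengths(idx$table)), 22L)  # 25 - 4 + 1
  expect_true(all(nchar(names(idx$table)) == 4))
})

test_that("segmentation finds exact spacer starts on clean reads", {
  lib <- fixture_library()
  idx <- spacer_index(lib$spacer, 4)
  read <- paste0(lib$address[[4]], lib$spacer, lib$payload[[18]])
  cand <- find_spacer_candidates(read, idx)
  expect_identical(cand$position, 25L)
  expect_identical(cand$votes, 22L)

  # string-search oracle across the whole clean pool
  pool <- fixture_pool()
  for (i in seq(1, 256, by = 37)) {
    truth <- as.integer(gregexpr(lib$spacer, pool$sequence[i],
                                 fixed = TRUE)[[1]]) - 1L
    cand <- find_spacer_candidates(pool$sequence[i], idx)
    expect_identical(cand$position, truth)
  }
})

test_that("one substitution in the spacer still clears the vote threshold", {
  lib <- fixture_library()
  idx <- spacer_index(lib$spacer, 4)
  sp <- lib$spacer
  substr(sp, 13, 13) <- setdiff(c("A", "C", "G", "T"), substr(sp, 13, 13))[1]
  read <- paste0(lib$address[[1]], sp, lib$payload[[1]])
  cand <- find_spacer_candidates(read, idx)
  expect_identical(cand$position, 25L)
  expect_gte(cand$votes, 18L)  # one substitution kills at most 4 of 22 votes
})

test_that("random reads essentially never produce spurious candidates", {
  lib <- fixture_library()
  idx <- spacer_index(lib$spacer, 4)
  set.seed(99)
  n_cand <- 0L
  for (i in 1:300) {
    read <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
    n_cand <- n_cand + nrow(find_spacer_candidates(read, idx))
  }
  expect_lte(n_cand, 3L)  # expected spurious votes per position << threshold
})

test_that("embedding-based refinement agrees with the edit-distance oracle", {
  lib <- fixture_library()
  params <- search_params(lib, seed = 42)
  # clean window refines to shift 0
  read <- paste0(lib$address[[1]], lib$spacer, lib$payload[[1]])
  expect_identical(refine_position(read, 25L, lib$spacer, params)$position,
                   25L)
  # single-indel cases: refined shift must match the argmin over shifts of
  # the exact edit distance >= 90% of the time
  set.seed(7)
  agree <- 0L
  n_cases <- 200L
  for (i in seq_len(n_cases)) {
    mut <- mutate_seq(lib$spacer, 1)
    read <- paste0(lib$address[[1 + i %% 8]], mut, lib$payload[[1 + i %% 96]])
    cand <- 25L + sample(-2:2, 1)  # jittered candidate, as after voting
    ref <- refine_position(read, cand, lib$spacer, params)
    oracle_d <- vapply(-3:3, function(s) {
      win <- substr(read, cand + s + 1, cand + s + 25)
      edit_dist(win, lib$spacer)
    }, 0L)
    best_shifts <- (-3:3)[oracle_d == min(oracle_d)]
    agree <- agree + as.integer((ref$position - cand) %in% best_shifts)
  }
  expect_gte(agree / n_cases, 0.9)
})

test_that("chain building respects the inter-spacer period", {
  expect_identical(build_chains(25L, M = 2, d = 50), list(25L))
  expect_identical(build_chains(c(25L, 75L, 125L), M = 4, d = 50,
                                tolerance = 5),
                   list(c(25L, 75L, 125L)))
  # exhaustive-enumeration oracle on an out-of-tolerance middle position
  expect_length(build_chains(c(25L, 70L, 125L), M = 4, d = 50,
                             tolerance = 2), 0)
  # M = 2 degenerates to singletons
  expect_identical(build_chains(c(10L, 90L), M = 2, d = 50),
                   list(10L, 90L))
})

test_that("mapping calls the true motif and scores with exact-DP agreement", {
  lib <- fixture_library()
  params <- search_params(lib)
  read <- paste0(lib$address[[4]], lib$spacer, lib$payload[[18]])
  inf <- infer_read(read, lib, params, "clean")
  expect_identical(inf$address_index, 3L)
  expect_identical(inf$payloads, "17")
  expect_identical(inf$score, 2 * 25 + 2 * 25)  # two perfect 25-mers at +2

  # two substitutions: still called, score down 2 x 6 from perfect
  mut <- lib$payload[[18]]
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mut, 5, 5))[1]
  substr(mut, 15, 15) <- setdiff(c("A", "C", "G", "T"), substr(mut, 15, 15))[1]
  read2 <- paste0(lib$address[[4]], lib$spacer, mut)
  inf2 <- infer_read(read2, lib, params, "mut")
  expect_identical(inf2$payloads, "17")
  expect_identical(inf2$score, 100 - 12)
})

test_that("alignment scores agree with an independent aligner", {
  lib <- fixture_library()
  set.seed(13)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  for (i in 1:20) {
    win <- mutate_seq(lib$payload[[i]], sample(0:3, 1))
    ours <- motifstore:::C_align_score_many(win, lib$payload[1:10],
                                            2L, -4L, 4L, 2L)
    theirs <- vapply(1:10, function(j) as.integer(Biostrings::pairwiseAlignment(
      win, lib$payload[[j]], type = "local", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 2, scoreOnly = TRUE)), 0L)
    expect_identical(as.integer(ours), theirs)
  }
})

test_that("motif calls agree with brute-force edit distance at <= 3 edits", {
  lib <- fixture_library()
  set.seed(23)
  n <- 400L
  agree <- 0L
  for (i in seq_len(n)) {
    true_idx <- sample(96, 1)
    win <- mutate_seq(lib$payload[[true_idx]], sample(0:3, 1))
    scores <- motifstore:::C_align_score_many(win, lib$payload,
                                              2L, -4L, 4L, 2L)
    call <- which.max(scores)
    oracle <- which.min(utils::adist(win, lib$payload))
    agree <- agree + as.integer(call == oracle)
  }
  expect_gte(agree / n, 0.995)
})

test_that("random windows are rejected by the score threshold", {
  lib <- fixture_library()
  params <- search_params(lib)
  set.seed(33)
  rejected <- 0L
  n <- 300L
  for (i in seq_len(n)) {
    win <- paste(sample(c("A", "C", "G", "T"), 33, replace = TRUE),
                 collapse = "")
    best <- max(motifstore:::C_align_score_many(win, lib$payload,
                                                2L, -4L, 4L, 2L))
    rejected <- rejected + as.integer(best < 0.6 * 50)
  }
  expect_gte(rejected / n, 0.99)
})

test_that("overlap resolution is greedy by score with no surviving overlap", {
  mk <- function(start, end, score) structure(
    list(spacer_positions = start + 25L,
         calls = data.frame(role = "address", index = 0L, score = score),
         total_score = score, span = c(start, end), rejected = FALSE),
    class = "motif_chain")
  # disjoint chains are both kept
  kept <- resolve_overlaps(list(mk(0, 75, 90), mk(80, 155, 85)))
  expect_length(kept, 2)
  # overlapping chains: higher score wins
  kept2 <- resolve_overlaps(list(mk(0, 80, 90), mk(60, 140, 100)))
  expect_length(kept2, 1)
  expect_identical(kept2[[1]]$total_score, 100)
  # documented greedy-vs-optimal divergence: A(0-80,90) B(60-140,100)
  # C(120-200,90); greedy keeps only B although {A,C} scores 180
  kept3 <- resolve_overlaps(list(mk(0, 80, 90), mk(60, 140, 100),
                                 mk(120, 200, 90)))
  expect_length(kept3, 1)
  expect_identical(kept3[[1]]$total_score, 100)
  # brute-force max-weight non-overlapping subset oracle, for the record
  combos <- list(1L, 2L, 3L, c(1L, 3L))
  weights <- c(90, 100, 90, 180)
  expect_identical(max(weights), 180)  # optimum differs from greedy here
})

test_that("kept chains never overlap across a noisy decoding run", {
  lib <- fixture_library()
  pool <- fixture_pool()
  reads <- simulate_reads(pool, channel_params(coverage = 2, seed = 17))
  params <- search_params(lib)
  idx <- spacer_index(lib$spacer, params$k)
  for (i in seq_len(min(nrow(reads$reads), 150))) {
    seq <- reads$reads$sequence[i]
    if (nchar(seq) < 4) next
    cand <- find_spacer_candidates(seq, idx)
    if (nrow(cand) == 0) next
    refined <- unique(vapply(cand$position, function(p)
      refine_position(seq, p, lib$spacer, params)$position, 0))
    chains <- lapply(build_chains(refined, 2L, params$d),
                     function(sp) motifstore:::map_chain(seq, sp, lib, params))
    kept <- resolve_overlaps(chains)
    if (length(kept) > 1) {
      spans <- t(vapply(kept, function(ch) ch$span, c(0, 0)))
      expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
    }
  }
})

test_that("merged reads yield one inferred oligo per molecule", {
  lib <- fixture_library()
  pool <- fixture_pool()
  params <- search_params(lib)
  read <- paste0(pool$sequence[10], pool$sequence[200])
  inf <- infer_read(read, lib, params, "merged")
  expect_identical(nrow(inf), 2L)
  expect_identical(sprintf("oligo_A%d_P%s", inf$address_index, inf$payloads),
                   pool$oligo_id[c(10, 200)])
})

test_that("decoding is strand symmetric and robust to junk", {
  lib <- fixture_library()
  pool <- fixture_pool()
  params <- search_params(lib)
  fwd <- infer_read(pool$sequence[42], lib, params, "f")
  rev <- infer_read(motifstore:::revcomp(pool$sequence[42]), lib, params, "r")
  expect_identical(fwd$address_index, rev$address_index)
  expect_identical(fwd$payloads, rev$payloads)
  expect_identical(rev$strand, "-")
  expect_identical(nrow(infer_read("", lib, params, "empty")), 0L)
  set.seed(3)
  junk <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  expect_identical(nrow(infer_read(junk, lib, params, "junk")), 0L)
})

test_that("consensus selects top-k motifs by support with tie rules", {
  # seven inferred oligos on one address, three positions, k = 2; the
  # support table makes {0,1}, {11,12}, {20,22} the per-position top-2 sets
  inf <- data.frame(
    read_id = sprintf("r%d", 1:7), strand = "+", address_index = 0L,
    payloads = c("0,11,20", "0,12,22", "1,11,20", "1,12,22",
                 "0,11,22", "1,12,20", "3,11,22"),
    score = 100, stringsAsFactors = FALSE)
  cons <- call_consensus(inf, k = 2, positions = 3, min_support = 2)
  a <- cons$addresses[["0"]]
  expect_false(a$recovery_failed)
  expect_identical(as.integer(a$composites[[1]]), c(0L, 1L))
  expect_identical(as.integer(a$composites[[2]]), c(11L, 12L))
  expect_identical(as.integer(a$composites[[3]]), c(20L, 22L))
  # the support-1 stray motif (index 3 at position 1) is excluded
  tab <- a$positions[[1]]
  expect_identical(tab$support[tab$motif == 3], 1L)

  # a wrong call with support 1 cannot displace true motifs with support 2
  inf2 <- data.frame(read_id = sprintf("r%d", 1:5), strand = "+",
                     address_index = 1L,
                     payloads = c("4", "4", "9", "9", "77"),
                     score = 100, stringsAsFactors = FALSE)
  cons2 <- call_consensus(inf2, k = 2, positions = 1, min_support = 2)
  expect_identical(as.integer(cons2$addresses[["1"]]$composites[[1]]),
                   c(4L, 9L))

  # too few supported motifs flags the address
  cons3 <- call_consensus(inf2, k = 3, positions = 1, min_support = 2)
  expect_true(cons3$addresses[["1"]]$recovery_failed)
})

test_that("error-free end-to-end recovery returns the exact bytes", {
  lib <- fixture_library()
  enc <- fixture_message(lib)
  pool <- expand_pool(enc, lib)
  ch <- channel_params(p_sub = 0, p_ins = 0, p_del = 0, p_clip5 = 0,
                       p_clip3 = 0, p_merge = 0, p_junk = 0, p_revcomp = 0,
                       coverage = 8, seed = 7)
  reads <- simulate_reads(pool, ch)
  res <- decode_from_reads(reads, lib, enc$manifest)
  expect_identical(rawToChar(res$bytes), "HelloWorld")
  ev <- evaluate_recovery(res$consensus, pool)
  expect_identical(ev$tp, 256L)
  expect_identical(ev$fp, 0L)
  expect_identical(ev$fn, 0L)
})
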