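# Minimizer / chain / banded-extend aligner, checked against brute-force
# window minima and the quadratic-DP oracle.

test_that("minimizer selection matches brute-force window minima", {
  withr::local_seed(11)
  seq <- random_dna(2000)
  k <- 15L; w <- 10L
  mz <- minimizers(seq, k, w)
  # brute force: hash every k-mer (via w = 1), then scan windows
  all_k <- minimizers(seq, k, 1L)
  expect_equal(nrow(all_k), length(gregexpr("N", seq)[[1]]) * 0 +
                 sum(!duplicated(all_k$pos)))
  brute <- integer(0)
  for (i in seq_len(nrow(all_k) - w + 1)) {
    win <- all_k[i:(i + w - 1), ]
    brute <- c(brute, win$pos[win$hash == min(win$hash)])
  }
  expect_setequal(mz$pos, unique(brute))
  dens <- nrow(mz) / nchar(seq)
  expect_gte(dens, 0.5 / w)
  expect_lte(dens, 2 / w)
})

test_that("minimizers are strand-canonical", {
  withr::local_seed(3)
  seq <- random_dna(500)
  a <- minimizers(seq, 15, 5)
  b <- minimizers(revcomp(seq), 15, 5)
  expect_setequal(a$hash, b$hash)
})

test_that("chaining finds exact matches and rejects outliers", {
  withr::local_seed(4)
  ref <- random_dna(8000)
  q <- substr(ref, 2001, 7000) # exact 5 kb substring
  mzq <- minimizers(q, 15, 10)
  mzr <- minimizers(ref, 15, 10)
  anchors <- dplyr::inner_join(mzq, mzr, by = "hash",
                               suffix = c("_q", "_r"),
                               relationship = "many-to-many")
  ch <- chain_anchors(tibble::tibble(q_pos = anchors$pos_q,
                                     t_pos = anchors$pos_r))
  expect_equal(length(unique(ch$chain)), 1)
  cc <- ch[ch$chain == 1, ]
  expect_lt(min(cc$t_pos), 2100)
  expect_gt(max(cc$t_pos), 6800)
  # exhaustive best-chain oracle on a small anchor set with one outlier
  set.seed(9)
  qp <- sort(sample(1000, 12)); tp <- qp + 500
  qp <- c(qp, 400L); tp <- c(tp, 5000L) # off-diagonal outlier
  ch2 <- chain_anchors(tibble::tibble(q_pos = qp, t_pos = tp),
                       min_chain_score = 10)
  best <- ch2[ch2$chain == 1, ]
  expect_false(5000 %in% best$t_pos)
  # independent exact DP (unbounded lookback) reproduces the chain score
  oracle_chain_score <- function(qp, tp, k = 15, max_gap = 5000) {
    ord <- order(tp, qp); qp <- qp[ord]; tp <- tp[ord]
    f <- rep(k, length(qp))
    for (i in seq_along(qp)) for (j in seq_len(max(0, i - 1))) {
      dq <- qp[i] - qp[j]; dt <- tp[i] - tp[j]
      if (dq <= 0 || dt <= 0 || dq > max_gap || dt > max_gap) next
      gap <- abs(dq - dt)
      cost <- 0.5 * gap + ifelse(gap > 0, 0.5 * log2(gap + 1), 0)
      f[i] <- max(f[i], f[j] + min(k, dq, dt) - cost)
    }
    max(f)
  }
  expect_equal(best$chain_score[1], oracle_chain_score(qp, tp))
})

test_that("banded global alignment equals the quadratic-DP oracle", {
  # identical sequences
  withr::local_seed(5)
  s <- random_dna(2000)
  a <- extend_align(s, s)
  expect_identical(a$cigar, "2000M")
  expect_equal(a$identity, 1)
  expect_equal(a$score, 2000)
  # a single internal 3 bp deletion in the target appears as one 3 bp gap
  t3 <- paste0(substr(s, 1, 1000), substring(s, 1004))
  a3 <- extend_align(s, t3)
  co <- poreclone:::cigar_ops(a3$cigar)
  expect_equal(sum(co$op == "I"), 1)
  expect_equal(co$len[co$op == "I"], 3)
  # score equality on random pairs up to 300 bp when the band covers all
  for (i in 1:15) {
    set.seed(100 + i)
    q <- random_dna(sample(40:300, 1)); t <- random_dna(sample(40:300, 1))
    mine <- extend_align(q, t, band = 350)
    expect_equal(mine$score, Biostrings::score(oracle_align(q, t)))
  }
})

test_that("chain-guided extension matches the oracle on corrupted reads", {
  withr::local_seed(6)
  t <- random_dna(5000)
  q <- poreclone:::cpp_mutate(t, 0.06, 0.02, 0.02, 1) # ~10% corruption
  aln <- map_read(q, c(ref = t), preset = "long", max_extended = 1L)
  expect_equal(nrow(aln) >= 1, TRUE)
  oid <- oracle_identity(q, t)
  expect_lt(abs(aln$identity[1] - oid), 0.02)
})

test_that("mapping is strand symmetric and covers full-length reads", {
  withr::local_seed(7)
  refs <- c(a = random_dna(10000), b = random_dna(10000))
  q <- substr(refs[["a"]], 2001, 6000)
  fwd <- map_read(q, refs, preset = "long")
  rev <- map_read(revcomp(q), refs, preset = "long")
  expect_identical(fwd$target_id[1], "a")
  expect_identical(rev$target_id[1], "a")
  expect_identical(fwd$strand[1], "+")
  expect_identical(rev$strand[1], "-")
  expect_equal(fwd$t_start[1], rev$t_start[1], tolerance = 1e-9)
  expect_equal(fwd$t_end[1], rev$t_end[1])
  expect_equal(fwd$score[1], rev$score[1])
  # zero-error full read covers >= 99% of itself
  cov <- (fwd$q_end[1] - fwd$q_start[1]) / nchar(q)
  expect_gte(cov, 0.99)
})

test_that("CIGAR lengths reconstruct the alignment intervals (fuzz)", {
  pool <- desk_pool(2, seed = 23)
  reads <- simulate_nanopore_run(pool, 25, seed = 6)
  drafts <- pool_drafts(pool)
  aln <- map_reads(setNames(reads$bases, reads$read_id), drafts,
                   preset = "long", max_secondary = 1L)
  aln <- aln[!is.na(aln$score), ]
  expect_gt(nrow(aln), 10)
  for (i in seq_len(nrow(aln))) {
    sp <- poreclone:::cigar_spans(aln$cigar[i])
    read_len <- nchar(reads$bases[reads$read_id == aln$query_id[i]])
    expect_equal(sp$query, read_len)
    expect_equal(sp$aligned_query, aln$q_end[i] - aln$q_start[i])
    expect_equal(sp$target, aln$t_end[i] - aln$t_start[i])
    co <- poreclone:::cigar_ops(aln$cigar[i])
    expect_false(any(co$len == 0))
    expect_false(any(co$op[-1] == co$op[-nrow(co)]))
  }
})

test_that("reads map to their true clone against a panel of drafts", {
  pool <- desk_pool(6, seed = 29)
  reads <- simulate_nanopore_run(pool, 100, seed = 8)
  drafts <- pool_drafts(pool)
  aln <- map_reads(setNames(reads$bases, reads$read_id), drafts,
                   preset = "long", extend = FALSE,
                   max_secondary = 1L)
  # a read whose aligned content is mostly the shared vector ties across
  # all drafts; score those out exactly as the demultiplexer does
  scores <- dplyr::summarise(
    dplyr::group_by(aln, .data$query_id),
    target = .data$target_id[which.max(.data$chain_score)],
    margin = (max(.data$chain_score) -
                ifelse(dplyr::n() > 1,
                       sort(.data$chain_score, decreasing = TRUE)[2], 0)) /
      max(.data$chain_score),
    .groups = "drop")
  informative <- scores[scores$margin >= 0.05, ]
  expect_gte(nrow(informative), 60)
  truth <- reads$clone_id[match(informative$query_id, reads$read_id)]
  expect_gte(mean(informative$target == truth), 0.99)
})
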