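# Synthetic clone pools: construction invariants, determinism, and the
# zero-error inversions that make every downstream stage testable.

test_that("a single clone pool is a vector-first construction", {
  pool <- desk_pool(1, seed = 7)
  expect_length(pool, 1)
  cl <- pool[[1]]
  expect_s3_class(cl, "clone_truth")
  expect_identical(cl$vector_interval, c(0L, 3000L))
  expect_identical(substr(cl$sequence, 1, 3000), attr(pool, "vector"))
  expect_equal(nchar(cl$sequence), 15000)
  expect_equal(nrow(cl$repeat_units), 0)
})

test_that("identical inputs and seed give byte-identical pools and reads", {
  p1 <- desk_pool(3, seed = 11)
  p2 <- desk_pool(3, seed = 11)
  expect_identical(lapply(p1, `[[`, "sequence"), lapply(p2, `[[`, "sequence"))
  r1 <- simulate_nanopore_run(p1, 15, seed = 4)
  r2 <- simulate_nanopore_run(p2, 15, seed = 4)
  expect_identical(r1, r2)
  # reads are drawn sequentially: a shorter run is a prefix of a longer one
  r3 <- simulate_nanopore_run(p1, 8, seed = 4)
  expect_identical(r3$bases, r1$bases[1:8])
})

test_that("planted repeat units align at >= 99% and < 100% identity", {
  pool <- desk_pool(1, insert = 13000, seed = 13,
                    repeat_spec = list(n_units = 2, unit_len = 1000,
                                       unit_identity = 0.99,
                                       arrangement = "tandem"),
                    sfv_per_unit = 2)
  units <- pool[[1]]$repeat_units
  expect_equal(nrow(units), 2)
  u <- substring(pool[[1]]$sequence, units$start + 1, units$end)
  id <- oracle_identity(u[1], u[2])
  expect_gte(id, 0.99)
  expect_lt(id, 1.0)
  # every planted SFV site is a real difference between the units
  sfv <- pool[[1]]$sfv_sites
  expect_gte(nrow(sfv), 2)
  for (i in seq_len(nrow(sfv))) {
    expect_identical(substr(pool[[1]]$sequence, sfv$pos[i] + 1, sfv$pos[i] + 1),
                     sfv$allele_base[i])
  }
})

test_that("indistinguishable units are refused without an explicit override", {
  spec <- list(n_units = 2, unit_len = 1000, unit_identity = 0.995,
               arrangement = "tandem")
  expect_error(desk_pool(1, insert = 13000, seed = 1, repeat_spec = spec,
                         sfv_per_unit = 0), "indistinguishable")
  expect_warning(desk_pool(1, insert = 13000, seed = 1, repeat_spec = spec,
                           sfv_per_unit = 0, allow_indistinct = TRUE),
                 "indistinguishable")
  expect_error(desk_pool(1, insert = 13000, seed = 1,
                         repeat_spec = list(n_units = 4, unit_len = 4000,
                                            unit_identity = 0.99,
                                            arrangement = "tandem")),
               "do not fit")
})

test_that("zero-error single-cut reads are exact rotations of their clone", {
  pool <- desk_pool(2, seed = 3)
  reads <- simulate_nanopore_run(pool, 12, p_single_cut = 1,
                                 error_model = nanopore_error_model(0, 0, 0, 1),
                                 seed = 5)
  for (i in seq_len(nrow(reads))) {
    truth <- pool[[match(reads$clone_id[i],
                         sapply(pool, `[[`, "clone_id"))]]$sequence
    expect_equal(nchar(reads$bases[i]), nchar(truth))
    rot <- poreclone:::rotate_seq(truth, reads$cut_position[i])
    if (reads$strand[i] == "-") rot <- revcomp(rot)
    expect_identical(reads$bases[i], rot)
  }
})

test_that("default-error reads match the declared error budget", {
  pool <- desk_pool(1, seed = 5)
  truth <- pool[[1]]$sequence
  reads <- simulate_nanopore_run(pool, 20, p_single_cut = 1, seed = 9)
  runs <- poreclone:::homopolymer_runs(truth, 3L)
  hp_frac <- sum(runs$length) / nchar(truth)
  em <- nanopore_error_model()
  mult_eff <- 1 + (em$homopolymer_indel_multiplier - 1) * hp_frac
  expected <- 1 - (em$sub + (em$ins + em$del) * mult_eff)
  ids <- vapply(seq_len(20), function(i) {
    tr <- poreclone:::rotate_seq(truth, reads$cut_position[i])
    if (reads$strand[i] == "-") tr <- revcomp(tr)
    oracle_identity(reads$bases[i], tr)
  }, numeric(1))
  # the DP aligner pairs some insertion/deletion errors into mismatch
  # columns, which lifts measured identity slightly above the naive
  # per-base budget; 3 points still separates this cleanly from an
  # unadjusted model (which would sit ~5 points higher)
  expect_lt(abs(mean(ids) - expected), 0.03)
})

test_that("Illumina simulation respects coverage arithmetic and exactness", {
  pool <- desk_pool(1, insert = 47000, seed = 21)
  ill <- simulate_illumina(pool, coverage = 50, read_len = 150, seed = 2,
                           sub_rate = 0)
  total <- sum(nchar(ill$bases1)) + sum(nchar(ill$bases2))
  expect_lt(abs(total - 50 * 50000) / (50 * 50000), 0.05)
  doubled <- paste0(pool[[1]]$sequence, pool[[1]]$sequence)
  idx <- sample(nrow(ill), 25)
  for (i in idx) {
    expect_true(grepl(ill$bases1[i], doubled, fixed = TRUE))
    expect_true(grepl(revcomp(ill$bases2[i]), doubled, fixed = TRUE))
  }
  expect_identical(simulate_illumina(pool, coverage = 2, seed = 9),
                   simulate_illumina(pool, coverage = 2, seed = 9))
})

test_that("draft degradation collapses tandem repeats and breaks contigs", {
  pool <- desk_pool(1, insert = 16000, seed = 31,
                    repeat_spec = list(n_units = 2, unit_len = 3000,
                                       unit_identity = 0.99,
                                       arrangement = "tandem"),
                    sfv_per_unit = 2)
  cl <- pool[[1]]
  # identity case
  d0 <- degrade_to_draft(cl, collapse_repeats = FALSE, error_rate = 0,
                         n_contig_breaks = 0, seed = 1)
  expect_identical(d0$sequence, cl$sequence)
  # collapse removes about one unit length
  d1 <- degrade_to_draft(cl, collapse_repeats = TRUE, seed = 1)
  expect_equal(nchar(cl$sequence) - nchar(d1$sequence), 3000)
  # contig breaks partition the clone
  d2 <- degrade_to_draft(cl, n_contig_breaks = 2, seed = 1)
  expect_equal(nrow(d2), 3)
  expect_identical(paste(d2$sequence, collapse = ""), cl$sequence)
})

test_that("balanced pools spread reads evenly", {
  pool <- desk_pool(4, seed = 17)
  reads <- simulate_nanopore_run(pool, 2000, seed = 3)
  shares <- table(reads$clone_id) / 2000
  expect_true(all(abs(shares - 0.25) < 0.035))
})

test_that("tiling pools share exact overlaps between neighbours", {
  pool <- make_tiling_pool(n_clones = 3, insert_len = 12000, overlap = 4000,
                           vector_len = 3000, seed = 8)
  expect_length(pool, 3)
  for (i in 1:2) {
    a <- pool[[i]]$sequence; b <- pool[[i + 1]]$sequence
    # last 4 kb of a's insert == first 4 kb of b's insert
    expect_identical(substring(a, nchar(a) - 3999), substr(b, 3001, 7000))
  }
})

test_that("the truth table round-trips through TSV", {
  pool <- desk_pool(1, seed = 2)
  reads <- simulate_nanopore_run(pool, 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(reads, path)
  back <- utils::read.delim(path)
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$cut_position, reads$cut_position)
})
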