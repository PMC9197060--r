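# Run statistics, troubleshooting flags, and overlap-based accuracy.

test_that("n50 matches the definition and a brute-force oracle", {
  expect_equal(compute_n50(c(10, 20, 30, 40)), 30)
  expect_equal(compute_n50(rep(7, 13)), 7)
  expect_error(compute_n50(numeric(0)), "empty")
  oracle_n50 <- function(lens) {
    half <- sum(lens) / 2
    max(Filter(function(L) sum(lens[lens >= L]) >= half, unique(lens)))
  }
  withr::local_seed(101)
  for (i in 1:20) {
    lens <- sample(1:5000, sample(5:200, 1), replace = TRUE)
    expect_equal(compute_n50(lens), oracle_n50(lens))
  }
})

test_that("run statistics aggregate demux, lengths and full-length counts", {
  pool <- desk_pool(3, seed = 103)
  reads <- simulate_nanopore_run(pool, 60, seed = 3)
  drafts <- pool_drafts(pool)
  dm <- demux_pool(reads, drafts)
  fc <- tibble::tibble(clone_id = reads$clone_id,
                       status = ifelse(reads$truncated, "PARTIAL",
                                       "FULL_VECTOR_ANCHORED"))
  st <- run_stats(dm, reads, full_calls = fc)
  expect_equal(st$total_reads, 60)
  expect_equal(st$total_bases, sum(nchar(reads$bases)))
  expect_equal(st$read_n50, compute_n50(nchar(reads$bases)))
  expect_lte(sum(st$per_clone$fraction), 1)
  expect_equal(sum(st$per_clone$full_length_count), sum(!reads$truncated))
})

test_that("troubleshooting flags mirror the protocol guidance", {
  pool <- desk_pool(3, seed = 105)
  reads <- simulate_nanopore_run(pool[1:2], 50, seed = 4)
  drafts <- pool_drafts(pool)
  dm <- demux_pool(reads, drafts)
  st <- run_stats(dm, reads)
  finished <- drafts
  finished["clone02"] <- substr(finished["clone02"], 1, 8000) # short clone
  fl <- flag_anomalies(st, drafts = drafts, finished = finished)
  expect_true("NO_READS" %in% fl$flag)
  expect_identical(fl$clone_id[fl$flag == "NO_READS"], "clone03")
  expect_true("SHORT_CLONE" %in% fl$flag)
  expect_identical(fl$clone_id[fl$flag == "SHORT_CLONE"], "clone02")
  expect_match(fl$guidance[fl$flag == "SHORT_CLONE"], "deletion during culture")
  # all nominal: no flags
  reads2 <- simulate_nanopore_run(pool, 60, seed = 5)
  dm2 <- demux_pool(reads2, drafts)
  fl2 <- flag_anomalies(run_stats(dm2, reads2), drafts = drafts,
                        finished = drafts)
  expect_equal(nrow(fl2), 0)
})

test_that("overlap error rate counts differences per aligned megabase", {
  withr::local_seed(107)
  shared <- random_dna(100000)
  a <- paste0(random_dna(5000), shared)
  b <- paste0(shared, random_dna(5000))
  ov <- overlap_error_rate(a, b)
  expect_equal(ov$n_differences, 0)
  expect_equal(ov$errors_per_mb, 0)
  expect_gte(ov$overlap_len, 99000)
  # one planted mismatch in the 100 kb overlap = 10 errors/Mb
  b2 <- b
  old <- substr(b2, 50000, 50000)
  substr(b2, 50000, 50000) <- setdiff(c("A", "C", "G", "T"), old)[1]
  ov2 <- overlap_error_rate(a, b2)
  expect_equal(ov2$n_differences, 1)
  expect_equal(ov2$errors_per_mb, 1e6 / ov2$overlap_len)
  # non-overlapping clones: NA with a message
  expect_message(ov3 <- overlap_error_rate(random_dna(20000),
                                           random_dna(20000)), "no overlap")
  expect_true(is.na(ov3$errors_per_mb))
})

test_that("tidiers and plots cover the result types", {
  pool <- desk_pool(2, seed = 109)
  reads <- simulate_nanopore_run(pool, 40, seed = 6)
  dm <- demux_pool(reads, pool_drafts(pool))
  expect_s3_class(tidy(dm), "tbl_df")
  g <- glance(dm)
  expect_equal(g$total_reads, 40)
  expect_s3_class(autoplot(dm), "ggplot")
  st <- run_stats(dm, reads)
  expect_equal(nrow(tidy(st)), 2)
  expect_s3_class(autoplot(st), "ggplot")
  expect_s3_class(plot_read_lengths(reads), "ggplot")
})
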