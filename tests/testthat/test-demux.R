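# Barcode-free read-to-clone assignment and its margin rule.

test_that("reads from distinct clones are assigned with positive margin", {
  pool <- desk_pool(3, seed = 33)
  reads <- simulate_nanopore_run(pool, 30, seed = 5)
  drafts <- pool_drafts(pool)
  asg <- assign_reads(reads, drafts)
  ok <- asg[asg$status == "ASSIGNED", ]
  expect_gt(nrow(ok), 20)
  expect_true(all(ok$margin > 0))
  truth <- reads$clone_id[match(ok$read_id, reads$read_id)]
  expect_identical(ok$clone_id, truth)
})

test_that("a read inside a shared amplicon is ambiguous; full-length reads are not", {
  # two clones share a 3 kb unit planted into both inserts
  withr::local_seed(44)
  vec <- random_dna(3000)
  shared <- random_dna(3000)
  mk <- function() paste0(vec, random_dna(4000), shared, random_dna(4000))
  c1 <- mk(); c2 <- mk()
  drafts <- c(clone1 = c1, clone2 = c2)
  # truncated read wholly inside the shared unit: equal scores by construction
  r_in <- substr(shared, 501, 2500)
  a1 <- assign_read(r_in, drafts)
  expect_identical(a1$status, "AMBIGUOUS")
  expect_lt(a1$margin, 0.05)
  # full-length reads carry unique flanks and assign uniquely and correctly
  pool <- list(
    structure(list(clone_id = "clone1", sequence = c1,
                   vector_interval = c(0L, 3000L),
                   repeat_units = poreclone:::empty_units(),
                   sfv_sites = poreclone:::empty_sfvs()),
              class = "clone_truth"),
    structure(list(clone_id = "clone2", sequence = c2,
                   vector_interval = c(0L, 3000L),
                   repeat_units = poreclone:::empty_units(),
                   sfv_sites = poreclone:::empty_sfvs()),
              class = "clone_truth"))
  reads <- simulate_nanopore_run(pool, 200, p_single_cut = 1, seed = 6)
  asg <- assign_reads(reads, drafts)
  truth <- reads$clone_id[match(asg$read_id, reads$read_id)]
  unique_correct <- mean(asg$status == "ASSIGNED" & asg$clone_id == truth)
  expect_gte(unique_correct, 0.95)
})

test_that("demux conserves reads across bins and flags empty bins", {
  pool <- desk_pool(4, seed = 37)
  # simulate reads from only three of the four clones
  reads <- simulate_nanopore_run(pool[1:3], 60, seed = 7)
  drafts <- pool_drafts(pool)
  dm <- demux_pool(reads, drafts)
  binned <- unlist(dm$bins, use.names = FALSE)
  expect_false(any(duplicated(binned)))
  expect_equal(length(binned) + length(dm$ambiguous) + length(dm$unassigned),
               nrow(reads))
  expect_identical(sort(c(binned, dm$ambiguous, dm$unassigned)),
                   sort(reads$read_id))
  # the unsequenced clone is flagged as a failed culture candidate
  expect_equal(dm$stats$n_reads[dm$stats$clone_id == "clone04"], 0)
  expect_true("NO_READS" %in% dm$flags$flag)
  expect_match(dm$flags$guidance[dm$flags$flag == "NO_READS"][1],
               "culture failed")
})

test_that("a single-clone run puts every assignable read in one bin", {
  pool <- desk_pool(2, seed = 39)
  reads <- simulate_nanopore_run(pool[1], 40, seed = 9)
  drafts <- pool_drafts(pool)
  dm <- demux_pool(reads, drafts)
  expect_equal(dm$stats$n_reads[dm$stats$clone_id == "clone02"], 0)
  expect_equal(length(dm$bins$clone01),
               nrow(reads) - length(dm$ambiguous) - length(dm$unassigned))
})

test_that("assignment accuracy on a balanced pool exceeds 99%", {
  pool <- desk_pool(6, seed = 41)
  reads <- simulate_nanopore_run(pool, 300, seed = 10)
  drafts <- pool_drafts(pool)
  dm <- demux_pool(reads, drafts)
  asg <- dm$assignments[dm$assignments$status == "ASSIGNED", ]
  truth <- reads$clone_id[match(asg$read_id, reads$read_id)]
  expect_gte(mean(asg$clone_id == truth), 0.99)
})
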