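# Backbone selection, long-read windowed consensus, and Illumina correction.

test_that("backbone selection prefers vector-anchored reads and breaks ties", {
  calls <- tibble::tibble(
    read_id = c("r_b", "r_a", "r_put"),
    status = c("FULL_VECTOR_ANCHORED", "FULL_VECTOR_ANCHORED",
               "PUTATIVE_FULL_BY_LENGTH"))
  withr::local_seed(6)
  draft <- random_dna(5000)
  reads <- c(r_b = draft, r_a = draft, r_put = draft) # equal identity
  bb <- select_backbone(calls, reads, draft)
  expect_identical(bb$read_id, "r_a") # lexicographic tie-break
  # putative considered only when no anchored read exists
  bb2 <- select_backbone(calls[3, ], reads, draft, include_putative = TRUE)
  expect_identical(bb2$read_id, "r_put")
  expect_warning(bb3 <- select_backbone(calls[0, ], reads, draft), "draft")
  expect_identical(bb3$sequence, draft)
  expect_error(suppressWarnings(select_backbone(calls[0, ], reads, NULL)),
               "re-sequenced")
})

test_that("long-read polish is a fixed point on clean data and corrects planted errors", {
  withr::local_seed(7)
  truth <- random_dna(8000)
  clean <- setNames(rep(truth, 10), paste0("r", 1:10))
  expect_identical(polish_long(truth, clean, circular = FALSE)$sequence, truth)
  # 50 planted random errors all corrected by 10 zero-error reads
  corrupt <- poreclone:::cpp_mutate(truth, 0.004, 0.002, 0.001, 1)
  expect_false(identical(corrupt, truth))
  fixed <- polish_long(corrupt, clean, rounds = 1, circular = FALSE)$sequence
  expect_identical(fixed, truth)
})

test_that("long-read polish beats the raw read identity", {
  withr::local_seed(8)
  truth <- random_dna(8000)
  reads <- setNames(vapply(1:15, function(i)
    poreclone:::cpp_mutate(truth, 0.04, 0.03, 0.03, 6), character(1)),
    paste0("r", 1:15))
  read_ids <- vapply(reads, function(r) oracle_identity(r, truth), numeric(1))
  cons <- polish_long(reads[[1]], reads, rounds = 2, circular = FALSE)$sequence
  expect_gt(oracle_identity(cons, truth), max(read_ids))
})

test_that("homopolymer run lengths are corrected to the Illumina consensus", {
  withr::local_seed(9)
  left <- random_dna(400); right <- random_dna(400)
  truth <- paste0(left, "AAAAA", right) # true 5-A run
  wrong <- paste0(left, "AAAAAA", right) # consensus over-calls 6 A
  # 30 clean reads, every one spanning the run
  starts <- sample(280:380, 30, replace = TRUE)
  reads <- substring(truth, starts, starts + 149)
  asm <- polish_short(wrong, reads, min_depth = 15, min_agree = 0.9)
  expect_identical(asm$sequence, truth)
  d <- asm$discrepancies
  expect_true(any(d$class == "HOMOPOLYMER_INDEL"))
})

test_that("a 50/50 split is left unresolved and unedited", {
  withr::local_seed(10)
  truth <- random_dna(1200)
  alt <- truth
  substr(alt, 601, 601) <- if (substr(truth, 601, 601) == "A") "C" else "A"
  mk_reads <- function(src) substring(src, seq(1, 1050, by = 15),
                                      seq(1, 1050, by = 15) + 149)
  reads <- c(mk_reads(truth), mk_reads(alt)) # exactly half support each allele
  asm <- polish_short(truth, reads)
  expect_identical(asm$sequence, truth)
  un <- asm$discrepancies[asm$discrepancies$class == "UNRESOLVED", ]
  expect_true(any(abs(un$position - 600) <= 1))
})

test_that("Illumina polishing is idempotent", {
  pool <- desk_pool(1, insert = 6000, seed = 61)
  truth <- pool[[1]]$sequence
  ill <- simulate_illumina(pool, coverage = 40, seed = 4)
  reads <- c(ill$bases1, ill$bases2)
  noisy <- poreclone:::cpp_mutate(truth, 0.01, 0.004, 0.004, 4)
  once <- polish_short(noisy, reads, circular = TRUE)
  twice <- polish_short(once$sequence, reads, circular = TRUE)
  expect_identical(twice$sequence, once$sequence)
  expect_equal(nrow(twice$discrepancies[twice$discrepancies$class !=
                                          "UNRESOLVED", ]), 0)
})

test_that("polishing without short reads returns the input with a warning", {
  expect_warning(asm <- polish_short("ACGTACGTAC", character(0)),
                 "long-read-only")
  expect_identical(asm$sequence, "ACGTACGTAC")
})

test_that("the vector prefix survives the whole polishing chain", {
  pool <- desk_pool(1, seed = 63)
  vec <- attr(pool, "vector")
  reads <- simulate_nanopore_run(pool, 30, p_single_cut = 0.4, seed = 5)
  ill <- simulate_illumina(pool, coverage = 50, seed = 6)
  draft <- pool_drafts(pool)[[1]]
  asm <- finish_clone("clone01", setNames(reads$bases, reads$read_id), draft,
                      vec, c(ill$bases1, ill$bases2))
  expect_identical(substr(asm$sequence, 1, nchar(vec)), vec)
  expect_identical(asm$clone_id, "clone01")
})
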