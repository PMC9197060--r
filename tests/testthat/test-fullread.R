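# Vector anchoring, full-length classification, canonical rotation, and the
# read-length-distribution estimate of clone length.

test_that("vector hits land where the cut dictates", {
  pool <- desk_pool(1, seed = 51)
  vec <- attr(pool, "vector")
  truth <- pool[[1]]$sequence
  # cut inside the vector: hits at both read ends
  r_vec <- poreclone:::rotate_seq(truth, 1500)
  h <- find_vector_hits(r_vec, vec)
  expect_equal(nrow(h), 2)
  expect_lt(h$start[1], 10)
  expect_gt(h$end[2], nchar(r_vec) - 10)
  expect_equal(h$identity, c(1, 1), tolerance = 1e-6)
  # cut inside the insert: single internal hit
  r_ins <- poreclone:::rotate_seq(truth, 8000)
  h2 <- find_vector_hits(r_ins, vec)
  expect_equal(nrow(h2), 1)
  expect_gt(h2$start, 1000)
  expect_lt(h2$end, nchar(r_ins) - 1000)
})

test_that("full-length classification follows the anchor rule", {
  pool <- desk_pool(1, seed = 53)
  vec <- attr(pool, "vector")
  truth <- pool[[1]]$sequence
  cl1 <- classify_full_length(poreclone:::rotate_seq(truth, 800), vec)
  expect_identical(cl1$status, "FULL_VECTOR_ANCHORED")
  # mid-insert cut: putative only when a length estimate is available
  r2 <- poreclone:::rotate_seq(truth, 9000)
  expect_identical(classify_full_length(r2, vec)$status, "PARTIAL")
  expect_identical(
    classify_full_length(r2, vec, clone_length_estimate = 15000)$status,
    "PUTATIVE_FULL_BY_LENGTH")
  # half-length truncation
  half <- substr(r2, 1, 7500)
  expect_identical(
    classify_full_length(half, vec, clone_length_estimate = 15000)$status,
    "PARTIAL")
})

test_that("rotation recovers the toy worked example and is a group action", {
  clone <- "AAAACCCCGGGGTTTT"
  read <- poreclone:::rotate_seq(clone, 8) # "GGGGTTTTAAAACCCC"
  expect_identical(read, "GGGGTTTTAAAACCCC")
  hit <- tibble::tibble(start = 8L, end = 12L, strand = "+",
                        identity = 1, v_start = 0L, v_end = 4L)
  rot <- rotate_to_vector(read, hit)
  expect_identical(rot$sequence, clone)
  # rotating by the full length is the identity; bases are conserved
  expect_identical(poreclone:::rotate_seq(clone, nchar(clone)), clone)
  expect_identical(sort(strsplit(rot$sequence, "")[[1]]),
                   sort(strsplit(read, "")[[1]]))
})

test_that("rotation refuses vector-vector chimeras", {
  withr::local_seed(5)
  vec <- random_dna(3000)
  chimera <- paste0(vec, random_dna(4000), vec, random_dna(4000))
  hits <- find_vector_hits(chimera, vec)
  expect_gte(nrow(hits), 2)
  expect_error(rotate_to_vector(chimera, hits[1, ], hits = hits), "chimera")
})

test_that("zero-error rotated reads equal the linearized truth", {
  pool <- desk_pool(1, seed = 55)
  vec <- attr(pool, "vector")
  truth <- pool[[1]]$sequence
  reads <- simulate_nanopore_run(pool, 20, p_single_cut = 1,
                                 error_model = nanopore_error_model(0, 0, 0, 1),
                                 seed = 3)
  n_anchored <- 0
  for (i in seq_len(nrow(reads))) {
    cl <- classify_full_length(reads$bases[i], vec,
                               clone_length_estimate = 15000)
    expect_true(cl$status %in% c("FULL_VECTOR_ANCHORED",
                                 "PUTATIVE_FULL_BY_LENGTH"))
    if (cl$status == "FULL_VECTOR_ANCHORED") n_anchored <- n_anchored + 1
    rot <- rotate_to_vector(reads$bases[i], cl)
    expect_identical(rot$sequence, truth)
  }
  # reads cut well inside the vector leave a detectable (>= 500 bp) vector
  # piece at both read ends and must all be vector-anchored
  in_vec <- reads$cut_position >= 600 & reads$cut_position <= 2400
  expect_gte(n_anchored, sum(in_vec))
})

test_that("clone length is read off the tail of the length distribution", {
  expect_equal(estimate_clone_length(rep(120000, 30)), 120500)
  set.seed(2)
  lens <- c(round(rexp(100, 1 / 20000)), round(runif(8, 150100, 150900)))
  expect_lt(abs(estimate_clone_length(lens) - 150000), 2000)
  # uniform lengths: no discernible peak
  set.seed(3)
  expect_true(is.na(estimate_clone_length(sample(1000:200000, 100))))
  expect_warning(est <- estimate_clone_length(c(100, 200)), "fewer than 20")
  expect_true(is.na(est))
})
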