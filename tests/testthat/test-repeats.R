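# Repeat-unit detection, SFV calling, and divide-and-conquer finishing.

tandem_spec <- list(n_units = 2, unit_len = 3000, unit_identity = 0.99,
                    arrangement = "tandem")

test_that("planted tandem and palindrome units are detected with correct structure", {
  pool <- desk_pool(1, insert = 16000, seed = 71, repeat_spec = tandem_spec,
                    sfv_per_unit = 2)
  u <- detect_self_repeats(pool[[1]]$sequence, 2000, 0.99)
  tu <- pool[[1]]$repeat_units
  expect_equal(nrow(u), 2)
  expect_equal(unique(u$group), 1L)
  expect_identical(u$orientation, c("direct", "direct"))
  expect_lt(max(abs(u$start - tu$start), abs(u$end - tu$end)), 60)
  # palindrome: inverted second arm
  pal <- desk_pool(1, insert = 16000, seed = 72,
                   repeat_spec = list(n_units = 2, unit_len = 3000,
                                      unit_identity = 0.99,
                                      arrangement = "palindrome"),
                   sfv_per_unit = 2)
  u2 <- detect_self_repeats(pal[[1]]$sequence, 2000, 0.99)
  expect_equal(nrow(u2), 2)
  expect_identical(u2$orientation, c("direct", "inverted"))
  # random sequence: nothing
  withr::local_seed(73)
  expect_equal(nrow(detect_self_repeats(random_dna(12000), 2000, 0.99)), 0)
})

test_that("a three-unit tandem array decomposes into one group of three", {
  pool <- desk_pool(1, insert = 16000, seed = 74,
                    repeat_spec = list(n_units = 3, unit_len = 2500,
                                       unit_identity = 0.99,
                                       arrangement = "tandem"),
                    sfv_per_unit = 2)
  u <- detect_self_repeats(pool[[1]]$sequence, 2000, 0.99)
  expect_equal(nrow(u), 3)
  expect_equal(length(unique(u$group)), 1)
})

test_that("a single planted difference yields exactly one SFV with correct alleles", {
  withr::local_seed(75)
  vec <- random_dna(3000)
  unit <- random_dna(3000)
  u2 <- unit
  old <- substr(u2, 1500, 1500)
  substr(u2, 1500, 1500) <- setdiff(c("A", "C", "G", "T"), old)[1]
  cons <- paste0(vec, random_dna(2000), unit, u2, random_dna(2000))
  units <- tibble::tibble(unit_id = c("u1", "u2"),
                          start = c(5000L, 8000L), end = c(8000L, 11000L),
                          group = 1L, orientation = "direct")
  truth <- list(structure(list(clone_id = "c", sequence = cons,
                               vector_interval = c(0L, 3000L),
                               repeat_units = units,
                               sfv_sites = poreclone:::empty_sfvs()),
                          class = "clone_truth"))
  ill <- simulate_illumina(truth, coverage = 50, seed = 5)
  sf <- call_sfvs(units, cons, c(ill$bases1, ill$bases2))
  expect_equal(length(unique(sf$sfv_id)), 1)
  expect_equal(sort(sf$column), c(1499L, 1499L))
  expect_setequal(sf$allele, c(substr(unit, 1500, 1500), substr(u2, 1500, 1500)))
  # identical units: no SFV at all
  cons0 <- paste0(vec, random_dna(2000), unit, unit, random_dna(2000))
  sf0 <- call_sfvs(units, cons0, c(ill$bases1, ill$bases2))
  expect_equal(nrow(sf0), 0)
})

test_that("all planted SFVs are recovered without spurious calls", {
  hit <- 0
  for (seed in 81:83) {
    pool <- desk_pool(1, insert = 16000, seed = seed,
                      repeat_spec = tandem_spec, sfv_per_unit = 2)
    cl <- pool[[1]]
    ill <- simulate_illumina(pool, coverage = 50, seed = seed + 100)
    sf <- call_sfvs(cl$repeat_units, cl$sequence, c(ill$bases1, ill$bases2))
    called <- sort(unique(sf$pos))
    # every planted SFV position must be called ...
    expect_true(all(cl$sfv_sites$pos %in% called))
    # ... and every call must be a genuine inter-unit difference
    tu <- cl$repeat_units
    m1 <- strsplit(substr(cl$sequence, tu$start[1] + 1, tu$end[1]), "")[[1]]
    m2 <- strsplit(substr(cl$sequence, tu$start[2] + 1, tu$end[2]), "")[[1]]
    true_cols <- which(m1 != m2) - 1L
    expect_true(all(sf$column %in% true_cols))
    hit <- hit + 1
  }
  expect_equal(hit, 3)
})

test_that("finish_repetitive is a no-op without units", {
  withr::local_seed(85)
  s <- random_dna(6000)
  out <- finish_repetitive(s, poreclone:::empty_repeat_units(),
                           poreclone:::empty_sfv_calls(),
                           c(r1 = s), c(s))
  expect_identical(out$sequence, s)
})

test_that("swapped SFV alleles are repaired by structure-anchored reads", {
  pool <- desk_pool(1, insert = 16000, seed = 86, repeat_spec = tandem_spec,
                    sfv_per_unit = 2)
  cl <- pool[[1]]
  truth <- cl$sequence
  # swap the planted alleles between the two units in the input consensus
  sfv <- cl$sfv_sites
  chars <- strsplit(truth, "")[[1]]
  u1s <- sfv[sfv$unit_index == 1, ]
  u2s <- sfv[sfv$unit_index == 2, ]
  period <- cl$repeat_units$start[2] - cl$repeat_units$start[1]
  swapped <- chars
  for (p in c(u1s$pos, u2s$pos)) {
    partner <- if (p < cl$repeat_units$end[1]) p + period else p - period
    swapped[p + 1] <- chars[partner + 1]
  }
  cons <- paste(swapped, collapse = "")
  expect_false(identical(cons, truth))
  reads <- simulate_nanopore_run(pool, 40, p_single_cut = 0.5, seed = 9)
  ill <- simulate_illumina(pool, coverage = 50, seed = 10)
  units <- detect_self_repeats(cons, 2000, 0.98)
  sfvs <- call_sfvs(units, cons, c(ill$bases1, ill$bases2))
  out <- finish_repetitive(cons, units, sfvs,
                           setNames(reads$bases, reads$read_id),
                           c(ill$bases1, ill$bases2))
  # the planted alleles must be restored at every swapped site
  for (i in seq_len(nrow(sfv))) {
    p <- sfv$pos[i]
    expect_identical(substr(out$sequence, p + 1, p + 1), sfv$allele_base[i])
  }
})

test_that("unit order and orientation survive repeat finishing", {
  pool <- desk_pool(1, insert = 16000, seed = 87, repeat_spec = tandem_spec,
                    sfv_per_unit = 2)
  cl <- pool[[1]]
  reads <- simulate_nanopore_run(pool, 40, p_single_cut = 0.5, seed = 11)
  ill <- simulate_illumina(pool, coverage = 50, seed = 12)
  units <- detect_self_repeats(cl$sequence, 2000, 0.99)
  sfvs <- call_sfvs(units, cl$sequence, c(ill$bases1, ill$bases2))
  out <- finish_repetitive(cl$sequence, units, sfvs,
                           setNames(reads$bases, reads$read_id),
                           c(ill$bases1, ill$bases2))
  u_out <- detect_self_repeats(out$sequence, 2000, 0.98)
  expect_equal(nrow(u_out), 2)
  expect_identical(u_out$orientation, units$orientation)
  expect_true(all(diff(u_out$start) > 0))
  # length conserved up to the logged edits
  net <- nchar(out$sequence) - nchar(cl$sequence)
  expect_lte(abs(net), nrow(out$discrepancies) + 1)
})
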