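# Shared fixtures: small simulated pools and toy records, built in code.

desk_pool <- function(n_clones = 1, insert = 12000, seed = 42, ...) {
  make_clone_pool(n_clones, vector_len = 3000,
                  insert_len_range = c(insert, insert), seed = seed, ...)
}

pool_drafts <- function(pool, error_rate = 0.001, seed = 3, ...) {
  setNames(
    sapply(pool, function(cl)
      paste(degrade_to_draft(cl, error_rate = error_rate, seed = seed,
                             ...)$sequence, collapse = "")),
    sapply(pool, function(cl) cl$clone_id))
}

# a mapped SAM record with an arbitrary CIGAR over a poly-A query
toy_sam <- function(cigar, qname = "q1") {
  co <- poreclone:::cigar_ops(cigar)
  qlen <- sum(co$len[co$op %in% c("M", "I", "S")])
  poreclone:::new_sam_record(qname, 0L, "ref", 1L, 60L, cigar,
                             strrep("A", qlen))
}

# global alignment oracle: Biostrings quadratic DP with the package scoring
oracle_align <- function(q, t) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(q, t, substitutionMatrix = mat,
                                gapOpening = 4, gapExtension = 2,
                                type = "global")
}

oracle_identity <- function(q, t) {
  pa <- oracle_align(q, t)
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  Biostrings::nmatch(pa) / cols
}

# circular equality: x reproduces the circular sequence `truth` exactly,
# up to rotation
circular_identical <- function(x, truth) {
  nchar(x) == nchar(truth) && grepl(x, paste0(truth, truth), fixed = TRUE)
}
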