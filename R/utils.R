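#' @useDynLib poreclone, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile median rexp rnorm runif
#' @importFrom rlang abort warn .data
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases; uses the current RNG state.
#'
#' @param n length in bp.
#' @return a single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Run code under a fixed seed, restoring RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

# Coerce sequences + names from tibble(name/read_id, sequence/bases) or a
# (named) character vector into a named character vector.
as_named_seqs <- function(x, default_prefix = "seq") {
  if (is.data.frame(x)) {
    seq_col <- intersect(c("sequence", "bases", "seq"), names(x))[1]
    id_col <- intersect(c("name", "read_id", "clone_id", "id"), names(x))[1]
    if (is.na(seq_col)) abort("no sequence column found")
    seqs <- x[[seq_col]]
    names(seqs) <- if (!is.na(id_col)) x[[id_col]] else NULL
    x <- seqs
  }
  nms <- names(x)
  x <- as.character(x)
  names(x) <- nms
  if (is.null(names(x)) || any(names(x) == "" | is.na(names(x)))) {
    nm <- names(x)
    if (is.null(nm)) nm <- rep("", length(x))
    fix <- nm == "" | is.na(nm)
    nm[fix] <- paste0(default_prefix, seq_along(x))[fix]
    names(x) <- nm
  }
  x
}

# Homopolymer runs of length >= min_len: tibble(start, end, base), 0-based
# half-open on the sequence.
homopolymer_runs <- function(seq, min_len = 3L) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_len
  tibble(start = starts[keep], end = ends[keep], base = r$values[keep],
         length = r$lengths[keep])
}

# Parse a CIGAR string into a tibble(op, len).
cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "" || cigar == "*")
    return(tibble(op = character(), len = integer()))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDSHNP=X]", cigar))[[1]]
  tibble(op = ops, len = lens)
}

cigar_string <- function(ops, lens) {
  keep <- lens > 0L
  ops <- ops[keep]; lens <- lens[keep]
  if (length(ops) == 0L) return("*")
  # merge adjacent identical ops
  grp <- cumsum(c(TRUE, ops[-1] != ops[-length(ops)]))
  lens <- as.integer(tapply(lens, grp, sum))
  ops <- ops[!duplicated(grp)]
  paste0(lens, ops, collapse = "")
}

# Query/target span implied by a CIGAR.
cigar_spans <- function(cigar) {
  co <- cigar_ops(cigar)
  list(
    query = sum(co$len[co$op %in% c("M", "I", "S", "=", "X")]),
    target = sum(co$len[co$op %in% c("M", "D", "N", "=", "X")]),
    aligned_query = sum(co$len[co$op %in% c("M", "I", "=", "X")])
  )
}
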