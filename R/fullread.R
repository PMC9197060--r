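# Full-length read identification and canonicalization. A nanopore read that
# traverses an entire once-cut circular clone starts and ends in cloning
# vector sequence; cut-in-insert full-length reads carry a single internal
# vector hit and are rotated so the vector comes first.

#' Find cloning-vector hits on a read
#'
#' Aligns the vector against the read (both strands) and reports all hits
#' above the identity and length thresholds (defaults tuned for raw nanopore
#' error rates).
#'
#' @param read read sequence.
#' @param vector vector sequence (>= 1 kb).
#' @param min_identity minimum alignment identity (default 0.75).
#' @param min_len minimum hit length on the read (default 500 bp).
#' @return tibble with `start`, `end` (read interval, 0-based half-open),
#'   `strand`, `identity`, and `v_start`/`v_end` (vector interval).
#' @export
find_vector_hits <- function(read, vector, min_identity = 0.75,
                             min_len = 500L) {
  stopifnot(nchar(vector) >= 1000)
  batch_vector_hits(c(read = read), vector, min_identity = min_identity,
                    min_len = min_len)[[1]]
}

# Vector hits for many reads against one shared vector index. The reads are
# the queries (one small index, one mapping call); minus-strand query
# coordinates are folded back to the forward read.
batch_vector_hits <- function(reads, vector, min_identity = 0.75,
                              min_len = 500L) {
  reads <- as_named_seqs(reads, default_prefix = "read")
  empty <- tibble(start = integer(), end = integer(), strand = character(),
                  identity = numeric(), v_start = integer(),
                  v_end = integer())
  out <- rep(list(empty), length(reads))
  names(out) <- names(reads)
  idx <- build_reference_index(c(vector = vector), preset = "long")
  aln <- map_reads(reads, idx, extend = TRUE, max_secondary = 3L,
                   max_extended = 4L)
  if (nrow(aln) == 0) return(out)
  rl <- nchar(reads)[aln$query_id]
  hits <- tibble(
    read_id = aln$query_id,
    start = as.integer(ifelse(aln$strand == "+", aln$q_start, rl - aln$q_end)),
    end = as.integer(ifelse(aln$strand == "+", aln$q_end, rl - aln$q_start)),
    strand = aln$strand,
    identity = aln$identity,
    v_start = aln$t_start, v_end = aln$t_end)
  hits <- hits[!is.na(hits$identity) & hits$identity >= min_identity &
                 (hits$end - hits$start) >= min_len, ]
  for (id in unique(hits$read_id)) {
    h <- hits[hits$read_id == id, -1]
    out[[id]] <- h[order(h$start), ]
  }
  out
}

#' Classify a read's full-length status
#'
#' `FULL_VECTOR_ANCHORED` iff vector hits fall within the first and last
#' `end_window` bp of the read (the molecule was cut inside the vector);
#' otherwise `PUTATIVE_FULL_BY_LENGTH` iff the read length is within 10% of
#' the clone length estimate; otherwise `PARTIAL`.
#'
#' @param read read sequence.
#' @param vector vector sequence.
#' @param clone_length_estimate optional clone length (bp) from
#'   [estimate_clone_length()].
#' @param end_window window at each read end within which a vector hit
#'   counts as an anchor (default 1 kb).
#' @param hits optional precomputed [find_vector_hits()] result.
#' @param read_id identifier carried into the result.
#' @return a one-row tibble: `read_id`, `status`, `n_vector_hits`,
#'   `rotation_offset`, `rotation_strand` (how to canonicalize, `NA` when not
#'   applicable) and the hit list as a nested `hits` column.
#' @export
classify_full_length <- function(read, vector, clone_length_estimate = NULL,
                                 end_window = 1000L, hits = NULL,
                                 read_id = "read") {
  if (is.null(hits)) hits <- find_vector_hits(read, vector)
  n <- nchar(read)
  in_start <- hits$start < end_window
  in_end <- hits$end > n - end_window
  status <- "PARTIAL"
  if (any(in_start) && any(in_end) && !all(in_start & in_end)) {
    status <- "FULL_VECTOR_ANCHORED"
  } else if (nrow(hits) == 1 && in_start[1] && in_end[1]) {
    # single hit covering both windows: short read dominated by vector
    status <- "PARTIAL"
  } else if (!is.null(clone_length_estimate) && !is.na(clone_length_estimate) &&
             abs(n - clone_length_estimate) <= 0.1 * clone_length_estimate) {
    status <- "PUTATIVE_FULL_BY_LENGTH"
  }
  rot <- rotation_from_hits(hits, n)
  tibble(read_id = read_id, status = status, n_vector_hits = nrow(hits),
         rotation_offset = rot$offset, rotation_strand = rot$strand,
         hits = list(hits))
}

# Rotation anchor: the hit whose vector interval starts earliest (the most
# complete vector start); rotate so that vector base 0 leads the read.
rotation_from_hits <- function(hits, read_len) {
  if (nrow(hits) == 0) return(list(offset = NA_integer_, strand = NA_character_))
  h <- hits[which.min(hits$v_start), ]
  if (h$strand == "+") {
    list(offset = as.integer((h$start - h$v_start) %% read_len), strand = "+")
  } else {
    # on the minus strand the vector start maps to the hit's end
    list(offset = as.integer((read_len - h$end - h$v_start) %% read_len),
         strand = "-")
  }
}

#' Rotate a full-length read to vector-first orientation
#'
#' Circular rotation placing the vector hit at position 0, after
#' reverse-complementing when the vector matched the minus strand. Exactly
#' length-preserving. Refuses reads with multiple well-separated vector hits
#' (vector-vector chimera or dimer).
#'
#' @param read read sequence.
#' @param vector_hit one row of [find_vector_hits()] output, or a
#'   classification row from [classify_full_length()].
#' @param hits full hit table used for the chimera check (optional).
#' @return list with `sequence`, `rotation_offset`, `strand`.
#' @export
rotate_to_vector <- function(read, vector_hit, hits = NULL) {
  n <- nchar(read)
  if (!is.null(hits) && nrow(hits) > 2) {
    abort("multiple well-separated vector hits: possible vector-vector chimera")
  }
  if (!is.null(hits) && nrow(hits) == 2) {
    # two hits are only consistent with a cut inside the vector (one at each
    # read end); anything else is a chimera
    if (!(hits$start[1] < 2000 && hits$end[2] > n - 2000))
      abort("multiple well-separated vector hits: possible vector-vector chimera")
  }
  if (is.data.frame(vector_hit) && "rotation_offset" %in% names(vector_hit)) {
    offset <- vector_hit$rotation_offset
    strand <- vector_hit$rotation_strand
  } else {
    rot <- rotation_from_hits(vector_hit, n)
    offset <- rot$offset; strand <- rot$strand
  }
  if (is.na(offset)) abort("no vector hit to rotate to")
  seq <- if (identical(strand, "-")) cpp_revcomp(read) else read
  list(sequence = rotate_seq(seq, offset), rotation_offset = as.integer(offset),
       strand = strand)
}

#' Estimate clone length from the read-length distribution
#'
#' The clone length shows up as a peak in the tail of the read-length
#' distribution (full-length reads pile up there while truncated reads decay
#' smoothly). Lengths above the 75th percentile are histogrammed in
#' `bin_width` bins; the centre of the modal bin is returned, or `NA` when
#' the modal bin holds fewer than 3 reads (no discernible peak) or fewer
#' than 20 reads are supplied.
#'
#' @param read_lengths integer vector of read lengths (bp).
#' @param bin_width histogram bin width (default 1 kb).
#' @return estimated clone length in bp, or `NA`.
#' @export
estimate_clone_length <- function(read_lengths, bin_width = 1000L) {
  if (length(read_lengths) < 20) {
    warn("fewer than 20 reads: no clone length estimate")
    return(NA_real_)
  }
  tail_lengths <- read_lengths[read_lengths >= quantile(read_lengths, 0.75)]
  bins <- floor(tail_lengths / bin_width)
  tab <- table(bins)
  modal <- tab[which.max(tab)]
  if (modal < 3) return(NA_real_)
  (as.numeric(names(modal)) + 0.5) * bin_width
}
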