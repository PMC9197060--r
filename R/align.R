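# Minimizer seed -> chain -> banded-extend pairwise alignment, the contract
# every downstream stage consumes. Alignments use 0-based half-open
# intervals; for minus-strand hits the CIGAR applies to the
# reverse-complemented query (SAM convention) and q_start/q_end are reported
# in that orientation.

#' Alignment scoring defaults
#'
#' Match +1, mismatch -2; a gap of length L costs `gap_open + L * gap_extend`
#' with open 4 and extend 2.
#'
#' @export
align_scoring <- function(match = 1L, mismatch = 2L, gap_open = 4L,
                          gap_extend = 2L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

preset_params <- function(preset = c("long", "short")) {
  preset <- match.arg(preset)
  if (preset == "long") {
    list(k = 15L, w = 10L, max_gap = 5000L, min_chain_score = 40,
         band = 500L)
  } else {
    list(k = 21L, w = 1L, max_gap = 500L, min_chain_score = 25, band = 100L)
  }
}

#' Extract canonical minimizers from a sequence
#'
#' Each window of `w` consecutive k-mers contributes its minimum-hash
#' canonical (strand-min) k-mer. Deterministic; k-mers containing non-ACGT
#' characters are skipped.
#'
#' @param seq DNA string.
#' @param k k-mer size (<= 28).
#' @param w window size in k-mers (>= 1); `w = 1` emits every k-mer.
#' @return a tibble with columns `hash`, `pos` (0-based) and `strand`
#'   (+1 forward / -1 reverse); empty if `nchar(seq) < k + w - 1`.
#' @export
minimizers <- function(seq, k = 15L, w = 10L) {
  stopifnot(k <= 28L, w >= 1L)
  if (nchar(seq) < k + w - 1) {
    return(tibble(hash = numeric(), pos = integer(), strand = integer()))
  }
  as_tibble(cpp_minimizers(seq, as.integer(k), as.integer(w)))
}

#' Build a minimizer index over reference sequences
#'
#' @param refs named character vector of sequences, or a tibble with
#'   `name`/`sequence` columns.
#' @param preset `"long"` (k=15, w=10) for noisy long reads or `"short"`
#'   (k=21, w=1) for accurate short reads.
#' @param k,w override the preset k-mer and window size.
#' @return an object of class `mz_index`.
#' @export
build_reference_index <- function(refs, preset = c("long", "short"),
                                  k = NULL, w = NULL) {
  p <- preset_params(preset)
  if (!is.null(k)) p$k <- as.integer(k)
  if (!is.null(w)) p$w <- as.integer(w)
  seqs <- as_named_seqs(refs, default_prefix = "ref")
  ptr <- cpp_index_build(unname(seqs), names(seqs), p$k, p$w)
  structure(list(ptr = ptr, k = p$k, w = p$w, names = names(seqs),
                 lengths = nchar(seqs), preset = match.arg(preset)),
            class = "mz_index")
}

#' @export
print.mz_index <- function(x, ...) {
  cat(sprintf("<mz_index> %d reference(s), k=%d w=%d\n",
              length(x$names), x$k, x$w))
  invisible(x)
}

#' Chain co-linear anchors
#'
#' Dynamic-programming co-linear chaining with a concave gap cost; returns
#' non-overlapping primary chains, best first. Anchors within one chain are
#' strictly increasing in both query and target coordinates.
#'
#' @param anchors tibble with columns `q_pos`, `t_pos` (0-based anchor
#'   starts), sorted or unsorted.
#' @param max_gap maximum gap (bp) between consecutive anchors in a chain.
#' @param min_chain_score minimum score for a chain to be reported.
#' @param k anchor (seed) length used for scoring.
#' @param max_chains maximum number of chains to return.
#' @return tibble with columns `chain` (1 = best), `q_pos`, `t_pos`,
#'   `chain_score`.
#' @export
chain_anchors <- function(anchors, max_gap = 5000L, min_chain_score = 40,
                          k = 15L, max_chains = 10L) {
  if (nrow(anchors) == 0) {
    return(tibble(chain = integer(), q_pos = integer(), t_pos = integer(),
                  chain_score = numeric()))
  }
  ch <- cpp_chain(as.integer(anchors$q_pos), as.integer(anchors$t_pos),
                  as.integer(k), as.integer(max_gap), min_chain_score,
                  as.integer(max_chains))
  if (length(ch) == 0) {
    return(tibble(chain = integer(), q_pos = integer(), t_pos = integer(),
                  chain_score = numeric()))
  }
  dplyr::bind_rows(lapply(seq_along(ch), function(i) {
    tibble(chain = i, q_pos = ch[[i]]$qpos, t_pos = ch[[i]]$tpos,
           chain_score = ch[[i]]$score)
  }))
}

#' Banded pairwise alignment with explicit CIGAR
#'
#' With `chain = NULL` performs a banded global alignment of the full
#' sequences (the band is widened automatically to cover the length
#' difference, and once more if the optimal path touches the band edge;
#' a path still pinned to the edge is flagged `low_conf`). With a chain of
#' anchors, aligns piecewise between consecutive anchors (banded global) and
#' extends past the terminal anchors, soft-clipping unaligned query flanks.
#'
#' @param query,target DNA strings.
#' @param chain optional tibble with `q_pos`/`t_pos` anchor columns
#'   (ascending), e.g. one chain from [chain_anchors()].
#' @param band band half-width in bp.
#' @param scoring see [align_scoring()].
#' @param query_id,target_id identifiers carried into the result.
#' @return a one-row alignment tibble: `query_id`, `target_id`, `strand`,
#'   `q_start`, `q_end`, `t_start`, `t_end` (0-based half-open), `cigar`
#'   (M/I/D/S), `score`, `identity` (matches / alignment columns),
#'   `low_conf`.
#' @export
extend_align <- function(query, target, chain = NULL, band = 500L,
                         scoring = align_scoring(), query_id = "query",
                         target_id = "target") {
  if (is.null(chain)) {
    r <- cpp_align_global(query, target, as.integer(band), scoring$match,
                          scoring$mismatch, scoring$gap_open, scoring$gap_extend)
    return(tibble(query_id = query_id, target_id = target_id, strand = "+",
                  q_start = 0L, q_end = nchar(query), t_start = 0L,
                  t_end = nchar(target), cigar = r$cigar, score = r$score,
                  identity = r$identity, low_conf = r$low_conf))
  }
  stopifnot(nrow(chain) >= 1)
  r <- cpp_extend_chain(query, target, as.integer(chain$q_pos),
                        as.integer(chain$t_pos), as.integer(band),
                        scoring$match, scoring$mismatch, scoring$gap_open,
                        scoring$gap_extend)
  tibble(query_id = query_id, target_id = target_id, strand = "+",
         q_start = r$q_start, q_end = r$q_end, t_start = r$t_start,
         t_end = r$t_end, cigar = r$cigar, score = r$score,
         identity = r$identity, low_conf = r$low_conf)
}

#' Map reads against reference sequences
#'
#' Minimizer seeding, co-linear chaining and (optionally) banded extension of
#' the best chains. Both strands are searched; alignments are returned
#' best-first per read. Reads with no chain above `min_chain_score` yield no
#' rows (unmappable).
#'
#' @param reads named character vector of read sequences, or a tibble with
#'   `read_id`/`bases` columns.
#' @param references an `mz_index`, a named character vector, or a tibble of
#'   reference sequences.
#' @param preset `"long"` or `"short"` (ignored when `references` is already
#'   an index).
#' @param extend compute full banded alignments (CIGAR, score, identity) for
#'   up to `max_extended` chains per read; otherwise only chain coordinates
#'   and `chain_score` are reported.
#' @param max_secondary secondary alignments retained per read.
#' @param max_extended number of top chains per read to extend.
#' @param min_chain_score,max_gap,band override preset parameters.
#' @param scoring see [align_scoring()].
#' @return a tibble with one row per (read, chain): `query_id`, `target_id`,
#'   `strand`, `q_start`, `q_end`, `t_start`, `t_end`, `n_anchors`,
#'   `chain_score`, `score`, `identity`, `cigar`, `low_conf`, `rank`.
#' @export
map_reads <- function(reads, references, preset = c("long", "short"),
                      extend = TRUE, max_secondary = 5L,
                      max_extended = max_secondary + 1L,
                      min_chain_score = NULL, max_gap = NULL, band = NULL,
                      scoring = align_scoring()) {
  if (inherits(references, "mz_index")) {
    idx <- references
    p <- preset_params(if (idx$k >= 21) "short" else "long")
  } else {
    p <- preset_params(preset)
    idx <- build_reference_index(references, preset = match.arg(preset))
  }
  if (!is.null(min_chain_score)) p$min_chain_score <- min_chain_score
  if (!is.null(max_gap)) p$max_gap <- as.integer(max_gap)
  if (!is.null(band)) p$band <- as.integer(band)
  seqs <- as_named_seqs(reads, default_prefix = "read")
  if (length(seqs) == 0) return(empty_alignment())
  raw <- cpp_map(idx$ptr, unname(seqs), p$max_gap, p$min_chain_score,
                 as.integer(max_secondary), extend, p$band, scoring$match,
                 scoring$mismatch, scoring$gap_open, scoring$gap_extend,
                 as.integer(max_extended))
  out <- as_tibble(raw)
  if (nrow(out) == 0) return(empty_alignment())
  out$query_id <- names(seqs)[out$query]
  out$target_id <- idx$names[out$target]
  out$low_conf <- out$low_conf > 0
  out <- out[order(out$query,
                   -ifelse(is.na(out$score), out$chain_score, out$score)), ]
  out <- dplyr::mutate(dplyr::group_by(out, .data$query),
                       rank = dplyr::row_number())
  out <- dplyr::ungroup(out)
  dplyr::select(out, "query_id", "target_id", "strand", "q_start", "q_end",
                "t_start", "t_end", "n_anchors", "chain_score", "score",
                "identity", "cigar", "low_conf", "rank")
}

empty_alignment <- function() {
  tibble(query_id = character(), target_id = character(), strand = character(),
         q_start = integer(), q_end = integer(), t_start = integer(),
         t_end = integer(), n_anchors = integer(), chain_score = numeric(),
         score = numeric(), identity = numeric(), cigar = character(),
         low_conf = logical(), rank = integer())
}

#' Map a single read (best alignments first)
#'
#' @inheritParams map_reads
#' @param read a single DNA string.
#' @return tibble of alignments, best first (empty if unmappable).
#' @export
map_read <- function(read, references, preset = c("long", "short"), ...) {
  map_reads(c(read1 = read), references, preset = preset, ...)
}
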