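# Run-level statistics, troubleshooting flags, and the overlap-based
# accuracy estimate used to validate finished clones against their
# neighbours in a tiling path.

#' Read-length n50
#'
#' The largest length L such that reads of length >= L contain at least half
#' of all bases.
#'
#' @param lengths numeric vector of read lengths (non-empty).
#' @return n50 in bp.
#' @export
#' @examples
#' compute_n50(c(10, 20, 30, 40)) # 30
compute_n50 <- function(lengths) {
  if (length(lengths) == 0) abort("empty length vector")
  s <- sort(lengths, decreasing = TRUE)
  unname(s[which(cumsum(s) >= sum(s) / 2)[1]])
}

#' Summarise a pooled run
#'
#' @param demux a `demux_result`.
#' @param reads the read tibble the demux ran on (for lengths).
#' @param full_calls optional tibble with `clone_id` and `status` columns
#'   (one row per classified read) to count full-length reads per clone.
#' @param clone_length_estimates optional named vector of
#'   [estimate_clone_length()] results.
#' @return object of class `run_stats`.
#' @export
run_stats <- function(demux, reads, full_calls = NULL,
                      clone_length_estimates = NULL) {
  lens <- nchar(as_named_seqs(reads, default_prefix = "read"))
  per_clone <- demux$stats
  per_clone$full_length_count <- if (!is.null(full_calls)) {
    vapply(per_clone$clone_id, function(cl)
      sum(full_calls$clone_id == cl &
            full_calls$status %in% c("FULL_VECTOR_ANCHORED",
                                     "PUTATIVE_FULL_BY_LENGTH")), integer(1))
  } else NA_integer_
  per_clone$clone_length_estimate <- if (!is.null(clone_length_estimates))
    unname(clone_length_estimates[per_clone$clone_id]) else NA_real_
  structure(list(
    total_reads = length(lens),
    total_bases = sum(as.numeric(lens)),
    read_n50 = compute_n50(lens),
    per_clone = per_clone,
    flags = demux$flags
  ), class = "run_stats")
}

#' @export
print.run_stats <- function(x, ...) {
  cat(sprintf("<run_stats> %d reads, %.1f Mb, n50 %d bp, %d clone(s)\n",
              x$total_reads, x$total_bases / 1e6, x$read_n50,
              nrow(x$per_clone)))
  invisible(x)
}

#' Troubleshooting flags for a run
#'
#' Mirrors the protocol troubleshooting table: clones with zero reads
#' (failed culture), finished sequences much shorter than their draft
#' (deletion during culture, or sequence toxic to the host), and runs with
#' a suspiciously low fraction of full-length reads (over-fragmentation
#' during library preparation).
#'
#' @param stats a `run_stats`.
#' @param drafts optional named vector of draft sequences.
#' @param finished optional named vector of finished sequences.
#' @param min_length_frac finished/draft length ratio below which a clone is
#'   flagged `SHORT_CLONE` (default 0.9).
#' @param min_full_length_frac run-level full-length read fraction below
#'   which `LOW_LONG_FRACTION` is raised (default 5e-4).
#' @return tibble with `clone_id` (`NA` for run-level flags), `flag`,
#'   `guidance`.
#' @export
flag_anomalies <- function(stats, drafts = NULL, finished = NULL,
                           min_length_frac = 0.9,
                           min_full_length_frac = 5e-4) {
  out <- list(stats$flags)
  pc <- stats$per_clone
  zero <- pc$clone_id[pc$n_reads == 0]
  zero <- setdiff(zero, stats$flags$clone_id)
  if (length(zero) > 0) {
    out[[length(out) + 1]] <- tibble(
      clone_id = zero, flag = "NO_READS",
      guidance = paste("No reads for one or more clones: clone culture",
                       "failed; regrow and add to the next run, or replace",
                       "the clone with another"))
  }
  if (!is.null(drafts) && !is.null(finished)) {
    common <- intersect(names(drafts), names(finished))
    short <- common[nchar(finished[common]) < min_length_frac *
                      nchar(drafts[common])]
    if (length(short) > 0) {
      out[[length(out) + 1]] <- tibble(
        clone_id = short, flag = "SHORT_CLONE",
        guidance = paste("Clone sequence is shorter than expected or missing",
                         "known sequence: possible deletion during culture;",
                         "regrow the clone from the original culture or",
                         "another library copy"))
    }
  }
  if (!all(is.na(pc$full_length_count))) {
    frac <- sum(pc$full_length_count, na.rm = TRUE) / stats$total_reads
    if (frac < min_full_length_frac) {
      out[[length(out) + 1]] <- tibble(
        clone_id = NA_character_, flag = "LOW_LONG_FRACTION",
        guidance = paste("Low fraction of long reads: transposase treatment",
                         "time too long, or shearing during library prep;",
                         "heat-inactivate promptly and use wide-bore tips"))
    }
  }
  dplyr::bind_rows(out)
}

#' Error rate in the overlap between two finished clones
#'
#' Aligns two finished neighbours, takes their best overlap alignment (at
#' least `min_overlap` aligned columns) and reports differences per aligned
#' megabase -- substitutions and indel columns each count as one error.
#'
#' @param finished_a,finished_b finished clone sequences.
#' @param min_overlap minimum overlap length in bp (default 10 kb).
#' @param band alignment band half-width.
#' @return list with `errors_per_mb`, `overlap_len` (aligned columns) and
#'   `n_differences`; `errors_per_mb` is `NA` when no sufficient overlap is
#'   found.
#' @export
overlap_error_rate <- function(finished_a, finished_b, min_overlap = 10000L,
                               band = 500L) {
  aln <- map_read(finished_b, c(a = finished_a), preset = "long",
                  extend = TRUE, max_secondary = 3L, max_extended = 4L,
                  band = band)
  if (nrow(aln) > 0) {
    cols <- vapply(aln$cigar, function(cg) {
      co <- cigar_ops(cg)
      sum(co$len[co$op %in% c("M", "I", "D")])
    }, numeric(1))
    aln$columns <- cols
    aln <- aln[!is.na(aln$identity) & aln$columns >= min_overlap, ]
  }
  if (nrow(aln) == 0) {
    message("no overlap of at least ", min_overlap, " bp found")
    return(list(errors_per_mb = NA_real_, overlap_len = NA_integer_,
                n_differences = NA_integer_))
  }
  best <- aln[which.max(aln$columns), ]
  cols <- unname(best$columns)
  n_diff <- cols - round(best$identity * cols)
  list(errors_per_mb = n_diff / cols * 1e6,
       overlap_len = as.integer(cols),
       n_differences = as.integer(n_diff))
}
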