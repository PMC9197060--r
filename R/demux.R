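# Barcode-free assignment of pooled nanopore reads to clones by alignment
# against per-clone draft sequences. A read is assigned to the top-scoring
# clone only when the relative score margin over the runner-up is large
# enough; reads inside sequence shared between clones (e.g. a common
# amplicon, or pure vector) tie and are held back as AMBIGUOUS.

#' Assign pooled reads to clones
#'
#' Every read is mapped against all drafts (chain scores on both strands).
#' It is assigned to the best clone iff `(best - second) / best >=
#' margin_frac`; reads with no alignment at all are `UNASSIGNED`; reads whose
#' two best clones are too close are `AMBIGUOUS`.
#'
#' @param reads tibble with `read_id`/`bases` (e.g. from
#'   [simulate_nanopore_run()]) or a named character vector.
#' @param drafts named character vector or tibble of per-clone draft
#'   sequences (one entry per pooled clone).
#' @param vector optional cloning vector sequence; only used to derive the
#'   `is_full_length_eligible` hint (read at least 90% of the shortest draft
#'   plus vector length).
#' @param margin_frac relative score margin in `[0, 0.5]` required for a
#'   unique assignment.
#' @param index optional prebuilt `mz_index` over the drafts.
#' @return a tibble with one row per read: `read_id`, `clone_id` (`NA` when
#'   not assigned), `status` (`ASSIGNED`/`AMBIGUOUS`/`UNASSIGNED`),
#'   `best_score`, `margin` and `is_full_length_eligible`.
#' @export
assign_reads <- function(reads, drafts, vector = NULL, margin_frac = 0.05,
                         index = NULL) {
  stopifnot(margin_frac >= 0, margin_frac <= 0.5)
  drafts <- as_named_seqs(drafts, default_prefix = "clone")
  if (length(drafts) == 0) abort("drafts must cover the pooled clones")
  seqs <- as_named_seqs(reads, default_prefix = "read")
  if (is.null(index)) index <- build_reference_index(drafts, preset = "long")
  aln <- map_reads(seqs, index, extend = FALSE, max_secondary = length(drafts))
  full_len_min <- 0.9 * min(nchar(drafts))
  base <- tibble(read_id = names(seqs),
                 read_len = nchar(unname(seqs)),
                 is_full_length_eligible = nchar(unname(seqs)) >= full_len_min)
  if (nrow(aln) == 0) {
    return(dplyr::mutate(base, clone_id = NA_character_, status = "UNASSIGNED",
                         best_score = NA_real_, margin = NA_real_)[,
      c("read_id", "clone_id", "status", "best_score", "margin",
        "is_full_length_eligible")])
  }
  per_target <- dplyr::summarise(
    dplyr::group_by(aln, .data$query_id, .data$target_id),
    score = max(.data$chain_score), .groups = "drop")
  best2 <- dplyr::summarise(
    dplyr::group_by(per_target, .data$query_id),
    clone_id = .data$target_id[which.max(.data$score)],
    best_score = max(.data$score),
    second = if (dplyr::n() > 1) sort(.data$score, decreasing = TRUE)[2] else 0,
    .groups = "drop")
  best2$margin <- (best2$best_score - best2$second) / best2$best_score
  out <- dplyr::left_join(base, best2, by = c(read_id = "query_id"))
  out$status <- dplyr::case_when(
    is.na(out$best_score) ~ "UNASSIGNED",
    out$margin >= margin_frac ~ "ASSIGNED",
    TRUE ~ "AMBIGUOUS"
  )
  out$clone_id[out$status != "ASSIGNED"] <- NA_character_
  out[, c("read_id", "clone_id", "status", "best_score", "margin",
          "is_full_length_eligible")]
}

#' @rdname assign_reads
#' @param read a single read sequence.
#' @export
assign_read <- function(read, drafts, vector = NULL, margin_frac = 0.05) {
  assign_reads(c(read1 = read), drafts, vector = vector,
               margin_frac = margin_frac)
}

#' Demultiplex a pooled run into per-clone read bins
#'
#' Runs [assign_reads()] and splits reads into per-clone bins plus a shared
#' overflow bin of ambiguous reads. Clones that receive zero reads are
#' flagged (`NO_READS`: usually a failed clone culture).
#'
#' @inheritParams assign_reads
#' @return an object of class `demux_result`: a list with `assignments`
#'   (tibble), `bins` (named list of read-id character vectors, one per
#'   draft), `ambiguous`, `unassigned`, and `stats` (per-clone tibble with
#'   `n_reads` and `fraction` of total reads).
#' @export
demux_pool <- function(reads, drafts, vector = NULL, margin_frac = 0.05) {
  drafts <- as_named_seqs(drafts, default_prefix = "clone")
  asg <- assign_reads(reads, drafts, vector = vector, margin_frac = margin_frac)
  total <- nrow(asg)
  bins <- lapply(names(drafts), function(cl)
    asg$read_id[!is.na(asg$clone_id) & asg$clone_id == cl])
  names(bins) <- names(drafts)
  stats <- tibble(
    clone_id = names(drafts),
    n_reads = unname(vapply(bins, length, integer(1))),
    fraction = unname(vapply(bins, length, integer(1))) / total
  )
  flags <- stats[stats$n_reads == 0, ]
  flag_tbl <- tibble(
    clone_id = flags$clone_id, flag = rep("NO_READS", nrow(flags)),
    guidance = rep(paste("No reads for one or more clones: clone culture",
                         "failed; regrow and add to the next run, or replace",
                         "the clone with another"), nrow(flags)))
  structure(list(
    assignments = asg,
    bins = bins,
    ambiguous = asg$read_id[asg$status == "AMBIGUOUS"],
    unassigned = asg$read_id[asg$status == "UNASSIGNED"],
    stats = stats,
    flags = flag_tbl,
    total_reads = total
  ), class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("<demux_result> %d reads: %d assigned over %d clones, %d ambiguous, %d unassigned\n",
              x$total_reads, sum(x$stats$n_reads), nrow(x$stats),
              length(x$ambiguous), length(x$unassigned)))
  if (nrow(x$flags) > 0)
    cat("  flags:", paste(x$flags$clone_id, x$flags$flag, collapse = "; "), "\n")
  invisible(x)
}
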