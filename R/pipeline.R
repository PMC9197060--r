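# End-to-end orchestration: demultiplex a pooled run, then finish each clone
# (full-length read identification and rotation, backbone selection, long-
# read polishing, Illumina correction, repeat resolution).

#' Default pipeline parameters
#'
#' @param margin_frac demultiplexing score margin (see [assign_reads()]).
#' @param end_window vector-anchor window at each read end (bp).
#' @param polish_window,polish_rounds long-read polishing window and rounds.
#' @param min_depth,min_agree Illumina correction thresholds.
#' @param repeat_min_len minimum repeat-unit length for self-repeat
#'   detection (desk-scale default 2 kb; the full-scale amplicon definition
#'   is 10 kb).
#' @param repeat_min_identity minimum unit-unit identity defining a repeat.
#' @export
pipeline_params <- function(margin_frac = 0.05, end_window = 1000L,
                            polish_window = 500L, polish_rounds = 2L,
                            min_depth = 15L, min_agree = 0.9,
                            repeat_min_len = 2000L,
                            repeat_min_identity = 0.99) {
  list(margin_frac = margin_frac, end_window = end_window,
       polish_window = polish_window, polish_rounds = polish_rounds,
       min_depth = min_depth, min_agree = min_agree,
       repeat_min_len = repeat_min_len,
       repeat_min_identity = repeat_min_identity)
}

#' Finish a single clone
#'
#' From one clone's long-read bin, draft and short reads: estimate the clone
#' length, classify and rotate full-length reads, select the backbone,
#' polish with long reads, correct to the Illumina consensus, and resolve
#' internal repeats when present.
#'
#' @param clone_id clone identifier.
#' @param long_reads named character vector (or tibble) of the clone's
#'   nanopore reads.
#' @param draft draft sequence (single string; concatenate contigs upstream
#'   if needed).
#' @param vector cloning vector sequence.
#' @param illumina_reads character vector of the clone's short reads (both
#'   mates).
#' @param params see [pipeline_params()].
#' @return a `consensus_assembly` with extra fields `full_calls` (tibble),
#'   `backbone_read` and `clone_length_estimate`.
#' @export
finish_clone <- function(clone_id, long_reads, draft, vector, illumina_reads,
                         params = pipeline_params()) {
  long_reads <- as_named_seqs(long_reads, default_prefix = "lr")
  if (length(long_reads) == 0)
    abort(sprintf("clone %s has no long reads", clone_id))
  lens <- nchar(long_reads)
  est <- if (length(lens) >= 20) estimate_clone_length(lens) else NA_real_
  # classify reads long enough to carry a vector hit (one batched vector
  # search over the whole bin)
  long_enough <- names(long_reads)[nchar(long_reads) >= 1000]
  all_hits <- batch_vector_hits(long_reads[long_enough], vector)
  calls <- dplyr::bind_rows(lapply(names(long_reads), function(id) {
    s <- long_reads[[id]]
    if (nchar(s) < 1000) {
      return(tibble(read_id = id, status = "PARTIAL", n_vector_hits = 0L,
                    rotation_offset = NA_integer_,
                    rotation_strand = NA_character_, hits = list(tibble())))
    }
    classify_full_length(s, vector, clone_length_estimate = est,
                         end_window = params$end_window, read_id = id,
                         hits = all_hits[[id]])
  }))
  rotatable <- calls$read_id[calls$status %in% c("FULL_VECTOR_ANCHORED",
                                                 "PUTATIVE_FULL_BY_LENGTH") &
                               !is.na(calls$rotation_offset)]
  rotated <- vapply(rotatable, function(id) {
    rotate_to_vector(long_reads[[id]],
                     calls[calls$read_id == id, ])$sequence
  }, character(1))
  names(rotated) <- rotatable
  # putative-full reads are unsafe backbones for internally repetitive
  # clones (a mid-repeat cut rotates ambiguously)
  repetitive_draft <- !is.null(draft) &&
    nchar(draft) >= 2 * params$repeat_min_len &&
    nrow(suppressWarnings(detect_self_repeats(
      draft, params$repeat_min_len, params$repeat_min_identity))) > 0
  backbone <- select_backbone(calls, rotated, draft,
                              include_putative = !repetitive_draft)
  pl <- polish_long(backbone$sequence, long_reads,
                    window = params$polish_window,
                    rounds = params$polish_rounds)
  # the backbone read's rotation is only as exact as its raw-read vector
  # alignment; re-anchor the origin on the polished sequence
  vhits <- find_vector_hits(pl$sequence, vector)
  if (nrow(vhits) > 0) {
    rot <- rotate_to_vector(pl$sequence, vhits[which.min(vhits$v_start), ])
    if (identical(rot$strand, "+") && rot$rotation_offset > 0) {
      o <- rot$rotation_offset
      pl$sequence <- rot$sequence
      pl$depth <- c(pl$depth[(o + 1):length(pl$depth)], pl$depth[1:o])
    }
  }
  ps <- polish_short(pl$sequence, illumina_reads,
                     min_depth = params$min_depth,
                     min_agree = params$min_agree, clone_id = clone_id,
                     long_depth = pl$depth, circular = TRUE)
  result <- ps
  if (nchar(result$sequence) >= 2 * params$repeat_min_len) {
    # residual unresolved errors inside repeat units depress their mutual
    # identity on the pre-resolution consensus; detect with slack, then let
    # unit-wise resolution restore the true identity
    detect_identity <- max(0.94, params$repeat_min_identity - 0.04)
    for (resolve_pass in 1:2) {
      units <- detect_self_repeats(result$sequence, params$repeat_min_len,
                                   detect_identity)
      if (nrow(units) == 0) break
      sfvs <- call_sfvs(units, result$sequence, illumina_reads,
                        min_depth = params$min_depth,
                        min_agree = params$min_agree)
      prev_seq <- result$sequence
      result <- finish_repetitive(result, units, sfvs, long_reads,
                                  illumina_reads,
                                  min_depth = params$min_depth,
                                  min_agree = params$min_agree,
                                  rebuild = (resolve_pass == 1))
      if (identical(result$sequence, prev_seq)) break
    }
  }
  # final canonicalization: anchor the origin exactly at vector base 0
  # (vector-first is the coordinate frame every report relies on)
  vh2 <- find_vector_hits(result$sequence, vector)
  if (nrow(vh2) > 0) {
    rot2 <- rotate_to_vector(result$sequence, vh2[which.min(vh2$v_start), ])
    if (identical(rot2$strand, "+") && rot2$rotation_offset > 0)
      result$sequence <- rot2$sequence
  }
  result$clone_id <- clone_id
  result$full_calls <- calls
  result$backbone_read <- backbone$read_id
  result$clone_length_estimate <- est
  result
}

#' Run the full pipeline on a pooled run
#'
#' Demultiplexes the pooled nanopore reads against the drafts, finishes each
#' clone independently, and assembles run statistics and troubleshooting
#' flags.
#'
#' @param reads pooled nanopore reads (tibble with `read_id`/`bases`, or a
#'   named character vector).
#' @param drafts named character vector (or tibble) of per-clone drafts.
#' @param vector cloning vector sequence.
#' @param illumina per-clone short reads: a tibble with `clone_id`,
#'   `bases1`, `bases2` (e.g. from [simulate_illumina()]), or a named list
#'   of character vectors.
#' @param params see [pipeline_params()].
#' @return object of class `finish_run`: list with `assemblies` (named list
#'   of `consensus_assembly`), `demux`, `stats`, `flags`.
#' @export
run_all <- function(reads, drafts, vector, illumina,
                    params = pipeline_params()) {
  drafts <- as_named_seqs(drafts, default_prefix = "clone")
  read_seqs <- as_named_seqs(reads, default_prefix = "read")
  demux <- demux_pool(read_seqs, drafts, vector,
                      margin_frac = params$margin_frac)
  illumina_of <- function(cl) {
    if (is.data.frame(illumina)) {
      sub <- illumina[illumina$clone_id == cl, ]
      c(sub$bases1, sub$bases2)
    } else illumina[[cl]]
  }
  assemblies <- list()
  full_calls <- list()
  ests <- numeric(0)
  for (cl in names(drafts)) {
    rid <- demux$bins[[cl]]
    if (length(rid) == 0) next
    asm <- finish_clone(cl, read_seqs[rid], drafts[[cl]], vector,
                        illumina_of(cl), params = params)
    assemblies[[cl]] <- asm
    fc <- asm$full_calls
    fc$clone_id <- cl
    full_calls[[cl]] <- fc[, c("clone_id", "read_id", "status")]
    ests[cl] <- asm$clone_length_estimate
  }
  stats <- run_stats(demux, read_seqs,
                     full_calls = dplyr::bind_rows(full_calls),
                     clone_length_estimates = ests)
  finished <- vapply(assemblies, function(a) a$sequence, character(1))
  flags <- flag_anomalies(stats, drafts = drafts, finished = finished)
  structure(list(assemblies = assemblies, demux = demux, stats = stats,
                 flags = flags), class = "finish_run")
}

#' @export
print.finish_run <- function(x, ...) {
  cat(sprintf("<finish_run> %d finished clone(s) of %d, %d flag(s)\n",
              length(x$assemblies), nrow(x$stats$per_clone), nrow(x$flags)))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Finished clones as FASTA, discrepancies as TSV, run statistics as JSON,
#' and (optionally) read alignments as SAM split under the BAM operation
#' limit.
#'
#' @param run a `finish_run`.
#' @param dir output directory (created if missing).
#' @param write_alignments also write per-clone read alignments (SAM, split
#'   every 1000 match operations).
#' @param reads the pooled reads (required for `write_alignments`).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir, write_alignments = FALSE,
                              reads = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  finished <- vapply(run$assemblies, function(a) a$sequence, character(1))
  write_fasta(finished, file.path(dir, "finished.fasta"))
  disc <- dplyr::bind_rows(lapply(run$assemblies, function(a) {
    d <- a$discrepancies
    if (nrow(d) > 0) d$clone_id <- a$clone_id
    d
  }))
  utils::write.table(disc, file.path(dir, "discrepancies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stats <- run$stats
  jsonlite::write_json(list(
    total_reads = stats$total_reads, total_bases = stats$total_bases,
    read_n50 = stats$read_n50, per_clone = stats$per_clone,
    flags = run$flags), file.path(dir, "run_stats.json"),
    auto_unbox = TRUE, digits = NA)
  if (write_alignments) {
    stopifnot(!is.null(reads))
    read_seqs <- as_named_seqs(reads, default_prefix = "read")
    recs <- list()
    for (cl in names(run$assemblies)) {
      asm <- run$assemblies[[cl]]
      rid <- run$demux$bins[[cl]]
      if (length(rid) == 0) next
      aln <- map_reads(read_seqs[rid], c(stats::setNames(asm$sequence, cl)),
                       preset = "long", max_secondary = 0L, max_extended = 1L)
      aln <- aln[aln$rank == 1 & !is.na(aln$score), ]
      for (i in seq_len(nrow(aln))) {
        rec <- alignment_to_sam(aln[i, ], read_seqs[[aln$query_id[i]]])
        recs[[length(recs) + 1]] <- split_alignment(rec)
      }
    }
    write_sam(dplyr::bind_rows(recs),
              vapply(run$assemblies, function(a) nchar(a$sequence),
                     numeric(1)),
              file.path(dir, "alignments.split.sam"))
  }
  invisible(dir)
}
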