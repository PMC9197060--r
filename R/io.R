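# Plain-text sequence and alignment I/O: FASTA, FASTQ and SAM, plus the
# alignment-splitting workaround for tools limited by CIGAR operation counts.

read_text_lines <- function(path) {
  con <- gzfile(path, open = "rb")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  sub("\r$", "", lines) # accept CRLF input
}

#' Read a FASTA file
#'
#' Accepts wrapped or unwrapped records and CRLF line endings; gzip input is
#' handled transparently. Malformed records are rejected with the offending
#' line number.
#'
#' @param path file path (optionally gzip-compressed).
#' @return a tibble with columns `name` (full header without the `>`) and
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nchar(lines) > 0 | c(rep(TRUE, length(lines) - 1), FALSE)]
  hdr <- startsWith(lines, ">")
  if (length(lines) == 0 || !hdr[1])
    abort(sprintf("%s: line 1: expected '>' header", path))
  rec <- cumsum(hdr)
  name <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1), collapse = "")
  # records with no sequence lines at all are missing from the split
  empty <- setdiff(seq_along(name), as.integer(names(seqs)))
  bad <- c(empty, as.integer(names(seqs))[nchar(seqs) == 0])
  if (length(bad) > 0) {
    line_no <- which(hdr)[min(bad)]
    abort(sprintf("%s: line %d: record '%s' has an empty sequence",
                  path, line_no, name[min(bad)]))
  }
  out <- character(length(name))
  out[as.integer(names(seqs))] <- seqs
  tibble(name = name, sequence = toupper(out))
}

#' Write a FASTA file
#'
#' @param x a named character vector of sequences, or a tibble with
#'   `name`/`sequence` columns.
#' @param path output path.
#' @param width line width for wrapping; 0 (default) writes one line per
#'   sequence, which round-trips byte-stably through [read_fasta()].
#' @export
write_fasta <- function(x, path, width = 0) {
  seqs <- as_named_seqs(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con, sep = "\n")
    s <- seqs[[i]]
    if (width > 0) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con, sep = "\n")
    } else writeLines(s, con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path file path (optionally gzip-compressed).
#' @return a tibble with columns `read_id`, `comment` (text after the first
#'   space in the header, `""` if absent), `sequence` and `quality`.
#' @export
read_fastq <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!(seq_along(lines) > length(lines) - 1 & lines == "")]
  if (length(lines) %% 4 != 0)
    abort(sprintf("%s: truncated FASTQ (%d lines, not a multiple of 4)",
                  path, length(lines)))
  n <- length(lines) / 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seqs <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0)
    abort(sprintf("%s: line %d: expected '@' header", path, (bad[1] - 1) * 4 + 1))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0)
    abort(sprintf("%s: line %d: expected '+' separator", path, (bad[1] - 1) * 4 + 3))
  bad <- which(nchar(seqs) == 0)
  if (length(bad) > 0)
    abort(sprintf("%s: line %d: empty sequence", path, (bad[1] - 1) * 4 + 2))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad) > 0)
    abort(sprintf("%s: line %d: sequence/quality length mismatch",
                  path, (bad[1] - 1) * 4 + 4))
  hdr <- sub("^@", "", hdr)
  sp <- regexpr(" ", hdr, fixed = TRUE)
  tibble(
    read_id = ifelse(sp > 0, substr(hdr, 1, sp - 1), hdr),
    comment = ifelse(sp > 0, substring(hdr, sp + 1), ""),
    sequence = toupper(seqs),
    quality = qual
  )
}

#' Write a FASTQ file
#'
#' @param x a tibble with `read_id`, `sequence` and optionally `comment` and
#'   `quality` columns (missing qualities are written as `I`).
#' @param path output path.
#' @export
write_fastq <- function(x, path) {
  qual <- if ("quality" %in% names(x)) x$quality
          else vapply(nchar(x$sequence), function(n) strrep("I", n), character(1))
  comment <- if ("comment" %in% names(x)) x$comment else rep("", nrow(x))
  hdr <- paste0("@", x$read_id, ifelse(comment == "", "", paste0(" ", comment)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(rbind(hdr, x$sequence, "+", qual), con, sep = "\n")
  invisible(path)
}

# ---------------------------------------------------------------------- SAM

sam_cols <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "rnext",
              "pnext", "tlen", "seq", "qual", "tags")

new_sam_record <- function(qname, flag, rname, pos, mapq, cigar, seq,
                           qual = "*", tags = "") {
  tibble(qname = qname, flag = as.integer(flag), rname = rname,
         pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
         rnext = "*", pnext = 0L, tlen = 0L, seq = seq, qual = qual,
         tags = tags)
}

#' Convert an alignment to a SAM record
#'
#' Internal 0-based half-open target coordinates become 1-based `POS`; minus
#' strand is encoded in flag bit `0x10` with the stored sequence
#' reverse-complemented; soft clips are preserved.
#'
#' @param aln a one-row alignment tibble (as produced by [map_read()] or
#'   [extend_align()]).
#' @param query_seq the read sequence in its original orientation.
#' @param mapq mapping quality to record.
#' @return a one-row SAM record tibble.
#' @export
alignment_to_sam <- function(aln, query_seq, mapq = 60L) {
  stopifnot(nrow(aln) == 1)
  minus <- aln$strand == "-"
  new_sam_record(
    qname = aln$query_id, flag = if (minus) 16L else 0L,
    rname = aln$target_id, pos = aln$t_start + 1L, mapq = mapq,
    cigar = aln$cigar, seq = if (minus) revcomp(query_seq) else query_seq
  )
}

#' Convert a SAM record back to an alignment tibble
#'
#' Inverse of [alignment_to_sam()] up to fields SAM does not carry
#' (chain score, identity).
#'
#' @param rec a one-row SAM record tibble.
#' @return a one-row alignment tibble.
#' @export
sam_to_alignment <- function(rec) {
  sp <- cigar_spans(rec$cigar)
  co <- cigar_ops(rec$cigar)
  lead <- if (nrow(co) > 0 && co$op[1] == "S") co$len[1] else 0L
  trail <- if (nrow(co) > 1 && co$op[nrow(co)] == "S") co$len[nrow(co)] else 0L
  tibble(query_id = rec$qname, target_id = rec$rname,
         strand = if (bitwAnd(rec$flag, 16L) > 0L) "-" else "+",
         q_start = lead, q_end = lead + sp$aligned_query,
         t_start = rec$pos - 1L, t_end = rec$pos - 1L + sp$target,
         cigar = rec$cigar, score = NA_real_, identity = NA_real_)
}

#' Write SAM records to a file
#'
#' @param records a tibble of SAM records.
#' @param ref_lengths named integer vector of reference lengths for `@SQ`
#'   header lines.
#' @param path output path.
#' @export
write_sam <- function(records, ref_lengths, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con, sep = "\n")
  for (i in seq_along(ref_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths)[i],
                       as.integer(ref_lengths[i])), con, sep = "\n")
  }
  if (nrow(records) > 0) {
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                    records$qname, records$flag, records$rname, records$pos,
                    records$mapq, records$cigar, records$rnext, records$pnext,
                    records$tlen, records$seq, records$qual)
    extra <- !is.na(records$tags) & records$tags != ""
    body[extra] <- paste(body[extra], records$tags[extra], sep = "\t")
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' Read a SAM file
#'
#' @param path path to a SAM file.
#' @return a list with `header` (character vector of header lines) and
#'   `records` (tibble of SAM records).
#' @export
read_sam <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nchar(lines) > 0]
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0)
    return(list(header = hdr, records = new_sam_record(character(), integer(),
                character(), integer(), integer(), character(), character())[0, ]))
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11)
  if (length(bad) > 0)
    abort(sprintf("%s: line %d: SAM record with fewer than 11 fields",
                  path, length(hdr) + bad[1]))
  recs <- tibble(
    qname = vapply(fields, `[[`, "", 1),
    flag = as.integer(vapply(fields, `[[`, "", 2)),
    rname = vapply(fields, `[[`, "", 3),
    pos = as.integer(vapply(fields, `[[`, "", 4)),
    mapq = as.integer(vapply(fields, `[[`, "", 5)),
    cigar = vapply(fields, `[[`, "", 6),
    rnext = vapply(fields, `[[`, "", 7),
    pnext = as.integer(vapply(fields, `[[`, "", 8)),
    tlen = as.integer(vapply(fields, `[[`, "", 9)),
    seq = vapply(fields, `[[`, "", 10),
    qual = vapply(fields, `[[`, "", 11),
    tags = vapply(fields, function(f)
      if (length(f) > 11) paste(f[-(1:11)], collapse = "\t") else "", "")
  )
  list(header = hdr, records = recs)
}

# ------------------------------------------------------- split / merge SAM

#' Split an alignment record under the BAM operation limit
#'
#' Ultra-long read alignments can exceed the 65535 CIGAR operations that the
#' BAM format can encode. This cuts a SAM record into uniquely named
#' sub-alignments after every `match_ops_per_chunk` M operations (counting
#' CIGAR elements, not bases, unless `count_bases = TRUE`). Each sub-record is
#' independently valid: `POS` is recomputed, the sequence is carried in full
#' with the out-of-chunk flanks soft-clipped, and concatenating the
#' sub-alignments reproduces the original aligned columns exactly. Every
#' emitted record is guaranteed to stay within 65535 operations regardless of
#' input composition.
#'
#' @param record a one-row SAM record tibble (mapped; unmapped records are
#'   passed through unchanged).
#' @param match_ops_per_chunk number of M operations per chunk (default 1000).
#' @param count_bases count M bases rather than M operations.
#' @return a tibble of SAM records; sub-records are named
#'   `{qname}.p0001`, `{qname}.p0002`, ...
#' @export
split_alignment <- function(record, match_ops_per_chunk = 1000L,
                            count_bases = FALSE) {
  stopifnot(nrow(record) == 1)
  if (bitwAnd(record$flag, 4L) > 0L || record$cigar == "*") return(record)
  co <- cigar_ops(record$cigar)
  q_len <- sum(co$len[co$op %in% c("M", "I", "S", "=", "X")])
  orig_lead_s <- if (co$op[1] == "S") co$len[1] else 0L
  b_ops <- co$op[co$op != "S"]; b_lens <- co$len[co$op != "S"]
  n <- length(b_ops)
  # when counting M bases, an M element may be cut at a chunk boundary;
  # pre-split such elements so chunk assignment stays element-wise
  if (count_bases) {
    is_m <- b_ops %in% c("M", "=", "X")
    n_extra <- sum(b_lens[is_m]) %/% match_ops_per_chunk + 8L
    new_ops <- character(n + n_extra); new_lens <- integer(n + n_extra)
    j <- 0L; m_acc <- 0L
    for (i in seq_len(n)) {
      op <- b_ops[i]; len <- b_lens[i]
      if (op %in% c("M", "=", "X")) {
        while (m_acc + len > match_ops_per_chunk) {
          take <- match_ops_per_chunk - m_acc
          if (take > 0L) {
            j <- j + 1L; new_ops[j] <- op; new_lens[j] <- take
            len <- len - take
          }
          m_acc <- 0L
        }
        m_acc <- m_acc + len
      }
      if (len > 0L) { j <- j + 1L; new_ops[j] <- op; new_lens[j] <- len }
    }
    b_ops <- new_ops[seq_len(j)]; b_lens <- new_lens[seq_len(j)]
    n <- j
  }
  # element-wise chunk assignment: a new chunk starts only at an M element
  # (I/D stay with the chunk they begin in), after match_ops_per_chunk M
  # units, and never later than 65533 ops into a chunk (leaving room for
  # two soft clips under the 65535-operation BAM limit)
  is_m <- b_ops %in% c("M", "=", "X")
  m_units <- if (count_bases) ifelse(is_m, b_lens, 0L) else as.integer(is_m)
  chunk <- integer(n)
  cur <- 1L; m_acc <- 0L; op_acc <- 0L
  for (i in seq_len(n)) {
    if ((m_acc >= match_ops_per_chunk && is_m[i]) || op_acc >= 65533L) {
      cur <- cur + 1L; m_acc <- 0L; op_acc <- 0L
    }
    chunk[i] <- cur
    m_acc <- m_acc + m_units[i]
    op_acc <- op_acc + 1L
  }
  n_chunks <- chunk[n]
  if (n_chunks == 1L) return(record)
  idx_of <- unname(split(seq_len(n), chunk))
  q_steps <- ifelse(b_ops %in% c("M", "I", "=", "X"), b_lens, 0L)
  t_steps <- ifelse(b_ops %in% c("M", "D", "=", "X"), b_lens, 0L)
  out <- vector("list", n_chunks)
  q_before <- orig_lead_s
  t_before <- 0L
  for (ch in seq_len(n_chunks)) {
    sel <- idx_of[[ch]]
    q_span <- sum(q_steps[sel])
    rec <- record
    rec$qname <- sprintf("%s.p%04d", record$qname, ch)
    rec$pos <- record$pos + t_before
    rec$cigar <- cigar_string(c("S", b_ops[sel], "S"),
                              c(q_before, b_lens[sel],
                                q_len - q_before - q_span))
    out[[ch]] <- rec
    q_before <- q_before + q_span
    t_before <- t_before + sum(t_steps[sel])
  }
  dplyr::bind_rows(out)
}

#' Merge split sub-alignments back into one record
#'
#' Inverse of [split_alignment()]: sub-records sharing a base qname and
#' coordinate-contiguous on the reference are reassembled into a single
#' record whose aligned columns equal the original's.
#'
#' @param sub_records tibble of SAM records produced by [split_alignment()]
#'   (any order).
#' @return a one-row SAM record tibble.
#' @export
merge_split <- function(sub_records) {
  if (nrow(sub_records) == 1) return(sub_records)
  base <- unique(sub("\\.p[0-9]{4}$", "", sub_records$qname))
  if (length(base) != 1) abort("sub-records do not share a base qname")
  sub_records <- sub_records[order(sub_records$qname), ]
  ops_all <- character(0); lens_all <- integer(0)
  q_cursor <- 0L; t_cursor <- NA_integer_
  for (i in seq_len(nrow(sub_records))) {
    co <- cigar_ops(sub_records$cigar[i])
    lead <- if (co$op[1] == "S") co$len[1] else 0L
    trail <- if (co$op[nrow(co)] == "S") co$len[nrow(co)] else 0L
    body <- co[!(seq_len(nrow(co)) %in% c(if (co$op[1] == "S") 1L,
                                          if (co$op[nrow(co)] == "S") nrow(co))), ]
    if (i == 1) {
      t_cursor <- sub_records$pos[i]
      first_lead <- lead
      ops_all <- c("S", body$op); lens_all <- c(first_lead, body$len)
    } else {
      if (lead != q_cursor)
        abort(sprintf("gap or overlap in query between sub-records (%d vs %d)",
                      lead, q_cursor))
      if (sub_records$pos[i] != t_cursor)
        abort(sprintf("gap or overlap on reference between sub-records (%d vs %d)",
                      sub_records$pos[i], t_cursor))
      ops_all <- c(ops_all, body$op); lens_all <- c(lens_all, body$len)
    }
    q_cursor <- lead + sum(body$len[body$op %in% c("M", "I", "=", "X")])
    t_cursor <- sub_records$pos[i] + sum(body$len[body$op %in% c("M", "D", "=", "X")])
  }
  q_len <- nchar(sub_records$seq[1])
  trail_s <- q_len - q_cursor
  rec <- sub_records[1, ]
  rec$qname <- base
  rec$cigar <- cigar_string(c(ops_all, "S"), c(lens_all, trail_s))
  rec
}
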