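# Per-clone consensus: pick the best full-length read as the backbone,
# polish it with all long reads (windowed weighted column consensus), then
# correct residual errors to the Illumina consensus -- frequent
# insertion/deletion errors at homopolymer runs and rarer substitutions.

new_consensus_assembly <- function(clone_id, sequence, support, discrepancies,
                                   rounds_applied, flags = tibble()) {
  structure(list(clone_id = clone_id, sequence = sequence, support = support,
                 discrepancies = discrepancies,
                 rounds_applied = rounds_applied, flags = flags),
            class = "consensus_assembly")
}

#' @export
print.consensus_assembly <- function(x, ...) {
  cat(sprintf("<consensus_assembly> %s: %d bp, %d discrepancy record(s), %d polish pass(es)\n",
              x$clone_id, nchar(x$sequence), nrow(x$discrepancies),
              x$rounds_applied))
  invisible(x)
}

# Orient query sequences to the target strand for pileup (the CIGAR of a
# minus-strand alignment applies to the reverse-complemented query).
oriented_query <- function(aln, seqs) {
  q <- unname(seqs[aln$query_id])
  minus <- aln$strand == "-"
  q[minus] <- revcomp(q[minus])
  q
}

#' Select the consensus backbone read
#'
#' The highest-identity (vs the draft) vector-anchored full-length read,
#' already rotated to canonical orientation; deterministic tie-break by
#' lexicographic read id. Falls back to the draft with a warning when no
#' full-length read exists.
#'
#' @param full_calls tibble of [classify_full_length()] rows.
#' @param reads named character vector of canonical (rotated) read
#'   sequences for the candidate reads.
#' @param draft draft sequence (fallback and identity reference).
#' @param include_putative also consider `PUTATIVE_FULL_BY_LENGTH` reads
#'   (keep `FALSE` for internally repetitive clones, where a mid-repeat cut
#'   cannot be rotated unambiguously).
#' @return list with `read_id` (`NA` for draft fallback), `sequence`,
#'   `identity`.
#' @export
select_backbone <- function(full_calls, reads, draft,
                            include_putative = FALSE) {
  cand <- full_calls$read_id[full_calls$status == "FULL_VECTOR_ANCHORED"]
  cand <- intersect(cand, names(reads))
  if (length(cand) == 0 && include_putative) {
    # by-length calls are a fallback only: they lack the vector anchor that
    # certifies a complete traversal
    cand <- intersect(
      full_calls$read_id[full_calls$status == "PUTATIVE_FULL_BY_LENGTH"],
      names(reads))
  }
  if (length(cand) == 0) {
    if (is.null(draft) || is.na(draft) || nchar(draft) == 0) {
      abort(paste("no full-length reads and no draft: the clone cannot be",
                  "assembled and should be re-sequenced"))
    }
    warn("no full-length reads: falling back to the draft as backbone")
    return(list(read_id = NA_character_, sequence = draft, identity = NA_real_))
  }
  ident <- vapply(cand, function(id) {
    a <- map_read(reads[[id]], c(draft = draft), preset = "long",
                  max_secondary = 0L, max_extended = 1L)
    if (nrow(a) == 0) NA_real_ else a$identity[1]
  }, numeric(1))
  ord <- order(-ident, cand)
  best <- cand[ord[1]]
  list(read_id = best, sequence = reads[[best]], identity = ident[[best]])
}

# One round of long-read column consensus against `cur`. Reads come from a
# circular molecule cut anywhere, so they are aligned against a doubled
# backbone and the column stack is folded back modulo the backbone length;
# a read spanning the origin then aligns contiguously.
long_consensus_round <- function(cur, read_seqs, window, band,
                                 ins_frac = 0.3, circular = TRUE) {
  L <- nchar(cur)
  target <- if (circular) paste0(cur, cur) else cur
  idx <- build_reference_index(c(backbone = target), preset = "long")
  aln <- map_reads(read_seqs, idx, extend = TRUE, max_secondary = 0L,
                   max_extended = 1L, band = band)
  aln <- aln[aln$rank == 1 & !is.na(aln$score), ]
  if (nrow(aln) == 0) {
    return(list(sequence = cur, zero_windows = seq(0, L - 1, by = window),
                depth = rep(0, L)))
  }
  pile <- cpp_pileup(nchar(target), aln$t_start, aln$cigar,
                     oriented_query(aln, read_seqs),
                     pmax(aln$identity, 0.01))
  if (circular) {
    counts <- pile$counts[, 1:L] + pile$counts[, (L + 1):(2 * L)]
    depth <- pile$depth[1:L] + pile$depth[(L + 1):(2 * L)]
    span <- pile$span[1:L] + pile$span[(L + 1):(2 * L)]
    pile$ins_pos <- pile$ins_pos %% L
  } else {
    counts <- pile$counts; depth <- pile$depth; span <- pile$span
  }
  chars <- strsplit(cur, "", fixed = TRUE)[[1]]
  best <- max.col(t(counts), ties.method = "first")
  newb <- c("A", "C", "G", "T", "")[best]
  keep_backbone <- depth == 0
  newb[keep_backbone] <- chars[keep_backbone]
  # majority insertions
  if (length(pile$ins_pos) > 0) {
    ins <- tibble(pos = pile$ins_pos, seq = pile$ins_seq, w = pile$ins_weight)
    ins <- dplyr::summarise(dplyr::group_by(ins, .data$pos, .data$seq),
                            w = sum(.data$w), .groups = "drop")
    ins <- dplyr::slice_max(dplyr::group_by(ins, .data$pos), .data$w,
                            n = 1, with_ties = FALSE)
    ins <- dplyr::ungroup(ins)
    # insertion support is structurally diluted: a read carrying its own
    # deletion error nearby absorbs the missing base into mismatches, so a
    # true missing base rarely reaches 50% exact-position support; accept at
    # ins_frac of depth (false insertions lose the majority-deletion vote in
    # the next round and under Illumina correction)
    denom <- pmax(span[ins$pos + 1], 1e-9)
    ins <- ins[ins$w >= ins_frac * denom & span[ins$pos + 1] > 0, ]
    if (nrow(ins) > 0)
      newb[ins$pos + 1] <- paste0(ins$seq, newb[ins$pos + 1])
  }
  win_start <- seq(0, L - 1, by = window)
  win_depth <- vapply(win_start, function(s)
    sum(depth[(s + 1):min(L, s + window)]), numeric(1))
  list(sequence = paste(newb, collapse = ""),
       zero_windows = win_start[win_depth == 0], depth = depth)
}

#' Polish a backbone with long reads
#'
#' Reads are aligned to the backbone; the backbone is partitioned into
#' windows and each column takes the weighted majority base (weight =
#' alignment identity) over the backbone-anchored column stack, with
#' majority insertions honoured; repeated `rounds` times. Windows with zero
#' coverage keep the backbone sequence and are flagged.
#'
#' @param backbone backbone sequence (canonical orientation).
#' @param long_reads named character vector of long-read sequences.
#' @param window window size in bp (>= 100).
#' @param rounds polishing rounds (>= 1).
#' @param band alignment band half-width.
#' @param ins_frac fraction of junction-spanning support required to accept
#'   a majority insertion (see Details in the methods vignette).
#' @param circular treat the backbone as a circular molecule (align against
#'   a doubled copy and fold the evidence).
#' @return list with `sequence`, `zero_coverage_windows` (window start
#'   positions in the final round) and `depth` (per-base weighted long-read
#'   depth from the final round).
#' @export
polish_long <- function(backbone, long_reads, window = 500L, rounds = 2L,
                        band = 500L, ins_frac = 0.3, circular = TRUE) {
  stopifnot(window >= 100, rounds >= 1)
  long_reads <- as_named_seqs(long_reads, default_prefix = "read")
  cur <- backbone
  res <- NULL
  for (r in seq_len(rounds)) {
    res <- long_consensus_round(cur, long_reads, window, band, ins_frac,
                                circular)
    cur <- res$sequence
  }
  list(sequence = cur, zero_coverage_windows = res$zero_windows,
       depth = res$depth)
}

# Push region boundaries outward until the base just outside differs from
# the base just inside, so no boundary cuts through a same-base run (where
# equivalent indel placements straddle the cut and split the vote).
snap_region <- function(chars, a, b) {
  L <- length(chars)
  # a boundary is stable when the bases on either side of it differ AND the
  # first two bases outside differ (an inserted base equal to the run just
  # outside could otherwise be placed on either side of the cut)
  while (a >= 2 && (chars[a] == chars[a + 1] || chars[a - 1] == chars[a]))
    a <- a - 1L
  while (b <= L - 2 && (chars[b] == chars[b + 1] || chars[b + 1] == chars[b + 2]))
    b <- b + 1L
  c(a, b)
}

# Tally of region observation strings with singletons removed: a clone is a
# single molecule, so a string seen in exactly one read is an individual
# read error, never a real second allele.
region_tab <- function(o) {
  tab <- sort(table(o), decreasing = TRUE)
  if (length(o) >= 6) tab <- tab[tab >= 2]
  if (length(tab) == 0) return(NULL)
  tab
}

# A region vote is accepted when the top string reaches min_agree, or when
# it dominates the runner-up 3:1 -- a clone is one molecule, so a genuinely
# contested region (e.g. reads mis-partitioned between repeat units) shows
# balanced support, while alignment-placement jitter at short tandem
# repeats shows a dominant string with shifted low-count variants.
region_accept <- function(tab, agree, min_agree, dominance = TRUE) {
  if (agree >= min_agree || length(tab) == 1) return(TRUE)
  dominance && tab[[1]] >= 3 * tab[[2]]
}

# Candidate edits for one short-read polishing pass. When `circular`, the
# alignments were made against the doubled sequence and all evidence is
# folded back modulo L, so edge columns and origin-spanning reads are
# handled like any interior column.
short_pass_edits <- function(cur, aln, read_seqs, min_depth, min_agree,
                             circular = FALSE, dominance = TRUE) {
  L <- nchar(cur)
  # region votes count only reads spanning the whole region plus a flank,
  # a systematically smaller pool than per-column depth; scale the floor
  region_min <- max(10L, as.integer(ceiling(min_depth * 2 / 3)))
  tlen <- if (circular) 2L * L else L
  chars <- strsplit(cur, "", fixed = TRUE)[[1]]
  oriented <- oriented_query(aln, read_seqs)
  pile <- cpp_pileup(tlen, aln$t_start, aln$cigar, oriented, rep(1, nrow(aln)))
  if (circular) {
    counts <- pile$counts[, 1:L] + pile$counts[, (L + 1):(2 * L)]
    depth <- pile$depth[1:L] + pile$depth[(L + 1):(2 * L)]
    span <- pile$span[1:L] + pile$span[(L + 1):(2 * L)]
    pile$ins_pos <- pile$ins_pos %% L
  } else {
    counts <- pile$counts; depth <- pile$depth; span <- pile$span
  }
  runs <- homopolymer_runs(cur, 3L)
  masked <- logical(L)
  ins_blocked <- logical(L) # strict region interior: boundary insertions at
                            # a region start stay eligible as column edits
  edits <- list(); unres <- list()
  # homopolymer regions (run plus one flank base each side, merged when
  # touching) are edited as a unit: per spanning read, the exact query
  # string observed across the region is tallied, so run-length changes and
  # non-run-base insertions at run boundaries are both captured
  if (nrow(runs) > 0) {
    ra <- runs$start - 3L
    rb <- runs$end + 3L
    if (!circular) {
      keep <- ra >= 1L & rb <= L - 1L # edge regions lack spanning reads
      ra <- ra[keep]; rb <- rb[keep]
    }
    if (length(ra) > 0) {
      for (i in seq_along(ra)) {
        sn <- snap_region(chars, ra[i], rb[i])
        ra[i] <- sn[1]; rb[i] <- sn[2]
      }
      ra <- pmax(if (circular) -L else 0L, ra)
      rb <- pmin(if (circular) 2L * L else L, rb)
      ord <- order(ra)
      ra <- ra[ord]; rb <- rb[ord]
      grp <- cumsum(c(TRUE, ra[-1] > cummax(rb)[-length(rb)]))
      ra <- as.integer(tapply(ra, grp, min))
      rb <- as.integer(tapply(rb, grp, max))
      # in circular mode evaluate each region in both copies of the doubled
      # sequence and pool the observations (an edge region has its flanks
      # intact in at least one copy)
      ca <- ra; cb <- rb; creg <- seq_along(ra)
      if (circular) {
        ok1 <- ra >= 1L & rb <= 2L * L - 1L
        ok2 <- (rb + L) <= 2L * L - 1L & (ra + L) >= 1L
        ca <- c(ra[ok1], ra[ok2] + L)
        cb <- c(rb[ok1], rb[ok2] + L)
        creg <- c(seq_along(ra)[ok1], seq_along(ra)[ok2])
      }
      obs_raw <- cpp_region_obs(ca, cb, aln$t_start, aln$cigar, oriented)
      obs <- lapply(seq_along(ra), function(i)
        unlist(obs_raw[creg == i], use.names = FALSE))
      for (i in seq_along(ra)) {
        ia <- max(0L, ra[i]); ib <- min(L, rb[i])
        for (p in ia:(ib - 1)) masked[p + 1] <- TRUE
        if (ib - ia >= 2)
          ins_blocked[(ia + 2):ib] <- TRUE
        # a region wrapping the origin cannot be edited in linear
        # coordinates; its columns stay masked and untouched (vanishingly
        # rare: a homopolymer within 1 bp of the vector start)
        if (ra[i] < 0 || rb[i] > L) next
        o <- obs[[i]]
        if (length(o) == 0) next
        tab <- region_tab(o)
        if (is.null(tab)) next
        m <- names(tab)[1]
        agree <- tab[[1]] / sum(tab)
        n_obs <- sum(tab)
        cur_str <- substr(cur, ra[i] + 1, rb[i])
        if (m == cur_str) {
          # majority agrees with the sequence, but a strong second string is
          # the signature of paralogous variation seen through mis-mapped
          # reads: surface it as UNRESOLVED for the repeat-phasing stage
          if (length(tab) >= 2 && n_obs >= min_depth &&
              tab[[2]] >= 0.25 * (tab[[1]] + tab[[2]])) {
            unres[[length(unres) + 1]] <- tibble(
              position = ra[i], nanopore_allele = cur_str,
              illumina_allele = names(tab)[2], class = "UNRESOLVED",
              depth = n_obs, agree = tab[[1]] / sum(tab))
          }
          next
        }
        cls <- if (nchar(m) != nchar(cur_str)) "HOMOPOLYMER_INDEL"
               else "SUBSTITUTION"
        rec <- tibble(position = ra[i], nanopore_allele = cur_str,
                      illumina_allele = m, class = cls,
                      depth = n_obs, agree = agree)
        if (n_obs >= region_min &&
            region_accept(tab, agree, min_agree, dominance)) {
          edits[[length(edits) + 1]] <- dplyr::mutate(
            rec, type = "run", start = ra[i], end = rb[i])
        } else {
          unres[[length(unres) + 1]] <- dplyr::mutate(rec, class = "UNRESOLVED")
        }
      }
    }
  }
  # per-column substitutions / deletions outside masked runs
  best <- max.col(t(counts), ties.method = "first")
  best_chr <- c("A", "C", "G", "T", "-")[best]
  best_cnt <- counts[cbind(best, seq_len(L))]
  # bimodal columns where the majority matches the sequence still signal
  # possible paralogous variation; record them for the phasing stage
  second_cnt <- apply(counts, 2, function(x) sort(x, decreasing = TRUE)[2])
  bimodal <- which(depth >= min_depth & !masked & best_chr == chars &
                     second_cnt >= 0.3 * depth)
  for (p in bimodal) {
    alt <- c("A", "C", "G", "T", "-")[order(counts[, p], decreasing = TRUE)[2]]
    unres[[length(unres) + 1]] <- tibble(
      position = p - 1L, nanopore_allele = chars[p], illumina_allele = alt,
      class = "UNRESOLVED", depth = depth[p], agree = best_cnt[p] / depth[p])
  }
  cand <- which(depth > 0 & !masked & best_chr != chars)
  for (p in cand) {
    agree <- best_cnt[p] / depth[p]
    near_run <- nrow(runs) > 0 &&
      any(p - 1 >= runs$start - 1 & p - 1 <= runs$end)
    is_del <- best_chr[p] == "-"
    cls <- if (is_del && near_run) "HOMOPOLYMER_INDEL" else "SUBSTITUTION"
    rec <- tibble(position = p - 1L, nanopore_allele = chars[p],
                  illumina_allele = best_chr[p], class = cls,
                  depth = depth[p], agree = agree)
    if (depth[p] >= min_depth && agree >= min_agree) {
      edits[[length(edits) + 1]] <- dplyr::mutate(
        rec, type = if (is_del) "del" else "sub",
        start = p - 1L, end = as.integer(p))
    } else {
      unres[[length(unres) + 1]] <- dplyr::mutate(rec, class = "UNRESOLVED")
    }
  }
  # majority insertions outside masked runs
  if (length(pile$ins_pos) > 0) {
    ins <- tibble(pos = pile$ins_pos, seq = pile$ins_seq, w = pile$ins_weight)
    ins <- dplyr::summarise(dplyr::group_by(ins, .data$pos, .data$seq),
                            w = sum(.data$w), .groups = "drop")
    ins <- dplyr::ungroup(dplyr::slice_max(dplyr::group_by(ins, .data$pos),
                                           .data$w, n = 1, with_ties = FALSE))
    ins <- ins[ins$pos >= 1 & !ins_blocked[ins$pos + 1] & span[ins$pos + 1] > 0, ]
    for (j in seq_len(nrow(ins))) {
      p <- ins$pos[j]
      # agreement among reads that span the insertion junction; reads whose
      # alignment merely ends at the column carry no indel evidence
      agree <- ins$w[j] / span[p + 1]
      if (agree < 0.5) next
      near_run <- nrow(runs) > 0 && any(p >= runs$start - 1 & p <= runs$end)
      cls <- if (near_run) "HOMOPOLYMER_INDEL" else "SUBSTITUTION"
      rec <- tibble(position = p, nanopore_allele = "-",
                    illumina_allele = ins$seq[j], class = cls,
                    depth = span[p + 1], agree = agree)
      if (span[p + 1] >= min_depth && agree >= min_agree) {
        edits[[length(edits) + 1]] <- dplyr::mutate(
          rec, type = "ins", start = p, end = p)
      } else {
        unres[[length(unres) + 1]] <- dplyr::mutate(rec, class = "UNRESOLVED")
      }
    }
  }
  edits_tbl <- dplyr::bind_rows(edits)
  unres_tbl <- dplyr::bind_rows(unres)
  if (nrow(edits_tbl) == 0) edits_tbl <- empty_edits()
  if (nrow(unres_tbl) == 0) unres_tbl <- empty_discrepancies()
  # joint realignment of clustered unresolved sites: nearby interacting
  # defects (e.g. a missing base a few bp from a mis-called run) depress
  # each other's per-column agreement below threshold; a single region vote
  # across the whole cluster resolves them jointly
  if (nrow(unres_tbl) > 0) {
    posu <- sort(unique(unres_tbl$position))
    grp <- cumsum(c(TRUE, diff(posu) > 12))
    cl_a <- pmax(1L, as.integer(tapply(posu, grp, min)) - 6L)
    cl_b <- pmin(L - 1L, as.integer(tapply(posu, grp, max)) + 7L)
    for (i in seq_along(cl_a)) {
      sn <- snap_region(chars, cl_a[i], cl_b[i])
      cl_a[i] <- max(1L, sn[1]); cl_b[i] <- min(L - 1L, sn[2])
    }
    keep <- cl_b > cl_a
    if (nrow(edits_tbl) > 0) {
      keep <- keep & vapply(seq_along(cl_a), function(i)
        !any(edits_tbl$start <= cl_b[i] & edits_tbl$end >= cl_a[i]),
        logical(1))
    }
    cl_a <- cl_a[keep]; cl_b <- cl_b[keep]
    if (length(cl_a) > 0) {
      ca <- cl_a; cb <- cl_b; creg <- seq_along(cl_a)
      if (circular) {
        ok2 <- (cl_b + L) <= 2L * L - 1L
        ca <- c(cl_a, cl_a[ok2] + L)
        cb <- c(cl_b, cl_b[ok2] + L)
        creg <- c(seq_along(cl_a), seq_along(cl_a)[ok2])
      }
      obs_raw <- cpp_region_obs(ca, cb, aln$t_start, aln$cigar, oriented)
      cluster_edits <- list()
      for (i in seq_along(cl_a)) {
        o <- unlist(obs_raw[creg == i], use.names = FALSE)
        tab <- region_tab(o)
        if (is.null(tab) || sum(tab) < region_min) next
        m <- names(tab)[1]
        agree <- tab[[1]] / sum(tab)
        cur_str <- substr(cur, cl_a[i] + 1, cl_b[i])
        if (m == cur_str || !region_accept(tab, agree, min_agree, dominance)) next
        cls <- if (nchar(m) != nchar(cur_str)) "HOMOPOLYMER_INDEL"
               else "SUBSTITUTION"
        cluster_edits[[length(cluster_edits) + 1]] <- tibble(
          position = cl_a[i], nanopore_allele = cur_str,
          illumina_allele = m, class = cls, depth = sum(tab),
          agree = agree, type = "run", start = cl_a[i], end = cl_b[i])
      }
      edits_tbl <- dplyr::bind_rows(c(list(edits_tbl), cluster_edits))
    }
  }
  list(edits = edits_tbl, unresolved = unres_tbl,
       depth = depth, counts = counts, chars = chars)
}

# Apply edits right-to-left so earlier positions stay valid.
apply_edits <- function(cur, edits) {
  if (nrow(edits) == 0) return(cur)
  edits <- edits[order(-edits$start), ]
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (e$type == "ins") {
      cur <- paste0(substr(cur, 1, e$start), e$illumina_allele,
                    substring(cur, e$start + 1))
    } else {
      repl <- if (e$type == "del") "" else e$illumina_allele
      cur <- paste0(substr(cur, 1, e$start), repl, substring(cur, e$end + 1))
    }
  }
  cur
}

#' Correct a consensus to the Illumina consensus
#'
#' Short reads are aligned to the sequence; wherever the Illumina column
#' consensus differs and is supported by at least `min_depth` reads agreeing
#' at `min_agree` or better, the base -- or the homopolymer run length,
#' edited as a unit -- is replaced. Every edit is logged as a discrepancy
#' (`HOMOPOLYMER_INDEL` for indels within/adjacent to runs >= 3 bp,
#' `SUBSTITUTION` otherwise); positions that differ but fail the thresholds
#' are logged `UNRESOLVED` and left unedited. Passes repeat until no edit is
#' applied (at most `max_passes`), so a second call is a no-op.
#'
#' @param sequence consensus sequence to correct.
#' @param illumina_reads character vector of short-read sequences (pairs
#'   treated as independent single-end reads).
#' @param min_depth minimum supporting depth (default 15, >= 10).
#' @param min_agree minimum agreement fraction (default 0.9, >= 0.8).
#' @param max_passes maximum align-edit passes.
#' @param clone_id identifier for the assembly.
#' @param long_depth optional per-base long-read depth to carry into the
#'   support table.
#' @param circular treat the sequence as a circular molecule (fold evidence
#'   over a doubled copy; polish the origin in a half-rotated frame).
#' @param dominance allow a region vote to pass on 3:1 dominance over the
#'   runner-up; disable where reads of mixed repeat-unit origin are used
#'   deliberately.
#' @return a `consensus_assembly`.
#' @export
polish_short <- function(sequence, illumina_reads, min_depth = 15L,
                         min_agree = 0.9, max_passes = 5L,
                         clone_id = "clone", long_depth = NULL,
                         circular = FALSE, dominance = TRUE) {
  stopifnot(min_depth >= 10, min_agree >= 0.8)
  illumina_reads <- as_named_seqs(illumina_reads, default_prefix = "sr")
  if (length(illumina_reads) == 0) {
    warn("no short reads: returning the input unchanged (long-read-only assembly)")
    L <- nchar(sequence)
    return(new_consensus_assembly(clone_id, sequence,
      tibble(pos = seq_len(L) - 1L, long_depth = NA_real_,
             short_depth = 0, short_agree = NA_real_),
      empty_discrepancies(), 0L))
  }
  cur <- sequence
  all_disc <- list()
  passes <- 0L
  last <- NULL
  for (pass in seq_len(max_passes)) {
    target <- if (circular) paste0(cur, cur) else cur
    idx <- build_reference_index(c(cons = target), preset = "short")
    aln <- map_reads(illumina_reads, idx, extend = TRUE, max_secondary = 0L,
                     max_extended = 1L)
    aln <- aln[aln$rank == 1 & !is.na(aln$score), ]
    passes <- pass
    if (nrow(aln) == 0) break
    res <- short_pass_edits(cur, aln, illumina_reads, min_depth, min_agree,
                            circular = circular, dominance = dominance)
    last <- res
    if (nrow(res$edits) > 0)
      all_disc[[length(all_disc) + 1]] <- res$edits[, c("position",
        "nanopore_allele", "illumina_allele", "class", "depth", "agree")]
    if (pass == max_passes || nrow(res$edits) == 0) {
      all_disc[[length(all_disc) + 1]] <- res$unresolved
      if (nrow(res$edits) == 0) break
    }
    cur <- apply_edits(cur, res$edits)
  }
  if (circular) {
    # defects at the origin sit inside edge-masked regions; polish once in a
    # half-rotated frame where the origin is interior, then rotate back
    k <- nchar(cur) %/% 2L
    shifted <- rotate_seq(cur, k)
    for (pass in seq_len(2L)) {
      idx <- build_reference_index(c(cons = paste0(shifted, shifted)),
                                   preset = "short")
      aln <- map_reads(illumina_reads, idx, extend = TRUE,
                       max_secondary = 0L, max_extended = 1L)
      aln <- aln[aln$rank == 1 & !is.na(aln$score), ]
      if (nrow(aln) == 0) break
      res <- short_pass_edits(shifted, aln, illumina_reads, min_depth,
                              min_agree, circular = TRUE,
                              dominance = dominance)
      if (nrow(res$edits) == 0) break
      d <- res$edits[, c("position", "nanopore_allele", "illumina_allele",
                         "class", "depth", "agree")]
      d$position <- (d$position + k) %% nchar(shifted)
      all_disc[[length(all_disc) + 1]] <- d
      shifted <- apply_edits(shifted, res$edits)
      passes <- passes + 1L
    }
    cur <- rotate_seq(shifted, nchar(shifted) - k)
  }
  disc <- dplyr::bind_rows(all_disc)
  if (nrow(disc) > 0) {
    disc <- disc[order(disc$position), ]
    disc <- disc[!duplicated(disc$position), ]
  } else disc <- empty_discrepancies()
  L <- nchar(cur)
  support <- if (!is.null(last)) {
    row_idx <- match(last$chars, c("A", "C", "G", "T"))
    cnt <- rep(NA_real_, length(row_idx))
    ok <- !is.na(row_idx)
    cnt[ok] <- last$counts[cbind(row_idx[ok], which(ok))]
    agree_final <- ifelse(last$depth > 0, cnt / last$depth, NA_real_)
    n_sup <- length(last$depth)
    tibble(pos = seq_len(n_sup) - 1L,
           long_depth = if (is.null(long_depth)) NA_real_ else
             long_depth[seq_len(n_sup)],
           short_depth = last$depth, short_agree = agree_final)
  } else {
    tibble(pos = seq_len(L) - 1L, long_depth = NA_real_, short_depth = 0,
           short_agree = NA_real_)
  }
  new_consensus_assembly(clone_id, cur, support, disc, passes)
}

empty_edits <- function() {
  dplyr::mutate(empty_discrepancies(), type = character(),
                start = integer(), end = integer())
}

empty_discrepancies <- function() {
  tibble(position = integer(), nanopore_allele = character(),
         illumina_allele = character(), class = character(),
         depth = numeric(), agree = numeric())
}
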