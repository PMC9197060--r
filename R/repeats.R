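# Divide-and-conquer resolution of near-identical internal repeats
# (amplicons): detect repeat units by self-alignment, call the sequence
# family variants (SFVs) that distinguish paralogous units, partition short
# reads by their SFV alleles, polish each unit separately, and merge --
# with the overall structure anchored by full-length long reads.

#' Detect near-identical internal repeat units
#'
#' Self-alignment of the consensus against itself (both strands, trivial
#' diagonal excluded): off-diagonal minimizer chains longer than `min_len`
#' whose arms align at `min_identity` or better define repeat units; plus
#' strand hits give direct (tandem) units, minus strand hits give inverted
#' (palindrome) arms. An empty result means a non-repetitive clone.
#'
#' @param consensus clone consensus sequence.
#' @param min_len minimum unit length in bp (2 kb default; the full-scale
#'   amplicon definition uses 10 kb).
#' @param min_identity minimum unit-unit identity (default 0.99).
#' @return tibble with `unit_id`, `start`, `end` (0-based half-open on the
#'   consensus), `group`, `orientation` (`direct`/`inverted`), `identity`.
#' @export
detect_self_repeats <- function(consensus, min_len = 2000L,
                                min_identity = 0.99) {
  L <- nchar(consensus)
  if (L < 2 * min_len) abort("consensus shorter than 2 * min_len")
  k <- 15L; w <- 10L
  mz <- cpp_minimizers(consensus, k, w)
  mz <- as_tibble(mz)
  dup <- mz[mz$hash %in% mz$hash[duplicated(mz$hash)], ]
  hits <- list()
  if (nrow(dup) > 1) {
    pairs <- dplyr::inner_join(dup, dup, by = "hash",
                               relationship = "many-to-many",
                               suffix = c("_a", "_b"))
    pairs <- pairs[pairs$pos_a < pairs$pos_b, ]
    direct <- pairs[pairs$strand_a == pairs$strand_b &
                      (pairs$pos_b - pairs$pos_a) >= min_len * 0.5, ]
    invert <- pairs[pairs$strand_a != pairs$strand_b, ]
    min_chain <- max(100, min_len / 5)
    if (nrow(direct) > 0) {
      ch <- chain_anchors(tibble(q_pos = direct$pos_a, t_pos = direct$pos_b),
                          max_gap = 2000L, min_chain_score = min_chain,
                          k = k, max_chains = 10L)
      for (ci in unique(ch$chain)) {
        cc <- trim_chain_ends(ch[ch$chain == ci, ])
        hits[[length(hits) + 1]] <- list(
          a = c(min(cc$q_pos), max(cc$q_pos) + k),
          b = c(min(cc$t_pos), max(cc$t_pos) + k), orient = "direct",
          period = stats::median(cc$t_pos - cc$q_pos))
      }
    }
    if (nrow(invert) > 0) {
      tprime <- L - k - invert$pos_b
      ch <- chain_anchors(tibble(q_pos = invert$pos_a, t_pos = tprime),
                          max_gap = 2000L, min_chain_score = min_chain,
                          k = k, max_chains = 10L)
      for (ci in unique(ch$chain)) {
        cc <- trim_chain_ends(ch[ch$chain == ci, ])
        a <- c(min(cc$q_pos), max(cc$q_pos) + k)
        b <- c(L - (max(cc$t_pos) + k), L - min(cc$t_pos))
        if (a[1] >= b[1]) next # keep left arm first; mirror hit dropped
        hits[[length(hits) + 1]] <- list(a = a, b = b, orient = "inverted")
      }
    }
  }
  if (length(hits) == 0) return(empty_repeat_units())
  # a tandem array of n >= 3 units produces one long period-offset self-hit
  # whose arms overlap by whole units: decompose it into consecutive unit
  # pairs at the period
  expanded <- list()
  for (h in hits) {
    la <- h$a[2] - h$a[1]; lb <- h$b[2] - h$b[1]
    ov <- h$a[2] - h$b[1]
    if (h$orient == "direct" && !is.null(h$period) &&
        ov > 0.1 * min(la, lb) && h$period >= min_len * 0.9) {
      p <- as.integer(h$period)
      span <- h$b[2] - h$a[1]
      n_units <- as.integer(round(span / p))
      if (n_units >= 3 && abs(span - n_units * p) < 0.1 * p) {
        starts <- h$a[1] + (seq_len(n_units) - 1L) * p
        for (i in seq_len(n_units - 1L)) {
          expanded[[length(expanded) + 1]] <- list(
            a = c(starts[i], starts[i] + p),
            b = c(starts[i + 1L], min(h$b[2], starts[i + 1L] + p)),
            orient = "direct", period = p)
        }
        next
      }
    }
    expanded[[length(expanded) + 1]] <- h
  }
  hits <- expanded
  # validate hits by global alignment of the two arms
  ok <- list()
  for (h in hits) {
    la <- h$a[2] - h$a[1]; lb <- h$b[2] - h$b[1]
    if (la < min_len * 0.9 || lb < min_len * 0.9) next
    # adjacent tandem arms can overlap by a few bp of chain-end noise: cut
    # at the repeat period so the two arms stay in phase; reject genuinely
    # interleaved hits
    if (h$a[2] > h$b[1]) {
      ov <- h$a[2] - h$b[1]
      if (ov > 0.1 * min(la, lb)) next
      if (h$orient == "direct") {
        # cut adjacent tandem arms at the repeat period to keep them in phase
        if (is.null(h$period)) next
        cut <- as.integer(h$a[1] + h$period)
        if (cut < h$b[1] || cut > h$a[2]) next
        h$a[2] <- cut; h$b[1] <- cut
        h$b[2] <- min(nchar(consensus), cut + (h$a[2] - h$a[1]))
      } else {
        # palindrome arms mirror around their centre: the midpoint is the
        # phase-correct cut
        mid <- as.integer((h$a[2] + h$b[1]) %/% 2)
        h$a[2] <- mid; h$b[1] <- mid
      }
    }
    sa <- substr(consensus, h$a[1] + 1, h$a[2])
    sb <- substr(consensus, h$b[1] + 1, h$b[2])
    if (h$orient == "inverted") sb <- cpp_revcomp(sb)
    # unit boundaries from chain ends are ragged by up to ~(k + w) bp;
    # measure identity on the arm cores so boundary noise cannot push a
    # genuine >= min_identity pair under the threshold
    m <- 16L + as.integer(0.005 * min(nchar(sa), nchar(sb)))
    core <- min(nchar(sa), nchar(sb)) - 2L * m
    sa_c <- substr(sa, m + 1, m + core)
    sb_c <- substr(sb, m + 1, m + core)
    aln <- extend_align(sa_c, sb_c,
                        band = abs(nchar(sa_c) - nchar(sb_c)) + 100L)
    if (is.na(aln$identity) || aln$identity < min_identity) next
    h$identity <- aln$identity
    ok[[length(ok) + 1]] <- h
  }
  if (length(ok) == 0) return(empty_repeat_units())
  # unit decomposition: merge arm intervals with reciprocal overlap >= 50%
  ivs <- do.call(rbind, lapply(ok, function(h) rbind(h$a, h$b)))
  n_iv <- nrow(ivs)
  parent <- seq_len(n_iv)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n_iv)) for (j in seq_len(n_iv)) {
    if (i >= j) next
    ov <- min(ivs[i, 2], ivs[j, 2]) - max(ivs[i, 1], ivs[j, 1])
    if (ov >= 0.5 * min(ivs[i, 2] - ivs[i, 1], ivs[j, 2] - ivs[j, 1])) {
      parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n_iv), find, integer(1))
  units <- dplyr::summarise(dplyr::group_by(tibble(
    comp = comp, start = ivs[, 1], end = ivs[, 2]), .data$comp),
    start = as.integer(round(mean(.data$start))),
    end = as.integer(round(mean(.data$end))), .groups = "drop")
  units <- units[order(units$start), ]
  # connect units into paralog groups via the hits; propagate orientation
  unit_of <- function(iv) {
    ov <- pmin(units$end, iv[2]) - pmax(units$start, iv[1])
    which.max(ov)
  }
  n_u <- nrow(units)
  gparent <- seq_len(n_u)
  gfind <- function(i) { while (gparent[i] != i) i <- gparent[i]; i }
  edges <- lapply(ok, function(h) c(unit_of(h$a), unit_of(h$b),
                                    h$orient == "inverted"))
  for (e in edges) gparent[gfind(e[2])] <- gfind(e[1])
  gcomp <- vapply(seq_len(n_u), gfind, integer(1))
  orientation <- rep(NA_character_, n_u)
  for (g in unique(gcomp)) {
    members <- which(gcomp == g)
    orientation[members[1]] <- "direct"
    for (rep_pass in 1:n_u) for (e in edges) {
      u <- e[1]; v <- e[2]; inv <- e[3] == 1
      if (!is.na(orientation[u]) && is.na(orientation[v]))
        orientation[v] <- if (inv) flip_orient(orientation[u]) else orientation[u]
      if (!is.na(orientation[v]) && is.na(orientation[u]))
        orientation[u] <- if (inv) flip_orient(orientation[v]) else orientation[v]
    }
  }
  ident <- vapply(ok, function(h) h$identity, numeric(1))
  tibble(
    unit_id = paste0("u", seq_len(n_u)),
    start = units$start, end = units$end,
    group = match(gcomp, unique(gcomp)),
    orientation = orientation,
    identity = rep(max(ident), n_u)
  )
}

flip_orient <- function(x) ifelse(x == "direct", "inverted", "direct")

# Drop stray terminal anchors separated from the chain body by more than
# 200 bp (random hash collisions chained onto a repeat hit corrupt the
# unit boundaries otherwise).
trim_chain_ends <- function(cc, max_end_gap = 200L) {
  cc <- cc[order(cc$q_pos), ]
  while (nrow(cc) > 2 &&
         (cc$q_pos[2] - cc$q_pos[1] > max_end_gap ||
          cc$t_pos[2] - cc$t_pos[1] > max_end_gap)) cc <- cc[-1, ]
  n <- nrow(cc)
  while (n > 2 &&
         (cc$q_pos[n] - cc$q_pos[n - 1] > max_end_gap ||
          cc$t_pos[n] - cc$t_pos[n - 1] > max_end_gap)) {
    cc <- cc[-n, ]; n <- nrow(cc)
  }
  cc
}

empty_repeat_units <- function() {
  tibble(unit_id = character(), start = integer(), end = integer(),
         group = integer(), orientation = character(), identity = numeric())
}

# Column map from the reference unit to another unit via a global alignment:
# for each reference-unit position, the aligned position in the other unit
# (NA across deletions) and the aligned base ('-' for a deletion).
unit_column_map <- function(ref_seq, other_seq) {
  aln <- extend_align(other_seq, ref_seq,
                      band = abs(nchar(other_seq) - nchar(ref_seq)) + 200L)
  co <- cigar_ops(aln$cigar)
  n_ref <- nchar(ref_seq)
  qpos <- rep(NA_integer_, n_ref)
  base <- rep("-", n_ref)
  oc <- strsplit(other_seq, "", fixed = TRUE)[[1]]
  tp <- 0L; qp <- 0L
  for (i in seq_len(nrow(co))) {
    op <- co$op[i]; len <- co$len[i]
    if (op == "M") {
      idx <- seq_len(len)
      qpos[tp + idx] <- qp + idx - 1L
      base[tp + idx] <- oc[qp + idx]
      tp <- tp + len; qp <- qp + len
    } else if (op == "D") {
      tp <- tp + len
    } else if (op %in% c("I", "S")) {
      qp <- qp + len
    }
  }
  list(qpos = qpos, base = base)
}

#' Call sequence family variants between repeat units
#'
#' Unit sequences are aligned column-wise (pairwise to the first unit, in
#' positional order); columns where units differ, supported by short reads
#' (depth >= `min_depth` and agreement >= `min_agree` on at least one unit),
#' are emitted as SFVs. Columns where the short reads contradict every
#' unit's allele are flagged as possible collapse artifacts and withheld.
#'
#' @param units tibble from [detect_self_repeats()].
#' @param consensus the clone consensus the units live on.
#' @param illumina_reads character vector of short reads.
#' @param min_depth,min_agree short-read support thresholds.
#' @return tidy tibble with one row per (SFV, unit): `sfv_id`, `group`,
#'   `column` (offset in the group's reference-unit alignment), `unit_id`,
#'   `allele` (alignment frame), `cons_allele` (consensus strand), `pos`
#'   (consensus coordinate; `NA` for a deletion allele), `depth`, `agree`.
#'   Withheld contradicted columns are in `attr(, "flagged")`.
#' @export
call_sfvs <- function(units, consensus, illumina_reads, min_depth = 15L,
                      min_agree = 0.9) {
  illumina_reads <- as_named_seqs(illumina_reads, default_prefix = "sr")
  out <- list(); flagged <- list()
  idx <- build_reference_index(c(cons = consensus), preset = "short")
  aln <- map_reads(illumina_reads, idx, extend = TRUE, max_secondary = 0L,
                   max_extended = 1L)
  aln <- aln[aln$rank == 1 & !is.na(aln$score), ]
  pile <- if (nrow(aln) > 0)
    cpp_pileup(nchar(consensus), aln$t_start, aln$cigar,
               oriented_query(aln, illumina_reads), rep(1, nrow(aln)))
  else NULL
  sfv_n <- 0L
  for (g in unique(units$group)) {
    ug <- units[units$group == g, ]
    if (nrow(ug) < 2) next
    ref <- ug[1, ]
    ref_seq <- unit_seq(consensus, ref)
    maps <- list(list(qpos = seq_len(nchar(ref_seq)) - 1L,
                      base = strsplit(ref_seq, "", fixed = TRUE)[[1]]))
    for (u in seq_len(nrow(ug))[-1])
      maps[[u]] <- unit_column_map(ref_seq, unit_seq(consensus, ug[u, ]))
    n_col <- nchar(ref_seq)
    allele_mat <- do.call(cbind, lapply(maps, function(m) m$base))
    differs <- which(apply(allele_mat, 1, function(x) length(unique(x)) > 1))
    for (col in differs) {
      rows <- list()
      support_ok <- FALSE
      contradiction <- TRUE
      for (u in seq_len(nrow(ug))) {
        al <- allele_mat[col, u]
        qp <- maps[[u]]$qpos[col]
        cons_info <- unit_consensus_pos(ug[u, ], qp, al)
        d <- NA_real_; agr <- NA_real_
        if (!is.null(pile) && !is.na(cons_info$pos)) {
          p <- cons_info$pos
          d <- pile$depth[p + 1]
          want <- cons_info$allele
          ri <- match(want, c("A", "C", "G", "T", "-"))
          cnt <- if (!is.na(ri)) pile$counts[ri, p + 1] else NA_real_
          agr <- if (!is.na(d) && d > 0) cnt / d else NA_real_
          if (!is.na(agr) && d >= min_depth && agr >= min_agree)
            support_ok <- TRUE
          maj <- c("A", "C", "G", "T", "-")[which.max(pile$counts[, p + 1])]
          if (d > 0 && maj %in% oriented_alleles(allele_mat[col, ], ug))
            contradiction <- FALSE
        }
        rows[[u]] <- tibble(group = g, column = col - 1L,
                            unit_id = ug$unit_id[u], allele = al,
                            cons_allele = cons_info$allele,
                            pos = cons_info$pos, depth = d, agree = agr)
      }
      rec <- dplyr::bind_rows(rows)
      if (support_ok && !contradiction) {
        sfv_n <- sfv_n + 1L
        rec$sfv_id <- sprintf("sfv%03d", sfv_n)
        out[[length(out) + 1]] <- rec
      } else if (contradiction) {
        flagged[[length(flagged) + 1]] <- rec
      }
    }
  }
  res <- if (length(out) > 0) {
    dplyr::bind_rows(out)[, c("sfv_id", "group", "column", "unit_id", "allele",
                              "cons_allele", "pos", "depth", "agree")]
  } else empty_sfv_calls()
  attr(res, "flagged") <- dplyr::bind_rows(flagged)
  res
}

empty_sfv_calls <- function() {
  tibble(sfv_id = character(), group = integer(), column = integer(),
         unit_id = character(), allele = character(),
         cons_allele = character(), pos = integer(), depth = numeric(),
         agree = numeric())
}

# Unit sequence in alignment frame (revcomp'd for inverted units).
unit_seq <- function(consensus, unit) {
  s <- substr(consensus, unit$start + 1, unit$end)
  if (unit$orientation == "inverted") cpp_revcomp(s) else s
}

# Consensus coordinate and consensus-strand allele for an alignment-frame
# offset within a unit.
unit_consensus_pos <- function(unit, qp, allele) {
  if (is.na(qp) || allele == "-")
    return(list(pos = NA_integer_, allele = allele))
  if (unit$orientation == "inverted") {
    list(pos = as.integer(unit$end - 1L - qp), allele = cpp_revcomp(allele))
  } else {
    list(pos = as.integer(unit$start + qp), allele = allele)
  }
}

# All alleles of a column expressed on the consensus strand.
oriented_alleles <- function(alleles, ug) {
  vapply(seq_along(alleles), function(u) {
    if (alleles[u] == "-") return("-")
    if (ug$orientation[u] == "inverted") cpp_revcomp(alleles[u]) else alleles[u]
  }, character(1))
}

#' Finish an internally repetitive clone
#'
#' The divide-and-conquer step: short reads are partitioned between repeat
#' units by their alleles at SFV columns (a read must match at least one SFV
#' allele of its unit and contradict none), each unit is polished separately
#' with its read subset, and the units are re-inserted at their intervals.
#' Before partitioning, the allele expected at each unit position is
#' re-anchored from the long reads, whose full-clone span fixes the overall
#' structure -- this repairs unit-allele swaps introduced upstream. Units
#' with no SFV-assignable reads are left at the long-read consensus and
#' flagged `UNRESOLVED`.
#'
#' @param consensus clone consensus (a sequence or a `consensus_assembly`).
#' @param units tibble from [detect_self_repeats()].
#' @param sfvs tibble from [call_sfvs()].
#' @param long_reads named character vector of long reads for the clone.
#' @param illumina_reads short reads for the clone.
#' @param min_depth,min_agree polishing thresholds within units.
#' @param cleanup run the final all-read polishing pass.
#' @param rebuild rebuild unit backbones from anchored long-read segments
#'   first (skip on a repeated invocation, where the units are already
#'   Illumina-polished).
#' @return a `consensus_assembly` for the merged sequence.
#' @export
finish_repetitive <- function(consensus, units, sfvs, long_reads,
                              illumina_reads, min_depth = 15L,
                              min_agree = 0.9, cleanup = TRUE,
                              rebuild = TRUE) {
  clone_id <- if (inherits(consensus, "consensus_assembly")) consensus$clone_id
              else "clone"
  prior <- if (inherits(consensus, "consensus_assembly"))
    consensus$discrepancies else empty_discrepancies()
  seq0 <- if (inherits(consensus, "consensus_assembly")) consensus$sequence
          else consensus
  if (nrow(units) == 0) {
    return(new_consensus_assembly(clone_id, seq0, tibble(), prior, 0L))
  }
  long_reads <- as_named_seqs(long_reads, default_prefix = "lr")
  illumina_reads <- as_named_seqs(illumina_reads, default_prefix = "sr")
  cur <- seq0
  disc <- list(); flags <- list()
  # 1. re-anchor SFV alleles positionally from the long reads
  lidx <- build_reference_index(c(cons = cur), preset = "long")
  laln <- map_reads(long_reads, lidx, extend = TRUE, max_secondary = 0L,
                    max_extended = 1L)
  laln <- laln[laln$rank == 1 & !is.na(laln$score), ]
  corrected <- sfvs
  # only structurally anchored long reads vote on unit alleles: a read that
  # also aligns outside the repeat region is positionally unambiguous, while
  # a read wholly inside it may sit on the wrong unit (the source of the
  # blur being repaired)
  if (nrow(laln) > 0 && nrow(units) > 0) {
    anchored <- laln$t_start < min(units$start) - 200 |
      laln$t_end > max(units$end) + 200
    laln <- laln[anchored, ]
  }
  if (nrow(laln) > 0 && rebuild) {
    # rebuild each unit's backbone from the aligned segments of the
    # anchored reads: each segment is positionally certain (its read spans
    # into unique sequence), so the rebuilt unit carries the true alleles
    # of that instance -- undoing any blur the pooled polishing introduced
    units <- units[order(units$start), ]
    for (ui in rev(seq_len(nrow(units)))) {
      segs <- cpp_region_obs(units$start[ui], units$end[ui], laln$t_start,
                             laln$cigar, oriented_query(laln, long_reads))[[1]]
      segs <- segs[nchar(segs) > 0.8 * (units$end[ui] - units$start[ui])]
      if (length(segs) < 5) next
      sub0 <- substr(cur, units$start[ui] + 1, units$end[ui])
      reb <- polish_long(sub0, segs, rounds = 2L, circular = FALSE)$sequence
      shift <- nchar(reb) - nchar(sub0)
      cur <- paste0(substr(cur, 1, units$start[ui]), reb,
                    substring(cur, units$end[ui] + 1))
      if (shift != 0L) {
        units$end[units$end > units$start[ui]] <-
          units$end[units$end > units$start[ui]] + shift
        sel <- units$start > units$start[ui]
        units$start[sel] <- units$start[sel] + shift
      }
    }
    # the distinguishing columns and their alleles are then re-derived from
    # the rebuilt consensus
    corrected <- call_sfvs(units, cur, illumina_reads,
                           min_depth = min_depth, min_agree = min_agree)
  }
  # 2. partition short reads by SFV alleles; after the first pass the SFV
  # columns are refined to their partition majorities and the partition is
  # redone -- a handful of residually wrong alleles otherwise mislabel
  # every read whose only distinguishing evidence is that one column
  for (partition_pass in 1:2) {
  sidx <- build_reference_index(c(cons = cur), preset = "short")
  saln <- map_reads(illumina_reads, sidx, extend = TRUE, max_secondary = 0L,
                    max_extended = 1L)
  saln <- saln[saln$rank == 1 & !is.na(saln$score), ]
  assignment <- rep(NA_character_, nrow(saln))
  covers_sfv <- rep(FALSE, nrow(saln))
  # partition only on validated marker columns: every unit's claimed allele
  # must be supported by the reads mapped to its own instance. A residual
  # consensus error masquerading as a distinguishing column has no support
  # at its own instance and would systematically mislabel reads.
  if (nrow(corrected) > 0) {
    ok_marker <- dplyr::summarise(
      dplyr::group_by(corrected, .data$sfv_id),
      ok = all(!is.na(.data$agree) & .data$agree >= 0.55 &
                 !is.na(.data$depth) & .data$depth >= 10),
      .groups = "drop")
    markers <- ok_marker$sfv_id[ok_marker$ok]
    sfv_pos <- corrected[!is.na(corrected$pos) &
                           corrected$sfv_id %in% markers, ]
  } else sfv_pos <- corrected
  if (nrow(saln) > 0 && nrow(sfv_pos) > 0) {
    ba <- cpp_bases_at(saln$t_start, saln$cigar,
                       oriented_query(saln, illumina_reads),
                       unique(sfv_pos$pos))
    covers_sfv[unique(ba$read)] <- TRUE
    if (length(ba$read) > 0) {
      votes <- tibble(read = ba$read, pos = ba$pos, base = ba$base)
      # at a covered position p (belonging to unit u_p of column c), convert
      # the observed base into alignment frame and match it against the
      # column's unit alleles
      votes <- dplyr::inner_join(votes, sfv_pos[, c("pos", "sfv_id", "unit_id",
                                                    "group", "column")],
                                 by = "pos", relationship = "many-to-many")
      host_orient <- units$orientation[match(votes$unit_id, units$unit_id)]
      votes$base_aln <- ifelse(host_orient == "inverted",
                               revcomp(votes$base), votes$base)
      key <- corrected[, c("sfv_id", "unit_id", "allele")]
      names(key) <- c("sfv_id", "voted_unit", "allele")
      votes <- dplyr::inner_join(votes, key, by = "sfv_id",
                                 relationship = "many-to-many")
      votes <- votes[votes$base_aln == votes$allele, ]
      tall <- dplyr::distinct(votes[, c("read", "voted_unit")])
      per_read <- dplyr::summarise(dplyr::group_by(tall, .data$read),
                                   n_units = dplyr::n(),
                                   unit = .data$voted_unit[1], .groups = "drop")
      ok <- per_read[per_read$n_units == 1, ]
      assignment[ok$read] <- ok$unit
    }
  }
  # 2b. force each SFV column to its partition-read majority (the purest
  # per-unit evidence); fall back to the long-read-anchored allele when the
  # partition is too thin
  if (nrow(saln) > 0 && nrow(sfv_pos) > 0 && any(!is.na(assignment))) {
    for (i in seq_len(nrow(sfv_pos))) {
      u_id <- sfv_pos$unit_id[i]; p <- sfv_pos$pos[i]
      rid <- which(!is.na(assignment) & assignment == u_id)
      if (length(rid) == 0) next
      sub_aln <- saln[rid, ]
      ba <- cpp_bases_at(sub_aln$t_start, sub_aln$cigar,
                         oriented_query(sub_aln, illumina_reads), p)
      if (length(ba$base) < 5) next
      tabb <- sort(table(ba$base), decreasing = TRUE)
      maj <- names(tabb)[1]
      if (maj == "-" || maj == substr(cur, p + 1, p + 1)) next
      disc[[length(disc) + 1]] <- tibble(
        position = p, nanopore_allele = substr(cur, p + 1, p + 1),
        illumina_allele = maj, class = "SUBSTITUTION",
        depth = length(ba$base), agree = tabb[[1]] / length(ba$base))
      cur <- paste0(substr(cur, 1, p), maj, substring(cur, p + 2))
      ui <- match(u_id, corrected$unit_id[match(sfv_pos$sfv_id[i],
                                                corrected$sfv_id)])
      ci <- which(corrected$sfv_id == sfv_pos$sfv_id[i] &
                    corrected$unit_id == u_id)
      if (length(ci) == 1) {
        uo <- units$orientation[match(u_id, units$unit_id)]
        corrected$cons_allele[ci] <- maj
        corrected$allele[ci] <- if (identical(uo, "inverted"))
          cpp_revcomp(maj) else maj
      }
    }
  }
  } # partition_pass
  # 3. polish each unit with its read subset, re-inserting right to left.
  # The subset is the SFV-assigned reads plus "neutral" reads -- reads whose
  # alignment covers no distinguishing column carry identical content in
  # every unit, so they are safe evidence for any of them and fill the
  # coverage holes between SFV columns.
  units <- units[order(-units$start), ]
  neutral <- saln$query_id[!covers_sfv &
                             saln$t_start < max(units$end) + 200 &
                             saln$t_end > min(units$start) - 200]
  unit_disc <- list()
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    sub <- substr(cur, u$start + 1, u$end)
    rid <- saln$query_id[!is.na(assignment) & assignment == u$unit_id]
    # once the SFV columns are re-anchored, primary placement is reliable:
    # reads with distinguishing content map to the matching instance and
    # content-neutral reads are safe anywhere, so reads primary-mapped onto
    # this instance round out the evidence
    mapped_here <- saln$query_id[saln$t_start < u$end + 100 &
                                   saln$t_end > u$start - 100]
    conflicted <- saln$query_id[covers_sfv] # SFV-covering reads only by vote
    mapped_here <- setdiff(mapped_here, conflicted)
    if (length(rid) > 0) rid <- unique(c(rid, neutral, mapped_here))
    if (length(rid) == 0) {
      flags[[length(flags) + 1]] <- tibble(
        clone_id = clone_id, flag = "UNRESOLVED_UNIT",
        guidance = sprintf("unit %s has no SFV-assignable short reads; left at long-read consensus",
                           u$unit_id))
      next
    }
    # the SFV-assignable subset is roughly half of the local coverage, so
    # the per-unit polish runs at the lower bound of the supported depth
    pa <- polish_short(sub, illumina_reads[rid],
                       min_depth = max(10L, min_depth - 5L),
                       min_agree = min_agree, clone_id = u$unit_id)
    if (nrow(pa$discrepancies) > 0) {
      d <- pa$discrepancies
      d$position <- d$position + u$start
      unit_disc[[length(unit_disc) + 1]] <- d
    }
    shift <- nchar(pa$sequence) - (u$end - u$start)
    cur <- paste0(substr(cur, 1, u$start), pa$sequence,
                  substring(cur, u$end + 1))
    if (shift != 0L) {
      # keep unit coordinates in register with the edited sequence
      units$end[units$end > u$start] <- units$end[units$end > u$start] + shift
      units$start[units$start > u$start] <-
        units$start[units$start > u$start] + shift
    }
  }
  # 3b. cleanup pass with ALL short reads: columns where the units agree are
  # safely polishable at full depth regardless of which unit a read mapped
  # to (the sparse SFV-assignable subset leaves coverage holes between SFV
  # columns); genuinely unit-distinguishing columns stay protected by the
  # agreement threshold because mis-partitioned reads split their votes,
  # and the 3:1 dominance shortcut is disabled here for the same reason
  if (cleanup) {
    pa_all <- polish_short(cur, illumina_reads, min_depth = min_depth,
                           min_agree = min_agree, clone_id = clone_id,
                           circular = TRUE, dominance = FALSE)
    if (nrow(pa_all$discrepancies) > 0)
      unit_disc[[length(unit_disc) + 1]] <-
        pa_all$discrepancies[pa_all$discrepancies$class != "UNRESOLVED", ]
    cur <- pa_all$sequence
  }
  # 3c. phase divergent regions (the final word on repeat content). A
  # paralog difference that was blurred to identity before SFV calling is
  # invisible to the partition: every position in it polls ~50/50 at full
  # depth (reads from both units map onto both instances), and a garbled
  # instance can even repel its own reads so that the locus looks clean.
  # Every window of every unit is therefore swept: the recurrent Illumina
  # strings over the pooled instances are the candidate alleles, and each
  # instance is assigned the candidate preferred by the structurally
  # anchored long reads spanning it. Iterated until no further region
  # changes.
  for (phase_iter in 1:5) {
    lidx2 <- build_reference_index(c(cons = cur), preset = "long")
    laln2 <- map_reads(long_reads, lidx2, extend = TRUE, max_secondary = 0L,
                       max_extended = 1L)
    laln2 <- laln2[laln2$rank == 1 & !is.na(laln2$score), ]
    if (nrow(laln2) > 0)
      laln2 <- laln2[laln2$t_start < min(units$start) - 200 |
                       laln2$t_end > max(units$end) + 200, ]
    sidx2 <- build_reference_index(c(cons = cur), preset = "short")
    saln2 <- map_reads(illumina_reads, sidx2, extend = TRUE,
                       max_secondary = 0L, max_extended = 1L)
    saln2 <- saln2[saln2$rank == 1 & !is.na(saln2$score), ]
    if (nrow(saln2) == 0 || nrow(laln2) == 0) break
    chars2 <- strsplit(cur, "", fixed = TRUE)[[1]]
    col_maps <- list() # host->unit column maps, cached within this iteration
    # windows: a full tile sweep over the first (host) unit of every direct
    # group, plus clusters around any unresolved positions from a scan pass
    cl_a <- integer(0); cl_b <- integer(0)
    for (g in unique(units$group)) {
      ug0 <- units[units$group == g, ]
      if (nrow(ug0) < 2 || any(ug0$orientation != "direct")) next
      h0 <- ug0$start[1]; h1 <- ug0$end[1]
      starts <- seq(h0 + 16L, h1 - 48L, by = 28L)
      cl_a <- c(cl_a, starts); cl_b <- c(cl_b, starts + 32L)
    }
    scan <- short_pass_edits(cur, saln2, illumina_reads, min_depth,
                             min_agree, circular = FALSE, dominance = FALSE)
    un <- scan$unresolved
    un <- un[!is.na(un$position) & un$agree >= 0.25 & un$depth >= 5, ]
    in_unit <- function(p) any(p >= units$start & p < units$end)
    un <- un[vapply(un$position, in_unit, logical(1)), ]
    if (nrow(un) > 0) {
      posu <- sort(unique(c(un$position,
                            un$position + pmax(1L, nchar(un$nanopore_allele)) - 1L)))
      grp2 <- cumsum(c(TRUE, diff(posu) > 40))
      cl_a <- c(cl_a, as.integer(tapply(posu, grp2, min)) - 10L)
      cl_b <- c(cl_b, as.integer(tapply(posu, grp2, max)) + 11L)
    }
    if (length(cl_a) == 0) break
    phase_edits <- list()
    for (i in seq_along(cl_a)) {
      sn <- snap_region(chars2, max(1L, cl_a[i]), min(nchar(cur) - 1L, cl_b[i]))
      a <- sn[1]; b <- sn[2]
      host <- which(units$start <= a & units$end >= b)
      if (length(host) != 1) next
      g <- units$group[host]
      ug <- units[units$group == g, ]
      if (nrow(ug) < 2 || any(ug$orientation != "direct")) next
      # instance intervals registered through an explicit host-to-unit
      # column map: paralog instances drift out of fixed-offset register by
      # the net indels accumulated between them
      off_a <- a - units$start[host]; off_b <- b - units$start[host]
      hw <- which(ug$unit_id == units$unit_id[host])
      host_seq <- substr(cur, ug$start[hw] + 1, ug$end[hw])
      inst_a <- integer(nrow(ug)); inst_b <- integer(nrow(ug))
      bad_map <- FALSE
      for (v in seq_len(nrow(ug))) {
        if (v == hw) { inst_a[v] <- a; inst_b[v] <- b; next }
        key <- paste(hw, v)
        if (is.null(col_maps[[key]])) {
          col_maps[[key]] <- unit_column_map(
            host_seq, substr(cur, ug$start[v] + 1, ug$end[v]))
        }
        qp <- col_maps[[key]]$qpos
        pa <- qp[off_a + 1]; pb <- qp[off_b]
        # step inward past deletion columns
        oa <- off_a; while (is.na(pa) && oa < off_b) { oa <- oa + 1L; pa <- qp[oa + 1] }
        ob <- off_b; while (is.na(pb) && ob > off_a) { ob <- ob - 1L; pb <- qp[ob] }
        if (is.na(pa) || is.na(pb) || pb <= pa) { bad_map <- TRUE; break }
        inst_a[v] <- ug$start[v] + pa
        inst_b[v] <- ug$start[v] + pb + 1L
      }
      if (bad_map) next
      if (any(inst_a < 1) || any(inst_b > nchar(cur) - 1)) next
      obs_all <- cpp_region_obs(inst_a, inst_b, saln2$t_start, saln2$cigar,
                                oriented_query(saln2, illumina_reads))
      pooled <- unlist(obs_all, use.names = FALSE)
      tabp <- region_tab(pooled) # singletons are read errors, drop them
      if (is.null(tabp) || sum(tabp) < 10) next
      lobs <- NULL
      decide <- function(v, pick, other) {
        # assign instance v the candidate the anchored long reads prefer,
        # rewriting it with its own phase-consistent short-read string (or,
        # for an instance garbled enough to repel its reads, splicing the
        # candidate at the best-matching span)
        lo <- lobs[[v]]
        if (length(lo) < 5) return(NULL)
        d1 <- utils::adist(lo, pick); d2 <- utils::adist(lo, other)
        v1 <- sum(d1 < d2); v2 <- sum(d2 < d1) # ties abstain
        decided <- v1 + v2
        if (decided < 4 || v1 < 0.7 * decided) return(NULL)
        o_v <- obs_all[[v]]
        dd1 <- utils::adist(o_v, pick); dd2 <- utils::adist(o_v, other)
        consistent <- o_v[dd1 < dd2]
        tabc <- if (length(consistent) > 0)
          sort(table(consistent), decreasing = TRUE) else NULL
        if (length(consistent) >= 5 && tabc[[1]] >= 0.6 * length(consistent)) {
          repl <- names(tabc)[1]
          e_start <- inst_a[v]; e_end <- inst_b[v]
          supp <- length(consistent); agr <- tabc[[1]] / length(consistent)
        } else {
          pad <- 8L
          wa <- max(0L, inst_a[v] - pad); wb <- min(nchar(cur), inst_b[v] + pad)
          win <- substr(cur, wa + 1, wb)
          best_d <- Inf; best_st <- NA_integer_; best_len <- NA_integer_
          for (st in 0:(nchar(win) - 1)) {
            for (lenv in max(1L, nchar(pick) - 4L):(nchar(pick) + 4L)) {
              if (st + lenv > nchar(win)) next
              dd <- utils::adist(substr(win, st + 1, st + lenv), pick)
              if (dd < best_d) { best_d <- dd; best_st <- st; best_len <- lenv }
            }
          }
          if (!is.finite(best_d) || best_d > nchar(pick) / 3) return(NULL)
          repl <- pick
          e_start <- wa + best_st; e_end <- wa + best_st + best_len
          supp <- decided; agr <- v1 / decided
        }
        cur_str <- substr(cur, e_start + 1, e_end)
        if (repl == cur_str) return(NULL)
        tibble(position = e_start, nanopore_allele = cur_str,
               illumina_allele = repl, class = "SUBSTITUTION",
               depth = supp, agree = agr, type = "run",
               start = e_start, end = e_end)
      }
      bimodal <- length(tabp) >= 2 &&
        tabp[[2]] >= 0.2 * (tabp[[1]] + tabp[[2]]) &&
        tabp[[1]] + tabp[[2]] >= 0.6 * length(pooled)
      unimodal <- tabp[[1]] >= 0.9 * sum(tabp)
      if (!bimodal && !unimodal) next
      s1 <- names(tabp)[1]
      s2 <- if (length(tabp) >= 2) names(tabp)[2] else NULL
      # fast path: a unimodal window already matching every instance
      if (unimodal) {
        cur_strs <- substring(cur, inst_a + 1, inst_b)
        if (all(cur_strs == s1)) next
      }
      lobs <- cpp_region_obs(inst_a, inst_b, laln2$t_start, laln2$cigar,
                             oriented_query(laln2, long_reads))
      for (v in seq_len(nrow(ug))) {
        e <- if (bimodal) {
          # each instance takes whichever candidate its long reads prefer
          lo <- lobs[[v]]
          if (length(lo) < 5) NULL
          else {
            d1 <- utils::adist(lo, s1); d2 <- utils::adist(lo, s2)
            if (sum(d1 < d2) >= sum(d2 < d1)) decide(v, s1, s2)
            else decide(v, s2, s1)
          }
        } else {
          # unimodal: overwrite a deviating instance only if its anchored
          # long reads also prefer the consensus string over what it has
          # (a real allele whose reads all sorted elsewhere stays put)
          cur_str <- substr(cur, inst_a[v] + 1, inst_b[v])
          if (cur_str == s1) NULL else decide(v, s1, cur_str)
        }
        if (!is.null(e)) phase_edits[[length(phase_edits) + 1]] <- e
      }
    }
    if (length(phase_edits) == 0) break
    pe <- dplyr::bind_rows(phase_edits)
    pe <- pe[order(-pe$start), ]
    # overlapping windows may nominate conflicting edits: keep a
    # non-overlapping subset, right to left
    keep <- rep(TRUE, nrow(pe))
    last_start <- Inf
    for (j in seq_len(nrow(pe))) {
      if (pe$end[j] > last_start) keep[j] <- FALSE
      else last_start <- pe$start[j]
    }
    pe <- pe[keep, ]
    if (nrow(pe) == 0) break
    if (isTRUE(getOption("poreclone.phase.debug")))
      message("phase iter ", phase_iter, ": ", nrow(pe), " edits at ",
              paste(pe$start, collapse = ","))
    # unit coordinates stay in register with the phase edits
    for (j in seq_len(nrow(pe))) {
      shift <- nchar(pe$illumina_allele[j]) - (pe$end[j] - pe$start[j])
      if (shift != 0L) {
        units$end[units$end > pe$start[j]] <-
          units$end[units$end > pe$start[j]] + shift
        sel <- units$start > pe$start[j]
        units$start[sel] <- units$start[sel] + shift
      }
    }
    cur <- apply_edits(cur, pe)
    unit_disc[[length(unit_disc) + 1]] <- pe[, c("position",
      "nanopore_allele", "illumina_allele", "class", "depth", "agree")]
  }
  # 4. junction support from long reads spanning unit boundaries
  units <- units[order(units$start), ]
  bounds <- sort(unique(c(units$start, units$end)))
  if (nrow(laln) > 0) {
    for (b in bounds) {
      span <- sum(laln$t_start <= b - 200 & laln$t_end >= b + 200)
      flags[[length(flags) + 1]] <- tibble(
        clone_id = clone_id, flag = "JUNCTION_SUPPORT",
        guidance = sprintf("boundary %d spanned by %d long read(s)", b, span))
    }
  }
  disc_all <- dplyr::bind_rows(c(list(prior), disc, unit_disc))
  if (nrow(disc_all) > 0) {
    disc_all <- disc_all[order(disc_all$position), ]
    disc_all <- disc_all[!duplicated(disc_all$position), ]
  }
  new_consensus_assembly(clone_id, cur,
                         if (inherits(consensus, "consensus_assembly"))
                           consensus$support else tibble(),
                         disc_all, 1L, dplyr::bind_rows(flags))
}
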