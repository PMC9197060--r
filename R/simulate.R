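# Synthetic clone pools with ground truth: circular BAC/fosmid molecules
# (cloning vector + insert), optional near-identical internal repeat units
# distinguished by planted sequence family variants (SFVs), pooled nanopore
# reads with homopolymer-biased indel errors, paired Illumina reads, and
# degraded draft assemblies. Every simulated read carries its truth labels;
# pipeline stages never consume them.

rotate_seq <- function(seq, offset) {
  n <- nchar(seq)
  offset <- offset %% n
  if (offset == 0) return(seq)
  paste0(substr(seq, offset + 1, n), substr(seq, 1, offset))
}

new_clone_truth <- function(clone_id, sequence, vector_len, repeat_units,
                            sfv_sites) {
  structure(list(
    clone_id = clone_id,
    sequence = sequence,
    vector_interval = c(0L, as.integer(vector_len)),
    repeat_units = repeat_units,
    sfv_sites = sfv_sites
  ), class = "clone_truth")
}

#' @export
print.clone_truth <- function(x, ...) {
  cat(sprintf("<clone_truth> %s: %d bp (vector %d bp), %d repeat unit(s), %d SFV site(s)\n",
              x$clone_id, nchar(x$sequence), x$vector_interval[2],
              nrow(x$repeat_units), nrow(x$sfv_sites)))
  invisible(x)
}

empty_units <- function() {
  tibble(unit_id = character(), start = integer(), end = integer(),
         group = integer(), orientation = character())
}

empty_sfvs <- function() {
  tibble(unit_index = integer(), offset = integer(), allele_base = character(),
         pos = integer())
}

# Substitution-only divergence at the given rate (repeat-unit background);
# uses the current RNG state.
diverge_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  cpp_mutate(seq, rate, 0, 0, 1)
}

# Build a repeat region from a template: n_units copies at the requested
# identity, planted SFVs, tandem or palindrome arrangement. Background
# divergence is substitution-only so units stay column-comparable.
# Returns list(sequence, units = tibble(start,end,orientation), sfvs).
build_repeat_region <- function(repeat_spec, sfv_per_unit) {
  n_units <- repeat_spec$n_units
  unit_len <- repeat_spec$unit_len
  identity <- repeat_spec$unit_identity %||% 0.99
  arrangement <- repeat_spec$arrangement %||% "tandem"
  template <- random_dna(unit_len)
  units_mat <- matrix(rep(strsplit(template, "", fixed = TRUE)[[1]], n_units),
                      nrow = n_units, byrow = TRUE)
  # deterministic divergence budget: every altered column is private to one
  # unit, so any unit pair differs at exactly 2*n_sub background columns
  # plus 2*sfv_per_unit SFV columns -- pairwise identity is guaranteed to
  # land in [unit_identity, 1)
  budget <- floor(unit_len * (1 - identity) * 0.8)
  n_sub <- max(0L, (budget - 2L * sfv_per_unit) %/% 2L)
  need <- n_units * (n_sub + sfv_per_unit)
  if (need > unit_len) abort("unit too short for the divergence budget")
  picked <- sample.int(unit_len, need)
  sfvs <- empty_sfvs()
  j <- 0L
  for (u in seq_len(n_units)) {
    for (i in seq_len(n_sub)) {
      j <- j + 1L; off <- picked[j]
      units_mat[u, off] <- sample(setdiff(BASES, units_mat[u, off]), 1)
    }
  }
  if (sfv_per_unit > 0 && n_units >= 2) {
    for (u in seq_len(n_units)) {
      for (i in seq_len(sfv_per_unit)) {
        j <- j + 1L; off <- picked[j]
        units_mat[u, off] <- sample(setdiff(BASES, units_mat[u, off]), 1)
        sfvs <- dplyr::bind_rows(sfvs, tibble(
          unit_index = u, offset = off - 1L,
          allele_base = units_mat[u, off], pos = NA_integer_))
      }
    }
  }
  sfvs <- sfvs[order(sfvs$unit_index, sfvs$offset), ]
  units_chr <- apply(units_mat, 1, paste, collapse = "")
  orientation <- rep("direct", n_units)
  if (arrangement == "palindrome") {
    if (n_units != 2) abort("palindrome arrangement requires n_units = 2")
    units_out <- c(units_chr[1], revcomp(units_chr[2]))
    orientation <- c("direct", "inverted")
  } else {
    units_out <- units_chr
  }
  starts <- (seq_len(n_units) - 1L) * unit_len
  list(
    sequence = paste(units_out, collapse = ""),
    units = tibble(start = starts, end = starts + unit_len,
                   orientation = orientation),
    sfvs = sfvs
  )
}

place_repeat <- function(insert, region, min_flank = 1000L) {
  ins_len <- nchar(insert)
  reg_len <- nchar(region$sequence)
  if (reg_len + 2 * min_flank > ins_len)
    abort("repeat region does not fit in the insert")
  at <- sample.int(ins_len - reg_len - 2 * min_flank, 1) + min_flank
  insert <- paste0(substr(insert, 1, at), region$sequence,
                   substring(insert, at + reg_len + 1))
  list(insert = insert, at = at)
}

#' Simulate a pool of circular clones with ground truth
#'
#' Each clone is a circular molecule written vector-first: the shared cloning
#' vector followed by a random insert. An optional repeat specification
#' plants `n_units` near-identical (>= `unit_identity`) repeat units in every
#' clone's insert, arranged as direct (tandem) or inverted (palindrome)
#' copies, distinguished by `sfv_per_unit` planted sequence family variants
#' per unit on top of the identity-level background divergence.
#'
#' @param n_clones number of clones (>= 1).
#' @param vector_len cloning vector length in bp (>= 2000).
#' @param insert_len_range two-element range for insert lengths.
#' @param repeat_spec `NULL`, or a list with `n_units`, `unit_len`,
#'   `unit_identity` (in `[0.99, 1)`) and `arrangement`
#'   (`"tandem"`/`"palindrome"`/`"none"`).
#' @param sfv_per_unit planted SFVs per repeat unit; 0 with two or more units
#'   makes units indistinguishable by construction and is refused unless
#'   `allow_indistinct = TRUE`.
#' @param seed integer seed; identical inputs and seed give byte-identical
#'   pools.
#' @param allow_indistinct permit `sfv_per_unit = 0` with a warning.
#' @return a list of `clone_truth` objects with the shared vector sequence in
#'   `attr(, "vector")`.
#' @export
make_clone_pool <- function(n_clones, vector_len = 3000L,
                            insert_len_range = c(30000L, 60000L),
                            repeat_spec = NULL, sfv_per_unit = 2L,
                            seed = 1L, allow_indistinct = FALSE) {
  stopifnot(n_clones >= 1, vector_len >= 2000)
  if (!is.null(repeat_spec) && identical(repeat_spec$arrangement, "none"))
    repeat_spec <- NULL
  if (!is.null(repeat_spec)) {
    stopifnot(repeat_spec$n_units >= 1)
    id <- repeat_spec$unit_identity %||% 0.99
    if (id < 0.99 || id >= 1) abort("unit_identity must be in [0.99, 1)")
    if (repeat_spec$n_units * repeat_spec$unit_len > min(insert_len_range))
      abort("repeat units do not fit: unit_len * n_units exceeds the insert length")
    if (sfv_per_unit == 0 && repeat_spec$n_units >= 2) {
      if (!allow_indistinct)
        abort(paste("sfv_per_unit = 0 with multiple units makes units",
                    "indistinguishable by construction; pass allow_indistinct",
                    "= TRUE to force"))
      warn("repeat units carry no SFVs and are indistinguishable by construction")
    }
  }
  with_seed(seed, {
    vector_seq <- random_dna(vector_len)
    pool <- lapply(seq_len(n_clones), function(i) {
      ins_len <- if (insert_len_range[1] == insert_len_range[2]) insert_len_range[1]
                 else sample(insert_len_range[1]:insert_len_range[2], 1)
      insert <- random_dna(ins_len)
      units <- empty_units(); sfvs <- empty_sfvs()
      if (!is.null(repeat_spec)) {
        region <- build_repeat_region(repeat_spec, sfv_per_unit)
        placed <- place_repeat(insert, region)
        insert <- placed$insert
        off <- vector_len + placed$at
        units <- tibble(
          unit_id = paste0("u", seq_len(nrow(region$units))),
          start = as.integer(region$units$start + off),
          end = as.integer(region$units$end + off),
          group = 1L,
          orientation = region$units$orientation
        )
        sfvs <- region$sfvs
        if (nrow(sfvs) > 0)
          sfvs$pos <- as.integer(units$start[sfvs$unit_index] + sfvs$offset)
      }
      new_clone_truth(sprintf("clone%02d", i), paste0(vector_seq, insert),
                      vector_len, units, sfvs)
    })
    attr(pool, "vector") <- vector_seq
    pool
  })
}

#' Simulate an overlapping tiling path of clones
#'
#' Cuts `n_clones` inserts of equal length from one simulated genomic
#' segment so that consecutive clones overlap by `overlap` bp; overlaps
#' between independently finished neighbours are the accuracy check used in
#' clone-based sequencing. Optionally plants one tandem repeat region (with
#' SFVs) inside the overlap of the middle clone pair, so that the pair
#' shares an amplicon.
#'
#' @inheritParams make_clone_pool
#' @param insert_len insert length of every clone.
#' @param overlap overlap between consecutive inserts (bp).
#' @return list of `clone_truth` objects; attributes `vector` (shared vector
#'   sequence) and `genome` (the underlying segment).
#' @export
make_tiling_pool <- function(n_clones = 6L, insert_len = 37000L,
                             overlap = 12000L, vector_len = 3000L,
                             repeat_spec = NULL, sfv_per_unit = 2L,
                             seed = 1L) {
  stopifnot(n_clones >= 2, overlap < insert_len)
  step <- insert_len - overlap
  genome_len <- insert_len + (n_clones - 1L) * step
  with_seed(seed, {
    vector_seq <- random_dna(vector_len)
    genome <- random_dna(genome_len)
    units_genome <- empty_units(); sfvs_genome <- empty_sfvs()
    if (!is.null(repeat_spec) && !identical(repeat_spec$arrangement, "none")) {
      reg_len <- repeat_spec$n_units * repeat_spec$unit_len
      if (reg_len + 2000L > overlap)
        abort("repeat region does not fit inside the clone overlap")
      region <- build_repeat_region(repeat_spec, sfv_per_unit)
      pair <- floor(n_clones / 2) # repeat goes into overlap of pair, pair+1
      ov_start <- pair * step
      at <- ov_start + (overlap - reg_len) %/% 2
      genome <- paste0(substr(genome, 1, at), region$sequence,
                       substring(genome, at + reg_len + 1))
      units_genome <- tibble(
        unit_id = paste0("u", seq_len(nrow(region$units))),
        start = as.integer(region$units$start + at),
        end = as.integer(region$units$end + at),
        group = 1L, orientation = region$units$orientation)
      sfvs_genome <- region$sfvs
      if (nrow(sfvs_genome) > 0)
        sfvs_genome$pos <- as.integer(units_genome$start[sfvs_genome$unit_index] +
                                        sfvs_genome$offset)
    }
    pool <- lapply(seq_len(n_clones), function(i) {
      g0 <- (i - 1L) * step
      insert <- substr(genome, g0 + 1, g0 + insert_len)
      units <- empty_units(); sfvs <- empty_sfvs()
      if (nrow(units_genome) > 0) {
        inside <- units_genome$start >= g0 & units_genome$end <= g0 + insert_len
        if (any(inside)) {
          units <- units_genome[inside, ]
          units$start <- as.integer(units$start - g0 + vector_len)
          units$end <- as.integer(units$end - g0 + vector_len)
          keep_units <- which(inside)
          sf <- sfvs_genome[sfvs_genome$unit_index %in% keep_units, ]
          if (nrow(sf) > 0) {
            sf$unit_index <- match(sf$unit_index, keep_units)
            sf$pos <- as.integer(sf$pos - g0 + vector_len)
          }
          sfvs <- sf
        }
      }
      new_clone_truth(sprintf("clone%02d", i), paste0(vector_seq, insert),
                      vector_len, units, sfvs)
    })
    attr(pool, "vector") <- vector_seq
    attr(pool, "genome") <- genome
    pool
  })
}

#' Default nanopore error model
#'
#' 10% total error (4% substitutions, 3% insertions, 3% deletions) with
#' indel rates multiplied 6-fold inside homopolymer runs of length >= 3,
#' where nanopore basecalls concentrate their insertion/deletion errors.
#'
#' @export
nanopore_error_model <- function(sub = 0.04, ins = 0.03, del = 0.03,
                                 homopolymer_indel_multiplier = 6) {
  stopifnot(sub >= 0, sub < 1, ins >= 0, ins < 1, del >= 0, del < 1)
  list(sub = sub, ins = ins, del = del,
       homopolymer_indel_multiplier = homopolymer_indel_multiplier)
}

#' Simulate a pooled nanopore run
#'
#' Each read is drawn from a uniformly chosen clone of the pool. With
#' probability `p_single_cut` the circular molecule is cut once at a uniform
#' position and read full-length (either orientation, equiprobably);
#' otherwise a truncated fragment starting at the cut is emitted with an
#' exponentially distributed length. Errors follow
#' [nanopore_error_model()]. Reads are generated sequentially from the seed,
#' so the first m reads of an n-read run (m < n) are identical to an m-read
#' run — adding reads never perturbs earlier ones.
#'
#' @param pool list of `clone_truth` objects.
#' @param n_reads number of reads (> 0).
#' @param p_single_cut probability that a molecule is cut exactly once and
#'   read full-length.
#' @param error_model see [nanopore_error_model()].
#' @param length_model list with `mean`: mean truncated-read length in bp.
#' @param seed integer seed.
#' @return a tibble with `read_id`, `bases`, and truth columns `clone_id`,
#'   `cut_position`, `strand`, `truncated` (truth is metadata for evaluation
#'   only; no pipeline stage reads it).
#' @export
simulate_nanopore_run <- function(pool, n_reads, p_single_cut = 0.3,
                                  error_model = nanopore_error_model(),
                                  length_model = list(mean = 6000),
                                  seed = 1L) {
  if (n_reads <= 0) abort("n_reads must be positive")
  if (length(pool) == 0) abort("pool is empty")
  em <- error_model
  with_seed(seed, {
    out <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      ci <- sample.int(length(pool), 1)
      clone <- pool[[ci]]
      n <- nchar(clone$sequence)
      cut <- sample.int(n, 1) - 1L
      full <- runif(1) < p_single_cut
      minus <- runif(1) < 0.5
      mol <- rotate_seq(clone$sequence, cut)
      if (minus) mol <- cpp_revcomp(mol)
      if (!full) {
        len <- max(50L, min(n - 1L, as.integer(ceiling(rexp(1, 1 / length_model$mean)))))
        mol <- substr(mol, 1, len)
      }
      bases <- cpp_mutate(mol, em$sub, em$ins, em$del,
                          em$homopolymer_indel_multiplier)
      out[[i]] <- list(read_id = sprintf("read%06d", i), bases = bases,
                       clone_id = clone$clone_id, cut_position = cut,
                       strand = if (minus) "-" else "+", truncated = !full)
    }
    tibble(
      read_id = vapply(out, `[[`, "", "read_id"),
      bases = vapply(out, `[[`, "", "bases"),
      clone_id = vapply(out, `[[`, "", "clone_id"),
      cut_position = vapply(out, function(x) x$cut_position, integer(1)),
      strand = vapply(out, `[[`, "", "strand"),
      truncated = vapply(out, `[[`, TRUE, "truncated")
    )
  })
}

#' Simulate paired-end Illumina reads for each clone
#'
#' Fragments are placed uniformly on each circular clone; pairs point inward;
#' errors are substitution-only.
#'
#' @param pool list of `clone_truth` objects.
#' @param coverage fold coverage per clone (> 0).
#' @param read_len read length (bp).
#' @param frag_len,frag_sd mean and s.d. of fragment length; must satisfy
#'   `frag_len > 2 * read_len`.
#' @param sub_rate per-base substitution error rate.
#' @param seed integer seed.
#' @return tibble with `read_id`, `bases1`, `bases2` and truth columns
#'   `clone_id`, `frag_start`, `frag_len`.
#' @export
simulate_illumina <- function(pool, coverage = 50, read_len = 150L,
                              frag_len = 500L, frag_sd = 50L,
                              sub_rate = 0.002, seed = 1L) {
  stopifnot(coverage > 0)
  if (frag_len < 2 * read_len) abort("frag_len must exceed 2 * read_len")
  with_seed(seed, {
    res <- lapply(pool, function(clone) {
      n <- nchar(clone$sequence)
      n_frags <- as.integer(round(coverage * n / (2 * read_len)))
      ext <- paste0(clone$sequence,
                    substr(clone$sequence, 1, frag_len + 6L * frag_sd))
      starts <- sample.int(n, n_frags, replace = TRUE) - 1L
      flens <- pmax(2L * read_len + 2L,
                    as.integer(round(rnorm(n_frags, frag_len, frag_sd))))
      frags <- substring(ext, starts + 1, starts + flens)
      r1 <- substr(frags, 1, read_len)
      r2 <- revcomp(substring(frags, flens - read_len + 1, flens))
      if (sub_rate > 0) {
        r1 <- vapply(r1, function(s) cpp_mutate(s, sub_rate, 0, 0, 1),
                     character(1), USE.NAMES = FALSE)
        r2 <- vapply(r2, function(s) cpp_mutate(s, sub_rate, 0, 0, 1),
                     character(1), USE.NAMES = FALSE)
      }
      tibble(
        read_id = sprintf("%s_frag%06d", clone$clone_id, seq_len(n_frags)),
        bases1 = r1, bases2 = r2, clone_id = clone$clone_id,
        frag_start = starts, frag_len = flens
      )
    })
    dplyr::bind_rows(res)
  })
}

#' Degrade a clone truth into a draft assembly
#'
#' Emulates a short-read-only draft: when `collapse_repeats`, every tandem
#' paralog group is merged into a single unit at the column-wise majority
#' base (the classic assembly collapse in the presence of multiple amplicon
#' copies); optional substitution errors; optional contig breaks. The draft
#' is linearized starting at the vector start.
#'
#' @param clone a `clone_truth`.
#' @param collapse_repeats merge tandem paralogous units into one.
#' @param error_rate substitution error rate applied to the draft.
#' @param n_contig_breaks number of random internal breaks.
#' @param seed integer seed.
#' @return tibble of draft contigs with `name` and `sequence`.
#' @export
degrade_to_draft <- function(clone, collapse_repeats = FALSE, error_rate = 0,
                             n_contig_breaks = 0L, seed = 1L) {
  stopifnot(inherits(clone, "clone_truth"))
  with_seed(seed, {
    seq <- clone$sequence
    if (collapse_repeats && nrow(clone$repeat_units) >= 2) {
      for (g in rev(unique(clone$repeat_units$group))) {
        units <- clone$repeat_units[clone$repeat_units$group == g, ]
        if (nrow(units) < 2 || any(units$orientation != "direct")) next
        if (any(diff(units$start) != (units$end[1] - units$start[1]))) next
        mat <- do.call(rbind, strsplit(substring(seq, units$start + 1, units$end),
                                       "", fixed = TRUE))
        merged <- paste(apply(mat, 2, function(col) names(sort(table(col),
                        decreasing = TRUE))[1]), collapse = "")
        seq <- paste0(substr(seq, 1, min(units$start)), merged,
                      substring(seq, max(units$end) + 1))
      }
    }
    if (error_rate > 0) seq <- cpp_mutate(seq, error_rate, 0, 0, 1)
    if (n_contig_breaks > 0) {
      cuts <- sort(sample.int(nchar(seq) - 1L, n_contig_breaks))
      bounds <- c(0L, cuts, nchar(seq))
      tibble(
        name = sprintf("%s_contig%d", clone$clone_id, seq_len(length(bounds) - 1)),
        sequence = substring(seq, bounds[-length(bounds)] + 1, bounds[-1])
      )
    } else {
      tibble(name = clone$clone_id, sequence = seq)
    }
  })
}

#' Write the read truth table as TSV
#'
#' @param reads tibble from [simulate_nanopore_run()].
#' @param path output path.
#' @export
write_truth_tsv <- function(reads, path) {
  utils::write.table(
    reads[, c("read_id", "clone_id", "cut_position", "strand", "truncated")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
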