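# broom-style tidiers for the pipeline's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn polish_short discrepancy list as a tibble.
#' @param x a `consensus_assembly`.
#' @param ... unused.
#' @export
tidy.consensus_assembly <- function(x, ...) {
  d <- x$discrepancies
  if (nrow(d) > 0) d <- dplyr::mutate(d, clone_id = x$clone_id,
                                      .before = 1)
  as_tibble(d)
}

#' @export
glance.consensus_assembly <- function(x, ...) {
  d <- x$discrepancies
  tibble(clone_id = x$clone_id, length = nchar(x$sequence),
         n_homopolymer_indel = sum(d$class == "HOMOPOLYMER_INDEL"),
         n_substitution = sum(d$class == "SUBSTITUTION"),
         n_unresolved = sum(d$class == "UNRESOLVED"),
         rounds_applied = x$rounds_applied)
}

#' @describeIn demux_pool per-read assignments as a tibble.
#' @param x a `demux_result`.
#' @param ... unused.
#' @export
tidy.demux_result <- function(x, ...) as_tibble(x$assignments)

#' @export
glance.demux_result <- function(x, ...) {
  tibble(total_reads = x$total_reads,
         n_assigned = sum(x$stats$n_reads),
         n_ambiguous = length(x$ambiguous),
         n_unassigned = length(x$unassigned),
         n_clones = nrow(x$stats),
         max_fraction = max(x$stats$fraction),
         n_empty_bins = sum(x$stats$n_reads == 0))
}

#' @describeIn run_stats per-clone statistics as a tibble.
#' @param x a `run_stats`.
#' @param ... unused.
#' @export
tidy.run_stats <- function(x, ...) as_tibble(x$per_clone)

#' @export
glance.run_stats <- function(x, ...) {
  tibble(total_reads = x$total_reads, total_bases = x$total_bases,
         read_n50 = x$read_n50, n_clones = nrow(x$per_clone),
         n_flags = nrow(x$flags))
}

#' @describeIn run_all one row per finished clone.
#' @param x a `finish_run`.
#' @param ... unused.
#' @export
tidy.finish_run <- function(x, ...) {
  dplyr::bind_rows(lapply(x$assemblies, glance))
}

#' @export
glance.finish_run <- function(x, ...) {
  tibble(n_clones = nrow(x$stats$per_clone),
         n_finished = length(x$assemblies),
         total_reads = x$stats$total_reads,
         read_n50 = x$stats$read_n50,
         n_flags = nrow(x$flags))
}
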