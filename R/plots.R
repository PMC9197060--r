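# ggplot2 displays for run QC.

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_col geom_vline
#'   labs theme_minimal
#' @export
ggplot2::autoplot

#' Read-length distribution with the clone-length peak
#'
#' Full-length reads pile up near the clone length, producing a peak in the
#' tail of the read-length distribution; the dashed line marks the
#' [estimate_clone_length()] estimate when one is found.
#'
#' @param read_lengths integer vector of read lengths, or a read tibble.
#' @param bin_width histogram bin width (bp).
#' @return a ggplot.
#' @export
plot_read_lengths <- function(read_lengths, bin_width = 1000L) {
  if (is.data.frame(read_lengths))
    read_lengths <- nchar(read_lengths$bases)
  est <- suppressWarnings(estimate_clone_length(read_lengths, bin_width))
  p <- ggplot(tibble(length = read_lengths), aes(x = .data$length)) +
    geom_histogram(binwidth = bin_width, boundary = 0) +
    labs(x = "read length (bp)", y = "reads") +
    theme_minimal()
  if (!is.na(est)) p <- p + geom_vline(xintercept = est, linetype = "dashed")
  p
}

#' @describeIn demux_pool bar plot of per-clone read shares.
#' @param object a `demux_result`.
#' @param ... unused.
#' @export
autoplot.demux_result <- function(object, ...) {
  ggplot(object$stats, aes(x = .data$clone_id, y = .data$fraction)) +
    geom_col() +
    labs(x = NULL, y = "fraction of total reads") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn run_stats per-clone read counts and full-length counts.
#' @param object a `run_stats`.
#' @param ... unused.
#' @export
autoplot.run_stats <- function(object, ...) {
  pc <- object$per_clone
  ggplot(pc, aes(x = .data$clone_id, y = .data$n_reads)) +
    geom_col() +
    labs(x = NULL, y = "reads assigned") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
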