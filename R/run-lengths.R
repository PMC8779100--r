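#' Run-length counts of equiconformational sequences
#'
#' Within each frame, scans the analysed residues in chain order and counts
#' the maximal runs of contiguous residues sharing the target state: a run
#' of 5 contributes one count at length 5, not nested sub-runs. Runs are
#' truncated at the chain ends (the chain is linear; residue n is not joined
#' to residue 1).
#'
#' @param states A `state_trajectory` (see [classify_trajectory()]).
#' @param target State label whose runs are counted.
#' @return A `run_length_record` tibble with columns `frame`, `length`,
#'   `n_runs`; attributes `target`, `t` (number of analysed frames) and
#'   `n_monomers`.
#' @export
run_lengths <- function(states, target) {
  labs <- attr(states, "labels")
  if (!is.null(labs) && !target %in% labs) {
    rlang::abort(sprintf("target state '%s' not in label alphabet", target))
  }
  x <- dplyr::arrange(states, .data$frame, .data$residue)
  v <- x$state == target
  f <- x$frame
  n <- length(v)
  frames <- sort(unique(f))

  if (n == 0) {
    rec <- tibble::tibble(frame = integer(), length = integer(),
                          n_runs = integer())
  } else {
    new_frame <- c(TRUE, f[-1] != f[-n])
    start <- v & (new_frame | !c(FALSE, v[-n]))
    end <- v & (c(new_frame[-1], TRUE) | !c(v[-1], FALSE))
    si <- which(start)
    ei <- which(end)
    rec <- tibble::tibble(frame = f[si], length = ei - si + 1L) |>
      dplyr::count(.data$frame, .data$length, name = "n_runs")
  }
  structure(
    rec,
    target = target,
    t = length(frames),
    n_monomers = attr(states, "n_monomers") %||%
      length(unique(states$residue)),
    class = c("run_length_record", class(tibble::tibble()))
  )
}

#' Fraction of monomers in long equiconformational sequences
#'
#' Converts run-length counts into the fraction of monomers sitting in runs
#' of at least `min_len` contiguous same-state residues, averaged over
#' frames:
#' \deqn{F = \frac{1}{t} \sum_j \sum_{i \ge \mathrm{min\_len}}
#'   \frac{i \, R_{ij}}{n_{\mathrm{monomers}}}}
#' where \eqn{R_{ij}} is the number of maximal runs of length \eqn{i} in
#' frame \eqn{j} and \eqn{t} the number of frames. The default threshold of
#' 4 corresponds to at least one helical turn (an alpha helix has 3.6
#' residues per turn, so a genuine helical stretch needs more than three
#' monomers); with `min_len = 1` the result equals the plain state fraction.
#'
#' @param record A [run_lengths()] record.
#' @param min_len Minimum run length counted (default 4).
#' @param n_monomers Number of analysed monomers per chain (default: taken
#'   from the record; 30 for a 32-residue chain with termini excluded).
#' @return A single proportion in `[0, 1]`.
#' @export
sequence_fraction <- function(record, min_len = 4,
                              n_monomers = attr(record, "n_monomers")) {
  if (min_len < 1) rlang::abort("min_len must be at least 1")
  if (is.null(n_monomers) || n_monomers <= 0) {
    rlang::abort("n_monomers must be positive")
  }
  t <- attr(record, "t")
  if (is.null(t) || t == 0) rlang::abort("record covers no frames")
  keep <- record$length >= min_len
  sum(record$length[keep] * record$n_runs[keep]) / (t * n_monomers)
}

#' Mean run-length distribution
#'
#' Average number of maximal runs of each length per frame,
#' \eqn{\bar R_i = \sum_j R_{ij} / t}.
#'
#' @param record A [run_lengths()] record.
#' @return Tibble with columns `length` and `mean_count` (lengths with zero
#'   counts are omitted; no length exceeds the number of analysed monomers).
#' @export
length_histogram <- function(record) {
  t <- attr(record, "t")
  if (is.null(t) || t < 1) rlang::abort("record covers no frames")
  record |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(mean_count = sum(.data$n_runs) / t, .groups = "drop") |>
    dplyr::arrange(.data$length)
}

#' Write a run-length histogram as TSV
#'
#' @param histogram Result of [length_histogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_length_histogram <- function(histogram, path) {
  utils::write.table(as.data.frame(histogram), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
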