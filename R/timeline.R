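#' Conformation timeline raster
#'
#' Aggregates a state trajectory into one pixel per (residue, time window):
#' each pixel carries the modal state of the frames inside its window, ties
#' broken by the state of the window's first frame. This is the per-monomer
#' conformation timeline view used to spot long-lived equiconformational
#' stretches and paired sequences.
#'
#' @param states A `state_trajectory`.
#' @param pixel_dt Width of one time pixel in ns; must be at least the frame
#'   spacing. Default: 10 frames per pixel.
#' @return Tibble with columns `residue`, `pixel`, `time_start_ns`, `state`;
#'   the number of pixels is `ceiling(total time / pixel_dt)`.
#' @export
conformation_timeline <- function(states, pixel_dt = NULL) {
  dt <- attr(states, "dt_ns")
  if (is.null(dt) || is.na(dt)) dt <- diff(sort(unique(states$time_ns)))[1]
  if (is.null(pixel_dt)) pixel_dt <- 10 * dt
  if (pixel_dt < dt) rlang::abort("pixel_dt must be at least the frame spacing")

  frames <- sort(unique(states$frame))
  frames_per_pixel <- pixel_dt / dt
  # guard against floating-point drift in the frame/pixel ratio
  n_pixels <- ceiling(length(frames) / frames_per_pixel - 1e-9)
  pixel_of_frame <- pmin(
    floor((match(states$frame, frames) - 1) / frames_per_pixel + 1e-9) + 1,
    n_pixels
  )

  states |>
    dplyr::mutate(pixel = pixel_of_frame) |>
    dplyr::group_by(.data$residue, .data$pixel) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      time_start_ns = min(.data$time_ns),
      state = {
        tab <- table(.data$state)
        winners <- names(tab)[tab == max(tab)]
        if (length(winners) == 1) winners else {
          # tie: state of the window's first frame
          first_hit <- .data$state[.data$state %in% winners][1]
          first_hit
        }
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$residue, .data$pixel)
}

#' Write a timeline raster as a TSV matrix
#'
#' Rows are residues, columns time pixels, cells state labels.
#'
#' @param timeline Result of [conformation_timeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  wide <- tidyr::pivot_wider(timeline[c("residue", "pixel", "state")],
                             names_from = "pixel", values_from = "state")
  utils::write.table(as.data.frame(wide), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
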