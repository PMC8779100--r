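#' Classify dihedral angles into Ramachandran states
#'
#' Assigns each (phi, psi) pair the label of the region box containing it,
#' or `"other"` when it lies in no box. Angles are wrapped first, so the
#' classification is invariant under adding multiples of 360 degrees.
#' `NA` angles yield `NA` labels.
#'
#' @param phi,psi Numeric vectors of angles in degrees (recycled to a
#'   common length).
#' @param regions A [region_set()].
#' @return Character vector of state labels.
#' @examples
#' rs <- builtin_region_set("standard_literature")
#' classify_state(c(-60, 60, 0), c(-45, 45, 0), rs)
#' @export
classify_state <- function(phi, psi, regions) {
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  out <- rep("other", n)
  unassigned <- rep(TRUE, n)
  for (i in seq_len(nrow(regions))) {
    hit <- unassigned & box_member(phi, psi, regions[i, , drop = FALSE])
    out[hit] <- regions$label[i]
    unassigned[hit] <- FALSE
  }
  out[is.na(phi) | is.na(psi)] <- NA_character_
  out
}

#' Classify a dihedral trajectory into a state trajectory
#'
#' Labels every (frame, residue) with its conformational state. By default
#' the two terminal residues are dropped: the first residue has no phi and
#' the last no psi, and both are excluded from all statistics (a 32-residue
#' chain yields 30 analysed monomers).
#'
#' @param traj A [dihedral_trajectory()].
#' @param regions A [region_set()].
#' @param exclude_termini Drop the first and last residue. Default `TRUE`.
#' @return A `state_trajectory` tibble with columns `frame`, `time_ns`,
#'   `residue`, `state`; attributes `labels` (the full label alphabet
#'   including `"other"`), `dt_ns` and `n_monomers`.
#' @export
classify_trajectory <- function(traj, regions, exclude_termini = TRUE) {
  times <- sort(unique(traj$time_ns))
  if (length(times) == 0) rlang::abort("no frames in trajectory")
  residues <- sort(unique(traj$residue))
  if (exclude_termini) {
    if (length(residues) <= 2) rlang::abort("too few residues after excluding termini")
    keep <- residues[-c(1, length(residues))]
    traj <- dplyr::filter(traj, .data$residue %in% keep)
    residues <- keep
  }
  states <- tibble::tibble(
    frame = match(traj$time_ns, times),
    time_ns = traj$time_ns,
    residue = traj$residue,
    state = classify_state(traj$phi_deg, traj$psi_deg, regions)
  )
  states <- dplyr::arrange(states, .data$frame, .data$residue)
  new_state_trajectory(states, labels = region_labels(regions),
                       dt_ns = attr(traj, "dt_ns"),
                       n_monomers = length(residues))
}

#' Build a state trajectory from a label matrix or long table
#'
#' Wraps pre-computed conformational-state labels in the container the
#' sequence and timeline analyses expect. Useful when labels come from an
#' external assignment rather than [classify_trajectory()].
#'
#' @param x Either a character matrix (rows = frames, columns = residues)
#'   or a data frame with columns `frame`, `residue`, `state` (and
#'   optionally `time_ns`).
#' @param labels Label alphabet; defaults to the labels present plus
#'   `"other"`.
#' @param dt Frame spacing in ns (default 1).
#' @return A `state_trajectory` tibble.
#' @export
state_trajectory <- function(x, labels = NULL, dt = 1) {
  if (is.matrix(x)) {
    long <- tibble::tibble(
      frame = rep(seq_len(nrow(x)), each = ncol(x)),
      time_ns = rep((seq_len(nrow(x)) - 1) * dt, each = ncol(x)),
      residue = rep(seq_len(ncol(x)), times = nrow(x)),
      state = as.vector(t(x))
    )
    n_monomers <- ncol(x)
  } else {
    long <- tibble::as_tibble(x)
    if (!"time_ns" %in% names(long)) {
      long$time_ns <- (long$frame - 1) * dt
    }
    long <- long[c("frame", "time_ns", "residue", "state")]
    n_monomers <- length(unique(long$residue))
  }
  labels <- labels %||% unique(c(sort(unique(long$state)), "other"))
  new_state_trajectory(dplyr::arrange(long, .data$frame, .data$residue),
                       labels = labels, dt_ns = dt, n_monomers = n_monomers)
}

new_state_trajectory <- function(x, labels, dt_ns, n_monomers) {
  structure(
    tibble::as_tibble(x),
    labels = labels,
    dt_ns = dt_ns,
    n_monomers = n_monomers,
    class = c("state_trajectory", class(tibble::tibble()))
  )
}

#' Two-dimensional dihedral density (Ramachandran histogram)
#'
#' Normalized histogram of all (phi, psi) residue-frames on a regular grid
#' over the torus. Terminal residues (undefined angles) are excluded.
#'
#' @param traj A [dihedral_trajectory()].
#' @param bin_width Bin width in degrees; must divide 360 evenly. Default 10.
#' @return A `density_2d` tibble with one row per bin: `phi_center`,
#'   `psi_center`, `weight` (weights sum to 1); attribute `bin_width`.
#' @export
ramachandran_density <- function(traj, bin_width = 10) {
  if (360 %% bin_width != 0) {
    rlang::abort("bin_width must divide 360 evenly")
  }
  ok <- !is.na(traj$phi_deg) & !is.na(traj$psi_deg)
  phi <- wrap_angle(traj$phi_deg[ok])
  psi <- wrap_angle(traj$psi_deg[ok])
  if (length(phi) == 0) rlang::abort("no defined (phi, psi) pairs")
  # bin k covers [-180 + k*w, -180 + (k+1)*w); +180 is periodically -180
  phi[phi == 180] <- -180
  psi[psi == 180] <- -180
  nb <- as.integer(360 / bin_width)
  ip <- pmin(floor((phi + 180) / bin_width), nb - 1)
  is <- pmin(floor((psi + 180) / bin_width), nb - 1)
  counts <- table(factor(ip, levels = 0:(nb - 1)),
                  factor(is, levels = 0:(nb - 1)))
  centers <- -180 + (seq_len(nb) - 0.5) * bin_width
  out <- tidyr::expand_grid(phi_center = centers, psi_center = centers)
  out$weight <- as.vector(counts[cbind(
    match(out$phi_center, centers), match(out$psi_center, centers)
  )]) / length(phi)
  structure(out, bin_width = bin_width,
            class = c("density_2d", class(tibble::tibble())))
}

#' Integrate a dihedral density over region boxes
#'
#' Each bin is assigned to the state containing its centre; the fraction of
#' a state is the sum of its bins' weights. When every box bound lies on a
#' bin edge this equals the direct classification-based fraction exactly.
#'
#' @param density A [ramachandran_density()] result.
#' @param regions A [region_set()].
#' @return A `fraction_table` tibble with columns `state`, `fraction`, `sd`
#'   (`NA`: integration carries no block error).
#' @export
integrate_regions <- function(density, regions) {
  lab <- classify_state(density$phi_center, density$psi_center, regions)
  labs <- region_labels(regions)
  fr <- vapply(labs, function(l) sum(density$weight[lab == l]), numeric(1))
  new_fraction_table(
    tibble::tibble(state = labs, fraction = unname(fr), sd = NA_real_),
    region_set_name = attr(regions, "name")
  )
}

new_fraction_table <- function(x, region_set_name = NULL, metadata = list()) {
  structure(
    tibble::as_tibble(x),
    region_set_name = region_set_name,
    metadata = metadata,
    class = c("fraction_table", class(tibble::tibble()))
  )
}

#' Conformational-state fractions with block-averaged errors
#'
#' The fraction of each state is its share of all residue-frames; the error
#' is the standard deviation of the per-block fractions over `n_blocks`
#' contiguous, equal-length time blocks.
#'
#' @param states A `state_trajectory` (see [classify_trajectory()]).
#' @param n_blocks Number of contiguous time blocks for the error estimate
#'   (default 5; must be at least 2 and at most the number of frames).
#' @return A `fraction_table` tibble (`state`, `fraction`, `sd`); fractions
#'   over the full alphabet, including `"other"`, sum to 1.
#' @export
state_fractions <- function(states, n_blocks = 5) {
  frames <- sort(unique(states$frame))
  if (n_blocks < 2) rlang::abort("n_blocks must be at least 2")
  if (length(frames) < n_blocks) {
    rlang::abort("too few frames for the requested number of blocks")
  }
  labs <- attr(states, "labels") %||% sort(unique(states$state))
  block_of_frame <- ceiling(seq_along(frames) / (length(frames) / n_blocks))
  block <- block_of_frame[match(states$frame, frames)]

  frac_in <- function(idx) {
    s <- states$state[idx]
    vapply(labs, function(l) mean(s == l), numeric(1))
  }
  overall <- frac_in(seq_len(nrow(states)))
  per_block <- vapply(seq_len(n_blocks), function(b) frac_in(which(block == b)),
                      numeric(length(labs)))
  sds <- apply(matrix(per_block, nrow = length(labs)), 1, stats::sd)

  new_fraction_table(
    tibble::tibble(state = labs, fraction = unname(overall), sd = unname(sds)),
    metadata = list(n_blocks = n_blocks)
  )
}

#' Write a fraction table as TSV
#'
#' @param fractions A `fraction_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fraction_table <- function(fractions, path) {
  utils::write.table(as.data.frame(fractions), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
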