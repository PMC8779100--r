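#' Radius of gyration per frame
#'
#' Mass-weighted root-mean-square distance of the selected atoms from their
#' centre of mass, computed independently for every frame.
#'
#' @param coords A [coordinate_trajectory()].
#' @param roles Atom roles included (default: all backbone and carboxylate
#'   atoms, i.e. everything except free ions).
#' @return Tibble with columns `frame`, `time_ns`, `rg_nm`.
#' @export
radius_of_gyration <- function(coords, roles = c("N", "CA", "C", "O_carboxyl")) {
  sel <- dplyr::filter(coords, .data$role %in% roles)
  if (nrow(sel) == 0) rlang::abort("no atoms selected")
  sel |>
    dplyr::group_by(.data$frame, .data$time_ns) |>
    dplyr::summarise(rg_nm = {
      m <- .data$mass
      if (sum(m) <= 0) rlang::abort("total mass must be positive")
      if (length(m) < 2) rlang::abort("radius of gyration needs at least 2 atoms")
      cx <- sum(m * .data$x) / sum(m)
      cy <- sum(m * .data$y) / sum(m)
      cz <- sum(m * .data$z) / sum(m)
      sqrt(sum(m * ((.data$x - cx)^2 + (.data$y - cy)^2 + (.data$z - cz)^2)) /
             sum(m))
    }, .groups = "drop")
}

#' End-to-end distance per frame
#'
#' Euclidean distance between the alpha-carbon of the first and last residue
#' (no minimum image: the chain is whole).
#'
#' @param coords A [coordinate_trajectory()] with CA atoms for the terminal
#'   residues.
#' @return Tibble with columns `frame`, `time_ns`, `ree_nm`.
#' @export
end_to_end_distance <- function(coords) {
  ca <- dplyr::filter(coords, .data$role == "CA")
  if (nrow(ca) == 0) rlang::abort("no CA atoms in trajectory")
  r1 <- min(ca$residue)
  rn <- max(ca$residue)
  ends <- dplyr::filter(ca, .data$residue %in% c(r1, rn))
  ends |>
    dplyr::group_by(.data$frame, .data$time_ns) |>
    dplyr::summarise(ree_nm = {
      if (dplyr::n() != 2) rlang::abort("missing terminal CA atom")
      sqrt(diff(.data$x)^2 + diff(.data$y)^2 + diff(.data$z)^2)
    }, .groups = "drop")
}

#' Counterion-bridge detection parameters
#'
#' An ion bridges two residues when it lies within the species cutoff of at
#' least one carboxylate oxygen of each, and the residues are at least
#' `min_residue_separation` apart in sequence. The default cutoffs are
#' typical first minima of ion-oxygen radial distribution functions
#' (Na-O 0.32 nm, K-O 0.36 nm).
#'
#' @param cutoffs Named numeric vector of cutoff radii per ion species (nm).
#' @param min_residue_separation Minimum `|a - b|` for a bridge (default 3),
#'   so that nearest-neighbour contacts do not count as bridges between
#'   distant groups.
#' @param default_cutoff Cutoff for species absent from `cutoffs` (nm).
#' @return A `bridge_spec` list.
#' @export
bridge_spec <- function(cutoffs = c("NA" = 0.32, "K" = 0.36),
                        min_residue_separation = 3,
                        default_cutoff = 0.32) {
  if (any(cutoffs <= 0) || default_cutoff <= 0) {
    rlang::abort("cutoffs must be positive")
  }
  if (min_residue_separation < 1) {
    rlang::abort("min_residue_separation must be at least 1")
  }
  structure(list(cutoffs = cutoffs,
                 min_residue_separation = min_residue_separation,
                 default_cutoff = default_cutoff),
            class = "bridge_spec")
}

# Pairwise distances between two coordinate matrices (rows = points),
# minimum-image for an orthorhombic box when box is non-NULL.
pair_distances <- function(a, b, box = NULL) {
  out <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) d <- d - box[k] * round(d / box[k])
    out <- out + d^2
  }
  sqrt(out)
}

#' Detect counterion bridges
#'
#' For every frame, finds all (ion, residue a, residue b) triples where the
#' ion lies within the species cutoff of at least one carboxylate oxygen of
#' both residues and `|a - b|` meets the minimum separation. An ion close to
#' three or more residues yields every qualifying pair. Distances use the
#' minimum-image convention when the trajectory has a box.
#'
#' @param coords A [coordinate_trajectory()] with carboxylate oxygens and
#'   ions annotated.
#' @param spec A [bridge_spec()].
#' @return Tibble with columns `frame`, `time_ns`, `ion`, `res_a`, `res_b`
#'   (`res_a < res_b`). Zero rows (with a warning) when no ions are present.
#' @export
detect_bridges <- function(coords, spec = bridge_spec()) {
  empty <- tibble::tibble(frame = integer(), time_ns = numeric(),
                          ion = integer(), res_a = integer(),
                          res_b = integer())
  ions <- dplyr::filter(coords, .data$role == "ion")
  oxy <- dplyr::filter(coords, .data$role == "O_carboxyl")
  if (nrow(ions) == 0) {
    rlang::warn("no ions in trajectory; bridge set is empty")
    return(empty)
  }
  if (nrow(oxy) == 0) rlang::abort("no carboxylate oxygens in trajectory")
  box <- attr(coords, "box")

  purrr::map_dfr(sort(unique(coords$frame)), function(f) {
    io <- ions[ions$frame == f, ]
    ox <- oxy[oxy$frame == f, ]
    if (nrow(io) == 0 || nrow(ox) == 0) return(empty)
    d <- pair_distances(cbind(io$x, io$y, io$z), cbind(ox$x, ox$y, ox$z), box)
    cut <- ifelse(io$species %in% names(spec$cutoffs),
                  spec$cutoffs[io$species], spec$default_cutoff)
    purrr::map_dfr(seq_len(nrow(io)), function(i) {
      near_res <- sort(unique(ox$residue[d[i, ] <= cut[i]]))
      if (length(near_res) < 2) return(empty)
      pairs <- utils::combn(near_res, 2)
      sep_ok <- abs(pairs[2, ] - pairs[1, ]) >= spec$min_residue_separation
      if (!any(sep_ok)) return(empty)
      tibble::tibble(frame = f, time_ns = io$time_ns[i], ion = io$atom[i],
                     res_a = pairs[1, sep_ok], res_b = pairs[2, sep_ok])
    })
  })
}

#' Time-averaged fraction of bridged carboxyl groups
#'
#' Per frame, the fraction of distinct carboxyl-bearing residues involved in
#' at least one counterion bridge; reported as the time average with a
#' block standard deviation.
#'
#' @param coords A [coordinate_trajectory()].
#' @param spec A [bridge_spec()].
#' @param n_blocks Contiguous time blocks for the error estimate (default 5;
#'   reduced to the frame count when there are fewer frames).
#' @return A list of class `bridge_report`: `fraction`, `sd`, `per_frame`
#'   (tibble `frame`, `time_ns`, `fraction`), `bridges` (the
#'   [detect_bridges()] table) and `n_carboxyl`.
#' @export
bridge_fraction <- function(coords, spec = bridge_spec(), n_blocks = 5) {
  frames <- sort(unique(coords$frame))
  if (length(frames) == 0) rlang::abort("no frames in trajectory")
  oxy <- dplyr::filter(coords, .data$role == "O_carboxyl")
  n_carboxyl <- length(unique(oxy$residue))
  if (n_carboxyl == 0) rlang::abort("no carboxylate oxygens in trajectory")

  bridges <- detect_bridges(coords, spec)
  per_frame <- tibble::tibble(
    frame = frames,
    time_ns = vapply(frames, function(f) coords$time_ns[coords$frame == f][1],
                     numeric(1)),
    fraction = vapply(frames, function(f) {
      b <- bridges[bridges$frame == f, ]
      length(unique(c(b$res_a, b$res_b))) / n_carboxyl
    }, numeric(1))
  )

  n_blocks <- min(n_blocks, length(frames))
  if (n_blocks >= 2) {
    block <- ceiling(seq_along(frames) / (length(frames) / n_blocks))
    block_means <- tapply(per_frame$fraction, block, mean)
    sd_blocks <- stats::sd(block_means)
  } else {
    sd_blocks <- 0
  }

  structure(list(
    fraction = mean(per_frame$fraction),
    sd = sd_blocks,
    per_frame = per_frame,
    bridges = bridges,
    n_carboxyl = n_carboxyl
  ), class = "bridge_report")
}
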