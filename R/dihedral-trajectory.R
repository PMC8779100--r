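#' Construct a dihedral trajectory from a long table
#'
#' A dihedral trajectory is a tibble with one row per (frame, residue) and
#' columns `time_ns`, `residue`, `phi_deg`, `psi_deg`. Angles are wrapped to
#' `(-180, 180]` on construction; `NA` marks an undefined terminal angle
#' (the first residue has no phi, the last no psi). The frame x residue grid
#' must be complete and the frame spacing uniform.
#'
#' @param x Data frame with columns `time_ns`, `residue`, `phi_deg`,
#'   `psi_deg`; rows may be in any order.
#' @return A `dihedral_trajectory` tibble sorted by time then residue, with
#'   attributes `dt_ns` (frame spacing) and `chain_length` (residue count).
#' @export
dihedral_trajectory <- function(x) {
  required <- c("time_ns", "residue", "phi_deg", "psi_deg")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "dihedral table must have columns time_ns, residue, phi_deg, psi_deg; ",
      "missing: ", paste(missing_cols, collapse = ", ")
    ))
  }
  x <- tibble::as_tibble(x)[required]
  for (col in required) {
    if (!is.numeric(x[[col]])) {
      rlang::abort(paste0("column '", col, "' is not numeric"))
    }
  }

  times <- sort(unique(x$time_ns))
  residues <- sort(unique(x$residue))
  if (any(duplicated(x[c("time_ns", "residue")]))) {
    rlang::abort("duplicated (time, residue) rows in dihedral table")
  }
  if (nrow(x) != length(times) * length(residues)) {
    full <- tidyr::expand_grid(time_ns = times, residue = residues)
    gap <- dplyr::anti_join(full, x, by = c("time_ns", "residue"))
    rlang::abort(sprintf(
      "incomplete grid: missing residue %s at time %g ns (and possibly more)",
      gap$residue[1], gap$time_ns[1]
    ))
  }

  if (length(times) >= 2) {
    dts <- diff(times)
    dt <- dts[1]
    if (dt <= 0 || any(abs(dts - dt) > 1e-9 * max(abs(dt), 1))) {
      rlang::abort("frame times must be uniformly spaced with dt > 0")
    }
  } else {
    dt <- NA_real_
  }

  x$phi_deg <- wrap_angle(x$phi_deg)
  x$psi_deg <- wrap_angle(x$psi_deg)
  x <- dplyr::arrange(x, .data$time_ns, .data$residue)

  structure(
    x,
    dt_ns = dt,
    chain_length = length(residues),
    class = c("dihedral_trajectory", class(tibble::tibble()))
  )
}

#' Read a dihedral table from delimited text
#'
#' Expects a header row with columns `time_ns`, `residue`, `phi_deg`,
#' `psi_deg` (comma- or tab-separated, auto-detected). The (frame, residue)
#' grid must be complete; angles are wrapped to `(-180, 180]`.
#'
#' @param path File path.
#' @param delim Optional delimiter; when `NULL` (default) it is auto-detected
#'   from the header line.
#' @return A [dihedral_trajectory()] tibble.
#' @export
read_dihedral_table <- function(path, delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  x <- utils::read.delim(path, sep = delim, header = TRUE,
                         stringsAsFactors = FALSE)
  for (col in c("phi_deg", "psi_deg")) {
    if (col %in% names(x) && !is.numeric(x[[col]])) {
      bad <- which(!is.na(x[[col]]) & is.na(suppressWarnings(as.numeric(x[[col]]))))
      if (length(bad) > 0) {
        rlang::abort(sprintf(
          "non-numeric value '%s' in column %s at data line %d of %s",
          x[[col]][bad[1]], col, bad[1], path
        ))
      }
      x[[col]] <- as.numeric(x[[col]])
    }
  }
  dihedral_trajectory(x)
}

#' Write a dihedral trajectory as delimited text
#'
#' @param traj A [dihedral_trajectory()].
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_dihedral_table <- function(traj, path, delim = ",") {
  utils::write.table(as.data.frame(traj), path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop the equilibration segment of a trajectory
#'
#' Removes the first `ceiling(fraction * n_frames)` frames (or, when
#' `time_ns` is given, all frames with time strictly below it). Long
#' molecular-dynamics runs need their initial relaxation discarded before
#' averaging; the default drops the first tenth of the frames.
#'
#' @param traj A [dihedral_trajectory()] or coordinate-trajectory tibble
#'   (any tibble with a `time_ns` column).
#' @param fraction Fraction of frames to discard, in `[0, 1)`. Default 0.1.
#' @param time_ns Alternative absolute cut: discard frames with
#'   `time < time_ns`. Overrides `fraction` when given.
#' @return Trajectory of the same type with the leading frames removed.
#' @export
discard_equilibration <- function(traj, fraction = 0.1, time_ns = NULL) {
  times <- sort(unique(traj$time_ns))
  if (!is.null(time_ns)) {
    keep <- times[times >= time_ns]
  } else {
    if (fraction < 0 || fraction >= 1) {
      rlang::abort("equilibration fraction must be in [0, 1)")
    }
    n_drop <- ceiling(fraction * length(times))
    keep <- if (n_drop == 0) times else times[-seq_len(n_drop)]
  }
  out <- dplyr::filter(traj, .data$time_ns %in% keep)
  attrs <- attributes(traj)
  for (a in setdiff(names(attrs), c("row.names", "names", "class"))) {
    attr(out, a) <- attrs[[a]]
  }
  class(out) <- class(traj)
  out
}

#' @export
print.dihedral_trajectory <- function(x, ...) {
  cat(sprintf(
    "<dihedral_trajectory: %d frames x %d residues, dt = %s ns>\n",
    length(unique(x$time_ns)), attr(x, "chain_length"),
    format(attr(x, "dt_ns"))
  ))
  NextMethod()
}
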