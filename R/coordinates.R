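#' Construct a coordinate trajectory
#'
#' A coordinate trajectory is a long tibble with one row per (frame, atom):
#' columns `frame`, `time_ns`, `atom` (id within frame), `role` (one of
#' `"N"`, `"CA"`, `"C"`, `"O_carboxyl"`, `"ion"`), `residue` (owning residue,
#' `NA` for ions), `species` (ion species, `NA` otherwise), `x`, `y`, `z`
#' (nm) and `mass` (amu; 1 for unit-mass bead models). An optional
#' orthorhombic box (nm, length-3 vector) enables minimum-image distances.
#'
#' @param x Data frame with the columns above (`mass` optional, default 1).
#' @param box Optional numeric length-3 vector of box edges in nm.
#' @return A `coordinate_trajectory` tibble with attribute `box`.
#' @export
coordinate_trajectory <- function(x, box = NULL) {
  required <- c("frame", "time_ns", "atom", "role", "residue", "species",
                "x", "y", "z")
  if (!"mass" %in% names(x)) x$mass <- 1
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("coordinate table missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)[c(required, "mass")]
  if (!is.null(box)) {
    if (length(box) != 3 || any(box <= 0)) {
      rlang::abort("box must be three strictly positive edge lengths (nm)")
    }
  }
  bad_role <- setdiff(unique(x$role), c("N", "CA", "C", "O_carboxyl", "ion"))
  if (length(bad_role) > 0) {
    rlang::abort(paste0("unknown atom roles: ", paste(bad_role, collapse = ", ")))
  }
  if (any(x$role == "O_carboxyl" & is.na(x$residue))) {
    rlang::abort("every carboxylate oxygen must map to exactly one residue")
  }
  x <- dplyr::arrange(x, .data$frame, .data$atom)
  structure(
    x,
    box = box,
    class = c("coordinate_trajectory", class(tibble::tibble()))
  )
}

#' Read coordinates from a PDB topology (and optional multi-model trajectory)
#'
#' Reads a PDB file with `bio3d` and maps atoms onto the roles the analyses
#' need: backbone `N`/`CA`/`C`, side-chain carboxylate oxygens, and free
#' counterions. Multi-model PDB files are read as trajectories, one frame
#' per MODEL. Coordinates are converted from Angstrom to nm.
#'
#' @param topology Path to a PDB file (single- or multi-model).
#' @param selection Named list mapping roles to PDB atom names:
#'   `backbone` (default `c("N", "CA", "C")`), `carboxylate` (default
#'   `c("OD1", "OD2", "OE1", "OE2")`) and `ions` (default
#'   `c("NA", "K", "NA+", "K+", "SOD", "POT")`). Matching is by atom name;
#'   ions are also matched by residue name.
#' @param dt_ns Frame spacing in ns used to build the time axis (PDB carries
#'   no time information). Default 1.
#' @return A [coordinate_trajectory()] tibble. If the PDB has a CRYST1
#'   record with positive edges, it is stored as the box.
#' @export
read_coordinate_trajectory <- function(topology,
                                       selection = list(),
                                       dt_ns = 1) {
  sel <- utils::modifyList(list(
    backbone = c("N", "CA", "C"),
    carboxylate = c("OD1", "OD2", "OE1", "OE2"),
    ions = c("NA", "K", "NA+", "K+", "SOD", "POT")
  ), selection)

  pdb <- bio3d::read.pdb(topology, multi = TRUE)
  at <- pdb$atom
  nm <- trimws(at$elety)
  resnm <- trimws(at$resid)

  role <- rep(NA_character_, nrow(at))
  role[nm %in% sel$backbone] <- nm[nm %in% sel$backbone]
  role[nm %in% sel$carboxylate] <- "O_carboxyl"
  is_ion <- nm %in% sel$ions | resnm %in% sel$ions
  role[is_ion] <- "ion"

  keep <- !is.na(role)
  if (!any(keep)) {
    rlang::abort("selection matched no atoms of any analysis role")
  }

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  idx <- which(keep)

  frames <- purrr::map_dfr(seq_len(n_frames), function(f) {
    tibble::tibble(
      frame = f,
      time_ns = (f - 1) * dt_ns,
      atom = idx,
      role = role[idx],
      residue = ifelse(role[idx] == "ion", NA_integer_, at$resno[idx]),
      species = ifelse(role[idx] == "ion",
                       ifelse(resnm[idx] %in% sel$ions, resnm[idx], nm[idx]),
                       NA_character_),
      x = xyz[f, 3 * idx - 2] / 10,
      y = xyz[f, 3 * idx - 1] / 10,
      z = xyz[f, 3 * idx] / 10,
      mass = 1
    )
  })

  box <- NULL
  cr <- pdb$cryst1
  if (!is.null(cr) && !is.null(cr$abc) && all(is.finite(cr$abc)) &&
      all(cr$abc > 0)) {
    if (!is.null(cr$abg) && any(abs(cr$abg - 90) > 1e-6)) {
      rlang::abort("only orthorhombic boxes are supported")
    }
    box <- cr$abc / 10
  }
  coordinate_trajectory(frames, box = box)
}

#' Write a coordinate trajectory as a (multi-model) PDB file
#'
#' One MODEL block per frame; coordinates converted to Angstrom. Backbone
#' atoms are written with their role as the atom name, carboxylate oxygens
#' as OD1/OD2, ions as their species. Intended for small synthetic fixtures.
#'
#' @param coords A [coordinate_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coordinate_pdb <- function(coords, path) {
  con <- file(path, "w")
  on.exit(close(con))
  box <- attr(coords, "box")
  if (!is.null(box)) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      box[1] * 10, box[2] * 10, box[3] * 10, 90, 90, 90
    ), con)
  }
  split_frames <- split(coords, coords$frame)
  for (f in seq_along(split_frames)) {
    fr <- split_frames[[f]]
    writeLines(sprintf("MODEL     %4d", f), con)
    ox_counter <- 0
    for (i in seq_len(nrow(fr))) {
      role <- fr$role[i]
      if (role == "O_carboxyl") {
        ox_counter <- ox_counter + 1
        name <- if (ox_counter %% 2 == 1) "OD1" else "OD2"
        resname <- "ASP"
        resno <- fr$residue[i]
      } else if (role == "ion") {
        # CHARMM-style names; a literal "NA" atom name would be read back
        # as a missing value by most PDB parsers
        name <- switch(fr$species[i], "NA" = "SOD", "K" = "POT",
                       fr$species[i])
        resname <- name
        resno <- 9000 + i
      } else {
        name <- role
        resname <- "ASP"
        resno <- fr$residue[i]
      }
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        i %% 100000, substr(name, 1, 4), substr(resname, 1, 3),
        resno %% 10000,
        fr$x[i] * 10, fr$y[i] * 10, fr$z[i] * 10, 1.0, 0.0
      ), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Backbone dihedral angles from a coordinate trajectory
#'
#' Computes phi(i) from C(i-1)-N(i)-CA(i)-C(i) and psi(i) from
#' N(i)-CA(i)-C(i)-N(i+1) for every residue and frame, using the IUPAC sign
#' convention (clockwise rotation of the far bond viewed along the central
#' bond is negative). Terminal residues lacking a neighbour get `NA` for the
#' undefined angle.
#'
#' @param coords A [coordinate_trajectory()] with complete backbone
#'   N, CA, C for every residue.
#' @return A [dihedral_trajectory()].
#' @export
compute_backbone_dihedrals <- function(coords) {
  bb <- dplyr::filter(coords, .data$role %in% c("N", "CA", "C"))
  residues <- sort(unique(bb$residue))
  frames <- sort(unique(bb$frame))
  times <- vapply(frames, function(f) bb$time_ns[bb$frame == f][1], numeric(1))

  per_frame <- purrr::map_dfr(seq_along(frames), function(fi) {
    fr <- bb[bb$frame == frames[fi], ]
    pos <- function(res, role) {
      row <- fr[fr$residue == res & fr$role == role, ]
      if (nrow(row) != 1) {
        rlang::abort(sprintf("missing backbone atom %s for residue %d", role, res))
      }
      c(row$x, row$y, row$z)
    }
    phi <- psi <- rep(NA_real_, length(residues))
    for (ri in seq_along(residues)) {
      r <- residues[ri]
      if (ri > 1) {
        phi[ri] <- torsion_angle(pos(residues[ri - 1], "C"), pos(r, "N"),
                                 pos(r, "CA"), pos(r, "C"))
      }
      if (ri < length(residues)) {
        psi[ri] <- torsion_angle(pos(r, "N"), pos(r, "CA"), pos(r, "C"),
                                 pos(residues[ri + 1], "N"))
      }
    }
    tibble::tibble(time_ns = times[fi], residue = residues,
                   phi_deg = phi, psi_deg = psi)
  })
  dihedral_trajectory(per_frame)
}
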