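#' Ramachandran region sets
#'
#' A region set partitions the (phi, psi) torus into named conformational
#' states. It is a tibble with one row per angular box: `label`, `phi_lo`,
#' `phi_hi`, `psi_lo`, `psi_hi` (degrees), four boundary-closure flags
#' (`phi_lo_closed`, `phi_hi_closed`, `psi_lo_closed`, `psi_hi_closed`),
#' an optional integration-area index `area`, and an `approximate` flag for
#' bounds that are documented reconstructions rather than published values.
#' A state may own several boxes. Everything outside every box is labelled
#' `"other"`. Overlap validation runs on construction over a 1-degree grid.
#'
#' @param boxes Data frame with the columns above (closure flags default to
#'   lower-closed / upper-open, `area` to `NA`, `approximate` to `FALSE`).
#' @param name Name of the set (stored as attribute).
#' @param validate Check the partition property on a 1-degree torus grid.
#' @return A `region_set` tibble.
#' @export
region_set <- function(boxes, name = "custom", validate = TRUE) {
  boxes <- tibble::as_tibble(boxes)
  defaults <- list(phi_lo_closed = TRUE, phi_hi_closed = FALSE,
                   psi_lo_closed = TRUE, psi_hi_closed = FALSE,
                   area = NA_integer_, approximate = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(boxes)) boxes[[nm]] <- defaults[[nm]]
  }
  required <- c("label", "phi_lo", "phi_hi", "psi_lo", "psi_hi")
  missing_cols <- setdiff(required, names(boxes))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("region boxes missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (any(boxes$label == "other")) {
    rlang::abort("'other' is the implicit complement and cannot own a box")
  }
  out <- structure(boxes, name = name,
                   class = c("region_set", class(tibble::tibble())))
  if (validate) validate_region_set(out)
  out
}

#' Validate the partition property of a region set
#'
#' Every point of a 1-degree grid over the full torus (129,600 points) must
#' receive exactly one label, counting the implicit `"other"` complement.
#'
#' @param regions A [region_set()].
#' @return Invisibly `TRUE`; errors if any grid point falls in two boxes.
#' @export
validate_region_set <- function(regions) {
  grid <- tidyr::expand_grid(
    phi = seq(-179, 180, by = 1),
    psi = seq(-179, 180, by = 1)
  )
  counts <- rep(0L, nrow(grid))
  for (i in seq_len(nrow(regions))) {
    counts <- counts + as.integer(box_member(
      grid$phi, grid$psi, regions[i, , drop = FALSE]
    ))
  }
  if (any(counts > 1L)) {
    bad <- which(counts > 1L)[1]
    rlang::abort(sprintf(
      "region boxes overlap at (phi = %d, psi = %d)",
      grid$phi[bad], grid$psi[bad]
    ))
  }
  invisible(TRUE)
}

# Membership of wrapped angles in one box row, honouring boundary closure
# and the torus (values are also tested shifted by +-360 so that boxes
# touching -180/180 behave periodically).
box_member <- function(phi, psi, box) {
  in_iv <- function(v, lo, hi, lo_closed, hi_closed) {
    hit <- rep(FALSE, length(v))
    for (shift in c(-360, 0, 360)) {
      w <- v + shift
      lo_ok <- if (lo_closed) w >= lo else w > lo
      hi_ok <- if (hi_closed) w <= hi else w < hi
      hit <- hit | (lo_ok & hi_ok)
    }
    hit
  }
  phi <- wrap_angle(phi)
  psi <- wrap_angle(psi)
  in_iv(phi, box$phi_lo, box$phi_hi, box$phi_lo_closed, box$phi_hi_closed) &
    in_iv(psi, box$psi_lo, box$psi_hi, box$psi_lo_closed, box$psi_hi_closed)
}

#' Built-in Ramachandran region sets
#'
#' `"standard_literature"` encodes the published basin bounds for anionic
#' polypeptide residues: alphaR (phi in \[-90, -30\], psi in \[-90, 0\]),
#' alphaL (phi in \[30, 90\], psi in \[0, 90\]), beta (phi in \[-180, -104),
#' psi in \[104, 180\]) and PPII (phi in \[-104, -46\], psi in \[116, 174\]).
#' All printed bounds are closed except the beta phi upper bound.
#'
#' The three integration variants (`"charmm_integration"`,
#' `"amber99_integration"`, `"opls_integration"`) reproduce the usual
#' integration-area topology of force-field Ramachandran maps (areas 0-4):
#' area 0 is the alphaR box, area 1 the surrounding screw region (labelled
#' `three10` for the CHARMM variant, where the 3-10 basin separates from
#' alphaR, and `add_screw` for the AMBER/OPLS variants where a broader
#' "additional screw" population appears instead), area 2 PPII, area 3 beta,
#' and area 4 the whole positive-phi half (mostly left-handed helix).
#' Area-1 bounds are documented approximations (`approximate = TRUE`):
#' the complement of the alphaR box inside the enclosing screw box
#' phi in \[-160, -30\], psi in \[-90, 50\].
#'
#' @param name One of `"standard_literature"`, `"charmm_integration"`,
#'   `"amber99_integration"`, `"opls_integration"`.
#' @param include_intermediate Also include the sparsely populated zeta and
#'   gamma-prime basins (point-centred boxes near (-135, 60) and (-80, 80),
#'   clipped so the partition stays overlap-free). Default `FALSE`.
#' @return A validated [region_set()].
#' @export
builtin_region_set <- function(name = c("standard_literature",
                                        "charmm_integration",
                                        "amber99_integration",
                                        "opls_integration"),
                               include_intermediate = FALSE) {
  name <- match.arg(name)

  closed_box <- function(label, phi, psi, area = NA_integer_,
                         approximate = FALSE) {
    tibble::tibble(
      label = label, phi_lo = phi[1], phi_hi = phi[2],
      psi_lo = psi[1], psi_hi = psi[2],
      phi_lo_closed = TRUE, phi_hi_closed = TRUE,
      psi_lo_closed = TRUE, psi_hi_closed = TRUE,
      area = area, approximate = approximate
    )
  }

  alphaR <- closed_box("alphaR", c(-90, -30), c(-90, 0), area = 0L)
  alphaL <- closed_box("alphaL", c(30, 90), c(0, 90), area = 4L)
  ppii <- closed_box("PPII", c(-104, -46), c(116, 174), area = 2L)
  beta <- closed_box("beta", c(-180, -104), c(104, 180), area = 3L)
  beta$phi_hi_closed <- FALSE # printed bound: -180 <= phi < -104

  # area 1: enclosing screw box [-160,-30] x [-90,50] minus the alphaR box,
  # decomposed into two boxes that tile it without touching alphaR
  screw_boxes <- function(label) {
    a <- closed_box(label, c(-160, -90), c(-90, 50), area = 1L,
                    approximate = TRUE)
    a$phi_hi_closed <- FALSE
    b <- closed_box(label, c(-90, -30), c(0, 50), area = 1L,
                    approximate = TRUE)
    b$psi_lo_closed <- FALSE
    dplyr::bind_rows(a, b)
  }

  # area 4: the positive-phi half, open at both phi ends so that the seam
  # point phi = 180 (identical to -180) stays with the printed beta box
  positive_phi_box <- function() {
    pos <- closed_box("alphaL", c(0, 180), c(-180, 180), area = 4L)
    pos$phi_lo_closed <- FALSE
    pos$phi_hi_closed <- FALSE
    pos$psi_lo_closed <- FALSE
    pos
  }

  intermediates <- {
    z <- closed_box("zeta", c(-165, -105), c(30, 90), approximate = TRUE)
    z$phi_hi_closed <- FALSE
    z$psi_hi_closed <- FALSE
    g <- closed_box("gamma_prime", c(-105, -50), c(50, 104),
                    approximate = TRUE)
    g$phi_hi_closed <- FALSE
    g$psi_hi_closed <- FALSE
    dplyr::bind_rows(z, g)
  }

  boxes <- switch(
    name,
    standard_literature = dplyr::bind_rows(alphaR, alphaL, beta, ppii),
    charmm_integration = dplyr::bind_rows(
      alphaR, screw_boxes("three10"), ppii, beta, positive_phi_box()
    ),
    amber99_integration = ,
    opls_integration = dplyr::bind_rows(
      alphaR, screw_boxes("add_screw"), ppii, beta, positive_phi_box()
    )
  )
  if (include_intermediate && name == "standard_literature") {
    boxes <- dplyr::bind_rows(boxes, intermediates)
  }
  region_set(boxes, name = name)
}

#' State labels of a region set, including the implicit complement
#'
#' @param regions A [region_set()].
#' @return Character vector of labels, ending in `"other"`.
#' @export
region_labels <- function(regions) {
  c(unique(regions$label), "other")
}

#' Write / read a region set as YAML
#'
#' Serialized as a list of boxes with `label`, `phi: [lo, hi]`,
#' `psi: [lo, hi]`, `closed_phi: [lo, hi]`, `closed_psi: [lo, hi]`,
#' and optional `area`.
#'
#' @param regions A [region_set()].
#' @param path File path.
#' @return `read_region_set()` returns a validated [region_set()];
#'   `write_region_set()` returns `path` invisibly.
#' @export
write_region_set <- function(regions, path) {
  entries <- purrr::pmap(regions, function(label, phi_lo, phi_hi, psi_lo,
                                           psi_hi, phi_lo_closed,
                                           phi_hi_closed, psi_lo_closed,
                                           psi_hi_closed, area, approximate) {
    list(label = label, phi = c(phi_lo, phi_hi), psi = c(psi_lo, psi_hi),
         closed_phi = c(phi_lo_closed, phi_hi_closed),
         closed_psi = c(psi_lo_closed, psi_hi_closed),
         area = if (is.na(area)) NULL else area,
         approximate = approximate)
  })
  yaml::write_yaml(list(name = attr(regions, "name"), regions = entries), path)
  invisible(path)
}

#' @rdname write_region_set
#' @export
read_region_set <- function(path) {
  spec <- yaml::read_yaml(path)
  boxes <- purrr::map_dfr(spec$regions, function(e) {
    tibble::tibble(
      label = e$label,
      phi_lo = e$phi[1], phi_hi = e$phi[2],
      psi_lo = e$psi[1], psi_hi = e$psi[2],
      phi_lo_closed = e$closed_phi[1], phi_hi_closed = e$closed_phi[2],
      psi_lo_closed = e$closed_psi[1], psi_hi_closed = e$closed_psi[2],
      area = if (is.null(e$area)) NA_integer_ else as.integer(e$area),
      approximate = isTRUE(e$approximate)
    )
  })
  region_set(boxes, name = spec$name %||% "custom")
}
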