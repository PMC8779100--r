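#' Analysis configuration
#'
#' Bundles every tunable the pipeline uses, with validation. Defaults follow
#' the conventions of long polypeptide trajectory analyses: discard the
#' first tenth of the frames as equilibration, analyse chain-length minus 2
#' monomers, count helical sequences from 4 contiguous residues, estimate
#' errors from 5 contiguous blocks.
#'
#' @param equilibration_fraction Fraction of frames discarded, `[0, 1)`.
#' @param region_set Name of a built-in region set (see
#'   [builtin_region_set()]) or a [region_set()] object.
#' @param min_run_length Minimum run length for sequence fractions (>= 2).
#' @param n_blocks Blocks for SD errors (>= 2).
#' @param bridge A [bridge_spec()].
#' @param acf_floor Noise-floor level ending the default fit window.
#' @param seed Random seed recorded in reports.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(equilibration_fraction = 0.1,
                            region_set = "standard_literature",
                            min_run_length = 4,
                            n_blocks = 5,
                            bridge = bridge_spec(),
                            acf_floor = 0.02,
                            seed = 1) {
  if (equilibration_fraction < 0 || equilibration_fraction >= 1) {
    rlang::abort("equilibration_fraction must be in [0, 1)")
  }
  if (min_run_length < 2) rlang::abort("min_run_length must be at least 2")
  if (n_blocks < 2) rlang::abort("n_blocks must be at least 2")
  regions <- if (inherits(region_set, "region_set")) region_set else {
    builtin_region_set(region_set)
  }
  structure(list(
    equilibration_fraction = equilibration_fraction,
    regions = regions,
    min_run_length = min_run_length,
    n_blocks = n_blocks,
    bridge = bridge,
    acf_floor = acf_floor,
    seed = seed
  ), class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Recognised keys: `equilibration_fraction`, `region_set` (built-in name),
#' `min_run_length`, `n_blocks`, `seed`, `acf_floor`, and a `bridge` block
#' with `cutoffs` (named map, nm), `min_residue_separation`,
#' `default_cutoff`.
#'
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  bridge <- if (is.null(y$bridge)) bridge_spec() else bridge_spec(
    cutoffs = unlist(y$bridge$cutoffs %||% list("NA" = 0.32, "K" = 0.36)),
    min_residue_separation = y$bridge$min_residue_separation %||% 3,
    default_cutoff = y$bridge$default_cutoff %||% 0.32
  )
  analysis_config(
    equilibration_fraction = y$equilibration_fraction %||% 0.1,
    region_set = y$region_set %||% "standard_literature",
    min_run_length = y$min_run_length %||% 4,
    n_blocks = y$n_blocks %||% 5,
    bridge = bridge,
    acf_floor = y$acf_floor %||% 0.02,
    seed = y$seed %||% 1
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates equilibration discard, state classification, population
#' fractions, sequence statistics, chain geometry and bridge analysis (when
#' coordinates are given), relaxation dynamics, and the comparison against
#' the experimental reference. Deterministic for fixed config: re-running
#' with the same inputs yields an identical report.
#'
#' @param dihedrals A [dihedral_trajectory()] (or path to a dihedral table).
#' @param config An [analysis_config()].
#' @param coords Optional [coordinate_trajectory()] for geometry, bridges
#'   and end-to-end relaxation.
#' @param molecule Optional reference molecule tag for the experimental
#'   comparison (e.g. `"PGA"`).
#' @param sequence_target State whose equiconformational sequences are
#'   analysed (default `"alphaR"`; the same machinery serves `"beta"`).
#' @param out_dir Optional directory: when given, writes `report.json`,
#'   `fractions.tsv`, `run_lengths.tsv`, and (with coordinates)
#'   `chain_metrics.tsv` and ACF TSVs there.
#' @return A list of class `ramadyn_report` with elements `fractions`,
#'   `sequence` (target, fraction, histogram), `timeline`, optional
#'   `geometry`, `bridges`, `relaxation`, optional `reference_comparison`,
#'   and `config_fingerprint`.
#' @export
run_pipeline <- function(dihedrals, config = analysis_config(), coords = NULL,
                         molecule = NULL, sequence_target = "alphaR",
                         out_dir = NULL) {
  if (is.character(dihedrals)) dihedrals <- read_dihedral_table(dihedrals)

  traj <- discard_equilibration(dihedrals, config$equilibration_fraction)
  if (!is.null(coords)) {
    coords <- discard_equilibration(coords, config$equilibration_fraction)
  }

  states <- classify_trajectory(traj, config$regions, exclude_termini = TRUE)
  fractions <- state_fractions(states, n_blocks = config$n_blocks)

  record <- run_lengths(states, sequence_target)
  seq_frac <- sequence_fraction(record, min_len = config$min_run_length)
  hist <- length_histogram(record)
  timeline <- conformation_timeline(states)

  report <- list(
    fractions = fractions,
    sequence = list(target = sequence_target, min_run_length =
                      config$min_run_length, fraction = seq_frac,
                    histogram = hist),
    timeline = timeline,
    config_fingerprint = config_fingerprint(config)
  )

  if (!is.null(coords)) {
    rg <- radius_of_gyration(coords)
    ree <- end_to_end_distance(coords)
    report$geometry <- dplyr::left_join(rg, ree, by = c("frame", "time_ns"))
    if (any(coords$role == "ion")) {
      report$bridges <- bridge_fraction(coords, config$bridge,
                                        n_blocks = config$n_blocks)
    }
    if (nrow(ree) >= 20 && stats::sd(ree$ree_nm) > 0) {
      acf_d <- distance_autocorrelation(ree)
      report$relaxation <- list(
        distance_acf = acf_d,
        distance_fit = tryCatch(
          fit_stretched_exponential(acf_d, floor_level = config$acf_floor),
          error = function(e) NULL
        )
      )
    }
  }

  n_frames <- length(unique(traj$time_ns))
  if (n_frames >= 20) {
    acf_psi <- dihedral_autocorrelation(traj, "psi")
    report$relaxation <- c(report$relaxation, list(
      psi_acf = acf_psi,
      psi_fit = tryCatch(
        fit_stretched_exponential(acf_psi, floor_level = config$acf_floor,
                                  baseline = "tail"),
        error = function(e) NULL
      )
    ))
  }

  if (!is.null(molecule)) {
    report$reference_comparison <- compare_to_reference(fractions, molecule)
  }

  class(report) <- "ramadyn_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

config_fingerprint <- function(config) {
  key <- list(
    equilibration_fraction = config$equilibration_fraction,
    region_set = attr(config$regions, "name"),
    min_run_length = config$min_run_length,
    n_blocks = config$n_blocks,
    bridge = unclass(config$bridge),
    acf_floor = config$acf_floor,
    seed = config$seed
  )
  json <- jsonlite::toJSON(key, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(json)) *
                        seq_along(utf8ToInt(as.character(json)))) %% 2^31)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` plus TSV artifacts (`fractions.tsv`,
#' `run_lengths.tsv`, `timeline.tsv`, `chain_metrics.tsv`, ACF series)
#' under `out_dir`. The JSON carries no timestamps, so identical inputs
#' yield byte-identical reports.
#'
#' @param report A `ramadyn_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fraction_table(report$fractions, file.path(out_dir, "fractions.tsv"))
  write_length_histogram(report$sequence$histogram,
                         file.path(out_dir, "run_lengths.tsv"))
  write_timeline(report$timeline, file.path(out_dir, "timeline.tsv"))

  json <- list(
    config_fingerprint = report$config_fingerprint,
    fractions = stats::setNames(as.list(report$fractions$fraction),
                                report$fractions$state),
    fraction_sd = stats::setNames(as.list(report$fractions$sd),
                                  report$fractions$state),
    sequence = list(target = report$sequence$target,
                    min_run_length = report$sequence$min_run_length,
                    fraction = report$sequence$fraction)
  )
  if (!is.null(report$geometry)) {
    utils::write.table(as.data.frame(report$geometry),
                       file.path(out_dir, "chain_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    json$geometry <- list(rg_mean_nm = mean(report$geometry$rg_nm),
                          ree_mean_nm = mean(report$geometry$ree_nm))
  }
  if (!is.null(report$bridges)) {
    json$bridge_fraction <- report$bridges$fraction
    json$bridge_fraction_sd <- report$bridges$sd
  }
  if (!is.null(report$relaxation)) {
    for (nm in c("distance_fit", "psi_fit")) {
      f <- report$relaxation[[nm]]
      if (!is.null(f)) {
        json[[nm]] <- list(A = f$A, tau_ns = f$tau_ns, beta = f$beta,
                           tau_mean_ns = f$tau_mean_ns)
      }
    }
    for (nm in c("distance_acf", "psi_acf")) {
      a <- report$relaxation[[nm]]
      if (!is.null(a)) write_acf(a, file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  if (!is.null(report$reference_comparison)) {
    json$reference_comparison <- report$reference_comparison
  }
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' @export
print.ramadyn_report <- function(x, ...) {
  cat("<ramadyn_report>\n")
  cat("  state fractions:\n")
  for (i in seq_len(nrow(x$fractions))) {
    cat(sprintf("    %-12s %.4f (sd %.4f)\n", x$fractions$state[i],
                x$fractions$fraction[i], x$fractions$sd[i]))
  }
  cat(sprintf("  %s sequences (runs >= %d): fraction %.4f\n",
              x$sequence$target, x$sequence$min_run_length,
              x$sequence$fraction))
  if (!is.null(x$bridges)) {
    cat(sprintf("  bridged carboxyl fraction: %.4f (sd %.4f)\n",
                x$bridges$fraction, x$bridges$sd))
  }
  invisible(x)
}
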