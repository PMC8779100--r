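test_that("the packaged reference table holds the published values", {
  ref <- load_reference()
  val <- function(mol, prot, conf, src = NULL) {
    rows <- ref[ref$molecule == mol & ref$protonation == prot &
                  ref$conformation == conf, ]
    if (!is.null(src)) rows <- rows[rows$source == src, ]
    rows
  }
  expect_equal(val("PGA", "I", "PPII")$value, 0.40)
  expect_equal(val("di-GA", "I", "beta")$value, 0.48)
  expect_equal(val("PGA", "I", "three10")$value, 0.09)
  expect_equal(val("PGA", "I", "alpha_beta")$value, 0.51)

  bound <- val("PGA", "I", "alpha", src = "pga_uv_raman")
  expect_equal(bound$value, 0.20)
  expect_equal(bound$comparison, "lt")
  approx <- val("PGA", "I", "alpha", src = "pga_cd")
  expect_equal(approx$value, 0.01)
  expect_equal(approx$comparison, "approx")

  expect_true(all(ref$value >= 0 & ref$value <= 1))

  # round-trips through serialization without loss
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(ref), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$value, ref$value)
  expect_equal(back$conformation, ref$conformation)
})

test_that("reference comparison computes deviations and bounds", {
  ft <- ramadyn:::new_fraction_table(tibble::tibble(
    state = c("alphaR", "beta", "PPII", "three10", "other"),
    fraction = c(0.05, 0.46, 0.40, 0.05, 0.04),
    sd = c(0.01, 0.02, 0.02, 0.01, 0.01)
  ))
  cmp <- compare_to_reference(ft, "PGA")
  ppii <- cmp[cmp$conformation == "PPII", ]
  expect_equal(ppii$deviation, 0)

  ab <- cmp[cmp$conformation == "alpha_beta", ]
  expect_equal(ab$computed, 0.51)
  expect_equal(ab$deviation, 0)

  bound <- cmp[cmp$conformation == "alpha" & cmp$comparison == "lt", ]
  expect_true(bound$within_bound)

  ft_high <- ramadyn:::new_fraction_table(tibble::tibble(
    state = c("alphaR", "beta", "PPII", "three10", "other"),
    fraction = c(0.25, 0.3, 0.3, 0.05, 0.10), sd = 0.01
  ))
  cmp2 <- compare_to_reference(ft_high, "PGA")
  expect_false(cmp2$within_bound[cmp2$conformation == "alpha" &
                                   cmp2$comparison == "lt"])

  expect_error(compare_to_reference(ft, "XX"), "no reference rows")
})

test_that("timelines aggregate pixels by modal state", {
  st <- state_trajectory(matrix("beta", nrow = 12, ncol = 4),
                         labels = c("beta", "other"), dt = 0.1)
  tl <- conformation_timeline(st, pixel_dt = 0.3)
  expect_true(all(tl$state == "beta"))
  expect_equal(max(tl$pixel), 4) # ceil(1.2 ns / 0.3 ns)

  m <- matrix(c("beta", "beta", "PPII"), nrow = 3, ncol = 1)
  st2 <- state_trajectory(m, labels = c("beta", "PPII", "other"), dt = 1)
  tl2 <- conformation_timeline(st2, pixel_dt = 3)
  expect_equal(tl2$state, "beta") # mode of the window

  # tie inside the window resolves to the first frame's state
  m3 <- matrix(c("PPII", "beta"), nrow = 2, ncol = 1)
  st3 <- state_trajectory(m3, labels = c("beta", "PPII", "other"), dt = 1)
  expect_equal(conformation_timeline(st3, pixel_dt = 2)$state, "PPII")

  expect_error(conformation_timeline(st, pixel_dt = 0.01),
               "at least the frame spacing")
})

test_that("the pipeline runs end to end and is deterministic", {
  def <- data.frame(label = c("alphaR", "PPII", "beta"),
                    pi = c(0.35, 0.35, 0.3), lifetime_ns = c(1, 1.5, 1))
  st <- markov_state_trajectory(300, def, n_residues = 30, dt = 0.1,
                                seed = 21)
  traj <- emit_dihedrals(st, std_regions(), jitter = 12, seed = 22)
  gm <- data.frame(state = def$label, bond_nm = c(0.15, 0.31, 0.33),
                   bend_deg = c(60, 15, 5))
  coords <- synthetic_chain(st, gm, seed = 23)

  cfg <- analysis_config(equilibration_fraction = 0.1, n_blocks = 5,
                         seed = 21)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  rep1 <- run_pipeline(traj, cfg, coords = coords, molecule = "PGA",
                       out_dir = out1)
  rep2 <- run_pipeline(traj, cfg, coords = coords, molecule = "PGA",
                       out_dir = out2)

  expect_s3_class(rep1$fractions, "fraction_table")
  expect_equal(sum(rep1$fractions$fraction), 1, tolerance = 1e-9)
  expect_true(rep1$sequence$fraction >= 0 && rep1$sequence$fraction <= 1)
  expect_true(all(c("rg_nm", "ree_nm") %in% names(rep1$geometry)))
  expect_false(is.null(rep1$reference_comparison))

  for (f in c("report.json", "fractions.tsv", "run_lengths.tsv",
              "timeline.tsv", "chain_metrics.tsv")) {
    expect_true(file.exists(file.path(out1, f)))
  }
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))
})

test_that("configuration validates before any computation", {
  expect_error(analysis_config(equilibration_fraction = 1), "\\[0, 1\\)")
  expect_error(analysis_config(min_run_length = 1), "at least 2")
  expect_error(analysis_config(n_blocks = 1), "at least 2")
  expect_error(analysis_config(region_set = "nope"))

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "equilibration_fraction: 0.2",
    "region_set: charmm_integration",
    "min_run_length: 5",
    "n_blocks: 4",
    "seed: 42",
    "bridge:",
    "  min_residue_separation: 4"
  ), path)
  cfg <- read_analysis_config(path)
  expect_equal(cfg$equilibration_fraction, 0.2)
  expect_equal(attr(cfg$regions, "name"), "charmm_integration")
  expect_equal(cfg$min_run_length, 5)
  expect_equal(cfg$bridge$min_residue_separation, 4)
  expect_equal(cfg$seed, 42)
})

test_that("plot constructors return ggplot objects", {
  def <- data.frame(label = c("alphaR", "beta"), pi = c(0.5, 0.5),
                    lifetime_ns = c(1, 1))
  st <- markov_state_trajectory(50, def, n_residues = 5, seed = 2)
  traj <- emit_dihedrals(st, std_regions(), jitter = 10, seed = 2)
  dens <- ramachandran_density(traj, 10)
  expect_s3_class(plot_ramachandran(dens, std_regions()), "ggplot")
  expect_s3_class(plot_timeline(conformation_timeline(st)), "ggplot")
  a <- synthetic_acf(1, 5, 1, n_lags = 50, seed = 1)
  expect_s3_class(autoplot(a, fit = fit_stretched_exponential(a)), "ggplot")
  expect_s3_class(autoplot(state_fractions(st, 5)), "ggplot")
})
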