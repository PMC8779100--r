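test_that("every shipped region set partitions the 1-degree torus grid", {
  for (nm in c("standard_literature", "charmm_integration",
               "amber99_integration", "opls_integration")) {
    expect_true(validate_region_set(builtin_region_set(nm)))
  }
  expect_true(validate_region_set(
    builtin_region_set("standard_literature", include_intermediate = TRUE)
  ))
})

test_that("standard region bounds match the published basin definitions", {
  rs <- std_regions()
  aR <- rs[rs$label == "alphaR", ]
  expect_equal(c(aR$phi_lo, aR$phi_hi, aR$psi_lo, aR$psi_hi),
               c(-90, -30, -90, 0))
  ppii <- rs[rs$label == "PPII", ]
  expect_equal(c(ppii$phi_lo, ppii$phi_hi, ppii$psi_lo, ppii$psi_hi),
               c(-104, -46, 116, 174))
  aL <- rs[rs$label == "alphaL", ]
  expect_equal(c(aL$phi_lo, aL$phi_hi, aL$psi_lo, aL$psi_hi),
               c(30, 90, 0, 90))
  beta <- rs[rs$label == "beta", ]
  expect_equal(c(beta$phi_lo, beta$phi_hi, beta$psi_lo, beta$psi_hi),
               c(-180, -104, 104, 180))
  expect_false(beta$phi_hi_closed) # printed as phi < -104
})

test_that("classification hits the expected basins and respects wrapping", {
  rs <- std_regions()
  expect_equal(classify_state(-60, -45, rs), "alphaR")
  expect_equal(classify_state(60, 45, rs), "alphaL")
  expect_equal(classify_state(0, 0, rs), "other")
  expect_equal(classify_state(-150, 150, rs), "beta")
  expect_equal(classify_state(-75, 145, rs), "PPII")
  expect_equal(classify_state(300, 45, rs), classify_state(-60, 45, rs))

  set.seed(3)
  phi <- runif(200, -180, 180)
  psi <- runif(200, -180, 180)
  k <- sample(-2:2, 200, replace = TRUE)
  m <- sample(-2:2, 200, replace = TRUE)
  expect_equal(classify_state(phi + 360 * k, psi + 360 * m, rs),
               classify_state(phi, psi, rs))

  # the periodic seam: +180 is the same point as -180
  expect_equal(classify_state(180, 150, rs), "beta")
})

test_that("overlapping user region sets are rejected", {
  boxes <- data.frame(
    label = c("a", "b"),
    phi_lo = c(-90, -60), phi_hi = c(-30, 0),
    psi_lo = c(-90, -60), psi_hi = c(0, 30),
    phi_lo_closed = TRUE, phi_hi_closed = TRUE,
    psi_lo_closed = TRUE, psi_hi_closed = TRUE
  )
  expect_error(region_set(boxes), "overlap")
})

test_that("region sets round-trip through YAML", {
  rs <- builtin_region_set("charmm_integration")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_region_set(rs, path)
  back <- read_region_set(path)
  expect_equal(as.data.frame(back)[order(back$label, back$phi_lo), ],
               as.data.frame(rs)[order(rs$label, rs$phi_lo), ],
               ignore_attr = TRUE)
  expect_equal(attr(back, "name"), "charmm_integration")
})

test_that("classify_trajectory drops termini and labels per residue-frame", {
  grid <- expand.grid(time_ns = 0:4, residue = 1:32)
  grid$phi_deg <- -60
  grid$psi_deg <- -45
  grid$phi_deg[grid$residue == 1] <- NA
  grid$psi_deg[grid$residue == 32] <- NA
  traj <- dihedral_trajectory(grid)
  st <- classify_trajectory(traj, std_regions())
  expect_equal(attr(st, "n_monomers"), 30)
  expect_equal(length(unique(st$residue)), 30)
  expect_true(all(st$state == "alphaR"))

  empty <- traj[traj$time_ns < 0, ]
  expect_error(classify_trajectory(empty, std_regions()), "no frames")
})

test_that("ramachandran density is a normalized torus histogram", {
  one <- dihedral_trajectory(data.frame(
    time_ns = 0, residue = 1:3,
    phi_deg = c(NA, -60, 10), psi_deg = c(100, -45, NA)
  ))
  # only residue 2 has both angles defined after the termini pattern
  d <- ramachandran_density(one, bin_width = 10)
  expect_equal(sum(d$weight), 1, tolerance = 1e-9)
  expect_equal(sum(d$weight > 0), 1)
  hit <- d[d$weight > 0, ]
  # -60 lies on a bin edge and belongs to the upper bin [-60, -50)
  expect_equal(c(hit$phi_center, hit$psi_center), c(-55, -45))

  expect_error(ramachandran_density(one, bin_width = 7), "divide")

  set.seed(9)
  grid <- expand.grid(time_ns = 1:200, residue = 1:10)
  grid$phi_deg <- runif(nrow(grid), -180, 180)
  grid$psi_deg <- runif(nrow(grid), -180, 180)
  d2 <- ramachandran_density(dihedral_trajectory(grid), bin_width = 30)
  expect_equal(sum(d2$weight), 1, tolerance = 1e-9)
  expect_true(all(d2$weight >= 0))
})

test_that("region integration matches direct classification on aligned bins", {
  rs <- std_regions()
  set.seed(21)
  grid <- expand.grid(time_ns = 1:50, residue = 1:32)
  grid$phi_deg <- runif(nrow(grid), -180, 180)
  grid$psi_deg <- runif(nrow(grid), -180, 180)
  traj <- dihedral_trajectory(grid)

  # every printed bound is even, so 2-degree bins align with all box edges
  dens <- ramachandran_density(traj, bin_width = 2)
  from_density <- integrate_regions(dens, rs)

  st <- classify_trajectory(traj, rs, exclude_termini = FALSE)
  direct <- state_fractions(st, n_blocks = 2)

  for (lab in region_labels(rs)) {
    expect_equal(from_density$fraction[from_density$state == lab],
                 direct$fraction[direct$state == lab], tolerance = 1e-12)
  }
})

test_that("uniform density integrates to the box area ratio", {
  rs <- std_regions()
  nb <- 360 / 10
  dens <- structure(
    tidyr::expand_grid(phi_center = -180 + (1:nb - 0.5) * 10,
                       psi_center = -180 + (1:nb - 0.5) * 10),
    class = c("density_2d", class(tibble::tibble()))
  )
  dens$weight <- 1 / nrow(dens)
  ft <- integrate_regions(dens, rs)
  expect_equal(ft$fraction[ft$state == "alphaR"], (60 * 90) / 360^2,
               tolerance = 1e-12)
  expect_equal(sum(ft$fraction), 1, tolerance = 1e-9)
})

test_that("state fractions carry block errors and sum to one", {
  st <- state_trajectory(matrix("alphaR", nrow = 10, ncol = 5),
                         labels = c("alphaR", "other"))
  ft <- state_fractions(st, n_blocks = 5)
  expect_equal(ft$fraction[ft$state == "alphaR"], 1)
  expect_equal(ft$sd[ft$state == "alphaR"], 0)
  expect_equal(sum(ft$fraction), 1, tolerance = 1e-12)

  expect_error(state_fractions(st, n_blocks = 11), "too few frames")

  # two-state Markov chain with unequal lifetimes: the exact stationary
  # alphaR weight is near 0.3; recovered fraction within 3 block-SDs
  def <- data.frame(label = c("alphaR", "beta"), pi = c(0.5, 0.5),
                    lifetime_ns = c(1, 2.33))
  mst <- markov_state_trajectory(4000, def, n_residues = 10, dt = 0.1,
                                 seed = 99)
  target <- attr(mst, "stationary")[["alphaR"]]
  ft2 <- state_fractions(mst, n_blocks = 5)
  got <- ft2$fraction[ft2$state == "alphaR"]
  sd_blocks <- ft2$sd[ft2$state == "alphaR"]
  expect_lt(abs(got - target), 3 * sd_blocks)
  expect_equal(sum(ft2$fraction), 1, tolerance = 1e-12)
})
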