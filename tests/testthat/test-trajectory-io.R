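test_that("angle wrapping is canonical and idempotent", {
  expect_equal(wrap_angle(190), -170)
  expect_equal(wrap_angle(-190), 170)
  expect_equal(wrap_angle(180), 180)
  expect_equal(wrap_angle(-180), 180)
  expect_equal(wrap_angle(540), 180)
  set.seed(11)
  x <- runif(500, -2000, 2000)
  w <- wrap_angle(x)
  expect_true(all(w > -180 & w <= 180))
  expect_equal(wrap_angle(w), w)
})

test_that("dihedral tables round-trip and validate their grid", {
  grid <- expand.grid(time_ns = seq(0, 0.9, by = 0.1), residue = 1:32)
  set.seed(5)
  grid$phi_deg <- runif(nrow(grid), -180, 180)
  grid$psi_deg <- runif(nrow(grid), -180, 180)
  traj <- dihedral_trajectory(grid)
  expect_s3_class(traj, "dihedral_trajectory")
  expect_equal(attr(traj, "dt_ns"), 0.1)
  expect_equal(attr(traj, "chain_length"), 32)

  path <- withr::local_tempfile(fileext = ".csv")
  write_dihedral_table(traj, path)
  back <- read_dihedral_table(path)
  expect_equal(back$phi_deg, traj$phi_deg, tolerance = 1e-6)
  expect_equal(back$psi_deg, traj$psi_deg, tolerance = 1e-6)
  expect_equal(back$time_ns, traj$time_ns)

  # tab-delimited variant auto-detects
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_dihedral_table(traj, path2, delim = "\t")
  expect_equal(read_dihedral_table(path2)$phi_deg, traj$phi_deg,
               tolerance = 1e-6)
})

test_that("out-of-range angles in a table are stored wrapped", {
  df <- expand.grid(time_ns = c(0, 1), residue = 1:3)
  df$phi_deg <- c(190, rep(-60, 5))
  df$psi_deg <- -45
  traj <- dihedral_trajectory(df)
  expect_equal(traj$phi_deg[traj$time_ns == 0 & traj$residue == 1], -170)
})

test_that("incomplete grids and non-numeric angles are structured errors", {
  df <- expand.grid(time_ns = c(0, 1), residue = 1:3)
  df$phi_deg <- -60
  df$psi_deg <- -45
  broken <- df[!(df$time_ns == 1 & df$residue == 3), ]
  expect_error(dihedral_trajectory(broken), "incomplete grid")

  path <- withr::local_tempfile(fileext = ".csv")
  df2 <- df
  df2$phi_deg <- as.character(df2$phi_deg)
  df2$phi_deg[3] <- "oops"
  write.csv(df2[c("time_ns", "residue", "phi_deg", "psi_deg")], path,
            row.names = FALSE, quote = FALSE)
  expect_error(read_dihedral_table(path), "non-numeric")
})

test_that("equilibration discard follows the ceiling rule", {
  grid <- expand.grid(time_ns = 0:999, residue = 1:2)
  grid$phi_deg <- 0
  grid$psi_deg <- 0
  traj <- dihedral_trajectory(grid)

  kept <- discard_equilibration(traj, 0.1)
  expect_equal(length(unique(kept$time_ns)), 900)
  expect_equal(min(kept$time_ns), 100)
  expect_equal(attr(kept, "dt_ns"), attr(traj, "dt_ns"))

  expect_equal(nrow(discard_equilibration(traj, 0)), nrow(traj))

  grid10 <- expand.grid(time_ns = 0:9, residue = 1:2)
  grid10$phi_deg <- 0
  grid10$psi_deg <- 0
  t10 <- dihedral_trajectory(grid10)
  expect_equal(length(unique(discard_equilibration(t10, 0.25)$time_ns)), 7)

  # absolute-time variant
  expect_equal(min(discard_equilibration(traj, time_ns = 100)$time_ns), 100)
})

test_that("torsion angles follow the IUPAC convention", {
  # planar cis: all four atoms in a plane, far bond eclipsing the near one
  expect_equal(ramadyn:::torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                       c(1, 1, 0)), 0, tolerance = 1e-10)
  # planar trans canonicalizes to +180
  expect_equal(ramadyn:::torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                       c(1, -1, 0)), 180, tolerance = 1e-10)
  # right-handed quadruple with perpendicular planes is -90 under IUPAC
  quad <- list(a = c(0, 1, 0), b = c(0, 0, 0), c = c(1, 0, 0),
               d = c(1, 0, -1))
  expect_equal(ramadyn:::torsion_angle(quad$a, quad$b, quad$c, quad$d),
               oracle_torsion(quad$a, quad$b, quad$c, quad$d),
               tolerance = 1e-10)
  expect_equal(sign(ramadyn:::torsion_angle(quad$a, quad$b, quad$c, quad$d)),
               -1)

  set.seed(42)
  for (i in 1:100) {
    pts <- matrix(rnorm(12), 4, 3)
    got <- ramadyn:::torsion_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    want <- oracle_torsion(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    # both canonicalize +-180 the same way except sign of exactly 180
    expect_equal(wrap_angle(got - want), 0, tolerance = 1e-6)
  }
})

test_that("backbone dihedrals computed from coordinates match the oracle", {
  set.seed(7)
  n_res <- 5
  rows <- list()
  for (f in 1:2) {
    # random but bonded-ish backbone: cumulative random steps
    pos <- matrix(cumsum(rnorm(n_res * 3 * 3, sd = 0.1)), ncol = 3)
    k <- 0
    for (r in 1:n_res) {
      for (role in c("N", "CA", "C")) {
        k <- k + 1
        rows[[length(rows) + 1]] <- data.frame(
          frame = f, time_ns = f - 1, atom = k, role = role, residue = r,
          species = NA_character_,
          x = pos[k, 1], y = pos[k, 2], z = pos[k, 3], mass = 1
        )
      }
    }
  }
  coords <- coordinate_trajectory(do.call(rbind, rows))
  traj <- compute_backbone_dihedrals(coords)

  # termini carry undefined markers
  expect_true(all(is.na(traj$phi_deg[traj$residue == 1])))
  expect_true(all(is.na(traj$psi_deg[traj$residue == n_res])))

  # interior angles match the independent oracle
  fr1 <- coords[coords$frame == 1, ]
  pos_of <- function(r, role) {
    row <- fr1[fr1$residue == r & fr1$role == role, ]
    c(row$x, row$y, row$z)
  }
  for (r in 2:(n_res - 1)) {
    want_phi <- oracle_torsion(pos_of(r - 1, "C"), pos_of(r, "N"),
                               pos_of(r, "CA"), pos_of(r, "C"))
    want_psi <- oracle_torsion(pos_of(r, "N"), pos_of(r, "CA"),
                               pos_of(r, "C"), pos_of(r + 1, "N"))
    got <- traj[traj$time_ns == 0 & traj$residue == r, ]
    expect_equal(got$phi_deg, want_phi, tolerance = 1e-6)
    expect_equal(got$psi_deg, want_psi, tolerance = 1e-6)
  }
})

test_that("coordinate PDB fixtures round-trip within format precision", {
  fix <- bridge_fixture(8, list(c(2, 6)), n_frames = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_coordinate_pdb(fix, path)
  back <- read_coordinate_trajectory(path)
  expect_equal(length(unique(back$frame)), 3)
  ox_fix <- fix[fix$role == "O_carboxyl", ]
  ox_back <- back[back$role == "O_carboxyl", ]
  expect_equal(nrow(ox_back), nrow(ox_fix))
  expect_equal(ox_back$x, ox_fix$x, tolerance = 1e-3)
  expect_equal(ox_back$y, ox_fix$y, tolerance = 1e-3)
  expect_equal(ox_back$z, ox_fix$z, tolerance = 1e-3)
  # ions recognised by species
  expect_equal(sum(back$role == "ion") / 3, sum(fix$role == "ion") / 3)
  # no box record: box absent
  expect_null(attr(back, "box"))
})
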