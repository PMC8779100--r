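# Independent brute-force oracles, coded directly from the defining
# formulas. They deliberately avoid the package's code paths.

# Torsion angle via the two plane normals; sign from the triple product.
oracle_torsion <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# Fraction of monomers sitting in maximal target-runs of length >= min_len,
# by re-scanning the label matrix frame by frame with rle().
oracle_sequence_fraction <- function(label_matrix, target, min_len,
                                     n_monomers = ncol(label_matrix)) {
  per_frame <- apply(label_matrix, 1, function(row) {
    r <- rle(row == target)
    sum(r$lengths[r$values & r$lengths >= min_len]) / n_monomers
  })
  mean(per_frame)
}

# O(N^2)-style lag sums for the scalar ACF definition.
oracle_distance_acf <- function(x, max_lag) {
  n <- length(x)
  d <- x - mean(x)
  denom <- sum(d^2) / n
  vapply(0:max_lag, function(k) {
    (sum(d[1:(n - k)] * d[(1 + k):n]) / (n - k)) / denom
  }, numeric(1))
}

# Unit-vector dihedral ACF, averaged over origins then residues.
oracle_dihedral_acf <- function(mat_deg, max_lag) {
  th <- mat_deg * pi / 180
  n <- nrow(th)
  per_res <- vapply(seq_len(ncol(th)), function(r) {
    vapply(0:max_lag, function(k) {
      idx <- 1:(n - k)
      mean(cos(th[idx, r]) * cos(th[idx + k, r]) +
             sin(th[idx, r]) * sin(th[idx + k, r]))
    }, numeric(1))
  }, numeric(max_lag + 1))
  rowMeans(per_res)
}

# Random label matrix over an alphabet, fixed RNG assumed set by caller.
random_label_matrix <- function(n_frames, n_residues, alphabet,
                                prob = NULL) {
  matrix(sample(alphabet, n_frames * n_residues, replace = TRUE, prob = prob),
         nrow = n_frames)
}

std_regions <- function() builtin_region_set("standard_literature")
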