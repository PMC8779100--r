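#' Transition matrix of the synthetic conformational Markov chain
#'
#' Each residue switches between conformational states as a discrete-time
#' Markov chain. The stay probability of state s is
#' \eqn{q_s = \exp(-dt/\lambda_s)} (lifetime \eqn{\lambda_s} in ns); leaving
#' probability is split over the other states proportionally to their target
#' stationary weights \eqn{\pi_{s'}}. The construction approximates the
#' requested stationary law; the matrix's exact stationary distribution is
#' available from [markov_stationary()] and is what tests and recovery
#' checks compare against.
#'
#' @param states Data frame with columns `label`, `pi` (target stationary
#'   weights, positive, summing to 1) and `lifetime_ns` (mean state
#'   lifetimes, positive).
#' @param dt Frame spacing in ns.
#' @return A stochastic matrix with `dimnames` set to the labels.
#' @export
markov_transition_matrix <- function(states, dt) {
  if (any(states$pi <= 0) || abs(sum(states$pi) - 1) > 1e-9) {
    rlang::abort("state weights pi must be positive and sum to 1")
  }
  if (any(states$lifetime_ns <= 0)) rlang::abort("lifetimes must be positive")
  k <- nrow(states)
  P <- matrix(0, k, k, dimnames = list(states$label, states$label))
  q <- exp(-dt / states$lifetime_ns)
  for (s in seq_len(k)) {
    P[s, s] <- q[s]
    if (k > 1) {
      others <- setdiff(seq_len(k), s)
      w <- states$pi[others] / sum(states$pi[others])
      P[s, others] <- (1 - q[s]) * w
    } else {
      P[s, s] <- 1
    }
  }
  P / rowSums(P)
}

#' Exact stationary law of a transition matrix
#'
#' Solved as the left eigenvector of the transition matrix for eigenvalue 1,
#' normalized to a probability vector.
#'
#' @param P Stochastic matrix (rows sum to 1).
#' @return Named numeric vector of stationary probabilities.
#' @export
markov_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(P))
}

#' Simulate a synthetic conformational-state trajectory
#'
#' Every residue evolves as an independent copy of the Markov chain defined
#' by [markov_transition_matrix()], initialized from the chain's exact
#' stationary law. This emulates the frame-wise conformational-state
#' structure of a peptide backbone-dihedral trajectory without running
#' molecular dynamics.
#'
#' @param n_frames Number of frames.
#' @param states Data frame with columns `label`, `pi`, `lifetime_ns`
#'   (see [markov_transition_matrix()]).
#' @param n_residues Number of analysed residues per chain (default 30,
#'   a 32-residue chain minus the two termini).
#' @param dt Frame spacing in ns (default 0.1, a typical trajectory
#'   sampling step).
#' @param seed Random seed (required for reproducibility).
#' @return A `state_trajectory` tibble (`frame`, `time_ns`, `residue`,
#'   `state`) with the alphabet, `dt_ns`, `n_monomers` attributes plus
#'   `transition_matrix` and `stationary` (the exact law).
#' @export
markov_state_trajectory <- function(n_frames, states, n_residues = 30,
                                    dt = 0.1, seed = 1) {
  P <- markov_transition_matrix(states, dt)
  pi_exact <- markov_stationary(P)
  k <- nrow(P)
  cum <- t(apply(P, 1, cumsum))

  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  cur <- findInterval(stats::runif(n_residues), cumsum(pi_exact)) + 1L
  mat <- matrix(0L, n_frames, n_residues)
  mat[1, ] <- cur
  if (n_frames > 1) {
    for (f in 2:n_frames) {
      u <- stats::runif(n_residues)
      # row-wise inverse-CDF draw for each residue's current state
      nxt <- integer(n_residues)
      for (s in seq_len(k)) {
        at <- cur == s
        if (any(at)) nxt[at] <- findInterval(u[at], cum[s, ]) + 1L
      }
      nxt[nxt > k] <- k
      cur <- nxt
      mat[f, ] <- cur
    }
  }

  out <- tibble::tibble(
    frame = rep(seq_len(n_frames), each = n_residues),
    time_ns = rep((seq_len(n_frames) - 1) * dt, each = n_residues),
    residue = rep(seq_len(n_residues) + 1L, times = n_frames),
    state = states$label[as.vector(t(mat))]
  )
  st <- new_state_trajectory(out, labels = unique(c(states$label, "other")),
                             dt_ns = dt, n_monomers = n_residues)
  attr(st, "transition_matrix") <- P
  attr(st, "stationary") <- pi_exact
  st
}

#' Emit dihedral angles for a state trajectory
#'
#' For every (frame, residue), draws (phi, psi) from a Gaussian centred at
#' the centroid of the state's region box with standard deviation `jitter`,
#' rejection-truncated to the box, so that classifying the emitted angles
#' under the same region set always returns the emitting state. States with
#' several boxes emit from their first box.
#'
#' @param states A `state_trajectory`.
#' @param regions A [region_set()] with a box for every emitted label.
#' @param jitter Emission SD in degrees (default 10).
#' @param seed Random seed.
#' @param max_attempts Rejection-sampling cap per round (default 10000).
#' @return A [dihedral_trajectory()] covering the same frames and residues
#'   (plus two terminal residues emitted in the first region's box so the
#'   chain has the usual undefined-angle termini when `add_termini = TRUE`).
#' @param add_termini Prepend/append terminal residues with undefined
#'   (`NA`) phi/psi markers so the emitted chain behaves like a real
#'   peptide's (default `TRUE`).
#' @export
emit_dihedrals <- function(states, regions, jitter = 10, seed = 1,
                           add_termini = TRUE, max_attempts = 10000) {
  labs <- unique(states$state)
  boxes <- purrr::map(stats::setNames(labs, labs), function(l) {
    b <- regions[regions$label == l, , drop = FALSE]
    if (nrow(b) == 0) {
      rlang::abort(sprintf("state '%s' has no region box to emit from", l))
    }
    b[1, , drop = FALSE]
  })

  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  phi <- psi <- numeric(nrow(states))
  for (l in labs) {
    idx <- which(states$state == l)
    b <- boxes[[l]]
    cphi <- (b$phi_lo + b$phi_hi) / 2
    cpsi <- (b$psi_lo + b$psi_hi) / 2
    need <- idx
    attempt <- 0
    while (length(need) > 0) {
      attempt <- attempt + 1
      if (attempt > max_attempts) {
        rlang::abort("rejection sampling did not terminate; reduce jitter")
      }
      p1 <- stats::rnorm(length(need), cphi, jitter)
      p2 <- stats::rnorm(length(need), cpsi, jitter)
      ok <- box_member(p1, p2, b)
      phi[need[ok]] <- p1[ok]
      psi[need[ok]] <- p2[ok]
      need <- need[!ok]
    }
  }

  out <- tibble::tibble(time_ns = states$time_ns, residue = states$residue,
                        phi_deg = phi, psi_deg = psi)
  if (add_termini) {
    residues <- sort(unique(states$residue))
    times <- sort(unique(states$time_ns))
    termini <- tidyr::expand_grid(
      time_ns = times,
      residue = c(min(residues) - 1L, max(residues) + 1L)
    )
    first_box <- boxes[[1]]
    termini$phi_deg <- ifelse(termini$residue < min(residues), NA_real_,
                              (first_box$phi_lo + first_box$phi_hi) / 2)
    termini$psi_deg <- ifelse(termini$residue < min(residues),
                              (first_box$psi_lo + first_box$psi_hi) / 2,
                              NA_real_)
    out <- dplyr::bind_rows(out, termini)
  }
  dihedral_trajectory(out)
}

#' Synthetic bead-chain coordinates from a state trajectory
#'
#' Places one CA bead per residue, frame by frame. The virtual bond length
#' and bend angle (deviation from the previous bond direction) are taken
#' per state from `geometry_map`, so stretched states give straighter,
#' longer chains and screw states compact ones -- a test bed for the
#' correlation between chain size and conformational content. The azimuth
#' of each bend is drawn uniformly.
#'
#' @param states A `state_trajectory`.
#' @param geometry_map Data frame with columns `state`, `bond_nm`,
#'   `bend_deg` covering the emitted alphabet.
#' @param seed Random seed.
#' @param dt Frame spacing override (default: trajectory attribute).
#' @return A [coordinate_trajectory()] of unit-mass CA beads.
#' @export
synthetic_chain <- function(states, geometry_map, seed = 1, dt = NULL) {
  missing_states <- setdiff(unique(states$state), geometry_map$state)
  if (length(missing_states) > 0) {
    rlang::abort(paste0("geometry_map lacks states: ",
                        paste(missing_states, collapse = ", ")))
  }
  dt <- dt %||% attr(states, "dt_ns") %||% 1

  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  frames <- sort(unique(states$frame))
  residues <- sort(unique(states$residue))
  n <- length(residues)

  purrr::map_dfr(frames, function(f) {
    st <- states$state[states$frame == f][order(states$residue[states$frame == f])]
    g <- geometry_map[match(st, geometry_map$state), ]
    pos <- matrix(0, n, 3)
    dir <- c(1, 0, 0)
    for (i in 2:n) {
      bend <- g$bend_deg[i] * pi / 180
      if (bend > 0) {
        # rotate dir by bend about a random perpendicular axis
        ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e1 <- cross3(dir, ref)
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- cross3(dir, e1)
        az <- stats::runif(1, 0, 2 * pi)
        perp <- cos(az) * e1 + sin(az) * e2
        dir <- cos(bend) * dir + sin(bend) * perp
        dir <- dir / sqrt(sum(dir^2))
      }
      pos[i, ] <- pos[i - 1, ] + g$bond_nm[i] * dir
    }
    tibble::tibble(
      frame = f, time_ns = (f - 1) * dt, atom = seq_len(n), role = "CA",
      residue = residues, species = NA_character_,
      x = pos[, 1], y = pos[, 2], z = pos[, 3], mass = 1
    )
  }) |> coordinate_trajectory()
}

#' Coordinate fixture with a programmed set of counterion bridges
#'
#' Builds a minimal carboxylate + ion geometry in which exactly the
#' requested residue pairs are bridged: each residue gets two carboxylate
#' oxygens along a line (1 nm spacing), and for every requested pair one
#' oxygen of each member is moved to a dedicated site 0.2 nm apart with an
#' ion centred between them (0.1 nm from each, well inside any realistic
#' cutoff). Extra "free" ions are placed at least 0.6 nm from every oxygen.
#' With `present`, the bridge ions are parked far away in the frames where
#' the entry is `FALSE`, giving on/off time structure.
#'
#' @param n_residues Number of carboxyl-bearing residues (default 32).
#' @param bridged_pairs List of 2-vectors of residue indices.
#' @param n_frames Number of identical (or on/off modulated) frames.
#' @param present Logical vector (length `n_frames`) switching the bridges
#'   on per frame; default all `TRUE`.
#' @param n_free_ions Ions placed far from all oxygens (default 1).
#' @param ion_species Ion species label (default `"NA"`, sodium).
#' @param dt Frame spacing in ns.
#' @return A [coordinate_trajectory()].
#' @export
bridge_fixture <- function(n_residues = 32, bridged_pairs = list(),
                           n_frames = 1, present = NULL, n_free_ions = 1,
                           ion_species = "NA", dt = 1) {
  if (is.null(present)) present <- rep(TRUE, n_frames)
  if (length(present) != n_frames) {
    rlang::abort("'present' must have one entry per frame")
  }
  for (p in bridged_pairs) {
    if (length(p) != 2 || p[1] == p[2]) {
      rlang::abort("bridged pairs must be two distinct residues")
    }
    if (any(p < 1) || any(p > n_residues)) {
      rlang::abort("bridged pair outside the residue range")
    }
  }

  one_frame <- function(f) {
    on <- present[f]
    ox <- tibble::tibble(
      residue = rep(seq_len(n_residues), each = 2),
      x = rep(seq_len(n_residues), each = 2) * 1.0 +
        rep(c(-0.05, 0.05), n_residues),
      y = 0, z = 0
    )
    ions <- tibble::tibble(x = numeric(), y = numeric(), z = numeric())
    for (k in seq_along(bridged_pairs)) {
      p <- bridged_pairs[[k]]
      cx <- mean(p) * 1.0
      cz <- 3 * k # separate clusters so bridges never cross-talk
      # move the second oxygen of each member next to the shared ion site
      ox$x[2 * p[1]] <- cx - 0.1
      ox$y[2 * p[1]] <- 1.0
      ox$z[2 * p[1]] <- cz
      ox$x[2 * p[2]] <- cx + 0.1
      ox$y[2 * p[2]] <- 1.0
      ox$z[2 * p[2]] <- cz
      ion_y <- if (on) 1.0 else 50.0
      ions <- dplyr::bind_rows(ions,
                               tibble::tibble(x = cx, y = ion_y, z = cz))
    }
    if (n_free_ions > 0) {
      ions <- dplyr::bind_rows(ions, tibble::tibble(
        x = seq_len(n_free_ions) * 2.0, y = -5, z = 0
      ))
    }
    dplyr::bind_rows(
      tibble::tibble(frame = f, time_ns = (f - 1) * dt,
                     atom = seq_len(nrow(ox)), role = "O_carboxyl",
                     residue = ox$residue, species = NA_character_,
                     x = ox$x, y = ox$y, z = ox$z, mass = 16),
      if (nrow(ions) > 0) tibble::tibble(
        frame = f, time_ns = (f - 1) * dt,
        atom = nrow(ox) + seq_len(nrow(ions)), role = "ion",
        residue = NA_integer_, species = ion_species,
        x = ions$x, y = ions$y, z = ions$z, mass = 23
      )
    )
  }
  coordinate_trajectory(purrr::map_dfr(seq_len(n_frames), one_frame))
}

#' Synthetic stretched-exponential autocorrelation series
#'
#' \eqn{C(t_k) = A \exp(-(t_k/\tau)^\beta) + \epsilon_k} with Gaussian noise
#' of standard deviation `noise_sd`; `C(0)` is forced to 1. A test bed for
#' [fit_stretched_exponential()].
#'
#' @param A Amplitude.
#' @param tau Relaxation time (ns).
#' @param beta Stretching exponent.
#' @param noise_sd Gaussian noise SD (default 0).
#' @param n_lags Number of positive lags (series has `n_lags + 1` points
#'   including lag 0).
#' @param dt Lag spacing (ns, default 1).
#' @param seed Random seed.
#' @return An `acf_series` tibble.
#' @export
synthetic_acf <- function(A, tau, beta, noise_sd = 0, n_lags = 200, dt = 1,
                          seed = 1) {
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  t <- (0:n_lags) * dt
  C <- A * exp(-(t / tau)^beta) + stats::rnorm(length(t), 0, noise_sd)
  C[1] <- 1
  new_acf_series(lag = t, C = C, kind = "synthetic", dt = dt)
}
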