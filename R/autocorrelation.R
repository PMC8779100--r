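#' Autocorrelation of a scalar time series (end-to-end distance)
#'
#' Mean-subtracted, variance-normalized autocorrelation estimator
#' \deqn{C(k) = \frac{\frac{1}{N-k}\sum_t \delta d_t \, \delta d_{t+k}}
#'                   {\frac{1}{N}\sum_t \delta d_t^2}}
#' with \eqn{\delta d = d - \langle d \rangle}, averaged over all time
#' origins. Computed with an FFT fast path; reported lags are limited to
#' half the series length.
#'
#' @param x Numeric vector of per-frame values, or a data frame whose value
#'   column is named by `value`; a `time_ns` column (or `dt`) sets the lag
#'   axis.
#' @param dt Frame spacing in ns (default 1; ignored when `x` has `time_ns`).
#' @param value Column holding the series when `x` is a data frame.
#' @return An `acf_series` tibble with columns `lag_ns`, `C`; attributes
#'   `kind = "distance"` and `dt_ns`.
#' @export
distance_autocorrelation <- function(x, dt = 1, value = "ree_nm") {
  if (is.data.frame(x)) {
    if ("time_ns" %in% names(x) && nrow(x) >= 2) {
      dt <- diff(sort(x$time_ns))[1]
    }
    x <- x[[value]]
  }
  n <- length(x)
  if (n < 10) rlang::abort("need at least 10 frames for an autocorrelation")
  d <- x - mean(x)
  if (sum(d^2) == 0) rlang::abort("constant series: autocorrelation undefined")
  max_lag <- floor(n / 2)
  s <- fft_lag_sums(d, d, max_lag)
  c_k <- (s / (n - 0:max_lag)) / (sum(d^2) / n)
  new_acf_series(lag = (0:max_lag) * dt, C = c_k, kind = "distance", dt = dt)
}

#' Circular autocorrelation of dihedral-angle series
#'
#' Each angle is embedded as a unit vector \eqn{u(t) = (\cos\theta,
#' \sin\theta)} so the estimator is invariant to 360-degree jumps;
#' \eqn{C(k) = \langle u(t) \cdot u(t+k) \rangle} is averaged over time
#' origins first, then over residues (equal weights), and rescaled so
#' \eqn{C(0) = 1}.
#'
#' @param traj A [dihedral_trajectory()], or a numeric matrix of angles
#'   (rows = frames, columns = residues) in degrees.
#' @param angle `"psi"` or `"phi"` when `traj` is a dihedral trajectory.
#' @param dt Frame spacing in ns for matrix input.
#' @param exclude_termini Drop the first and last residue (default `TRUE`;
#'   their phi/psi are undefined anyway).
#' @return An `acf_series` tibble (`lag_ns`, `C`) with `kind` attribute
#'   `"dihedral-phi"` or `"dihedral-psi"`.
#' @export
dihedral_autocorrelation <- function(traj, angle = c("psi", "phi"), dt = 1,
                                     exclude_termini = TRUE) {
  angle <- match.arg(angle)
  if (is.data.frame(traj)) {
    col <- paste0(angle, "_deg")
    residues <- sort(unique(traj$residue))
    if (exclude_termini && length(residues) > 2) {
      residues <- residues[-c(1, length(residues))]
    }
    dt <- attr(traj, "dt_ns") %||% dt
    wide <- traj |>
      dplyr::filter(.data$residue %in% residues) |>
      dplyr::arrange(.data$time_ns, .data$residue)
    mat <- matrix(wide[[col]], ncol = length(residues), byrow = TRUE)
  } else {
    mat <- as.matrix(traj)
  }
  mat <- mat[, colSums(is.na(mat)) == 0, drop = FALSE]
  n <- nrow(mat)
  if (n < 10) rlang::abort("need at least 10 frames for an autocorrelation")
  max_lag <- floor(n / 2)

  theta <- mat * pi / 180
  acc <- rep(0, max_lag + 1)
  for (r in seq_len(ncol(mat))) {
    sc <- fft_lag_sums(cos(theta[, r]), cos(theta[, r]), max_lag) +
      fft_lag_sums(sin(theta[, r]), sin(theta[, r]), max_lag)
    acc <- acc + sc / (n - 0:max_lag)
  }
  c_k <- acc / ncol(mat)
  c_k <- c_k / c_k[1] # u.u = 1, so C(0) is already 1 up to rounding
  new_acf_series(lag = (0:max_lag) * dt, C = c_k,
                 kind = paste0("dihedral-", angle), dt = dt)
}

# Sum over origins t of a_t * b_{t+k} for k = 0..max_lag, via FFT
# cross-correlation with zero padding.
fft_lag_sums <- function(a, b, max_lag) {
  n <- length(a)
  m <- stats::nextn(2 * n, 2)
  fa <- stats::fft(c(a, rep(0, m - n)))
  fb <- stats::fft(c(b, rep(0, m - n)))
  s <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / m
  s[1:(max_lag + 1)]
}

new_acf_series <- function(lag, C, kind, dt) {
  structure(
    tibble::tibble(lag_ns = lag, C = C),
    kind = kind,
    dt_ns = dt,
    class = c("acf_series", class(tibble::tibble()))
  )
}

#' Write an autocorrelation series as TSV
#'
#' @param acf An `acf_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_acf <- function(acf, path) {
  utils::write.table(as.data.frame(acf), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
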