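#' Wrap angles onto the canonical (-180, 180] degree interval
#'
#' All angular comparisons in the package happen after canonical wrapping,
#' so `wrap_angle()` is idempotent and classification is invariant under
#' adding multiples of 360 degrees.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length with every finite value in
#'   `(-180, 180]`. `NA` values pass through.
#' @examples
#' wrap_angle(c(190, -190, 180, -180, 360))
#' @export
wrap_angle <- function(x) {
  y <- x %% 360
  out <- ifelse(y > 180, y - 360, y)
  # x %% 360 of exact -180 is 180, which is what we want; NA propagates
  out
}

# Torsion angle (degrees, IUPAC sign convention) for one atom quadruple.
# a, b, c, d are length-3 numeric vectors. Clockwise rotation of the far
# bond viewed along b -> c is negative.
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sqrt(sum(b2^2)) * sum(b1 * n2)
  ang <- atan2(y, x) * 180 / pi
  # canonicalize -180 to +180
  if (isTRUE(all.equal(ang, -180, tolerance = 1e-12))) ang <- 180
  ang
}

cross3 <- function(u, v) {
  c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}
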