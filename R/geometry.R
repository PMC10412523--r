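#' Angular separation between two unit gaze directions
#'
#' Arc-cosine of the (clamped) dot product, in degrees. Both inputs must be
#' (approximately) unit 3-vectors; zero vectors are rejected.
#'
#' @param a,b Numeric unit 3-vectors.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
#' @examples
#' angular_separation(c(1, 0, 0), c(0, 1, 0)) # 90
angular_separation <- function(a, b) {
  if (length(a) != 3 || length(b) != 3) {
    abort_argument("gaze directions must be 3-vectors")
  }
  a <- unit3(a)
  b <- unit3(b)
  rad2deg(acos(clamp(sum(a * b), -1, 1)))
}

# angles (degrees) between each row of unit matrix `m` and unit vector `v`
ang_rows_deg <- function(m, v) {
  rad2deg(acos(clamp(as.numeric(m %*% v), -1, 1)))
}

# linear interpolation of an AOI track (clamped at the ends)
interp_track <- function(track, t) {
  c(
    approx(track$t, track$x, t, rule = 2)$y,
    approx(track$t, track$y, t, rule = 2)$y,
    approx(track$t, track$z, t, rule = 2)$y
  )
}

# spherical linear interpolation between unit vectors a and b, f in [0, 1]
slerp <- function(a, b, f) {
  d <- clamp(sum(a * b), -1, 1)
  om <- acos(d)
  if (om < 1e-9) return(a)
  (sin((1 - f) * om) * a + sin(f * om) * b) / sin(om)
}
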