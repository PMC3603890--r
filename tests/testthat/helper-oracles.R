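# Independent oracles used by the test suite.  Each one solves the same
# physical question as the package code by a different route (brute-force
# geometry, exact series, direct root finding) so agreement is evidence,
# not tautology.

# Squeeze length by brute-force sphere--arc tangency: the largest axial
# center position s > 0 at which a sphere of radius R_cell centered on the
# axis clears the constriction arc (radius r_arc about a center c_lat off
# the axis, straddling the throat plane).  Clearance is minimized over a
# dense parametrization of the arc and refined with optimize; the contact
# position is the root of the clearance in s.
oracle_squeeze_length <- function(r_arc, c_lat, R_cell) {
  clearance <- function(s) {
    d2 <- function(phi) {
      px <- r_arc * sin(phi)
      py <- c_lat - r_arc * cos(phi)
      (s - px)^2 + py^2
    }
    phi <- seq(-pi / 2, pi / 2, length.out = 2001)
    j <- which.min(d2(phi))
    lo <- phi[max(1, j - 1)]; hi <- phi[min(length(phi), j + 1)]
    opt <- stats::optimize(d2, c(lo, hi), tol = 1e-14)
    sqrt(opt$objective) - R_cell
  }
  throat_gap <- c_lat - r_arc
  if (throat_gap >= R_cell) return(NA_real_)
  stats::uniroot(clearance, c(1e-6, c_lat + r_arc + R_cell),
                 tol = 1e-12)$root
}

# Crossing abscissa of two power laws by direct root finding on the log
# difference (independent of the closed form used in crossing_radius).
oracle_crossing <- function(c1, p1, c2, p2, interval = c(1e-3, 1e6)) {
  f <- function(lx) (log(c1) + p1 * lx) - (log(c2) + p2 * lx)
  exp(stats::uniroot(f, log(interval), tol = 1e-14)$root)
}

# Hagen-Poiseuille conductance of a circular duct (closed form).
oracle_circular_conductance <- function(a, length, plasma) {
  pi * a^4 / (8 * plasma$viscosity * length)
}
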