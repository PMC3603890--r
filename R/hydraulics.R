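#' Plasma properties
#'
#' Incompressible Newtonian plasma.  Density is recorded only: at these
#' scales the flow is inertia-free.
#'
#' @param viscosity dynamic viscosity, Pa s.
#' @param density density, kg/m^3 (recorded).
#' @return an object of class \code{"plasma_model"}.
#' @export
plasma_model <- function(viscosity = 1.2e-3, density = 1.03e3) {
  stopifnot(viscosity > 0, density > 0)
  structure(list(viscosity = viscosity, density = density),
            class = "plasma_model")
}

#' @export
print.plasma_model <- function(x, ...) {
  cat(sprintf("Plasma: viscosity %g Pa s, density %g kg/m^3\n",
              x$viscosity, x$density))
  invisible(x)
}

# Friction-factor Reynolds product f*Re for fully developed laminar flow in
# a rectangular duct of aspect ratio alpha = min(h,w)/max(h,w)
# (Shah & London polynomial; within 0.05% of the exact series).
.fre_rect <- function(alpha) {
  a <- pmin(alpha, 1 / alpha)
  24 * (1 - 1.3553 * a + 1.9467 * a^2 - 1.7012 * a^3 +
          0.9564 * a^4 - 0.2537 * a^5)
}

#' Poiseuille conductance of a rectangular duct
#'
#' Volumetric flow per unit pressure drop, \code{Q / dP}, of fully
#' developed laminar flow in a rectangular duct, from the friction-factor
#' correlation \code{C = A D_h^2 / (2 fRe mu L)} (Fanning \code{fRe}).
#' Lengths in um give the conductance in um^3/(Pa s).
#'
#' @param width,height duct sides, um.
#' @param length duct length, um.
#' @param plasma a \code{\link{plasma_model}}.
#' @return conductance, um^3/(Pa s).
#' @export
rect_duct_conductance <- function(width, height, length, plasma) {
  stopifnot(width > 0, height > 0, length > 0)
  A <- width * height
  Dh <- 2 * width * height / (width + height)
  A * Dh^2 / (2 * .fre_rect(height / width) * plasma$viscosity * length)
}

#' Exact series conductance of a rectangular duct
#'
#' The exact eigenfunction-series solution for rectangular Poiseuille flow,
#' \deqn{Q = \frac{b h^3 \Delta P}{12 \mu L}\Big[1 - \frac{192 h}{\pi^5 b}
#'   \sum_{n odd} \frac{\tanh(n \pi b / 2 h)}{n^5}\Big],}
#' used as the reference against which the correlation-based
#' \code{\link{rect_duct_conductance}} is checked.
#'
#' @inheritParams rect_duct_conductance
#' @param nterms number of (odd) series terms.
#' @return conductance, um^3/(Pa s).
#' @export
rect_duct_conductance_series <- function(width, height, length, plasma,
                                         nterms = 100) {
  stopifnot(width > 0, height > 0, length > 0)
  h <- min(width, height); b <- max(width, height)
  n <- seq(1, by = 2, length.out = nterms)
  S <- sum(tanh(n * pi * b / (2 * h)) / n^5)
  (b * h^3 / (12 * plasma$viscosity * length)) * (1 - 192 * h / (pi^5 * b) * S)
}

#' Conductance of the corner gutters along an occluded cell
#'
#' Each gutter (corner clearance between the squeezed cell's rounded flank
#' and the channel wall) is modelled as a straight duct of its local
#' cross-section with conductance \code{k A^3 / (mu P^2 L)}, where \code{A}
#' is the gutter area, \code{P} its wetted perimeter and \code{k} a duct
#' shape factor.  The default \code{k = 0.5} reproduces the
#' Hagen-Poiseuille law \code{pi a^4 / (8 mu L)} exactly for a circular
#' section and lies between the slot and circular limits for the lens- and
#' triangle-like sections that actually occur.  Zero gutter area (the
#' axisymmetric model's perfect seal) gives zero conductance.
#'
#' @param areas gutter cross-section areas, um^2 (one per gutter).
#' @param perimeters matching wetted perimeters, um.
#' @param length occluded length the gutters span, um.
#' @param plasma a \code{\link{plasma_model}}.
#' @param k duct shape factor.
#' @return total conductance, um^3/(Pa s).
#' @export
gutter_conductance <- function(areas, perimeters, length, plasma, k = 0.5) {
  stopifnot(length > 0, all(areas >= 0), all(perimeters >= 0))
  keep <- areas > 0 & perimeters > 0
  if (!any(keep)) return(0)
  sum(k * areas[keep]^3 / (plasma$viscosity * perimeters[keep]^2 * length))
}

#' Partition of the channel pressure drop across an occluded region
#'
#' Series-parallel resistance network for a channel occluded by a cell:
#' open duct upstream (resistance \code{R_up}), the occluded region -
#' bypassed in parallel by the gutters (conductance \code{C_gutter}) and,
#' optionally, by an open-duct path of resistance \code{R_occluded} - and
#' open duct downstream (\code{R_down}).  A moving cell adds its piston
#' flux \code{Q_cell} through the occluded region.  Solving the network for
#' the pressure drop across the occluded region:
#' \deqn{\Delta P_{cell} = \frac{\Delta P - Q_{cell}(R_{up}+R_{down})}
#'   {1 + (C_{gutter} + 1/R_{occluded})(R_{up}+R_{down})}.}
#' With zero gutter conductance the drop is the plain series-circuit share;
#' infinite gutter conductance short-circuits the cell entirely.
#'
#' @param dP_total total pressure drop across the channel, Pa.
#' @param R_up,R_down open-duct resistances up/downstream, Pa s/um^3.
#' @param C_gutter gutter conductance, um^3/(Pa s).
#' @param R_occluded open-duct resistance of the occluded span (default
#'   \code{Inf}: the cell seals everything but the gutters).
#' @param Q_cell piston flux of the advancing cell, um^3/s.
#' @return a list with \code{dP_cell} (Pa), \code{Q_total},
#'   \code{Q_gutter}, \code{Q_bypass} (um^3/s).
#' @export
pressure_partition <- function(dP_total, R_up, R_down, C_gutter,
                               R_occluded = Inf, Q_cell = 0) {
  stopifnot(dP_total >= 0, R_up >= 0, R_down >= 0, C_gutter >= 0)
  C_byp <- if (is.finite(R_occluded)) 1 / R_occluded else 0
  Rs <- R_up + R_down
  dP_cell <- (dP_total - Q_cell * Rs) / (1 + (C_gutter + C_byp) * Rs)
  list(dP_cell = dP_cell,
       Q_total = Q_cell + dP_cell * (C_gutter + C_byp),
       Q_gutter = dP_cell * C_gutter,
       Q_bypass = dP_cell * C_byp)
}

# Per-unit-length open-duct resistance profile of a channel on a grid, and
# its cumulative integral; used for R_up/R_down lookups during a transit.
.channel_resistance_fun <- function(channel, plasma, dx = 0.25) {
  x <- seq(channel$x_inlet, channel$x_outlet, by = dx)
  if (inherits(channel, "axisym_channel")) {
    r <- axisym_radius_at(channel, x, imaginary = FALSE)
    rpl <- 8 * plasma$viscosity / (pi * r^4)
  } else {
    hw <- rect_half_width_at(channel, x, imaginary = FALSE)
    h <- rect_height_at(channel, x, imaginary = FALSE)
    A <- 2 * hw * h
    Dh <- 4 * A / (2 * (2 * hw + h))
    rpl <- 2 * .fre_rect(h / (2 * hw)) * plasma$viscosity / (A * Dh^2)
  }
  cum <- c(0, cumsum((rpl[-1] + rpl[-length(rpl)]) / 2 * diff(x)))
  approxfun(x, cum, rule = 2)
}

#' Open-duct resistance of a channel segment
#'
#' Axially integrated laminar resistance of the open lumen between two
#' stations, using the circular Hagen-Poiseuille law (axisymmetric model)
#' or the rectangular-duct friction-factor correlation.
#'
#' @param channel a channel object.
#' @param from,to axial stations, um.
#' @param plasma a \code{\link{plasma_model}}.
#' @param dx integration step, um.
#' @return resistance, Pa s/um^3.
#' @export
channel_resistance <- function(channel, from, to, plasma, dx = 0.25) {
  cumR <- .channel_resistance_fun(channel, plasma, dx)
  cumR(max(from, to)) - cumR(min(from, to))
}
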