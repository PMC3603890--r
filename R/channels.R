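#' Axisymmetric capillary model
#'
#' A straight cylindrical pipe carrying an axisymmetric arc-shaped
#' constriction whose throat sits 50 um downstream of the inlet (the throat
#' plane defines the axial origin \code{x = 0}).  An "imaginary wall" is
#' offset \code{delta} into the lumen from every constriction surface; the
#' cell slides on the imaginary wall without friction while plasma may
#' penetrate it.
#'
#' @param L channel length, um.
#' @param r_pipe pipe radius, um.
#' @param r_con curvature radius of the constriction arc, um.
#' @param r_min throat radius, um.
#' @param delta imaginary-wall offset, um.
#'
#' @return An object of class \code{c("axisym_channel", "channel")}.
#' @examples
#' ch <- axisym_channel()
#' axisym_radius_at(ch, 0, imaginary = TRUE)  # 2.75 um imaginary throat
#' constricted_length(ch)                     # 26 um
#' @export
axisym_channel <- function(L = 150, r_pipe = 6, r_con = 27.525,
                           r_min = 2.85, delta = 0.1) {
  stopifnot(L > 0, r_pipe > 0, r_con > 0, r_min > 0, delta >= 0)
  if (r_min >= r_pipe)
    stop("throat radius must be smaller than the pipe radius")
  if (delta >= r_min)
    stop("imaginary-wall offset must be smaller than the throat radius")
  if (r_con < r_pipe - r_min)
    stop("constriction arc never reaches the pipe wall (r_con too small)")
  ch <- list(L = L, r_pipe = r_pipe, r_con = r_con, r_min = r_min,
             delta = delta, x_inlet = -50, x_outlet = L - 50)
  class(ch) <- c("axisym_channel", "channel")
  ch
}

#' Rectangular channel model
#'
#' A rectangular channel whose two side walls each carry an arc-shaped
#' constriction of curvature radius \code{R_con}, leaving a throat of width
#' \code{W_con} 50 um downstream of the inlet (\code{x = 0} at the throat).
#' Imaginary walls are offset \code{delta} into the lumen from the side
#' walls, ceiling and floor.  When \code{H < H_inlet} the channel height is
#' \code{H_inlet} at the inlet and tapers linearly to \code{H} over
#' \code{ramp} so the cell is pre-compressed before the constriction.
#'
#' @param W channel width, um.
#' @param L channel length, um.
#' @param H channel height, um.
#' @param R_con curvature radius of each side-wall constriction arc, um.
#' @param W_con throat width, um.
#' @param delta imaginary-wall offset, um.
#' @param H_inlet inlet height used when \code{H < H_inlet}, um.
#' @param ramp axial interval of the height taper, um (x from the throat).
#'
#' @return An object of class \code{c("rect_channel", "channel")}.
#' @examples
#' ch <- rect_channel()  # the control geometry
#' rect_half_width_at(ch, 0, imaginary = TRUE)
#' squeeze_length(ch)
#' @export
rect_channel <- function(W = 22.36, L = 150, H = 8.2, R_con = 27.525,
                         W_con = 4.368, delta = 0.1, H_inlet = 8.2,
                         ramp = c(-40.17, -35)) {
  stopifnot(W > 0, L > 0, H > 0, R_con > 0, W_con > 0, delta >= 0)
  if (W_con >= W) stop("throat width must be smaller than the channel width")
  if (delta >= W_con / 2) stop("offset must be smaller than the half throat")
  if (H <= 2 * delta) stop("channel height must exceed twice the offset")
  if (R_con < (W - W_con) / 2)
    stop("constriction arc never reaches the side wall (R_con too small)")
  ch <- list(W = W, L = L, H = H, R_con = R_con, W_con = W_con,
             delta = delta, H_inlet = H_inlet, ramp = sort(ramp),
             x_inlet = -50, x_outlet = L - 50)
  class(ch) <- c("rect_channel", "channel")
  ch
}

#' @export
print.axisym_channel <- function(x, ...) {
  cat("Axisymmetric capillary model\n")
  cat(sprintf("  pipe radius  %.3f um, length %.1f um\n", x$r_pipe, x$L))
  cat(sprintf("  constriction r_con = %.3f um, r_min = %.3f um\n",
              x$r_con, x$r_min))
  cat(sprintf("  imaginary-wall offset %.2f um (imaginary throat %.3f um)\n",
              x$delta, x$r_min - x$delta))
  cat(sprintf("  constricted region %.2f um\n", constricted_length(x)))
  invisible(x)
}

#' @export
print.rect_channel <- function(x, ...) {
  cat("Rectangular channel model\n")
  cat(sprintf("  W = %.3f um, H = %.3f um, L = %.1f um\n", x$W, x$H, x$L))
  cat(sprintf("  constriction R_con = %.3f um, W_con = %.3f um\n",
              x$R_con, x$W_con))
  cat(sprintf("  imaginary-wall offset %.2f um\n", x$delta))
  cat(sprintf("  throat D_h (nominal) %.3f um\n",
              hydraulic_diameter(x$H, x$W_con)))
  invisible(x)
}

.check_domain <- function(channel, x) {
  if (any(x < channel$x_inlet - 1e-9 | x > channel$x_outlet + 1e-9))
    stop("axial station outside the channel [",
         channel$x_inlet, ", ", channel$x_outlet, "] um")
}

# half-length of the constricted region along x; the arc (radius r_arc about
# a center offset c_lat from the axis) meets the straight wall at lat_wide
.arc_half_span <- function(r_arc, c_lat, lat_wide) {
  d <- c_lat - lat_wide
  if (d < 0 || d > r_arc) stop("constriction arc does not reach the wall")
  sqrt(r_arc^2 - d^2)
}

#' Lumen radius of the axisymmetric capillary
#'
#' @param channel an \code{\link{axisym_channel}}.
#' @param x axial station(s), um (0 at the throat).
#' @param imaginary if \code{TRUE}, return the imaginary-wall (offset)
#'   surface on which the cell slides.
#' @return lumen radius (um), vectorized over \code{x}.
#' @export
axisym_radius_at <- function(channel, x, imaginary = FALSE) {
  .check_domain(channel, x)
  with(channel, {
    c_lat <- r_min + r_con                 # lateral position of arc center
    r_arc <- if (imaginary) r_con + delta else r_con
    span <- .arc_half_span(r_arc, c_lat, r_pipe)
    r <- rep(r_pipe, length(x))
    inarc <- abs(x) <= span
    r[inarc] <- c_lat - sqrt(r_arc^2 - x[inarc]^2)
    pmin(r, r_pipe)
  })
}

#' Effective lumen half-width of the rectangular channel
#'
#' Outside the constricted region the half-width is \code{W/2} (minus
#' \code{delta} on the imaginary surface); inside it follows the side-wall
#' arc \code{(W_con/2 + R_con) - sqrt(R_arc^2 - x^2)}.
#'
#' @inheritParams axisym_radius_at
#' @param channel a \code{\link{rect_channel}}.
#' @return lumen half-width (um), vectorized over \code{x}.
#' @export
rect_half_width_at <- function(channel, x, imaginary = FALSE) {
  .check_domain(channel, x)
  with(channel, {
    c_lat <- W_con / 2 + R_con
    off <- if (imaginary) delta else 0
    r_arc <- R_con + off
    wide <- W / 2 - off
    span <- .arc_half_span(r_arc, c_lat, wide)
    hw <- rep(wide, length(x))
    inarc <- abs(x) <= span
    hw[inarc] <- c_lat - sqrt(r_arc^2 - x[inarc]^2)
    pmin(hw, wide)
  })
}

#' Effective lumen height of the rectangular channel
#'
#' For \code{H < H_inlet} the height is \code{H_inlet} upstream of the ramp,
#' tapers linearly across it, and is \code{H} downstream; otherwise it is
#' constant.  The imaginary surface is \code{2 delta} lower.
#'
#' @inheritParams rect_half_width_at
#' @return lumen height (um), vectorized over \code{x}.
#' @export
rect_height_at <- function(channel, x, imaginary = FALSE) {
  .check_domain(channel, x)
  with(channel, {
    if (H >= H_inlet) {
      h <- rep(H, length(x))
    } else {
      h <- approx(x = c(x_inlet, ramp[1], ramp[2], x_outlet),
                  y = c(H_inlet, H_inlet, H, H),
                  xout = x, rule = 2)$y
    }
    if (imaginary) h <- h - 2 * delta
    h
  })
}

#' Lumen cross-section at an axial station
#'
#' Reports half-width, height, area, wetted perimeter and hydraulic diameter
#' of the lumen at each requested station.  For the axisymmetric model the
#' half-width and height both equal the local radius (and \code{D_h = 2 r}).
#'
#' @param channel a channel object.
#' @param x axial station(s), um.
#' @param imaginary use the imaginary-wall surface.
#' @return a \code{data.frame} with columns \code{x}, \code{half_width},
#'   \code{height}, \code{area}, \code{perimeter}, \code{D_h}.
#' @export
lumen_section <- function(channel, x, imaginary = FALSE) {
  UseMethod("lumen_section")
}

#' @export
lumen_section.axisym_channel <- function(channel, x, imaginary = FALSE) {
  r <- axisym_radius_at(channel, x, imaginary)
  data.frame(x = x, half_width = r, height = 2 * r,
             area = pi * r^2, perimeter = 2 * pi * r, D_h = 2 * r)
}

#' @export
lumen_section.rect_channel <- function(channel, x, imaginary = FALSE) {
  hw <- rect_half_width_at(channel, x, imaginary)
  h <- rect_height_at(channel, x, imaginary)
  area <- 2 * hw * h
  per <- 2 * (2 * hw + h)
  data.frame(x = x, half_width = hw, height = h,
             area = area, perimeter = per, D_h = 4 * area / per)
}

#' Length of the constricted region
#'
#' Axial extent over which the constriction surface departs from the
#' straight wall.  On the imaginary surface of the reference axisymmetric
#' capillary this is 26 um.
#'
#' @param channel a channel object.
#' @param imaginary measure on the imaginary-wall surface (default).
#' @return length, um.
#' @export
constricted_length <- function(channel, imaginary = TRUE) {
  UseMethod("constricted_length")
}

#' @export
constricted_length.axisym_channel <- function(channel, imaginary = TRUE) {
  with(channel, {
    if (r_min == r_pipe) return(0)
    off <- if (imaginary) delta else 0
    2 * .arc_half_span(r_con + off, r_min + r_con, r_pipe)
  })
}

#' @export
constricted_length.rect_channel <- function(channel, imaginary = TRUE) {
  with(channel, {
    off <- if (imaginary) delta else 0
    2 * .arc_half_span(R_con + off, W_con / 2 + R_con, W / 2 - off)
  })
}

#' Hydraulic diameter of a rectangular lumen
#'
#' \code{D_h = 4 area / perimeter = 2 h w / (h + w)}; symmetric in its
#' arguments.
#'
#' @param height,width duct sides, um (or any consistent unit).
#' @return hydraulic diameter in the same unit.
#' @examples
#' hydraulic_diameter(8.2, 4.368)  # 5.70 um
#' @export
hydraulic_diameter <- function(height, width) {
  if (any(height <= 0) || any(width <= 0))
    stop("duct dimensions must be positive")
  2 * height * width / (height + width)
}

#' Throat width with the same cross-sectional area as a circular throat
#'
#' Width of a rectangular throat of height \code{H} whose area equals that
#' of a circular throat of radius \code{r_min}: \code{pi r_min^2 / H}.
#'
#' @param H throat height, um.
#' @param r_min circular throat radius, um.
#' @return throat width, um.
#' @examples
#' equal_area_width(8.2, 2.85)  # 3.112 um
#' @export
equal_area_width <- function(H, r_min = 2.85) {
  stopifnot(all(H > 0), all(r_min > 0))
  pi * r_min^2 / H
}

#' Throat width matching a target hydraulic diameter
#'
#' Width \code{W} such that \code{hydraulic_diameter(H, W) == d_target}:
#' \code{d H / (2 H - d)}.  Infeasible when \code{2 H <= d_target}.
#'
#' @param H throat height, um.
#' @param d_target target hydraulic diameter, um.
#' @return throat width, um.
#' @examples
#' equal_dh_width(8.2, 5.7)   # 4.368 um
#' equal_dh_width(10.2, 5.7)  # 3.955 um
#' @export
equal_dh_width <- function(H, d_target = 5.7) {
  stopifnot(all(H > 0), all(d_target > 0))
  if (any(2 * H <= d_target))
    stop("infeasible: need 2 H > d_target")
  d_target * H / (2 * H - d_target)
}

#' First contact of a spherical cell with the constriction
#'
#' Position and contact angle at which a spherical cell of radius
#' \code{R_cell}, centered on the channel axis, first touches the
#' imaginary side-wall arc of the constriction.  The squeeze length
#' \code{s} is the axial distance from the throat plane to the sphere
#' center at that first tangency; the contact angle \code{theta} is the
#' elevation from the axis at the cell center to the contact point and
#' reaches \code{pi/2} at the throat.
#'
#' @param channel a channel object.
#' @param R_cell cell radius, um.
#' @return a list with \code{s} (um), \code{theta} (radians) and
#'   \code{contact_exists}.
#' @export
first_contact <- function(channel, R_cell = 4) {
  UseMethod("first_contact")
}

.first_contact_arc <- function(r_arc, c_lat, throat_gap, R_cell) {
  if (throat_gap >= R_cell)       # cell passes without touching
    return(list(s = NA_real_, theta = NA_real_, contact_exists = FALSE))
  reach <- r_arc + R_cell         # center-to-center distance at tangency
  s <- sqrt(reach^2 - c_lat^2)
  list(s = s, theta = atan2(c_lat, s), contact_exists = TRUE)
}

#' @export
first_contact.rect_channel <- function(channel, R_cell = 4) {
  with(channel,
       .first_contact_arc(R_con + delta, W_con / 2 + R_con,
                          W_con / 2 - delta, R_cell))
}

#' @export
first_contact.axisym_channel <- function(channel, R_cell = 4) {
  with(channel,
       .first_contact_arc(r_con + delta, r_min + r_con,
                          r_min - delta, R_cell))
}

#' Squeeze length of the constriction
#'
#' Axial distance from the throat plane to the center of a spherical cell
#' when it first touches the imaginary side-wall arc (\code{NA} when the
#' cell clears the throat without contact).
#'
#' @inheritParams first_contact
#' @return squeeze length, um.
#' @examples
#' squeeze_length(rect_channel(W_con = 4.368))  # 10.8 um
#' squeeze_length(rect_channel(W_con = 3.112))  # 12.4 um
#' @export
squeeze_length <- function(channel, R_cell = 4) {
  first_contact(channel, R_cell)$s
}

#' Contact angle at first contact
#'
#' @inheritParams first_contact
#' @return contact angle, radians, in \code{(0, pi/2]}.
#' @export
contact_angle_first_contact <- function(channel, R_cell = 4) {
  fc <- first_contact(channel, R_cell)
  if (!fc$contact_exists)
    stop("cell does not contact the constriction side walls")
  fc$theta
}
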