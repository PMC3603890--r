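#' Reduced-order cell shape
#'
#' Capsule-family stand-in for the deformed cell surface: a prismatic
#' central body whose cross-section is a rounded rectangle of half-extents
#' \code{w_cell} (lateral) and \code{h_cell} (vertical) with corner radius
#' \code{min(w_cell, h_cell)} (the gutter flank set by cortical tension
#' rounding), closed by half-spheroidal end caps of axial semi-length
#' \code{sqrt(w_cell h_cell)}.  The body length is chosen so the shape
#' volume equals the resting sphere volume exactly; an undeformed state
#' (\code{w_cell = h_cell = R_cell}) is the sphere itself.
#'
#' @param w_cell current lateral half-extent, um.
#' @param h_cell current vertical half-extent, um.
#' @param cell a \code{\link{cell_model}}.
#' @return a list with cross-section \code{area} (um^2), corner radius
#'   \code{r_corner}, cap semi-length \code{a_cap}, \code{body_length},
#'   total \code{length}, \code{volume} (um^3) and the contact-band width
#'   \code{l_band} (= body length, floored at a small minimum).
#' @examples
#' cell_shape(4, 4, cell_model())$volume  # (4/3) pi 4^3 = 268.08 um^3
#' @export
cell_shape <- function(w_cell, h_cell, cell) {
  if (w_cell <= 0 || h_cell <= 0)
    stop("infeasible shape: half-extents must be positive")
  V0 <- 4 / 3 * pi * cell$R_cell^3
  rg <- min(w_cell, h_cell)
  A <- 4 * w_cell * h_cell - (4 - pi) * rg^2
  a_cap <- sqrt(w_cell * h_cell)
  cap_vol <- 4 / 3 * A * a_cap          # two half-spheroid caps
  if (cap_vol > V0) {                   # caps alone exceed the cell volume
    a_cap <- V0 / (4 / 3 * A)
    body <- 0
  } else {
    body <- (V0 - cap_vol) / A
  }
  list(area = A, r_corner = rg, a_cap = a_cap, body_length = body,
       length = body + 2 * a_cap, volume = A * body + 4 / 3 * A * a_cap,
       l_band = max(body, 0.5))
}

# fast, clamped (no domain check) imaginary/actual lumen profile closures
.profiles <- function(channel) {
  xin <- channel$x_inlet; xout <- channel$x_outlet
  clampx <- function(x) pmin(pmax(x, xin), xout)
  if (inherits(channel, "axisym_channel")) {
    c_lat <- channel$r_min + channel$r_con
    r_arc <- channel$r_con + channel$delta
    wide <- channel$r_pipe
    span <- sqrt(r_arc^2 - (c_lat - wide)^2)
    hw <- function(x) {
      x <- clampx(x)
      out <- rep(wide, length(x))
      i <- abs(x) <= span
      out[i] <- c_lat - sqrt(r_arc^2 - x[i]^2)
      pmin(out, wide)
    }
    list(hw = hw, hh = hw, c_lat = c_lat, x_half = span,
         area = function(x) pi * hw(x)^2, axisym = TRUE)
  } else {
    c_lat <- channel$W_con / 2 + channel$R_con
    r_arc <- channel$R_con + channel$delta
    wide <- channel$W / 2 - channel$delta
    span <- sqrt(r_arc^2 - (c_lat - wide)^2)
    hw <- function(x) {
      x <- clampx(x)
      out <- rep(wide, length(x))
      i <- abs(x) <= span
      out[i] <- c_lat - sqrt(r_arc^2 - x[i]^2)
      pmin(out, wide)
    }
    H <- channel$H; Hin <- channel$H_inlet; rmp <- channel$ramp
    d2 <- channel$delta
    hh <- if (H >= Hin) {
      function(x) rep((H - 2 * d2) / 2, length(x))
    } else {
      function(x) {
        x <- clampx(x)
        h <- ifelse(x <= rmp[1], Hin,
                    ifelse(x >= rmp[2], H,
                           Hin + (H - Hin) * (x - rmp[1]) / (rmp[2] - rmp[1])))
        (h - 2 * d2) / 2
      }
    }
    list(hw = hw, hh = hh, c_lat = c_lat, x_half = span,
         area = function(x) 4 * hw(x) * hh(x), axisym = FALSE)
  }
}

# required half-extent so the capsule (body + sampled cap profile) clears
# the given lumen profile; prof is a half-extent profile function of x
.req_extent <- function(prof, x_mid, body, a_cap, x_back = x_mid,
                        u = c(0.15, 0.3, 0.45, 0.6, 0.72, 0.83, 0.92, 0.975)) {
  # governing body point, over the interval swept since x_back so a large
  # step cannot tunnel the body past the throat unchecked
  xb <- max(min(0, x_mid + body / 2), x_back - body / 2)
  lead <- x_mid + body / 2 + a_cap * u
  trail <- x_mid - body / 2 - a_cap * u
  scale <- sqrt(1 - u^2)
  min(prof(xb), prof(lead) / scale, prof(trail) / scale)
}

#' Simulate the transit of a cell through a constricted channel
#'
#' Quasi-static time stepping of the reduced-order model.  At each step the
#' cell's lateral and vertical half-extents must clear the imaginary-wall
#' lumen everywhere along the capsule; the advance velocity is the largest
#' value, up to the hydraulic (pressure-driven) velocity, for which Maxwell
#' creep of the interior under the wall reaction stress can supply the
#' squeezing the constriction demands.  The pressure drop actually driving
#' the cell follows from the series-parallel leakage network
#' (\code{\link{pressure_partition}}); corner-gutter conductance follows
#' the current cell cross-section.  Volume is conserved exactly by the
#' shape family (\code{\link{cell_shape}}).
#'
#' Lateral squeezing splits between vertical bulge and axial elongation
#' with partition exponent \code{chi} (vertical half-extent
#' \code{R (R/w)^chi} before any ceiling constraint); \code{chi = 0} is
#' used automatically for the axisymmetric channel.
#'
#' @param channel an \code{\link{axisym_channel}} or \code{\link{rect_channel}}.
#' @param cell a \code{\link{cell_model}}.
#' @param plasma a \code{\link{plasma_model}}.
#' @param dP_total pressure drop across the channel, Pa.
#' @param dt time step, s.
#' @param x_start initial axial position of the cell center, um.
#' @param max_steps step budget; the run is reported incomplete beyond it.
#' @param chi vertical bulge partition exponent (rectangular channel).
#' @param k_gutter gutter duct shape factor (see
#'   \code{\link{gutter_conductance}}).
#' @param l_min floor on the contact-band width, um.
#' @return an object of class \code{"transit_record"}: time series of
#'   position, axial velocity, driving pressure, half-extents and contact
#'   flags, detected velocity peaks, the transit time \code{T} (time
#'   between the first and last velocity peak) and completion flags.
#' @seealso \code{\link{detect_velocity_peaks}}, \code{\link{transit_time}}
#' @export
simulate_transit <- function(channel, cell = cell_model(),
                             plasma = plasma_model(), dP_total = 40,
                             dt = 0.001, x_start = NULL, max_steps = 20000,
                             chi = 0.5, k_gutter = 0.5, l_min = 1.5) {
  stopifnot(dt > 0, dP_total >= 0, max_steps >= 1)
  pr <- .profiles(channel)
  if (is.null(x_start)) x_start <- -20
  if (pr$axisym) chi <- 0
  R <- cell$R_cell
  mu <- cell$mu_cell
  Tc <- cell$cortical_tension
  lam <- relaxation_time(cell)
  E <- exp(-dt / lam)
  mfac <- mu * (1 - E)
  cumR <- .channel_resistance_fun(channel, plasma)
  R_open <- cumR(channel$x_outlet) - cumR(channel$x_inlet)
  pcrit <- function(r) pmax(0, 2 * Tc * (1 / pmin(r, R) - 1 / R))
  reff <- function(x) {
    w <- pr$hw(x); h <- pr$hh(x)
    pmin(R, 2 * w * h / (w + h))
  }

  # state; the initial shape conforms to the local lumen at x_start with
  # fully relaxed stresses (the cell starts at rest inside the channel,
  # pre-compressed by any shallow section it already sits in)
  x <- x_start
  w <- R; h <- R
  for (it in 1:30) {
    shp0 <- cell_shape(w, h, cell)
    wr0 <- .req_extent(pr$hw, x, shp0$body_length, shp0$a_cap)
    hr0 <- .req_extent(pr$hh, x, shp0$body_length, shp0$a_cap)
    w2 <- min(w, wr0)
    h2 <- if (pr$axisym) w2 else min(R * (R / w2)^chi, hr0)
    if (abs(w2 - w) < 1e-13 && abs(h2 - h) < 1e-13) { w <- w2; h <- h2; break }
    w <- w2; h <- h2
  }
  eps_v <- if (pr$axisym) 0 else max(0, 1 - h / (R * (R / w)^chi))
  sig_l <- 0; sig_v <- 0
  dP_cell <- NA_real_
  stall_run <- 0

  n <- max_steps
  out_t <- numeric(n); out_x <- numeric(n); out_v <- numeric(n)
  out_dp <- numeric(n); out_w <- numeric(n); out_h <- numeric(n)
  out_cs <- logical(n); out_cc <- logical(n)
  vol_err_max <- 0; clear_min <- Inf
  completed <- FALSE; stalled <- FALSE
  V0 <- 4 / 3 * pi * R^3

  for (i in seq_len(n)) {
    shp <- cell_shape(w, h, cell)
    body <- shp$body_length; acap <- shp$a_cap; A_cs <- shp$area
    x_tr <- x - body / 2 - acap
    x_ld <- x + body / 2 + acap
    wr0 <- .req_extent(pr$hw, x, body, acap)
    hr0 <- .req_extent(pr$hh, x, body, acap)
    side <- w >= wr0 - 1e-6
    ceil <- h >= hr0 - 1e-6
    # occluded when a contacting dimension is inside the constriction, or
    # (at the exact-touch threshold) when the requirement shrinks just
    # ahead, so a cell resting against a ramp still builds plug pressure
    wr_a <- .req_extent(pr$hw, x + 0.25, body, acap)
    hr_a <- .req_extent(pr$hh, x + 0.25, body, acap)
    occluded <- (side && (wr0 < pr$hw(channel$x_inlet) - 1e-9 ||
                            wr_a < w - 1e-9)) ||
      (ceil && (hr0 < pr$hh(channel$x_inlet) - 1e-9 || hr_a < h - 1e-9))

    # resisting pressure: entry barrier ahead minus release behind
    dPr <- pcrit(reff(x_ld)) - pcrit(reff(x_tr))

    # hydraulics: once any wall contact exists the cell is a leaky plug in
    # a series-parallel network; the pressure drop across it supplies the
    # reaction stress.  A free cell rides the plasma near centerline speed.
    if (occluded) {
      gut <- .gutters(pr, w, h, wr0, hr0, A_cs, side, ceil)
      C_g <- gutter_conductance(gut$areas, gut$perims,
                                max(body + acap, 1), plasma, k = k_gutter)
      R_u <- cumR(max(x_tr, channel$x_inlet)) - cumR(channel$x_inlet)
      R_d <- cumR(channel$x_outlet) - cumR(min(x_ld, channel$x_outlet))
      Rs <- R_u + R_d
      V_up <- if (dP_total > dPr)
        max(0, ((dP_total - dPr) / Rs - C_g * max(dPr, 0)) / A_cs) else 0
    } else {
      C_g <- 0; Rs <- R_open
      A_lum <- pr$area(x)
      rho <- min(1, A_cs / A_lum)
      V_up <- (2 - rho) * (dP_total / R_open) / A_lum
    }

    # driving pressure for a candidate step velocity: the network solution
    # with the cell's piston flux included.  Solving this inside the
    # feasibility check (rather than lagging last step's value) makes the
    # pressure-velocity coupling implicit; a lagged value limit-cycles at
    # period 2 dt because an advance step depresses the pressure that the
    # next step needs to sustain the advance
    dp_at <- function(V) {
      if (!occluded) return(0)
      min(max((dP_total - V * A_cs * Rs) / (1 + C_g * Rs), 0), dP_total)
    }

    # unconstrained (recovery) evolution under cortical tension alone
    rl_free <- (-2 * Tc * (1 / w - 1 / R) - sig_l * E) / mfac
    w_unc <- min(R, w - R * rl_free * dt)
    rv_free <- (-2 * Tc * (1 / h - 1 / R) - sig_v * E) / mfac
    eps_v_unc <- eps_v + rv_free * dt

    # applied squeezing stresses of a candidate (destination) configuration:
    # reaction stress from the plugged-cell force balance, projected with
    # the angular efficiency sin(theta)*(1 - cos(theta)) laterally and
    # taken at theta = pi/2 against the flat ceiling/floor
    sapp_at <- function(xn, wn, hn, body_n, dp_drv) {
      wr_n <- .req_extent(pr$hw, xn, body_n, sqrt(wn * hn), x_back = x)
      hr_n <- .req_extent(pr$hh, xn, body_n, sqrt(wn * hn), x_back = x)
      r_g <- min(R, 2 * wr_n * hr_n / (wr_n + hr_n))
      # contact-band width: a straight capsule in an arc-walled channel
      # touches the wall only in a narrow band near the tangency station
      # (it never conforms over its whole body), so the band scale is a
      # fixed geometric length, not the body length
      l_n <- l_min
      # seal fraction: only the blocked share of the lumen pressure force
      # loads the cell; the rest is carried by the bypassing plasma
      rg_n <- min(wn, hn)
      A_n <- if (pr$axisym) pi * wn^2 else 4 * wn * hn - (4 - pi) * rg_n^2
      A_lum_n <- if (pr$axisym) pi * wr_n^2 else 4 * wr_n * hr_n
      phi <- min(1, A_n / A_lum_n)
      b <- max(0, dp_drv - pcrit(r_g)) * phi * r_g^2 / (2 * l_n)
      thn <- atan2(pr$c_lat, max(0, -(xn + body_n / 2)))
      c(lat = b / max(wn, 0.1) * (1 - cos(thn)), vert = b / max(hn, 0.1))
    }

    # a step is feasible when the Maxwell stress implied by the squeezing
    # the walls demand does not exceed the stress the pressure can apply
    # in the destination configuration (implicit quasi-static balance)
    feas <- function(V) {
      xn <- x + V * dt
      wrn <- .req_extent(pr$hw, xn, body, acap, x_back = x)
      wn <- min(w_unc, wrn)
      hbn <- R * (R / wn)^chi
      hrn <- .req_extent(pr$hh, xn, body, acap, x_back = x)
      hn <- if (pr$axisym) wn else min(hbn * (1 - eps_v_unc), hrn)
      shp_n <- cell_shape(wn, hn, cell)
      sap <- sapp_at(xn, wn, hn, shp_n$body_length, dp_at(V))
      rate_l_n <- (w - wn) / (R * dt)
      if (rate_l_n > 0 && sig_l * E + mfac * rate_l_n > sap[["lat"]] + 1e-9)
        return(FALSE)
      # the vertical stress gate applies only where the ceiling/floor
      # profile descends along the advance (a sloped wall does axial work
      # on the cell); a flat frictionless ceiling clamps the height but
      # cannot retard the advance
      if (!pr$axisym && hrn < h - 1e-12) {
        evn <- 1 - hn / hbn
        rate_v_n <- (evn - eps_v) / dt
        if (rate_v_n > 0 && sig_v * E + mfac * rate_v_n > sap[["vert"]] + 1e-9)
          return(FALSE)
      }
      TRUE
    }

    if (V_up <= 0 || feas(V_up)) {
      V <- max(V_up, 0)
    } else {
      lo <- 0; hi <- V_up
      for (k in 1:32) {
        mid <- (lo + hi) / 2
        if (feas(mid)) lo <- mid else hi <- mid
      }
      V <- lo
    }

    # commit: walls are rigid — clamp to the lumen, iterating because the
    # body elongates (volume conservation) as the cross-section shrinks
    xn <- x + V * dt
    wrn <- .req_extent(pr$hw, xn, body, acap, x_back = x)
    hrn <- .req_extent(pr$hh, xn, body, acap, x_back = x)
    wn <- min(w_unc, wrn)
    hn <- if (pr$axisym) wn else
      min(R * (R / wn)^chi * (1 - eps_v_unc), hrn)
    for (it in 1:30) {
      shpn <- cell_shape(wn, hn, cell)
      wrn <- .req_extent(pr$hw, xn, shpn$body_length, shpn$a_cap, x_back = x)
      hrn <- .req_extent(pr$hh, xn, shpn$body_length, shpn$a_cap, x_back = x)
      w2 <- min(wn, wrn)
      h2 <- if (pr$axisym) w2 else
        min(R * (R / w2)^chi * (1 - eps_v_unc), hrn)
      if (abs(w2 - wn) < 1e-13 && abs(h2 - hn) < 1e-13) { wn <- w2; hn <- h2; break }
      wn <- w2; hn <- h2
    }
    ev_new <- if (pr$axisym) 0 else 1 - hn / (R * (R / wn)^chi)
    rate_l <- (w - wn) / (R * dt)
    sig_l <- sig_l * E + mfac * rate_l
    if (!pr$axisym) {
      rate_v <- (ev_new - eps_v) / dt
      sig_v <- sig_v * E + mfac * rate_v
    }

    dP_cell <- if (occluded) dp_at(V) else NA_real_

    x <- xn; w <- wn; h <- hn; eps_v <- ev_new

    out_t[i] <- i * dt; out_x[i] <- x; out_v[i] <- V
    out_dp[i] <- dP_cell; out_w[i] <- w; out_h[i] <- h
    out_cs[i] <- side; out_cc[i] <- ceil
    shp2 <- cell_shape(w, h, cell)
    vol_err_max <- max(vol_err_max, abs(shp2$volume - V0) / V0)
    clear_min <- min(clear_min, wrn - w, hrn - h)

    stall_run <- if (V < 1e-7) stall_run + 1 else 0
    if (stall_run * dt > 2) { stalled <- TRUE; break }
    x_tr_new <- x - shp2$body_length / 2 - shp2$a_cap
    if (x_tr_new > pr$x_half || x + shp2$length / 2 >= channel$x_outlet - 1) {
      completed <- TRUE
      break
    }
  }

  keep <- seq_len(min(i, n))
  rec <- list(t = out_t[keep], x = out_x[keep], v = out_v[keep],
              dP_cell = out_dp[keep], w = out_w[keep], h = out_h[keep],
              contact_side = out_cs[keep], contact_ceiling = out_cc[keep],
              volume_error_max = vol_err_max, clearance_min = clear_min,
              completed = completed, stalled = stalled,
              channel = channel, cell = cell, dP_total = dP_total, dt = dt)
  # single-sample dips (e.g. the last free-flight step truncated to the
  # exact touch distance) are below the scheme's time resolution; a 3-point
  # median despike removes them before peak detection
  pk <- tryCatch(detect_velocity_peaks(stats::runmed(rec$v, 3)),
                 error = function(e) integer(0))
  rec$peaks <- pk
  rec$T <- if (length(pk) >= 2 && completed)
    rec$t[pk[length(pk)]] - rec$t[pk[1]] else NA_real_
  rec$T_lower <- if (!completed && length(pk) >= 1)
    rec$t[length(rec$t)] - rec$t[pk[1]] else NA_real_
  class(rec) <- "transit_record"
  rec
}

# corner-gutter cross sections at the governing lumen station.  With four-
# wall contact the free area is the four rounded-corner clearances; without
# ceiling contact (or without side contact) the gutters on each side unite
# into two larger channels.
.gutters <- function(pr, w, h, wr, hr, A_cs, side, ceil) {
  if (pr$axisym)
    return(list(areas = 0, perims = 1, united = FALSE))
  A_lum <- 4 * wr * hr
  A_free <- max(0, A_lum - A_cs)
  rg <- min(w, h)
  if (side && ceil) {
    list(areas = rep(A_free / 4, 4),
         perims = rep((2 + pi / 2) * max(rg, 0.1), 4), united = FALSE)
  } else if (side) {
    list(areas = rep(A_free / 2, 2),
         perims = rep(4 * wr + 2 * max(hr - h, 0.05), 2), united = TRUE)
  } else {
    list(areas = rep(A_free / 2, 2),
         perims = rep(4 * hr + 2 * max(wr - w, 0.05), 2), united = TRUE)
  }
}

#' Detect velocity peaks of a transit record
#'
#' Local maxima of the axial-velocity series with topographic prominence of
#' at least \code{prominence} times the maximum velocity (ties broken by
#' the earliest index).  A transit shows two such peaks: just before the
#' cell contacts the constriction side walls, and at expulsion through the
#' throat.
#'
#' @param v a numeric velocity series, or a \code{transit_record}.
#' @param prominence minimum prominence as a fraction of \code{max(v)}.
#' @return integer indices of the qualifying peaks, in time order.
#' @export
detect_velocity_peaks <- function(v, prominence = 0.05) {
  if (inherits(v, "transit_record")) v <- v$v
  if (length(v) < 3) stop("need at least 3 samples to detect peaks")
  vp <- c(0, v, 0)      # the cell starts from and ends at rest
  # compress equal-value runs so a flat-topped peak counts once (reported
  # at the first sample of its plateau)
  r <- rle(vp)
  vals <- r$values
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  n <- length(vals)
  cand <- which(diff(sign(diff(vals))) < 0) + 1
  vmax <- max(v)
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    k <- i
    while (k > 1 && vals[k - 1] <= vals[i]) k <- k - 1
    lo_l <- min(vals[k:i])
    k <- i
    while (k < n && vals[k + 1] <= vals[i]) k <- k + 1
    lo_r <- min(vals[i:k])
    keep[j] <- vals[i] - max(lo_l, lo_r) >= prominence * vmax
  }
  starts[cand[keep]] - 1L
}

#' Transit time from a transit record
#'
#' Time between the first and last qualifying velocity peaks.  Uses the
#' peaks stored on the record when present (the simulator despikes its
#' trace before detecting them); otherwise detects peaks on the raw trace.
#'
#' @param record a \code{transit_record}.
#' @return transit time, s.
#' @export
transit_time <- function(record) {
  pk <- if (length(record$peaks) >= 2) record$peaks
        else detect_velocity_peaks(record$v)
  if (length(pk) < 2)
    stop("no transit time: fewer than two velocity peaks detected")
  record$t[pk[length(pk)]] - record$t[pk[1]]
}

#' @export
print.transit_record <- function(x, ...) {
  cat("Transit record\n")
  cat(sprintf("  %d steps of %g s (%.3f s simulated)\n",
              length(x$t), x$dt, x$t[length(x$t)]))
  if (x$completed) {
    if (!is.na(x$T))
      cat(sprintf("  completed; transit time T = %.3f s (%d velocity peaks)\n",
                  x$T, length(x$peaks)))
    else
      cat("  completed; no transit time (fewer than two velocity peaks)\n")
  } else if (x$stalled) {
    cat(sprintf("  stalled (cell cannot pass); T > %.3f s\n",
                ifelse(is.na(x$T_lower), 0, x$T_lower)))
  } else {
    cat(sprintf("  incomplete (step budget); T > %.3f s\n",
                ifelse(is.na(x$T_lower), 0, x$T_lower)))
  }
  invisible(x)
}

#' @export
summary.transit_record <- function(object, ...) {
  x <- object
  cat(sprintf("Transit of a %.1f um cell, dP = %g Pa\n",
              x$cell$R_cell, x$dP_total))
  print(x)
  cat(sprintf("  straight-region velocity %.0f um/s; minimum velocity %.2f um/s\n",
              max(x$v), min(x$v[x$v > 0])))
  cat(sprintf("  max |volume error| %.2e (relative); min wall clearance %.2e um\n",
              x$volume_error_max, x$clearance_min))
  cat(sprintf("  tightest half-extents: w = %.3f um, h = %.3f um\n",
              min(x$w), min(x$h)))
  invisible(x)
}

#' @export
as.data.frame.transit_record <- function(x, ...) {
  data.frame(t = x$t, x = x$x, v = x$v, dP_cell = x$dP_cell,
             w = x$w, h = x$h, contact_side = x$contact_side,
             contact_ceiling = x$contact_ceiling)
}

#' Plot a transit record
#'
#' Axial velocity (left axis) and cell midpoint position (right axis)
#' against time, with the detected velocity peaks marked.
#'
#' @param x a \code{transit_record}.
#' @param ... passed to \code{plot}.
#' @export
plot.transit_record <- function(x, ...) {
  op <- par(mar = c(4, 4, 2, 4))
  on.exit(par(op))
  plot(x$t, x$v, type = "l", xlab = "time (s)",
       ylab = "axial velocity (um/s)", ...)
  if (length(x$peaks))
    points(x$t[x$peaks], x$v[x$peaks], pch = 19, col = 2)
  par(new = TRUE)
  plot(x$t, x$x, type = "l", lty = 2, axes = FALSE, xlab = "", ylab = "",
       col = 4)
  axis(4, col.axis = 4)
  mtext("position (um)", side = 4, line = 2.5, col = 4)
  invisible(x)
}
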