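#' Reference scenario grids
#'
#' The parameter grids of the study's experiments, as complete run
#' configurations (channel + cell + plasma + pressure drop + time step):
#' \describe{
#'   \item{control}{the rectangular control geometry, H = 8.2 um,
#'     R_con = 27.525 um, W_con = 4.368 um at dP = 40 Pa.}
#'   \item{height}{channel height H swept over 7.2--16.2 um (the printed
#'     endpoints plus the height of the maximally deformed cell, 10.86 um,
#'     and intermediate stations).}
#'   \item{width}{throat width W_con in {3.112, 4.368, 5.7} um: equal
#'     throat area, equal throat hydraulic diameter, and equal width
#'     relative to the axisymmetric capillary.}
#'   \item{radius}{constriction curvature radius R_con in
#'     {16.15, 27.525, 42.15} um.}
#'   \item{aspect}{the three equal-hydraulic-diameter (5.7 um)
#'     height/width combinations (7.2, 4.717), (8.2, 4.368), (10.2, 3.955).}
#'   \item{axisym}{the axisymmetric capillary model.}
#' }
#'
#' @param experiment one of \code{"control"}, \code{"height"},
#'   \code{"width"}, \code{"radius"}, \code{"aspect"}, \code{"axisym"}.
#' @return an object of class \code{"scenario_grid"}: a named list with
#'   \code{name} and \code{configs}.
#' @examples
#' scenario_grid("aspect")
#' @export
scenario_grid <- function(experiment = c("control", "height", "width",
                                         "radius", "aspect", "axisym")) {
  experiment <- match.arg(experiment)
  base <- function(channel, parameter = NA_character_, value = NA_real_,
                   id = NULL, provenance = "reference") {
    list(id = id, channel = channel, cell = cell_model(),
         plasma = plasma_model(), dP_total = 40, dt = 0.001,
         parameter = parameter, value = value, provenance = provenance)
  }
  configs <- switch(
    experiment,
    control = list(base(rect_channel(), id = "control",
                        provenance = "reference-control")),
    height = {
      Hs <- c(7.2, 8.2, 9.2, 10.2, 10.86, 11.2, 12.2, 14.2, 16.2)
      lapply(Hs, function(H)
        base(rect_channel(H = H), parameter = "H", value = H,
             id = sprintf("H_%.2f", H)))
    },
    width = {
      Ws <- c(3.112, 4.368, 5.7)
      lapply(Ws, function(W)
        base(rect_channel(W_con = W), parameter = "W_con", value = W,
             id = sprintf("Wcon_%.3f", W)))
    },
    radius = {
      Rs <- c(16.15, 27.525, 42.15)
      lapply(Rs, function(R)
        base(rect_channel(R_con = R), parameter = "R_con", value = R,
             id = sprintf("Rcon_%.3f", R)))
    },
    aspect = {
      HW <- list(c(7.2, 4.717), c(8.2, 4.368), c(10.2, 3.955))
      lapply(seq_along(HW), function(k)
        base(rect_channel(H = HW[[k]][1], W_con = HW[[k]][2]),
             parameter = "aspect", value = HW[[k]][1] / HW[[k]][2],
             id = sprintf("aspect_%d", k)))
    },
    axisym = list(base(axisym_channel(), id = "axisym",
                       provenance = "reference-axisym")))
  structure(list(name = experiment, configs = configs),
            class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf("Scenario grid '%s': %d configuration(s)\n",
              x$name, length(x$configs)))
  invisible(x)
}

#' Random valid rectangular-channel scenarios
#'
#' Reproducible random geometries for property testing.  Ranges are chosen
#' so every draw is a valid channel in which the cell contacts the
#' constriction side walls (squeeze length defined).
#'
#' @param seed integer seed; the grid is a pure function of it.
#' @param n number of configurations.
#' @param H_range,W_con_range,R_con_range parameter ranges, um.
#' @return a \code{"scenario_grid"}.
#' @export
random_scenarios <- function(seed, n,
                             H_range = c(7.2, 16.2),
                             W_con_range = c(2.6, 6.5),
                             R_con_range = c(10.5, 45)) {
  stopifnot(n >= 1)
  if (W_con_range[2] / 2 - 0.1 >= cell_model()$R_cell)
    stop("infeasible range: widest throat would not contact the cell")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  configs <- lapply(seq_len(n), function(j) {
    H <- runif(1, H_range[1], H_range[2])
    W <- runif(1, W_con_range[1], W_con_range[2])
    R <- runif(1, max(R_con_range[1], (22.36 - W) / 2 + 0.5), R_con_range[2])
    list(id = sprintf("rand_%d", j),
         channel = rect_channel(H = H, W_con = W, R_con = R),
         cell = cell_model(), plasma = plasma_model(),
         dP_total = 40, dt = 0.001,
         parameter = "random", value = NA_real_, provenance = "random")
  })
  structure(list(name = sprintf("random_seed%d", seed), configs = configs),
            class = "scenario_grid")
}

#' Synthetic two-peak velocity trace
#'
#' A smooth velocity series with Gaussian peaks at known times over a known
#' baseline, optionally perturbed with reproducible noise: a fixture for
#' peak detection and the transit-time definition.
#'
#' @param peak_times peak centers, s.
#' @param peak_heights peak heights above baseline, um/s.
#' @param peak_widths Gaussian standard deviations, s.
#' @param baseline baseline velocity, um/s.
#' @param t_end trace length, s.
#' @param dt sampling step, s.
#' @param noise noise amplitude as a fraction of the maximum velocity.
#' @param seed seed for the noise (ignored when \code{noise = 0}).
#' @return a minimal object of class \code{"transit_record"} with fields
#'   \code{t}, \code{v}, \code{x}.
#' @export
synthetic_velocity_trace <- function(peak_times = c(0.05, 0.90),
                                     peak_heights = c(300, 400),
                                     peak_widths = c(0.01, 0.02),
                                     baseline = 20, t_end = 1, dt = 0.001,
                                     noise = 0, seed = 1) {
  stopifnot(all(peak_times >= 0), all(peak_times <= t_end))
  t <- seq(dt, t_end, by = dt)
  v <- rep(baseline, length(t))
  for (k in seq_along(peak_times))
    v <- v + peak_heights[k] * exp(-(t - peak_times[k])^2 /
                                     (2 * peak_widths[k]^2))
  if (noise > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    v <- v + noise * max(v) * rnorm(length(v))
  }
  structure(list(t = t, v = v, x = cumsum(v) * dt, dt = dt,
                 completed = TRUE, stalled = FALSE,
                 peaks = integer(0), T = NA_real_),
            class = "transit_record")
}

#' Synthetic power-law samples
#'
#' \code{y = coeff x^exponent exp(eps)} with \code{eps ~ N(0, sigma^2)},
#' reproducible from the seed: a fixture for the log-log fitting machinery.
#'
#' @param x positive abscissae.
#' @param coeff,exponent power-law parameters.
#' @param sigma lognormal noise scale (0 gives exact data).
#' @param seed seed for the noise.
#' @return a \code{data.frame} with columns \code{x}, \code{y}.
#' @export
synthetic_powerlaw_samples <- function(x, coeff, exponent, sigma = 0,
                                       seed = 1) {
  stopifnot(all(x > 0), coeff > 0)
  y <- coeff * x^exponent
  if (sigma > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    y <- y * exp(rnorm(length(x), 0, sigma))
  }
  data.frame(x = x, y = y)
}
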