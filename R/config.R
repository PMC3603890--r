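#' Read a run configuration from a YAML file
#'
#' A run configuration holds a \code{channel} block
#' (\code{channel_type: axisym} with \code{L, r_pipe, r_con, r_min, delta},
#' or \code{channel_type: rect} with \code{W, L, H, R_con, W_con, delta}),
#' an optional \code{cell} block (\code{mu_cell_Pa_s, G_cell_Pa,
#' cortical_tension_pN_per_um, R_cell_um, poisson, membrane_E_Pa,
#' membrane_thickness_nm}), an optional \code{plasma} block
#' (\code{viscosity_Pa_s, density_kg_m3}) and optional scalars
#' \code{dP_total} (Pa) and \code{dt} (s).  Missing blocks take the model
#' defaults.
#'
#' @param path path to a YAML file.
#' @return a run-config list usable as one element of a sweep grid.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geo <- cfg$channel
  if (is.null(geo) || is.null(geo$channel_type))
    stop("config must contain a channel block with channel_type")
  pick <- function(lst, nm, default) if (is.null(lst[[nm]])) default else lst[[nm]]
  channel <- if (geo$channel_type == "axisym") {
    axisym_channel(L = pick(geo, "L", 150), r_pipe = pick(geo, "r_pipe", 6),
                   r_con = pick(geo, "r_con", 27.525),
                   r_min = pick(geo, "r_min", 2.85),
                   delta = pick(geo, "delta", 0.1))
  } else if (geo$channel_type == "rect") {
    rect_channel(W = pick(geo, "W", 22.36), L = pick(geo, "L", 150),
                 H = pick(geo, "H", 8.2), R_con = pick(geo, "R_con", 27.525),
                 W_con = pick(geo, "W_con", 4.368),
                 delta = pick(geo, "delta", 0.1))
  } else stop("channel_type must be 'axisym' or 'rect'")
  cl <- cfg$cell
  cell <- cell_model(
    mu_cell = pick(cl, "mu_cell_Pa_s", 31),
    G_cell = pick(cl, "G_cell_Pa", 186),
    cortical_tension = pick(cl, "cortical_tension_pN_per_um", 31),
    R_cell = pick(cl, "R_cell_um", 4),
    poisson = pick(cl, "poisson", 0.4999),
    membrane_E = pick(cl, "membrane_E_Pa", 1e-4),
    membrane_thickness = pick(cl, "membrane_thickness_nm", 1))
  pl <- cfg$plasma
  plasma <- plasma_model(viscosity = pick(pl, "viscosity_Pa_s", 1.2e-3),
                         density = pick(pl, "density_kg_m3", 1.03e3))
  list(id = pick(cfg, "id", basename(path)), channel = channel, cell = cell,
       plasma = plasma, dP_total = pick(cfg, "dP_total", 40),
       dt = pick(cfg, "dt", 0.001))
}

#' Write a run configuration to a YAML file
#'
#' @param config a run-config list (as from \code{\link{read_run_config}}
#'   or an element of a \code{\link{scenario_grid}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  ch <- config$channel
  geo <- if (inherits(ch, "axisym_channel")) {
    list(channel_type = "axisym", L = ch$L, r_pipe = ch$r_pipe,
         r_con = ch$r_con, r_min = ch$r_min, delta = ch$delta)
  } else {
    list(channel_type = "rect", W = ch$W, L = ch$L, H = ch$H,
         R_con = ch$R_con, W_con = ch$W_con, delta = ch$delta)
  }
  cl <- config$cell %||% cell_model()
  pl <- config$plasma %||% plasma_model()
  yaml::write_yaml(list(
    id = config$id %||% "run",
    channel = geo,
    cell = list(mu_cell_Pa_s = cl$mu_cell, G_cell_Pa = cl$G_cell,
                cortical_tension_pN_per_um = cl$cortical_tension,
                R_cell_um = cl$R_cell, poisson = cl$poisson,
                membrane_E_Pa = cl$membrane_E,
                membrane_thickness_nm = cl$membrane_thickness),
    plasma = list(viscosity_Pa_s = pl$viscosity, density_kg_m3 = pl$density),
    dP_total = config$dP_total %||% 40,
    dt = config$dt %||% 0.001), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
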