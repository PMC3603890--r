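#' Run a sweep of transit simulations
#'
#' Simulates every configuration of a scenario grid and collects one row
#' per configuration with the throat hydraulic diameter, aspect ratio,
#' squeeze length, first-contact angle and transit time.  Failed or
#' incomplete runs are recorded (with a lower-bound transit time where a
#' first velocity peak exists), never fatal.
#'
#' @param grid a \code{\link{scenario_grid}} or plain list of run configs
#'   (each a list with \code{channel}, and optionally \code{cell},
#'   \code{plasma}, \code{dP_total}, \code{dt}).
#' @param ... further arguments passed to \code{\link{simulate_transit}}.
#' @param keep_records keep the full \code{transit_record}s as an attribute.
#' @return a \code{data.frame} of class \code{"sweep_result"}.
#' @export
run_sweep <- function(grid, ..., keep_records = FALSE) {
  configs <- if (inherits(grid, "scenario_grid")) grid$configs else grid
  rows <- vector("list", length(configs))
  recs <- if (keep_records) vector("list", length(configs)) else NULL
  for (j in seq_along(configs)) {
    cf <- configs[[j]]
    ch <- cf$channel
    cell <- if (is.null(cf$cell)) cell_model() else cf$cell
    plas <- if (is.null(cf$plasma)) plasma_model() else cf$plasma
    dP <- if (is.null(cf$dP_total)) 40 else cf$dP_total
    dt <- if (is.null(cf$dt)) 0.001 else cf$dt
    rec <- tryCatch(
      simulate_transit(ch, cell, plas, dP_total = dP, dt = dt, ...),
      error = function(e) e)
    failed <- inherits(rec, "error")
    if (keep_records && !failed) recs[[j]] <- rec
    fc <- tryCatch(first_contact(ch, cell$R_cell),
                   error = function(e)
                     list(s = NA_real_, theta = NA_real_,
                          contact_exists = NA))
    geo <- tryCatch({
      if (inherits(ch, "rect_channel")) {
        H_throat <- rect_height_at(ch, 0)
        c(hydraulic_diameter(H_throat, ch$W_con), H_throat / ch$W_con)
      } else {
        c(2 * ch$r_min, 1)
      }
    }, error = function(e) c(NA_real_, NA_real_))
    dh <- geo[1]; aspect <- geo[2]
    rows[[j]] <- data.frame(
      id = if (is.null(cf$id)) paste0("config_", j) else cf$id,
      parameter = if (is.null(cf$parameter)) NA_character_ else cf$parameter,
      value = if (is.null(cf$value)) NA_real_ else cf$value,
      D_h_throat = dh, aspect_ratio = aspect,
      squeeze_length = fc$s, theta_first_contact = fc$theta,
      T = if (failed) NA_real_ else rec$T,
      T_lower = if (failed) NA_real_ else rec$T_lower,
      completed = if (failed) FALSE else rec$completed,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(stringsAsFactors = FALSE)))
  if (is.null(out)) out <- data.frame()
  class(out) <- c("sweep_result", "data.frame")
  if (keep_records) attr(out, "records") <- recs
  out
}

#' Hydraulic-diameter collapse of transit times
#'
#' Groups sweep rows by throat hydraulic diameter and reports, per group,
#' the mean transit time and the maximum relative deviation from that
#' mean, flagging groups whose spread exceeds \code{tol}.  Used to test the
#' claim that transit time is dominated by the throat hydraulic diameter
#' (so equal-\code{D_h} configurations of different aspect ratio should
#' collapse).
#'
#' @param sweep a \code{\link{run_sweep}} result.
#' @param tol flagging tolerance on the maximum relative deviation.
#' @param digits rounding applied to \code{D_h} to form groups.
#' @return a \code{data.frame} with one row per \code{D_h} group.
#' @export
dh_collapse <- function(sweep, tol = 0.1, digits = 2) {
  stopifnot(nrow(sweep) >= 1)
  g <- round(sweep$D_h_throat, digits)
  out <- do.call(rbind, lapply(split(seq_len(nrow(sweep)), g), function(ix) {
    Ts <- sweep$T[ix]
    Ts <- Ts[!is.na(Ts)]
    m <- if (length(Ts)) mean(Ts) else NA_real_
    dev <- if (length(Ts)) max(abs(Ts - m)) / m else NA_real_
    data.frame(D_h = round(sweep$D_h_throat[ix[1]], digits),
               n = length(ix), n_completed = length(Ts),
               T_mean = m, max_rel_dev = dev,
               within_tol = !is.na(dev) & dev <= tol)
  }))
  rownames(out) <- NULL
  out
}
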