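#' Neutrophil cell model
#'
#' Rheological and geometric parameters of the neutrophil: a homogeneous
#' Maxwell liquid interior (viscosity \code{mu_cell}, shear modulus
#' \code{G_cell}) encapsulated by a thin membrane under a constant cortical
#' tension.  Poisson ratio and the membrane modulus/thickness are recorded
#' for fidelity but unused by the reduced-order model, which imposes
#' incompressibility exactly and neglects membrane bending.
#'
#' Units: \code{cortical_tension} is in pN/um; with radii in um,
#' \code{2 T_c (1/r - 1/R)} is directly in Pa.
#'
#' @param mu_cell interior viscosity, Pa s.
#' @param G_cell elastic shear modulus, Pa.
#' @param cortical_tension cortical tension, pN/um.
#' @param R_cell resting (spherical) cell radius, um.
#' @param poisson Poisson ratio of the interior (recorded).
#' @param membrane_E membrane Young's modulus, Pa (recorded).
#' @param membrane_thickness membrane thickness, nm (recorded).
#'
#' @return an object of class \code{"cell_model"}.
#' @examples
#' cell <- cell_model()
#' relaxation_time(cell)  # 31/186 s
#' @export
cell_model <- function(mu_cell = 31, G_cell = 186, cortical_tension = 31,
                       R_cell = 4, poisson = 0.4999, membrane_E = 1e-4,
                       membrane_thickness = 1) {
  stopifnot(mu_cell > 0, G_cell > 0, cortical_tension > 0, R_cell > 0)
  cell <- list(mu_cell = mu_cell, G_cell = G_cell,
               cortical_tension = cortical_tension, R_cell = R_cell,
               poisson = poisson, membrane_E = membrane_E,
               membrane_thickness = membrane_thickness)
  class(cell) <- "cell_model"
  cell
}

#' @export
print.cell_model <- function(x, ...) {
  cat("Maxwell liquid-drop cell model\n")
  cat(sprintf("  mu_cell = %g Pa s, G_cell = %g Pa (lambda = %.4f s)\n",
              x$mu_cell, x$G_cell, relaxation_time(x)))
  cat(sprintf("  cortical tension %g pN/um, resting radius %g um\n",
              x$cortical_tension, x$R_cell))
  invisible(x)
}

#' Maxwell relaxation time
#'
#' \code{lambda = mu_cell / G_cell}.
#'
#' @param cell a \code{\link{cell_model}}.
#' @return relaxation time, s.
#' @export
relaxation_time <- function(cell) cell$mu_cell / cell$G_cell

#' Maxwell element state
#'
#' Deviatoric stress and accumulated strain of a scalar Maxwell element
#' (spring and dashpot in series).
#'
#' @param sigma current stress, Pa.
#' @param epsilon accumulated strain (dimensionless).
#' @return an object of class \code{"maxwell_state"}.
#' @export
maxwell_state <- function(sigma = 0, epsilon = 0) {
  structure(list(sigma = sigma, epsilon = epsilon),
            class = "maxwell_state")
}

#' Advance a Maxwell element under an imposed strain rate
#'
#' Integrates \code{sigma + lambda sigma_dot = mu eps_dot} over one step
#' with the strain rate held constant, using the exact exponential update
#' \code{sigma' = sigma e^{-dt/lambda} + mu eps_dot (1 - e^{-dt/lambda})}.
#' The update is unconditionally stable and reproduces the analytic stress
#' relaxation \code{sigma_0 e^{-t/lambda}} to machine precision.
#'
#' @param state a \code{\link{maxwell_state}}.
#' @param strain_rate imposed strain rate, 1/s.
#' @param dt time step, s.
#' @param cell a \code{\link{cell_model}}.
#' @return the updated \code{maxwell_state}.
#' @export
maxwell_update <- function(state, strain_rate, dt, cell) {
  stopifnot(dt > 0)
  E <- exp(-dt / relaxation_time(cell))
  maxwell_state(sigma = state$sigma * E + cell$mu_cell * strain_rate * (1 - E),
                epsilon = state$epsilon + strain_rate * dt)
}

#' Strain rate that brings a Maxwell element to a target stress in one step
#'
#' Inverse of \code{\link{maxwell_update}}: the constant strain rate over
#' \code{dt} for which the element's end-of-step stress equals
#' \code{stress}.  At first loading this contains the instantaneous elastic
#' response; once \code{state$sigma} has reached the applied stress it
#' tends to the viscous creep rate \code{stress / mu_cell}.
#'
#' @param state a \code{\link{maxwell_state}}.
#' @param stress target (applied) stress, Pa.
#' @param dt time step, s.
#' @param cell a \code{\link{cell_model}}.
#' @return strain rate, 1/s.
#' @export
maxwell_creep_rate <- function(state, stress, dt, cell) {
  stopifnot(dt > 0)
  E <- exp(-dt / relaxation_time(cell))
  (stress - state$sigma * E) / (cell$mu_cell * (1 - E))
}

#' Critical aspiration pressure of a cortical-tension drop
#'
#' Law-of-Laplace threshold for a liquid drop of resting radius
#' \code{R_cell} held by constant cortical tension to flow into an opening
#' of radius \code{r_throat}: \code{2 T_c (1/r_throat - 1/R_cell)}.  Zero at
#' \code{r_throat = R_cell}; openings wider than the cell pose no barrier
#' (returned as 0 with a warning).
#'
#' @param cell a \code{\link{cell_model}}.
#' @param r_throat opening radius, um (vectorized).
#' @return critical pressure drop, Pa.
#' @examples
#' critical_pressure(cell_model(), 2.75)  # 7.045 Pa
#' @export
critical_pressure <- function(cell, r_throat) {
  if (any(r_throat <= 0)) stop("opening radius must be positive")
  if (any(r_throat > cell$R_cell))
    warning("opening wider than the cell: no plugging, critical pressure 0")
  pmax(0, 2 * cell$cortical_tension * (1 / r_throat - 1 / cell$R_cell))
}

#' Reaction stress on the contact band of a plugged cell
#'
#' Normal stress applied by the constriction surface to the elastically
#' deformed cell, from the axial force balance of the plugged cell: the
#' pressure force in excess of the critical aspiration pressure,
#' \code{(dP - dP_crit) pi r_min^2}, is supported by the ring-shaped
#' contact band of width \code{l} at lateral position \code{r_contact},
#' whose normal has axial component \code{sin(theta)}:
#' \deqn{\tau = (\Delta P - \Delta P_{crit})\, r_{min}^2 /
#'       (2\, r_{contact}\, l \sin\theta),} clipped at zero.
#'
#' @param dP pressure drop across the cell, Pa.
#' @param dP_crit critical aspiration pressure, Pa.
#' @param l width of the contact band, um.
#' @param theta contact angle, radians, in \code{(0, pi/2]}.
#' @param r_contact lateral/radial position of the band center, um.
#' @param r_min throat radius of the constriction, um.
#' @return reaction stress, Pa (non-negative).
#' @export
reaction_stress <- function(dP, dP_crit, l, theta, r_contact, r_min) {
  if (any(l <= 0)) stop("undefined contact: band width must be positive")
  stopifnot(all(theta > 0), all(theta <= pi / 2 + 1e-12), all(r_contact > 0))
  pmax(0, dP - dP_crit) * r_min^2 / (2 * r_contact * l * sin(theta))
}
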