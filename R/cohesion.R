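#' Soil and sediment parameters for the cohesion back-calculation
#'
#' @param d50 Median grain-size diameter, m (clay-loam in these assays:
#'   16e-6 m).
#' @param rho_s Sediment particle density, kg m^-3.
#' @param rho_w Water density, kg m^-3.
#' @param viscosity Dynamic viscosity of water, Pa s.
#' @param bulk_density Dry soil bulk density, g cm^-3 (measured range
#'   1.07-1.27; mid-range default).
#' @param gravity Gravitational acceleration, m s^-2.
#' @return An object of class `soil_params`.
#' @export
soil_params <- function(d50 = 16e-6, rho_s = 2650, rho_w = 1000,
                        viscosity = 1.0e-3, bulk_density = 1.17,
                        gravity = 9.81) {
  check_positive(d50, "d50")
  check_positive(rho_w, "rho_w")
  if (rho_s <= rho_w) stop_invalid("`rho_s` must exceed `rho_w`.")
  check_positive(viscosity, "viscosity")
  check_positive(bulk_density, "bulk_density")
  check_positive(gravity, "gravity")
  structure(list(d50 = d50, rho_s = rho_s, rho_w = rho_w,
                 viscosity = viscosity, bulk_density = bulk_density,
                 gravity = gravity),
            class = "soil_params")
}

#' Drag coefficient of a settling grain
#'
#' Standard intermediate-Reynolds drag law
#' \eqn{C_D = 24/Re + 3/\sqrt{Re} + 0.34}, which reduces to Stokes drag at
#' low Re and approaches 0.34 in the inertial limit.
#'
#' @param re Grain Reynolds number, > 0; vectorised.
#' @return Dimensionless drag coefficient.
#' @export
#' @examples
#' drag_coefficient(1) # 27.34
drag_coefficient <- function(re) {
  check_positive(re, "re")
  24 / re + 3 / sqrt(re) + 0.34
}

#' Terminal settling velocity of the median grain
#'
#' \eqn{v_s = \sqrt{4 d_{50} (\rho_s - \rho_w) g / (3 C_D \rho_w)}}. When
#' `cd` is not supplied the drag coefficient is made self-consistent with
#' the velocity by fixed-point iteration of \eqn{C_D(Re(v_s))} (for the
#' 16 um grains used here the result agrees with Stokes' law to within a
#' few percent).
#'
#' @param soil A [soil_params()].
#' @param cd Optional fixed drag coefficient; if `NULL`, iterate to
#'   self-consistency.
#' @param tol Relative convergence tolerance of the fixed-point iteration.
#' @param max_iter Iteration cap.
#' @return Settling velocity in m s^-1.
#' @export
settling_velocity <- function(soil = soil_params(), cd = NULL,
                              tol = 1e-8, max_iter = 100) {
  v_of_cd <- function(cdi) {
    sqrt(4 * soil$d50 * (soil$rho_s - soil$rho_w) * soil$gravity /
           (3 * cdi * soil$rho_w))
  }
  if (!is.null(cd)) {
    check_positive(cd, "cd")
    return(v_of_cd(cd))
  }
  # Stokes-law start
  v <- soil$gravity * soil$d50^2 * (soil$rho_s - soil$rho_w) /
    (18 * soil$viscosity)
  for (i in seq_len(max_iter)) {
    re <- soil$rho_w * v * soil$d50 / soil$viscosity
    v_new <- v_of_cd(drag_coefficient(re))
    if (abs(v_new - v) <= tol * v) return(v_new)
    v <- v_new
  }
  abort("Settling-velocity iteration did not converge.",
        class = c("rhizo_iteration_failure", "rhizo_error"))
}

#' Flow detachment efficiency from a measured detachment rate
#'
#' Back-calculates the EUROSEM runoff-detachment efficiency
#' \eqn{\beta = ASD / (B_D\, v_s\, C_{TC})}, where ASD is the measured
#' average soil detachment rate, \eqn{B_D} the dry bulk density, \eqn{v_s}
#' the settling velocity of the median grain and \eqn{C_{TC}} the transport
#' capacity term of the flow. The denominator is evaluated in CGS units
#' (ASD in g cm^-2 s^-1, \eqn{B_D} in g cm^-3, \eqn{v_s} in cm s^-1) as
#' conventional for this equation; inputs here are SI and converted
#' internally.
#'
#' @param asd Measured detachment rate in kg m^-2 s^-1 (SI; converted to
#'   g cm^-2 s^-1 internally); vectorised.
#' @param soil A [soil_params()].
#' @param c_tc Transport-capacity term (sediment concentration units); how
#'   it was derived per run is experiment-specific, so it is a required
#'   input.
#' @param v_s Optional settling velocity (m s^-1); computed
#'   self-consistently from `soil` when `NULL`.
#' @return Dimensionless efficiency \eqn{\beta \ge 0}.
#' @export
detachment_efficiency <- function(asd, soil = soil_params(), c_tc,
                                  v_s = NULL) {
  check_non_negative(asd, "asd")
  check_positive(c_tc, "c_tc")
  if (is.null(v_s)) v_s <- settling_velocity(soil)
  check_positive(v_s, "v_s")
  asd_cgs <- asd * 0.1      # kg m^-2 s^-1 -> g cm^-2 s^-1
  v_cgs <- v_s * 100        # m s^-1 -> cm s^-1
  denom <- soil$bulk_density * v_cgs * c_tc
  if (denom <= 0) stop_invalid("Denominator of the efficiency is zero.")
  asd_cgs / denom
}

#' Soil cohesion from the detachment efficiency
#'
#' Empirical inverse relation \eqn{C = -\ln(\beta / 0.79) / 0.85} (kPa): a
#' fully efficient flow (\eqn{\beta = 0.79}) detaches cohesionless soil,
#' and efficiency decays exponentially as cohesion grows. Efficiencies
#' above 0.79 would imply negative cohesion; they are floored at 0 kPa with
#' a warning rather than returned.
#'
#' @param beta Flow detachment efficiency, in (0, 0.79]; vectorised.
#' @return Cohesion in kPa.
#' @export
#' @examples
#' cohesion_from_beta(0.79) # 0 kPa
#' cohesion_from_beta(0.0344) # ~3.69 kPa
cohesion_from_beta <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta)) || any(beta <= 0)) {
    stop_invalid("`beta` must be positive and finite.")
  }
  if (any(beta > 0.79)) {
    warn(paste("Efficiency above 0.79 implies non-positive cohesion;",
               "returning 0 kPa for those values."),
         class = "rhizo_negative_cohesion")
  }
  pmax(-log(beta / 0.79) / 0.85, 0)
}

#' @describeIn cohesion_from_beta Inverse map: the efficiency that
#'   corresponds to a given cohesion (kPa).
#' @param cohesion Soil cohesion in kPa, >= 0.
#' @export
beta_from_cohesion <- function(cohesion) {
  check_non_negative(cohesion, "cohesion")
  0.79 * exp(-0.85 * cohesion)
}

#' Root reinforcement
#'
#' The gain in soil cohesion attributable to roots: cohesion of the rooted
#' soil minus cohesion of bare soil, in kPa. Negative values (rooted soil
#' apparently weaker) are allowed but flagged with a warning.
#'
#' @param c_rooted,c_bare Cohesion of rooted and bare soil, kPa; vectorised.
#' @return Reinforcement in kPa.
#' @export
root_reinforcement <- function(c_rooted, c_bare) {
  if (any(!is.finite(c_rooted)) || any(!is.finite(c_bare))) {
    stop_invalid("Cohesion values must be finite.")
  }
  out <- c_rooted - c_bare
  if (any(out < 0)) {
    warn("Negative reinforcement value(s): rooted soil weaker than bare.",
         class = "rhizo_negative_reinforcement")
  }
  out
}

#' Logarithmic reinforcement-RLD model
#'
#' Root reinforcement grows logarithmically with root length density:
#' \eqn{\Delta C = a \ln(RLD + 1)} (kPa), anchored through the origin so
#' bare soil gains nothing. `fit_log_reinforcement()` estimates `a` by
#' least squares; `evaluate_log_reinforcement()` evaluates the curve.
#'
#' @param points Data frame with columns `rld` (km m^-3, >= 0) and
#'   `reinforcement` (kPa); at least 3 points with some `rld > 0`.
#' @return A `reinforcement_model` object with elements `a`, `se`,
#'   `r.squared`, `nobs`.
#' @export
#' @examples
#' pts <- tibble::tibble(rld = c(0, 5, 10, 19),
#'                       reinforcement = 1.23 * log(c(0, 5, 10, 19) + 1))
#' fit_log_reinforcement(pts)
fit_log_reinforcement <- function(points) {
  check_columns(points, c("rld", "reinforcement"), "points")
  check_non_negative(points$rld, "rld")
  if (nrow(points) < 3 || all(points$rld == 0)) {
    abort("Need at least 3 points with non-zero RLD to fit.",
          class = c("rhizo_insufficient_data", "rhizo_error"))
  }
  fit <- lm(reinforcement ~ 0 + I(log(rld + 1)), data = points)
  s <- summary(fit)
  structure(
    list(a = unname(coef(fit)[1]),
         se = s$coefficients[1, "Std. Error"],
         r.squared = s$r.squared,
         nobs = nrow(points),
         data = as_tibble(points)),
    class = "reinforcement_model"
  )
}

#' @rdname fit_log_reinforcement
#' @param model A `reinforcement_model`, or a bare coefficient `a` (kPa).
#' @param rld Root length densities, km m^-3; vectorised.
#' @export
evaluate_log_reinforcement <- function(model, rld) {
  check_non_negative(rld, "rld")
  a <- if (is.numeric(model)) model else model$a
  a * log(rld + 1)
}

#' @export
print.reinforcement_model <- function(x, ...) {
  cat(sprintf("<reinforcement_model> a = %.3f kPa (se %.3g), R^2 = %.2f, n = %d\n",
              x$a, x$se, x$r.squared, x$nobs))
  invisible(x)
}

#' @method tidy reinforcement_model
#' @export
tidy.reinforcement_model <- function(x, ...) {
  tibble(term = "a", estimate = x$a, std.error = x$se)
}

#' @method glance reinforcement_model
#' @export
glance.reinforcement_model <- function(x, ...) {
  tibble(r.squared = x$r.squared, nobs = x$nobs)
}
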