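#' Spin protocol for the centrifuge gel-adhesion assay
#'
#' Describes the hanging-bucket centrifuge used to peel seedlings off the
#' surface of a gel plate. The rotor speed at setting \eqn{n} is
#' \eqn{720\sqrt{n}} rpm, the bucket is attached (and the gel surface sits)
#' 0.07 m from the axis, and the moment arm of the centrifugal force on the
#' bucket is likewise 0.07 m.
#'
#' @param base_rpm Rotor speed at setting 1, revolutions per minute.
#' @param settings Ordered integer speed settings applied during the assay.
#' @param radius Distance from rotation axis to the seedlings, metres.
#' @param arm Moment-arm coefficient of the centrifugal force acting on the
#'   bucket, metres.
#' @param gravity Gravitational acceleration, m s^-2.
#'
#' @return An object of class `spin_protocol`.
#' @export
#' @examples
#' spin_protocol()
spin_protocol <- function(base_rpm = 720, settings = 1:5, radius = 0.07,
                          arm = 0.07, gravity = 9.81) {
  check_positive(base_rpm, "base_rpm")
  check_positive(radius, "radius")
  check_positive(arm, "arm")
  check_positive(gravity, "gravity")
  settings <- as.integer(settings)
  if (length(settings) == 0 || any(settings <= 0) ||
      any(diff(settings) <= 0)) {
    stop_invalid("`settings` must be strictly increasing positive integers.")
  }
  structure(
    list(base_rpm = base_rpm, settings = settings, radius = radius,
         arm = arm, gravity = gravity),
    class = "spin_protocol"
  )
}

#' @export
print.spin_protocol <- function(x, ...) {
  cat("<spin_protocol>\n")
  cat(sprintf("  speed at setting n: %g * sqrt(n) rpm\n", x$base_rpm))
  cat(sprintf("  settings: %s\n", paste(x$settings, collapse = ", ")))
  cat(sprintf("  radius: %g m, arm: %g m, g: %g m s^-2\n",
              x$radius, x$arm, x$gravity))
  invisible(x)
}

check_setting <- function(setting) {
  if (!is.numeric(setting) || any(!is.finite(setting)) || any(setting < 1)) {
    stop_invalid("`setting` must be a speed index >= 1.")
  }
  invisible(setting)
}

#' Rotor speed and angular velocity at a speed setting
#'
#' The rotor turns at \eqn{720\sqrt{n}} rpm at setting \eqn{n};
#' `angular_velocity()` converts this to rad s^-1.
#'
#' @param setting Speed setting index (>= 1); vectorised.
#' @param protocol A [spin_protocol()].
#'
#' @return `spin_speed_rpm()`: revolutions per minute.
#'   `angular_velocity()`: rad s^-1.
#' @export
#' @examples
#' spin_speed_rpm(1:5) # 720, 1018, 1247, 1440, 1610 rpm
#' angular_velocity(1) # 75.4 rad/s
angular_velocity <- function(setting, protocol = spin_protocol()) {
  check_setting(setting)
  spin_speed_rpm(setting, protocol) * 2 * pi / 60
}

#' @rdname angular_velocity
#' @export
spin_speed_rpm <- function(setting, protocol = spin_protocol()) {
  check_setting(setting)
  protocol$base_rpm * sqrt(setting)
}

#' Upper bound on bucket inclination from the vertical
#'
#' Balancing moments about the bucket's attachment point, the swing-out
#' bucket deviates from the plane of rotation by at most
#' \eqn{\arctan(g / (0.07\,\omega^2))}: the centrifugal force (at least
#' \eqn{0.07 m \omega^2}) dominates gravity at assay speeds, so the plate is
#' effectively perpendicular to the rotor.
#'
#' @inheritParams angular_velocity
#' @return Degrees of deviation (upper bound); vectorised over `setting`.
#' @export
#' @examples
#' bucket_inclination(1) # < 1.41 degrees at the slowest setting
bucket_inclination <- function(setting, protocol = spin_protocol()) {
  omega <- angular_velocity(setting, protocol)
  atan(protocol$gravity / (protocol$arm * omega^2)) * 180 / pi
}

#' Centrifugal force on a seedling
#'
#' \eqn{F_c = M_s \cdot \mathrm{radius} \cdot \omega^2}: the aerial tissue
#' mass of each seedling sets the peeling force its root system must resist.
#'
#' @param aerial_mass Aerial tissue mass in kg; vectorised.
#' @inheritParams angular_velocity
#' @return Force in newtons.
#' @export
#' @examples
#' centrifugal_force(2e-5, 1) # ~8 mN on a 20 mg seedling at setting 1
centrifugal_force <- function(aerial_mass, setting,
                              protocol = spin_protocol()) {
  check_positive(aerial_mass, "aerial_mass")
  omega <- angular_velocity(setting, protocol)
  aerial_mass * protocol$radius * omega^2
}

#' Relative centrifugal force (multiples of g)
#'
#' @inheritParams angular_velocity
#' @return Centripetal acceleration at the gel surface in multiples of g.
#' @export
#' @examples
#' relative_centrifugal_force(1) # >= 40 g even at the slowest setting
relative_centrifugal_force <- function(setting, protocol = spin_protocol()) {
  omega <- angular_velocity(setting, protocol)
  protocol$radius * omega^2 / protocol$gravity
}

# Standardise a cohort data frame: per-seedling force at the recorded
# detachment setting (or at the maximum tested setting for seedlings that
# never detached), plus an event flag.
cohort_events <- function(cohort, protocol) {
  check_columns(cohort, c("aerial_mass_mg", "detach_setting"), "cohort")
  if (nrow(cohort) == 0) stop_invalid("`cohort` must be non-empty.")
  check_positive(cohort$aerial_mass_mg, "aerial_mass_mg")
  if (!"genotype" %in% names(cohort)) cohort$genotype <- "all"
  if (!"id" %in% names(cohort)) cohort$id <- seq_len(nrow(cohort))
  ok <- is.na(cohort$detach_setting) |
    cohort$detach_setting %in% protocol$settings
  if (!all(ok)) {
    stop_invalid("`detach_setting` must be one of the protocol settings or NA.")
  }
  max_setting <- max(protocol$settings)
  event <- !is.na(cohort$detach_setting)
  at_setting <- ifelse(event, cohort$detach_setting, max_setting)
  cohort |>
    dplyr::mutate(
      event = as.integer(event),
      spin_count = as.integer(at_setting),
      force = centrifugal_force(.data$aerial_mass_mg * 1e-6,
                                at_setting, protocol)
    )
}

#' Detachment survival curve of a seedling cohort
#'
#' Converts per-seedling detachment settings into seedling-specific forces
#' (mass-dependent, via [centrifugal_force()]) and estimates the proportion
#' of seedlings still adhered as force increases, one Kaplan-Meier step
#' curve per genotype. Seedlings still attached after the maximum tested
#' speed are censored at that speed's force.
#'
#' @param cohort Data frame with columns `aerial_mass_mg`, `detach_setting`
#'   (speed index at detachment; `NA` for seedlings that never detached) and
#'   optionally `genotype` and `id`.
#' @param protocol A [spin_protocol()].
#'
#' @return A tibble of class `detachment_curve` with columns `genotype`,
#'   `force` (N), `n_risk`, `n_event`, `n_censor` and `proportion_attached`.
#'   Each genotype's curve starts at (0, 1).
#' @export
#' @examples
#' cohort <- tibble::tibble(
#'   aerial_mass_mg = rep(20, 4),
#'   detach_setting = c(1, 2, NA, NA)
#' )
#' detachment_curve(cohort)
detachment_curve <- function(cohort, protocol = spin_protocol()) {
  events <- cohort_events(cohort, protocol)
  curves <- events |>
    dplyr::group_by(.data$genotype) |>
    dplyr::group_modify(function(df, key) {
      fit <- survival::survfit(
        survival::Surv(df$force, df$event) ~ 1,
        conf.type = "none"
      )
      tibble(
        force = c(0, fit$time),
        n_risk = c(nrow(df), fit$n.risk),
        n_event = c(0, fit$n.event),
        n_censor = c(0, fit$n.censor),
        proportion_attached = c(1, fit$surv)
      )
    }) |>
    dplyr::ungroup()
  structure(curves, class = c("detachment_curve", class(curves)),
            protocol = protocol)
}

#' Analysis-ready detachment event table
#'
#' One row per seedling with its detachment force, event/censor flag and
#' covariates, suitable for downstream proportional-hazards regression with
#' e.g. `survival::coxph()` (not performed here).
#'
#' @inheritParams detachment_curve
#' @return A tibble with columns `id`, `genotype`, `aerial_mass_mg`,
#'   `detach_setting`, `spin_count`, `force` (N) and `event` (1 = detached,
#'   0 = censored at the maximum tested speed), plus any extra covariate
#'   columns present in `cohort` (e.g. plate id).
#' @export
export_event_table <- function(cohort, protocol = spin_protocol()) {
  events <- cohort_events(cohort, protocol)
  front <- c("id", "genotype", "aerial_mass_mg", "detach_setting",
             "spin_count", "force", "event")
  dplyr::select(events, dplyr::all_of(front), dplyr::everything()) |>
    as_tibble()
}

#' Read a detachment cohort from CSV
#'
#' Expects columns `id`, `genotype`, `aerial_mass_mg` and `detach_setting`
#' (blank for seedlings that never detached). Masses are kept in mg and
#' converted to kg internally by the force calculations.
#'
#' @param file Path to a CSV file.
#' @return A tibble.
#' @export
read_cohort <- function(file) {
  readr::read_csv(file, show_col_types = FALSE)
}

#' @describeIn detachment_curve Step-curve plot of proportion attached
#'   against force, coloured by genotype.
#' @param object A `detachment_curve`.
#' @param ... Unused.
#' @method autoplot detachment_curve
#' @export
autoplot.detachment_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$force,
                                       .data$proportion_attached,
                                       colour = .data$genotype)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Centrifugal force (N)",
                  y = "Proportion attached", colour = NULL)
}
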