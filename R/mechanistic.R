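#' Flume configuration for the mechanistic erosion model
#'
#' @param flow_rate Water volume flow rate Q, m^3 s^-1.
#' @param velocity Surface flow velocity V, m s^-1.
#' @param slope_deg Flume slope, degrees.
#' @param width Flume width W, m.
#' @param permeability Bare-soil permeability k, m^2.
#' @param d50 Median grain diameter, m.
#' @param gravity Gravitational acceleration, m s^-2.
#' @return An object of class `flume_config`.
#' @export
flume_config <- function(flow_rate = 1e-3, velocity = 1.0, slope_deg = 28,
                         width = 0.36, permeability = 0.2273e-12,
                         d50 = 16e-6, gravity = 9.81) {
  check_positive(flow_rate, "flow_rate")
  check_positive(velocity, "velocity")
  if (slope_deg <= 0 || slope_deg >= 90) {
    stop_invalid("`slope_deg` must be in (0, 90).")
  }
  check_positive(width, "width")
  check_positive(permeability, "permeability")
  check_positive(d50, "d50")
  check_positive(gravity, "gravity")
  structure(list(flow_rate = flow_rate, velocity = velocity,
                 slope_deg = slope_deg, width = width,
                 permeability = permeability, d50 = d50, gravity = gravity),
            class = "flume_config")
}

#' Bed shear stress of the flume flow
#'
#' For a parabolic flow profile over a permeable bed,
#' \eqn{\tau = 3 g Q d_{50}^2 \sin(\mathrm{slope}) / (2 V k W)}. With the
#' default 1 l s^-1 flow this sits in the 13-24 Pa range spanned by the
#' experimental runs.
#'
#' @param cfg A [flume_config()].
#' @return Shear stress in Pa.
#' @export
#' @examples
#' bed_shear_stress(flume_config()) # ~21.6 Pa at V = 1 m/s
bed_shear_stress <- function(cfg = flume_config()) {
  3 * cfg$gravity * cfg$flow_rate * cfg$d50^2 *
    sin(cfg$slope_deg * pi / 180) /
    (2 * cfg$velocity * cfg$permeability * cfg$width)
}

#' Root-system geometry within a soil box
#'
#' The volume occupied by one root system is idealised as a kite-shaped
#' solid of revolution: two coaxial cones sharing a base of diameter
#' `spread` at depth `spread_depth`, with total vertical extent `depth`.
#' Erosion parameters `R` (maximum erosion depth) and `r` (reinforced depth
#' midway between plants) are carried in mm because the root-hair
#' enhancement rate gamma is expressed per mm of depth.
#'
#' @param depth Vertical extent D of the root system, m.
#' @param spread Maximum lateral extent of the root system, m.
#' @param spread_depth Depth d of maximum lateral spread, m (0.020-0.030
#'   observed; mid-range default).
#' @param max_erosion_depth_mm Maximum erosion depth R, mm.
#' @param reinforced_depth_mm Reinforced depth r between plants, mm
#'   (23-42 observed; mid-range default). Must not exceed R.
#' @param box_length,box_width,box_depth Soil box inner dimensions, m.
#' @param plant_count Plants per box.
#' @return An object of class `root_geometry`.
#' @export
root_geometry <- function(depth = 0.100, spread = 0.100,
                          spread_depth = 0.025,
                          max_erosion_depth_mm = 50,
                          reinforced_depth_mm = 32.5,
                          box_length = 0.25, box_width = 0.25,
                          box_depth = 0.15, plant_count = 49) {
  check_positive(depth, "depth")
  check_positive(spread, "spread")
  check_positive(spread_depth, "spread_depth")
  if (spread_depth >= depth) stop_invalid("`spread_depth` must be < `depth`.")
  check_positive(max_erosion_depth_mm, "max_erosion_depth_mm")
  check_positive(reinforced_depth_mm, "reinforced_depth_mm")
  if (reinforced_depth_mm > max_erosion_depth_mm) {
    stop_invalid("`reinforced_depth_mm` must be <= `max_erosion_depth_mm`.")
  }
  check_positive(box_length, "box_length")
  check_positive(box_width, "box_width")
  check_positive(box_depth, "box_depth")
  if (plant_count < 1) stop_invalid("`plant_count` must be >= 1.")
  structure(list(depth = depth, spread = spread, spread_depth = spread_depth,
                 max_erosion_depth_mm = max_erosion_depth_mm,
                 reinforced_depth_mm = reinforced_depth_mm,
                 box_length = box_length, box_width = box_width,
                 box_depth = box_depth,
                 plant_count = as.integer(plant_count)),
            class = "root_geometry")
}

#' @describeIn root_geometry Volume of one kite-shaped root region (two
#'   coaxial cones sharing a base of diameter `spread`):
#'   \eqn{V = \pi\, \mathrm{spread}^2 \mathrm{depth} / 12}.
#' @param geom A `root_geometry`.
#' @export
kite_volume <- function(geom = root_geometry()) {
  pi * geom$spread^2 * geom$depth / 12
}

#' True root length density within the root-occupied volume
#'
#' Box-scale RLD understates how concentrated roots are around each plant.
#' The total root length (box RLD x box volume) is divided by the volume
#' the roots actually occupy: `plant_count` kite volumes, capped at the
#' rooted slab (box area x rooting depth) once neighbouring kites overlap.
#'
#' @param box_rld Box-scale root length density, km m^-3; vectorised.
#' @param geom A [root_geometry()].
#' @return True RLD (km m^-3), >= `box_rld` whenever the occupied volume is
#'   a subset of the box.
#' @export
true_rld <- function(box_rld, geom = root_geometry()) {
  check_non_negative(box_rld, "box_rld")
  box_volume <- geom$box_length * geom$box_width * geom$box_depth
  occupied <- min(geom$plant_count * kite_volume(geom),
                  geom$box_length * geom$box_width * geom$depth)
  box_rld * box_volume / occupied
}

#' Mechanistic model parameters
#'
#' Holds the root-hair cohesion-enhancement parameters and the Coulomb
#' failure inputs. The enhancement rate saturates with true RLD as
#' \eqn{\gamma(x) = M_{max} \tanh(M_1 x / M_{max})} with
#' \eqn{M_{max} = M_1 / M_2}; `M1` is the initial enhancement rate per unit
#' true RLD and `M_max` the saturation value (both mm^-1 scale).
#'
#' `c_bare` is the effective bare-soil shear-strength threshold entered in
#' the Coulomb comparison, in the same unit (Pa) as the bed shear stress;
#' only the ratio tau/c_bare matters to the predicted curve, and the
#' default is set so that bare soil erodes under the default flume stress.
#'
#' @param M1 Initial enhancement rate, mm^-1 per (km m^-3 of true RLD).
#' @param M_max Saturation enhancement, mm^-1 (equals `M1 / M2`).
#' @param c_bare Effective bare-soil threshold, Pa (see Details).
#' @param friction_mu Coulomb friction coefficient (surface erosion
#'   default 0).
#' @param normal_stress Normal stress N, Pa.
#' @return An object of class `mech_params`.
#' @export
mech_params <- function(M1 = 5.45e-3, M_max = 139, c_bare = 2.4,
                        friction_mu = 0, normal_stress = 0) {
  check_positive(M1, "M1")
  check_positive(M_max, "M_max")
  check_positive(c_bare, "c_bare")
  check_non_negative(friction_mu, "friction_mu")
  if (!is.finite(normal_stress)) stop_invalid("`normal_stress` must be finite.")
  structure(list(M1 = M1, M_max = M_max, M2 = M1 / M_max, c_bare = c_bare,
                 friction_mu = friction_mu, normal_stress = normal_stress),
            class = "mech_params")
}

#' Root-hair cohesion enhancement rate
#'
#' \eqn{\gamma(x) = M_{max} \tanh(M_1 x / M_{max})}: linear with slope
#' \eqn{M_1} at low true RLD and saturating at \eqn{M_{max}} (there is a
#' limit to how much root hairs can reinforce a unit depth of soil).
#'
#' @param rld_t True root length density, km m^-3; vectorised.
#' @param params A [mech_params()].
#' @return Enhancement rate in mm^-1.
#' @export
hair_enhancement <- function(rld_t, params = mech_params()) {
  check_non_negative(rld_t, "rld_t")
  params$M_max * tanh(params$M1 * rld_t / params$M_max)
}

#' Cohesion extremes of root-reinforced soil
#'
#' Reinforcement is strongest along the tap root, where roots persist to
#' the maximum erosion depth R, and weakest midway between plants, where
#' they reach only depth r: \eqn{c_{max} = c_{bare}(1 + \gamma R)} and
#' \eqn{c_{min} = c_{bare}(1 + \gamma r)} with R, r in mm.
#'
#' @inheritParams hair_enhancement
#' @param geom A [root_geometry()].
#' @return A tibble with columns `rld_t`, `gamma`, `c_min`, `c_max`
#'   (same unit as `params$c_bare`).
#' @export
cohesion_extremes <- function(rld_t, params = mech_params(),
                              geom = root_geometry()) {
  g <- hair_enhancement(rld_t, params)
  tibble(
    rld_t = rld_t,
    gamma = g,
    c_min = params$c_bare * (1 + g * geom$reinforced_depth_mm),
    c_max = params$c_bare * (1 + g * geom$max_erosion_depth_mm)
  )
}

#' Eroded fraction of a spatial period
#'
#' Between regularly spaced plants the reinforced depth varies sinusoidally
#' from R at a stem to r midway between stems, so local cohesion is
#' \eqn{c(x) = c_{bare}(1 + \gamma \rho(x))} with
#' \eqn{\rho(x) = (R + r)/2 + ((R - r)/2)\cos(2\pi x / L)}. Erosion occurs
#' where the effective shear \eqn{\tau_{eff} = \tau + \mu N} exceeds
#' \eqn{c(x)}; the eroded (relative detachment) fraction of one period has
#' the closed form \eqn{F = 1 - \arccos(w)/\pi} with
#' \eqn{w = (u - (R+r)/2) / ((R-r)/2)} clamped to \[-1, 1\] and
#' \eqn{u = (\tau_{eff}/c_{bare} - 1)/\gamma} (mm). Bare soil
#' (\eqn{\gamma = 0}) erodes fully whenever \eqn{\tau_{eff} > c_{bare}}.
#' The period length cancels, so plant spacing does not enter the fraction.
#'
#' @param tau Bed shear stress, same unit as `params$c_bare` (Pa).
#' @inheritParams cohesion_extremes
#' @return Eroded fraction in \[0, 1\]; vectorised over `rld_t`.
#' @export
erosion_fraction <- function(tau, rld_t, params = mech_params(),
                             geom = root_geometry()) {
  check_positive(tau, "tau")
  g <- hair_enhancement(rld_t, params)
  tau_eff <- tau + params$friction_mu * params$normal_stress
  R <- geom$max_erosion_depth_mm
  r <- geom$reinforced_depth_mm
  excess <- tau_eff / params$c_bare - 1
  out <- numeric(length(g))
  bare <- g == 0
  if (any(bare)) {
    if (excess <= 0) {
      warn("Bare soil does not erode: effective shear <= bare threshold.",
           class = "rhizo_bare_uneroded")
      out[bare] <- 0
    } else {
      out[bare] <- 1
    }
  }
  rooted <- !bare
  if (any(rooted)) {
    u <- excess / g[rooted] # reinforced depth (mm) at the erosion threshold
    if (R == r) {
      out[rooted] <- ifelse(u > R, 1, 0)
    } else {
      w <- pmin(pmax((u - (R + r) / 2) / ((R - r) / 2), -1), 1)
      out[rooted] <- 1 - acos(w) / pi
    }
  }
  out
}

#' Predicted erosion-reduction curve of the mechanistic model
#'
#' Composes [true_rld()], [hair_enhancement()] and [erosion_fraction()]
#' over a grid of box-scale RLD values: the model's counterpart of the
#' empirically fitted relative-detachment curve. Equals 1 at RLD 0 (bare
#' soil) and is non-increasing in RLD.
#'
#' @param rld_grid Box-scale RLD values, km m^-3.
#' @param params A [mech_params()].
#' @param geom A [root_geometry()].
#' @param cfg A [flume_config()]; sets the bed shear stress.
#' @return A tibble with columns `rld`, `rld_t`, `gamma` and `ratio`.
#' @export
erosion_curve <- function(rld_grid, params = mech_params(),
                          geom = root_geometry(), cfg = flume_config()) {
  check_non_negative(rld_grid, "rld_grid")
  tau <- bed_shear_stress(cfg)
  rld_t <- true_rld(rld_grid, geom)
  tibble(
    rld = rld_grid,
    rld_t = rld_t,
    gamma = hair_enhancement(rld_t, params),
    ratio = erosion_fraction(tau, rld_t, params, geom)
  )
}

# Max relative error between predicted and observed ratios; observations
# near zero are compared on an absolute floor so the objective stays
# defined where the curve bottoms out.
curve_objective <- function(observed, params, geom, cfg, floor = 0.05) {
  pred <- erosion_curve(observed$rld, params, geom, cfg)$ratio
  max(abs(pred - observed$ratio) / pmax(abs(observed$ratio), floor))
}

#' Calibrate the root-hair enhancement parameters
#'
#' Fits \eqn{(M_1, M_{max})} so the mechanistic curve reproduces an
#' observed erosion-reduction curve, minimising the maximum relative error
#' (the scale on which model accuracy is quoted). Deterministic, in three
#' stages:
#' 1. analytic inversion — interior observations (0 < ratio < 1) are
#'    inverted through the closed-form fraction to enhancement values
#'    \eqn{\gamma_i}, and the series expansion
#'    \eqn{\gamma/x = M_1 - (M_1^3/3M_{max}^2)\,x^2} is regressed to give
#'    starting estimates, polished by nonlinear least squares on the tanh
#'    law (saturation is a small correction in the observed RLD range, so
#'    this inversion is what makes \eqn{M_{max}} resolvable from clean
#'    curves);
#' 2. a bounded log-spaced grid scan of the objective;
#' 3. Nelder-Mead refinement from the best candidate.
#'
#' @param observed Data frame with columns `rld` (box-scale, km m^-3) and
#'   `ratio`; at least 4 points.
#' @param geom A [root_geometry()].
#' @param cfg A [flume_config()].
#' @param c_bare Effective bare-soil threshold, Pa (see [mech_params()]).
#' @param bounds List with elements `M1` and `M_max`, each `c(lower,
#'   upper)`.
#' @param grid_n Grid-scan resolution per parameter.
#' @return An object of class `mech_calibration`: the fitted
#'   [mech_params()], `M1`, `M2`, `M_max`, the achieved `max_rel_error` and
#'   the winning `method`.
#' @export
calibrate_enhancement <- function(observed, geom = root_geometry(),
                                  cfg = flume_config(), c_bare = 2.4,
                                  bounds = list(M1 = c(1e-4, 5e-2),
                                                M_max = c(20, 400)),
                                  grid_n = 21) {
  check_columns(observed, c("rld", "ratio"), "observed")
  observed <- as_tibble(observed)
  if (nrow(observed) < 4) {
    abort("Calibration is under-determined with fewer than 4 observations.",
          class = c("rhizo_calibration_failure", "rhizo_error"))
  }
  tau <- bed_shear_stress(cfg)
  excess <- tau / c_bare - 1
  if (excess <= 0) {
    abort("Effective shear does not exceed the bare threshold; no erosion to fit.",
          class = c("rhizo_calibration_failure", "rhizo_error"))
  }
  R <- geom$max_erosion_depth_mm
  r <- geom$reinforced_depth_mm
  make_params <- function(M1, M_max) {
    mech_params(M1 = M1, M_max = M_max, c_bare = c_bare,
                friction_mu = 0, normal_stress = 0)
  }
  obj <- function(M1, M_max) curve_objective(observed, make_params(M1, M_max),
                                             geom, cfg)
  clamp <- function(v, b) pmin(pmax(v, b[1]), b[2])

  candidates <- list()

  # Stage 1: analytic inversion of interior points. Observations close to
  # the flat regions (ratio ~ 1 or ~ 0) carry no depth information and,
  # under noise, invert to badly biased enhancement values, so only the
  # transition region is used.
  interior <- observed$ratio > 0.02 & observed$ratio < 0.95 &
    observed$rld > 0
  if (sum(interior) >= 4) {
    Fi <- observed$ratio[interior]
    xi <- true_rld(observed$rld[interior], geom)
    w <- cos(pi * (1 - Fi))
    u <- (R + r) / 2 + (R - r) / 2 * w
    gi <- excess / u
    ratio_i <- gi / xi
    sq <- xi^2
    co <- coef(lm(ratio_i ~ sq))
    M1_hat <- clamp(unname(co[1]), bounds$M1)
    slope <- unname(co[2])
    M_max_hat <- if (is.finite(slope) && slope < 0) {
      clamp(sqrt(M1_hat^3 / (-3 * slope)), bounds$M_max)
    } else {
      bounds$M_max[2]
    }
    polished <- tryCatch({
      fit <- nls(gi ~ Mmax * tanh(M1 * xi / Mmax),
                 start = list(M1 = M1_hat, Mmax = M_max_hat),
                 algorithm = "port",
                 lower = c(bounds$M1[1], bounds$M_max[1]),
                 upper = c(bounds$M1[2], bounds$M_max[2]),
                 control = list(warnOnly = TRUE))
      coef(fit)
    }, error = function(e) c(M1 = M1_hat, Mmax = M_max_hat))
    candidates$inversion <- c(M1 = unname(polished["M1"]),
                              M_max = unname(polished["Mmax"]))
  }

  # Stage 2: log-spaced grid scan.
  g1 <- exp(seq(log(bounds$M1[1]), log(bounds$M1[2]), length.out = grid_n))
  g2 <- exp(seq(log(bounds$M_max[1]), log(bounds$M_max[2]),
                length.out = grid_n))
  grid_pts <- expand.grid(M1 = g1, M_max = g2)
  grid_obj <- vapply(seq_len(nrow(grid_pts)),
                     function(i) obj(grid_pts$M1[i], grid_pts$M_max[i]),
                     numeric(1))
  best <- which.min(grid_obj)
  candidates$grid <- c(M1 = grid_pts$M1[best], M_max = grid_pts$M_max[best])

  # Stage 3: local refinement from the best candidate so far — first on a
  # smooth least-squares surface (the max-relative objective is cliff-like
  # where the curve reaches zero), then directly on the reported objective.
  cand_obj <- vapply(candidates, function(p) obj(p["M1"], p["M_max"]),
                     numeric(1))
  start <- candidates[[which.min(cand_obj)]]
  bounded <- function(p) {
    p[1] >= bounds$M1[1] && p[1] <= bounds$M1[2] &&
      p[2] >= bounds$M_max[1] && p[2] <= bounds$M_max[2]
  }
  l2 <- function(M1, M_max) {
    pred <- erosion_curve(observed$rld, make_params(M1, M_max),
                          geom, cfg)$ratio
    sum((pred - observed$ratio)^2)
  }
  ref_l2 <- optim(
    log(start),
    function(lp) {
      p <- exp(lp)
      if (!bounded(p)) return(1e6)
      l2(p[1], p[2])
    },
    method = "Nelder-Mead",
    control = list(maxit = 400, reltol = 1e-12)
  )
  candidates$least_squares <- setNames(exp(ref_l2$par), c("M1", "M_max"))
  cand_obj <- vapply(candidates, function(p) obj(p[["M1"]], p[["M_max"]]),
                     numeric(1))
  refined <- optim(
    log(candidates[[which.min(cand_obj)]]),
    function(lp) {
      p <- exp(lp)
      if (!bounded(p)) return(1e6)
      obj(p[1], p[2])
    },
    method = "Nelder-Mead",
    control = list(maxit = 400, reltol = 1e-12)
  )
  candidates$refined <- setNames(exp(refined$par), c("M1", "M_max"))

  cand_obj <- vapply(candidates, function(p) obj(p[["M1"]], p[["M_max"]]),
                     numeric(1))
  winner <- names(candidates)[which.min(cand_obj)]
  p <- candidates[[winner]]
  err <- min(cand_obj)
  if (!is.finite(err)) {
    abort("No feasible parameters within bounds.",
          class = c("rhizo_calibration_failure", "rhizo_error"))
  }
  structure(
    list(params = make_params(p[["M1"]], p[["M_max"]]),
         M1 = p[["M1"]], M_max = p[["M_max"]],
         M2 = p[["M1"]] / p[["M_max"]],
         max_rel_error = err, method = winner,
         observed = observed),
    class = "mech_calibration"
  )
}

#' @export
print.mech_calibration <- function(x, ...) {
  cat("<mech_calibration>\n")
  cat(sprintf("  M1 = %.4g mm^-1 per km m^-3\n", x$M1))
  cat(sprintf("  M_max = M1/M2 = %.4g mm^-1 (M2 = %.4g)\n", x$M_max, x$M2))
  cat(sprintf("  max relative error = %.3g (%s stage)\n",
              x$max_rel_error, x$method))
  invisible(x)
}

#' @method tidy mech_calibration
#' @export
tidy.mech_calibration <- function(x, ...) {
  tibble(term = c("M1", "M2", "M_max"),
         estimate = c(x$M1, x$M2, x$M_max))
}

#' @method glance mech_calibration
#' @export
glance.mech_calibration <- function(x, ...) {
  tibble(max_rel_error = x$max_rel_error, nobs = nrow(x$observed),
         method = x$method)
}
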