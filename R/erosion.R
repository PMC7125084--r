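#' Soil detachment rate of a flume run
#'
#' Each soil box is exposed to concentrated overland flow and run-off is
#' captured for short intervals; the per-interval detachment rate is the
#' captured sediment dry mass divided by box surface area and capture
#' duration, and a run's rate is the arithmetic mean over its intervals.
#'
#' @param runs Tibble with one row per box and a list-column `intervals`,
#'   each element a data frame with columns `start_s`, `duration_s` and
#'   `sediment_kg` (see [gen_erosion_runs()]); any other columns (genotype,
#'   `rld`, flow conditions) are carried through.
#' @param box_area Eroded surface area of a box, m^2 (0.25 m x 0.25 m).
#' @return `runs` with an added column `asd`, the average soil detachment
#'   rate in kg m^-2 s^-1.
#' @export
detachment_rate <- function(runs, box_area = 0.0625) {
  check_columns(runs, "intervals", "runs")
  check_positive(box_area, "box_area")
  asd <- purrr::map_dbl(runs$intervals, function(iv) {
    check_columns(iv, c("duration_s", "sediment_kg"), "intervals")
    if (nrow(iv) < 1) stop_invalid("Each run needs at least one interval.")
    if (any(iv$duration_s <= 0)) stop_invalid("Interval durations must be positive.")
    if (any(iv$sediment_kg < 0)) stop_invalid("Sediment masses must be >= 0.")
    mean(iv$sediment_kg / (box_area * iv$duration_s))
  })
  dplyr::mutate(runs, asd = asd)
}

#' Normalise detachment rates by the extrapolated bare-soil rate
#'
#' Fits \eqn{ASD = A_0 e^{b\,RLD}} to the unnormalised rates (bare boxes
#' enter at RLD 0) and divides every rate by the fitted \eqn{\hat A_0}, the
#' detachment rate extrapolated to zero root density. The resulting
#' dimensionless ratios average to ~1 for bare soil and are the response
#' modelled by [fit_empirical()].
#'
#' @param rates Tibble with columns `asd` (kg m^-2 s^-1) and `rld`
#'   (km m^-3); typically the output of [detachment_rate()].
#' @param extrapolate_below Restrict the extrapolation fit to runs with
#'   `rld <= extrapolate_below` (bare boxes always included). Useful when
#'   the response plateaus beyond a breakpoint (hairless lines) and only
#'   the exponential region should inform the zero-RLD extrapolation.
#' @return `rates` with an added `ratio` column; the fitted `a0` and the
#'   underlying `nls` fit are attached as attributes `a0` and `a0_fit`.
#' @export
relative_detachment <- function(rates, extrapolate_below = Inf) {
  check_columns(rates, c("asd", "rld"), "rates")
  check_non_negative(rates$rld, "rld")
  has_bare <- any(rates$rld == 0)
  if (!has_bare && dplyr::n_distinct(rates$rld) < 3) {
    abort(paste("Cannot extrapolate the bare-soil rate: need bare boxes",
                "(rld = 0) or at least 3 distinct RLD levels."),
          class = c("rhizo_insufficient_data", "rhizo_error"))
  }
  fit_data <- rates[rates$rld <= extrapolate_below, c("asd", "rld")]
  if (dplyr::n_distinct(fit_data$rld) < 2) {
    # Degenerate design (e.g. only bare boxes): the extrapolated value is
    # the mean observed rate.
    a0 <- mean(fit_data$asd)
    fit <- NULL
  } else {
    b0 <- local({
      pos <- fit_data$asd > 0
      if (sum(pos) >= 2) {
        unname(coef(lm(log(fit_data$asd[pos]) ~ fit_data$rld[pos]))[2])
      } else {
        -0.05
      }
    })
    a0_start <- if (has_bare) mean(rates$asd[rates$rld == 0]) else
      max(rates$asd)
    fit <- tryCatch(
      minpack.lm::nlsLM(asd ~ a0 * exp(b * rld), data = fit_data,
                        start = list(a0 = a0_start, b = b0)),
      error = function(e) {
        abort(paste0("Bare-soil extrapolation fit failed: ",
                     conditionMessage(e)),
              class = c("rhizo_fit_failure", "rhizo_error"))
      }
    )
    a0 <- unname(coef(fit)["a0"])
  }
  out <- dplyr::mutate(rates, ratio = .data$asd / a0)
  attr(out, "a0") <- a0
  attr(out, "a0_fit") <- fit
  out
}

new_erosion_model <- function(form, estimate, se, breakpoint, data) {
  pred <- evaluate_empirical(
    structure(list(form = form, estimate = estimate, se = se,
                   breakpoint = breakpoint), class = "erosion_model"),
    data$rld
  )
  resid <- data$ratio - pred
  structure(
    list(form = form, estimate = estimate, se = se, breakpoint = breakpoint,
         nobs = nrow(data), sigma = sqrt(sum(resid^2) / max(1, nrow(data) -
                                                              length(estimate))),
         r.squared = 1 - sum(resid^2) / max(sum((data$ratio -
                                                   mean(data$ratio))^2),
                                            .Machine$double.eps),
         data = as_tibble(data)),
    class = "erosion_model"
  )
}

#' Fit an empirical erosion-reduction model
#'
#' Models the relative detachment ratio as a function of root length
#' density. Three functional forms are supported, matching how different
#' root-hair genotypes behave:
#' * `"exponential"`: \eqn{e^{b\,RLD}} — reduction keeps deepening with RLD
#'   (lines with root hairs);
#' * `"decay_plateau"`: \eqn{p + (1 - p) e^{b\,RLD}} — exponential decay to
#'   a constant floor;
#' * `"piecewise"`: exponential at \eqn{RLD \le} `breakpoint` and a fitted
#'   constant (the mean ratio) above it — hairless lines show no further
#'   reduction beyond ~19 km m^-3.
#'
#' All forms equal 1 at RLD 0. Least squares is on the untransformed
#' ratios; standard errors are asymptotic.
#'
#' @param points Data frame with columns `rld` (km m^-3) and `ratio`
#'   (dimensionless relative detachment).
#' @param form Functional form; see Details.
#' @param breakpoint RLD (km m^-3) splitting the piecewise form.
#' @return An `erosion_model` object; see [tidy()] and [glance()] methods.
#' @export
#' @examples
#' pts <- tibble::tibble(rld = seq(0, 50, 5), ratio = exp(-0.095 * rld))
#' fit_empirical(pts)
fit_empirical <- function(points,
                          form = c("exponential", "decay_plateau",
                                   "piecewise"),
                          breakpoint = 19) {
  form <- match.arg(form)
  check_columns(points, c("rld", "ratio"), "points")
  check_non_negative(points$rld, "rld")
  points <- as_tibble(points)

  fit_exp <- function(df) {
    if (nrow(df) < 4) {
      abort("Exponential fit needs at least 4 points.",
            class = c("rhizo_insufficient_data", "rhizo_error"))
    }
    b0 <- local({
      pos <- df$ratio > 0
      if (sum(pos) >= 2) unname(coef(lm(log(df$ratio[pos]) ~ df$rld[pos]))[2])
      else -0.05
    })
    tryCatch(
      minpack.lm::nlsLM(ratio ~ exp(b * rld), data = df,
                        start = list(b = b0)),
      error = function(e) {
        abort(paste0("Exponential fit failed: ", conditionMessage(e)),
              class = c("rhizo_fit_failure", "rhizo_error"))
      }
    )
  }

  if (form == "exponential") {
    fit <- fit_exp(points)
    s <- summary(fit)$coefficients
    new_erosion_model(form, c(b = unname(coef(fit)["b"])),
                      c(b = unname(s["b", "Std. Error"])), NA_real_, points)
  } else if (form == "piecewise") {
    below <- dplyr::filter(points, .data$rld <= breakpoint)
    above <- dplyr::filter(points, .data$rld > breakpoint)
    if (nrow(above) < 2) {
      abort("Piecewise fit needs at least 2 points above the breakpoint.",
            class = c("rhizo_insufficient_data", "rhizo_error"))
    }
    fit <- fit_exp(below)
    s <- summary(fit)$coefficients
    plateau <- mean(above$ratio)
    plateau_se <- sd(above$ratio) / sqrt(nrow(above))
    if (!is.finite(plateau_se)) plateau_se <- 0
    new_erosion_model(form,
                      c(b = unname(coef(fit)["b"]), plateau = plateau),
                      c(b = unname(s["b", "Std. Error"]),
                        plateau = plateau_se),
                      breakpoint, points)
  } else {
    if (nrow(points) < 4) {
      abort("Decay-to-plateau fit needs at least 4 points.",
            class = c("rhizo_insufficient_data", "rhizo_error"))
    }
    p0 <- min(max(min(points$ratio), 0), 0.9)
    fit <- tryCatch(
      minpack.lm::nlsLM(ratio ~ p + (1 - p) * exp(b * rld), data = points,
                        start = list(b = -0.1, p = p0),
                        lower = c(-Inf, 0), upper = c(0, 1)),
      error = function(e) {
        abort(paste0("Decay-to-plateau fit failed: ", conditionMessage(e)),
              class = c("rhizo_fit_failure", "rhizo_error"))
      }
    )
    s <- summary(fit)$coefficients
    new_erosion_model(form,
                      c(b = unname(coef(fit)["b"]),
                        plateau = unname(coef(fit)["p"])),
                      c(b = unname(s["b", "Std. Error"]),
                        plateau = unname(s["p", "Std. Error"])),
                      NA_real_, points)
  }
}

#' Evaluate an empirical erosion-reduction model
#'
#' @param model An `erosion_model` from [fit_empirical()], or a list with
#'   elements `form`, `estimate` (named vector with `b` and, for plateau
#'   forms, `plateau`) and `breakpoint`.
#' @param rld Root length densities (km m^-3), >= 0; vectorised.
#' @return Dimensionless relative detachment. The piecewise form is not
#'   constrained to be continuous at the breakpoint.
#' @export
#' @examples
#' m <- list(form = "exponential", estimate = c(b = -0.095))
#' evaluate_empirical(m, c(25, 35, 45)) # ~0.09, 0.04, 0.01
evaluate_empirical <- function(model, rld) {
  check_non_negative(rld, "rld")
  est <- model$estimate
  switch(model$form,
    exponential = exp(est[["b"]] * rld),
    decay_plateau = est[["plateau"]] +
      (1 - est[["plateau"]]) * exp(est[["b"]] * rld),
    piecewise = ifelse(rld <= model$breakpoint,
                       exp(est[["b"]] * rld), est[["plateau"]]),
    stop_invalid(sprintf("Unknown model form '%s'.", model$form))
  )
}

#' @export
predict.erosion_model <- function(object, newdata = NULL, ...) {
  rld <- if (is.null(newdata)) object$data$rld else newdata$rld
  evaluate_empirical(object, rld)
}

#' @export
print.erosion_model <- function(x, ...) {
  cat(sprintf("<erosion_model: %s>\n", x$form))
  for (nm in names(x$estimate)) {
    cat(sprintf("  %s = %.4g (se %.3g)\n", nm, x$estimate[[nm]], x$se[[nm]]))
  }
  if (is.finite(x$breakpoint %||% NA_real_)) {
    cat(sprintf("  breakpoint = %g km m^-3\n", x$breakpoint))
  }
  cat(sprintf("  n = %d, R^2 = %.3f\n", x$nobs, x$r.squared))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method tidy erosion_model
#' @export
tidy.erosion_model <- function(x, ...) {
  tibble(term = names(x$estimate),
         estimate = unname(x$estimate),
         std.error = unname(x$se))
}

#' @method glance erosion_model
#' @export
glance.erosion_model <- function(x, ...) {
  tibble(form = x$form, nobs = x$nobs, sigma = x$sigma,
         r.squared = x$r.squared,
         breakpoint = x$breakpoint %||% NA_real_)
}

#' Monte-Carlo confidence band for a fitted erosion model
#'
#' Perturbs the fitted parameters `draws` times from independent normal
#' distributions centred on the estimates with standard deviation equal to
#' their standard errors, evaluates the model curve for every draw, and
#' reports pointwise 2.5% / 97.5% quantiles: the 95% confidence band of the
#' fitted curve. Curves whose point estimate leaves another model's band
#' differ at P < 0.05 (see [compare_bands()]).
#'
#' @param model An `erosion_model` with finite standard errors.
#' @param grid RLD values (km m^-3) at which to evaluate the band.
#' @param draws Number of parameter draws.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble of class `mc_band` with columns `rld`, `fit`, `lower`,
#'   `upper`; attributes `draws` and `seed`.
#' @export
monte_carlo_band <- function(model, grid, draws = 10000, seed = NULL) {
  check_non_negative(grid, "grid")
  if (is.null(model$se) || any(!is.finite(model$se))) {
    abort("Model standard errors are missing; cannot simulate.",
          class = c("rhizo_invalid_model", "rhizo_error"))
  }
  check_positive(draws, "draws")
  par_draws <- with_seed_if(seed, {
    vapply(names(model$estimate), function(nm) {
      rnorm(draws, model$estimate[[nm]], model$se[[nm]])
    }, numeric(draws))
  })
  par_draws <- matrix(par_draws, nrow = draws,
                      dimnames = list(NULL, names(model$estimate)))
  curves <- vapply(seq_len(draws), function(i) {
    m_i <- list(form = model$form,
                estimate = par_draws[i, , drop = TRUE],
                breakpoint = model$breakpoint)
    evaluate_empirical(m_i, grid)
  }, numeric(length(grid)))
  curves <- matrix(curves, nrow = length(grid))
  band <- tibble(
    rld = grid,
    fit = evaluate_empirical(model, grid),
    lower = apply(curves, 1, quantile, probs = 0.025, names = FALSE),
    upper = apply(curves, 1, quantile, probs = 0.975, names = FALSE)
  )
  structure(band, class = c("mc_band", class(band)),
            draws = draws, seed = seed, form = model$form)
}

#' Flag where two erosion curves separate
#'
#' Two fitted curves are significantly different (P < 0.05) wherever one
#' model's point curve falls outside the other's 95% Monte-Carlo band.
#'
#' @param a,b `mc_band` objects on the same RLD grid.
#' @return A tibble with columns `rld`, `a_outside_b`, `b_outside_a` and
#'   `significant` (either curve outside the other's band).
#' @export
compare_bands <- function(a, b) {
  if (length(a$rld) != length(b$rld) ||
      any(abs(a$rld - b$rld) > 1e-9)) {
    stop_invalid("Bands must share the same RLD grid.")
  }
  a_out <- a$fit < b$lower | a$fit > b$upper
  b_out <- b$fit < a$lower | b$fit > a$upper
  tibble(rld = a$rld, a_outside_b = a_out, b_outside_a = b_out,
         significant = a_out | b_out)
}

#' @method autoplot mc_band
#' @export
autoplot.mc_band <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$rld, .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(RLD ~ (km ~ m^-3)),
                  y = "Relative detachment")
}

#' @method autoplot erosion_model
#' @export
autoplot.erosion_model <- function(object, band = NULL, ...) {
  grid <- seq(0, max(object$data$rld), length.out = 200)
  curve <- tibble(rld = grid, fit = evaluate_empirical(object, grid))
  p <- ggplot2::ggplot(object$data, ggplot2::aes(.data$rld, .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$fit)) +
    ggplot2::labs(x = expression(RLD ~ (km ~ m^-3)),
                  y = "Relative detachment")
  if (!is.null(band)) {
    p <- p + ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$rld, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.25
    )
  }
  p
}
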