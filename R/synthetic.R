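#' Genotype profiles used by the synthetic-data generators
#'
#' Bundles the per-genotype quantities the generators and models share:
#' substrate-specific specific root length (m mg^-1), the detachment hazard
#' ratio relative to wild type, the empirical erosion-reduction model
#' (exponent, and plateau/breakpoint for the hairless line), the RLD range
#' realised in erosion boxes, the logarithmic reinforcement coefficient and
#' the mechanistic enhancement parameters. The three named profiles carry
#' the published characterisations of the wild-type, hairless (*cpc try*)
#' and hair-overproducing (*wer myb23*) lines; aerial-mass settings are
#' generator placeholders, not measured values.
#'
#' @param name One of `"wild_type"`, `"cpc_try"`, `"wer_myb23"`.
#' @return A list of class `genotype_profile`.
#' @export
#' @examples
#' genotype_profile("wild_type")$empirical_b # -0.095
genotype_profile <- function(name = c("wild_type", "cpc_try", "wer_myb23")) {
  name <- match.arg(name)
  defaults <- list(
    wild_type = list(
      name = "wild_type",
      srl = c(clay = 0.63, compost = 0.51, erosion = 0.44),
      srl_sd = c(clay = 0.04, compost = 0.03, erosion = 0.05),
      detach_hazard_ratio = 1,
      form = "exponential",
      empirical_b = -0.095, empirical_b_se = 0.007,
      plateau = NA_real_, plateau_se = NA_real_, breakpoint = NA_real_,
      rld_range = c(3, 56),
      reinforcement_a = 1.23,
      M1 = 5.45e-3, M_max = 139
    ),
    cpc_try = list(
      name = "cpc_try",
      srl = c(clay = 0.43, compost = 0.39, erosion = 0.52),
      srl_sd = c(clay = 0.07, compost = 0.02, erosion = 0.10),
      detach_hazard_ratio = 6.369,
      form = "piecewise",
      empirical_b = -0.069, empirical_b_se = 0.007,
      plateau = 0.268, plateau_se = 0.033, breakpoint = 19,
      rld_range = c(8, 48),
      reinforcement_a = 0.50,
      M1 = 3.815e-3, M_max = 88
    ),
    wer_myb23 = list(
      name = "wer_myb23",
      srl = c(clay = 1.02, compost = 0.53, erosion = 0.58),
      srl_sd = c(clay = 0.31, compost = 0.02, erosion = 0.15),
      detach_hazard_ratio = 0.553,
      form = "exponential",
      empirical_b = -0.066, empirical_b_se = 0.008,
      plateau = NA_real_, plateau_se = NA_real_, breakpoint = NA_real_,
      rld_range = c(5, 34),
      reinforcement_a = 0.86,
      M1 = 3.085e-3, M_max = 134
    )
  )
  structure(defaults[[name]], class = "genotype_profile")
}

# Empirical relative-detachment model implied by a profile.
profile_model <- function(profile) {
  if (profile$form == "piecewise") {
    list(form = "piecewise",
         estimate = c(b = profile$empirical_b, plateau = profile$plateau),
         breakpoint = profile$breakpoint)
  } else {
    list(form = "exponential", estimate = c(b = profile$empirical_b))
  }
}

#' Simulate a centrifuge detachment cohort
#'
#' Draws aerial masses from a lognormal distribution and detachment forces
#' from a Weibull baseline under a proportional-hazards construction on the
#' force scale: a profile with hazard ratio HR has survival
#' \eqn{S(f) = S_0(f)^{HR}}, so hairless lines (HR > 1) detach at lower
#' forces. Each seedling's force is mapped to the first spin setting whose
#' seedling-specific centrifugal force reaches it; seedlings surviving the
#' maximum tested setting are censored.
#'
#' @param n Number of seedlings.
#' @param profile A [genotype_profile()].
#' @param protocol A [spin_protocol()].
#' @param seed Optional integer seed.
#' @param mass_median_mg Median aerial mass, mg (placeholder default 20).
#' @param mass_cv Coefficient of variation of aerial mass.
#' @param baseline_scale,baseline_shape Weibull scale (N) and shape of the
#'   wild-type detachment-force distribution.
#' @return A cohort tibble (columns `id`, `genotype`, `aerial_mass_mg`,
#'   `detach_setting`) ready for [detachment_curve()] and
#'   [export_event_table()].
#' @export
gen_detachment_cohort <- function(n, profile = genotype_profile("wild_type"),
                                  protocol = spin_protocol(), seed = NULL,
                                  mass_median_mg = 20, mass_cv = 0.3,
                                  baseline_scale = 0.02,
                                  baseline_shape = 2) {
  if (n < 1) stop_invalid("`n` must be >= 1.")
  check_positive(profile$detach_hazard_ratio, "detach_hazard_ratio")
  with_seed_if(seed, {
    sdlog <- sqrt(log(1 + mass_cv^2))
    mass_mg <- rlnorm(n, meanlog = log(mass_median_mg), sdlog = sdlog)
    # Inverse-transform under S(f) = S0(f)^HR with Weibull S0.
    u <- runif(n)
    force <- baseline_scale *
      (-log(u) / profile$detach_hazard_ratio)^(1 / baseline_shape)
    # Force at setting n scales linearly in n for a given seedling.
    f1 <- centrifugal_force(mass_mg * 1e-6, 1, protocol)
    setting <- ceiling(force / f1)
    max_setting <- max(protocol$settings)
    detach_setting <- ifelse(setting <= max_setting,
                             pmax(setting, min(protocol$settings)),
                             NA_integer_)
    tibble(
      id = paste0(profile$name, "_", seq_len(n)),
      genotype = profile$name,
      aerial_mass_mg = mass_mg,
      detach_setting = as.integer(detach_setting)
    )
  })
}

#' Simulate an uprooting force-displacement trace
#'
#' Piecewise-linear damage model: load rises elastically at stiffness `k0`
#' to the peak `k0 * x_p`, then declines at slope `-h0` to zero at the
#' uprooting displacement \eqn{x_u = x_p (1 + k_0/h_0)}, giving the
#' closed-form energy \eqn{k_0 x_p x_u / 2}. Planted instantaneous drops
#' are superimposed on the rising branch (each followed by an elastic
#' reload at slope `2 k0` back to the envelope) so their magnitudes are
#' recoverable by [detect_force_drops()]; Gaussian noise is optional.
#'
#' @param k0 Elastic stiffness, N m^-1.
#' @param x_p Displacement at peak force, m.
#' @param h0 Post-peak softening slope magnitude, N m^-1.
#' @param drops Optional data frame with columns `at` (displacement, m,
#'   < `x_p`) and `size` (N); a bare numeric vector of sizes is placed
#'   evenly over the rising branch.
#' @param noise_sd Additive load noise, N.
#' @param n Number of samples.
#' @param seed Optional integer seed (noise only).
#' @return A `force_trace` tibble.
#' @export
gen_uprooting_trace <- function(k0, x_p, h0, drops = NULL, noise_sd = 0,
                                n = 2000, seed = NULL) {
  check_positive(k0, "k0")
  check_positive(x_p, "x_p")
  check_positive(h0, "h0")
  check_non_negative(noise_sd, "noise_sd")
  if (is.numeric(drops) && !is.data.frame(drops)) {
    k <- length(drops)
    drops <- tibble(at = x_p * seq_len(k) / (k + 1), size = drops)
  }
  x_u <- x_p * (1 + k0 / h0)
  # Include the peak displacement so peak force and energy are exact.
  x <- sort(unique(c(seq(0, x_u, length.out = n), x_p)))
  envelope <- function(x) {
    ifelse(x <= x_p, k0 * x, pmax(k0 * x_p - h0 * (x - x_p), 0))
  }
  if (!is.null(drops)) {
    check_columns(drops, c("at", "size"), "drops")
    if (any(drops$at >= x_p)) {
      stop_invalid("Planted drops must sit on the rising branch (`at` < `x_p`).")
    }
    if (any(drops$size > envelope(drops$at))) {
      stop_invalid("A drop cannot exceed the instantaneous load.")
    }
    # Duplicate samples at each drop so the discontinuity is exact.
    x <- sort(c(x, rep(drops$at, 2)))
  }
  load <- envelope(x)
  if (!is.null(drops) && nrow(drops) > 0) {
    for (i in seq_len(nrow(drops))) {
      a <- drops$at[i]
      sz <- drops$size[i]
      reload <- envelope(a) - sz + 2 * k0 * (x - a)
      after <- x >= a
      # Second duplicated sample at `a` takes the dropped value.
      dup <- which(x == a)
      load[after] <- pmin(load[after], reload[after])
      if (length(dup) >= 2) load[dup[1]] <- envelope(a)
    }
  }
  if (noise_sd > 0) {
    load <- with_seed_if(seed, load + rnorm(length(load), 0, noise_sd))
  }
  as_force_trace(tibble(displacement = x, load = load))
}

#' Simulate a batch of flume erosion runs
#'
#' Boxes are assigned plant densities cycled through `densities`; each
#' box's RLD is placed within the genotype's observed range according to
#' its density rank, with multiplicative jitter. The expected relative
#' detachment of a box follows the genotype's empirical model, and each
#' 5-s capture's sediment mass is `bare_rate * ratio * area * duration`
#' under mean-one multiplicative lognormal noise. Bare control boxes enter
#' at RLD 0.
#'
#' @param n_boxes Number of rooted boxes.
#' @param profile A [genotype_profile()].
#' @param densities Plants per box, cycled over rooted boxes.
#' @param bare_rate Bare-soil detachment rate, kg m^-2 s^-1.
#' @param sigma Lognormal noise sigma of interval sediment masses (0 for a
#'   noiseless batch).
#' @param n_bare Number of bare control boxes.
#' @param rld_jitter Lognormal sigma of the within-range RLD placement.
#' @param box_area Box surface area, m^2.
#' @param seed Optional integer seed.
#' @return A tibble with one row per box: `box_id`, `genotype`,
#'   `plant_count`, `rld`, `ratio_true` (the generating relative
#'   detachment) and the `intervals` list-column consumed by
#'   [detachment_rate()].
#' @export
gen_erosion_runs <- function(n_boxes = 18,
                             profile = genotype_profile("wild_type"),
                             densities = c(9, 16, 32, 49, 81, 100),
                             bare_rate = 0.5, sigma = 0.3, n_bare = 3,
                             rld_jitter = 0.15, box_area = 0.0625,
                             seed = NULL) {
  if (n_boxes < 1) stop_invalid("`n_boxes` must be >= 1.")
  check_positive(bare_rate, "bare_rate")
  check_non_negative(sigma, "sigma")
  model <- profile_model(profile)
  with_seed_if(seed, {
    plant_count <- rep_len(densities, n_boxes)
    dens_pos <- (plant_count - min(densities)) /
      max(max(densities) - min(densities), 1)
    lo <- profile$rld_range[1]
    hi <- profile$rld_range[2]
    rld <- (lo + dens_pos * (hi - lo)) *
      rlnorm(n_boxes, -rld_jitter^2 / 2, rld_jitter)
    rld <- pmin(pmax(rld, lo), hi)
    boxes <- tibble(
      box_id = c(paste0(profile$name, "_", seq_len(n_boxes)),
                 paste0("bare_", seq_len(n_bare))),
      genotype = c(rep(profile$name, n_boxes), rep("bare", n_bare)),
      plant_count = c(plant_count, rep(0L, n_bare)),
      rld = c(rld, rep(0, n_bare))
    )
    boxes$ratio_true <- evaluate_empirical(model, boxes$rld)
    starts <- seq(0, 110, by = 10)
    boxes$intervals <- purrr::map(boxes$ratio_true, function(ratio) {
      expected <- bare_rate * ratio * box_area * 5
      noise <- if (sigma > 0) {
        rlnorm(length(starts), -sigma^2 / 2, sigma)
      } else {
        rep(1, length(starts))
      }
      tibble(start_s = starts, duration_s = 5,
             sediment_kg = expected * noise)
    })
    boxes
  })
}

#' Simulate specific-root-length records
#'
#' SRL values are normal (truncated positive) around the genotype's
#' substrate-specific mean; dry masses are lognormal.
#'
#' @param n Number of records.
#' @param profile A [genotype_profile()].
#' @param substrate One of `"clay"`, `"compost"`, `"erosion"`.
#' @param mass_median_mg Median root dry mass, mg.
#' @param mass_cv Coefficient of variation of dry mass.
#' @param srl_sd Override of the profile's SRL standard deviation (e.g. 0
#'   for a degenerate batch).
#' @param container_volume Pot volume, m^3.
#' @param seed Optional integer seed.
#' @return A tibble with columns `dry_mass_mg`, `srl`, `container_volume`
#'   and `rld` (via [root_length_density()]).
#' @export
gen_root_population <- function(n, profile = genotype_profile("wild_type"),
                                substrate = c("clay", "compost", "erosion"),
                                mass_median_mg = 5, mass_cv = 0.4,
                                srl_sd = NULL, container_volume = 3.75e-4,
                                seed = NULL) {
  if (n < 1) stop_invalid("`n` must be >= 1.")
  substrate <- match.arg(substrate)
  mu <- profile$srl[[substrate]]
  sdv <- if (is.null(srl_sd)) profile$srl_sd[[substrate]] else srl_sd
  with_seed_if(seed, {
    srl <- rnorm(n, mu, sdv)
    while (any(srl <= 0)) {
      srl[srl <= 0] <- rnorm(sum(srl <= 0), mu, sdv)
    }
    sdlog <- sqrt(log(1 + mass_cv^2))
    mass <- rlnorm(n, log(mass_median_mg), sdlog)
    tibble(
      genotype = profile$name,
      substrate = substrate,
      dry_mass_mg = mass,
      srl = srl,
      container_volume = container_volume,
      rld = root_length_density(mass, srl, container_volume)
    )
  })
}
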