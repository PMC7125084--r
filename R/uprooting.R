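#' Force-displacement trace utilities
#'
#' An uprooting trace records load (N) against vertical displacement (m)
#' while a plant is pulled from its substrate at constant speed. The
#' root-soil system first deforms quasi-elastically (`f(x) = k(x) x` up to
#' the peak), then accumulates damage and the force decays to zero at the
#' uprooting displacement; discrete force drops along the way mark root or
#' bond failures.
#'
#' @param df Data frame with numeric columns `displacement` (m,
#'   non-decreasing) and `load` (N).
#' @return `df` as a tibble of class `force_trace`.
#' @export
as_force_trace <- function(df) {
  check_columns(df, c("displacement", "load"), "trace")
  validate_trace(df)
  structure(as_tibble(df), class = c("force_trace", class(as_tibble(df))))
}

validate_trace <- function(trace) {
  check_columns(trace, c("displacement", "load"), "trace")
  if (nrow(trace) < 2) stop_invalid("A trace needs at least 2 samples.")
  if (any(!is.finite(trace$load))) stop_invalid("Loads must be finite.")
  if (any(diff(trace$displacement) < 0)) {
    stop_invalid("`displacement` must be non-decreasing.",
                 class = "rhizo_invalid_trace")
  }
  invisible(trace)
}

#' Read an uprooting trace from CSV
#'
#' Expects columns `displacement_mm` and `load_N`; displacement is converted
#' to metres.
#'
#' @param file Path to a CSV file.
#' @return A `force_trace` tibble.
#' @export
read_trace <- function(file) {
  df <- readr::read_csv(file, show_col_types = FALSE)
  check_columns(df, c("displacement_mm", "load_N"), "trace file")
  as_force_trace(tibble(displacement = df$displacement_mm / 1000,
                        load = df$load_N))
}

#' Peak uprooting force
#'
#' Maximum load over samples at or above the load-cell noise threshold
#' (default 0.05 N, the stated accuracy floor of a 10 N cell; 0.1 and
#' 0.035 N are conventional sensitivity alternates).
#'
#' @param trace A force trace (see [as_force_trace()]).
#' @param threshold Noise threshold in N.
#' @return Peak force in N.
#' @export
peak_force <- function(trace, threshold = 0.05) {
  validate_trace(trace)
  above <- trace$load >= threshold
  if (!any(above)) {
    abort("No load sample reaches the noise threshold.",
          class = c("rhizo_no_signal", "rhizo_error"))
  }
  max(trace$load[above])
}

# Index of the uprooting endpoint: the last downward crossing of the
# threshold after the global peak, else the end of the trace.
uprooting_index <- function(trace, threshold) {
  n <- nrow(trace)
  peak_idx <- which.max(trace$load)
  if (peak_idx >= n) return(n)
  idx <- seq(peak_idx + 1L, n)
  crossing <- idx[trace$load[idx] < threshold & trace$load[idx - 1L] >= threshold]
  if (length(crossing) == 0) n else max(crossing)
}

#' Total uprooting energy
#'
#' Trapezoidal integral of load over displacement from the start of the
#' pull to the uprooting point, taken as the last sample where the load
#' falls back below the noise threshold (or the end of the trace if it
#' never does).
#'
#' @inheritParams peak_force
#' @return Energy in joules.
#' @export
total_energy <- function(trace, threshold = 0.05) {
  validate_trace(trace)
  end <- uprooting_index(trace, threshold)
  if (end < 2) return(0)
  pracma::trapz(trace$displacement[1:end], trace$load[1:end])
}

#' Incremental force drops
#'
#' A drop is the decline in load from a local maximum to the next local
#' minimum of the load sequence; only drops of at least `min_drop` are
#' returned, in displacement order. Boundary extrema are not counted, so a
#' monotone rise yields no drops and the terminal decline to zero is not
#' itself a drop. An optional moving-median smoother (off by default) can
#' be applied before detection for noisy traces.
#'
#' @inheritParams peak_force
#' @param min_drop Smallest drop magnitude to report, N.
#' @param smooth_window Odd window width for a running-median smoother;
#'   0 disables smoothing.
#' @return A tibble with columns `displacement` (location of the local
#'   maximum, m) and `drop` (N); zero rows if none.
#' @export
detect_force_drops <- function(trace, min_drop = 0.05, smooth_window = 0) {
  validate_trace(trace)
  y <- trace$load
  if (smooth_window >= 3) {
    y <- runmed(y, k = 2 * (smooth_window %/% 2) + 1, endrule = "keep")
  }
  # Compress runs of equal values so plateaus form single extrema.
  r <- rle(y)
  v <- r$values
  last_idx <- cumsum(r$lengths) # original index of each run's last sample
  m <- length(v)
  if (m < 3) return(tibble(displacement = numeric(), drop = numeric()))
  s <- sign(diff(v))
  interior <- 2:(m - 1)
  is_max <- s[interior - 1] > 0 & s[interior] < 0
  is_min <- s[interior - 1] < 0 & s[interior] > 0
  maxima <- interior[is_max]
  minima <- interior[is_min]
  if (length(maxima) == 0 || length(minima) == 0) {
    return(tibble(displacement = numeric(), drop = numeric()))
  }
  drops <- purrr::map_dfr(maxima, function(i) {
    nxt <- minima[minima > i]
    if (length(nxt) == 0) return(NULL)
    j <- nxt[1]
    tibble(displacement = trace$displacement[last_idx[i]],
           drop = v[i] - v[j])
  })
  dplyr::filter(drops, .data$drop >= min_drop)
}

#' Root length density from dry mass and specific root length
#'
#' Converts a dry root mass to total root length through the genotype- and
#' substrate-specific specific root length (SRL, m mg^-1) and divides by
#' the container volume.
#'
#' @param dry_mass_mg Root dry mass, mg.
#' @param srl Specific root length, m mg^-1.
#' @param volume_m3 Container (pot or box) volume, m^3.
#' @return Root length density in km m^-3; vectorised.
#' @export
#' @examples
#' root_length_density(5, 0.63, 3.75e-4) # 8.4 km m^-3
root_length_density <- function(dry_mass_mg, srl, volume_m3) {
  check_positive(dry_mass_mg, "dry_mass_mg")
  check_positive(srl, "srl")
  check_positive(volume_m3, "volume_m3")
  dry_mass_mg * srl / volume_m3 / 1000
}

#' Summarise an uprooting trace
#'
#' Aggregates peak force, total energy and force drops, and normalises the
#' peak and energy per metre of root (metric divided by total root length =
#' RLD x container volume), the scale on which genotypes are compared.
#'
#' @inheritParams peak_force
#' @inheritParams detect_force_drops
#' @param dry_mass_mg,srl,volume_m3 Passed to [root_length_density()].
#' @return A one-row tibble with `peak_force` (N), `total_energy` (J),
#'   `n_drops`, `drops` (list column of the drop table), `rld` (km m^-3),
#'   `root_length_m`, `peak_per_m_root` and `energy_per_m_root`.
#' @export
summarize_uproot <- function(trace, dry_mass_mg, srl, volume_m3 = 3.75e-4,
                             min_drop = 0.05, threshold = 0.05) {
  rld <- root_length_density(dry_mass_mg, srl, volume_m3)
  root_length <- rld * 1000 * volume_m3 # metres of root
  drops <- detect_force_drops(trace, min_drop = min_drop)
  pk <- peak_force(trace, threshold = threshold)
  en <- total_energy(trace, threshold = threshold)
  tibble(
    peak_force = pk,
    total_energy = en,
    n_drops = nrow(drops),
    drops = list(drops),
    rld = rld,
    root_length_m = root_length,
    peak_per_m_root = pk / root_length,
    energy_per_m_root = en / root_length
  )
}

#' @method autoplot force_trace
#' @export
autoplot.force_trace <- function(object, min_drop = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$displacement, .data$load)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Displacement (m)", y = "Load (N)")
  if (!is.null(min_drop)) {
    drops <- detect_force_drops(object, min_drop = min_drop)
    if (nrow(drops) > 0) {
      p <- p + ggplot2::geom_vline(
        xintercept = drops$displacement, linetype = "dotted", colour = "red"
      )
    }
  }
  p
}
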