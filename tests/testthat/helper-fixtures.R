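# Shared fixtures, built in code.

# Symmetric triangular trace: rise to `peak` N at `x_peak`, back to zero at
# 2 * x_peak.
triangle_trace <- function(peak = 1, x_peak = 0.01, n = 2001) {
  x <- seq(0, 2 * x_peak, length.out = n)
  load <- ifelse(x <= x_peak, peak * x / x_peak,
                 peak * (2 * x_peak - x) / x_peak)
  tibble::tibble(displacement = x, load = load)
}

# Evaluate a detachment curve (step function, right-continuous) at given
# forces for one genotype.
curve_at <- function(curve, forces, genotype = NULL) {
  if (!is.null(genotype)) {
    curve <- curve[curve$genotype == genotype, ]
  }
  stats::approx(curve$force, curve$proportion_attached, xout = forces,
                method = "constant", f = 0, rule = 2)$y
}

# Erosion model object with hand-set coefficients (for evaluation and
# Monte-Carlo tests that do not need a fit).
manual_model <- function(b, b_se = NA_real_, plateau = NULL,
                         plateau_se = NA_real_, form = "exponential",
                         breakpoint = NA_real_) {
  est <- c(b = b)
  se <- c(b = b_se)
  if (!is.null(plateau)) {
    est <- c(est, plateau = plateau)
    se <- c(se, plateau = plateau_se)
  }
  structure(list(form = form, estimate = est, se = se,
                 breakpoint = breakpoint),
            class = "erosion_model")
}

# Brute-force spatial integration of the eroded fraction: midpoint rule on
# the indicator over half a period (cosine symmetry).
erosion_fraction_oracle <- function(tau, gamma, c_bare, R, r, n = 2e6) {
  theta <- (seq_len(n) - 0.5) * pi / n
  rho <- (R + r) / 2 + (R - r) / 2 * cos(theta)
  mean(tau > c_bare * (1 + gamma * rho))
}
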