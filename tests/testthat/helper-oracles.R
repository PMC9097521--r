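# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: slopes from explicit sums, particle counts from
# mass bookkeeping, roots from bisection.

# Closed-form OLS slope/intercept/SE from the normal-equation sums.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sigma2 <- sum(resid^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(sigma2 / sxx),
       intercept_se = sqrt(sigma2 * (1 / n + mean(x)^2 / sxx)))
}

# Brute-force count of particles holding 1 mmol of SiO2: mass of 1 mmol
# divided by the mass of one particle.
oracle_particles_per_mmol <- function(R, density = 2.196, molar_mass = 60.08) {
  (molar_mass / 1000) / ((4 / 3) * pi * R^3 * density)
}

# Bisection root of f on [lo, hi]; assumes a sign change.
oracle_bisect <- function(f, lo, hi, iter = 200) {
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

default_radii_cm <- nm_to_cm(c(6.75, 15, 25, 46, 66, 86))
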