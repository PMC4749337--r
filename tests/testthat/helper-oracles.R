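# Shared fixtures and independent oracles for the test suite.

basis <- load_basis_tables()

# Independent transcription of the average-observer (zero-deviation) recipe,
# written as an explicit per-wavelength loop so it shares no code with the
# vectorised implementation.  Returns unit-peak l, m, s columns.
average_observer_recipe <- function(age, v, basis) {
  grid <- basis$wavelength_nm
  n <- length(grid)
  out <- matrix(0, n, 3L)
  aging <- if (age <= 60) 1 + 0.02 * (age - 32) else 1.56 + 0.0667 * (age - 60)
  dmax_lm <- 0.38 + 0.54 * exp(-v / 1.333)
  dmax_s <- 0.30 + 0.45 * exp(-v / 1.333)
  mac_peak <- 0.485 * exp(-v / 6.132)
  for (i in seq_len(n)) {
    docul <- basis$docul1[i] * aging + basis$docul2[i]
    dmac <- mac_peak * basis$d_rel_macula[i]
    filt <- 10^(-dmac - docul)
    for (j in 1:3) {
      dmax <- if (j == 3) dmax_s else dmax_lm
      alpha <- 1 - 10^(-dmax * basis$absorbance[i, j])
      out[i, j] <- alpha * filt * grid[i]
    }
  }
  for (j in 1:3) out[, j] <- out[, j] / max(out[, j])
  colnames(out) <- c("l", "m", "s")
  out
}

# Random smooth nonnegative spectrum on the stimulus grid (mixture of broad
# Gaussians plus a floor); used to build random full-rank match setups.
random_spectrum <- function(grid = 380:780) {
  centers <- stats::runif(3, 420, 680)
  widths <- stats::runif(3, 30, 90)
  amps <- stats::runif(3, 0.2, 1)
  v <- rep(0.02, length(grid))
  for (k in 1:3) v <- v + amps[k] * exp(-((grid - centers[k]) / widths[k])^2)
  spectral_function(grid, v)
}

random_match_setup <- function(label = "random", grid = 380:780) {
  prim <- cbind(exp(-((grid - stats::runif(1, 580, 650)) / stats::runif(1, 15, 30))^2),
                exp(-((grid - stats::runif(1, 510, 570)) / stats::runif(1, 20, 35))^2),
                exp(-((grid - stats::runif(1, 430, 480)) / stats::runif(1, 12, 25))^2))
  match_setup(random_spectrum(grid), prim,
              sample(c("reference-shape", "equal-energy"), 1L), label = label)
}

# SD of a zero-mean normal left-truncated at `bound` (the sampler rejects
# and redraws below the physical -100% bound, so its true SD is the
# truncated-normal SD, not the input SD).
truncated_sd <- function(sigma, bound = -100) {
  if (sigma == 0) return(0)
  a <- bound / sigma
  lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
  sigma * sqrt(1 + a * lam - lam^2)
}
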