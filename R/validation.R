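#' Validation scenario
#'
#' Describes one population-variability prediction: the kind of measurement
#' being emulated (`"cmf_rgb"` — primary-normalised CMF dispersion across a
#' wavelength list; `"color_matches"` — CIELAB a*/b* dispersion over a set
#' of metameric matches; `"rayleigh"` — dispersion of anomaloscope red
#' fractions), the cohort size and age source, the field size, the stimuli,
#' and how many independent Monte Carlo repeats to average.
#'
#' @param kind One of `"cmf_rgb"`, `"color_matches"`, `"rayleigh"`.
#' @param n_observers Observers per Monte Carlo draw.
#' @param ages An [age_source()].
#' @param field_size Field size in degrees.
#' @param setups List of [match_setup()]s (required for `"color_matches"`).
#' @param wavelengths Evaluation wavelengths for `"cmf_rgb"`; `NULL` uses a
#'   documented default of 35 wavelengths equally spaced in wavenumber
#'   across 392.2--714.3 nm.
#' @param primary_wavelengths rgb-normalisation primaries for `"cmf_rgb"`
#'   (default 645.2, 526.3, 444.4 nm).
#' @param rayleigh_primaries `c(red, green, yellow)` wavelengths for
#'   `"rayleigh"` (default 700, 550, 589 nm).
#' @param n_repeats Monte Carlo repeats to average (default 100).
#' @return A list of class `validation_scenario`.
#' @export
validation_scenario <- function(kind = c("cmf_rgb", "color_matches",
                                         "rayleigh"),
                                n_observers, ages, field_size,
                                setups = NULL, wavelengths = NULL,
                                primary_wavelengths = c(645.2, 526.3, 444.4),
                                rayleigh_primaries = c(700, 550, 589),
                                n_repeats = 100L) {
  kind <- match.arg(kind)
  if (n_repeats < 1L) {
    stop("validation_scenario: n_repeats must be >= 1", call. = FALSE)
  }
  if (n_observers < 2L) {
    stop("validation_scenario: n_observers must be >= 2", call. = FALSE)
  }
  if (kind == "color_matches" && length(setups) == 0L) {
    stop("validation_scenario: color_matches needs setups", call. = FALSE)
  }
  if (kind == "cmf_rgb" && is.null(wavelengths)) {
    wavelengths <- 1e7 / seq(1e7 / 392.2, 1e7 / 714.3, length.out = 35)
  }
  structure(list(kind = kind, n_observers = as.integer(n_observers),
                 ages = ages, field_size = field_size, setups = setups,
                 wavelengths = wavelengths,
                 primary_wavelengths = primary_wavelengths,
                 rayleigh_primaries = rayleigh_primaries,
                 n_repeats = as.integer(n_repeats)),
            class = "validation_scenario")
}

#' Predict a population standard deviation
#'
#' Runs the scenario's Monte Carlo prediction: for each repeat, sample a
#' cohort of observers, simulate the scenario's measurement, and take the
#' dispersion statistic; the prediction is the mean over repeats (averaging
#' repeats tightens the estimate roughly as 1/sqrt(n_repeats)).
#'
#' For `"cmf_rgb"` each observer's fundamentals are transformed to
#' primary-normalised rgb CMFs ([lms_to_rgb()]), evaluated at the scenario
#' wavelengths; the SD across observers is taken per (wavelength, primary)
#' and all of them averaged.  For `"color_matches"` the statistic is the
#' mean over matches of the a*/b* SDs ([simulate_matches()]).  For
#' `"rayleigh"` it is the SD of the red fraction across observers.
#'
#' @param scenario A [validation_scenario()].
#' @param sds An [sd_table()].
#' @param basis A `basis_tables` object.
#' @param seed Integer seed; each repeat uses a derived substream.
#' @return A list with `sd` (mean predicted SD), `per_repeat` (vector of
#'   per-repeat SDs) and `kind`.
#' @export
predict_population_sd <- function(scenario, sds = sd_table("step2"),
                                  basis = default_basis(), seed = 1L) {
  stopifnot(inherits(scenario, "validation_scenario"))
  seeds <- substream_seeds(seed, scenario$n_repeats)
  per_repeat <- vapply(seq_len(scenario$n_repeats), function(r) {
    specs <- sample_observers(scenario$n_observers, scenario$ages,
                              scenario$field_size, sds, seed = seeds[r])
    lms <- population_lms(specs, basis)
    switch(scenario$kind,
           cmf_rgb = cmf_rgb_sd(lms, scenario),
           color_matches = mean(simulate_matches_lms(lms, scenario$setups,
                                                     basis)$summary$sd_ab),
           rayleigh = stats::sd(rayleigh_matches_lms(
             lms, scenario$rayleigh_primaries[1L],
             scenario$rayleigh_primaries[2L],
             scenario$rayleigh_primaries[3L])))
  }, numeric(1))
  list(sd = mean(per_repeat), per_repeat = per_repeat, kind = scenario$kind)
}

# SD of primary-normalised rgb CMFs across a cohort: per observer, build the
# rgb transform from its own fundamentals, evaluate at the scenario
# wavelengths, then SD over observers per (wavelength, primary), averaged.
cmf_rgb_sd <- function(lms, scenario) {
  n <- nrow(lms$l)
  wl <- scenario$wavelengths
  op_w <- t(resample_operator(lms$grid, wl))       # 89 x n_wl
  op_p <- t(resample_operator(lms$grid, scenario$primary_wavelengths))
  lw <- lms$l %*% op_w; mw <- lms$m %*% op_w; sw <- lms$s %*% op_w
  lp <- lms$l %*% op_p; mp <- lms$m %*% op_p; sp <- lms$s %*% op_p
  rgb <- array(0, dim = c(n, 3L, length(wl)))
  for (i in seq_len(n)) {
    k <- rbind(c(lp[i, ]), c(mp[i, ]), c(sp[i, ]))  # lms x primaries
    rgb[i, , ] <- solve(k) %*% rbind(lw[i, ], mw[i, ], sw[i, ])
  }
  mean(apply(rgb, c(2L, 3L), stats::sd))
}

#' Two-sample variance-ratio (F) test
#'
#' Two-tailed F test of equality of variances (sample variances with the
#' n - 1 convention), as used to compare measured against simulated
#' dispersion variable by variable.  Thin wrapper over [stats::var.test()].
#'
#' @param sample_a,sample_b Numeric vectors with at least two values each.
#' @param alpha Significance level for the rejection flag (default 0.05,
#'   i.e. a 95% confidence level).
#' @return A list with `statistic` (F = var_a / var_b), `p_value` (two
#'   tailed), `df` (numerator, denominator), and `reject`.
#' @export
variance_ratio_test <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("variance_ratio_test: each sample needs >= 2 values", call. = FALSE)
  }
  if (stats::var(sample_b) == 0) {
    stop("variance_ratio_test: zero variance in the denominator sample",
         call. = FALSE)
  }
  ht <- stats::var.test(sample_a, sample_b, alternative = "two.sided")
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), reject = ht$p.value < alpha)
}
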