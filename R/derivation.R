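#' Pool study standard deviations
#'
#' Combines the reported standard deviations of several studies of one
#' physiological parameter into a single SD: convert to variances, average
#' with equal weights, and take the square root, i.e. `sqrt(mean(values^2))`.
#' No study weighting is applied — methodologies are too diverse for any
#' weighting to be non-arbitrary.
#'
#' @param values Numeric vector of per-study SDs (>= 0, non-empty).
#' @return The pooled SD (scalar).
#' @export
pool_sds <- function(values) {
  if (length(values) == 0L) {
    stop("pool_sds: empty value list", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("pool_sds: SDs must be finite and >= 0", call. = FALSE)
  }
  sqrt(mean(values^2))
}

#' Literature SD table for the eight physiological parameters
#'
#' Reads the packaged per-study standard deviations (columns `study`, `year`,
#' `meas_type`, `method`, `repetitions`, `subjects`, `age_range`,
#' `parameter`, `sd`).  Parameters are `lens`, `macula`, `density_L`,
#' `density_M`, `density_S` (SDs in percent) and `shift_L`, `shift_M`,
#' `shift_S` (SDs in nm).  Studies reporting a joint L/M photopigment
#' density appear as one row per cone.
#'
#' @param path CSV path; `NULL` uses the packaged table.
#' @return A data frame of per-study SDs.
#' @export
load_study_sds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "studies", "study_sds.csv",
                        package = "indivobs")
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("study", "parameter", "sd")
  if (!all(need %in% names(df))) {
    stop("load_study_sds: required columns missing", call. = FALSE)
  }
  df
}

#' Pooled (step 1) SD table
#'
#' Applies [pool_sds()] per parameter to a per-study SD table to produce the
#' first-stage SD estimates of the eight physiological parameters.
#'
#' @param studies Data frame as returned by [load_study_sds()].
#' @return An [sd_table()] with stage `"step1"` holding the pooled values at
#'   full precision.
#' @export
derive_step1 <- function(studies = load_study_sds()) {
  fields <- c("lens", "macula", "density_L", "density_M", "density_S",
              "shift_L", "shift_M", "shift_S")
  vals <- vapply(fields, function(p) {
    pool_sds(studies$sd[studies$parameter == p])
  }, numeric(1))
  out <- sd_table("custom", vals)
  out$stage <- "step1"
  out
}

#' Per-study lens-density SDs from subject-level records
#'
#' Age strongly drives lens density, so a study's SD must be taken within
#' age windows: for every integer age centre with at least two subjects
#' within +/- `window_halfwidth` years, the sample SD of the windowed
#' densities is divided by the windowed mean (times 100, giving percent);
#' the study SD is the mean over all feasible centres.
#'
#' @param records Data frame with columns `study`, `age` (years, > 0) and
#'   `density` (> 0).
#' @param window_halfwidth Half-width of the age window in years (default 5).
#' @return Named numeric vector: one SD (percent) per study.
#' @export
lens_windowed_sds <- function(records, window_halfwidth = 5) {
  stopifnot(all(c("study", "age", "density") %in% names(records)))
  if (any(records$age <= 0) || any(records$density <= 0)) {
    stop("lens_windowed_sds: ages and densities must be > 0", call. = FALSE)
  }
  out <- vapply(split(records, records$study), function(df) {
    centers <- seq(floor(min(df$age)), ceiling(max(df$age)))
    sds <- vapply(centers, function(ctr) {
      sel <- abs(df$age - ctr) <= window_halfwidth
      if (sum(sel) < 2L) return(NA_real_)
      100 * stats::sd(df$density[sel]) / mean(df$density[sel])
    }, numeric(1))
    sds <- sds[!is.na(sds)]
    if (length(sds) == 0L) {
      stop("lens_windowed_sds: no age window with >= 2 subjects",
           call. = FALSE)
    }
    mean(sds)
  }, numeric(1))
  out
}

#' Scalar pair for the two-group SD rescaling
#'
#' @param c1 Scalar for the prereceptoral-filter SDs (lens, macula), in
#'   [0, 1].
#' @param c2 Scalar for the photopigment SDs (densities and shifts), in
#'   [0, 1].
#' @return A list of class `scalar_pair`.
#' @export
scalar_pair <- function(c1, c2) {
  if (!is.finite(c1) || !is.finite(c2) || c1 < 0 || c1 > 1 || c2 < 0 ||
      c2 > 1) {
    stop("scalar_pair: scalars must lie in [0, 1]", call. = FALSE)
  }
  structure(list(c1 = c1, c2 = c2), class = "scalar_pair")
}

#' Apply the two rescaling scalars to a step-1 SD table
#'
#' The first scalar multiplies the prereceptoral SDs (lens, macula); the
#' second multiplies the photopigment SDs (three densities, three shifts).
#'
#' @param step1 An [sd_table()].
#' @param scalars A [scalar_pair()].
#' @return An [sd_table()] with stage `"step2"`.
#' @export
apply_scalars <- function(step1, scalars) {
  stopifnot(inherits(step1, "sd_table"), inherits(scalars, "scalar_pair"))
  v <- sd_table_values(step1)
  v[1:2] <- v[1:2] * scalars$c1
  v[3:8] <- v[3:8] * scalars$c2
  out <- sd_table("custom", v)
  out$stage <- "step2"
  out
}

# Common-random-number Monte Carlo engine for the scalar fit: the age draw
# and a fixed queue of standard normals per (observer, parameter) are frozen
# from the seed, so the predicted SDs are a deterministic function of
# (c1, c2).  Rejection of deviations <= -100% walks along the queue instead
# of redrawing, preserving determinism.
make_sd_objective <- function(step1, target_sds, setups, ages, field_size,
                              n_mc, seed, metric = "cityblock",
                              basis = default_basis(), queue = 6L) {
  seeds <- substream_seeds(seed, 2L)
  set.seed(seeds[1L])
  age <- draw_ages(ages, n_mc)
  set.seed(seeds[2L])
  zq <- array(stats::rnorm(n_mc * 8L * queue), dim = c(n_mc, 8L, queue))
  pct <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)

  predict_sds <- function(pair) {
    sdv <- sd_table_values(apply_scalars(step1, pair))
    draws <- matrix(0, n_mc, 8L)
    for (j in seq_len(8L)) {
      d <- zq[, j, 1L] * sdv[j]
      if (pct[j]) {
        for (q in 2L:queue) {
          bad <- d <= -100
          if (!any(bad)) break
          d[bad] <- zq[bad, j, q] * sdv[j]
        }
        d[d <= -100] <- -99.99
      }
      draws[, j] <- d
    }
    params <- data.frame(age = age, field_size = field_size,
                         d_lens = draws[, 1L], d_macula = draws[, 2L],
                         d_L = draws[, 3L], d_M = draws[, 4L],
                         d_S = draws[, 5L], s_L = draws[, 6L],
                         s_M = draws[, 7L], s_S = draws[, 8L])
    lms <- cmf_matrix(params, basis)
    simulate_matches_lms(lms, setups, basis)$summary$sd_ab
  }

  function(par, return_sds = FALSE) {
    pair <- scalar_pair(min(max(par[1L], 0), 1), min(max(par[2L], 0), 1))
    pred <- predict_sds(pair)
    if (return_sds) return(pred)
    if (metric == "cityblock") {
      sum(abs(target_sds - pred))
    } else {
      sqrt(sum((target_sds - pred)^2))
    }
  }
}

#' Fit the two SD-rescaling scalars to target match variabilities
#'
#' Minimises the distance between per-match target SDs (the mean of the a*
#' and b* SDs for each match) and the SDs predicted by a Monte Carlo
#' forward simulation, over the two rescaling scalars in [0, 1]^2.  The
#' forward simulation draws `n_mc` observers at the given field size with
#' ages from `ages`; common random numbers across objective evaluations make
#' the objective deterministic, so the minimiser is well defined at finite
#' `n_mc`.  The search is a coarse grid followed by a Nelder--Mead polish.
#'
#' @param step1 The stage-1 [sd_table()] to rescale.
#' @param target_sds Numeric vector of per-match target SDs (one per setup,
#'   > 0).
#' @param setups List of [match_setup()]s (same order as `target_sds`).
#' @param ages An [age_source()].
#' @param field_size Field size in degrees for the simulated population
#'   (default 6.5).
#' @param n_mc Observers per objective evaluation (default 10000).
#' @param seed Integer seed for the common random numbers.
#' @param metric `"cityblock"` (default) or `"euclidean"` distance between
#'   target and predicted SD vectors.
#' @param basis A `basis_tables` object.
#' @param grid_step Spacing of the coarse initial grid over [0, 1]^2.
#' @param maxit Nelder--Mead iteration budget for the polish.
#' @return A [scalar_pair()] with attributes `objective` (value at the
#'   optimum), `predicted_sds`, and `evaluations`.
#' @export
optimize_scalars <- function(step1, target_sds, setups, ages,
                             field_size = 6.5, n_mc = 10000, seed = 1L,
                             metric = c("cityblock", "euclidean"),
                             basis = default_basis(), grid_step = 0.25,
                             maxit = 80L) {
  metric <- match.arg(metric)
  if (length(target_sds) != length(setups) || any(target_sds <= 0)) {
    stop("optimize_scalars: need one positive target SD per setup",
         call. = FALSE)
  }
  obj <- make_sd_objective(step1, target_sds, setups, ages, field_size,
                           n_mc, seed, metric, basis)
  n_eval <- 0L
  counted <- function(p) {
    n_eval <<- n_eval + 1L
    obj(p)
  }
  grid <- seq(0, 1, by = grid_step)
  cand <- as.matrix(expand.grid(c1 = grid, c2 = grid))
  vals <- apply(cand, 1L, counted)
  start <- cand[which.min(vals), ]
  fit <- stats::optim(start, counted, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-4))
  best <- pmin(pmax(fit$par, 0), 1)
  out <- scalar_pair(best[1L], best[2L])
  attr(out, "objective") <- fit$value
  attr(out, "predicted_sds") <- obj(best, return_sds = TRUE)
  attr(out, "evaluations") <- n_eval
  out
}

#' Synthetic target match variabilities from a finite cohort
#'
#' Stands in for a measured colour-matching dataset: forward-simulates a
#' cohort of `n_observers` and returns its per-match SDs (mean of the a* and
#' b* SDs).  Optionally each observer's a* and b* receive additive Gaussian
#' noise emulating intra-observer match variability.
#'
#' @param setups List of [match_setup()]s.
#' @param ages An [age_source()].
#' @param sds An [sd_table()] generating the cohort.
#' @param n_observers Cohort size (default 75).
#' @param field_size Field size in degrees (default 6.5).
#' @param intra_observer_sd SD (CIELAB units) of additive per-observer match
#'   noise; default 1.4, use 0 for a noise-free target.
#' @param seed Integer seed.
#' @param basis A `basis_tables` object.
#' @return Named numeric vector of per-match target SDs.
#' @export
synthetic_target <- function(setups, ages, sds, n_observers = 75,
                             field_size = 6.5, intra_observer_sd = 1.4,
                             seed = 1L, basis = default_basis()) {
  seeds <- substream_seeds(seed, 2L)
  specs <- sample_observers(n_observers, ages, field_size, sds,
                            seed = seeds[1L])
  lms <- population_lms(specs, basis)
  res <- simulate_matches_lms(lms, setups, basis)
  set.seed(seeds[2L])
  out <- vapply(seq_along(setups), function(k) {
    sel <- res$matches$label == setups[[k]]$label
    a <- res$matches$a[sel] + stats::rnorm(n_observers, 0, intra_observer_sd)
    b <- res$matches$b[sel] + stats::rnorm(n_observers, 0, intra_observer_sd)
    mean(c(stats::sd(a), stats::sd(b)))
  }, numeric(1))
  names(out) <- vapply(setups, `[[`, character(1), "label")
  out
}
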