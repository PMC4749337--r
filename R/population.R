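#' Standard-deviation table for the eight physiological parameters
#'
#' Holds one standard deviation per deviation parameter: lens and macular
#' densities and the three photopigment peak densities in percent, the three
#' lambda-max shifts in nm.  The `"step1"` stage is the pooled literature
#' row (19.1, 37.2, 17.9, 17.9, 14.7, 4.0, 3.0, 2.5); the `"step2"` stage is
#' the scaled row adopted by the model (18.7, 36.5, 9.0, 9.0, 7.4, 2.0, 1.5,
#' 1.3).
#'
#' @param stage `"step1"`, `"step2"` (default rows above) or `"custom"`, in
#'   which case `values` must be supplied.
#' @param values Named or positional numeric vector of the eight SDs in the
#'   order lens, macula, density_L, density_M, density_S, shift_L, shift_M,
#'   shift_S.  All must be >= 0.
#' @return A list of class `sd_table` with fields `lens`, `macula`,
#'   `density_L`, `density_M`, `density_S`, `shift_L`, `shift_M`, `shift_S`
#'   and `stage`.
#' @export
sd_table <- function(stage = c("step2", "step1", "custom"), values = NULL) {
  stage <- match.arg(stage)
  defaults <- list(
    step1 = c(19.1, 37.2, 17.9, 17.9, 14.7, 4.0, 3.0, 2.5),
    step2 = c(18.7, 36.5, 9.0, 9.0, 7.4, 2.0, 1.5, 1.3)
  )
  fields <- c("lens", "macula", "density_L", "density_M", "density_S",
              "shift_L", "shift_M", "shift_S")
  if (stage == "custom") {
    if (is.null(values) || length(values) != 8L) {
      stop("sd_table: stage 'custom' needs 8 values", call. = FALSE)
    }
    if (!is.null(names(values))) values <- values[fields]
  } else {
    if (!is.null(values)) {
      stop("sd_table: values are only accepted with stage 'custom'",
           call. = FALSE)
    }
    values <- defaults[[stage]]
  }
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("sd_table: SDs must be finite and >= 0", call. = FALSE)
  }
  out <- as.list(values)
  names(out) <- fields
  out$stage <- stage
  class(out) <- "sd_table"
  out
}

sd_table_values <- function(sds) {
  unlist(sds[c("lens", "macula", "density_L", "density_M", "density_S",
               "shift_L", "shift_M", "shift_S")])
}

#' @export
print.sd_table <- function(x, ...) {
  v <- sd_table_values(x)
  cat(sprintf("<sd_table> stage %s\n", x$stage))
  print(round(v, 2))
  invisible(x)
}

#' Age source for population sampling
#'
#' Either an explicit list of ages (drawn exactly when `n` equals the list
#' length, otherwise uniformly with replacement) or a uniform sampler over an
#' age range.
#'
#' @param ages Numeric vector of ages in years (all > 0), or `NULL`.
#' @param range Length-2 numeric `c(lo, hi)` for a uniform sampler, used when
#'   `ages` is `NULL`.
#' @return A list of class `age_source`.
#' @export
age_source <- function(ages = NULL, range = NULL) {
  if (!is.null(ages)) {
    ages <- as.numeric(ages)
    if (length(ages) == 0L || any(!is.finite(ages)) || any(ages <= 0)) {
      stop("age_source: ages must be positive and finite", call. = FALSE)
    }
    out <- list(kind = "list", ages = ages)
  } else if (!is.null(range)) {
    if (length(range) != 2L || range[1] <= 0 || range[2] < range[1]) {
      stop("age_source: range must be c(lo, hi) with 0 < lo <= hi",
           call. = FALSE)
    }
    out <- list(kind = "uniform", lo = range[1], hi = range[2])
  } else {
    stop("age_source: supply ages or range", call. = FALSE)
  }
  class(out) <- "age_source"
  out
}

draw_ages <- function(src, n) {
  stopifnot(inherits(src, "age_source"))
  if (src$kind == "uniform") {
    return(stats::runif(n, src$lo, src$hi))
  }
  if (n == length(src$ages)) src$ages else {
    sample(src$ages, n, replace = TRUE)
  }
}

# Substream seeds derived from one master seed so that the age stream and the
# eight parameter streams are independent and stable: adding draws to one
# stream does not reshuffle the others.
substream_seeds <- function(seed, n_streams) {
  set.seed(seed)
  sample.int(2147483646L, n_streams)
}

#' Sample a Monte Carlo population of observer specifications
#'
#' Each of the eight physiological deviations is drawn independently from a
#' zero-mean normal distribution with the SD given in `sds`.  Draws that
#' would violate physical validity (a percentage deviation <= -100, i.e. a
#' negative optical density) are rejected and redrawn; the number of
#' rejections is recorded in the `"rejections"` attribute and a warning is
#' issued if more than 1% of draws were rejected.  Ages come from `ages`
#' (see [age_source()]).  A single `seed` makes the whole draw reproducible;
#' ages and each parameter use separate derived substreams.
#'
#' @param n Number of observers (>= 1).
#' @param ages An [age_source()].
#' @param field_size Field size in degrees shared by the population.
#' @param sds An [sd_table()].
#' @param seed Integer seed.
#' @return A list of `n` [observer_spec()] objects, with attributes
#'   `"params"` (the sampled parameter data frame) and `"rejections"`.
#' @export
sample_observers <- function(n, ages, field_size, sds = sd_table("step2"),
                             seed = 1L) {
  if (n <= 0) stop("sample_observers: n must be >= 1", call. = FALSE)
  stopifnot(inherits(sds, "sd_table"))
  seeds <- substream_seeds(seed, 9L)
  set.seed(seeds[1L])
  age <- draw_ages(ages, n)

  sdv <- sd_table_values(sds)
  pct <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)  # %-type params
  draws <- matrix(0, n, 8L)
  rejections <- 0L
  for (j in seq_len(8L)) {
    set.seed(seeds[j + 1L])
    d <- stats::rnorm(n, 0, sdv[j])
    if (pct[j]) {
      bad <- d <= -100
      while (any(bad)) {
        rejections <- rejections + sum(bad)
        d[bad] <- stats::rnorm(sum(bad), 0, sdv[j])
        bad <- d <= -100
      }
    }
    draws[, j] <- d
  }
  if (rejections > 0.01 * 8 * n) {
    warning("sample_observers: rejection rate above 1% of parameter draws (",
            rejections, " redraws for n = ", n,
            "); the supplied SDs push hard against the -100% bound")
  }
  params <- data.frame(age = age, field_size = field_size,
                       d_lens = draws[, 1L], d_macula = draws[, 2L],
                       d_L = draws[, 3L], d_M = draws[, 4L], d_S = draws[, 5L],
                       s_L = draws[, 6L], s_M = draws[, 7L], s_S = draws[, 8L])
  specs <- lapply(seq_len(n), function(i) {
    do.call(observer_spec, as.list(params[i, ]))
  })
  attr(specs, "params") <- params
  attr(specs, "rejections") <- rejections
  specs
}

#' Generate cone fundamentals for a list of observers
#'
#' Order-preserving: one `cone_fundamentals` per [observer_spec()].
#'
#' @param specs Non-empty list of [observer_spec()] objects (for example from
#'   [sample_observers()]).
#' @param basis A `basis_tables` object.
#' @return A list of `cone_fundamentals`.
#' @export
generate_population <- function(specs, basis = default_basis()) {
  if (length(specs) == 0L) {
    stop("generate_population: empty population", call. = FALSE)
  }
  lms <- population_lms(specs, basis)
  lapply(seq_along(specs), function(i) {
    structure(list(wavelength_nm = basis$wavelength_nm,
                   lms = cbind(l = lms$l[i, ], m = lms$m[i, ],
                               s = lms$s[i, ]),
                   spec = specs[[i]],
                   basis_version = basis$version),
              class = "cone_fundamentals")
  })
}

# Matrix form of a population's fundamentals (n x 89 per cone); the
# simulation modules use this directly to stay vectorised.
population_lms <- function(specs, basis) {
  params <- attr(specs, "params")
  if (is.null(params)) {
    params <- do.call(rbind, lapply(specs, function(s) {
      as.data.frame(unclass(s))
    }))
  }
  tryCatch(cmf_matrix(params, basis), error = function(e) {
    stop("generate_population: ", conditionMessage(e), call. = FALSE)
  })
}
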