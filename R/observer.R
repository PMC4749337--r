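#' Individual observer specification
#'
#' The ten inputs of the individual colorimetric observer model: the two
#' physiological-observer inputs (age and field size) that fix the baseline
#' average observer, plus eight deviation parameters that perturb it.
#' Percentage deviations act multiplicatively as `(1 + d/100)` on the
#' corresponding optical density; shift parameters translate the photopigment
#' absorbance spectra along the wavelength axis.  With all eight deviations
#' zero the model reduces exactly to the baseline average observer.
#'
#' @param age Observer age in years (> 0).  The lens-aging relation is
#'   validated for roughly 20--80 years; younger ages use the same linear
#'   relation (documented extrapolation) and ages above 80 are accepted with
#'   the same caveat.
#' @param field_size Field size (visual angle) in degrees, in (0, 10].
#' @param d_lens Deviation (%) of ocular-media (lens) optical density.
#' @param d_macula Deviation (%) of the peak optical density of the macular
#'   pigment.
#' @param d_L,d_M,d_S Deviations (%) of the peak optical densities of the L,
#'   M and S cone photopigments.
#' @param s_L,s_M,s_S Peak-wavelength (lambda-max) shifts (nm) of the L, M
#'   and S photopigment absorbances; |shift| <= 30 nm.
#' @return A list of class `observer_spec`.
#' @export
observer_spec <- function(age, field_size,
                          d_lens = 0, d_macula = 0,
                          d_L = 0, d_M = 0, d_S = 0,
                          s_L = 0, s_M = 0, s_S = 0) {
  out <- list(age = age, field_size = field_size,
              d_lens = d_lens, d_macula = d_macula,
              d_L = d_L, d_M = d_M, d_S = d_S,
              s_L = s_L, s_M = s_M, s_S = s_S)
  vals <- unlist(out)
  if (any(!is.finite(vals))) {
    stop("observer_spec: all parameters must be finite", call. = FALSE)
  }
  if (age <= 0) stop("observer_spec: age must be > 0", call. = FALSE)
  if (field_size <= 0 || field_size > 10) {
    stop("observer_spec: field_size must be in (0, 10] degrees", call. = FALSE)
  }
  for (nm in c("d_lens", "d_macula", "d_L", "d_M", "d_S")) {
    if (out[[nm]] < -100) {
      stop("observer_spec: ", nm,
           " < -100% would imply a negative optical density", call. = FALSE)
    }
  }
  for (nm in c("s_L", "s_M", "s_S")) {
    if (abs(out[[nm]]) > 30) {
      stop("observer_spec: |", nm, "| must be <= 30 nm", call. = FALSE)
    }
  }
  class(out) <- "observer_spec"
  out
}

#' @export
print.observer_spec <- function(x, ...) {
  cat(sprintf("<observer_spec> age %.1f y, field %.1f deg\n", x$age,
              x$field_size))
  cat(sprintf("  d_lens %+.2f%%  d_macula %+.2f%%\n", x$d_lens, x$d_macula))
  cat(sprintf("  d_L %+.2f%%  d_M %+.2f%%  d_S %+.2f%%\n", x$d_L, x$d_M, x$d_S))
  cat(sprintf("  s_L %+.2f nm  s_M %+.2f nm  s_S %+.2f nm\n",
              x$s_L, x$s_M, x$s_S))
  invisible(x)
}

# Lens-aging factor applied to the age-dependent ocular-media component:
# linear in age up to 60, steeper linear branch above 60; the two branches
# agree exactly at age 60 (factor 1.56).
lens_age_factor <- function(age) {
  ifelse(age <= 60, 1 + 0.02 * (age - 32), 1.56 + 0.0667 * (age - 60))
}

#' Ocular media (lens) spectral optical density
#'
#' Average ocular-media density for the given age (age-dependent component
#' scaled by the aging factor plus the age-independent component), then
#' scaled as a whole by `(1 + d_lens/100)` for the individual deviation.
#'
#' @param age Age in years (> 0).
#' @param d_lens Deviation (%) from the average density, > -100.
#' @param basis A `basis_tables` object.
#' @return A [spectral_function()] of optical density on the model grid.
#' @export
ocular_media_density <- function(age, d_lens = 0, basis = default_basis()) {
  if (age <= 0) stop("ocular_media_density: age must be > 0", call. = FALSE)
  ave <- basis$docul1 * lens_age_factor(age) + basis$docul2
  spectral_function(basis$wavelength_nm, ave * (1 + d_lens / 100))
}

#' Peak optical density of the macular pigment
#'
#' `0.485 * exp(-field_size / 6.132) * (1 + d_macula/100)`: the peak density
#' declines exponentially with field size and the individual deviation acts
#' multiplicatively.
#'
#' @inheritParams ocular_media_density
#' @param field_size Field size in degrees (> 0).
#' @param d_macula Deviation (%) from the average peak density.
#' @return A nonnegative scalar optical density.
#' @export
macular_peak_density <- function(field_size, d_macula = 0) {
  if (any(field_size <= 0)) {
    stop("macular_peak_density: field_size must be > 0", call. = FALSE)
  }
  0.485 * exp(-field_size / 6.132) * (1 + d_macula / 100)
}

#' Macular pigment spectral optical density
#'
#' Peak density ([macular_peak_density()]) times the peak-normalised relative
#' density table.
#'
#' @inheritParams macular_peak_density
#' @param basis A `basis_tables` object.
#' @return A [spectral_function()] on the model grid.
#' @export
macular_density_spectrum <- function(field_size, d_macula = 0,
                                     basis = default_basis()) {
  peak <- macular_peak_density(field_size, d_macula)
  spectral_function(basis$wavelength_nm, peak * basis$d_rel_macula)
}

#' Peak optical density of a cone photopigment
#'
#' Field-size dependent self-screening density with the individual deviation
#' applied multiplicatively.  L and M cones share the same average relation
#' `0.38 + 0.54 exp(-v/1.333)`; the S cone uses `0.30 + 0.45 exp(-v/1.333)`.
#'
#' @param cone One of `"L"`, `"M"`, `"S"`.
#' @param field_size Field size in degrees (> 0).
#' @param d Deviation (%) from the average peak density.
#' @return A scalar optical density.
#' @export
photopigment_peak_density <- function(cone = c("L", "M", "S"), field_size,
                                      d = 0) {
  cone <- match.arg(cone)
  if (any(field_size <= 0)) {
    stop("photopigment_peak_density: field_size must be > 0", call. = FALSE)
  }
  base <- if (cone == "S") {
    0.30 + 0.45 * exp(-field_size / 1.333)
  } else {
    0.38 + 0.54 * exp(-field_size / 1.333)
  }
  base * (1 + d / 100)
}

#' Cone photopigment absorptance spectrum
#'
#' The low-density absorbance template is translated by the lambda-max shift
#' (natural-spline evaluation at `lambda - s`, zero outside the table span)
#' and converted to absorptance `1 - 10^(-D_max * A(lambda - s))` with the
#' field-size- and deviation-dependent peak density.
#'
#' @inheritParams photopigment_peak_density
#' @param s Lambda-max shift in nm, |s| <= 30.
#' @param basis A `basis_tables` object.
#' @return A [spectral_function()] with values in [0, 1).
#' @export
cone_absorptance <- function(cone = c("L", "M", "S"), field_size, d = 0,
                             s = 0, basis = default_basis()) {
  cone <- match.arg(cone)
  if (abs(s) > 30) {
    stop("cone_absorptance: |s| must be <= 30 nm", call. = FALSE)
  }
  dmax <- photopigment_peak_density(cone, field_size, d)
  a <- shifted_absorbance(basis, cone, s)
  spectral_function(basis$wavelength_nm, 1 - 10^(-dmax * a))
}

# Absorbance template translated by s nm; clamped at zero (spline ringing in
# the flat tails must not produce negative absorbance).
shifted_absorbance <- function(basis, cone, s) {
  grid <- basis$wavelength_nm
  a <- spline_eval(grid, basis$absorbance[, cone], grid - s)
  pmax(a, 0)
}

#' Individual cone fundamentals
#'
#' Computes the cone fundamentals for one observer: quanta-based fundamentals
#' are the cone absorptances filtered by the macular and ocular-media
#' densities, `l_q = alpha_L * 10^(-D_macula - D_ocul)` (and likewise for M,
#' S); energy-based fundamentals multiply by wavelength; finally each of the
#' three functions is normalised to unit maximum.
#'
#' @param spec An [observer_spec()].
#' @param basis A `basis_tables` object.
#' @return A list of class `cone_fundamentals`: `wavelength_nm`, `lms`
#'   (matrix with unit-peak columns `l`, `m`, `s`), `spec`, `basis_version`.
#' @export
cone_fundamentals <- function(spec, basis = default_basis()) {
  stopifnot(inherits(spec, "observer_spec"))
  lms <- cmf_matrix(as.data.frame(unclass(spec)), basis)
  structure(list(wavelength_nm = basis$wavelength_nm,
                 lms = cbind(l = lms$l[1L, ], m = lms$m[1L, ], s = lms$s[1L, ]),
                 spec = spec,
                 basis_version = basis$version),
            class = "cone_fundamentals")
}

#' @export
print.cone_fundamentals <- function(x, ...) {
  cat(sprintf("<cone_fundamentals> %d wavelengths (%g-%g nm), age %.1f y, field %.1f deg\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), x$spec$age, x$spec$field_size))
  invisible(x)
}

# Vectorised core: one row of `params` per observer (columns age, field_size,
# d_lens, d_macula, d_L, d_M, d_S, s_L, s_M, s_S).  Returns unit-peak l, m, s
# as n x 89 matrices.  All heavy work is dense matrix algebra so Monte Carlo
# populations of 10^4 observers are cheap.
cmf_matrix <- function(params, basis) {
  grid <- basis$wavelength_nm
  n <- nrow(params)

  docul <- outer(lens_age_factor(params$age), basis$docul1) +
    matrix(basis$docul2, n, length(grid), byrow = TRUE)
  docul <- docul * (1 + params$d_lens / 100)

  mac_peak <- 0.485 * exp(-params$field_size / 6.132) *
    (1 + params$d_macula / 100)
  mac <- outer(mac_peak, basis$d_rel_macula)

  filt <- 10^(-(docul + mac))

  one_cone <- function(cone, d, s) {
    base <- if (cone == "S") {
      0.30 + 0.45 * exp(-params$field_size / 1.333)
    } else {
      0.38 + 0.54 * exp(-params$field_size / 1.333)
    }
    dmax <- base * (1 + d / 100)
    # evaluate the absorbance spline at grid - s_i for all observers at once
    shifted <- outer(-s, grid, `+`)  # n x 89 matrix of lambda - s_i
    a <- matrix(spline_eval(grid, basis$absorbance[, cone], as.vector(shifted)),
                n, length(grid))
    a <- pmax(a, 0)
    alpha <- 1 - 10^(-dmax * a)
    lq <- alpha * filt
    e <- sweep(lq, 2L, grid, `*`)      # energy basis
    e / apply(e, 1L, max)              # unit peak per observer
  }

  list(grid = grid,
       l = one_cone("L", params$d_L, params$s_L),
       m = one_cone("M", params$d_M, params$s_M),
       s = one_cone("S", params$d_S, params$s_S))
}

# Packaged default basis, loaded once per session.
default_basis <- function() {
  b <- .indivobs_cache[["default_basis"]]
  if (is.null(b)) {
    b <- load_basis_tables()
    .indivobs_cache[["default_basis"]] <- b
  }
  b
}
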