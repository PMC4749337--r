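#' Spectral function
#'
#' A minimal container for a sampled spectral quantity: a strictly increasing
#' wavelength grid (nm) paired with values.  Optical densities, relative
#' densities, absorbances, stimulus spectra and single colour-matching-function
#' channels all share this shape.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param value Numeric vector of the same length; must be finite.
#' @return A data frame of class `spectral_function` with columns
#'   `wavelength_nm` and `value`.
#' @export
spectral_function <- function(wavelength_nm, value) {
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) == 0L) {
    stop("spectral_function: empty wavelength grid", call. = FALSE)
  }
  if (length(wavelength_nm) != length(value)) {
    stop("spectral_function: wavelength and value lengths differ", call. = FALSE)
  }
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(value))) {
    stop("spectral_function: non-finite entries", call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("spectral_function: wavelength grid must be strictly increasing",
         call. = FALSE)
  }
  out <- data.frame(wavelength_nm = wavelength_nm, value = value)
  class(out) <- c("spectral_function", "data.frame")
  out
}

#' Resample a spectral function onto a new wavelength grid
#'
#' Natural cubic-spline interpolation.  Values at the source knots are
#' reproduced exactly; target wavelengths outside the source span are set to
#' zero rather than extrapolated (steep prereceptoral densities make
#' extrapolation unsafe).
#'
#' @param fn A [spectral_function()].
#' @param target_grid Numeric vector of target wavelengths in nm.
#' @param method Interpolation method; only `"spline"` (natural cubic) is
#'   supported.
#' @return A [spectral_function()] on `target_grid`.
#' @export
resample_spectral <- function(fn, target_grid, method = "spline") {
  method <- match.arg(method, "spline")
  if (length(target_grid) == 0L) {
    stop("resample_spectral: empty target grid", call. = FALSE)
  }
  vals <- spline_eval(fn$wavelength_nm, fn$value, target_grid)
  spectral_function(target_grid, vals)
}

# Natural-cubic-spline evaluation with zero fill outside the source span.
# `x_out` may be any numeric vector (not necessarily sorted).
spline_eval <- function(x, y, x_out) {
  f <- stats::splinefun(x, y, method = "natural")
  out <- f(x_out)
  out[x_out < min(x) | x_out > max(x)] <- 0
  out
}

# Natural-spline interpolation is linear in the ordinates, so resampling a
# fixed source grid onto a fixed target grid is a matrix.  Building the matrix
# once (one spline solve per source knot) turns per-observer resampling in the
# Monte Carlo loops into a single matrix product.
resample_operator <- function(src_grid, dst_grid) {
  key <- paste(c(length(src_grid), range(src_grid), sum(src_grid),
                 length(dst_grid), range(dst_grid), sum(dst_grid),
                 sum(dst_grid * seq_along(dst_grid))), collapse = "|")
  cached <- .indivobs_cache[[key]]
  if (!is.null(cached)) {
    return(cached)
  }
  n <- length(src_grid)
  op <- matrix(0, nrow = length(dst_grid), ncol = n)
  basis <- diag(n)
  for (j in seq_len(n)) {
    op[, j] <- spline_eval(src_grid, basis[, j], dst_grid)
  }
  .indivobs_cache[[key]] <- op
  op
}

.indivobs_cache <- new.env(parent = emptyenv())
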