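#' Colour-match setup
#'
#' A metameric matching task: a reference spectrum and the maximum-energy
#' spectra of three matching primaries, all on the stimulus grid (380--780 nm
#' at 1 nm, 401 samples), plus the rule used to construct the reference
#' white for CIELAB evaluation.
#'
#' @param reference A [spectral_function()] on the stimulus grid (nonnegative).
#' @param primaries_max A 401 x 3 matrix of the maximum-energy primary
#'   spectra (columns are primaries), or a list of three
#'   [spectral_function()]s.
#' @param white_rule `"reference-shape"` (reference white shares the spectral
#'   shape of the reference stimulus; used for neutral references) or
#'   `"equal-energy"` (flat spectrum; used for saturated references).  In
#'   both cases the white is scaled so the reference stimulus has CIELAB
#'   L* = 50 under the standard observer.
#' @param label Identifier used in messages and outputs.
#' @return A list of class `match_setup`.
#' @export
match_setup <- function(reference, primaries_max,
                        white_rule = c("reference-shape", "equal-energy"),
                        label = "match") {
  white_rule <- match.arg(white_rule)
  stopifnot(inherits(reference, "spectral_function"))
  grid <- reference$wavelength_nm
  if (is.list(primaries_max) && !is.matrix(primaries_max)) {
    primaries_max <- vapply(primaries_max, function(p) {
      stopifnot(inherits(p, "spectral_function"))
      if (length(p$wavelength_nm) != length(grid) ||
          any(p$wavelength_nm != grid)) {
        stop("match_setup: primaries must share the reference grid",
             call. = FALSE)
      }
      p$value
    }, numeric(length(grid)))
  }
  primaries_max <- as.matrix(primaries_max)
  if (nrow(primaries_max) != length(grid) || ncol(primaries_max) != 3L) {
    stop("match_setup: primaries_max must be length(grid) x 3", call. = FALSE)
  }
  if (any(reference$value < 0) || any(primaries_max < 0)) {
    stop("match_setup: spectra must be nonnegative", call. = FALSE)
  }
  structure(list(grid = grid, reference = reference$value,
                 primaries_max = primaries_max, white_rule = white_rule,
                 label = label),
            class = "match_setup")
}

# 3 x n_grid observer matrix: fundamentals spline-resampled to the stimulus
# grid, zero outside the model span.
observer_matrix <- function(cmfs, grid) {
  op <- resample_operator(cmfs$wavelength_nm, grid)
  t(op %*% cmfs$lms)
}

# Standard-observer (XYZ) matrix on a stimulus grid.
xyz_matrix <- function(basis, grid) {
  op <- resample_operator(basis$xyz_wavelength_nm, grid)
  t(op %*% basis$xyz)
}

#' Solve a colour match
#'
#' Finds the three primary intensities `R` such that the observer's cone
#' excitations of the mixed primaries equal those of the reference:
#' `C %*% S_ref = C %*% S_match_max %*% R`, solved by inversion of the 3 x 3
#' system.  Negative intensities are permitted (the solve is unconstrained).
#'
#' @param cmfs A `cone_fundamentals` object (the matching observer).
#' @param setup A [match_setup()].
#' @return Numeric length-3 vector of primary intensities.
#' @export
solve_match <- function(cmfs, setup) {
  stopifnot(inherits(setup, "match_setup"))
  cm <- observer_matrix(cmfs, setup$grid)
  a <- cm %*% setup$primaries_max
  if (!all(is.finite(a)) || kappa(a, exact = TRUE) > 1e10) {
    stop("solve_match: near-singular primary system for setup '",
         setup$label, "'", call. = FALSE)
  }
  drop(solve(a, cm %*% setup$reference))
}

#' Reference white for a match setup
#'
#' Builds the reference-white spectrum according to the setup's rule
#' (reference shape or equal energy) and scales it so that the reference
#' stimulus has CIELAB L* = 50 under the standard observer, i.e.
#' `Y_ref / Y_n = ((50 + 16)/116)^3`.
#'
#' @param setup A [match_setup()].
#' @param basis A `basis_tables` object (provides the standard observer).
#' @return A list with `s_refw` (a [spectral_function()]) and `t_n` (the
#'   white tristimulus vector).
#' @export
reference_white <- function(setup, basis = default_basis()) {
  stopifnot(inherits(setup, "match_setup"))
  if (all(setup$reference == 0)) {
    stop("reference_white: zero reference spectrum", call. = FALSE)
  }
  xm <- xyz_matrix(basis, setup$grid)
  t_ref <- drop(683 * xm %*% setup$reference)
  shape <- if (setup$white_rule == "reference-shape") {
    setup$reference
  } else {
    rep(1, length(setup$grid))
  }
  t_shape <- drop(683 * xm %*% shape)
  y_n <- t_ref[2L] / ((50 + 16) / 116)^3
  k <- y_n / t_shape[2L]
  list(s_refw = spectral_function(setup$grid, k * shape), t_n = k * t_shape)
}

#' CIELAB coordinates of a solved match
#'
#' Reconstructs the matched spectrum from the primary intensities,
#' integrates it against the standard observer (683 factor, 1 nm step) and
#' converts to CIELAB against the supplied white.
#'
#' @param R Length-3 primary intensities from [solve_match()].
#' @param setup A [match_setup()].
#' @param white White tristimulus vector (e.g. `reference_white(setup)$t_n`);
#'   `NULL` computes it from the setup.
#' @param basis A `basis_tables` object.
#' @return Named numeric `c(L, a, b)`.
#' @export
match_to_cielab <- function(R, setup, white = NULL, basis = default_basis()) {
  stopifnot(inherits(setup, "match_setup"))
  if (is.null(white)) white <- reference_white(setup, basis)$t_n
  if (white[2L] <= 0) {
    stop("match_to_cielab: white must have positive Y", call. = FALSE)
  }
  xm <- xyz_matrix(basis, setup$grid)
  s_matched <- setup$primaries_max %*% R
  t_matched <- drop(683 * xm %*% s_matched)
  xyz_to_lab(t_matched, white)
}

# Standard CIELAB conversion with the linear small-signal branch.
xyz_to_lab <- function(xyz, white) {
  xyz <- unname(xyz)
  white <- unname(white)
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(xyz[1L] / white[1L])
  fy <- f(xyz[2L] / white[2L])
  fz <- f(xyz[3L] / white[3L])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Simulate colour matches for a population of observers
#'
#' Solves every setup for every observer, evaluates the matched spectra in
#' CIELAB under the standard observer, and summarises the inter-observer
#' spread: per setup the standard deviations of a* and b* over observers and
#' their mean (`sd_ab`), the single variability number used per match.
#'
#' @param population List of `cone_fundamentals` (see
#'   [generate_population()]).
#' @param setups List of [match_setup()]s.
#' @param basis A `basis_tables` object.
#' @return A list with `matches` (data frame: observer, label, R1..R3, L, a,
#'   b) and `summary` (data frame: label, sd_a, sd_b, sd_ab).
#' @export
simulate_matches <- function(population, setups, basis = default_basis()) {
  if (length(population) == 0L || length(setups) == 0L) {
    stop("simulate_matches: empty population or setups", call. = FALSE)
  }
  if (inherits(setups, "match_setup")) setups <- list(setups)
  n <- length(population)
  src_grid <- population[[1L]]$wavelength_nm
  lmat <- t(vapply(population, function(p) p$lms[, "l"], numeric(length(src_grid))))
  mmat <- t(vapply(population, function(p) p$lms[, "m"], numeric(length(src_grid))))
  smat <- t(vapply(population, function(p) p$lms[, "s"], numeric(length(src_grid))))
  simulate_matches_lms(list(grid = src_grid, l = lmat, m = mmat, s = smat),
                       setups, basis)
}

# Core worker on the matrix form of a population (as from population_lms()).
simulate_matches_lms <- function(lms, setups, basis) {
  n <- nrow(lms$l)
  grid <- setups[[1L]]$grid
  op <- t(resample_operator(lms$grid, grid))       # 89 x 401
  l1 <- lms$l %*% op
  m1 <- lms$m %*% op
  s1 <- lms$s %*% op

  rows <- list()
  summ <- list()
  for (k in seq_along(setups)) {
    st <- setups[[k]]
    if (any(st$grid != grid)) {
      stop("simulate_matches: all setups must share one stimulus grid",
           call. = FALSE)
    }
    lp <- l1 %*% st$primaries_max                  # n x 3
    mp <- m1 %*% st$primaries_max
    sp <- s1 %*% st$primaries_max
    bl <- drop(l1 %*% st$reference)                # n
    bm <- drop(m1 %*% st$reference)
    bs <- drop(s1 %*% st$reference)

    # vectorised Cramer solve of the per-observer 3x3 systems
    det <- lp[, 1] * (mp[, 2] * sp[, 3] - mp[, 3] * sp[, 2]) -
      lp[, 2] * (mp[, 1] * sp[, 3] - mp[, 3] * sp[, 1]) +
      lp[, 3] * (mp[, 1] * sp[, 2] - mp[, 2] * sp[, 1])
    scale <- sqrt(rowSums(lp^2) * rowSums(mp^2) * rowSums(sp^2))
    if (any(!is.finite(det)) || any(abs(det) <= 1e-12 * scale)) {
      stop("simulate_matches: near-singular primary system for setup '",
           st$label, "'", call. = FALSE)
    }
    r1 <- (bl * (mp[, 2] * sp[, 3] - mp[, 3] * sp[, 2]) -
             lp[, 2] * (bm * sp[, 3] - mp[, 3] * bs) +
             lp[, 3] * (bm * sp[, 2] - mp[, 2] * bs)) / det
    r2 <- (lp[, 1] * (bm * sp[, 3] - mp[, 3] * bs) -
             bl * (mp[, 1] * sp[, 3] - mp[, 3] * sp[, 1]) +
             lp[, 3] * (mp[, 1] * bs - bm * sp[, 1])) / det
    r3 <- (lp[, 1] * (mp[, 2] * bs - bm * sp[, 2]) -
             lp[, 2] * (mp[, 1] * bs - bm * sp[, 1]) +
             bl * (mp[, 1] * sp[, 2] - mp[, 2] * sp[, 1])) / det

    white <- reference_white(st, basis)
    xm <- xyz_matrix(basis, grid)
    bmat <- 683 * xm %*% st$primaries_max          # 3 x 3
    txyz <- cbind(r1, r2, r3) %*% t(bmat)          # n x 3 tristimulus
    lab <- t(apply(txyz, 1L, xyz_to_lab, white = white$t_n))

    rows[[k]] <- data.frame(observer = seq_len(n), label = st$label,
                            R1 = r1, R2 = r2, R3 = r3,
                            L = lab[, 1], a = lab[, 2], b = lab[, 3])
    sd_a <- stats::sd(lab[, 2])
    sd_b <- stats::sd(lab[, 3])
    summ[[k]] <- data.frame(label = st$label, sd_a = sd_a, sd_b = sd_b,
                            sd_ab = mean(c(sd_a, sd_b)))
  }
  list(matches = do.call(rbind, rows), summary = do.call(rbind, summ))
}

#' Rayleigh match for an observer
#'
#' Solves the anomaloscope equation: mixture weights of monochromatic red
#' and green primaries whose combined L and M excitations equal those of the
#' monochromatic yellow test light.  The primaries are treated as ideal
#' single-wavelength lights (the fundamentals are spline-evaluated off-grid),
#' and the result is reported as the red fraction `w_R / (w_R + w_G)`; an
#' optional affine map converts to instrument units.
#'
#' @param cmfs A `cone_fundamentals` object.
#' @param red_nm,green_nm,yellow_nm Primary and test wavelengths in nm
#'   (defaults 700, 550, 589).
#' @param scale Length-2 `c(offset, gain)` affine map applied to the red
#'   fraction (default identity).
#' @return The (possibly rescaled) red fraction, a scalar.
#' @export
rayleigh_match <- function(cmfs, red_nm = 700, green_nm = 550,
                           yellow_nm = 589, scale = c(0, 1)) {
  lm <- vapply(c(red_nm, green_nm, yellow_nm), function(w) {
    c(spline_eval(cmfs$wavelength_nm, cmfs$lms[, "l"], w),
      spline_eval(cmfs$wavelength_nm, cmfs$lms[, "m"], w))
  }, numeric(2L))
  det <- lm[1L, 1L] * lm[2L, 2L] - lm[1L, 2L] * lm[2L, 1L]
  if (abs(det) < 1e-12) {
    stop("rayleigh_match: singular red/green system", call. = FALSE)
  }
  w_r <- (lm[1L, 3L] * lm[2L, 2L] - lm[1L, 2L] * lm[2L, 3L]) / det
  w_g <- (lm[1L, 1L] * lm[2L, 3L] - lm[1L, 3L] * lm[2L, 1L]) / det
  scale[1L] + scale[2L] * w_r / (w_r + w_g)
}

# Vectorised Rayleigh matches for a population in matrix form.
rayleigh_matches_lms <- function(lms, red_nm = 700, green_nm = 550,
                                 yellow_nm = 589) {
  op <- t(resample_operator(lms$grid, c(red_nm, green_nm, yellow_nm)))
  lv <- lms$l %*% op                               # n x 3 (red, green, yellow)
  mv <- lms$m %*% op
  det <- lv[, 1] * mv[, 2] - lv[, 2] * mv[, 1]
  w_r <- (lv[, 3] * mv[, 2] - lv[, 2] * mv[, 3]) / det
  w_g <- (lv[, 1] * mv[, 3] - lv[, 3] * mv[, 1]) / det
  w_r / (w_r + w_g)
}

#' Transform cone fundamentals to an rgb-normalised CMF set
#'
#' Finds the 3 x 3 matrix `M` such that `rgb(lambda) = M %*% lms(lambda)`
#' takes the value unit vectors at the three instrument primary wavelengths,
#' i.e. the rgb functions are normalised at the primaries.  This puts
#' individually varying fundamentals in a common rgb space for
#' dispersion comparisons against primary-based matching experiments.
#'
#' @param cmfs A `cone_fundamentals` object.
#' @param primary_wavelengths Named or positional `c(r, g, b)` wavelengths in
#'   nm; default `c(645.2, 526.3, 444.4)`.
#' @return A list with `wavelength_nm`, `rgb` (matrix with columns `r`, `g`,
#'   `b`, unit at the respective primaries) and the transform matrix `m`.
#' @export
lms_to_rgb <- function(cmfs, primary_wavelengths = c(645.2, 526.3, 444.4)) {
  if (length(primary_wavelengths) != 3L) {
    stop("lms_to_rgb: need three primary wavelengths", call. = FALSE)
  }
  k <- vapply(primary_wavelengths, function(w) {
    c(spline_eval(cmfs$wavelength_nm, cmfs$lms[, "l"], w),
      spline_eval(cmfs$wavelength_nm, cmfs$lms[, "m"], w),
      spline_eval(cmfs$wavelength_nm, cmfs$lms[, "s"], w))
  }, numeric(3L))                                  # lms values, one column per primary
  if (abs(det(k)) < 1e-12 * prod(sqrt(colSums(k^2)))) {
    stop("lms_to_rgb: singular lms matrix at the primary wavelengths",
         call. = FALSE)
  }
  m <- solve(k)
  rgb <- cmfs$lms %*% t(m)
  colnames(rgb) <- c("r", "g", "b")
  list(wavelength_nm = cmfs$wavelength_nm, rgb = rgb, m = m)
}
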