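.stimulus_grid <- 380:780

#' Generate packaged stimulus fixtures for colour-match simulation
#'
#' The matching dataset the model's SDs were fitted against consists of five
#' colour matches on display-like primaries: three neutral broadband
#' references (evaluated against a reference-shaped white) and two saturated
#' references — a cyan and an orange — evaluated against an equal-energy
#' white.  The measured spectra are not published, so this generator emits
#' synthetic stand-ins with the stated character: three broadband
#' display-like primaries (Gaussian emitters at 612, 543 and 452 nm) shared
#' by all matches, three smooth broadband neutral references, a saturated
#' cyan reference (dominant wavelength near 490 nm) and a saturated orange
#' reference.
#'
#' @param kind `"five_matches"` (default) or `"toy"` (a single flat-reference
#'   setup for quick tests).
#' @param seed Integer seed; the spectra are deterministic, the seed is kept
#'   in the API so that any future randomised variants remain reproducible.
#' @return A list of [match_setup()]s on the stimulus grid (380--780 nm,
#'   1 nm).
#' @export
generate_fixture_stimuli <- function(kind = c("five_matches", "toy"),
                                     seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  wl <- .stimulus_grid
  prim <- cbind(r = exp(-((wl - 612) / 22)^2),
                g = exp(-((wl - 543) / 26)^2),
                b = exp(-((wl - 452) / 18)^2))
  if (kind == "toy") {
    return(list(match_setup(spectral_function(wl, rep(1, length(wl))), prim,
                            "reference-shape", label = "toy")))
  }
  refs <- list(
    match1 = rep(1, length(wl)),
    match2 = 0.55 + 0.45 * exp(-((wl - 520) / 180)^2),
    match3 = 0.01 + exp(-((wl - 490) / 32)^2),
    match4 = 0.01 + 1 / (1 + exp(-(wl - 585) / 12)),
    match5 = 0.30 + 0.70 * (wl - 380) / 400
  )
  rules <- c(match1 = "reference-shape", match2 = "reference-shape",
             match3 = "equal-energy", match4 = "equal-energy",
             match5 = "reference-shape")
  lapply(names(refs), function(nm) {
    match_setup(spectral_function(wl, refs[[nm]]), prim, rules[[nm]],
                label = nm)
  })
}

#' Write match setups to CSV files
#'
#' One `reference_<label>.csv` per setup plus a shared `primaries.csv`
#' (columns `wavelength_nm,r,g,b`) and a `manifest.csv` recording each
#' setup's label, white rule and reference file.
#'
#' @param setups List of [match_setup()]s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_match_setups <- function(setups, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- setups[[1L]]$grid
  utils::write.csv(data.frame(wavelength_nm = grid,
                              r = setups[[1L]]$primaries_max[, 1L],
                              g = setups[[1L]]$primaries_max[, 2L],
                              b = setups[[1L]]$primaries_max[, 3L]),
                   file.path(dir, "primaries.csv"), row.names = FALSE)
  manifest <- do.call(rbind, lapply(setups, function(st) {
    fn <- paste0("reference_", st$label, ".csv")
    utils::write.csv(data.frame(wavelength_nm = st$grid, value = st$reference),
                     file.path(dir, fn), row.names = FALSE)
    data.frame(label = st$label, white_rule = st$white_rule, reference = fn,
               primaries = "primaries.csv")
  }))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read match setups written by [write_match_setups()]
#'
#' @param dir Directory with `manifest.csv`, reference CSVs and
#'   `primaries.csv`.
#' @return A list of [match_setup()]s.
#' @export
read_match_setups <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    ref <- utils::read.csv(file.path(dir, manifest$reference[i]))
    prim <- utils::read.csv(file.path(dir, manifest$primaries[i]))
    match_setup(spectral_function(ref$wavelength_nm, ref$value),
                as.matrix(prim[, c("r", "g", "b")]),
                manifest$white_rule[i], label = manifest$label[i])
  })
}

# Dominant wavelength of a stimulus under the standard observer, relative to
# the equal-energy white: the spectral-locus wavelength whose chromaticity
# direction from the white best aligns with the stimulus direction.
dominant_wavelength <- function(spectrum, basis = default_basis()) {
  stopifnot(inherits(spectrum, "spectral_function"))
  grid <- spectrum$wavelength_nm
  xm <- xyz_matrix(basis, grid)
  chrom <- function(t) t[1:2] / sum(t)
  xy <- chrom(drop(xm %*% spectrum$value))
  xy_w <- chrom(drop(xm %*% rep(1, length(grid))))
  ang <- atan2(xy[2L] - xy_w[2L], xy[1L] - xy_w[1L])
  locus_wl <- grid[colSums(xm) > 1e-4]
  locus_ang <- vapply(locus_wl, function(w) {
    p <- chrom(xm[, match(w, grid)])
    atan2(p[2L] - xy_w[2L], p[1L] - xy_w[1L])
  }, numeric(1))
  d <- abs(atan2(sin(locus_ang - ang), cos(locus_ang - ang)))
  locus_wl[which.min(d)]
}
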