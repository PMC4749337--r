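#' @title Physiological basis tables
#' @description
#' The individual observer model is driven by five fixed spectral reference
#' tables on the model-native grid (390--830 nm at 5 nm): the age-dependent
#' and age-independent components of the ocular-media optical density
#' (`docul1`, `docul2`), the peak-normalised relative optical density of the
#' macular pigment (`d_rel_macula`), and the peak-normalised low-density
#' spectral absorbances of the L, M and S cone photopigments
#' (`absorbance`).  A standard XYZ-type 10 degree observer (`xyz`) is carried
#' alongside for colorimetric (CIELAB) evaluation of simulated matches.
#'
#' The tables shipped with the package are *synthetic stand-ins*, generated by
#' [synthetic_basis_tables()] from published analytic templates (see that
#' function); users with access to the tabulated physiological-observer
#' reference data can drop replacement CSVs into a directory and point
#' `load_basis_tables()` at it.
#' @name basis_tables
NULL

.basis_components <- c("docul1", "docul2", "d_rel_macula",
                       "absorbance_l", "absorbance_m", "absorbance_s")

.model_grid <- seq(390, 830, by = 5)

#' Load and validate the basis tables
#'
#' Reads the per-component CSV files (two columns `wavelength_nm,value`; the
#' standard-observer file has columns `wavelength_nm,x,y,z`), checks the grid
#' and value invariants, and returns a validated `basis_tables` object.
#' Validation failures are fatal.
#'
#' @param source Directory holding the component CSVs.  `NULL` (default) uses
#'   the synthetic tables packaged under `extdata/basis`.  For each component
#'   `<name>.csv` is tried first, then `<name>_synthetic.csv`.
#' @return A list of class `basis_tables` with elements `wavelength_nm`,
#'   `docul1`, `docul2`, `d_rel_macula`, `absorbance` (matrix with columns
#'   `L`, `M`, `S`), `xyz_wavelength_nm`, `xyz` (matrix with columns `x`,
#'   `y`, `z`) and a `version` checksum of the source files.
#' @export
load_basis_tables <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "basis", package = "indivobs")
  }
  if (!dir.exists(source)) {
    stop("load_basis_tables: directory not found: ", source, call. = FALSE)
  }
  find_file <- function(name) {
    for (cand in file.path(source, paste0(name, c(".csv", "_synthetic.csv")))) {
      if (file.exists(cand)) return(cand)
    }
    stop("load_basis_tables: missing component file for '", name, "' in ",
         source, call. = FALSE)
  }
  read_component <- function(name) {
    path <- find_file(name)
    df <- utils::read.csv(path, comment.char = "#")
    if (!all(c("wavelength_nm", "value") %in% names(df))) {
      stop("load_basis_tables: ", path,
           " must have columns wavelength_nm,value", call. = FALSE)
    }
    df[order(df$wavelength_nm), , drop = FALSE]
  }
  comp <- lapply(.basis_components, read_component)
  names(comp) <- .basis_components

  grid <- comp[[1L]]$wavelength_nm
  for (name in .basis_components) {
    g <- comp[[name]]$wavelength_nm
    if (length(g) != length(grid) || any(g != grid)) {
      stop("load_basis_tables: component '", name,
           "' is not on the shared wavelength grid", call. = FALSE)
    }
  }
  validate_basis_grid(grid)

  xyz_path <- find_file("xyz10")
  xyz_df <- utils::read.csv(xyz_path, comment.char = "#")
  if (!all(c("wavelength_nm", "x", "y", "z") %in% names(xyz_df))) {
    stop("load_basis_tables: ", xyz_path,
         " must have columns wavelength_nm,x,y,z", call. = FALSE)
  }
  xyz_df <- xyz_df[order(xyz_df$wavelength_nm), , drop = FALSE]

  files <- c(vapply(.basis_components, find_file, character(1)), xyz_path)
  obj <- structure(list(
    wavelength_nm = grid,
    docul1 = comp$docul1$value,
    docul2 = comp$docul2$value,
    d_rel_macula = comp$d_rel_macula$value,
    absorbance = cbind(L = comp$absorbance_l$value,
                       M = comp$absorbance_m$value,
                       S = comp$absorbance_s$value),
    xyz_wavelength_nm = xyz_df$wavelength_nm,
    xyz = cbind(x = xyz_df$x, y = xyz_df$y, z = xyz_df$z),
    version = unname(paste(tools::md5sum(files), collapse = "")),
    source = source
  ), class = "basis_tables")
  validate_basis_tables(obj)
  obj
}

validate_basis_grid <- function(grid) {
  if (any(diff(grid) <= 0)) {
    stop("basis tables: wavelength grid must be strictly increasing",
         call. = FALSE)
  }
  if (any(abs(diff(grid) - 5) > 1e-9)) {
    stop("basis tables: wavelength grid step must be a constant 5 nm",
         call. = FALSE)
  }
  if (min(grid) > 390 || max(grid) < 830) {
    stop("basis tables: wavelength coverage of 390-830 nm required",
         call. = FALSE)
  }
  invisible(grid)
}

validate_basis_tables <- function(x) {
  stopifnot(inherits(x, "basis_tables"))
  validate_basis_grid(x$wavelength_nm)
  dens <- cbind(x$docul1, x$docul2, x$d_rel_macula, x$absorbance)
  if (any(!is.finite(dens))) {
    stop("basis tables: non-finite density/absorbance values", call. = FALSE)
  }
  if (any(dens < 0)) {
    stop("basis tables: negative density/absorbance values", call. = FALSE)
  }
  peaked <- cbind(macula = x$d_rel_macula, x$absorbance)
  peak <- apply(peaked, 2L, max)
  bad <- abs(peak - 1) > 1e-6
  if (any(bad)) {
    stop("basis tables: peak-normalised table(s) with max != 1: ",
         paste(colnames(peaked)[bad], collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$xyz)) || any(x$xyz < 0)) {
    stop("basis tables: standard-observer values must be finite and >= 0",
         call. = FALSE)
  }
  invisible(x)
}

#' Write basis tables to a directory of CSV files
#'
#' Inverse of [load_basis_tables()]; used to materialise the packaged
#' synthetic tables and for user overrides.  Filenames carry a `_synthetic`
#' suffix when `synthetic = TRUE`.
#'
#' @param basis A `basis_tables` object.
#' @param dir Output directory (created if needed).
#' @param synthetic Mark the files as synthetic stand-ins (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_basis_tables <- function(basis, dir, synthetic = TRUE) {
  stopifnot(inherits(basis, "basis_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  suffix <- if (synthetic) "_synthetic.csv" else ".csv"
  header <- if (synthetic) {
    "# synthetic stand-in basis table generated by indivobs::synthetic_basis_tables()"
  } else {
    "# basis table"
  }
  write_one <- function(name, values) {
    path <- file.path(dir, paste0(name, suffix))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.csv(
      data.frame(wavelength_nm = basis$wavelength_nm,
                 value = format(values, digits = 15, trim = TRUE)),
      con, row.names = FALSE, quote = FALSE)
  }
  write_one("docul1", basis$docul1)
  write_one("docul2", basis$docul2)
  write_one("d_rel_macula", basis$d_rel_macula)
  write_one("absorbance_l", basis$absorbance[, "L"])
  write_one("absorbance_m", basis$absorbance[, "M"])
  write_one("absorbance_s", basis$absorbance[, "S"])
  path <- file.path(dir, paste0("xyz10", suffix))
  con <- file(path, "w")
  writeLines(header, con)
  utils::write.csv(
    data.frame(wavelength_nm = basis$xyz_wavelength_nm,
               x = format(basis$xyz[, "x"], digits = 15, trim = TRUE),
               y = format(basis$xyz[, "y"], digits = 15, trim = TRUE),
               z = format(basis$xyz[, "z"], digits = 15, trim = TRUE)),
    con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(dir)
}

#' Generate the synthetic basis tables
#'
#' Builds a complete set of stand-in basis tables on the model-native grid
#' (390--830 nm, 5 nm step) from published analytic templates:
#'
#' * **Photopigment absorbances** use the Govardovskii A1 visual-pigment
#'   nomogram (alpha band plus beta band) with absorbance peaks at 558, 530
#'   and 421 nm for L, M and S, peak-normalised on the grid.
#' * **Ocular media** is split into an age-dependent exponential component
#'   and a smaller age-independent exponential component, tuned so the
#'   32-year-old total density resembles typical human ocular-media curves
#'   (about 1.9 at 390 nm, falling below 0.05 beyond 550 nm).
#' * **Macular pigment** relative density is a three-Gaussian mixture peaking
#'   at 460 nm with a short-wave shoulder, peak-normalised.
#' * **Standard observer**: an XYZ-like 10 degree observer obtained by a fixed
#'   trichromatic recombination of the zero-deviation fundamentals for a
#'   32-year-old at 10 degrees, scaled to unit peak in the y channel.
#'
#' These tables emulate the spectral structure of the physiological-observer
#' reference data but are not numerically identical to it; all package
#' results derived from them are internally consistent rather than tied to
#' the archival tabulations.
#'
#' @return A validated `basis_tables` object.
#' @export
synthetic_basis_tables <- function() {
  grid <- .model_grid

  docul1 <- 1.45 * exp(-(grid - 390) / 45)
  docul2 <- 0.45 * exp(-(grid - 390) / 40)

  mac <- 0.95 * exp(-((grid - 460) / 26)^2) +
    0.60 * exp(-((grid - 432) / 28)^2) +
    0.30 * exp(-((grid - 488) / 20)^2)
  mac <- mac / max(mac)

  absorb <- cbind(L = pigment_template(grid, 558),
                  M = pigment_template(grid, 530),
                  S = pigment_template(grid, 421))
  absorb <- sweep(absorb, 2L, apply(absorb, 2L, max), "/")

  obj <- structure(list(
    wavelength_nm = grid,
    docul1 = docul1,
    docul2 = docul2,
    d_rel_macula = mac,
    absorbance = absorb,
    xyz_wavelength_nm = grid,
    xyz = matrix(0, length(grid), 3L, dimnames = list(NULL, c("x", "y", "z"))),
    version = "synthetic",
    source = "synthetic"
  ), class = "basis_tables")

  # Standard observer: fixed cone -> XYZ-like recombination of the baseline
  # (zero-deviation, age 32, 10 degree) fundamentals.
  base <- cone_fundamentals(observer_spec(age = 32, field_size = 10), obj)
  m <- matrix(c(1.93986443, -1.34664359, 0.43044935,
                0.69283932,  0.34967567, 0.00000000,
                0.00000000,  0.00000000, 2.14687945),
              nrow = 3L, byrow = TRUE)
  xyz <- base$lms %*% t(m)
  xyz[xyz < 0] <- 0
  xyz <- xyz / max(xyz[, 2L])
  colnames(xyz) <- c("x", "y", "z")
  obj$xyz <- xyz
  validate_basis_tables(obj)
  obj
}

# Govardovskii et al. A1 pigment absorbance nomogram (alpha + beta band),
# parameterised by the absorbance peak wavelength in nm.
pigment_template <- function(lambda, lambda_max) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max
  bb <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((lambda - lmb) / bb)^2)
  alpha + beta
}
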