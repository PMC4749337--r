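test_that("ocular media density follows the aging and deviation rules", {
  # at the pivot age the aging factor is exactly 1
  d32 <- ocular_media_density(32, 0, basis)
  expect_equal(d32$value, basis$docul1 + basis$docul2, tolerance = 1e-12)
  # the two age branches agree exactly at the 60-year breakpoint
  lo <- ocular_media_density(60, 0, basis)
  expect_equal(lo$value, basis$docul1 * 1.56 + basis$docul2, tolerance = 1e-12)
  expect_equal(ocular_media_density(60 + 1e-9, 0, basis)$value, lo$value,
               tolerance = 1e-7)
  # +100% deviation doubles the density at every wavelength
  expect_equal(ocular_media_density(32, 100, basis)$value, 2 * d32$value,
               tolerance = 1e-12)
  expect_error(ocular_media_density(0, 0, basis), "age")
})

test_that("macular peak density follows the field-size exponential", {
  expect_equal(macular_peak_density(2, 0), 0.485 * exp(-2 / 6.132),
               tolerance = 1e-12)
  expect_equal(macular_peak_density(2, -100), 0)
  expect_equal(macular_peak_density(7.3, 50), 1.5 * macular_peak_density(7.3, 0),
               tolerance = 1e-12)
  # strictly decreasing in field size
  v <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(macular_peak_density(v, 0)) < 0))
  # spectrum peaks at the scalar peak density and is proportional to the table
  sp <- macular_density_spectrum(2, 10, basis)
  expect_equal(max(sp$value), macular_peak_density(2, 10), tolerance = 1e-12)
  expect_equal(sp$value, macular_peak_density(2, 10) * basis$d_rel_macula,
               tolerance = 1e-12)
  expect_equal(macular_density_spectrum(4, -100, basis)$value,
               rep(0, 89))
})

test_that("photopigment peak densities use the L/M and S relations", {
  expect_equal(photopigment_peak_density("L", 10), 0.38 + 0.54 * exp(-10 / 1.333),
               tolerance = 1e-12)
  expect_equal(photopigment_peak_density("M", 3.7),
               photopigment_peak_density("L", 3.7))
  expect_equal(photopigment_peak_density("S", 10), 0.30 + 0.45 * exp(-10 / 1.333),
               tolerance = 1e-12)
  # large-field limits approach the asymptotic densities
  expect_equal(photopigment_peak_density("L", 10), 0.38, tolerance = 1e-3)
  expect_equal(photopigment_peak_density("S", 10), 0.30, tolerance = 1e-3)
  expect_equal(photopigment_peak_density("L", 2, 10),
               1.1 * photopigment_peak_density("L", 2, 0), tolerance = 1e-12)
})

test_that("cone absorptance respects the density limit and the shift translation", {
  expect_equal(cone_absorptance("L", 2, d = -100, s = 0, basis = basis)$value,
               rep(0, 89))
  a0 <- cone_absorptance("M", 2, 0, 0, basis)
  dmax <- photopigment_peak_density("M", 2)
  expect_equal(a0$value, 1 - 10^(-dmax * basis$absorbance[, "M"]),
               tolerance = 1e-12)
  expect_true(all(a0$value >= 0 & a0$value < 1))
  # a +5 nm shift equals the unshifted curve read 5 nm lower (grid-aligned)
  a5 <- cone_absorptance("M", 2, 0, 5, basis)
  idx <- 2:89
  expect_equal(a5$value[idx], a0$value[idx - 1L], tolerance = 1e-12)
  expect_error(cone_absorptance("M", 2, 0, 31, basis), "30 nm")
})

test_that("zero-deviation fundamentals reduce to the average-observer recipe", {
  for (cond in list(c(32, 2), c(32, 10), c(55, 6.5))) {
    cf <- cone_fundamentals(observer_spec(cond[1], cond[2]), basis)
    oracle <- average_observer_recipe(cond[1], cond[2], basis)
    expect_lt(max(abs(cf$lms - oracle)), 1e-9)
  }
})

test_that("fundamentals are unit-peak, nonnegative, and shift with s_j", {
  spec <- observer_spec(45, 6.5, d_lens = 12, d_macula = -30, d_L = 5,
                        d_M = -8, d_S = 2, s_L = 2, s_M = -1.5, s_S = 0.5)
  cf <- cone_fundamentals(spec, basis)
  expect_equal(unname(apply(cf$lms, 2, max)), c(1, 1, 1))
  expect_true(all(cf$lms >= 0))
  # absorptance peak translates by the shift within one grid step
  a_base <- cone_absorptance("L", 6.5, 0, 0, basis)
  a_shift <- cone_absorptance("L", 6.5, 0, 10, basis)
  peak_d <- basis$wavelength_nm[which.max(a_shift$value)] -
    basis$wavelength_nm[which.max(a_base$value)]
  expect_lte(abs(peak_d - 10), 5)
})

test_that("increasing lens density depresses short-wave sensitivity before normalisation", {
  i400 <- match(400, basis$wavelength_nm)
  lq_at_400 <- function(d_lens) {
    alpha <- cone_absorptance("L", 2, 0, 0, basis)$value[i400]
    filt <- 10^(-(ocular_media_density(32, d_lens, basis)$value[i400] +
                    macular_density_spectrum(2, 0, basis)$value[i400]))
    alpha * filt
  }
  vals <- vapply(c(0, 10, 25, 50), lq_at_400, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("with no macular pigment the quanta fundamentals are absorptance times the lens filter", {
  spec <- observer_spec(32, 2, d_macula = -100)
  cf_q <- local({
    alpha <- cone_absorptance("L", 2, 0, 0, basis)$value
    docul <- ocular_media_density(32, 0, basis)$value
    e <- alpha * 10^(-docul) * basis$wavelength_nm
    e / max(e)
  })
  cf <- cone_fundamentals(spec, basis)
  expect_equal(cf$lms[, "l"], cf_q, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("observer_spec rejects unphysical parameters", {
  expect_error(observer_spec(-5, 2), "age")
  expect_error(observer_spec(32, 11), "field_size")
  expect_error(observer_spec(32, 2, d_macula = -100.5), "-100")
  expect_error(observer_spec(32, 2, s_S = 40), "30 nm")
  expect_error(observer_spec(NA, 2), "finite")
})
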