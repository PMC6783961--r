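test_that("a single charge state is not enough support", {
  one <- envelope_centroids(24000)[6, , drop = FALSE]
  expect_identical(nrow(deconvolute(one)), 0L)
})

test_that("two species one oxidation apart are resolved", {
  cen <- rbind(envelope_centroids(24000, total = 1e5),
               envelope_centroids(24016, total = 4e4))
  cen <- cen[order(cen$mz), ]
  dp <- deconvolute(cen)
  expect_gte(nrow(dp), 2)
  sep <- abs(dp$mass[2] - dp$mass[1])
  expect_lt(abs(sep - 16), 0.5)
  # output sorted by abundance
  expect_true(!is.unsorted(-dp$abundance))
})

test_that("centroiding finds symmetric peak centres", {
  mz <- seq(1195, 1205, by = 0.01)
  spec <- list(mz = mz, intensity = 1000 * exp(-(mz - 1200)^2 / (2 * 0.12^2)))
  cen <- centroid_peaks(spec)
  expect_identical(nrow(cen), 1L)
  expect_lt(abs(cen$mz - 1200), 0.005)

  two <- list(mz = mz, intensity =
                1000 * exp(-(mz - 1198)^2 / (2 * 0.12^2)) +
                600 * exp(-(mz - 1203)^2 / (2 * 0.12^2)))
  expect_identical(nrow(centroid_peaks(two)), 2L)

  empty <- list(mz = numeric(), intensity = numeric())
  expect_identical(nrow(centroid_peaks(empty)), 0L)
})

test_that("spectrum averaging is the arithmetic mean on the common grid", {
  mk_run <- function(scans) {
    structure(list(scans = scans, acq = acquisition_params()),
              class = "chromatographic_run")
  }
  s1 <- list(rt = 1, mz = c(1000, 1000.01, 1000.02), intensity = c(1, 10, 2))
  s3 <- list(rt = 2, mz = s1$mz, intensity = 3 * s1$intensity)
  run <- mk_run(list(s1, s1, s1))
  avg <- average_spectrum(run, c(0.5, 2.5))
  expect_equal(avg$intensity, s1$intensity)
  avg2 <- average_spectrum(mk_run(list(s1, s3)), c(0.5, 2.5))
  expect_equal(avg2$intensity, 2 * s1$intensity)
  expect_error(average_spectrum(run, c(5, 6)), "no scans")
  # scans on differing grids are aligned, absent points count as zero
  s2 <- list(rt = 1.5, mz = c(1000.01, 1000.03), intensity = c(4, 8))
  avg3 <- average_spectrum(mk_run(list(s1, s2)), c(0.5, 2.5))
  expect_equal(avg3$mz, c(1000, 1000.01, 1000.02, 1000.03))
  expect_equal(avg3$intensity, c(0.5, 7, 1, 4))
})

test_that("peak detection handles degenerate chromatograms", {
  flat <- structure(list(scans = lapply(1:50, function(i)
    list(rt = i / 10, mz = c(1000, 1001), intensity = c(2, 2))),
    acq = acquisition_params()), class = "chromatographic_run")
  expect_identical(nrow(detect_chromatographic_peaks(flat)), 0L)
  zero <- structure(list(scans = lapply(1:50, function(i)
    list(rt = i / 10, mz = c(1000, 1001), intensity = c(0, 0))),
    acq = acquisition_params()), class = "chromatographic_run")
  expect_identical(nrow(detect_chromatographic_peaks(zero)), 0L)
})

test_that("EIC peak height is linear in simulated abundance", {
  fractions <- c(0.004, 0.02, 0.08, 0.4)
  heights <- vapply(fractions, function(f) {
    mab <- mab_definition("lin", bev("RP")$heavy_chain, bev("RP")$light_chain,
                          pyroglu_fraction = 0,
                          glycan_fractions = c(G0F = f, G1F = 0, none = 1 - f),
                          label_offsets = c("LC" = 0, "Fd'" = 0, "Fc/2" = 236))
    run <- simulate_run(mab, default_scenario(mab), "con", 0,
                        acq = noiseless_acq(), seed = 3)
    lib <- mab_library(mab)
    m <- lib$avg_mass[lib$subunit == "Fc/2" & lib$glycan == "G0F" &
                        lib$n_ox == 0 & !lib$cterm_lys][1]
    z <- apex_charge(m)
    extract_eic(run, (m + z * 1.00728) / z,
                rt_window = c(4.8, 5.2))$peak_height
  }, numeric(1))
  expect_gt(cor(heights, fractions)^2, 0.99)
  # doubling the abundance doubles the height within 5%
  expect_equal(heights[3] / heights[2], 4, tolerance = 0.05)
})

test_that("EIC windows behave monotonically and validate their centre", {
  mab <- bev("RP")
  run <- fixture("eic_run", function()
    simulate_run(mab, default_scenario(mab), "oxi", 24, acq = test_acq(),
                 seed = 17))
  lib <- mab_library(mab)
  m <- lib$avg_mass[lib$subunit == "LC" & lib$n_ox == 0 & !lib$pyroglu][1]
  z <- apex_charge(m)
  mzc <- (m + z * 1.00728) / z
  narrow <- extract_eic(run, mzc, tol = 0.01, rt_window = c(7.5, 8.5))
  wide <- extract_eic(run, mzc, tol = 0.1, rt_window = c(7.5, 8.5))
  expect_gte(wide$peak_height, narrow$peak_height)
  # a species absent from the run reads out at noise level
  absent <- extract_eic(run, mzc + 200, tol = 0.01, rt_window = c(7.5, 8.5))
  expect_lt(absent$peak_height, 0.001 * narrow$peak_height)
  expect_error(extract_eic(run, 5000), "outside acquisition range")
})
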