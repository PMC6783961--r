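test_that("identical seed and parameters give a bit-identical run", {
  mab <- bev("RP")
  kin <- default_scenario(mab)
  acq <- test_acq()
  r1 <- simulate_run(mab, kin, "oxi", 24, acq = acq, seed = 99)
  r2 <- simulate_run(mab, kin, "oxi", 24, acq = acq, seed = 99)
  expect_identical(r1$scans, r2$scans)
  r3 <- simulate_run(mab, kin, "oxi", 24, acq = acq, seed = 100)
  expect_false(identical(r1$scans, r3$scans))
})

test_that("scans are rt-ordered with strictly increasing m/z in range", {
  mab <- inf("RP")
  run <- simulate_run(mab, default_scenario(mab), "oxi", 48,
                      acq = test_acq(), seed = 5)
  rts <- vapply(run$scans, `[[`, numeric(1), "rt")
  expect_true(!is.unsorted(rts, strictly = TRUE))
  for (s in run$scans[seq(1, length(run$scans), by = 97)]) {
    expect_true(!is.unsorted(s$mz, strictly = TRUE))
    expect_true(all(s$mz >= 600 & s$mz <= 3200))
  }
})

test_that("control runs carry the 0 h ground-truth profile", {
  mab <- bev("BS")
  kin <- default_scenario(mab)
  g0 <- simulate_run(mab, kin, "con", 0, acq = test_acq(),
                     seed = 1)$ground_truth
  g72 <- simulate_run(mab, kin, "con", 72, acq = test_acq(),
                      seed = 2)$ground_truth
  expect_equal(g0$fraction, g72$fraction, tolerance = 1e-12)
  # unoxidized everywhere
  expect_equal(sum(g72$fraction[g72$n_ox == 0L]), 3, tolerance = 1e-9)
})

test_that("a noiseless unmodified scenario yields one clean peak per subunit", {
  mab <- fixture("plain_mab", function() {
    path <- system.file("extdata", "bevacizumab_synthetic.fasta",
                        package = "forceox")
    load_mab_fasta(path, role = "RP", name = "plain",
                   cterm_lys_fraction = 0, pyroglu_fraction = 0,
                   glycan_fractions = c(G0F = 1, G1F = 0, none = 0),
                   label_offsets = c("LC" = 0, "Fd'" = 0, "Fc/2" = 236))
  })
  kin <- default_scenario(mab)
  run <- simulate_run(mab, kin, "con", 0, acq = noiseless_acq(), seed = 1)
  pk <- detect_chromatographic_peaks(run)
  expect_identical(nrow(pk), 3L)
  expect_true(!is.unsorted(pk$rt_apex))
  # the three apexes sit at the configured base RTs
  expect_true(all(abs(pk$rt_apex -
                        unname(run$acq$base_rt[c("Fc/2", "LC", "Fd'")])) <
                    0.05))
  # deconvolution of each window recovers the theoretical subunit mass
  subs <- ides_digest(mab)
  masses <- c(average_mass(subs[["Fc/2"]]$sequence,
                           modification_state(glycan = "G0F")),
              average_mass(subs[["LC"]]$sequence),
              average_mass(subs[["Fd'"]]$sequence))
  for (i in 1:3) {
    spec <- average_spectrum(run, c(pk$rt_min[i], pk$rt_max[i]))
    dp <- deconvolute(centroid_peaks(spec))
    expect_gt(nrow(dp), 0)
    expect_lt(abs(dp$mass[1] - masses[i]) / masses[i] * 1e6, 20)
  }
})

test_that("species that cannot ionize inside the m/z window are dropped", {
  tiny <- mab_definition("tiny", heavy_chain = "QVKSSCPAPELLGGPSVFK",
                         light_chain = "DIQK", pyroglu_fraction = 0,
                         glycan_fractions = c(G0F = 0, G1F = 0, none = 1))
  kin <- default_scenario(tiny)
  expect_warning(
    simulate_run(tiny, kin, "con", 0, acq = test_acq(), seed = 1),
    "outside the m/z range")
})

test_that("mzML round-trips through mzR numerically intact", {
  mab <- bev("RP")
  acq <- acquisition_params(rt_span = c(4.5, 5.5))
  run <- simulate_run(mab, default_scenario(mab), "oxi", 24, acq = acq,
                      seed = 8)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, path)
  back <- read_mzml(path, acq = acq)
  expect_identical(length(back$scans), length(run$scans))
  i <- which.max(vapply(run$scans, function(s) sum(s$intensity), numeric(1)))
  expect_equal(back$scans[[i]]$mz, run$scans[[i]]$mz, tolerance = 1e-9)
  expect_equal(back$scans[[i]]$intensity, run$scans[[i]]$intensity,
               tolerance = 1e-6)
  expect_equal(back$scans[[i]]$rt, run$scans[[i]]$rt, tolerance = 1e-9)
})

test_that("the design table mirrors the study layout", {
  d <- table1_design()
  expect_identical(nrow(d), 2L * 2L * 7L * 3L)
  expect_setequal(unique(d$duration[d$treatment == "oxi"]), c(24, 48, 72))
  expect_setequal(unique(d$duration[d$treatment == "con"]), c(0, 24, 48, 72))
  expect_identical(max(d$replicate), 3L)
})
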