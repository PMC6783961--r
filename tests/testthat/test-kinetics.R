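test_that("degenerate kinetics collapse to the expected states", {
  d0 <- oxidation_state_distribution(c(0, 0), t = 48, k_u = 0)
  expect_equal(unname(d0[1]), 1, tolerance = 1e-12)
  dsat <- oxidation_state_distribution(5, t = 1000, k_u = 0)
  expect_equal(unname(dsat["1"]), 1, tolerance = 1e-9)
  expect_error(oxidation_state_distribution(0.1, t = -1), "non-negative")
})

test_that("site-count distribution equals the subset-enumeration oracle", {
  # two half-oxidized sites
  d <- oxidation_state_distribution(c(log(2), log(2)), t = 1, k_u = 0)
  expect_equal(unname(d[1:3]), c(0.25, 0.5, 0.25), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:5) {
    k <- runif(5, 0, 0.2)
    t <- runif(1, 1, 72)
    d <- oxidation_state_distribution(k, t = t, k_u = 0)
    oracle <- oracle_site_count_distribution(1 - exp(-k * t))
    expect_equal(unname(d[1:6]), oracle, tolerance = 1e-10)
  }
})

test_that("distributions are proper and monotone in dose", {
  set.seed(4)
  for (i in 1:10) {
    k <- runif(3, 0, 0.3)
    d <- oxidation_state_distribution(k, t = runif(1, 0, 72))
    expect_equal(sum(d), 1, tolerance = 1e-9)
    expect_true(all(d >= 0))
  }
  expect_n <- function(k, t, k_u = 0.01) {
    d <- oxidation_state_distribution(k, t, k_u = k_u)
    sum(as.numeric(names(d)) * d)
  }
  ts <- c(0, 12, 24, 48, 72)
  en <- vapply(ts, function(t) expect_n(c(0.01, 0.05), t), numeric(1))
  expect_true(all(diff(en) > 0))
  ks <- c(0.001, 0.01, 0.1)
  en_k <- vapply(ks, function(k) expect_n(c(k, 0.05), 48), numeric(1))
  expect_true(all(diff(en_k) > 0))
})

test_that("control treatment nullifies all rates", {
  d <- oxidation_state_distribution(c(0.15, 0.15), t = 72,
                                    treatment = "con", k_u = 0.01)
  expect_equal(unname(d[1]), 1, tolerance = 1e-12)
})

test_that("the default scenario encodes the exposure classes", {
  kin_rp <- default_scenario(bev("RP"))
  kin_bs <- default_scenario(bev("BS"))
  expect_true(all(kin_rp$sites$exposure_class[
    kin_rp$sites$subunit == "Fc/2"] == "fast"))
  expect_true(all(kin_rp$sites$exposure_class[
    kin_rp$sites$subunit != "Fc/2"] == "slow"))
  # fast class exceeds the slow default
  expect_true(min(kin_rp$sites$rate_constant[
    kin_rp$sites$exposure_class == "fast"]) >
      max(kin_rp$sites$rate_constant[kin_rp$sites$exposure_class == "slow"]))
  # >= 97% conversion of fast sites at 24 h
  expect_gte(1 - exp(-0.15 * 24), 0.97)
  # RP and BS differ only in the slow class
  m <- merge(kin_rp$sites, kin_bs$sites,
             by = c("subunit", "site_label", "exposure_class"))
  fast <- m$exposure_class == "fast"
  expect_equal(m$rate_constant.x[fast], m$rate_constant.y[fast])
  expect_equal(m$rate_constant.y[!fast], 2 * m$rate_constant.x[!fast])
  # infliximab-like LC M55 and Fd' M18 are fast
  kin_inf <- default_scenario(inf())
  expect_identical(
    kin_inf$sites$exposure_class[kin_inf$sites$site_label %in%
                                   c("M55", "M18")], c("fast", "fast"))
})

test_that("default presets reproduce the qualitative endpoint modes", {
  kin <- default_scenario(bev("RP"))
  mode_of <- function(sites_subunit, t, kin) {
    k <- kin$sites$rate_constant[kin$sites$subunit == sites_subunit]
    d <- oxidation_state_distribution(k, t, k_u = kin$k_u)
    as.integer(names(d)[which.max(d)])
  }
  expect_identical(mode_of("Fc/2", 24, kin), 3L)
  expect_identical(mode_of("LC", 48, kin), 0L)
  expect_identical(mode_of("Fd'", 48, kin), 0L)
  kin_inf <- default_scenario(inf())
  expect_identical(mode_of("Fc/2", 24, kin_inf), 2L)
  expect_identical(mode_of("LC", 24, kin_inf), 1L)
  expect_identical(mode_of("Fd'", 48, kin_inf), 1L)
})

test_that("ground-truth fractions are proper per subunit", {
  mab <- inf("RP")
  gt <- ground_truth_fractions(mab, default_scenario(mab), "oxi", 48)
  sums <- tapply(gt$library$fraction, gt$library$subunit, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-9)
  # retained-lysine forms appear only on Fc/2 and at the configured level
  kfrac <- sum(gt$library$fraction[gt$library$cterm_lys])
  expect_equal(kfrac, mab$cterm_lys_fraction, tolerance = 1e-9)
  expect_true(all(gt$library$subunit[gt$library$cterm_lys] == "Fc/2"))
})
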