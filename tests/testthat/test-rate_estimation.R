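make_const_series <- function(time = seq(0, 1, 0.1), volume = 1,
                              biomass = 10, conc) {
  structure(data.frame(time_h = time, volume_L = volume,
                       biomass_gL = biomass, foo_gL = conc),
            class = c("fedbatch_series", "data.frame"))
}

test_that("specific rate: hand-computed cases", {
  ## X = 10 g/L, V = 1 L, concentration 0 -> 1 g/L over 1 h, no feed
  s <- make_const_series(conc = seq(0, 1, 0.1))
  expect_equal(specific_rate(s, "foo", 0, 1), 100)
  ## flat concentration -> zero rate
  expect_equal(specific_rate(make_const_series(conc = 0.7), "foo", 0, 1), 0)
  expect_error(specific_rate(s, "foo", 1, 0), "t1")
  expect_error(specific_rate(s, "bar", 0, 1), "bar")
  expect_error(specific_rate(s, "foo", 0.01, 0.02), "fewer than 2")
})

test_that("specific rates recover the generator's production kinetics", {
  fb <- clean_fedbatch()
  p <- attr(fb, "truth")$params
  ## independent expectation from the carbon-partition construction:
  ## product formation = f_cys x (consumed glucose carbon) / (g C/g cys)
  consumedC <- function(t1, t2) {
    fedC <- stats::approx(fb$time_h, fb$feed_glucose_g_cum, c(t1, t2))$y
    pool <- stats::approx(fb$time_h, fb$glucose_gL * fb$volume_L,
                          c(t1, t2))$y
    (diff(fedC) - diff(pool)) * 6 * 12.011 / 180.156
  }
  gcc <- 3 * 12.011 / 121.158
  sel <- fb$time_h >= 20 & fb$time_h <= 30
  tt <- fb$time_h[sel]
  y <- fb$biomass_gL[sel] * fb$volume_L[sel]
  biomass_int <- sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2)
  expected <- 1000 * p$f_cys * consumedC(20, 30) / gcc / biomass_int
  got <- specific_rate(fb, "cysteine", 20, 30)
  expect_equal(got, expected, tolerance = 0.02)
})

test_that("volumetric productivity arithmetic and sign convention", {
  s <- make_const_series(time = seq(0, 10, 1), conc = seq(10, 20, 1))
  expect_equal(volumetric_productivity(s, "foo", 0, 10), 1.0)
  expect_error(volumetric_productivity(s, "foo", 5, 5), "t1")
  declining <- make_const_series(time = seq(0, 10, 1), conc = seq(20, 10, -1))
  expect_lt(volumetric_productivity(declining, "foo", 0, 10), 0)
})

test_that("selectivity reproduces the worked rate pairs", {
  expect_equal(selectivity(24.6, 30.1), 24.6 / 30.1, tolerance = 1e-12)
  expect_equal(round(selectivity(24.6, 30.1), 3), 0.817)
  expect_equal(selectivity(5, 5), 1.0)
  expect_equal(round(selectivity(20.7, 17.6), 3), 1.176)
  expect_error(selectivity(10, 0), "undefined")
  expect_error(selectivity(10, -2), "undefined")
  ## reciprocity
  expect_equal(selectivity(24.6, 30.1) * selectivity(30.1, 24.6), 1)
})

test_that("gas exchange: null case, truth recovery, respiratory quotient", {
  ## identical inlet and outlet composition -> no exchange
  null_series <- structure(
    data.frame(time_h = 0:5, volume_L = 10, offgas_o2 = 0.2095,
               offgas_co2 = 0.0004, gas_flow_NL_min = 20),
    class = c("fedbatch_series", "data.frame"))
  g0 <- gas_exchange_rates(null_series, 2.5)
  expect_equal(g0$OUR_mmol_L_h, 0, tolerance = 1e-9)
  expect_equal(g0$CER_mmol_L_h, 0, tolerance = 1e-9)
  expect_error(gas_exchange_rates(make_const_series(conc = 1), 0.5),
               "off-gas")
  ## recovery of the imposed rates from the synthetic off-gas profile
  fb <- clean_fedbatch()
  truth <- attr(fb, "truth")
  at <- c(10, 25, 40)
  ger <- gas_exchange_rates(fb, at)
  idx <- match(at, fb$time_h)
  want <- truth$CER_mol_h[idx] / fb$volume_L[idx] * 1000
  expect_equal(ger$CER_mmol_L_h, want, tolerance = 0.01)
  expect_equal(ger$OUR_mmol_L_h, want / truth$params$RQ, tolerance = 0.01)
  expect_equal(ger$CER_mmol_L_h / ger$OUR_mmol_L_h,
               rep(truth$params$RQ, 3), tolerance = 1e-6)
})

test_that("carbon balance: closure, linearity in biomass carbon, density invariance", {
  fb <- clean_fedbatch()
  cb <- carbon_balance(fb)
  expect_equal(attr(cb, "unaccounted_pct"), 0, tolerance = 1e-6)
  expect_gte(attr(cb, "accounted_pct"), 99)
  ## doubling the biomass carbon fraction doubles the biomass share
  cb2 <- carbon_balance(fb, biomass_carbon_fraction = 2 * 0.474)
  expect_equal(cb2$share_pct[cb2$sink == "biomass"],
               2 * cb$share_pct[cb$sink == "biomass"], tolerance = 1e-9)
  expect_equal(cb2$share_pct[cb2$sink == "nas"],
               cb$share_pct[cb$sink == "nas"], tolerance = 1e-9)
  ## refining the sampling grid moves shares by < 0.5 percentage points
  fb_fine <- generate_fedbatch_series(params = list(dt = 0.25))
  cb_fine <- carbon_balance(fb_fine)
  common <- intersect(cb$sink, cb_fine$sink)
  expect_lt(max(abs(cb$share_pct[match(common, cb$sink)] -
                      cb_fine$share_pct[match(common, cb_fine$sink)])), 0.5)
})

test_that("fed-batch CSV round trip and monotone-time validation", {
  fb <- clean_fedbatch()
  path <- withr::local_tempfile(fileext = ".csv")
  write_fedbatch(fb, path)
  fb2 <- read_fedbatch(path)
  expect_equal(fb2$cysteine_gL, fb$cysteine_gL, tolerance = 1e-12)
  bad <- as.data.frame(fb)[c(1, 1, 2), ]
  badp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, badp, row.names = FALSE)
  expect_error(read_fedbatch(badp), "strictly increasing")
})
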