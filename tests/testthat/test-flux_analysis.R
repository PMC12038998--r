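test_that("FBA finds the bottleneck of a linear chain", {
  expect_equal(fba(toy_chain(), "EX")$objective_value, 10)
  expect_equal(fba(toy_chain(cap_conv = 4), "EX")$objective_value, 4)
})

test_that("FBA matches a brute-force vertex-enumeration oracle", {
  ## random small networks with exchange columns; optimum must agree with
  ## exhaustive enumeration of basic feasible solutions
  set.seed(11)
  for (rep in 1:5) {
    m <- 3; n <- 6
    N <- matrix(sample(c(-1, 0, 1), m * n, replace = TRUE, prob = c(.3, .4, .3)),
                m, n)
    N[, 1] <- c(1, 0, 0); N[, n] <- c(0, 0, -1)   # source and sink
    lb <- rep(0, n); ub <- rep(5, n)
    obj <- as.numeric(seq_len(n) == n)
    sol <- solve_lp(obj, Aeq = N, beq = rep(0, m), lb = lb, ub = ub,
                    maximize = TRUE)
    ref <- brute_force_lp_max(N, obj, lb, ub)
    if (sol$status == "optimal" && is.finite(ref))
      expect_equal(sol$objective, ref, tolerance = 1e-6)
  }
})

test_that("FBA reports conflicting measured-rate constraints when infeasible", {
  err <- tryCatch(
    fba(toy_chain(), "EX", rate_constraints = list(UP = c(8, 8),
                                                   CONV = c(3, 3))),
    error = conditionMessage)
  expect_match(err, "infeasible")
  expect_match(err, "UP|CONV")
})

test_that("FVA ranges behave: degenerate at fraction 1, contain FBA flux, shrink monotonically", {
  m <- toy_chain()
  fv1 <- fva(m, "EX", fraction = 1.0)
  expect_true(all(abs(fv1$ranges[, "max"] - fv1$ranges[, "min"]) < 1e-8))
  fv <- fva(m, "EX", fraction = 0.9)
  fd <- fba(m, "EX")
  expect_true(all(fd$flux >= fv$ranges[, "min"] - 1e-8))
  expect_true(all(fd$flux <= fv$ranges[, "max"] + 1e-8))
  fv95 <- fva(m, "EX", fraction = 0.95)
  expect_true(all(fv95$ranges[, "min"] >= fv$ranges[, "min"] - 1e-8))
  expect_true(all(fv95$ranges[, "max"] <= fv$ranges[, "max"] + 1e-8))
})

test_that("loopless FVA suppresses an internal two-cycle", {
  m <- toy_cycle()
  plain <- fva(m, "EX", fraction = 1.0, loopless = FALSE)
  ll <- fva(m, "EX", fraction = 1.0, loopless = TRUE)
  ## without loop removal the cycle pair can carry arbitrary flux
  expect_gt(plain$ranges["C1", "max"], 50)
  expect_lt(ll$ranges["C1", "max"], 1e-8)
  expect_lt(ll$ranges["C2", "max"], 1e-8)
  ## the actual pathway is untouched
  expect_equal(unname(ll$ranges["EX", "max"]), 5, tolerance = 1e-6)
})

test_that("Gibbs reaction energy evaluation", {
  expect_equal(delta_g_reaction(0, c(S = -1, P = 1),
                                c(S = log(1), P = log(1))), 0)
  ## 10 mM substrate, 1 mM product at 305.15 K
  expect_equal(delta_g_reaction(-5, c(S = -1, P = 1),
                                c(S = log(0.01), P = log(0.001)),
                                temperature = 305.15),
               -5 + 8.314e-3 * 305.15 * log(0.1), tolerance = 1e-12)
  expect_equal(round(delta_g_reaction(-5, c(S = -1, P = 1),
                                      c(S = log(0.01), P = log(0.001)),
                                      305.15), 2), -10.84)
  ## 1:1 stoichiometry is invariant to doubling both concentrations
  d1 <- delta_g_reaction(-5, c(S = -1, P = 1), c(S = log(0.01), P = log(0.001)))
  d2 <- delta_g_reaction(-5, c(S = -1, P = 1), c(S = log(0.02), P = log(0.002)))
  expect_equal(d1, d2)
  expect_error(delta_g_reaction(-5, c(S = -1, P = 1), c(S = log(0.01))),
               "missing concentrations")
})

test_that("equilibrium classification follows the -10 kJ/mol rule", {
  expect_equal(unname(classify_equilibrium(c(-5, -12, -10, 3, NA))),
               c("near", "far", "near", "unclassified", "unclassified"))
})

test_that("TFA couples flux direction to the Gibbs energy sign", {
  ## a single conversion whose dG_r is forced positive by the bounds can
  ## carry no forward flux; the chain around it must shut down
  m <- toy_chain()
  b <- concentration_bounds(m, cmin_mM = 1, cmax_mM = 2)
  res <- tfa(m, b, dG0 = c(CONV = +30), variables = "flux")
  expect_lt(res$flux_ranges["CONV", "max"], 1e-6)
  ## thermodynamically consistent chain: TFA ranges within FVA ranges
  res2 <- tfa(m, b, dG0 = c(CONV = -30), variables = c("flux", "dGr"))
  fv <- fva(m, "EX", fraction = 0)   # whole feasible box
  expect_true(all(res2$flux_ranges[, "min"] >= fv$ranges[, "min"] - 1e-6))
  expect_true(all(res2$flux_ranges[, "max"] <= fv$ranges[, "max"] + 1e-6))
  expect_true(res2$thermo$dGr_max < 0)
  expect_equal(res2$thermo$eq_class, "far")
})

test_that("TFA direction-energy consistency holds on randomized instances", {
  set.seed(21)
  for (rep in 1:4) {
    m <- toy_chain(cap_up = 5 + rep)
    dg <- c(CONV = stats::runif(1, -40, 40))
    b <- concentration_bounds(m, cmin_mM = 0.5, cmax_mM = 5)
    res <- tfa(m, b, dG0 = dg, variables = c("flux", "dGr"))
    ## audit: positive admissible flux requires admissible negative dG_r
    if (res$flux_ranges["CONV", "max"] > 1e-6)
      expect_lt(res$thermo$dGr_min, 0)
    if (res$thermo$dGr_min > 0)
      expect_lt(res$flux_ranges["CONV", "max"], 1e-6)
  }
})

test_that("TFA on the reduced reference state shrinks the FVA space", {
  km <- default_km()
  ds <- clean_dataset()
  net <- km$model
  rc <- lapply(ds$observable, function(id) {
    v <- ds$reference$rates[[id]]; c(v * 0.98, v * 1.02)
  })
  names(rc) <- ds$observable
  bounds <- concentration_bounds(net, measured = ds$reference$concentrations)
  probe <- c("PTS", "PGI", "G6PDH", "CS", "CYSS", "SLCYSS", "YdeD", "ACS")
  ## same constraint set for both analyses (no optimum cut): the TFA
  ## admissible ranges must be contained in the FVA ranges
  fv <- fva(net, "BIOMASS", fraction = 0, rate_constraints = rc,
            reactions = probe)
  res <- tfa(net, bounds, km$dG0, rate_constraints = rc,
             variables = "flux", reactions = probe)
  expect_false(any(is.na(res$flux_ranges)))
  expect_true(all(res$flux_ranges[probe, "min"] >=
                    fv$ranges[probe, "min"] - 1e-4))
  expect_true(all(res$flux_ranges[probe, "max"] <=
                    fv$ranges[probe, "max"] + 1e-4))
})
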