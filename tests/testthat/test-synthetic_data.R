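test_that("default kinetic model assigns the expected rate-law families", {
  km <- default_km()
  expect_equal(sum(km$law == "thermokinetic"), 17L)
  expect_equal(sum(km$law == "linlog"), 20L)
  expect_equal(sum(km$law == "fixed"), 3L)
  expect_setequal(names(km$law)[km$law == "thermokinetic"],
                  near_equilibrium_enzymes())
  expect_setequal(names(km$law)[km$law == "linlog"],
                  far_from_equilibrium_enzymes())
  ## same seed reproduces the parameter draw exactly
  km2 <- make_default_kinetic_model(seed = 1)
  expect_identical(km2$eps_true, km$eps_true)
  expect_identical(km2$dG0, km$dG0)
  ## lin-log elasticity signs follow the stoichiometry
  expect_gt(km$eps_true["PFK", "f6p"], 0)     # substrate
  expect_lt(km$eps_true["PFK", "fdp"], 0)     # product
})

test_that("reference fluxes balance the augmented network and stay positive", {
  net <- build_kinetic_network()
  J <- reference_fluxes(net)
  N <- stoichiometric_matrix(net, internal_only = TRUE)
  expect_lt(max(abs(N %*% J)), 1e-10)
  expect_true(all(J > 0))
  expect_equal(unname(J["YdeD"]), unname(J["CYSS"] + J["SLCYSS"]))
})

test_that("steady-state solver reproduces the reference fixed point exactly", {
  km <- default_km()
  ref <- solve_steady_state(km, label = "ref")
  expect_lt(max(abs(ref$rates - km$J_ref)), 1e-9)
  expect_lt(max(abs(ref$concentrations -
                      km$c_ref[names(ref$concentrations)])), 1e-9)
})

test_that("perturbed steady states satisfy the internal mass balances", {
  km <- default_km()
  st <- solve_steady_state(km, boundary = list(externals = c(glc_e = 14.4)),
                           label = "glc")
  N <- stoichiometric_matrix(km$model, internal_only = TRUE)
  expect_lt(max(abs(N %*% st$rates)), 1e-8 * max(abs(st$rates)))
  expect_true(all(st$concentrations > 0))
  ## conserved CoA moiety stays at its reference total
  pool <- c("coa", "accoa", "succoa")
  expect_equal(sum(st$concentrations[pool]), sum(km$c_ref[pool]),
               tolerance = 1e-8)
})

test_that("an unreachable boundary produces a clear non-convergence error", {
  km <- default_km()
  expect_error(
    solve_steady_state(km, boundary = list(
      fluxes = c(PYRt = unname(km$J_ref["PYRt"]) * 50)), label = "bad"),
    "no steady state")
})

test_that("perturbation dataset: 13 states, reproducible, cysteine exported", {
  ds <- clean_dataset()
  expect_s3_class(ds, "mca_dataset")
  expect_length(ds$perturbations, 12L)
  expect_true(ds$reference$is_reference)
  states <- c(list(ds$reference), ds$perturbations)
  expect_true(all(vapply(states, function(s) s$rates[["YdeD"]] > 0,
                         logical(1))))
  ## noise-free states satisfy N v = 0
  N <- stoichiometric_matrix(default_km()$model, internal_only = TRUE)
  for (s in states)
    expect_lt(max(abs(N %*% s$rates)), 1e-8 * max(abs(s$rates)))
  ## seeded noise is reproducible and seed-sensitive
  km <- default_km()
  d1 <- generate_perturbation_dataset(km, noise_cv = 0.1, seed = 5)
  d2 <- generate_perturbation_dataset(km, noise_cv = 0.1, seed = 5)
  d3 <- generate_perturbation_dataset(km, noise_cv = 0.1, seed = 6)
  ## same seed reproduces the dataset (up to BLAS floating-point jitter)
  expect_equal(d1$reference$concentrations, d2$reference$concentrations,
               tolerance = 1e-12)
  expect_gt(max(abs(d1$reference$concentrations -
                      d3$reference$concentrations)), 1e-3)
  ## zero noise reproduces the exact model outputs
  expect_equal(ds$reference$rates, ds$ground_truth$J_ref, tolerance = 1e-12)
})

test_that("dataset CSV round trip preserves states and ground truth", {
  ds <- clean_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("metabolome.csv", "rates.csv",
                                               "ground_truth.json")))))
  ds2 <- read_dataset(dir)
  expect_length(ds2$perturbations, 12L)
  expect_equal(ds2$reference$rates, ds$reference$rates, tolerance = 1e-12)
  expect_equal(ds2$ground_truth$eps_true, ds$ground_truth$eps_true,
               tolerance = 1e-12)
})

test_that("finite-difference control coefficients: closed form on a chain", {
  km <- two_step_km()
  tc <- true_control_coefficients(km, relative_step = 1e-4)
  expect_equal(unname(tc$C_J), matrix(0.5, 2, 2), tolerance = 1e-6)
  expect_equal(unname(tc$C_S), matrix(c(0.5, -0.5), 1, 2), tolerance = 1e-6)
})

test_that("finite-difference oracle obeys the summation theorems and is second order", {
  km <- two_step_km()
  t2 <- true_control_coefficients(km, relative_step = 1e-3)
  expect_true(all(abs(rowSums(t2$C_J) - 1) < 1e-4))
  expect_true(all(abs(rowSums(t2$C_S)) < 1e-4))
  ## second-order convergence against the closed form, on an asymmetric
  ## chain (eps -1.3 / +0.7 -> C1 = 0.7/2 = 0.35) where the truncation
  ## error does not cancel by symmetry
  mets <- rbind(metabolite_spec("s_e", "S ext", FALSE, 1),
                metabolite_spec("s", "S", TRUE, 1),
                metabolite_spec("p_e", "P ext", FALSE, 1))
  mdl <- metabolic_model(mets, list(
    reaction_spec("SUPPLY", c(s_e = -1, s = 1)),
    reaction_spec("DEMAND", c(s = -1, p_e = 1))), id = "two_step_asym")
  eps <- matrix(0, 2, 3, dimnames = list(c("SUPPLY", "DEMAND"),
                                         c("s_e", "s", "p_e")))
  eps["SUPPLY", "s"] <- -1.3
  eps["DEMAND", "s"] <- 0.7
  ka <- kinetic_model(mdl, J_ref = c(SUPPLY = 1, DEMAND = 1),
                      c_ref = c(s_e = 10, s = 1, p_e = 1),
                      law = c(SUPPLY = "linlog", DEMAND = "linlog"),
                      eps_true = eps)
  Ctrue <- matrix(c(0.35, 0.35, 0.65, 0.65), 2, 2)
  err <- function(h)
    max(abs(true_control_coefficients(ka, relative_step = h)$C_J - Ctrue))
  e1 <- err(0.16); e2 <- err(0.08)
  expect_equal(e1 / e2, 4, tolerance = 0.2)
})

test_that("fed-batch generator: depletion-triggered feed and exact balance", {
  fb <- clean_fedbatch()
  truth <- attr(fb, "truth")
  ## glucose is (numerically) exhausted at the switch and feeding starts
  glc_at_switch <- stats::approx(fb$time_h, fb$glucose_gL,
                                 truth$t_switch)$y
  expect_lt(glc_at_switch, 1e-3)
  expect_true(all(fb$feed_glucose_L_h[fb$time_h < truth$t_switch] == 0))
  expect_true(any(fb$feed_glucose_L_h[fb$time_h > truth$t_switch] > 0))
  ## noise-free carbon balance closes
  cb <- carbon_balance(fb)
  expect_equal(attr(cb, "accounted_pct"), 100, tolerance = 1e-6)
  ## seeded noisy series reproducible
  n1 <- generate_fedbatch_series(noise_cv = 0.05, seed = 3)
  n2 <- generate_fedbatch_series(noise_cv = 0.05, seed = 3)
  expect_equal(n1$cysteine_gL, n2$cysteine_gL, tolerance = 1e-12)
})
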