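RT32 <- 8.314e-3 * 305.15

test_that("thermokinetic elasticity closed form and limits", {
  dgr_half <- RT32 * log(0.5)             # Gamma = 0.5
  expect_equal(thermokinetic_elasticity(-1, dgr_half), 1.0, tolerance = 1e-12)
  expect_equal(thermokinetic_elasticity(+1, dgr_half), -1.0, tolerance = 1e-12)
  ## saturated forward limit: elasticity vanishes
  expect_lt(abs(thermokinetic_elasticity(-1, -100)), 1e-12)
  ## near equilibrium the magnitude diverges
  expect_gt(thermokinetic_elasticity(-1, -0.01), 100)
  expect_error(thermokinetic_elasticity(-1, 0), "dGr < 0")
  expect_error(thermokinetic_elasticity(-1, 5), "dGr < 0")
  ## substrate elasticity increases monotonically as dGr -> 0-
  dgr <- seq(-20, -0.1, length.out = 50)
  eps <- vapply(dgr, function(d) thermokinetic_elasticity(-1, d), numeric(1))
  expect_true(all(diff(eps) > 0))
})

test_that("two-point lin-log regression solves exactly", {
  mets <- rbind(metabolite_spec("x", "X", TRUE, 1),
                metabolite_spec("x_e", "X ext", FALSE, 1))
  mdl <- metabolic_model(mets, list(reaction_spec("R", c(x = -1, x_e = 1))),
                         id = "one")
  mk_state <- function(label, cx, v, ref = FALSE)
    structure(list(label = label, concentrations = c(x = cx),
                   rates = c(R = v), is_reference = ref),
              class = "steady_state")
  ds <- structure(list(
    reference = mk_state("ref", 1, 1, TRUE),
    perturbations = list(mk_state("up", exp(0.1), 1.1),
                         mk_state("dn", exp(-0.1), 0.9))),
    class = "mca_dataset")
  fit <- linlog_elasticities(ds, mdl, "R")
  expect_equal(unname(fit$eps["x"]), 1.0, tolerance = 1e-12)
  expect_lt(fit$diagnostics$residual_variance, 1e-20)
  ## all states identical to the reference: no identifiable signal
  ds0 <- ds
  ds0$perturbations <- list(mk_state("same1", 1, 1), mk_state("same2", 1, 1))
  expect_error(linlog_elasticities(ds0, mdl, "R"), "zero design")
})

test_that("noise-free self-generated data is recovered to 6+ significant digits", {
  km <- default_km()
  ds <- clean_dataset()
  E <- default_elasticities()
  ll <- names(km$law)[km$law == "linlog"]
  truth <- km$eps_true[ll, colnames(E$E)]
  expect_lt(max(abs(E$E[ll, ] - truth)), 1e-7)
  ## external boundary effectors recovered too
  expect_equal(E$E_ext["PTS", "glc_e"], km$eps_true["PTS", "glc_e"],
               tolerance = 1e-7)
  expect_equal(E$E_ext["CYSS", "h2s"], km$eps_true["CYSS", "h2s"],
               tolerance = 1e-7)
  ## thermokinetic rows match the generating closed form at the reference
  nr <- names(km$law)[km$law == "thermokinetic"]
  expect_lt(max(abs(E$E[nr, ] - km$eps_true[nr, colnames(E$E)])), 1e-7)
})

test_that("elasticity matrix sparsity and method bookkeeping", {
  km <- default_km()
  E <- default_elasticities()
  expect_equal(E$E["PGI", "pyr"], 0)      # pyruvate is not a PGI effector
  expect_equal(sum(E$method == "thermokinetic"), 17L)
  expect_equal(sum(E$method == "linlog"), 20L)
  ## boundary uptake/drain reactions carry no elasticities
  expect_true(all(E$E[c("PYRt", "SUCCt", "BIOMASS"), ] == 0))
  ## every stored entry outside a reaction's effector set is zero
  for (id in c("PFK", "CYSS")) {
    s <- km$model$reactions[[id]]$stoichiometry
    zero_cols <- setdiff(colnames(E$E), names(s))
    expect_true(all(E$E[id, zero_cols] == 0))
  }
})

test_that("scaled/unscaled elasticity conversion is an involution", {
  E <- default_elasticities()$E
  km <- default_km()
  internal <- colnames(E)
  J <- km$J_ref[rownames(E)]
  conc <- km$c_ref[internal]
  U <- convert_elasticities(E, J, conc, "unscaled")
  back <- convert_elasticities(U, J, conc, "scaled")
  expect_equal(unname(back), unname(E), tolerance = 1e-12)
})

test_that("elasticity error under measurement noise scales with the design conditioning", {
  ## The boundary-perturbation design is exactly identified but
  ## ill-conditioned (condition number ~1e3 for the worst reactions), so
  ## the regression error grows roughly as condition x CV: recovery is
  ## accurate at low noise and degrades monotonically. This is the
  ## identifiability limitation that motivates the Monte Carlo analysis.
  km <- default_km()
  ds0 <- clean_dataset()
  ll <- names(km$law)[km$law == "linlog"]
  th <- default_thermo()
  err_at <- function(cv, reps = 15) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::median(replicate(reps, {
      ds <- ds0
      jit <- function(x) x * exp(stats::rnorm(length(x), 0, sdlog))
      ds$reference$concentrations <- jit(ds$reference$concentrations)
      ds$reference$rates <- jit(ds$reference$rates)
      ds$perturbations <- lapply(ds$perturbations, function(s) {
        s$concentrations <- jit(s$concentrations); s$rates <- jit(s$rates); s
      })
      E <- tryCatch(
        suppressWarnings(assemble_elasticity_matrix(km$model, th, ds)),
        error = function(e) NULL)
      if (is.null(E)) return(NA_real_)
      truth <- km$eps_true[ll, colnames(E$E)]
      nz <- truth != 0
      stats::median(abs((E$E[ll, ][nz] - truth[nz]) / truth[nz]))
    }), na.rm = TRUE)
  }
  set.seed(99)
  errs <- vapply(c(1e-4, 1e-3, 1e-2), err_at, numeric(1))
  expect_lt(errs[1], 0.03)    # ~0.4% at CV 0.01%
  expect_lt(errs[2], 0.15)    # ~4% at CV 0.1%
  expect_true(all(diff(errs) > 0))
})
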