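# Shared fixtures, built lazily and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

default_km <- function() memo("km", function() make_default_kinetic_model(seed = 1))

# noise-free 13-state dataset from the default kinetic model
clean_dataset <- function() memo("ds0", function()
  generate_perturbation_dataset(default_km(), noise_cv = 0, seed = 1))

default_thermo <- function() memo("thermo", function() {
  km <- default_km()
  thermo_annotation(km$model, km$dG0, clean_dataset()$reference$concentrations)
})

default_elasticities <- function() memo("E", function()
  assemble_elasticity_matrix(default_km()$model, default_thermo(),
                             clean_dataset()))

default_mca <- function() memo("mca", function() {
  km <- default_km()
  internal <- metabolite_ids(km$model, internal_only = TRUE)
  N <- stoichiometric_matrix(km$model, internal_only = TRUE)
  ds <- clean_dataset()
  control_coefficients(N, default_elasticities(), ds$reference$rates,
                       ds$reference$concentrations[internal])
})

oracle_cc <- function() memo("oracle", function()
  true_control_coefficients(default_km(), relative_step = 1e-3))

clean_fedbatch <- function() memo("fb", function() generate_fedbatch_series())

# linear uptake -> conversion -> export chain for LP tests
toy_chain <- function(cap_up = 10, cap_conv = 1000) {
  mets <- rbind(metabolite_spec("a_e", "A ext", FALSE, 1),
                metabolite_spec("a", "A", TRUE, 1),
                metabolite_spec("b", "B", TRUE, 1),
                metabolite_spec("b_e", "B ext", FALSE, 1))
  metabolic_model(mets, list(
    reaction_spec("UP", c(a_e = -1, a = 1), ub = cap_up),
    reaction_spec("CONV", c(a = -1, b = 1), ub = cap_conv),
    reaction_spec("EX", c(b = -1, b_e = 1))), id = "chain")
}

# chain plus an internal 2-cycle that a loopless analysis must suppress
toy_cycle <- function() {
  mets <- rbind(metabolite_spec("a_e", "A ext", FALSE, 1),
                metabolite_spec("a", "A", TRUE, 1),
                metabolite_spec("b", "B", TRUE, 1),
                metabolite_spec("x_e", "X ext", FALSE, 1))
  metabolic_model(mets, list(
    reaction_spec("UP", c(a_e = -1, a = 1), ub = 5),
    reaction_spec("EX", c(a = -1, x_e = 1)),
    reaction_spec("C1", c(a = -1, b = 1), ub = 100),
    reaction_spec("C2", c(b = -1, a = 1), ub = 100)), id = "cycle")
}

# two-step linear pathway with elasticities -1 (supply) and +1 (demand):
# closed form gives all flux control coefficients 0.5
two_step_km <- function() {
  mets <- rbind(metabolite_spec("s_e", "S ext", FALSE, 1),
                metabolite_spec("s", "S", TRUE, 1),
                metabolite_spec("p_e", "P ext", FALSE, 1))
  mdl <- metabolic_model(mets, list(
    reaction_spec("SUPPLY", c(s_e = -1, s = 1)),
    reaction_spec("DEMAND", c(s = -1, p_e = 1))), id = "two_step")
  eps <- matrix(0, 2, 3, dimnames = list(c("SUPPLY", "DEMAND"),
                                         c("s_e", "s", "p_e")))
  eps["SUPPLY", "s"] <- -1
  eps["DEMAND", "s"] <- 1
  kinetic_model(mdl,
                J_ref = c(SUPPLY = 1, DEMAND = 1),
                c_ref = c(s_e = 10, s = 1, p_e = 1),
                law = c(SUPPLY = "linlog", DEMAND = "linlog"),
                eps_true = eps)
}

# brute-force LP maximization by vertex enumeration (small problems only):
# fixes (n - rank) variables at bound combinations and solves the rest
brute_force_lp_max <- function(N, obj, lb, ub) {
  n <- ncol(N)
  r <- qr(N)$rank
  free <- n - r
  best <- -Inf
  combos <- utils::combn(n, free)
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    grid <- as.matrix(expand.grid(rep(list(c(1, 2)), free)))
    for (g in seq_len(nrow(grid))) {
      fixed <- ifelse(grid[g, ] == 1, lb[idx], ub[idx])
      rest <- setdiff(seq_len(n), idx)
      A <- N[, rest, drop = FALSE]
      b <- -N[, idx, drop = FALSE] %*% fixed
      sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(n); v[idx] <- fixed; v[rest] <- sol
      if (all(v >= lb - 1e-8) && all(v <= ub + 1e-8) &&
          max(abs(N %*% v)) < 1e-8)
        best <- max(best, sum(obj * v))
    }
  }
  best
}
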