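## Constraint-based flux estimation: FBA, (loopless) FVA, thermodynamics-
## based flux analysis (TFA) and near/far-from-equilibrium classification.

#' Gas constant, kJ mol-1 K-1
#' @export
R_GAS <- 8.314e-3

## bounds per reaction, with optional per-reaction overrides
.reaction_bounds <- function(model, rate_constraints = NULL) {
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  if (!is.null(rate_constraints)) {
    for (id in names(rate_constraints)) {
      if (!id %in% names(lb))
        stop("rate constraint for unknown reaction: ", id)
      rc <- rate_constraints[[id]]
      if (length(rc) == 1L) rc <- c(rc, rc)
      lb[id] <- rc[1]; ub[id] <- rc[2]
    }
  }
  list(lb = lb, ub = ub)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through an objective reaction subject to
#' internal steady state `N v = 0` and flux bounds, optionally tightened by
#' measured extracellular rates.
#'
#' @param model A `metabolic_model`.
#' @param objective_reaction Reaction id of the objective.
#' @param rate_constraints Named list: reaction id -> single value (equality)
#'   or `c(lo, hi)` band, mmol/g/h.
#' @param maximize Logical, default `TRUE`.
#' @param state_label Label carried into the result.
#' @return Object of class `flux_distribution` with elements `flux` (named
#'   vector), `objective_value`, `objective_reaction`, `state_label`,
#'   and `ranges` (`NULL` until [fva()] fills it).
#' @export
fba <- function(model, objective_reaction, rate_constraints = NULL,
                maximize = TRUE, state_label = "state") {
  rxns <- reaction_ids(model)
  if (!objective_reaction %in% rxns)
    stop("objective reaction not in model: ", objective_reaction)
  N <- stoichiometric_matrix(model, internal_only = TRUE)
  bd <- .reaction_bounds(model, rate_constraints)
  obj <- as.numeric(rxns == objective_reaction)
  sol <- solve_lp(obj, Aeq = N, beq = rep(0, nrow(N)),
                  lb = bd$lb, ub = bd$ub, maximize = maximize)
  if (sol$status == "unbounded")
    stop("FBA problem is unbounded for objective ", objective_reaction)
  if (sol$status != "optimal") {
    ## try to name a conflicting constraint subset: drop one measured rate
    ## at a time and see whether feasibility is restored
    culprits <- character(0)
    if (!is.null(rate_constraints) && length(rate_constraints) > 1L) {
      for (id in names(rate_constraints)) {
        bd1 <- .reaction_bounds(model, rate_constraints[setdiff(names(rate_constraints), id)])
        s1 <- solve_lp(obj, Aeq = N, beq = rep(0, nrow(N)),
                       lb = bd1$lb, ub = bd1$ub, maximize = maximize)
        if (s1$status == "optimal") culprits <- c(culprits, id)
      }
    }
    stop("FBA infeasible",
         if (length(culprits)) paste0("; relaxing any one of {",
                                      paste(culprits, collapse = ", "),
                                      "} restores feasibility") else "")
  }
  structure(list(state_label = state_label,
                 flux = stats::setNames(sol$x, rxns),
                 objective_value = sol$objective,
                 objective_reaction = objective_reaction,
                 maximize = maximize,
                 rate_constraints = rate_constraints,
                 ranges = NULL),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> ", x$state_label, ": objective ",
      x$objective_reaction, " = ", signif(x$objective_value, 6),
      " (", length(x$flux), " reactions)\n", sep = "")
  invisible(x)
}

## reactions crossing the system boundary: touch an extracellular species
## (id ending in "_e"); used to hold exchanges fixed during cycle removal
.exchange_reactions <- function(model) {
  ids <- reaction_ids(model)
  touches <- vapply(model$reactions, function(r)
    any(grepl("_e$", names(r$stoichiometry))), logical(1))
  ids[touches]
}

## CycleFreeFlux post-processing: given a flux vector v, find the flux w with
## identical exchange fluxes, sign-compatible with v and |w| <= |v| on
## interior reactions, minimizing total |w|; internal cycles carry no flux in w
.remove_cycles <- function(model, v, N = NULL) {
  if (is.null(N)) N <- stoichiometric_matrix(model, internal_only = TRUE)
  rxns <- reaction_ids(model)
  exch <- rxns %in% .exchange_reactions(model)
  lo <- pmin(v, 0); hi <- pmax(v, 0)
  lo[exch] <- v[exch]; hi[exch] <- v[exch]
  obj <- sign(v)                      # minimizes sum |w| under sign boxes
  sol <- solve_lp(obj, Aeq = N, beq = rep(0, nrow(N)), lb = lo, ub = hi,
                  maximize = FALSE)
  if (sol$status != "optimal") return(v)   # conservative fallback
  stats::setNames(sol$x, rxns)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective retaining
#' at least `fraction` of the FBA optimum. With `loopless = TRUE`, each
#' extreme flux distribution is post-processed by cycle removal (minimum
#' total flux with exchange fluxes held fixed), so that thermodynamically
#' infeasible internal cycles do not inflate the ranges.
#'
#' @inheritParams fba
#' @param fraction Fraction of the FBA optimum to retain (default 0.999).
#' @param loopless Remove internal-cycle contributions from the ranges.
#' @param reactions Subset of reaction ids to scan (all by default).
#' @return `flux_distribution` whose `ranges` element is a matrix with
#'   columns `min`, `max` (rows = reactions).
#' @export
fva <- function(model, objective_reaction, fraction = 0.999,
                rate_constraints = NULL, loopless = FALSE,
                maximize = TRUE, reactions = NULL, state_label = "state") {
  fd <- fba(model, objective_reaction, rate_constraints, maximize, state_label)
  rxns <- reaction_ids(model)
  if (is.null(reactions)) reactions <- rxns
  N <- stoichiometric_matrix(model, internal_only = TRUE)
  bd <- .reaction_bounds(model, rate_constraints)
  ## objective >= fraction * optimum, as a tightened bound on the objective
  ## reaction (single-flux objective makes the cut a box constraint)
  cut <- fraction * fd$objective_value
  iobj <- match(objective_reaction, rxns)
  if (maximize) bd$lb[iobj] <- max(bd$lb[iobj], cut)
  else bd$ub[iobj] <- min(bd$ub[iobj], cut)
  ranges <- matrix(NA_real_, length(reactions), 2,
                   dimnames = list(reactions, c("min", "max")))
  for (id in reactions) {
    obj <- as.numeric(rxns == id)
    for (dir in c("min", "max")) {
      sol <- solve_lp(obj, Aeq = N, beq = rep(0, nrow(N)),
                      lb = bd$lb, ub = bd$ub,
                      maximize = (dir == "max"))
      if (sol$status != "optimal")
        stop("FVA ", dir, " failed for reaction ", id, " (", sol$status, ")")
      val <- sol$objective
      if (loopless) {
        w <- .remove_cycles(model, stats::setNames(sol$x, rxns), N)
        val <- w[id]
      }
      ranges[id, dir] <- val
    }
  }
  ## numerical guard: ensure min <= max after cycle removal
  sw <- ranges[, "min"] > ranges[, "max"]
  if (any(sw)) ranges[sw, ] <- ranges[sw, c(2, 1)]
  fd$ranges <- ranges
  fd$fraction <- fraction
  fd$loopless <- loopless
  fd
}

#' Reconcile measured rates with the steady-state constraint
#'
#' Orthogonal least-squares projection of a measured flux vector onto the
#' null space of the internal stoichiometric matrix: the closest flux
#' vector satisfying `N v = 0`. Standard data reconciliation before any
#' control analysis; a no-op for already-balanced fluxes.
#'
#' @param model A `metabolic_model`.
#' @param rates Named flux vector over all reactions, mmol/g/h.
#' @return Named balanced flux vector.
#' @export
reconcile_fluxes <- function(model, rates) {
  N <- stoichiometric_matrix(model, internal_only = TRUE)
  rxns <- reaction_ids(model)
  v <- rates[rxns]
  qt <- qr(t(N))
  r <- qt$rank
  Z <- qr.Q(qt, complete = TRUE)[, -seq_len(r), drop = FALSE]
  stats::setNames(as.numeric(Z %*% crossprod(Z, v)), rxns)
}

#' Gibbs energy of reaction at given concentrations
#'
#' Evaluates `dG_r = dG0 + R T sum_j s_j ln c_j` with concentrations in
#' mol/L. Water is excluded from the sum (activity one).
#'
#' @param dG0 Standard transformed Gibbs reaction energy, kJ/mol.
#' @param stoichiometry Named signed coefficient vector.
#' @param ln_concentrations Named vector of log concentrations (ln of mol/L)
#'   for every participating species except water.
#' @param temperature Temperature in K (default 305.15, i.e. 32 degC).
#' @return dG_r in kJ/mol.
#' @export
delta_g_reaction <- function(dG0, stoichiometry, ln_concentrations,
                             temperature = 305.15) {
  s <- stoichiometry[names(stoichiometry) != "h2o"]
  missing <- setdiff(names(s), names(ln_concentrations))
  if (length(missing))
    stop("missing concentrations for: ", paste(missing, collapse = ", "))
  as.numeric(dG0 + R_GAS * temperature *
               sum(s * ln_concentrations[names(s)]))
}

#' Classify reactions by distance from thermodynamic equilibrium
#'
#' Reactions with representative Gibbs reaction energy in `[-10, 0]` kJ/mol
#' are near equilibrium; below -10 kJ/mol they are far from equilibrium.
#' The -10 boundary is assigned to "near" (inclusive convention). `NA` or
#' positive values yield "unclassified".
#'
#' @param dGr Numeric vector of representative dG_r values, kJ/mol.
#' @param threshold Equilibrium threshold, kJ/mol (default -10).
#' @return Character vector: "near", "far" or "unclassified".
#' @export
classify_equilibrium <- function(dGr, threshold = -10) {
  out <- rep("unclassified", length(dGr))
  out[!is.na(dGr) & dGr >= threshold & dGr <= 0] <- "near"
  out[!is.na(dGr) & dGr < threshold] <- "far"
  stats::setNames(out, names(dGr))
}

#' Default metabolite concentration bounds for TFA
#'
#' @param model A `metabolic_model`.
#' @param cmin_mM,cmax_mM Default bounds in mM (1e-2 to 50 mM, the
#'   conventional physiological window).
#' @param measured Optional named vector of measured concentrations (mM);
#'   measured species get bounds value * (1 -/+ `rel_sd`).
#' @param rel_sd Relative half-width applied around measured values.
#' @return data.frame with columns `met`, `cmin_mM`, `cmax_mM`.
#' @export
concentration_bounds <- function(model, cmin_mM = 1e-2, cmax_mM = 50,
                                 measured = NULL, rel_sd = 0.2) {
  mets <- metabolite_ids(model)
  mets <- setdiff(mets, "h2o")
  b <- data.frame(met = mets, cmin_mM = cmin_mM, cmax_mM = cmax_mM,
                  stringsAsFactors = FALSE)
  if (!is.null(measured)) {
    for (id in intersect(names(measured), mets)) {
      b$cmin_mM[b$met == id] <- measured[[id]] * (1 - rel_sd)
      b$cmax_mM[b$met == id] <- measured[[id]] * (1 + rel_sd)
    }
  }
  b
}

#' Thermodynamics-based flux analysis
#'
#' Mixed-integer extension of FVA in which, for every reaction with a known
#' standard Gibbs energy, flux direction is coupled to the sign of
#' `dG_r = dG0 + R T s' ln c`: positive flux requires `dG_r <= -eps`,
#' negative flux `dG_r >= eps`. Returns admissible ranges for fluxes, Gibbs
#' reaction energies and log-concentrations.
#'
#' @inheritParams fba
#' @param bounds Concentration bounds as returned by
#'   [concentration_bounds()] (mM).
#' @param dG0 Named vector of standard Gibbs reaction energies, kJ/mol;
#'   reactions absent from it are flux-constrained only.
#' @param temperature Kelvin.
#' @param eps Strictness margin on dG_r, kJ/mol.
#' @param big_M Big-M constant for the direction coupling, kJ/mol.
#' @param variables Which ranges to compute.
#' @param reactions Subset of reaction ids for the flux ranges (all by
#'   default).
#' @return List with `flux_ranges`, `thermo` (data.frame: reaction, dG0,
#'   dGr_min, dGr_max, eq_class) and `lnc_ranges` (ln mol/L).
#' @export
tfa <- function(model, bounds, dG0, rate_constraints = NULL,
                temperature = 305.15, eps = 1e-3, big_M = 1000,
                variables = c("flux", "dGr", "lnc"), reactions = NULL) {
  rxns <- reaction_ids(model)
  nr <- length(rxns)
  thermo_rxns <- intersect(rxns, names(dG0))
  mets_x <- unique(unlist(lapply(model$reactions[thermo_rxns], function(r)
    setdiff(names(r$stoichiometry), "h2o"))))
  missing_b <- setdiff(mets_x, bounds$met)
  if (length(missing_b))
    stop("concentration bounds missing for: ", paste(missing_b, collapse = ", "))
  nx <- length(mets_x)
  nb <- length(thermo_rxns)
  RT <- R_GAS * temperature

  bd <- .reaction_bounds(model, rate_constraints)
  bidx <- match(mets_x, bounds$met)
  xlb <- log(bounds$cmin_mM[bidx] / 1000)
  xub <- log(bounds$cmax_mM[bidx] / 1000)

  srow <- function(r) {       # RT-weighted stoichiometric row over x
    out <- numeric(nx)
    s <- r$stoichiometry[names(r$stoichiometry) != "h2o"]
    out[match(names(s), mets_x)] <- RT * s
    out
  }

  ## presolve: fix direction binaries whose dG_r sign is already decided by
  ## the concentration bounds alone; fixed binaries are substituted out
  zfix <- stats::setNames(rep(NA_integer_, nb), thermo_rxns)
  for (id in thermo_rxns) {
    sx <- srow(model$reactions[[id]])
    dg_min <- dG0[[id]] + sum(pmin(sx * xlb, sx * xub))
    dg_max <- dG0[[id]] + sum(pmax(sx * xlb, sx * xub))
    if (dg_min > -eps) zfix[id] <- 0L     # can never run forward
    if (dg_max < eps)  zfix[id] <- 1L     # can never run backward
  }
  free_rxns <- thermo_rxns[is.na(zfix)]
  nf <- length(free_rxns)

  ## variable layout: [v (nr) | x = ln c (nx) | z_free (nf)]
  ntot <- nr + nx + nf
  lb <- c(bd$lb, xlb, rep(0, nf))
  ub <- c(bd$ub, xub, rep(1, nf))
  forced_flags <- character(0)
  for (id in thermo_rxns[!is.na(zfix)]) {
    i <- match(id, rxns)
    if (zfix[[id]] == 1L) {               # forward only
      lb[i] <- max(lb[i], 0)
    } else {                              # backward only
      ub[i] <- min(ub[i], 0)
      if (lb[i] > 0) forced_flags <- c(forced_flags, id)
    }
    if (lb[i] > ub[i])
      stop("TFA infeasible: reaction ", id,
           " requires positive flux but dG_r > 0 under the bounds")
  }

  N <- stoichiometric_matrix(model, internal_only = TRUE)
  Aeq <- cbind(N, matrix(0, nrow(N), nx + nf))
  beq <- rep(0, nrow(N))

  rows <- list(); rhs <- numeric(0)
  add_row <- function(row, b) {
    rows[[length(rows) + 1L]] <<- row
    rhs <<- c(rhs, b)
  }
  for (id in thermo_rxns) {
    r <- model$reactions[[id]]
    i <- match(id, rxns)
    sx <- srow(r)
    if (is.na(zfix[[id]])) {
      k <- match(id, free_rxns)
      zrow <- numeric(nf); zrow[k] <- 1
      ## z=1 -> dG <= -eps :  RT s x + (M+eps) z <= M - dG0
      add_row(c(numeric(nr), sx, (big_M + eps) * zrow), big_M - dG0[[id]])
      ## z=0 -> dG >= eps  : -RT s x - (M+eps) z <= dG0 - eps
      add_row(c(numeric(nr), -sx, -(big_M + eps) * zrow), dG0[[id]] - eps)
      ## v <= ub z ; v >= lb (1 - z)
      vrow <- numeric(nr); vrow[i] <- 1
      add_row(c(vrow, numeric(nx), -bd$ub[i] * zrow), 0)
      add_row(c(-vrow, numeric(nx), -bd$lb[i] * zrow), -bd$lb[i])
    } else if (zfix[[id]] == 1L) {
      add_row(c(numeric(nr), sx, numeric(nf)), -eps - dG0[[id]])
    } else {
      add_row(c(numeric(nr), -sx, numeric(nf)), dG0[[id]] - eps)
    }
  }
  Ain <- do.call(rbind, rows); bin <- rhs
  free_int <- nr + nx + seq_len(nf)

  opt_range <- function(obj) {
    lo <- solve_milp(obj, Aeq, beq, Ain, bin, lb, ub, free_int, maximize = FALSE)
    hi <- solve_milp(obj, Aeq, beq, Ain, bin, lb, ub, free_int, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") return(NULL)
    c(lo$objective, hi$objective)
  }

  ## feasibility check up front, to name the offending reactions if possible
  feas <- solve_milp(numeric(ntot), Aeq, beq, Ain, bin, lb, ub, free_int)
  if (feas$status != "optimal") {
    stop("TFA infeasible",
         if (length(forced_flags)) paste0(": reaction(s) ",
                                          paste(forced_flags, collapse = ", "),
                                          " are thermodynamically blocked") else "")
  }

  flux_ranges <- NULL
  if ("flux" %in% variables) {
    scan <- if (is.null(reactions)) rxns else intersect(rxns, reactions)
    flux_ranges <- matrix(NA_real_, length(scan), 2,
                          dimnames = list(scan, c("min", "max")))
    for (id in scan) {
      obj <- numeric(ntot); obj[match(id, rxns)] <- 1
      rg <- opt_range(obj)
      if (!is.null(rg)) flux_ranges[id, ] <- rg
    }
  }
  thermo <- NULL
  if ("dGr" %in% variables) {
    thermo <- data.frame(reaction = thermo_rxns,
                         dG0 = as.numeric(dG0[thermo_rxns]),
                         dGr_min = NA_real_, dGr_max = NA_real_,
                         eq_class = NA_character_, stringsAsFactors = FALSE)
    for (k in seq_along(thermo_rxns)) {
      r <- model$reactions[[thermo_rxns[k]]]
      obj <- c(numeric(nr), srow(r), numeric(nf))
      rg <- opt_range(obj)
      if (!is.null(rg)) {
        thermo$dGr_min[k] <- dG0[[thermo_rxns[k]]] + rg[1]
        thermo$dGr_max[k] <- dG0[[thermo_rxns[k]]] + rg[2]
      }
    }
    thermo$eq_class <- ifelse(
      is.na(thermo$dGr_max), "unclassified",
      ifelse(thermo$dGr_min >= -10 & thermo$dGr_max <= 0, "near",
             ifelse(thermo$dGr_max < -10, "far", "unclassified")))
  }
  lnc_ranges <- NULL
  if ("lnc" %in% variables) {
    lnc_ranges <- matrix(NA_real_, nx, 2, dimnames = list(mets_x, c("min", "max")))
    for (k in seq_len(nx)) {
      obj <- numeric(ntot); obj[nr + k] <- 1
      rg <- opt_range(obj)
      if (!is.null(rg)) lnc_ranges[k, ] <- rg
    }
  }
  list(flux_ranges = flux_ranges, thermo = thermo, lnc_ranges = lnc_ranges)
}
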