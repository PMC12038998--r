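## Synthetic perturbation-experiment generator: a kinetic parameterization of
## the reduced network (thermokinetic rate laws near equilibrium, lin-log
## laws far from equilibrium, fixed boundary fluxes), a Newton steady-state
## solver, the 4-regime x 3-level short-term perturbation design, and a
## finite-difference control-coefficient oracle.

#' Enzymes near thermodynamic equilibrium in the reduced model
#' @return Character vector of 17 reaction ids.
#' @export
near_equilibrium_enzymes <- function() {
  c("PGI", "FBA", "TPI", "GAPD", "PGK", "PGM", "ENO", "ACONT", "SUCOAS",
    "FUM", "MDH", "RPE", "RPI", "TKT1", "TALA", "PGCD", "PSERT")
}

#' Enzymes far from thermodynamic equilibrium in the reduced model
#' @return Character vector of 20 reaction ids.
#' @export
far_from_equilibrium_enzymes <- function() {
  c("PTS", "PFK", "PDH", "PPC", "ACS", "CS", "ICDH", "AKGDH", "SUCDH",
    "G6PDH", "GND", "TKT2", "PSPL", "SERAT", "CYSS", "SLCYSS", "SCYSSL",
    "YdeD", "NADH5", "ATPS")
}

#' Biomass precursor drain stoichiometry
#'
#' Standard E. coli precursor demands (mmol per g cell dry weight) over the
#' species of the reduced model; acetyl-CoA consumption returns free CoA so
#' the CoA moiety stays balanced.
#' @return Named numeric vector (signed coefficients).
#' @export
biomass_drain_stoichiometry <- function() {
  c(g6p = -0.205, f6p = -0.071, r5p = -0.898, e4p = -0.361, gap = -0.129,
    `3pg` = -1.496, pep = -0.519, pyr = -2.833, accoa = -3.748, coa = 3.748,
    oaa = -1.787, akg = -1.079)
}

#' Augment the reduced model with boundary reactions for perturbation
#' experiments
#'
#' Adds pyruvate and succinate uptake (the perturbation carbon sources enter
#' here) and a lumped biomass-precursor drain.
#'
#' @param model A `metabolic_model` (default the reduced model).
#' @return Augmented `metabolic_model` (40 reactions).
#' @export
build_kinetic_network <- function(model = build_reduced_model()) {
  mets <- rbind(
    metabolite_spec("pyr_e", "pyruvate (ext)", FALSE, 3),
    metabolite_spec("succ_e", "succinate (ext)", FALSE, 4))
  augment_model(model, list(
    reaction_spec("PYRt", c(pyr_e = -1, pyr = 1), "pyruvate uptake",
                  pseudo = TRUE),
    reaction_spec("SUCCt", c(succ_e = -1, succ = 1), "succinate uptake",
                  pseudo = TRUE),
    reaction_spec("BIOMASS", biomass_drain_stoichiometry(),
                  "biomass precursor drain", pseudo = TRUE)),
    metabolites = mets)
}

#' Reference steady-state fluxes of the synthetic kinetic model
#'
#' A strictly positive flux distribution on the augmented network (mmol/g/h)
#' satisfying all internal mass balances to machine precision. The flux
#' space of the augmented network has eight degrees of freedom; they are
#' pinned at a glucose uptake of 4.5 mmol/g/h, small pyruvate/succinate
#' co-uptake, an oxidative pentose-phosphate flux of 1.17 mmol/g/h, the
#' L-cysteine synthase / S-sulfo-L-cysteine synthase split 0.35/0.25, and
#' lumped respiration fluxes; every remaining flux follows from the mass
#' balances.
#'
#' @param net The augmented network (default [build_kinetic_network()]).
#' @return Named numeric vector over the 40 reactions.
#' @export
reference_fluxes <- function(net = build_kinetic_network()) {
  if (missing(net)) {
    ## memoize the default: avoids repeated solves and keeps one bitwise
    ## value per session (threaded BLAS is not ULP-reproducible)
    cached <- get0("J_ref_default", envir = .ivm_cache)
    if (!is.null(cached)) return(cached)
  }
  N <- stoichiometric_matrix(net, internal_only = TRUE)
  rxns <- reaction_ids(net)
  qt <- qr(t(N))
  r <- qt$rank
  Z <- qr.Q(qt, complete = TRUE)[, (r + 1):length(rxns), drop = FALSE]
  pins <- c(PTS = 4.5, PYRt = 0.3, SUCCt = 0.2, G6PDH = 1.17,
            CYSS = 0.35, SLCYSS = 0.25, NADH5 = 10, ATPS = 12)
  P <- Z[match(names(pins), rxns), , drop = FALSE]
  v <- as.numeric(Z %*% solve(P, pins))
  v <- stats::setNames(v, rxns)
  if (missing(net)) assign("J_ref_default", v, envir = .ivm_cache)
  v
}

.ivm_cache <- new.env(parent = emptyenv())

#' Reference metabolite concentrations of the synthetic kinetic model
#'
#' Physiologically plausible E. coli concentrations in mM for every species
#' of the augmented network (clamped currency metabolites included; they are
#' held constant across states).
#' @return Named numeric vector, mM.
#' @export
reference_concentrations <- function() {
  c(g6p = 2.0, f6p = 0.6, fdp = 2.5, dhap = 0.4, gap = 0.1, `13dpg` = 0.05,
    `3pg` = 1.5, `2pg` = 0.4, pep = 0.3, pyr = 1.0, accoa = 0.3, oaa = 0.05,
    cit = 1.5, icit = 0.1, akg = 0.5, succoa = 0.15, succ = 0.8, fum = 0.3,
    mal = 2.0, `6pgc` = 0.5, ru5p = 0.3, xu5p = 0.2, r5p = 0.4, s7p = 0.3,
    e4p = 0.1, `3php` = 0.05, pser = 0.1, ser = 1.0, oas = 0.5, cys = 0.2,
    slcys = 0.1, ac = 2.0, coa = 0.5,
    atp = 3.0, adp = 0.8, amp = 0.3, nad = 2.0, nadh = 0.1, nadp = 0.02,
    nadph = 0.15, q8 = 0.5, q8h2 = 0.5, pi = 10, ppi = 0.5, co2 = 1.0,
    h2s = 0.05, so3 = 0.1, tsul = 2.0, glu = 100,
    glc_e = 12, oas_e = 10, cys_e = 50, pyr_e = 0.5, succ_e = 0.5)
}

#' Construct a kinetic model
#'
#' @param model A `metabolic_model`.
#' @param J_ref Named reference fluxes (every reaction).
#' @param c_ref Named reference concentrations in mM (every species except
#'   water).
#' @param law Named character: "linlog", "thermokinetic" or "fixed" per
#'   reaction.
#' @param eps_true Elasticity matrix (reactions x species) used by the
#'   lin-log laws; thermokinetic rows hold the reference-state elasticities
#'   implied by their Gibbs energies (ground truth only).
#' @param dG0 Named standard Gibbs reaction energies, kJ/mol (at least for
#'   thermokinetic reactions).
#' @param temperature Kelvin.
#' @return Object of class `kinetic_model`.
#' @export
kinetic_model <- function(model, J_ref, c_ref, law, eps_true, dG0 = NULL,
                          temperature = 305.15) {
  rxns <- reaction_ids(model)
  stopifnot(all(rxns %in% names(J_ref)), all(rxns %in% names(law)))
  needs_dG0 <- rxns[law[rxns] == "thermokinetic"]
  if (length(setdiff(needs_dG0, names(dG0))))
    stop("thermokinetic reactions need dG0: ",
         paste(setdiff(needs_dG0, names(dG0)), collapse = ", "))
  ## reference mass-action ratio Gamma per thermokinetic reaction
  RT <- R_GAS * temperature
  lnc_ref <- log(c_ref / 1000)                       # mM -> ln M
  gamma_ref <- stats::setNames(rep(NA_real_, length(rxns)), rxns)
  for (id in needs_dG0) {
    dgr <- delta_g_reaction(dG0[[id]], model$reactions[[id]]$stoichiometry,
                            lnc_ref, temperature)
    if (dgr >= 0)
      stop("thermokinetic reaction ", id, " has dG_r >= 0 at reference")
    gamma_ref[id] <- exp(dgr / RT)
  }
  structure(list(model = model, J_ref = J_ref[rxns], c_ref = c_ref,
                 law = law[rxns], eps_true = eps_true, dG0 = dG0,
                 gamma_ref = gamma_ref, temperature = temperature),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model> ", length(x$J_ref), " reactions (",
      sum(x$law == "thermokinetic"), " thermokinetic, ",
      sum(x$law == "linlog"), " lin-log, ",
      sum(x$law == "fixed"), " fixed boundary)\n", sep = "")
  invisible(x)
}

## evaluate all rate laws at log-concentrations lnc (ln M, all species),
## enzyme activity factors e_rel, and fixed boundary fluxes
.evaluate_rates <- function(km, lnc, e_rel = NULL, fixed = NULL) {
  rxns <- names(km$J_ref)
  if (is.null(e_rel)) e_rel <- stats::setNames(rep(1, length(rxns)), rxns)
  RT <- R_GAS * km$temperature
  lnc_ref <- log(km$c_ref / 1000)
  v <- km$J_ref * e_rel[rxns]
  dln <- lnc - lnc_ref[names(lnc)]
  for (id in rxns) {
    if (km$law[id] == "linlog") {
      eps <- km$eps_true[id, ]
      nz <- which(eps != 0)
      v[id] <- v[id] * (1 + sum(eps[nz] * dln[colnames(km$eps_true)[nz]]))
    } else if (km$law[id] == "thermokinetic") {
      dgr <- delta_g_reaction(km$dG0[[id]],
                              km$model$reactions[[id]]$stoichiometry,
                              lnc, km$temperature)
      gam <- exp(min(dgr / RT, 50))     # overflow guard for trial steps
      v[id] <- v[id] * (1 - gam) / (1 - km$gamma_ref[id])
    } else {                              # fixed boundary flux
      if (!is.null(fixed) && id %in% names(fixed))
        v[id] <- e_rel[id] * fixed[[id]]
    }
  }
  v
}

#' Default kinetic parameterization of the reduced network
#'
#' Seventeen near-equilibrium reactions get thermokinetic affinity rate
#' laws; the twenty far-from-equilibrium reactions get lin-log laws with
#' elasticities drawn from a uniform prior (magnitude 0.1-2, sign from
#' stoichiometry: positive for substrates, negative for products; the
#' extracellular glucose concentration is an additional effector of PTS).
#' Standard Gibbs energies are chosen so that the reference-state Gibbs
#' reaction energies fall in (-8, -1) kJ/mol for near-equilibrium and
#' (-35, -12) kJ/mol for far-from-equilibrium reactions. Parameter draws
#' failing the structural-stability check (well-conditioned steady-state
#' Jacobian) are rejected and redrawn deterministically.
#'
#' @param model The reduced `metabolic_model`.
#' @param seed Integer seed; same seed, same parameters.
#' @return A `kinetic_model` on the augmented 40-reaction network.
#' @export
make_default_kinetic_model <- function(model = build_reduced_model(),
                                       seed = 1) {
  net <- build_kinetic_network(model)
  rxns <- reaction_ids(net)
  species <- setdiff(metabolite_ids(net), "h2o")
  J_ref <- reference_fluxes(net)[rxns]
  c_ref <- reference_concentrations()[species]
  near <- near_equilibrium_enzymes()
  far <- far_from_equilibrium_enzymes()
  law <- stats::setNames(rep("fixed", length(rxns)), rxns)
  law[near] <- "thermokinetic"
  law[far] <- "linlog"
  temperature <- 305.15
  RT <- R_GAS * temperature
  lnc_ref <- log(c_ref / 1000)
  internal <- metabolite_ids(net, internal_only = TRUE)
  N <- stoichiometric_matrix(net, internal_only = TRUE)

  for (attempt in 0:49) {
    set.seed(seed + 1000L * attempt)
    dgr_target <- c(stats::setNames(stats::runif(length(near), -6, -1.5), near),
                    stats::setNames(stats::runif(length(far), -35, -12), far))
    dG0 <- vapply(c(near, far), function(id) {
      s <- net$reactions[[id]]$stoichiometry
      s <- s[names(s) != "h2o"]
      dgr_target[[id]] - RT * sum(s * lnc_ref[names(s)])
    }, numeric(1))
    eps <- matrix(0, length(rxns), length(species),
                  dimnames = list(rxns, species))
    ## boundary substrates with appreciable elasticity: extracellular
    ## glucose drives PTS, the clamped sulphur donors drive the two
    ## cysteine-forming reactions
    boundary_eff <- list(PTS = "glc_e", CYSS = "h2s", SLCYSS = "tsul")
    for (id in far) {
      s <- net$reactions[[id]]$stoichiometry
      eff <- c(intersect(names(s), internal), boundary_eff[[id]])
      for (j in eff)
        eps[id, j] <- -sign(s[[j]]) * stats::runif(1, 0.1, 2)
    }
    for (id in near) {   # ground-truth reference elasticities, closed form
      s <- net$reactions[[id]]$stoichiometry
      s <- s[names(s) != "h2o"]
      gam <- exp(dgr_target[[id]] / RT)
      eps[id, names(s)] <- -s * gam / (1 - gam)
    }
    ## structural stability at reference: Jacobian of the MCA system
    Ei <- eps[, internal, drop = FALSE]
    ld <- link_decomposition(N)
    Ev <- diag(J_ref) %*% Ei %*% diag(1 / c_ref[internal])
    M <- ld$N_R %*% Ev %*% ld$L
    if (!is.finite(rcond(M)) || rcond(M) <= 1e-8 ||
        any(Re(eigen(M, only.values = TRUE)$values) >= 0)) next
    km <- kinetic_model(net, J_ref, c_ref, law, eps, dG0, temperature)
    ## the draw must also support every state of the default perturbation
    ## design (thermokinetic saturation can make aggressive boundaries
    ## unreachable for unlucky draws)
    des <- perturbation_design()
    solvable <- TRUE
    for (i in seq_len(nrow(des$scales))) {
      b <- des$boundary(des$scales$regime[i], des$scales$level[i], km)
      st <- tryCatch(solve_steady_state(km, boundary = b, label = "probe"),
                     error = function(e) NULL)
      if (is.null(st) || st$rates[["YdeD"]] <= 0) { solvable <- FALSE; break }
    }
    if (solvable) return(km)
  }
  stop("no stable kinetic parameterization found after 50 attempts")
}

#' Solve for a metabolic steady state of a kinetic model
#'
#' Damped Newton iteration on the log-concentrations of the internal
#' metabolites, holding clamped/external species at their (possibly
#' overridden) values, until all independent internal mass balances vanish.
#' Conserved-moiety totals are held at their reference values.
#'
#' @param km A `kinetic_model`.
#' @param boundary List with optional elements `fluxes` (named fixed
#'   boundary fluxes, mmol/g/h, for "fixed"-law reactions) and `externals`
#'   (named clamped/external concentrations in mM overriding the reference).
#' @param e_rel Named enzyme activity factors (default all 1).
#' @param label State label.
#' @param tol Relative tolerance on the internal mass-balance residual.
#' @param max_iter Newton iteration limit.
#' @return Object of class `steady_state`: list with `label`,
#'   `concentrations` (mM, all species), `rates` (all reactions),
#'   `is_reference`, `residual`.
#' @export
solve_steady_state <- function(km, boundary = list(), e_rel = NULL,
                               label = "state", tol = 1e-10,
                               max_iter = 100) {
  net <- km$model
  internal <- metabolite_ids(net, internal_only = TRUE)
  N <- stoichiometric_matrix(net, internal_only = TRUE)
  ld <- link_decomposition(N)
  ## moiety basis: orthonormal complement of the column space of N
  qN <- qr(N)
  m <- nrow(N); r <- qN$rank
  Y <- if (r < m) qr.Q(qN, complete = TRUE)[, (r + 1):m, drop = FALSE]
       else matrix(0, m, 0)

  bad <- intersect(names(boundary$externals), internal)
  if (length(bad))
    stop("boundary externals must be clamped/external species, not: ",
         paste(bad, collapse = ", "))
  c_ref_int <- km$c_ref[internal]

  ## Newton iteration at boundary interpolation t in [0, 1] (t = 1 is the
  ## requested boundary; smaller t blends towards the reference boundary)
  newton <- function(u0, t) {
    c_all <- km$c_ref
    ext <- boundary$externals
    if (!is.null(ext))
      c_all[names(ext)] <- (1 - t) * c_all[names(ext)] + t * ext
    fixed <- boundary$fluxes
    if (!is.null(fixed))
      fixed <- (1 - t) * km$J_ref[names(fixed)] + t * fixed
    lnc_all <- log(c_all / 1000)
    gfun <- function(u) {
      lnc <- lnc_all
      lnc[internal] <- log(c_ref_int / 1000) + u
      v <- .evaluate_rates(km, lnc, e_rel, fixed)
      cint <- c_ref_int * exp(u)
      list(res = c(as.numeric(ld$N_R %*% v),
                   if (ncol(Y)) as.numeric(t(Y) %*% (cint - c_ref_int))),
           v = v, cint = cint)
    }
    u <- u0
    g <- gfun(u)
    for (iter in seq_len(max_iter)) {
      vmax <- max(1, max(abs(g$v)))
      if (max(abs(g$res)) <= tol * vmax)
        return(list(u = u, g = g, c_all = c_all, converged = TRUE))
      h <- 1e-6                        # numerical Jacobian
      Jm <- matrix(0, length(g$res), length(u))
      for (j in seq_along(u)) {
        uj <- u; uj[j] <- uj[j] + h
        Jm[, j] <- (gfun(uj)$res - g$res) / h
      }
      step <- tryCatch(solve(Jm, -g$res), error = function(e) NULL)
      if (is.null(step))
        return(list(u = u, g = g, c_all = c_all, converged = FALSE,
                    why = "singular Jacobian"))
      lam <- 1
      repeat {
        g_new <- gfun(u + lam * step)
        ss <- sum(g_new$res^2)
        if ((is.finite(ss) && ss < sum(g$res^2)) || lam < 1e-8) break
        lam <- lam / 2
      }
      if (lam < 1e-8)
        return(list(u = u, g = g, c_all = c_all, converged = FALSE,
                    why = "stalled line search"))
      u <- u + lam * step
      g <- g_new
    }
    list(u = u, g = g, c_all = c_all, converged = FALSE,
         why = "iteration limit")
  }

  sol <- newton(rep(0, length(internal)), 1)
  if (!sol$converged) {
    ## continuation from the reference boundary in small steps
    u <- rep(0, length(internal))
    for (t in seq(0.1, 1, by = 0.1)) {
      sol <- newton(u, t)
      if (!sol$converged) break
      u <- sol$u
    }
  }
  if (!sol$converged)
    stop("no steady state found for boundary '", label, "' (",
         sol$why, "; residual ", format(max(abs(sol$g$res)), digits = 3),
         ")")
  conc <- sol$c_all
  conc[internal] <- sol$g$cint
  structure(list(label = label, concentrations = conc,
                 rates = sol$g$v, is_reference = FALSE,
                 residual = max(abs(sol$g$res))),
            class = "steady_state")
}

#' Default short-term perturbation design
#'
#' Four carbon-source regimes (glucose, pyruvate, glucose+pyruvate,
#' glucose+succinate) at three feed levels each, 7-minute stages. Feed
#' levels translate into boundary settings: extracellular glucose
#' concentration (driving PTS), pyruvate/succinate uptake fluxes, and a
#' mild short-term modulation of the biomass-precursor demand (growth
#' responds to carbon availability within a stage). The level mixes are
#' deliberately non-collinear across regimes so that the 12 states span
#' four independent boundary directions (identifiability of the lin-log
#' regressions).
#'
#' @param stage_minutes Stage duration (min), metadata only.
#' @return Object of class `perturbation_design` with a `scales` table
#'   (columns `regime`, `level`, `glc`, `pyr`, `succ`, `bio` -- multiplier
#'   per boundary knob) and `$boundary(regime, level, km)`.
#' @export
perturbation_design <- function(stage_minutes = 7) {
  scales <- data.frame(
    regime = rep(c("glucose", "pyruvate", "glucose_pyruvate",
                   "glucose_succinate"), each = 3),
    level = rep(1:3, 4),
    glc  = c(1.10, 1.20, 1.28,  1.00, 1.00, 1.00,
             1.10, 1.16, 1.06,  0.94, 1.12, 1.20),
    pyr  = c(1.00, 1.00, 1.00,  1.08, 1.16, 1.24,
             1.06, 1.03, 1.09,  1.00, 1.00, 1.00),
    succ = c(1.00, 1.00, 1.00,  1.00, 1.00, 1.00,
             1.00, 1.00, 1.00,  1.12, 1.20, 1.08),
    bio  = c(1.02, 0.96, 1.05,  0.98, 1.04, 0.96,
             1.03, 0.95, 1.01,  0.97, 1.04, 0.98),
    tsul = c(0.90, 1.12, 0.95,  1.15, 0.88, 1.06,
             0.93, 1.10, 1.18,  1.08, 0.90, 1.14),
    h2s  = c(1.12, 0.92, 1.08,  0.94, 1.10, 0.90,
             1.15, 0.88, 1.05,  0.92, 1.12, 0.96),
    stringsAsFactors = FALSE)
  boundary <- function(regime, level, km) {
    row <- scales[scales$regime == regime & scales$level == level, ]
    if (!nrow(row)) stop("unknown design point ", regime, "/", level)
    list(externals = c(glc_e = unname(km$c_ref["glc_e"]) * row$glc,
                       tsul = unname(km$c_ref["tsul"]) * row$tsul,
                       h2s = unname(km$c_ref["h2s"]) * row$h2s),
         fluxes = c(PYRt = unname(km$J_ref["PYRt"]) * row$pyr,
                    SUCCt = unname(km$J_ref["SUCCt"]) * row$succ,
                    BIOMASS = unname(km$J_ref["BIOMASS"]) * row$bio))
  }
  structure(list(scales = scales,
                 regimes = unique(scales$regime),
                 levels = 1:3, boundary = boundary,
                 feed_rates_mL_h = c(30, 60, 90),
                 stage_minutes = stage_minutes),
            class = "perturbation_design")
}

#' Generate a synthetic steady-state perturbation dataset
#'
#' Solves the kinetic model at the reference boundary and at the 12
#' perturbation boundaries (4 regimes x 3 levels), then applies
#' multiplicative log-normal measurement noise to every observed
#' concentration and rate. All states must retain strictly positive
#' L-cysteine export or generation fails.
#'
#' @param km A `kinetic_model`.
#' @param design A `perturbation_design`.
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   0 gives exact model outputs.
#' @param seed Integer seed.
#' @return Object of class `mca_dataset`: `reference`, `perturbations`
#'   (12 `steady_state`s), `noise_cv`, `seed`, `observable` (extracellular
#'   reaction ids), and `ground_truth` (true elasticities, laws, dG0,
#'   reference state).
#' @export
generate_perturbation_dataset <- function(km, design = perturbation_design(),
                                          noise_cv = 0.1, seed = 1) {
  states <- list()
  ref <- solve_steady_state(km, boundary = list(), label = "reference")
  ref$is_reference <- TRUE
  export_rxn <- if ("YdeD" %in% names(ref$rates)) "YdeD" else "YdeD_cys"
  for (rg in design$regimes) {
    for (lev in design$levels) {
      b <- design$boundary(rg, lev, km)
      lab <- paste0(rg, "_", design$feed_rates_mL_h[lev], "mLh")
      st <- solve_steady_state(km, boundary = b, label = lab)
      states[[lab]] <- st
    }
  }
  all_states <- c(list(ref), states)
  exports <- vapply(all_states, function(s) s$rates[[export_rxn]], numeric(1))
  if (any(exports <= 0))
    stop("parameter set rejected: non-positive L-cysteine export in state(s) ",
         paste(vapply(all_states[exports <= 0], `[[`, character(1), "label"),
               collapse = ", "))
  set.seed(seed)
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  jitter <- function(x) if (sdlog == 0) x else
    x * exp(stats::rnorm(length(x), 0, sdlog))
  noisy <- lapply(all_states, function(s) {
    s$concentrations <- jitter(s$concentrations)
    s$rates <- jitter(s$rates)
    s
  })
  structure(list(
    reference = noisy[[1]],
    perturbations = noisy[-1],
    noise_cv = noise_cv, seed = seed,
    observable = intersect(c("PTS", "PYRt", "SUCCt", "YdeD", "YdeD_cys",
                             "YdeD_oas", "BIOMASS"), names(km$J_ref)),
    ground_truth = list(eps_true = km$eps_true, law = km$law, dG0 = km$dG0,
                        J_ref = km$J_ref, c_ref = km$c_ref,
                        temperature = km$temperature,
                        reference_state = ref)),
    class = "mca_dataset")
}

#' @export
print.mca_dataset <- function(x, ...) {
  cat("<mca_dataset> reference + ", length(x$perturbations),
      " perturbation states, noise CV ", x$noise_cv, ", seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Finite-difference ground-truth control coefficients
#'
#' Central-difference perturbation of every enzyme activity (including the
#' fixed boundary fluxes, whose "activity" scales the imposed flux):
#' `C_J[i,k] = d ln J_i / d ln e_k`, `C_S[j,k] = d ln c_j / d ln e_k`.
#' Independent of the MCA algebra; used as its validation oracle.
#'
#' @param km A `kinetic_model`.
#' @param relative_step Relative step of the central difference.
#' @return List with matrices `C_J` (reactions x enzymes) and `C_S`
#'   (internal metabolites x enzymes).
#' @export
true_control_coefficients <- function(km, relative_step = 1e-3) {
  rxns <- names(km$J_ref)
  internal <- metabolite_ids(km$model, internal_only = TRUE)
  h <- relative_step
  C_J <- matrix(NA_real_, length(rxns), length(rxns),
                dimnames = list(rxns, rxns))
  C_S <- matrix(NA_real_, length(internal), length(rxns),
                dimnames = list(internal, rxns))
  base_e <- stats::setNames(rep(1, length(rxns)), rxns)
  for (k in rxns) {
    sols <- lapply(c(+h, -h), function(d) {
      e <- base_e; e[k] <- exp(d)
      tryCatch(solve_steady_state(km, e_rel = e, label = k),
               error = function(err)
                 stop("steady-state failure while perturbing enzyme ", k,
                      ": ", conditionMessage(err)))
    })
    C_J[, k] <- (log(abs(sols[[1]]$rates)) - log(abs(sols[[2]]$rates))) / (2 * h)
    C_S[, k] <- (log(sols[[1]]$concentrations[internal]) -
                   log(sols[[2]]$concentrations[internal])) / (2 * h)
  }
  list(C_J = C_J, C_S = C_S)
}

#' Write a perturbation dataset to CSV (+ JSON ground truth)
#'
#' @param dataset An `mca_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly the directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  states <- c(list(dataset$reference), dataset$perturbations)
  conc <- do.call(rbind, lapply(states, function(s)
    data.frame(state = s$label, is_reference = s$is_reference,
               t(s$concentrations), check.names = FALSE)))
  rates <- do.call(rbind, lapply(states, function(s)
    data.frame(state = s$label, t(s$rates), check.names = FALSE)))
  utils::write.csv(conc, file.path(dir, "metabolome.csv"), row.names = FALSE)
  utils::write.csv(rates, file.path(dir, "rates.csv"), row.names = FALSE)
  gt <- dataset$ground_truth
  jsonlite::write_json(
    list(noise_cv = dataset$noise_cv, seed = dataset$seed,
         observable = dataset$observable,
         law = as.list(gt$law), dG0 = as.list(gt$dG0),
         J_ref = as.list(gt$J_ref), c_ref = as.list(gt$c_ref),
         temperature = gt$temperature,
         eps_true = list(values = gt$eps_true,
                         rows = rownames(gt$eps_true),
                         cols = colnames(gt$eps_true))),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a perturbation dataset written by [write_dataset()]
#'
#' @param dir Directory containing `metabolome.csv`, `rates.csv` and
#'   `ground_truth.json`.
#' @return An `mca_dataset`.
#' @export
read_dataset <- function(dir) {
  conc <- utils::read.csv(file.path(dir, "metabolome.csv"),
                          check.names = FALSE)
  rates <- utils::read.csv(file.path(dir, "rates.csv"), check.names = FALSE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  states <- lapply(seq_len(nrow(conc)), function(i) {
    cv <- unlist(conc[i, setdiff(names(conc), c("state", "is_reference"))])
    rv <- unlist(rates[i, setdiff(names(rates), "state")])
    structure(list(label = conc$state[i], concentrations = cv, rates = rv,
                   is_reference = isTRUE(conc$is_reference[i]),
                   residual = NA_real_),
              class = "steady_state")
  })
  is_ref <- vapply(states, `[[`, logical(1), "is_reference")
  eps <- NULL
  if (!is.null(gt$eps_true)) {
    eps <- matrix(unlist(gt$eps_true$values), length(gt$eps_true$rows),
                  length(gt$eps_true$cols), byrow = FALSE,
                  dimnames = list(gt$eps_true$rows, gt$eps_true$cols))
    eps <- t(apply(gt$eps_true$values, 1, as.numeric))
    dimnames(eps) <- list(gt$eps_true$rows, gt$eps_true$cols)
  }
  structure(list(reference = states[is_ref][[1]],
                 perturbations = states[!is_ref],
                 noise_cv = gt$noise_cv, seed = gt$seed,
                 observable = gt$observable,
                 ground_truth = list(eps_true = eps, law = unlist(gt$law),
                                     dG0 = unlist(gt$dG0),
                                     J_ref = unlist(gt$J_ref),
                                     c_ref = unlist(gt$c_ref),
                                     temperature = gt$temperature)),
            class = "mca_dataset")
}
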