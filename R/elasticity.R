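## Scaled elasticities: thermokinetic affinity closed form for reactions
## near thermodynamic equilibrium, lin-log regression across the short-term
## perturbation states for reactions far from equilibrium.

#' Thermokinetic elasticity of a near-equilibrium reaction
#'
#' For a reaction operating forward (`dGr < 0`) with mass-action
#' displacement `Gamma = exp(dGr / RT)`, the scaled elasticity with respect
#' to a metabolite with signed stoichiometric coefficient `s` is
#' `eps = -s * Gamma / (1 - Gamma)`: it diverges as the reaction approaches
#' equilibrium (`dGr -> 0-`) and vanishes in the saturated forward limit
#' (`dGr -> -Inf`).
#'
#' @param s_ij Signed stoichiometric coefficient (reactant negative).
#' @param dGr Gibbs reaction energy, kJ/mol; must be negative.
#' @param temperature Kelvin.
#' @return Dimensionless scaled elasticity.
#' @export
thermokinetic_elasticity <- function(s_ij, dGr, temperature = 305.15) {
  if (any(!is.finite(dGr)) || any(dGr >= 0))
    stop("thermokinetic elasticity requires dGr < 0 (forward-operating); got ",
         paste(format(dGr, digits = 4), collapse = ", "))
  if (temperature <= 0) stop("temperature must be positive")
  gam <- exp(dGr / (R_GAS * temperature))
  -s_ij * gam / (1 - gam)
}

## perturbation design matrix and response for one reaction
.linlog_xy <- function(dataset, reaction, effectors) {
  ref <- dataset$reference
  J_ref <- ref$rates[[reaction]]
  if (is.null(J_ref) || !is.finite(J_ref) || J_ref == 0)
    stop("no nonzero reference flux for reaction ", reaction)
  miss <- setdiff(effectors, names(ref$concentrations))
  if (length(miss))
    stop("effector concentrations missing from dataset: ",
         paste(miss, collapse = ", "))
  states <- dataset$perturbations
  X <- t(vapply(states, function(s)
    log(s$concentrations[effectors] / ref$concentrations[effectors]),
    numeric(length(effectors))))
  if (length(effectors) == 1L) X <- matrix(X, ncol = 1)
  colnames(X) <- effectors
  y <- vapply(states, function(s) s$rates[[reaction]] / J_ref - 1, numeric(1))
  list(X = X, y = y)
}

#' Lin-log elasticities of one reaction by regression
#'
#' Fits `v_k / J_ref - 1 = sum_j eps_j ln(c_jk / c_j,ref)` across the
#' perturbation states (enzyme levels at reference: the short-term
#' assumption), by least squares or ridge regression.
#'
#' @param dataset An `mca_dataset` (or compatible list with `reference` and
#'   `perturbations`).
#' @param model `metabolic_model` used for the default effector set.
#' @param reaction Reaction id.
#' @param effectors Effector metabolite ids; default: the reaction's
#'   reactants/products that are internal metabolites.
#' @param lambda Ridge penalty (`>= 0`); 0 means ordinary least squares.
#' @param auto_ridge Apply a small ridge penalty automatically (with a
#'   warning) when the design condition number exceeds 1e6.
#' @return List: `eps` (named), `diagnostics` (residual variance, condition
#'   number, n_states, lambda).
#' @export
linlog_elasticities <- function(dataset, model, reaction, effectors = NULL,
                                lambda = 0, auto_ridge = TRUE) {
  if (is.null(dataset$reference)) stop("dataset has no reference state")
  if (is.null(effectors)) {
    s <- model$reactions[[reaction]]$stoichiometry
    effectors <- intersect(names(s), metabolite_ids(model, internal_only = TRUE))
  }
  if (!length(effectors)) stop("empty effector set for reaction ", reaction)
  xy <- .linlog_xy(dataset, reaction, effectors)
  X <- xy$X; y <- xy$y
  if (nrow(X) < length(effectors))
    stop("need at least ", length(effectors), " perturbation states for ",
         reaction, "; got ", nrow(X))
  if (all(abs(X) < 1e-12))
    stop("zero design matrix: all states identical to the reference")
  sv <- svd(X)$d
  cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (lambda == 0 && cond > 1e6) {
    if (auto_ridge) {
      warning("design condition number ", format(cond, digits = 3),
              " for ", reaction, "; applying ridge lambda = 1e-6")
      lambda <- 1e-6
    } else {
      stop("rank-deficient design for reaction ", reaction,
           " (condition number ", format(cond, digits = 3),
           "); use ridge regularization (lambda > 0)")
    }
  }
  p <- ncol(X)
  if (lambda > 0) {
    eps <- solve(crossprod(X) + diag(lambda, p), crossprod(X, y))
  } else {
    eps <- qr.solve(X, y)
  }
  eps <- stats::setNames(as.numeric(eps), effectors)
  resid <- y - as.numeric(X %*% eps)
  dfree <- max(1L, nrow(X) - p)
  list(eps = eps,
       diagnostics = list(residual_variance = sum(resid^2) / dfree,
                          condition_number = cond,
                          n_states = nrow(X), lambda = lambda))
}

#' Thermodynamic annotation of a model at given concentrations
#'
#' Evaluates the Gibbs reaction energy of every dG0-annotated reaction at a
#' set of (typically reference-state) concentrations and classifies each as
#' near or far from equilibrium.
#'
#' @param model A `metabolic_model`.
#' @param dG0 Named standard Gibbs reaction energies, kJ/mol.
#' @param concentrations Named concentrations, mM (all participating
#'   species except water).
#' @param temperature Kelvin.
#' @param threshold Near/far threshold, kJ/mol.
#' @return data.frame: `reaction`, `dG0`, `dGr`, `eq_class`.
#' @export
thermo_annotation <- function(model, dG0, concentrations,
                              temperature = 305.15, threshold = -10) {
  ids <- intersect(reaction_ids(model), names(dG0))
  lnc <- log(concentrations / 1000)
  dGr <- vapply(ids, function(id)
    delta_g_reaction(dG0[[id]], model$reactions[[id]]$stoichiometry, lnc,
                     temperature), numeric(1))
  data.frame(reaction = ids, dG0 = as.numeric(dG0[ids]),
             dGr = as.numeric(dGr),
             eq_class = classify_equilibrium(dGr, threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the full scaled elasticity matrix
#'
#' Thermokinetic rows (near-equilibrium reactions) are filled from the
#' closed form at the annotated Gibbs reaction energy; far-from-equilibrium
#' rows are estimated by lin-log regression from the dataset. Boundary
#' (pseudo, unannotated) reactions such as fixed uptake/drain fluxes get
#' zero rows. Entries for species that are not effectors of a reaction stay
#' zero.
#'
#' @param model Augmented `metabolic_model`.
#' @param thermo data.frame from [thermo_annotation()] (columns `reaction`,
#'   `dGr`, `eq_class`).
#' @param dataset An `mca_dataset`.
#' @param effectors Optional named list reaction -> effector ids overriding
#'   the default (internal reactants/products).
#' @param external_effectors Clamped/extracellular species included as
#'   additional regression effectors for reactions that consume them
#'   (identifiability of boundary substrate uptake and of the sulphur-donor
#'   reactions).
#' @param lambda Ridge penalty for the regressions.
#' @param temperature Kelvin.
#' @return Object of class `elasticity_matrix`: `E` (reactions x internal
#'   metabolites), `E_ext` (reactions x external effectors), `method`
#'   (named), `diagnostics` (per regressed reaction).
#' @export
assemble_elasticity_matrix <- function(model, thermo, dataset,
                                       effectors = NULL,
                                       external_effectors = c("glc_e",
                                                              "pyr_e",
                                                              "succ_e",
                                                              "h2s",
                                                              "tsul"),
                                       lambda = 0, temperature = 305.15) {
  rxns <- reaction_ids(model)
  internal <- metabolite_ids(model, internal_only = TRUE)
  cls <- stats::setNames(thermo$eq_class, thermo$reaction)
  dGr <- stats::setNames(thermo$dGr, thermo$reaction)
  E <- matrix(0, length(rxns), length(internal),
              dimnames = list(rxns, internal))
  E_ext <- matrix(0, length(rxns), length(external_effectors),
                  dimnames = list(rxns, external_effectors))
  method <- stats::setNames(rep("boundary", length(rxns)), rxns)
  diagnostics <- list()
  for (id in rxns) {
    s <- model$reactions[[id]]$stoichiometry
    if (!id %in% names(cls)) {
      if (model$reactions[[id]]$pseudo) next       # fixed boundary flux
      stop("reaction ", id, " has no thermodynamic classification")
    }
    if (cls[[id]] == "near") {
      method[id] <- "thermokinetic"
      eff <- intersect(names(s), internal)
      E[id, eff] <- thermokinetic_elasticity(s[eff], dGr[[id]], temperature)
    } else if (cls[[id]] == "far") {
      method[id] <- "linlog"
      eff <- if (!is.null(effectors) && id %in% names(effectors))
        effectors[[id]]
      else {
        base <- intersect(names(s), internal)
        obs <- intersect(intersect(names(s), external_effectors),
                         names(dataset$reference$concentrations))
        c(base, obs)
      }
      if (!length(eff)) next   # only clamped participants: no elasticities
      fit <- linlog_elasticities(dataset, model, id, effectors = eff,
                                 lambda = lambda)
      ei <- intersect(names(fit$eps), internal)
      ee <- intersect(names(fit$eps), external_effectors)
      E[id, ei] <- fit$eps[ei]
      E_ext[id, ee] <- fit$eps[ee]
      diagnostics[[id]] <- fit$diagnostics
    } else {
      stop("reaction ", id, " is unclassified (dGr = ",
           format(dGr[[id]], digits = 4), " kJ/mol)")
    }
  }
  structure(list(E = E, E_ext = E_ext, method = method,
                 diagnostics = diagnostics),
            class = "elasticity_matrix")
}

#' @export
print.elasticity_matrix <- function(x, ...) {
  cat("<elasticity_matrix> ", nrow(x$E), " reactions x ", ncol(x$E),
      " metabolites (", sum(x$method == "thermokinetic"),
      " thermokinetic, ", sum(x$method == "linlog"), " lin-log, ",
      sum(x$method == "boundary"), " boundary)\n", sep = "")
  invisible(x)
}

#' Convert between scaled and unscaled elasticities
#'
#' `dv/dc = dg(J) E dg(c)^-1`; converting to unscaled and back is the
#' identity.
#'
#' @param E Scaled elasticity matrix (reactions x metabolites).
#' @param J Reference fluxes (reaction order of `E`).
#' @param conc Reference concentrations (metabolite order of `E`).
#' @param to `"unscaled"` or `"scaled"`.
#' @return Converted matrix.
#' @export
convert_elasticities <- function(E, J, conc, to = c("unscaled", "scaled")) {
  to <- match.arg(to)
  if (to == "unscaled") diag(J) %*% E %*% diag(1 / conc)
  else diag(1 / J) %*% E %*% diag(conc)
}

#' Full MCA from a perturbation dataset
#'
#' Re-evaluates the Gibbs reaction energies at the dataset's reference
#' concentrations (classification fixed by `thermo`), assembles the
#' elasticity matrix, and computes control coefficients at the measured
#' reference state.
#'
#' @param dataset An `mca_dataset`.
#' @param model Augmented `metabolic_model`.
#' @param thermo data.frame with `reaction`, `dG0`, `eq_class` (the near/far
#'   classification is held fixed; `dGr` is recomputed from the dataset).
#' @param effectors Optional effector override.
#' @param lambda Ridge penalty.
#' @param temperature Kelvin.
#' @return A `control_analysis` object.
#' @export
mca_from_dataset <- function(dataset, model, thermo, effectors = NULL,
                             lambda = 0, temperature = 305.15) {
  lnc <- log(dataset$reference$concentrations / 1000)
  dGr <- vapply(thermo$reaction, function(id)
    delta_g_reaction(thermo$dG0[match(id, thermo$reaction)],
                     model$reactions[[id]]$stoichiometry, lnc, temperature),
    numeric(1))
  th <- thermo
  th$dGr <- as.numeric(dGr)
  E <- assemble_elasticity_matrix(model, th, dataset, effectors = effectors,
                                  lambda = lambda, temperature = temperature)
  internal <- metabolite_ids(model, internal_only = TRUE)
  N <- stoichiometric_matrix(model, internal_only = TRUE)
  ## measured rates carry noise and need not balance; the summation
  ## theorems require a steady-state-consistent reference flux
  J <- reconcile_fluxes(model, dataset$reference$rates)
  control_coefficients(N, E, J,
                       dataset$reference$concentrations[internal])
}
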