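## Metabolic control analysis: link-matrix decomposition of the
## stoichiometric matrix, concentration/flux control coefficients from
## scaled elasticities (Visser & Heijnen formalism), Monte Carlo uncertainty
## propagation, and control-pattern reporting.

#' Link-matrix decomposition of a stoichiometric matrix
#'
#' Splits the internal stoichiometric matrix into a full-row-rank part `N_R`
#' and a link matrix `L` with `N = L N_R`, identifying conserved moieties
#' (dependent metabolite rows). `L` carries an identity block on the
#' independent rows.
#'
#' @param N Internal stoichiometric matrix (metabolites x reactions).
#' @return List with `N_R`, `L`, `independent` and `dependent` (row names or
#'   indices of the metabolites).
#' @export
link_decomposition <- function(N) {
  if (!length(N)) stop("empty stoichiometric matrix")
  N <- as.matrix(N)
  qrT <- qr(t(N))
  r <- qrT$rank
  piv <- qrT$pivot
  indep <- sort(piv[seq_len(r)])
  dep <- sort(piv[-seq_len(r)])
  N_R <- N[indep, , drop = FALSE]
  ## L solves N = L N_R (least squares; exact since rows of N lie in
  ## rowspace of N_R)
  L <- t(qr.solve(t(N_R), t(N)))
  ## clean the identity block
  L[indep, ] <- diag(r)
  rn <- rownames(N)
  list(N_R = N_R, L = L,
       independent = if (is.null(rn)) indep else rn[indep],
       dependent = if (is.null(rn)) dep else rn[dep])
}

#' Control coefficients from stoichiometry and scaled elasticities
#'
#' Computes scaled concentration control coefficients `C_S` and flux control
#' coefficients `C_J` at a reference steady state. With unscaled elasticity
#' `dv/dc = dg(J) E dg(c)^-1` and Jacobian `M = N_R (dv/dc) L`:
#' `C_S^u = -L M^-1 N_R`, `C_J^u = I + (dv/dc) C_S^u`, then
#' `C_J = dg(J)^-1 C_J^u dg(J)` and `C_S = dg(c)^-1 C_S^u dg(J)`.
#' Rows of `C_J` sum to 1 and rows of `C_S` to 0 (summation theorems).
#'
#' @param N_internal Internal stoichiometric matrix (metabolites x
#'   reactions).
#' @param E_scaled Scaled elasticity matrix (reactions x internal
#'   metabolites); an `elasticity_matrix` object is accepted.
#' @param J Reference fluxes (named or in reaction order), nonzero.
#' @param conc Reference internal concentrations (named or in metabolite
#'   order), positive.
#' @return Object of class `control_analysis` with `C_J` (fluxes x
#'   enzymes), `C_S` (metabolites x enzymes), `J`, `conc`.
#' @export
control_coefficients <- function(N_internal, E_scaled, J, conc) {
  N <- as.matrix(N_internal)
  E <- if (inherits(E_scaled, "elasticity_matrix")) E_scaled$E else as.matrix(E_scaled)
  mets <- rownames(N); rxns <- colnames(N)
  if (!is.null(names(J))) J <- J[rxns]
  if (!is.null(names(conc))) conc <- conc[mets]
  if (!is.null(rownames(E))) E <- E[rxns, mets, drop = FALSE]
  if (any(!is.finite(J)) || any(abs(J) < 1e-9))
    stop("reference fluxes must be nonzero for scaled control coefficients; ",
         "offending: ", paste(rxns[!is.finite(J) | abs(J) < 1e-9], collapse = ", "))
  if (any(conc <= 0)) stop("reference concentrations must be positive")

  Ev <- diag(J) %*% E %*% diag(1 / conc)          # unscaled dv/dc
  ld <- link_decomposition(N)
  M <- ld$N_R %*% Ev %*% ld$L
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-12)
    stop("singular steady-state Jacobian (rcond = ", format(rc, digits = 3),
         "); the reference state is structurally unstable")
  Minv <- solve(M)
  CSu <- -ld$L %*% Minv %*% ld$N_R
  CJu <- diag(length(J)) + Ev %*% CSu
  C_J <- diag(1 / J) %*% CJu %*% diag(J)
  C_S <- diag(1 / conc) %*% CSu %*% diag(J)
  dimnames(C_J) <- list(rxns, rxns)
  dimnames(C_S) <- list(mets, rxns)
  structure(list(C_J = C_J, C_S = C_S, J = stats::setNames(J, rxns),
                 conc = stats::setNames(conc, mets)),
            class = "control_analysis")
}

#' @export
print.control_analysis <- function(x, ...) {
  cat("<control_analysis> C_J: ", nrow(x$C_J), "x", ncol(x$C_J),
      ", C_S: ", nrow(x$C_S), "x", ncol(x$C_S), "\n", sep = "")
  cat("  max |row sum C_J - 1|: ",
      format(max(abs(rowSums(x$C_J) - 1)), digits = 3),
      ";  max |row sum C_S|: ",
      format(max(abs(rowSums(x$C_S))), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Monte Carlo uncertainty propagation for the MCA
#'
#' Resamples every measured concentration and rate from a normal
#' distribution truncated at zero (or log-normal), re-runs elasticity
#' assembly and the control-coefficient calculation, and summarizes the
#' distribution of every coefficient.
#'
#' @param dataset An `mca_dataset` (see
#'   [generate_perturbation_dataset()]) or compatible list.
#' @param model Augmented `metabolic_model` matching the dataset.
#' @param thermo Thermodynamic annotation data.frame (`reaction`, `dGr`,
#'   `eq_class`) as produced by [thermo_annotation()].
#' @param n_iter Number of iterations (the full analysis uses 10000;
#'   scaled-down values are fine for checks).
#' @param noise_cv Coefficient of variation applied to every measured
#'   concentration and rate.
#' @param seed Integer seed; the summary is reproducible.
#' @param distribution "truncnorm" (normal truncated at 0) or "lognormal".
#' @param effectors Optional effector override passed to
#'   [assemble_elasticity_matrix()].
#' @return Object of class `mca_montecarlo`: list with `summary`
#'   (data.frame: matrix, row, col, median, lo2.5, hi97.5, sign_stability),
#'   `point` (the noise-free `control_analysis`), `n_iter`, `n_dropped`,
#'   `seed`.
#' @export
monte_carlo_mca <- function(dataset, model, thermo, n_iter = 10000,
                            noise_cv = 0.1, seed = 1,
                            distribution = c("truncnorm", "lognormal"),
                            effectors = NULL) {
  distribution <- match.arg(distribution)
  set.seed(seed)
  point <- mca_from_dataset(dataset, model, thermo, effectors = effectors)
  dims <- dim(point$C_J); dimsS <- dim(point$C_S)
  acc_J <- array(NA_real_, c(n_iter, dims))
  acc_S <- array(NA_real_, c(n_iter, dimsS))
  dropped <- 0L
  jitter <- function(x) {
    if (noise_cv <= 0) return(x)
    if (distribution == "truncnorm") {
      y <- x
      y[] <- stats::rnorm(length(x), x, abs(x) * noise_cv)
      bad <- y <= 0 & x > 0
      while (any(bad)) {       # resample below-zero draws (truncation at 0)
        y[bad] <- stats::rnorm(sum(bad), x[bad], abs(x[bad]) * noise_cv)
        bad <- y <= 0 & x > 0
      }
      y
    } else {
      sdlog <- sqrt(log(1 + noise_cv^2))
      x * exp(stats::rnorm(length(x), 0, sdlog))
    }
  }
  for (it in seq_len(n_iter)) {
    ds <- dataset
    ds$reference$concentrations <- jitter(ds$reference$concentrations)
    ds$reference$rates <- jitter(ds$reference$rates)
    ds$perturbations <- lapply(ds$perturbations, function(st) {
      st$concentrations <- jitter(st$concentrations)
      st$rates <- jitter(st$rates)
      st
    })
    res <- tryCatch(
      suppressWarnings(mca_from_dataset(ds, model, thermo,
                                        effectors = effectors)),
      error = function(e) NULL)
    if (is.null(res)) { dropped <- dropped + 1L; next }
    acc_J[it, , ] <- res$C_J
    acc_S[it, , ] <- res$C_S
  }
  if (dropped > n_iter / 2)
    stop("more than half of the Monte Carlo iterations were dropped (",
         dropped, "/", n_iter, "); inference unstable")
  summarize <- function(acc, dn, matname) {
    out <- expand.grid(row = dn[[1]], col = dn[[2]], stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
    out$matrix <- matname
    qs <- apply(acc, c(2, 3), stats::quantile,
                probs = c(0.025, 0.5, 0.975), na.rm = TRUE)
    out$median <- as.vector(qs[2, , ])
    out$lo2.5 <- as.vector(qs[1, , ])
    out$hi97.5 <- as.vector(qs[3, , ])
    med_sign <- sign(qs[2, , ])
    ss <- sapply(seq_len(dim(acc)[3]), function(j)
      sapply(seq_len(dim(acc)[2]), function(i) {
        v <- acc[, i, j]; v <- v[!is.na(v)]
        if (!length(v)) return(NA_real_)
        s <- med_sign[i, j]
        if (s == 0) return(1)
        mean(sign(v) == s)
      }))
    out$sign_stability <- as.vector(ss)
    out[, c("matrix", "row", "col", "median", "lo2.5", "hi97.5",
            "sign_stability")]
  }
  summary <- rbind(
    summarize(acc_J, dimnames(point$C_J), "C_J"),
    summarize(acc_S, dimnames(point$C_S), "C_S"))
  structure(list(summary = summary, point = point, n_iter = n_iter,
                 n_dropped = dropped, noise_cv = noise_cv, seed = seed),
            class = "mca_montecarlo")
}

#' @export
print.mca_montecarlo <- function(x, ...) {
  cat("<mca_montecarlo> ", x$n_iter, " iterations (", x$n_dropped,
      " dropped), noise CV ", x$noise_cv, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Ranked control pattern over a target flux
#'
#' For a target flux (by default the L-cysteine/OAS export), ranks all
#' enzymes by their signed flux control coefficient, annotating competitive
#' pairs (negative cross-control).
#'
#' @param result A `control_analysis` or `mca_montecarlo` object.
#' @param target Reaction id of the target flux.
#' @param use Which coefficient to rank when `result` is a Monte Carlo
#'   summary: "median" or "point".
#' @return data.frame: `enzyme`, `C_J`, `rank`; sorted by decreasing
#'   coefficient, ties broken by enzyme id.
#' @export
control_pattern_report <- function(result, target = "YdeD",
                                   use = c("median", "point")) {
  use <- match.arg(use)
  if (inherits(result, "mca_montecarlo")) {
    if (use == "point") {
      CJ <- result$point$C_J
    } else {
      s <- result$summary
      s <- s[s$matrix == "C_J", ]
      CJ <- stats::xtabs(median ~ row + col, data = s)
      CJ <- matrix(CJ, nrow(result$point$C_J),
                   dimnames = dimnames(result$point$C_J)[c(1, 2)])
      ## xtabs sorts dimnames; rebuild by direct indexing instead
      CJ <- result$point$C_J
      for (k in seq_len(nrow(s))) CJ[s$row[k], s$col[k]] <- s$median[k]
    }
  } else if (inherits(result, "control_analysis")) {
    CJ <- result$C_J
  } else stop("result must be a control_analysis or mca_montecarlo object")
  if (!target %in% rownames(CJ))
    stop("unknown target flux: ", target)
  v <- CJ[target, ]
  ord <- order(-v, names(v))
  data.frame(enzyme = names(v)[ord], C_J = as.numeric(v[ord]),
             rank = seq_along(v), row.names = NULL)
}
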