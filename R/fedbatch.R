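## Synthetic fed-batch time series with exact elemental carbon balance:
## batch glucose depletion, dual glucose/thiosulfate feeding, biomass,
## L-cysteine and NAS accumulation, off-gas profiles from an inert-balance
## consistent gas model.

.MOLAR_MASS <- c(glucose = 180.156, cysteine = 121.158, nas = 147.129,
                 oas = 147.129, acetate = 60.052, co2 = 44.009)
.CARBON_ATOMS <- c(glucose = 6, cysteine = 3, nas = 5, oas = 5, acetate = 2,
                   co2 = 1)
.MC <- 12.011

## g carbon per g species
.gc_per_g <- function(species) {
  .CARBON_ATOMS[species] * .MC / .MOLAR_MASS[species]
}

#' Default fed-batch process parameters
#'
#' Process scale and kinetics emulating a 10-L-initial-volume dual-feed
#' (glucose + thiosulfate) L-cysteine fed-batch: 10 g/L batch glucose,
#' 670 g/L glucose feed, 320 g/L thiosulfate feed starting 2 h after
#' inoculation, cultivation at 32 degC. Carbon partition fractions (biomass,
#' L-cysteine, NAS, acetate; CO2 takes the remainder) control where consumed
#' glucose carbon goes.
#'
#' @return Named list of parameters.
#' @export
fedbatch_params <- function() {
  list(
    t_end = 50, dt = 0.5,                  # h
    V0 = 10, X0 = 1.8, S0 = 10,            # L, g/L, g/L batch glucose
    feed_glc_rate = 0.075,                 # L/h
    feed_glc_conc = 670,                   # g/L
    feed_tso_rate = 0.05, feed_tso_start = 2,  # L/h, h
    qS_batch = 0.6,                        # g glucose / g CDW / h (batch)
    draw_k = 2,                            # 1/h residual-glucose drawdown
    f_biomass_batch = 0.5,                 # batch carbon partition
    f_biomass = 0.184, f_cys = 0.09, f_nas = 0.194, f_acetate = 0.01,
    cys_lag = 7,                           # h before cysteine production
    biomass_carbon_fraction = 0.474,       # g C / g CDW
    RQ = 1.0,
    gas_flow_NL_min = 20, y_o2_in = 0.2095, y_co2_in = 0.0004,
    temperature = 305.15)
}

#' Generate a synthetic fed-batch time series
#'
#' Integrates carbon-amount balances: consumed glucose carbon is partitioned
#' into biomass, L-cysteine, NAS, acetate and CO2 (remainder), so total
#' carbon in feeds equals carbon in pools + CO2 at every time point up to
#' integrator tolerance. Feeding starts automatically when the batch glucose
#' is depleted. Off-gas fractions are computed from the carbon evolution
#' rate via a nitrogen balance at the stated respiratory quotient.
#'
#' @param params List as from [fedbatch_params()]; partial lists are merged
#'   over the defaults.
#' @param noise_cv Multiplicative measurement noise CV on concentration
#'   columns (0 = exact).
#' @param seed Integer seed for the noise.
#' @return A data.frame of class `fedbatch_series` with columns `time_h`,
#'   `volume_L`, `biomass_gL`, `glucose_gL`, `cysteine_gL`, `nas_gL`,
#'   `acetate_gL`, `co2_cum_mol`, `feed_glucose_L_h`, `feed_tso_L_h`,
#'   `offgas_o2`, `offgas_co2`, `gas_flow_NL_min`; parameters and the
#'   noise-free truth attached as attributes.
#' @export
generate_fedbatch_series <- function(params = list(), noise_cv = 0,
                                     seed = 1) {
  p <- utils::modifyList(fedbatch_params(), params)
  stopifnot(p$V0 > 0, p$X0 > 0, p$S0 > 0, p$feed_glc_conc > 0)
  fX_c <- p$biomass_carbon_fraction
  gc <- .gc_per_g(c("glucose", "cysteine", "nas", "acetate"))

  ## states: V [L], Glc [g], Xc, Cysc, NASc, Acc, CO2c [g C], fedC [g C]
  deriv <- function(t, y, phase) {
    V <- y[1]; Glc <- y[2]; Xc <- y[3]
    X <- Xc / fX_c                       # g biomass
    F_glc <- if (phase == 2) p$feed_glc_rate else 0
    F_tso <- if (t >= p$feed_tso_start) p$feed_tso_rate else 0
    supply <- F_glc * p$feed_glc_conc    # g glucose / h
    cap <- p$qS_batch * X                # uptake capacity, g/h
    cons <- if (phase == 1) min(cap, p$qS_batch * X)
            else min(cap, supply + p$draw_k * max(Glc, 0))
    u <- cons * gc[["glucose"]]          # consumed carbon, g C / h
    if (phase == 1) {
      fX <- p$f_biomass_batch; fcys <- 0; fnas <- 0; fac <- 0
    } else {
      fX <- p$f_biomass
      fcys <- if (t >= p$cys_lag) p$f_cys else 0
      fnas <- p$f_nas; fac <- p$f_acetate
    }
    fco2 <- 1 - fX - fcys - fnas - fac
    c(dV = F_glc + F_tso,
      dGlc = supply - cons,
      dXc = fX * u,
      dCysc = fcys * u,
      dNASc = fnas * u,
      dAcc = fac * u,
      dCO2c = fco2 * u,
      dfedC = supply * gc[["glucose"]])
  }
  y0 <- c(V = p$V0, Glc = p$S0 * p$V0, Xc = p$X0 * p$V0 * fX_c,
          Cysc = 0, NASc = 0, Acc = 0, CO2c = 0, fedC = 0)
  times <- seq(0, p$t_end, by = p$dt)

  ## phase 1: batch until glucose depletion (root)
  out1 <- deSolve::lsodar(
    y = y0, times = times,
    func = function(t, y, parms) list(deriv(t, y, 1)),
    rootfunc = function(t, y, parms) y[2] - 1e-6,
    rtol = 1e-10, atol = 1e-10)
  t_switch <- attr(out1, "troot")
  if (is.null(t_switch) || !length(t_switch)) t_switch <- p$t_end
  keep1 <- out1[out1[, "time"] < t_switch, , drop = FALSE]
  y_sw <- out1[nrow(out1), -1]
  y_sw["Glc"] <- max(y_sw[["Glc"]], 0)

  times2 <- sort(unique(c(t_switch, times[times >= t_switch])))
  out2 <- deSolve::ode(
    y = y_sw, times = times2,
    func = function(t, y, parms) list(deriv(t, y, 2)),
    rtol = 1e-10, atol = 1e-10)
  ## keep1 holds strictly pre-switch samples; out2 starts at the switch
  out <- rbind(keep1, out2)

  tt <- out[, "time"]; V <- out[, "V"]
  X <- out[, "Xc"] / fX_c
  CER <- vapply(seq_along(tt), function(i) {
    ph <- if (tt[i] < t_switch) 1 else 2
    deriv(tt[i], out[i, -1], ph)[["dCO2c"]] / .MC   # mol CO2 / h
  }, numeric(1))
  OUR <- CER / p$RQ
  n_in <- p$gas_flow_NL_min * 60 / 22.414           # mol gas / h
  n_N2 <- n_in * (1 - p$y_o2_in - p$y_co2_in)
  o2_out <- n_in * p$y_o2_in - OUR
  co2_out <- n_in * p$y_co2_in + CER
  n_out <- n_N2 + o2_out + co2_out
  series <- data.frame(
    time_h = tt, volume_L = V,
    biomass_gL = X / V,
    glucose_gL = out[, "Glc"] / V,
    cysteine_gL = out[, "Cysc"] / gc[["cysteine"]] / V,
    nas_gL = out[, "NASc"] / gc[["nas"]] / V,
    acetate_gL = out[, "Acc"] / gc[["acetate"]] / V,
    co2_cum_mol = out[, "CO2c"] / .MC,
    feed_glucose_L_h = ifelse(tt >= t_switch, p$feed_glc_rate, 0),
    feed_glucose_g_cum = out[, "fedC"] / .gc_per_g("glucose"),
    feed_tso_L_h = ifelse(tt >= p$feed_tso_start, p$feed_tso_rate, 0),
    offgas_o2 = o2_out / n_out,
    offgas_co2 = co2_out / n_out,
    gas_flow_NL_min = p$gas_flow_NL_min)
  truth <- list(t_switch = t_switch, CER_mol_h = CER, OUR_mol_h = OUR,
                fed_carbon_g = out[, "fedC"],
                params = p)
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    for (col in c("biomass_gL", "glucose_gL", "cysteine_gL", "nas_gL",
                  "acetate_gL"))
      series[[col]] <- series[[col]] *
        exp(stats::rnorm(nrow(series), 0, sdlog))
  }
  structure(series, class = c("fedbatch_series", "data.frame"),
            truth = truth, noise_cv = noise_cv, seed = seed)
}

#' Write / read a fed-batch series as tidy CSV
#'
#' @param series A `fedbatch_series` (or plain data.frame with the same
#'   columns).
#' @param path CSV file path.
#' @return `write_fedbatch` returns the path invisibly; `read_fedbatch`
#'   returns a `fedbatch_series` (without generator truth).
#' @export
write_fedbatch <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fedbatch
#' @export
read_fedbatch <- function(path) {
  df <- utils::read.csv(path)
  if (any(diff(df$time_h) <= 0)) stop("time must be strictly increasing")
  structure(df, class = c("fedbatch_series", "data.frame"))
}
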