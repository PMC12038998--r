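## Bioprocess rate estimation from fed-batch time series: cell-specific and
## volumetric rates, exporter selectivity, gas-exchange rates by nitrogen
## balance, and carbon molar balances.

.species_col <- function(series, species) {
  col <- paste0(species, "_gL")
  if (!col %in% names(series))
    stop("species '", species, "' not present in series (no column ", col, ")")
  col
}

.interp <- function(x, y, at) stats::approx(x, y, xout = at, rule = 2)$y

## trapezoid integral of y(t) over [t1, t2] using the sample grid plus the
## interval end points
.trapz_between <- function(t, y, t1, t2) {
  tt <- sort(unique(c(t1, t2, t[t > t1 & t < t2])))
  yy <- .interp(t, y, tt)
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' Cell-specific rate of a species over a time interval
#'
#' Total-amount based rate for fed-batch operation:
#' `q = [V(t2) C(t2) - V(t1) C(t1) - fed] / integral(X V dt)`, in
#' mg per g cell dry weight per h. Negative values mean uptake. The feed
#' correction uses the `feed_<species>_L_h` column and the corresponding
#' feed concentration (attribute or argument); it is zero when the species
#' is not fed.
#'
#' @param series A `fedbatch_series`.
#' @param species Species name, e.g. `"cysteine"`, `"nas"`, `"glucose"`.
#' @param t1,t2 Interval limits, h, with `t1 < t2`; at least two samples
#'   must fall inside.
#' @param feed_conc Feed concentration (g/L) for the species when fed;
#'   taken from the generator parameters when available.
#' @return Specific rate, mg/g/h.
#' @export
specific_rate <- function(series, species, t1, t2, feed_conc = NULL) {
  if (t1 >= t2) stop("t1 must be smaller than t2")
  if (sum(series$time_h >= t1 & series$time_h <= t2) < 2)
    stop("fewer than 2 samples in [", t1, ", ", t2, "]")
  col <- .species_col(series, species)
  tt <- series$time_h
  amt <- series$volume_L * series[[col]]              # g in reactor
  dA <- .interp(tt, amt, t2) - .interp(tt, amt, t1)
  fed <- 0
  feed_col <- paste0("feed_", species, "_L_h")
  cum_col <- paste0("feed_", species, "_g_cum")
  if (cum_col %in% names(series)) {
    fed <- .interp(tt, series[[cum_col]], t2) -
      .interp(tt, series[[cum_col]], t1)
  } else if (feed_col %in% names(series)) {
    if (is.null(feed_conc)) {
      truth <- attr(series, "truth")
      feed_conc <- if (species == "glucose" && !is.null(truth))
        truth$params$feed_glc_conc else NULL
    }
    if (is.null(feed_conc))
      stop("species '", species, "' is fed; supply feed_conc (g/L)")
    fed <- feed_conc * .trapz_between(tt, series[[feed_col]], t1, t2)
  }
  biomass_int <- .trapz_between(tt, series$biomass_gL * series$volume_L,
                                t1, t2)               # g CDW * h
  1000 * (dA - fed) / biomass_int
}

#' Volumetric productivity of a species
#'
#' `(C(t2) - C(t1)) / (t2 - t1)` in g/L/h; negative values permitted
#' (declining concentration).
#'
#' @inheritParams specific_rate
#' @return Volumetric productivity, g/L/h.
#' @export
volumetric_productivity <- function(series, species, t1, t2) {
  if (t1 >= t2) stop("t1 must be smaller than t2")
  if (sum(series$time_h >= t1 & series$time_h <= t2) < 2)
    stop("fewer than 2 samples in [", t1, ", ", t2, "]")
  col <- .species_col(series, species)
  (.interp(series$time_h, series[[col]], t2) -
     .interp(series$time_h, series[[col]], t1)) / (t2 - t1)
}

#' Exporter selectivity
#'
#' Ratio of the product export rate to the by-product export rate. The
#' medium NAS concentration is the accepted proxy for exported
#' O-acetylserine (spontaneous isomerization; identical molar mass), so
#' mg-based rates are interchangeable between OAS and NAS.
#'
#' @param q_product Product (L-cysteine) specific export rate, mg/g/h.
#' @param q_byproduct By-product (OAS/NAS) specific export rate, mg/g/h;
#'   must be positive.
#' @return Dimensionless selectivity.
#' @export
selectivity <- function(q_product, q_byproduct) {
  if (any(q_byproduct <= 0))
    stop("selectivity undefined for zero or negative by-product rate")
  q_product / q_byproduct
}

#' Gas exchange rates from off-gas data
#'
#' Inert (nitrogen) balance method: the molar air inflow follows from the
#' gas flow at norm conditions; the outflow from the nitrogen balance; then
#' `OUR = (n_in y_O2,in - n_out y_O2,out)/V` and
#' `CER = (n_out y_CO2,out - n_in y_CO2,in)/V`.
#'
#' @param series A `fedbatch_series` with `offgas_o2`, `offgas_co2` and
#'   `gas_flow_NL_min` columns.
#' @param t Time point(s), h.
#' @param y_o2_in,y_co2_in Inlet gas composition (volume fractions).
#' @return data.frame with `time_h`, `OUR_mmol_L_h`, `CER_mmol_L_h`.
#' @export
gas_exchange_rates <- function(series, t, y_o2_in = 0.2095,
                               y_co2_in = 0.0004) {
  need <- c("offgas_o2", "offgas_co2", "gas_flow_NL_min")
  if (!all(need %in% names(series)))
    stop("missing off-gas columns: ",
         paste(setdiff(need, names(series)), collapse = ", "))
  tt <- series$time_h
  y_o2 <- .interp(tt, series$offgas_o2, t)
  y_co2 <- .interp(tt, series$offgas_co2, t)
  V <- .interp(tt, series$volume_L, t)
  n_in <- .interp(tt, series$gas_flow_NL_min, t) * 60 / 22.414   # mol/h
  n_N2 <- n_in * (1 - y_o2_in - y_co2_in)
  n_out <- n_N2 / (1 - y_o2 - y_co2)
  OUR <- (n_in * y_o2_in - n_out * y_o2) / V * 1000              # mmol/L/h
  CER <- (n_out * y_co2 - n_in * y_co2_in) / V * 1000
  data.frame(time_h = t, OUR_mmol_L_h = OUR, CER_mmol_L_h = CER)
}

#' Carbon molar balance of a fed-batch process
#'
#' Shares of the carbon moles fed as glucose (initial batch charge plus
#' feed) recovered in each sink at the end of the interval: biomass, CO2
#' (cumulative or integrated CER), L-cysteine, NAS, acetate and residual
#' glucose; `unaccounted = 100 - sum(shares)`.
#'
#' @param series A `fedbatch_series`.
#' @param biomass_carbon_fraction g carbon per g cell dry weight (default
#'   0.474, standard E. coli composition CH1.77O0.49N0.24).
#' @param species_carbon Named carbon atoms per molecule for the tracked
#'   species (override/add to the built-in map).
#' @param molar_mass Named molar masses, g/mol (override/add).
#' @param feed_conc Glucose feed concentration (g/L); from the generator
#'   parameters when available.
#' @param t1,t2 Interval (defaults: full series).
#' @return Object of class `carbon_balance`: data.frame of `sink`,
#'   `carbon_mol`, `share_pct`, plus attributes `accounted_pct`,
#'   `unaccounted_pct` and `fed_carbon_mol`.
#' @export
carbon_balance <- function(series, biomass_carbon_fraction = 0.474,
                           species_carbon = NULL, molar_mass = NULL,
                           feed_conc = NULL, t1 = NULL, t2 = NULL) {
  carbon <- .CARBON_ATOMS
  mm <- .MOLAR_MASS
  if (!is.null(species_carbon)) carbon[names(species_carbon)] <- species_carbon
  if (!is.null(molar_mass)) mm[names(molar_mass)] <- molar_mass
  tt <- series$time_h
  if (is.null(t1)) t1 <- min(tt)
  if (is.null(t2)) t2 <- max(tt)
  if (is.null(feed_conc)) {
    truth <- attr(series, "truth")
    if (!is.null(truth)) feed_conc <- truth$params$feed_glc_conc
  }
  if (is.null(feed_conc))
    stop("glucose feed concentration unknown; supply feed_conc")
  sinks <- c("cysteine", "nas", "acetate")
  missing_ann <- sinks[!(sinks %in% names(carbon)) |
                         !(sinks %in% names(mm))]
  if (length(missing_ann))
    stop("missing carbon/molar-mass annotation for: ",
         paste(missing_ann, collapse = ", "))

  amount <- function(col) series$volume_L * series[[col]]        # g
  d_amount <- function(col)
    .interp(tt, amount(col), t2) - .interp(tt, amount(col), t1)
  molC <- function(species, grams) grams / mm[[species]] * carbon[[species]]

  fed_feed_g <- if ("feed_glucose_g_cum" %in% names(series))
    .interp(tt, series$feed_glucose_g_cum, t2) -
      .interp(tt, series$feed_glucose_g_cum, t1)
  else
    feed_conc * .trapz_between(tt, series$feed_glucose_L_h, t1, t2)
  fed_g <- .interp(tt, amount("glucose_gL"), t1) + fed_feed_g
  ## carbon actually released from the glucose pool over the interval:
  ## initial + fed - residual
  resid_g <- .interp(tt, amount("glucose_gL"), t2)
  fedC <- molC("glucose", fed_g)

  biomassC <- d_amount("biomass_gL") * biomass_carbon_fraction / .MC  # mol
  co2C <- if ("co2_cum_mol" %in% names(series))
    .interp(tt, series$co2_cum_mol, t2) - .interp(tt, series$co2_cum_mol, t1)
  else {
    ger <- gas_exchange_rates(series, tt[tt >= t1 & tt <= t2])
    .trapz_between(ger$time_h, ger$CER_mmol_L_h *
                     .interp(tt, series$volume_L, ger$time_h) / 1000,
                   t1, t2)
  }
  pools <- c(biomass = biomassC, co2 = co2C,
             cysteine = molC("cysteine", d_amount("cysteine_gL")),
             nas = molC("nas", d_amount("nas_gL")),
             acetate = molC("acetate", d_amount("acetate_gL")),
             residual_glucose = molC("glucose", resid_g))
  shares <- 100 * pools / fedC
  out <- data.frame(sink = names(pools), carbon_mol = as.numeric(pools),
                    share_pct = as.numeric(shares), row.names = NULL)
  structure(out, class = c("carbon_balance", "data.frame"),
            accounted_pct = sum(shares),
            unaccounted_pct = 100 - sum(shares),
            fed_carbon_mol = fedC)
}

#' @export
print.carbon_balance <- function(x, ...) {
  cat("Carbon molar balance (% of glucose carbon fed):\n")
  print.data.frame(transform(as.data.frame(x),
                             share_pct = round(share_pct, 2)), ...)
  cat("accounted: ", round(attr(x, "accounted_pct"), 2), "%, unaccounted: ",
      round(attr(x, "unaccounted_pct"), 2), "%\n", sep = "")
  invisible(x)
}
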