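# shared fixtures: small columns and forcing blocks built in code

# a reference layer with round-number van Genuchten parameters
vg_layer <- function(theta_r = 0.1, theta_s = 0.8, vg_alpha = 2, vg_n = 2,
                     ksat = 1, thickness = 0.1, bd = 0.1, om = 0.9) {
  soil_layer(thickness, bd, om, theta_r = theta_r, theta_s = theta_s,
             vg_alpha = vg_alpha, vg_n = vg_n, ksat = ksat)
}

# uniform column of n identical layers
uniform_column <- function(n = 10, thickness = 0.1, om = 0.9, bd = 0.1,
                           landuse = "pristine_forest", wtdx = 0.5, ...) {
  layers <- replicate(n, soil_layer(thickness, bd, om, ...), simplify = FALSE)
  soil_column(layers, landuse = landuse, wtdx = wtdx)
}

# one forcing day (precip in mm/d)
forcing_day <- function(precip = 0, tair = 27, radiation = 16, rh = 85,
                        wind = 2, date = as.Date("2008-01-01")) {
  data.frame(date = date, precip = precip, tair = tair,
             radiation = radiation, rh = rh, wind = wind)
}

# n-day forcing block with constant weather
forcing_block <- function(n, precip = 5, start = as.Date("2008-01-01"), ...) {
  f <- do.call(rbind, replicate(n, forcing_day(precip = precip, ...),
                                simplify = FALSE))
  f$date <- seq(start, by = "day", length.out = n)
  f
}

# a state with saturation from a given depth down and field capacity above
state_saturated_below <- function(column, depth) {
  p <- peatfire:::column_params(column)
  tops <- cumsum(c(0, p$dz))[seq_along(p$dz)]
  theta <- ifelse(tops >= depth - 1e-9, p$theta_s, p$theta_fc)
  st <- initial_state(column)
  st$theta <- theta
  st$wtd <- diagnose_wtd(column, st)
  st
}

ledger_residual <- function(ledger) {
  abs(ledger["precip"] - ledger["et_actual"] - ledger["lateral"] -
        ledger["runoff"] - ledger["delta_storage"])
}
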