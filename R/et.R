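#' Potential evapotranspiration from daily weather
#'
#' Penman-Monteith-style reference evapotranspiration (FAO-56 daily form, grass
#' reference, soil heat flux 0, net radiation from shortwave with albedo 0.23
#' and a clear-sky longwave term), scaled by a land-cover (plant functional
#' type) coefficient:
#' \deqn{PET = c_{pft}\,\frac{0.408\,\Delta (R_n) + \gamma\,\frac{900}{T+273}u_2(e_s-e_a)}
#'   {\Delta + \gamma(1+0.34 u_2)}}
#' in mm/d, returned in m/d.  Negative reference values (radiative loss under
#' saturated, calm conditions) are clamped to zero before scaling, so PET is
#' nonnegative and exactly linear in the coefficient.
#'
#' @param forcing data.frame of daily weather with columns `tair` (deg C),
#'   `radiation` (MJ/m2/d shortwave), `rh` (%), `wind` (m/s at 2 m).
#' @param pft_coefficient land-cover scaling, in `(0, 2]` (1 = reference crop).
#' @return PET in m/d, one value per forcing row.
#' @export
potential_et <- function(forcing, pft_coefficient = 1) {
  if (pft_coefficient <= 0 || pft_coefficient > 2)
    stop("pft_coefficient must be in (0, 2]")
  if (any(!is.finite(forcing$tair)) || any(!is.finite(forcing$radiation)) ||
      any(!is.finite(forcing$rh)) || any(!is.finite(forcing$wind)))
    stop("forcing fields must be finite")
  if (any(forcing$rh < 0 | forcing$rh > 100))
    stop("relative humidity outside [0, 100]")
  t <- forcing$tair
  es <- 0.6108 * exp(17.27 * t / (t + 237.3))          # kPa
  ea <- forcing$rh / 100 * es
  delta <- 4098 * es / (t + 237.3)^2                   # kPa/degC
  gamma <- 0.0665                                      # kPa/degC at sea level
  rns <- (1 - 0.23) * forcing$radiation                # net shortwave
  rnl <- 4.903e-9 * (t + 273.16)^4 * (0.34 - 0.14 * sqrt(pmax(ea, 0)))
  rn <- rns - rnl
  u2 <- forcing$wind
  et0 <- (0.408 * delta * rn + gamma * 900 / (t + 273) * u2 * (es - ea)) /
         (delta + gamma * (1 + 0.34 * u2))
  pmax(et0, 0) / 1000 * pft_coefficient
}

# default land-cover ET coefficients by land use
PFT_COEFFICIENTS <- c(pristine_forest = 1.00, degraded_forest = 0.95,
                      industrial_plantation = 0.90, smallholder = 0.85,
                      mangrove = 1.00, non_peat_other = 0.90)
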