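#' Simulate a soil column over consecutive days
#'
#' Runs the layered tipping-bucket water balance for one stand-alone column:
#' daily precipitation wets the litter and infiltrates, evapotranspiration is
#' withdrawn under a root-zone moisture stress ramp, water above field
#' capacity drains downward rate-limited by Mualem-van Genuchten unsaturated
#' conductivity, the column exchanges water laterally with the boundary water
#' table WTDx by a Darcy flux, and saturation excess runs off.  Each day is
#' integrated with `sub_steps` internal sub-steps.
#'
#' @param column a [soil_column()] with a finite `wtdx`.
#' @param state starting [initial_state()] / `column_state`.
#' @param forcing data.frame with columns `precip` (mm/d), `tair`, `radiation`,
#'   `rh`, `wind` (see [potential_et()]); one row per day.
#' @param pft_coefficient land-cover ET coefficient (default looked up from
#'   the column's land use).
#' @param sub_steps internal sub-steps per day (default 24).
#' @param pond_max maximum ponded depth before runoff, m.
#' @return object of class `column_run`: data.frame `daily` with columns
#'   `wtd`, `theta_ns`, `precip`, `et_actual`, `lateral`, `runoff`,
#'   `delta_storage` (all water fluxes in m/d, `wtd` in m below surface,
#'   positive down) plus the final `state`.
#' @export
simulate_column <- function(column, state, forcing,
                            pft_coefficient = NULL, sub_steps = 24,
                            pond_max = 0.05) {
  if (is.na(column$wtdx)) stop("column has no boundary wtdx; see assign_boundary_wtdx()")
  if (any(forcing$precip < 0)) stop("negative precipitation in forcing")
  if (is.null(pft_coefficient))
    pft_coefficient <- unname(PFT_COEFFICIENTS[column$landuse])
  p <- column_params(column)
  pet <- potential_et(forcing, pft_coefficient)
  res <- .simulate_column_cpp(p$dz, p$theta_r, p$theta_s, p$vg_alpha, p$vg_n,
                              p$ksat, p$theta_fc, p$theta_wilt,
                              column$litter_thickness, LITTER_THETA_R,
                              LITTER_THETA_S, LITTER_THETA_FC,
                              column$wtdx, column$lateral_length, pond_max,
                              0.3, SATURATION_FRACTION,
                              state$theta, state$litter_theta, state$ponded,
                              forcing$precip / 1000, pet, as.integer(sub_steps))
  end_state <- structure(list(theta = res$theta, litter_theta = res$litter_theta,
                              ponded = res$ponded, wtd = res$wtd[length(res$wtd)]),
                         class = "column_state")
  daily <- data.frame(wtd = res$wtd, theta_ns = res$theta_ns,
                      precip = forcing$precip / 1000,
                      et_actual = res$et_actual, lateral = res$lateral,
                      runoff = res$runoff, delta_storage = res$delta_storage)
  if (!is.null(forcing$date)) daily <- cbind(date = forcing$date, daily)
  structure(list(daily = daily, state = end_state, column = column),
            class = "column_run")
}

# a layer counts as saturated at this fraction of theta_s
SATURATION_FRACTION <- 0.999

#' Advance a column state by one day
#'
#' Single-day wrapper around [simulate_column()], returning the new state and
#' the day's conserved flux ledger (all terms in m of water over the day):
#' `precip - et_actual - lateral - runoff - delta_storage = 0` to within
#' 1e-6 m.  Lateral flux is positive for discharge out of the column (boundary
#' water table deeper than the column's) and negative for recharge.
#'
#' @inheritParams simulate_column
#' @param forcing one-row data.frame of daily weather.
#' @return list with `state` (new `column_state`) and `ledger` (named numeric:
#'   `precip`, `et_actual`, `lateral`, `runoff`, `delta_storage`).
#' @export
step_day <- function(column, state, forcing, pft_coefficient = NULL,
                     sub_steps = 24, pond_max = 0.05) {
  if (nrow(forcing) != 1) stop("step_day takes exactly one forcing day")
  run <- simulate_column(column, state, forcing, pft_coefficient,
                         sub_steps, pond_max)
  d <- run$daily
  list(state = run$state,
       ledger = c(precip = d$precip, et_actual = d$et_actual,
                  lateral = d$lateral, runoff = d$runoff,
                  delta_storage = d$delta_storage))
}

#' Diagnose water table depth from a column state
#'
#' The water table depth is the depth below which the profile is completely
#' saturated: the top of the contiguous saturated stack reaching the column
#' bottom (a layer counts as saturated at `theta >= 0.999 * theta_s`),
#' linearly interpolated into the first unsaturated layer above the stack.
#' With ponded surface water the water table is at the surface (0); with no
#' bottom saturation it is capped at `total_depth`.
#'
#' @param column a [soil_column()].
#' @param state a `column_state`.
#' @return water table depth, m below surface (positive down), in
#'   `[0, total_depth]`.
#' @export
diagnose_wtd <- function(column, state) {
  p <- column_params(column)
  .diagnose_wtd_cpp(p$dz, p$theta_s, p$theta_fc, state$theta, state$ponded,
                    SATURATION_FRACTION)
}

#' Near-surface soil moisture
#'
#' Thickness-weighted mean moisture of the surface litter layer and the top
#' two soil layers -- the model analogue of a satellite 0-5 cm soil moisture
#' retrieval (0.02 m litter + two 0.03 m layers in the default grids).
#'
#' @param column a [soil_column()] with at least 2 soil layers.
#' @param state a `column_state`.
#' @return volumetric moisture, m3/m3.
#' @export
near_surface_moisture <- function(column, state) {
  if (length(column$layers) < 2)
    stop("near-surface moisture needs litter + at least 2 soil layers")
  dz1 <- column$layers[[1]]$thickness
  dz2 <- column$layers[[2]]$thickness
  dzl <- column$litter_thickness
  (dzl * state$litter_theta + dz1 * state$theta[1] + dz2 * state$theta[2]) /
    (dzl + dz1 + dz2)
}

#' @export
print.column_run <- function(x, ...) {
  d <- x$daily
  cat("<column_run>", nrow(d), "days;", x$column$landuse,
      sprintf("(wtdx %.2f m)\n", x$column$wtdx))
  cat(sprintf("  WTD  mean %.3f m, range [%.3f, %.3f] m below surface\n",
              mean(d$wtd), min(d$wtd), max(d$wtd)))
  cat(sprintf("  theta_ns mean %.3f m3/m3; ET %.0f mm; lateral %+.0f mm; runoff %.0f mm\n",
              mean(d$theta_ns), sum(d$et_actual) * 1000,
              sum(d$lateral) * 1000, sum(d$runoff) * 1000))
  invisible(x)
}

#' @export
plot.column_run <- function(x, ...) {
  d <- x$daily
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(-d$wtd, type = "l", ylab = "WTD (m, negative down)",
                 xlab = "", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::plot(d$theta_ns, type = "l", ylab = "near-surface theta (m3/m3)",
                 xlab = "day", ...)
  invisible(x)
}
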