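#' Simulation run configuration
#'
#' Bundles the knobs shared by grid runs: spin-up length, production calendar,
#' sub-daily stepping, tolerances, and the land-use table of boundary water
#' table depths (WTDx, m below surface).  Non-peatland cells outside mangroves
#' drain to a 6 m boundary; peatland defaults deepen from pristine forest to
#' smallholder farmland, encoding progressively more intensive artificial
#' drainage; mangroves are tidal and get a surface boundary.
#'
#' @param spin_up_years maximum spin-up cycles of the repeated first forcing
#'   year (default 56); spin-up exits early once the annual-mean water table
#'   drifts by less than `spin_up_tol_m` between cycles.
#' @param start,end production period (default 2008-01-01 to 2015-12-31).
#' @param sub_steps internal sub-steps per day.
#' @param seed integer seed recorded with the run.
#' @param spin_up_tol_m spin-up convergence tolerance on annual-mean WTD, m.
#' @param pond_max maximum ponded depth before runoff, m.
#' @param wtdx_peat named numeric of WTDx defaults for peatland land uses, m.
#' @param wtdx_non_peat WTDx for non-peatland, non-mangrove cells, m.
#' @param wtdx_mangrove WTDx for mangrove cells, m.
#' @return list of class `run_config`.
#' @export
run_config <- function(spin_up_years = 56,
                       start = as.Date("2008-01-01"),
                       end = as.Date("2015-12-31"),
                       sub_steps = 24, seed = 1L,
                       spin_up_tol_m = 0.001, pond_max = 0.05,
                       wtdx_peat = c(pristine_forest = 0.25,
                                     degraded_forest = 0.30,
                                     industrial_plantation = 0.55,
                                     smallholder = 0.65),
                       wtdx_non_peat = 6.0, wtdx_mangrove = 0.0) {
  if (spin_up_years < 0) stop("spin_up_years must be >= 0")
  if (end < start) stop("production period is not well-ordered")
  structure(list(spin_up_years = spin_up_years, start = start, end = end,
                 sub_steps = sub_steps, seed = as.integer(seed),
                 spin_up_tol_m = spin_up_tol_m, pond_max = pond_max,
                 wtdx_peat = wtdx_peat, wtdx_non_peat = wtdx_non_peat,
                 wtdx_mangrove = wtdx_mangrove),
            class = "run_config")
}

#' Boundary water table depth for a land use
#'
#' @param landuse land-use class (see [soil_column()]).
#' @param classification `"peatland_grid"` or `"non_peatland_grid"` from
#'   [classify_profile()].
#' @param config a [run_config()].
#' @return WTDx in m below surface (positive down).
#' @export
assign_boundary_wtdx <- function(landuse, classification, config = run_config()) {
  if (!landuse %in% LANDUSE_LEVELS)
    stop("unknown land use: ", landuse)
  if (landuse == "mangrove") return(config$wtdx_mangrove)
  if (classification == "non_peatland_grid" || landuse == "non_peat_other")
    return(config$wtdx_non_peat)
  unname(config$wtdx_peat[landuse])
}

#' Spin up a column to quasi-equilibrium
#'
#' Repeats one forcing year until the annual-mean water table depth changes by
#' less than the configured tolerance between consecutive cycles (or the
#' maximum number of cycles is reached), removing dependence on the arbitrary
#' initial moisture state before production years are simulated.
#'
#' @param column a [soil_column()] with finite `wtdx`.
#' @param one_year_forcing data.frame of daily weather for one full year.
#' @param config a [run_config()].
#' @param state optional starting state (default [initial_state()]).
#' @return converged `column_state`, with attributes `cycles` and `drift_m`.
#' @export
spin_up <- function(column, one_year_forcing, config = run_config(),
                    state = NULL) {
  if (nrow(one_year_forcing) < 365)
    stop("spin-up forcing must cover at least one full year")
  if (is.null(state)) state <- initial_state(column)
  if (config$spin_up_years == 0) {
    attr(state, "cycles") <- 0
    return(state)
  }
  prev_mean <- NA_real_
  drift <- NA_real_
  cycles <- 0
  for (cy in seq_len(config$spin_up_years)) {
    run <- simulate_column(column, state, one_year_forcing,
                           sub_steps = config$sub_steps,
                           pond_max = config$pond_max)
    if (any(!is.finite(run$daily$wtd)))
      stop("non-finite state during spin-up at cycle ", cy)
    state <- run$state
    cycles <- cy
    cur_mean <- mean(run$daily$wtd)
    if (!is.na(prev_mean)) {
      drift <- abs(cur_mean - prev_mean)
      if (drift < config$spin_up_tol_m) break
    }
    prev_mean <- cur_mean
  }
  attr(state, "cycles") <- cycles
  attr(state, "drift_m") <- drift
  state
}

#' Run a grid of stand-alone columns
#'
#' Spins up and simulates every cell independently over the production period.
#' Cells do not exchange water, so outputs are invariant to cell ordering and
#' to the presence of other cells, and deterministic given the inputs.
#'
#' @param cells list of grid cells, each a list with `cell_id`, `column`
#'   (a [soil_column()]), and `classification`; [gen_grid()] produces this
#'   shape.  A missing/NA `wtdx` on a column is filled from
#'   [assign_boundary_wtdx()].
#' @param forcing data.frame of daily weather with columns `cell_id`, `date`,
#'   `precip`, `tair`, `radiation`, `rh`, `wind`, covering the production
#'   period for every cell (a single shared block without `cell_id` is
#'   broadcast to all cells).
#' @param config a [run_config()].
#' @return data.frame, one row per cell per production day: `cell_id`, `date`,
#'   `wtd` (m below surface), `wtd_signed` (negative below surface), `theta_ns`,
#'   and the flux ledger columns in m/d.
#' @export
run_grid <- function(cells, forcing, config = run_config()) {
  shared <- is.null(forcing$cell_id)
  out <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    f <- if (shared) forcing else forcing[forcing$cell_id == cell$cell_id, ]
    f <- f[order(f$date), ]
    days <- seq(config$start, config$end, by = "day")
    missing <- setdiff(as.character(days), as.character(f$date))
    if (length(missing))
      stop("forcing gaps for cell ", cell$cell_id, ": ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ..." else "")
    f <- f[f$date >= config$start & f$date <= config$end, ]
    col <- cell$column
    if (is.na(col$wtdx))
      col$wtdx <- assign_boundary_wtdx(col$landuse, cell$classification, config)
    yr1 <- f[format(f$date, "%Y") == format(config$start, "%Y"), ]
    st <- spin_up(col, yr1, config)
    run <- simulate_column(col, st, f, sub_steps = config$sub_steps,
                           pond_max = config$pond_max)
    d <- run$daily
    out[[i]] <- data.frame(cell_id = cell$cell_id, date = f$date,
                           wtd = d$wtd, wtd_signed = -d$wtd,
                           theta_ns = d$theta_ns, precip = d$precip,
                           et_actual = d$et_actual, lateral = d$lateral,
                           runoff = d$runoff, delta_storage = d$delta_storage)
  }
  do.call(rbind, out)
}

#' Write / read daily grid outputs
#'
#' Long-format CSV, one row per cell per day.  `wtd` is stored in both sign
#' conventions (`wtd` positive below surface, `wtd_signed` negative below
#' surface, matching figure conventions).
#'
#' @param daily data.frame from [run_grid()].
#' @param path file path.
#' @return `read_daily_outputs` returns the data.frame with `date` restored
#'   to `Date`.
#' @export
write_daily_outputs <- function(daily, path) {
  utils::write.csv(daily, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_daily_outputs
#' @export
read_daily_outputs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}
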