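#' Synthetic-truth parameters
#'
#' Generator settings for a synthetic tropical peatland province with the
#' study region's climate structure: a short dry season (day-of-year 15-59,
#' mid-January to late February) and a prolonged intense dry season
#' (day-of-year 166-300, mid-June to late October), occasional drought years
#' that scale rainfall down, a peat/mineral soil-column mixture with
#' land-use-dependent drainage, and Poisson fire counts driven by water table
#' depth through a soft threshold at `d_star` with a near-surface dryness
#' modifier.  The parameters are returned alongside generated data so recovery
#' tests are self-validating.
#'
#' @param seed integer seed; all generator functions derive their streams
#'   from it.
#' @param years simulated calendar years.
#' @param drought_years subset of `years` with rainfall scaled by
#'   `drought_multiplier`.
#' @param drought_multiplier rainfall multiplier in drought years, `(0, 1]`.
#' @param annual_precip_mm expected non-drought annual rainfall total.
#' @param wet_p,short_dry_p,long_dry_p daily wet-day probability in the wet
#'   season and the two dry windows.
#' @param short_dry,long_dry day-of-year windows `c(first, last)` of the two
#'   dry seasons.
#' @param peat_fraction fraction of grid cells on peat.
#' @param landuse_mix_peat named fractions of peat-cell land uses.
#' @param d_star fire-occurrence water table threshold, m below surface.
#' @param fire_s sigmoid width of the threshold response, m.
#' @param lambda_max maximum expected fire count per cell per fortnight.
#' @param dryness_weight weight of the near-surface dryness modifier, 0-1.
#' @param theta_wet,theta_dry near-surface moisture (m3/m3) at which the
#'   dryness modifier reaches its minimum / maximum.
#' @param obs_sigma gaussian noise s.d. for synthetic observed moisture.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed = 1L, years = 2008:2015,
                            drought_years = c(2009L, 2015L),
                            drought_multiplier = 0.6,
                            annual_precip_mm = 2500,
                            wet_p = 0.65, short_dry_p = 0.45, long_dry_p = 0.25,
                            short_dry = c(15L, 59L), long_dry = c(166L, 300L),
                            peat_fraction = 0.6,
                            landuse_mix_peat = c(pristine_forest = 0.3,
                                                 degraded_forest = 0.2,
                                                 industrial_plantation = 0.3,
                                                 smallholder = 0.2),
                            d_star = 0.4, fire_s = 0.04, lambda_max = 2,
                            dryness_weight = 0.5,
                            theta_wet = 0.7, theta_dry = 0.2,
                            obs_sigma = 0.05) {
  if (d_star <= 0) stop("d_star must be > 0")
  if (lambda_max <= 0) stop("lambda_max must be > 0")
  if (drought_multiplier <= 0 || drought_multiplier > 1)
    stop("drought_multiplier must be in (0, 1]")
  if (abs(sum(landuse_mix_peat) - 1) > 1e-8)
    stop("landuse_mix_peat fractions must sum to 1")
  structure(as.list(environment()), class = "synthetic_truth")
}

# wet-day probability by day of year
wet_probability <- function(truth, doy) {
  p <- rep(truth$wet_p, length(doy))
  p[doy >= truth$short_dry[1] & doy <= truth$short_dry[2]] <- truth$short_dry_p
  p[doy >= truth$long_dry[1] & doy <= truth$long_dry[2]] <- truth$long_dry_p
  p
}

# run code under a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  code
}

#' Generate daily weather forcing for one cell
#'
#' Rainfall is a per-day Bernoulli wet/dry process with seasonal wet
#' probability and gamma-distributed wet-day amounts whose mean is calibrated
#' so the expected non-drought annual total equals `annual_precip_mm`; drought
#' years scale amounts by the drought multiplier.  Temperature, radiation,
#' relative humidity and wind get dry-season shifts plus noise.  Deterministic
#' for a given `(truth$seed, cell_index)`.
#'
#' @param truth a [synthetic_truth()].
#' @param cell_index integer used to derive the cell's RNG stream.
#' @return data.frame of daily forcing: `date`, `precip` (mm/d), `tair`
#'   (deg C), `radiation` (MJ/m2/d), `rh` (%), `wind` (m/s).
#' @export
gen_weather <- function(truth, cell_index = 1L) {
  dates <- seq(as.Date(paste0(min(truth$years), "-01-01")),
               as.Date(paste0(max(truth$years), "-12-31")), by = "day")
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  p_wet <- wet_probability(truth, doy)
  exp_wet_days <- sum(wet_probability(truth, 1:365))
  mean_amt <- truth$annual_precip_mm / exp_wet_days
  dry <- as.numeric(doy >= truth$short_dry[1] & doy <= truth$short_dry[2] |
                    doy >= truth$long_dry[1] & doy <= truth$long_dry[2])
  mult <- ifelse(yr %in% truth$drought_years, truth$drought_multiplier, 1)
  with_seed(truth$seed * 100000L + cell_index, {
    wet <- stats::rbinom(length(dates), 1, p_wet)
    amt <- stats::rgamma(length(dates), shape = 0.9, scale = mean_amt / 0.9)
    precip <- wet * amt * mult
    tair <- 26.5 + 1.2 * dry + stats::rnorm(length(dates), 0, 0.5)
    radiation <- pmin(30, pmax(5, 16 + 4 * dry + stats::rnorm(length(dates), 0, 2)))
    rh <- pmin(100, pmax(40, 88 - 15 * dry - 4 * (1 - mult) +
                           stats::rnorm(length(dates), 0, 3)))
    wind <- pmin(10, pmax(0.2, stats::rgamma(length(dates), shape = 4, scale = 0.5)))
    data.frame(date = dates, precip = precip, tair = tair,
               radiation = radiation, rh = rh, wind = wind)
  })
}

# layer thicknesses of the default 15-layer, 2 m column
DEFAULT_LAYER_DZ <- c(0.03, 0.03, 0.04, 0.05, 0.05, 0.10, 0.10, 0.15, 0.15,
                      0.20, 0.20, 0.20, 0.20, 0.25, 0.25)

archetype_column <- function(kind, landuse, bd_jitter = 0) {
  dz <- DEFAULT_LAYER_DZ
  frac <- cumsum(dz) / sum(dz)
  if (kind == "peat") {
    bd <- pmax(0.05, 0.08 + 0.07 * frac + bd_jitter)
    om <- 0.92 - 0.07 * frac
  } else {
    bd <- pmax(0.9, 1.25 + 0.15 * frac + bd_jitter)
    om <- pmax(0.01, 0.05 - 0.04 * frac)
  }
  layers <- lapply(seq_along(dz), function(i) soil_layer(dz[i], bd[i], om[i]))
  soil_column(layers, landuse = landuse)
}

#' Generate a synthetic grid of soil columns
#'
#' Builds `n_cells` grid cells with the requested peat/mineral mixture and
#' peat land-use mix (deterministic rounding, so 50 cells at 60% peat gives
#' exactly 30 peat cells), per-cell bulk-density jitter, and 0.05-degree
#' lat/lon metadata.  Every column satisfies the layer/column invariants and
#' its [classify_profile()] classification agrees with its archetype.
#'
#' @param truth a [synthetic_truth()].
#' @param n_cells number of grid cells (>= 1).
#' @return list of cells, each a list with `cell_id`, `lat`, `lon`, `column`,
#'   `classification`, `landuse`.
#' @export
gen_grid <- function(truth, n_cells) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  n_peat <- round(n_cells * truth$peat_fraction)
  mix <- truth$landuse_mix_peat
  if (any(mix < 0)) stop("impossible land-use mixture fractions")
  lu_counts <- diff(c(0, round(cumsum(mix) * n_peat)))
  peat_lus <- rep(names(mix), lu_counts)
  landuse <- c(peat_lus, rep("non_peat_other", n_cells - n_peat))
  kind <- c(rep("peat", n_peat), rep("mineral", n_cells - n_peat))
  jit <- with_seed(truth$seed * 100000L + 99999L,
                   stats::rnorm(n_cells, 0, 0.01))
  lapply(seq_len(n_cells), function(i) {
    col <- archetype_column(kind[i], landuse[i],
                            if (kind[i] == "peat") jit[i] else jit[i] * 10)
    cls <- classify_profile(col)$classification
    stopifnot((kind[i] == "peat") == (cls == "peatland_grid"))
    list(cell_id = sprintf("c%03d", i),
         lat = 0.5 + 0.05 * ((i - 1) %/% 10),
         lon = 101 + 0.05 * ((i - 1) %% 10),
         column = col, classification = cls, landuse = landuse[i])
  })
}

#' Generate fortnightly fire counts from hydrology
#'
#' Poisson counts with rate
#' \deqn{\lambda_t = \lambda_{max}\,\mathrm{sigmoid}((wtd_t - d^*)/s)\,
#'   dryness(\theta_{ns,t}),}
#' where the dryness modifier ramps linearly from 1 (near-surface moisture at
#' or below `theta_dry`) down to `1 - dryness_weight` (at or above
#' `theta_wet`).  A saturated column (`wtd = 0`) therefore has essentially
#' zero expected fires and a deeply drained dry column approaches
#' `lambda_max`.
#'
#' @param truth a [synthetic_truth()].
#' @param wtd fortnightly mean water table depth per record, m below surface.
#' @param theta_ns fortnightly mean near-surface moisture per record.
#' @param stream integer offsetting the RNG stream (default 0).
#' @return integer fire counts, same length as `wtd`.
#' @export
gen_fire_counts <- function(truth, wtd, theta_ns, stream = 0L) {
  lam <- fire_rate(truth, wtd, theta_ns)
  with_seed(truth$seed * 100000L + 55555L + stream,
            stats::rpois(length(lam), lam))
}

#' @rdname gen_fire_counts
#' @export
fire_rate <- function(truth, wtd, theta_ns) {
  ramp <- pmin(1, pmax(0, (truth$theta_wet - theta_ns) /
                            (truth$theta_wet - truth$theta_dry)))
  dryness <- (1 - truth$dryness_weight) + truth$dryness_weight * ramp
  truth$lambda_max * stats::plogis((wtd - truth$d_star) / truth$fire_s) * dryness
}

#' Generate satellite-like observed moisture
#'
#' Adds gaussian observation noise to a true moisture series and clamps to
#' `[0, 1]`; with `sigma = 0` the series is returned unchanged.
#'
#' @param theta true moisture series.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return observation-like series in `[0, 1]`.
#' @export
gen_obs_moisture <- function(theta, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(theta)
  with_seed(seed, pmin(1, pmax(0, theta + stats::rnorm(length(theta), 0, sigma))))
}
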