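#' Fortnight calendar
#'
#' Non-overlapping 14-day blocks anchored at 1 January of each year; the short
#' remainder at the end of each year (1-2 days) is dropped.  This is the
#' two-week prediction time step of the fire models.
#'
#' @param dates vector of `Date`s.
#' @return data.frame aligned with `dates`: `year`, `step_index` (1-26 within
#'   the year, `NA` for dropped remainder days), and `block_start` date.
#' @export
fortnight_calendar <- function(dates) {
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  step <- (doy - 1L) %/% 14L + 1L
  step[step > 26L] <- NA_integer_
  block_start <- as.Date(paste0(yr, "-01-01")) + (step - 1L) * 14L
  data.frame(year = yr, step_index = step, block_start = block_start)
}

#' Aggregate daily series to fortnightly records
#'
#' Means over each 14-day block for air temperature, radiation, wind, relative
#' humidity, water table depth and near-surface moisture; sums for
#' precipitation; plus the 28-day antecedent precipitation total.  Records
#' whose antecedent window is not fully covered by the daily series are
#' dropped (see [antecedent_precip()]).
#'
#' @param daily data.frame with columns `cell_id`, `date`, `precip` (m/d, as
#'   produced by [run_grid()]), `tair`, `radiation`, `rh`, `wind`, and
#'   (optionally) `wtd`, `theta_ns`.  Must be gap-free within each block.
#' @param forcing optional data.frame carrying the weather columns if `daily`
#'   holds only hydrology (joined on `cell_id`, `date`).
#' @return data.frame of fortnight records: `cell_id`, `year`, `step_index`,
#'   `block_start`, `mean_tair`, `mean_radiation`, `mean_wind`, `mean_rh`,
#'   `sum_precip_2wk` (mm), `sum_precip_prior_4wk` (mm), and `mean_wtd`,
#'   `mean_theta_ns` when hydrology columns are present.
#' @export
aggregate_fortnights <- function(daily, forcing = NULL) {
  if (!is.null(forcing)) {
    keep <- setdiff(names(forcing), setdiff(names(daily), c("cell_id", "date")))
    daily <- merge(daily, forcing[, keep], by = c("cell_id", "date"))
  }
  need <- c("cell_id", "date", "precip", "tair", "radiation", "rh", "wind")
  if (!all(need %in% names(daily)))
    stop("daily series needs columns: ", paste(need, collapse = ", "))
  daily <- daily[order(daily$cell_id, daily$date), ]
  cal <- fortnight_calendar(daily$date)
  daily <- cbind(daily, cal)
  blk <- daily[!is.na(daily$step_index), ]
  key <- interaction(blk$cell_id, blk$year, blk$step_index, drop = TRUE)
  n_days <- tapply(blk$date, key, length)
  if (any(n_days != 14)) {
    bad <- names(n_days)[n_days != 14]
    stop("fortnight blocks with missing days: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  first <- function(v) tapply(as.character(v), key, `[`, 1L)
  hydro <- all(c("wtd", "theta_ns") %in% names(blk))
  # precip in the daily table is m/d; fortnight features are reported in mm
  rec <- data.frame(cell_id = first(blk$cell_id),
                    year = as.integer(first(blk$year)),
                    step_index = as.integer(first(blk$step_index)),
                    block_start = as.Date(first(blk$block_start)),
                    mean_tair = agg(blk$tair, mean),
                    mean_radiation = agg(blk$radiation, mean),
                    mean_wind = agg(blk$wind, mean),
                    mean_rh = agg(blk$rh, mean),
                    sum_precip_2wk = agg(blk$precip, sum) * 1000,
                    stringsAsFactors = FALSE)
  if (hydro) {
    rec$mean_wtd <- agg(blk$wtd, mean)
    rec$mean_theta_ns <- agg(blk$theta_ns, mean)
  }
  rec$sum_precip_prior_4wk <- antecedent_precip(daily, rec)
  rec <- rec[!is.na(rec$sum_precip_prior_4wk), ]
  rec <- rec[order(rec$cell_id, rec$year, rec$step_index), ]
  rownames(rec) <- NULL
  rec
}

#' Antecedent four-week precipitation
#'
#' Precipitation summed over the 28 calendar days strictly before each
#' fortnight block start, representing pre-drying.  Returns `NA` (caller drops
#' the record) when the daily series does not cover the full window.
#'
#' @param daily data.frame with `cell_id`, `date`, `precip` (m/d).
#' @param records fortnight records with `cell_id` and `block_start`.
#' @return numeric vector (mm) aligned with `records`.
#' @export
antecedent_precip <- function(daily, records) {
  out <- rep(NA_real_, nrow(records))
  for (cid in unique(records$cell_id)) {
    d <- daily[daily$cell_id == cid, ]
    d <- d[order(d$date), ]
    if (nrow(d) > 1 && any(diff(as.integer(d$date)) != 1L))
      stop("daily series for cell ", cid, " is not gap-free")
    csum <- c(0, cumsum(d$precip))
    idx <- which(records$cell_id == cid)
    # block start position within the contiguous daily series
    pos <- as.integer(records$block_start[idx] - d$date[1]) + 1L
    ok <- pos - 28L >= 1L & pos <= nrow(d) + 1L
    out[idx[ok]] <- (csum[pos[ok]] - csum[pos[ok] - 28L]) * 1000
  }
  out
}

# fixed, documented feature order of the two model variants
FEATURES_WTHR <- c("mean_tair", "mean_radiation", "mean_wind", "mean_rh",
                   "sum_precip_2wk", "sum_precip_prior_4wk")
FEATURES_HYDROL <- c("mean_wtd", "mean_theta_ns")

#' Build the fire-model design matrix
#'
#' Assembles the feature matrix for one of the two model variants: `"wthr"`
#' uses the 6 fortnightly weather aggregates (5 block aggregates + 28-day
#' antecedent precipitation); `"wthr_hydrol"` appends the 2 hydrology features
#' (`mean_wtd`, `mean_theta_ns`) for 8 columns.  The weather-only matrix is
#' exactly the first 6 columns of the weather+hydrology matrix.  Features are
#' returned in raw units; z-scoring happens per training fold inside
#' [train_loocv()].
#'
#' @param records fortnight records from [aggregate_fortnights()], with a
#'   `fire_count` column for `y` (may be absent for prediction-only use).
#' @param mode `"wthr"` or `"wthr_hydrol"`.
#' @return list with matrix `X` (6 or 8 named columns), numeric `y` (or NULL),
#'   and integer `years`.
#' @export
build_design_matrix <- function(records, mode = c("wthr", "wthr_hydrol")) {
  mode <- match.arg(mode)
  cols <- if (mode == "wthr") FEATURES_WTHR else c(FEATURES_WTHR, FEATURES_HYDROL)
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop("mode '", mode, "' needs columns absent from records: ",
         paste(missing, collapse = ", "))
  X <- as.matrix(records[, cols, drop = FALSE])
  if (nrow(X) == 0) X <- matrix(numeric(0), 0, length(cols),
                                dimnames = list(NULL, cols))
  y <- if ("fire_count" %in% names(records)) as.numeric(records$fire_count) else NULL
  list(X = X, y = y, years = as.integer(records$year))
}
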