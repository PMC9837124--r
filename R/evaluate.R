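#' Pool fire counts over peatland and non-peatland subsets
#'
#' Sums predicted and observed counts per fortnight over all cells of each
#' subset, the aggregation at which the fire models are scored.  Subset sums
#' add up to the whole-grid sums each fortnight.
#'
#' @param pred,obs numeric vectors aligned per (cell, fortnight) record.
#' @param cell_id cell identifier per record.
#' @param fortnight fortnight identifier per record (e.g. `year * 100 +
#'   step_index`); pooled series are ordered by this value.
#' @param is_peat logical per record: cell classified `peatland_grid`.
#' @return list with data.frames `peat`, `non_peat`, `all`, each with columns
#'   `fortnight`, `pred`, `obs`.
#' @export
pool_counts <- function(pred, obs, cell_id, fortnight, is_peat) {
  n <- length(pred)
  if (length(obs) != n || length(cell_id) != n || length(fortnight) != n ||
      length(is_peat) != n)
    stop("pool_counts inputs are misaligned (differing lengths)")
  pool <- function(keep) {
    if (!any(keep)) {
      warning("empty subset in pool_counts")
      return(data.frame(fortnight = numeric(0), pred = numeric(0),
                        obs = numeric(0)))
    }
    f <- fortnight[keep]
    data.frame(fortnight = sort(unique(f)),
               pred = as.numeric(tapply(pred[keep], f, sum)),
               obs = as.numeric(tapply(obs[keep], f, sum)))
  }
  list(peat = pool(is_peat), non_peat = pool(!is_peat),
       all = pool(rep(TRUE, n)))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} of predictions against observations.
#' Can be negative for predictions worse than the observation mean.
#'
#' @param pred,obs equal-length numeric vectors (length >= 3).
#' @return R-squared, `<= 1`.
#' @export
r2 <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (length(obs) < 3) stop("r2 needs at least 3 points")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot < 1e-300) stop("r2 undefined: observations have zero variance")
  1 - sum((pred - obs)^2) / ss_tot
}

#' Mean absolute error
#'
#' @param pred,obs equal-length numeric vectors.
#' @return mean of `|pred - obs|` (counts per two-week step when applied to
#'   pooled fortnightly series).
#' @export
mae <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (length(obs) < 1) stop("mae needs at least 1 point")
  mean(abs(pred - obs))
}

#' First differences of a fortnightly series
#'
#' Time-differenced counts \eqn{n_{t+1} - n_t}, used to score the timing of
#' predicted fire peaks.
#'
#' @param series numeric vector, length >= 2.
#' @return vector of length `length(series) - 1`.
#' @export
time_difference <- function(series) {
  if (length(series) < 2) stop("time_difference needs length >= 2")
  diff(series)
}

#' Estimate the fire-occurrence water table threshold
#'
#' Scans candidate depths 0.00-1.00 m (0.01 m steps) and returns the depth
#' maximizing Youden's J (= sensitivity + specificity - 1) for classifying
#' fire fortnights by `wtd >= depth` (deeper water table = drier = fire).
#' Ties are broken toward the shallower depth.
#'
#' @param wtd fortnightly mean water table depth per record, m below surface.
#' @param fire_event logical (or 0/1) fire-event indicator per record.
#' @param candidates candidate depth grid, m.
#' @return list with `threshold` (m), `J` (Youden's J at the optimum), and
#'   logical `informative` (`FALSE` when max J is indistinguishable from
#'   chance, < 0.05).
#' @export
estimate_wtd_threshold <- function(wtd, fire_event,
                                   candidates = seq(0, 1, by = 0.01)) {
  fire_event <- as.logical(fire_event)
  if (length(wtd) != length(fire_event)) stop("inputs misaligned")
  n_pos <- sum(fire_event)
  n_neg <- sum(!fire_event)
  if (n_pos == 0 || n_neg == 0)
    stop("threshold estimation needs both fire and no-fire records")
  j <- vapply(candidates, function(c0) {
    sens <- sum(wtd[fire_event] >= c0) / n_pos
    spec <- sum(wtd[!fire_event] < c0) / n_neg
    sens + spec - 1
  }, numeric(1))
  best <- which.max(j)  # first maximum = shallowest under ties
  list(threshold = candidates[best], J = j[best], informative = j[best] >= 0.05)
}

#' Per-cell correlation of modelled and observed daily moisture
#'
#' Pearson correlation between modelled and observed near-surface moisture per
#' cell, with subset medians for peatland, non-peatland and all cells -- the
#' satellite-benchmark statistic of the hydrology module.  Cells with constant
#' series (undefined correlation) are excluded with a warning.
#'
#' @param modelled,observed numeric vectors aligned per (cell, day); >= 30
#'   paired days per cell required.
#' @param cell_id cell identifier per record.
#' @param is_peat logical per record.
#' @return list with data.frame `per_cell` (`cell_id`, `r`, `is_peat`) and
#'   named numeric `medians` (`peat`, `non_peat`, `all`).
#' @export
daily_correlation <- function(modelled, observed, cell_id, is_peat) {
  n <- length(modelled)
  if (length(observed) != n || length(cell_id) != n || length(is_peat) != n)
    stop("daily_correlation inputs are misaligned")
  cells <- unique(cell_id)
  rows <- lapply(cells, function(cid) {
    k <- cell_id == cid
    if (sum(k) < 30) stop("cell ", cid, " has < 30 paired days")
    if (stats::sd(modelled[k]) < 1e-12 || stats::sd(observed[k]) < 1e-12) {
      warning("cell ", cid, " excluded: constant series, correlation undefined")
      return(NULL)
    }
    data.frame(cell_id = cid, r = stats::cor(modelled[k], observed[k]),
               is_peat = is_peat[k][1])
  })
  per_cell <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  med <- function(k) if (any(k)) stats::median(per_cell$r[k]) else NA_real_
  list(per_cell = per_cell,
       medians = c(peat = med(per_cell$is_peat),
                   non_peat = med(!per_cell$is_peat),
                   all = med(rep(TRUE, nrow(per_cell)))))
}

#' Evaluation report for a pair of fire-model fits
#'
#' Scores out-of-sample predictions against observed counts on pooled
#' fortnightly series: per-year and pooled R-squared and MAE, time-differenced
#' R-squared, per-cell mean-annual residual summaries split by peatland class,
#' and the Youden-J water-table fire threshold.
#'
#' @param fit a [train_loocv()] fit.
#' @param records the fortnight records the fit was trained on (must carry
#'   `cell_id`, `year`, `step_index`, `fire_count`, `mean_wtd`).
#' @param is_peat logical per record.
#' @return list of class `evaluation_report`.
#' @export
evaluation_report <- function(fit, records, is_peat) {
  stopifnot(nrow(records) == length(fit$oos))
  fortnight <- records$year * 100 + records$step_index
  pooled <- pool_counts(fit$oos, records$fire_count, records$cell_id,
                        fortnight, is_peat)
  score <- function(s) {
    if (nrow(s) < 3) return(c(r2 = NA_real_, mae = NA_real_, r2_diff = NA_real_))
    c(r2 = r2(s$pred, s$obs), mae = mae(s$pred, s$obs),
      r2_diff = r2(time_difference(s$pred), time_difference(s$obs)))
  }
  per_year <- t(vapply(sort(unique(records$year)), function(yy) {
    s <- pooled$all[pooled$all$fortnight %/% 100 == yy, ]
    c(year = yy, score(s))
  }, numeric(4)))
  resid <- records$fire_count - fit$oos
  ann <- stats::aggregate(resid,
                          by = list(cell_id = records$cell_id,
                                    year = records$year,
                                    is_peat = is_peat), FUN = mean)
  resid_summary <- lapply(split(ann$x, ann$is_peat), function(v)
    stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95)))
  thr <- estimate_wtd_threshold(records$mean_wtd, records$fire_count > 0)
  structure(list(pooled = lapply(pooled, score), per_year = as.data.frame(per_year),
                 residual_quantiles = resid_summary, wtd_threshold = thr,
                 series = pooled),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n  pooled fortnightly series (all cells):\n")
  p <- x$pooled$all
  cat(sprintf("    R2 %.3f | time-differenced R2 %.3f | MAE %.2f counts/fortnight\n",
              p["r2"], p["r2_diff"], p["mae"]))
  cat(sprintf("  fire WTD threshold: %.2f m (J = %.2f%s)\n",
              x$wtd_threshold$threshold, x$wtd_threshold$J,
              if (x$wtd_threshold$informative) "" else ", uninformative"))
  invisible(x)
}
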