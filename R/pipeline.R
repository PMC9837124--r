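#' Run the full synthetic pipeline
#'
#' Convenience driver used by the examples, the command-line interface and the
#' acceptance checks: generate a synthetic grid and forcing, simulate the
#' hydrology of every cell (spin-up + production years), aggregate to
#' fortnight records, draw fire counts from the synthetic truth, and
#' (optionally) train and score the two fire-model variants.
#'
#' @param truth a [synthetic_truth()].
#' @param n_cells number of grid cells.
#' @param config a [run_config()]; its period should cover `truth$years`.
#' @param train if `TRUE`, fit both ANN variants with [train_loocv()] and
#'   attach an [evaluation_report()].
#' @return list with `cells`, `daily` (per-cell daily hydrology + weather),
#'   `records` (fortnight records incl. `fire_count`), `is_peat` (per record),
#'   and when `train = TRUE`: `fit_wthr`, `fit_hydrol`, `report`.
#' @export
peatfire_pipeline <- function(truth = synthetic_truth(), n_cells = 50,
                              config = NULL, train = FALSE) {
  if (is.null(config))
    config <- run_config(start = as.Date(paste0(min(truth$years), "-01-01")),
                         end = as.Date(paste0(max(truth$years), "-12-31")),
                         seed = truth$seed)
  cells <- gen_grid(truth, n_cells)
  forcing <- do.call(rbind, lapply(seq_along(cells), function(i)
    cbind(cell_id = cells[[i]]$cell_id, gen_weather(truth, i))))
  daily <- run_grid(cells, forcing, config)
  daily <- merge(daily,
                 forcing[, c("cell_id", "date", "tair", "radiation", "rh", "wind")],
                 by = c("cell_id", "date"))
  records <- aggregate_fortnights(daily)
  records$fire_count <- gen_fire_counts(truth, records$mean_wtd,
                                        records$mean_theta_ns)
  peat_cells <- vapply(cells, function(c) c$classification == "peatland_grid",
                       logical(1))
  names(peat_cells) <- vapply(cells, `[[`, character(1), "cell_id")
  is_peat <- unname(peat_cells[records$cell_id])
  out <- list(truth = truth, cells = cells, daily = daily,
              records = records, is_peat = is_peat, config = config)
  if (train) {
    dw <- build_design_matrix(records, "wthr")
    dh <- build_design_matrix(records, "wthr_hydrol")
    out$fit_wthr <- train_loocv(dw$X, dw$y, dw$years, seed = truth$seed)
    out$fit_hydrol <- train_loocv(dh$X, dh$y, dh$years, seed = truth$seed)
    out$report <- evaluation_report(out$fit_hydrol, records, is_peat)
  }
  out
}

#' Pooled out-of-sample skill of the two model variants
#'
#' Fortnightly counts are summed over all cells and the out-of-sample
#' R-squared of each variant is computed on the pooled series, the headline
#' comparison between the weather-only and weather+hydrology models.
#'
#' @param pipe result of [peatfire_pipeline()] with `train = TRUE`.
#' @return named numeric: pooled `r2_wthr`, `r2_hydrol`, `mae_wthr`,
#'   `mae_hydrol`.
#' @export
pooled_skill <- function(pipe) {
  rec <- pipe$records
  fortnight <- rec$year * 100 + rec$step_index
  s_w <- pool_counts(pipe$fit_wthr$oos, rec$fire_count, rec$cell_id,
                     fortnight, pipe$is_peat)$all
  s_h <- pool_counts(pipe$fit_hydrol$oos, rec$fire_count, rec$cell_id,
                     fortnight, pipe$is_peat)$all
  c(r2_wthr = r2(s_w$pred, s_w$obs), r2_hydrol = r2(s_h$pred, s_h$obs),
    mae_wthr = mae(s_w$pred, s_w$obs), mae_hydrol = mae(s_h$pred, s_h$obs))
}
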