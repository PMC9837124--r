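#' Fire-count network specification
#'
#' The fixed four-layer regression network used for fortnightly fire counts:
#' an input layer of 6 (weather-only) or 8 (weather + hydrology) features, two
#' hidden layers of 32 and 16 relu neurons, and a linear output neuron.  Loss
#' is mean squared error, optimised with Adam at learning rate 0.001; training
#' uses mini-batches and early stopping on an internal validation split.
#'
#' @param n_features number of input features, 6 or 8.
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience, epochs without validation
#'   improvement.
#' @param val_fraction fraction of training rows held as the internal
#'   early-stopping validation set (taken deterministically, stratified by
#'   year).
#' @param seed integer seed for weight initialisation and batch shuffling.
#' @return list of class `network_spec` with `layer_sizes = c(n_features, 32, 16, 1)`.
#' @export
build_network <- function(n_features, learning_rate = 0.001, batch_size = 256,
                          max_epochs = 500, patience = 20, val_fraction = 0.1,
                          seed = 1L) {
  if (!n_features %in% c(6L, 8L))
    stop("n_features must be 6 (weather) or 8 (weather + hydrology), got ",
         n_features)
  structure(list(layer_sizes = c(as.integer(n_features), 32L, 16L, 1L),
                 hidden_activation = "relu", loss = "mse", optimizer = "adam",
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "network_spec")
}

# deterministic internal validation indices: every k-th row within each year,
# so a fold's fit depends only on its own training rows (fold hygiene)
val_split_idx <- function(years, val_fraction) {
  k <- max(2L, round(1 / val_fraction))
  idx <- integer(0)
  for (y in sort(unique(years))) {
    rows <- which(years == y)
    idx <- c(idx, rows[seq_along(rows) %% k == 0L])
  }
  sort(idx)
}

#' Fit one cross-validation fold
#'
#' Trains the network on all rows whose year differs from `held_out_year`.
#' Feature scaling constants (column mean/sd) are computed on those training
#' rows only.  The seed is derived from `spec$seed` and the held-out year, so
#' the fitted weights depend only on the training rows -- deleting the
#' held-out rows beforehand leaves the fit bit-identical.
#'
#' @param X numeric feature matrix (raw units).
#' @param y numeric fire counts.
#' @param years integer year label per row.
#' @param held_out_year the year excluded from fitting and scaling.
#' @param spec a [build_network()] specification.
#' @return list of class `trained_fold`: `held_out_year`, `weights`, `biases`,
#'   `center`, `scale`, `epochs`, `best_epoch`, `val_mse`.
#' @export
fit_fire_fold <- function(X, y, years, held_out_year, spec) {
  tr <- years != held_out_year
  Xtr <- X[tr, , drop = FALSE]
  ytr <- y[tr]
  ytr_years <- years[tr]
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
  vi <- val_split_idx(ytr_years, spec$val_fraction)
  ti <- setdiff(seq_len(nrow(Xs)), vi)
  fit <- .mlp_fit_cpp(Xs[ti, , drop = FALSE], ytr[ti],
                      Xs[vi, , drop = FALSE], ytr[vi],
                      spec$layer_sizes[2], spec$layer_sizes[3],
                      spec$learning_rate, spec$batch_size,
                      spec$max_epochs, spec$patience,
                      spec$seed + as.integer(held_out_year) %% 100000L)
  structure(list(held_out_year = as.integer(held_out_year),
                 weights = fit$weights, biases = fit$biases,
                 center = ctr, scale = scl,
                 epochs = fit$epochs, best_epoch = fit$best_epoch,
                 val_mse = fit$val_mse),
            class = "trained_fold")
}

#' Predict fire counts from a trained fold
#'
#' Applies the fold's feature scaling and network; negative raw outputs are
#' clipped to zero (counts are nonnegative).
#'
#' @param object a `trained_fold`.
#' @param X feature matrix with the width the fold was trained on.
#' @param ... unused.
#' @return nonnegative numeric predictions.
#' @export
predict.trained_fold <- function(object, X, ...) {
  if (ncol(X) != length(object$center))
    stop("feature width ", ncol(X), " does not match fold width ",
         length(object$center))
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  pmax(.mlp_predict_cpp(object$weights, object$biases, Xs), 0)
}

#' Leave-one-year-out training of a fire-count network
#'
#' Trains one network per calendar year, holding that year's records out, and
#' assembles out-of-sample predictions: every record is predicted exactly once,
#' by the fold that never saw its year during fitting or scaling.
#'
#' @param X numeric feature matrix (6 or 8 named columns, raw units; see
#'   [build_design_matrix()]).
#' @param y numeric fire counts per record.
#' @param years integer year label per record (need >= 2 distinct years).
#' @param spec a [build_network()] specification (default built for
#'   `ncol(X)` with `seed`).
#' @param seed seed used when `spec` is not supplied.
#' @return object of class `fire_loocv`: list with `folds` (one
#'   `trained_fold` per year), `oos` (out-of-sample predictions aligned with
#'   rows), `y`, `years`, `spec`.
#' @export
#' @examples
#' \donttest{
#' set.seed(1)
#' X <- matrix(rnorm(1200), ncol = 6,
#'             dimnames = list(NULL, c("a","b","c","d","e","f")))
#' y <- pmax(X %*% rnorm(6) + 3, 0)
#' fit <- train_loocv(X, y, years = rep(2008:2011, each = 50))
#' summary(fit)
#' }
train_loocv <- function(X, y, years, spec = NULL, seed = 1L) {
  if (anyNA(X)) stop("NAs in feature matrix")
  if (length(y) != nrow(X) || length(years) != nrow(X))
    stop("X, y, years must align")
  yrs <- sort(unique(years))
  if (length(yrs) < 2) stop("leave-one-year-out needs >= 2 distinct years")
  if (is.null(spec)) spec <- build_network(ncol(X), seed = seed)
  if (spec$layer_sizes[1] != ncol(X))
    stop("spec expects ", spec$layer_sizes[1], " features, X has ", ncol(X))
  folds <- lapply(yrs, function(yy) fit_fire_fold(X, y, years, yy, spec))
  names(folds) <- yrs
  oos <- rep(NA_real_, length(y))
  for (f in folds) {
    rows <- which(years == f$held_out_year)
    oos[rows] <- predict(f, X[rows, , drop = FALSE])
  }
  structure(list(folds = folds, oos = oos, y = as.numeric(y),
                 years = as.integer(years), spec = spec,
                 feature_names = colnames(X)),
            class = "fire_loocv")
}

#' @export
print.fire_loocv <- function(x, ...) {
  cat("<fire_loocv>", length(x$folds), "leave-one-year-out folds,",
      x$spec$layer_sizes[1], "features,", length(x$y), "records\n")
  cat(sprintf("  out-of-sample R2 (record level): %.3f, MAE: %.3f\n",
              r2(x$oos, x$y), mae(x$oos, x$y)))
  invisible(x)
}

#' @export
summary.fire_loocv <- function(object, ...) {
  per_year <- t(vapply(object$folds, function(f) {
    rows <- object$years == f$held_out_year
    c(year = f$held_out_year,
      n = sum(rows),
      r2 = r2(object$oos[rows], object$y[rows]),
      mae = mae(object$oos[rows], object$y[rows]),
      epochs = f$best_epoch)
  }, numeric(5)))
  out <- list(per_year = as.data.frame(per_year),
              pooled_r2 = r2(object$oos, object$y),
              pooled_mae = mae(object$oos, object$y),
              spec = object$spec)
  class(out) <- "summary.fire_loocv"
  out
}

#' @export
print.summary.fire_loocv <- function(x, ...) {
  cat("Leave-one-year-out fire-count network (",
      paste(x$spec$layer_sizes, collapse = "-"), ")\n", sep = "")
  print(round(x$per_year, 3), row.names = FALSE)
  cat(sprintf("record-level out-of-sample R2 %.3f, MAE %.3f\n",
              x$pooled_r2, x$pooled_mae))
  invisible(x)
}

#' Predict from a leave-one-year-out fit
#'
#' For rows labelled with a year that has a fold, that fold (out-of-sample for
#' its year) is used; other rows get the mean prediction across folds.
#' Omitting `newdata` returns the stored out-of-sample predictions.
#'
#' @param object a `fire_loocv` fit.
#' @param newdata feature matrix.
#' @param years optional year labels for `newdata`.
#' @param ... unused.
#' @return nonnegative predictions.
#' @export
predict.fire_loocv <- function(object, newdata = NULL, years = NULL, ...) {
  if (is.null(newdata)) return(object$oos)
  preds <- matrix(0, nrow(newdata), length(object$folds))
  for (j in seq_along(object$folds))
    preds[, j] <- predict(object$folds[[j]], newdata)
  out <- rowMeans(preds)
  if (!is.null(years)) {
    for (j in seq_along(object$folds)) {
      rows <- which(years == object$folds[[j]]$held_out_year)
      if (length(rows)) out[rows] <- preds[rows, j]
    }
  }
  out
}

#' @export
fitted.fire_loocv <- function(object, ...) object$oos

#' @export
residuals.fire_loocv <- function(object, ...) object$y - object$oos

#' @export
plot.fire_loocv <- function(x, ...) {
  graphics::plot(x$oos, x$y, xlab = "predicted fire count (out-of-sample)",
                 ylab = "observed fire count", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
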