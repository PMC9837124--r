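#' Soil water retention: van Genuchten moisture at a given suction
#'
#' Evaluates the van Genuchten (1980) retention curve
#' \deqn{\theta(\psi) = \theta_r + (\theta_s-\theta_r)\,[1+(\alpha\psi)^n]^{-m},
#'   \quad m = 1 - 1/n,}
#' the closed monotone family used throughout the package to describe how much
#' water a peat or mineral layer holds at suction head \eqn{\psi} (m of water,
#' positive for unsaturated conditions).
#'
#' @param layer a [soil_layer()] (fields `theta_r`, `theta_s`, `vg_alpha`,
#'   `vg_n` are used).
#' @param psi suction head in m, `>= 0` (0 = saturation). Vectorised.
#' @return volumetric moisture content(s), m3/m3, in `(theta_r, theta_s]`.
#' @seealso [psi_of_theta()] for the inverse, [k_unsat()] for the matching
#'   Mualem conductivity.
#' @export
#' @examples
#' ly <- soil_layer(0.1, bulk_density = 0.1, om_fraction = 0.9,
#'                  theta_r = 0.1, theta_s = 0.8, vg_alpha = 2, vg_n = 2, ksat = 1)
#' theta_of_psi(ly, 0.5)  # ~0.595
theta_of_psi <- function(layer, psi) {
  if (any(psi < 0)) stop("suction head psi must be >= 0")
  m <- 1 - 1 / layer$vg_n
  se <- (1 + (layer$vg_alpha * psi)^layer$vg_n)^(-m)
  layer$theta_r + (layer$theta_s - layer$theta_r) * se
}

#' Inverse retention: suction at a given moisture content
#'
#' @param layer a [soil_layer()].
#' @param theta volumetric moisture in `(theta_r, theta_s]`. Vectorised.
#' @return suction head in m (0 at saturation).
#' @export
psi_of_theta <- function(layer, theta) {
  if (any(theta <= layer$theta_r) || any(theta > layer$theta_s))
    stop("theta must lie in (theta_r, theta_s]")
  m <- 1 - 1 / layer$vg_n
  se <- (theta - layer$theta_r) / (layer$theta_s - layer$theta_r)
  (se^(-1 / m) - 1)^(1 / layer$vg_n) / layer$vg_alpha
}

#' Unsaturated hydraulic conductivity (Mualem closure)
#'
#' Mualem (1976) conductivity for the van Genuchten retention curve,
#' \deqn{K(\theta) = K_{sat}\sqrt{S_e}\,[1-(1-S_e^{1/m})^m]^2,}
#' with effective saturation \eqn{S_e = (\theta-\theta_r)/(\theta_s-\theta_r)}.
#'
#' @param layer a [soil_layer()].
#' @param theta volumetric moisture in `[theta_r, theta_s]`. Vectorised.
#' @return conductivity in m/d, between 0 (at `theta_r`) and `ksat` (at
#'   `theta_s`), monotone nondecreasing in `theta`.
#' @export
k_unsat <- function(layer, theta) {
  if (any(theta < layer$theta_r - 1e-12) || any(theta > layer$theta_s + 1e-12))
    stop("theta outside [theta_r, theta_s]")
  m <- 1 - 1 / layer$vg_n
  se <- pmin(1, pmax(0, (theta - layer$theta_r) / (layer$theta_s - layer$theta_r)))
  layer$ksat * sqrt(se) * (1 - (1 - se^(1 / m))^m)^2
}

#' Fit van Genuchten retention parameters to (suction, moisture) samples
#'
#' Least-squares estimation of `(theta_r, theta_s, vg_alpha, vg_n)` from
#' laboratory-style retention samples, the per-layer "parameter optimization"
#' step used to localise the retention curve to each grid cell.  Uses
#' box-constrained Levenberg-Marquardt ([minpack.lm::nlsLM()]).
#'
#' @param psi suction heads, m (need >= 4 distinct values spanning wet and dry).
#' @param theta matching volumetric moistures.
#' @return named list `theta_r`, `theta_s`, `vg_alpha`, `vg_n` satisfying
#'   `0 <= theta_r < theta_s <= 1`, `vg_alpha > 0`, `vg_n > 1`.
#' @export
#' @examples
#' psi <- c(0, 0.05, 0.1, 0.3, 1, 3, 10, 50)
#' ly <- soil_layer(0.1, 0.1, 0.9, theta_r = 0.15, theta_s = 0.85,
#'                  vg_alpha = 3, vg_n = 1.5, ksat = 1)
#' fit_retention(psi, theta_of_psi(ly, psi))
fit_retention <- function(psi, theta) {
  if (length(psi) != length(theta)) stop("psi and theta lengths differ")
  if (length(unique(psi)) < 4)
    stop("retention fit needs >= 4 distinct suction values (got ",
         length(unique(psi)), ")")
  if (diff(range(theta)) < 1e-8)
    stop("retention fit is degenerate: all moisture values equal (",
         signif(theta[1], 4), ")")
  dat <- data.frame(psi = psi, theta = theta)
  # multi-start over plausible (alpha, n) pairs; keep the best least-squares fit
  best <- NULL
  best_ss <- Inf
  for (a0 in c(0.5, 2, 8)) for (n0 in c(1.2, 1.6, 2.5)) {
    start <- list(tr = max(0, min(theta) * 0.8),
                  ts = min(1, max(theta) * 1.02),
                  la = log(a0), ln = log(n0 - 1))
    fit <- try(minpack.lm::nlsLM(
      theta ~ tr + (ts - tr) * (1 + (exp(la) * psi)^(1 + exp(ln)))^(-(1 - 1 / (1 + exp(ln)))),
      data = dat, start = start,
      lower = c(tr = 0, ts = max(theta), la = log(1e-3), ln = log(1e-3)),
      upper = c(tr = min(theta), ts = 1, la = log(1e3), ln = log(20)),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ss <- sum(stats::residuals(fit)^2)
    if (ss < best_ss) { best_ss <- ss; best <- fit }
  }
  if (is.null(best)) stop("retention fit failed to converge from any start")
  cf <- stats::coef(best)
  out <- list(theta_r = unname(cf["tr"]), theta_s = unname(cf["ts"]),
              vg_alpha = unname(exp(cf["la"])), vg_n = unname(1 + exp(cf["ln"])))
  if (out$theta_r >= out$theta_s)
    stop("retention fit failed: theta_r >= theta_s")
  out
}

#' Pedo-transfer function for saturated hydraulic conductivity
#'
#' Maps dry bulk density and organic-matter fraction to saturated hydraulic
#' conductivity.  Peat layers use a log-linear decrease with bulk density
#' (`10^(a - b*BD)`, defaults `a = 2`, `b = 13`: loose fibric peat near
#' 0.08 Mg/m3 conducts ~9 m/d, dense sapric peat near 0.2 Mg/m3 ~0.1 m/d);
#' mineral layers use a bulk-density/organic-matter regression
#' (`10^(c - d*BD + e*OM)`).  Output is clamped to a configurable floor and
#' ceiling.  Lateral conductivity is taken identical to this vertical value.
#'
#' @param bulk_density dry bulk density, Mg/m3 (> 0). Vectorised.
#' @param om_fraction organic matter mass fraction, 0-1.
#' @param is_peat logical, peat-layer flag (organic matter > 0.65).
#' @param coef named list overriding the default coefficients
#'   `peat_a`, `peat_b`, `min_c`, `min_d`, `min_e`, `floor`, `ceiling`.
#' @return saturated conductivity, m/d, strictly decreasing in bulk density
#'   within each soil kind (until clamped).
#' @export
pedotransfer_ksat <- function(bulk_density, om_fraction, is_peat,
                              coef = list()) {
  if (any(bulk_density <= 0)) stop("bulk_density must be > 0")
  cf <- utils::modifyList(list(peat_a = 2.0, peat_b = 13.0,
                               min_c = 1.2, min_d = 1.2, min_e = 2.0,
                               floor = 0.001, ceiling = 50), coef)
  k <- ifelse(is_peat,
              10^(cf$peat_a - cf$peat_b * bulk_density),
              10^(cf$min_c - cf$min_d * bulk_density + cf$min_e * om_fraction))
  pmin(cf$ceiling, pmax(cf$floor, k))
}

#' Pedo-transfer defaults for van Genuchten retention parameters
#'
#' Fills retention parameters from bulk density and organic matter when no
#' fitted values are supplied: porous, highly retentive curves for peat and a
#' loam-like curve for mineral soil, with saturated content decreasing in bulk
#' density.
#'
#' @inheritParams pedotransfer_ksat
#' @return data.frame with columns `theta_r`, `theta_s`, `vg_alpha`, `vg_n`.
#' @export
pedotransfer_retention <- function(bulk_density, om_fraction, is_peat) {
  n <- max(length(bulk_density), length(om_fraction), length(is_peat))
  bulk_density <- rep_len(bulk_density, n)
  is_peat <- rep_len(is_peat, n)
  theta_s <- ifelse(is_peat,
                    pmin(0.95, pmax(0.70, 0.97 - 0.5 * bulk_density)),
                    pmin(0.60, pmax(0.30, 0.83 - 0.35 * bulk_density)))
  data.frame(theta_r = ifelse(is_peat, 0.10, 0.06),
             theta_s = theta_s,
             vg_alpha = ifelse(is_peat, 6.0, 3.6),
             vg_n = ifelse(is_peat, 1.35, 1.56))
}

# head (m) conventions used for the tipping-bucket thresholds
PSI_FIELD_CAPACITY <- 0.34  # ~3.3 kPa
PSI_WILTING <- 153          # ~1.5 MPa
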