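#' Construct a soil layer
#'
#' One horizontal layer of a simulated soil column.  Hydraulic parameters
#' (`theta_r`, `theta_s`, `vg_alpha`, `vg_n`, `ksat`) may be omitted, in which
#' case they are filled by the package pedo-transfer functions
#' ([pedotransfer_retention()], [pedotransfer_ksat()]) from bulk density and
#' organic matter.  A layer is a peat layer when its organic matter fraction
#' exceeds 0.65.
#'
#' @param thickness layer thickness, m (> 0).
#' @param bulk_density dry bulk density, Mg/m3 (> 0).
#' @param om_fraction organic matter mass fraction, 0-1.
#' @param theta_r,theta_s residual and saturated volumetric moisture, m3/m3.
#' @param vg_alpha van Genuchten alpha, 1/m.
#' @param vg_n van Genuchten n (> 1).
#' @param ksat saturated hydraulic conductivity, m/d.
#' @return an object of class `soil_layer`.
#' @export
soil_layer <- function(thickness, bulk_density, om_fraction,
                       theta_r = NULL, theta_s = NULL,
                       vg_alpha = NULL, vg_n = NULL, ksat = NULL) {
  if (thickness <= 0) stop("thickness must be > 0")
  if (bulk_density <= 0) stop("bulk_density must be > 0")
  if (om_fraction < 0 || om_fraction > 1) stop("om_fraction must be in [0, 1]")
  is_peat <- om_fraction > 0.65
  if (is.null(theta_r) || is.null(theta_s) || is.null(vg_alpha) || is.null(vg_n)) {
    pt <- pedotransfer_retention(bulk_density, om_fraction, is_peat)
    if (is.null(theta_r)) theta_r <- pt$theta_r
    if (is.null(theta_s)) theta_s <- pt$theta_s
    if (is.null(vg_alpha)) vg_alpha <- pt$vg_alpha
    if (is.null(vg_n)) vg_n <- pt$vg_n
  }
  if (is.null(ksat)) ksat <- pedotransfer_ksat(bulk_density, om_fraction, is_peat)
  if (!(theta_r >= 0 && theta_r < theta_s && theta_s <= 1))
    stop("need 0 <= theta_r < theta_s <= 1")
  if (vg_n <= 1) stop("vg_n must be > 1")
  if (ksat <= 0) stop("ksat must be > 0")
  structure(list(thickness = thickness, bulk_density = bulk_density,
                 om_fraction = om_fraction, theta_r = theta_r,
                 theta_s = theta_s, vg_alpha = vg_alpha, vg_n = vg_n,
                 ksat = ksat, is_peat = is_peat),
            class = "soil_layer")
}

#' Construct a soil column
#'
#' A stand-alone, vertically layered soil profile (surface down) with a thin
#' surface litter layer, a land-use class, and a lateral boundary water table
#' depth (WTDx) that drives Darcy exchange with the surrounding watershed or
#' drainage canal.
#'
#' @param layers list of [soil_layer()] objects, ordered surface-down
#'   (15 layers in the default grids).
#' @param landuse one of `"pristine_forest"`, `"degraded_forest"`,
#'   `"industrial_plantation"`, `"smallholder"`, `"mangrove"`,
#'   `"non_peat_other"`.
#' @param litter_thickness surface litter layer thickness, m (default 0.02).
#' @param wtdx boundary water table depth, m below surface (positive down);
#'   `NA` to assign later via [assign_boundary_wtdx()].
#' @param lateral_length effective lateral flow distance to the boundary, m.
#' @return an object of class `soil_column`; `total_depth` is the summed layer
#'   thickness.
#' @export
soil_column <- function(layers, landuse = "non_peat_other",
                        litter_thickness = 0.02, wtdx = NA_real_,
                        lateral_length = 100) {
  if (length(layers) == 0) stop("invalid profile: empty layer list")
  if (!all(vapply(layers, inherits, logical(1), "soil_layer")))
    stop("layers must all be soil_layer objects")
  landuse <- match.arg(landuse, LANDUSE_LEVELS)
  if (!is.na(wtdx) && wtdx < 0) stop("wtdx must be >= 0 (m below surface)")
  if (lateral_length <= 0) stop("lateral_length must be > 0")
  structure(list(layers = layers, landuse = landuse,
                 litter_thickness = litter_thickness,
                 total_depth = sum(vapply(layers, `[[`, numeric(1), "thickness")),
                 wtdx = wtdx, lateral_length = lateral_length),
            class = "soil_column")
}

LANDUSE_LEVELS <- c("pristine_forest", "degraded_forest",
                    "industrial_plantation", "smallholder",
                    "mangrove", "non_peat_other")

# per-layer parameter vectors, for the compiled stepper
column_params <- function(column) {
  g <- function(f) vapply(column$layers, `[[`, numeric(1), f)
  dz <- g("thickness")
  out <- list(dz = dz, theta_r = g("theta_r"), theta_s = g("theta_s"),
              vg_alpha = g("vg_alpha"), vg_n = g("vg_n"), ksat = g("ksat"))
  m <- 1 - 1 / out$vg_n
  se_fc <- (1 + (out$vg_alpha * PSI_FIELD_CAPACITY)^out$vg_n)^(-m)
  se_w <- (1 + (out$vg_alpha * PSI_WILTING)^out$vg_n)^(-m)
  out$theta_fc <- out$theta_r + (out$theta_s - out$theta_r) * se_fc
  out$theta_wilt <- out$theta_r + (out$theta_s - out$theta_r) * se_w
  out
}

#' Classify a soil profile as peatland or non-peatland
#'
#' A layer is peat when its organic matter fraction exceeds 0.65.  A column is
#' a `peatland_grid` when every layer whose top lies above 0.3 m depth is peat
#' and the profile reaches at least 0.3 m, i.e. the profile is continuously
#' peat from the surface down to 0.3 m or deeper; otherwise it is a
#' `non_peatland_grid`.
#'
#' @param column a [soil_column()].
#' @return list with `classification` (`"peatland_grid"` or
#'   `"non_peatland_grid"`) and logical `layer_is_peat`.
#' @export
#' @examples
#' peat <- soil_column(replicate(5, soil_layer(0.2, 0.1, 0.9), simplify = FALSE))
#' classify_profile(peat)$classification
classify_profile <- function(column) {
  if (!inherits(column, "soil_column")) stop("column must be a soil_column")
  flags <- vapply(column$layers, `[[`, logical(1), "is_peat")
  tops <- cumsum(c(0, vapply(column$layers, `[[`, numeric(1), "thickness")))
  tops <- tops[-length(tops)]
  upper <- tops < 0.3 - 1e-12
  peaty <- column$total_depth >= 0.3 - 1e-12 && all(flags[upper])
  list(classification = if (peaty) "peatland_grid" else "non_peatland_grid",
       layer_is_peat = flags)
}

#' Initial column state
#'
#' Moisture state used to start a simulation: each layer at a uniform suction
#' (field capacity by default), litter at its field capacity, no ponded water.
#'
#' @param column a [soil_column()].
#' @param psi initial uniform suction head, m (default the field-capacity
#'   suction, 0.34 m).
#' @return object of class `column_state` with per-layer `theta`,
#'   `litter_theta`, `ponded`, and diagnosed `wtd`.
#' @export
initial_state <- function(column, psi = PSI_FIELD_CAPACITY) {
  theta <- vapply(column$layers, function(ly) theta_of_psi(ly, psi), numeric(1))
  st <- structure(list(theta = theta, litter_theta = LITTER_THETA_FC,
                       ponded = 0, wtd = NA_real_),
                  class = "column_state")
  st$wtd <- diagnose_wtd(column, st)
  st
}

# litter-layer water constants (thin organic litter bucket)
LITTER_THETA_R <- 0.02
LITTER_THETA_S <- 0.90
LITTER_THETA_FC <- 0.30

#' Read soil profiles from CSV
#'
#' One row per (cell_id, layer_index), surface-down, with columns
#' `cell_id`, `layer_index`, `thickness_m`, `bulk_density`, `om_fraction`, and
#' optional overrides `theta_r`, `theta_s`, `vg_alpha`, `vg_n`, `ksat`.
#'
#' @param path CSV file path.
#' @param landuse optional named character vector mapping cell_id to land use.
#' @return named list of [soil_column()] objects, one per cell.
#' @export
read_soil_profiles <- function(path, landuse = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "layer_index", "thickness_m", "bulk_density", "om_fraction")
  if (!all(need %in% names(df)))
    stop("soil profile CSV needs columns: ", paste(need, collapse = ", "))
  opt <- function(row, nm) if (nm %in% names(df) && !is.na(row[[nm]])) row[[nm]] else NULL
  cols <- split(df, df$cell_id)
  lapply(cols, function(d) {
    d <- d[order(d$layer_index), ]
    layers <- lapply(seq_len(nrow(d)), function(i) {
      r <- d[i, ]
      soil_layer(r$thickness_m, r$bulk_density, r$om_fraction,
                 theta_r = opt(r, "theta_r"), theta_s = opt(r, "theta_s"),
                 vg_alpha = opt(r, "vg_alpha"), vg_n = opt(r, "vg_n"),
                 ksat = opt(r, "ksat"))
    })
    lu <- if (!is.null(landuse)) unname(landuse[as.character(d$cell_id[1])])
          else "non_peat_other"
    soil_column(layers, landuse = lu)
  })
}

#' Read retention samples from CSV
#'
#' Columns `cell_id`, `layer_index`, `psi_m`, `theta`; returns a data.frame
#' suitable for looping [fit_retention()] over (cell, layer) groups.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_retention_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "layer_index", "psi_m", "theta")
  if (!all(need %in% names(df)))
    stop("retention sample CSV needs columns: ", paste(need, collapse = ", "))
  df
}
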