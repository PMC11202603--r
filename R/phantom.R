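#' Acoustic property ranges of the abdominal tissue classes
#'
#' Per-tissue uniform sampling ranges for speed of sound (m/s), attenuation
#' coefficient (dB/cm/MHz) and mass density (kg/m^3) used by
#' [sample_phantom()]. One row per tissue class.
#'
#' @return A tibble with columns `tissue`, `sos_lo`, `sos_hi`, `ac_lo`,
#'   `ac_hi`, `rho_lo`, `rho_hi`.
#' @export
tissue_property_table <- function() {
  tibble::tribble(
    ~tissue,  ~sos_lo, ~sos_hi, ~ac_lo, ~ac_hi, ~rho_lo, ~rho_hi,
    "liver",     1500,    1600,    0.0,    1.0,    1050,    1150,
    "vessel",    1500,    1600,    0.0,    0.5,    1050,    1150,
    "muscle",    1500,    1650,    0.0,    1.5,    1000,    1200,
    "fat",       1400,    1500,    0.0,    0.5,     800,     950,
    "skin",      1500,    1700,    0.0,    1.0,    1100,    1150,
    "other",     1450,    1650,    0.0,    1.5,     850,    1150
  )
}

# integer codes used in label maps; "water" is the couplant introduced by
# warp_axial_grid and carries fixed (non-sampled) properties.
TISSUE_LEVELS <- c("water", "skin", "fat", "muscle", "liver", "vessel", "other")

#' Phantom sampling specification
#'
#' Describes the geometry and acoustic-property sampling law of the randomized
#' abdominal phantoms: one elliptical liver (semi-axes drawn from
#' `liver_radius_range`), up to `vessel_count_max - 1` circular vessels inside
#' the liver, 6-10 superficial layers (skin/fat/muscle) confined to the top
#' `layer_zone_depth` mm, and sub-wavelength scatterers placed uniformly with
#' fewer than `scatterer_count_max_per_unit_area` per wavelength-squared area.
#'
#' @param grid_shape Integer pair, grid cells as (axial, lateral).
#' @param cell_size Cell edge length in mm.
#' @param liver_radius_range Liver ellipse semi-axis range in mm.
#' @param vessel_count_max Exclusive upper bound on the vessel count.
#' @param vessel_radius_range Vessel radius range in mm.
#' @param layer_count_range Inclusive range for the superficial layer count.
#' @param layer_zone_depth Depth (mm) containing all superficial layers.
#' @param scatterer_count_max_per_unit_area Exclusive upper bound on scatterers
#'   per wavelength-by-wavelength area.
#' @param scatterer_density_range Scatterer density range, kg/m^3.
#' @param property_ranges Per-tissue property ranges; defaults to
#'   [tissue_property_table()].
#' @param probe_curvature_radius Convex-probe curvature radius in mm (used by
#'   [warp_axial_grid()]).
#' @param wavelength_ref_sos Reference speed of sound (m/s) defining the
#'   scatterer unit area together with `wavelength_ref_freq` (MHz).
#' @param wavelength_ref_freq Transmit center frequency (MHz) defining the
#'   scatterer unit area.
#' @param seed Integer seed; phantom sampling is fully reproducible from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(400L, 200L),
                         cell_size = 0.2,
                         liver_radius_range = c(50, 80),
                         vessel_count_max = 10L,
                         vessel_radius_range = c(3, 50),
                         layer_count_range = c(6L, 10L),
                         layer_zone_depth = 30,
                         scatterer_count_max_per_unit_area = 10L,
                         scatterer_density_range = c(800, 1200),
                         property_ranges = tissue_property_table(),
                         probe_curvature_radius = 60,
                         wavelength_ref_sos = 1550,
                         wavelength_ref_freq = 3.0,
                         seed = 1L) {
  check_range <- function(r, name) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop_config("'%s' must be an ordered (low <= high) pair", name)
    }
  }
  check_range(liver_radius_range, "liver_radius_range")
  check_range(vessel_radius_range, "vessel_radius_range")
  check_range(layer_count_range, "layer_count_range")
  check_range(scatterer_density_range, "scatterer_density_range")
  if (any(grid_shape < 4L)) stop_config("grid_shape too small")
  if (cell_size <= 0) stop_config("cell_size must be positive")
  depth_mm <- grid_shape[1] * cell_size
  if (depth_mm <= layer_zone_depth) {
    stop_config(
      "grid depth (%.1f mm) leaves no room below the %.0f mm layer zone for the liver",
      depth_mm, layer_zone_depth
    )
  }
  stopifnot(all(c("tissue", "sos_lo", "sos_hi", "ac_lo", "ac_hi",
                  "rho_lo", "rho_hi") %in% names(property_ranges)))
  structure(
    list(
      grid_shape = as.integer(grid_shape),
      cell_size = cell_size,
      liver_radius_range = liver_radius_range,
      vessel_count_max = as.integer(vessel_count_max),
      vessel_radius_range = vessel_radius_range,
      layer_count_range = as.integer(layer_count_range),
      layer_zone_depth = layer_zone_depth,
      scatterer_count_max_per_unit_area = as.integer(scatterer_count_max_per_unit_area),
      scatterer_density_range = scatterer_density_range,
      property_ranges = property_ranges,
      probe_curvature_radius = probe_curvature_radius,
      wavelength_ref_sos = wavelength_ref_sos,
      wavelength_ref_freq = wavelength_ref_freq,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d cells @ %.2f mm (%.0f x %.0f mm), seed %d\n",
    x$grid_shape[1], x$grid_shape[2], x$cell_size,
    x$grid_shape[1] * x$cell_size, x$grid_shape[2] * x$cell_size, x$seed
  ))
  invisible(x)
}

#' Construct a tissue map directly
#'
#' Low-level constructor for a gridded tissue map; [sample_phantom()] is the
#' usual entry point. All maps are matrices indexed (axial, lateral).
#'
#' @param sos,ac,density Numeric matrices: speed of sound (m/s), attenuation
#'   coefficient (dB/cm/MHz), density (kg/m^3).
#' @param label Integer matrix of tissue codes (see `TISSUE_LEVELS`), or a
#'   character matrix of tissue names.
#' @param scatterers Data frame with columns `z_mm`, `x_mm`, `density`,
#'   `amplitude`.
#' @param liver_ac_truth Ground-truth liver attenuation coefficient,
#'   dB/cm/MHz.
#' @param cell_size Cell edge, mm.
#' @param seed Seed the map was generated from (bookkeeping).
#' @return An object of class `tissue_map`.
#' @export
tissue_map <- function(sos, ac, density, label, scatterers,
                       liver_ac_truth, cell_size, seed = NA_integer_) {
  if (is.character(label)) {
    code <- matrix(match(label, TISSUE_LEVELS) - 1L, nrow(label), ncol(label))
    if (any(is.na(code))) stop_input("unknown tissue label")
    label <- code
  }
  stopifnot(
    identical(dim(sos), dim(ac)), identical(dim(sos), dim(density)),
    identical(dim(sos), dim(label))
  )
  structure(
    list(
      sos = sos, ac = ac, density = density, label = label,
      scatterers = tibble::as_tibble(scatterers),
      liver_ac_truth = liver_ac_truth,
      cell_size = cell_size,
      seed = seed
    ),
    class = "tissue_map"
  )
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(sprintf(
    "<tissue_map> %d x %d cells @ %.2f mm, %d scatterers, liver AC %.3f dB/cm/MHz\n",
    nrow(x$sos), ncol(x$sos), x$cell_size, nrow(x$scatterers), x$liver_ac_truth
  ))
  invisible(x)
}

tissue_code <- function(name) match(name, TISSUE_LEVELS) - 1L

#' Sample a randomized abdominal phantom
#'
#' Draws one phantom realization: superficial skin/fat/muscle layers stacked in
#' the top 30 mm, an elliptical liver with semi-axes in 50-80 mm, 0-9 circular
#' vessels centered inside the liver, an "other abdominal tissue" background,
#' per-tissue acoustic properties drawn uniformly from the class ranges, and a
#' uniform sub-wavelength scatterer field (1-9 scatterers per wavelength^2,
#' densities 800-1200 kg/m^3). Vessel scatterers are strongly hypoechoic
#' (blood), so vessels appear dark in B-mode.
#'
#' @param spec A [phantom_spec()].
#' @param with_scatterers Generate the scatterer field (default `TRUE`). Set
#'   `FALSE` for property/geometry studies where only the gridded maps are
#'   needed.
#' @return A [tissue_map()] carrying `liver_ac_truth` equal to the attenuation
#'   coefficient assigned to liver-labelled cells.
#' @export
sample_phantom <- function(spec, with_scatterers = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, sample_phantom_impl(spec, with_scatterers))
}

sample_phantom_impl <- function(spec, with_scatterers) {
  nz <- spec$grid_shape[1]; nx <- spec$grid_shape[2]
  cs <- spec$cell_size
  depth_mm <- nz * cs; width_mm <- nx * cs
  z_mm <- (seq_len(nz) - 0.5) * cs
  x_mm <- (seq_len(nx) - 0.5) * cs
  Z <- matrix(z_mm, nz, nx)
  X <- matrix(x_mm, nz, nx, byrow = TRUE)

  pr <- spec$property_ranges
  draw_props <- function(tissue) {
    row <- pr[pr$tissue == tissue, ]
    c(
      sos = runif(1, row$sos_lo, row$sos_hi),
      ac = runif(1, row$ac_lo, row$ac_hi),
      rho = runif(1, row$rho_lo, row$rho_hi)
    )
  }

  label <- matrix(tissue_code("other"), nz, nx)
  sos <- matrix(0, nz, nx); ac <- matrix(0, nz, nx); rho <- matrix(0, nz, nx)
  bg <- draw_props("other")
  sos[] <- bg["sos"]; ac[] <- bg["ac"]; rho[] <- bg["rho"]

  # liver ellipse: semi-axes sampled independently; centered near the lateral
  # midline with the upper edge just below the layer zone, emulating an
  # intercostal liver view where parenchyma fills the deep field
  a_lat <- runif(1, spec$liver_radius_range[1], spec$liver_radius_range[2])
  b_ax <- runif(1, spec$liver_radius_range[1], spec$liver_radius_range[2])
  liver_cx <- width_mm / 2 + runif(1, -5, 5)
  liver_cz <- spec$layer_zone_depth + runif(1, 2, 8) + b_ax * runif(1, 0.85, 1.0)
  in_liver <- ((X - liver_cx) / a_lat)^2 + ((Z - liver_cz) / b_ax)^2 <= 1
  liver_props <- draw_props("liver")
  label[in_liver] <- tissue_code("liver")
  sos[in_liver] <- liver_props["sos"]
  ac[in_liver] <- liver_props["ac"]
  rho[in_liver] <- liver_props["rho"]

  # vessels: circles centered inside the liver ellipse (precedence over liver)
  n_vessel <- sample.int(spec$vessel_count_max, 1) - 1L  # 0 .. max-1
  vessel_mask <- matrix(FALSE, nz, nx)
  vessel_radii <- numeric(0)
  if (n_vessel > 0) {
    for (i in seq_len(n_vessel)) {
      # rejection-sample a center inside the ellipse
      repeat {
        u <- runif(1, -1, 1); v <- runif(1, -1, 1)
        if (u^2 + v^2 <= 1) break
      }
      vcx <- liver_cx + u * a_lat
      vcz <- liver_cz + v * b_ax
      # vessel calibers follow a many-small / few-large law (truncated
      # exponential) spanning the allowed 3-50 mm radius range
      r <- min(
        spec$vessel_radius_range[2],
        spec$vessel_radius_range[1] + stats::rexp(1, rate = 1 / 7)
      )
      vessel_radii <- c(vessel_radii, r)
      vp <- draw_props("vessel")
      inside <- (X - vcx)^2 + (Z - vcz)^2 <= r^2
      inside <- inside & in_liver  # vessels are liver structures
      vessel_mask <- vessel_mask | inside
      label[inside] <- tissue_code("vessel")
      sos[inside] <- vp["sos"]; ac[inside] <- vp["ac"]; rho[inside] <- vp["rho"]
    }
  }

  # superficial layers: skin on top, then random fat/muscle laminae, all
  # within layer_zone_depth; layers take precedence over everything
  n_layer <- sample(seq(spec$layer_count_range[1], spec$layer_count_range[2]), 1)
  cuts <- sort(runif(n_layer - 1, 0.02, 0.98)) * spec$layer_zone_depth
  bounds <- c(0, cuts, spec$layer_zone_depth)
  layer_tissue <- c("skin", sample(c("fat", "muscle"), n_layer - 1, replace = TRUE))
  for (i in seq_len(n_layer)) {
    sel <- Z >= bounds[i] & Z < bounds[i + 1]
    lp <- draw_props(layer_tissue[i])
    label[sel] <- tissue_code(layer_tissue[i])
    sos[sel] <- lp["sos"]; ac[sel] <- lp["ac"]; rho[sel] <- lp["rho"]
  }

  # scatterer field: k per unit area (wavelength x wavelength), k in 1..max-1
  scat <- tibble::tibble(
    z_mm = numeric(0), x_mm = numeric(0),
    density = numeric(0), amplitude = numeric(0)
  )
  if (with_scatterers) {
    lambda_mm <- spec$wavelength_ref_sos / spec$wavelength_ref_freq / 1000
    n_units <- (depth_mm * width_mm) / lambda_mm^2
    k_per_unit <- sample.int(spec$scatterer_count_max_per_unit_area, 1) - 1L
    k_per_unit <- max(1L, k_per_unit)
    n_scat <- round(n_units * k_per_unit)
    sz <- runif(n_scat, 0, depth_mm)
    sx <- runif(n_scat, 0, width_mm)
    sd_ <- runif(n_scat, spec$scatterer_density_range[1], spec$scatterer_density_range[2])
    iz <- pmin(nz, pmax(1L, ceiling(sz / cs)))
    ix <- pmin(nx, pmax(1L, ceiling(sx / cs)))
    idx <- cbind(iz, ix)
    amp <- (sd_ - rho[idx]) / rho[idx]
    # blood is nearly anechoic: suppress vessel-lumen speckle
    in_vessel <- label[idx] == tissue_code("vessel")
    amp[in_vessel] <- amp[in_vessel] * 0.05
    scat <- tibble::tibble(z_mm = sz, x_mm = sx, density = sd_, amplitude = amp)
  }

  out <- tissue_map(
    sos = sos, ac = ac, density = rho, label = label, scatterers = scat,
    liver_ac_truth = unname(liver_props["ac"]), cell_size = cs, seed = spec$seed
  )
  out$geometry <- list(
    liver_semi_axes = c(lateral = a_lat, axial = b_ax),
    liver_center = c(x = liver_cx, z = liver_cz),
    n_vessels = n_vessel, vessel_radii = vessel_radii,
    n_layers = n_layer, layer_bounds = bounds,
    scatterers_per_unit = if (with_scatterers) k_per_unit else NA_integer_
  )
  out
}

#' Construct a homogeneous speckle phantom
#'
#' Uniform medium with a prescribed attenuation coefficient and a uniform
#' sub-wavelength scatterer field — the standard calibration target for
#' attenuation estimators. With `scatterers_per_unit = 0` and a non-`NULL`
#' `point_scatterers` table, builds a sparse point-target phantom instead.
#'
#' @param alpha Attenuation coefficient, dB/cm/MHz.
#' @param grid_shape,cell_size Grid geometry (cells, mm).
#' @param sos Speed of sound, m/s.
#' @param density Background density, kg/m^3.
#' @param scatterers_per_unit Scatterers per wavelength-squared area.
#' @param scatterer_density_range Scatterer density range, kg/m^3.
#' @param point_scatterers Optional tibble (`z_mm`, `x_mm`, `amplitude`)
#'   of additional discrete targets.
#' @param label Tissue label for all cells (default "liver").
#' @param wavelength_ref_sos,wavelength_ref_freq Unit-area definition.
#' @param seed Seed for the scatterer draw.
#' @return A [tissue_map()] with `liver_ac_truth = alpha`.
#' @export
homogeneous_phantom <- function(alpha, grid_shape = c(200L, 100L),
                                cell_size = 0.4, sos = 1540, density = 1060,
                                scatterers_per_unit = 5,
                                scatterer_density_range = c(800, 1200),
                                point_scatterers = NULL,
                                label = "liver",
                                wavelength_ref_sos = 1550,
                                wavelength_ref_freq = 3.0,
                                seed = 1L) {
  nz <- grid_shape[1]; nx <- grid_shape[2]
  depth_mm <- nz * cell_size; width_mm <- nx * cell_size
  scat <- tibble::tibble(z_mm = numeric(0), x_mm = numeric(0),
                         density = numeric(0), amplitude = numeric(0))
  if (scatterers_per_unit > 0) {
    lambda_mm <- wavelength_ref_sos / wavelength_ref_freq / 1000
    n_scat <- round(depth_mm * width_mm / lambda_mm^2 * scatterers_per_unit)
    scat <- with_seed(seed, {
      sd_ <- runif(n_scat, scatterer_density_range[1], scatterer_density_range[2])
      amp <- (sd_ - density) / density
      tibble::tibble(
        z_mm = runif(n_scat, 0, depth_mm),
        x_mm = runif(n_scat, 0, width_mm),
        density = sd_,
        amplitude = amp
      )
    })
  }
  if (!is.null(point_scatterers)) {
    ps <- tibble::as_tibble(point_scatterers)
    ps$density <- density
    scat <- dplyr::bind_rows(scat, ps[, c("z_mm", "x_mm", "density", "amplitude")])
  }
  tissue_map(
    sos = matrix(sos, nz, nx), ac = matrix(alpha, nz, nx),
    density = matrix(density, nz, nx),
    label = matrix(tissue_code(label), nz, nx),
    scatterers = scat, liver_ac_truth = alpha, cell_size = cell_size,
    seed = as.integer(seed)
  )
}

#' Warp the axial grid to a convex-probe arc
#'
#' Models the deformation of superficial tissue coupled to a convex probe:
#' each lateral column is shifted deeper by the arc sag
#' `R - sqrt(R^2 - (x - x0)^2)` so that the skin surface follows the probe
#' curvature. Cells entering at the transducer face are labelled couplant
#' ("water", SoS 1540 m/s, AC 0, density 1000 kg/m^3). Scatterer coordinates
#' are shifted consistently. The shift is nearest-cell quantized, so interior
#' labels and property values are conserved exactly; only rows pushed past the
#' bottom of the grid are lost.
#'
#' @param map A [tissue_map()].
#' @param curvature_radius Probe curvature radius in mm, or `"flat"` for the
#'   linear-array (identity) limit.
#' @return A warped [tissue_map()].
#' @export
warp_axial_grid <- function(map, curvature_radius = "flat") {
  stopifnot(inherits(map, "tissue_map"))
  if (identical(curvature_radius, "flat") || is.infinite(curvature_radius)) {
    return(map)
  }
  if (!is.numeric(curvature_radius) || curvature_radius <= 0) {
    stop_config("curvature_radius must be positive or \"flat\"")
  }
  nz <- nrow(map$sos); nx <- ncol(map$sos); cs <- map$cell_size
  x_mm <- (seq_len(nx) - 0.5) * cs
  x0 <- nx * cs / 2
  dx <- x_mm - x0
  if (any(abs(dx) >= curvature_radius)) {
    stop_config("curvature radius smaller than the half-aperture")
  }
  sag_mm <- curvature_radius - sqrt(curvature_radius^2 - dx^2)
  shift <- round(sag_mm / cs)  # cells, >= 0

  out <- map
  wcode <- tissue_code("water")
  for (j in seq_len(nx)) {
    s <- shift[j]
    if (s == 0) next
    keep <- seq_len(nz - s)
    for (fld in c("sos", "ac", "density", "label")) {
      col <- map[[fld]][, j]
      newcol <- c(rep(NA_real_, s), col[keep])
      out[[fld]][, j] <- newcol
    }
    out$label[seq_len(s), j] <- wcode
    out$sos[seq_len(s), j] <- 1540
    out$ac[seq_len(s), j] <- 0
    out$density[seq_len(s), j] <- 1000
  }
  storage.mode(out$label) <- "integer"
  if (nrow(map$scatterers) > 0) {
    ix <- pmin(nx, pmax(1L, ceiling(map$scatterers$x_mm / cs)))
    z_new <- map$scatterers$z_mm + shift[ix] * cs
    keep <- z_new <= nz * cs
    out$scatterers <- map$scatterers[keep, , drop = FALSE]
    out$scatterers$z_mm <- z_new[keep]
  }
  out
}

#' Summarize per-class property containment of a tissue map
#'
#' For each tissue class present in the map, reports the min/max of speed of
#' sound, attenuation coefficient and density over its cells, joined to the
#' sampling ranges — a convenience for verifying that every cell lies within
#' its class range.
#'
#' @param map A [tissue_map()].
#' @param property_ranges Ranges to check against, default
#'   [tissue_property_table()].
#' @return A tibble, one row per class present, with logical `contained`.
#' @export
phantom_property_summary <- function(map, property_ranges = tissue_property_table()) {
  codes <- sort(unique(as.vector(map$label)))
  rows <- lapply(codes, function(cd) {
    nm <- TISSUE_LEVELS[cd + 1L]
    sel <- map$label == cd
    tibble::tibble(
      tissue = nm,
      n_cells = sum(sel),
      sos_min = min(map$sos[sel]), sos_max = max(map$sos[sel]),
      ac_min = min(map$ac[sel]), ac_max = max(map$ac[sel]),
      rho_min = min(map$density[sel]), rho_max = max(map$density[sel])
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(out, property_ranges, by = "tissue")
  out$contained <- ifelse(
    is.na(out$sos_lo), out$tissue == "water",
    out$sos_min >= out$sos_lo & out$sos_max <= out$sos_hi &
      out$ac_min >= out$ac_lo & out$ac_max <= out$ac_hi &
      out$rho_min >= out$rho_lo & out$rho_max <= out$rho_hi
  )
  out
}

#' Plot a tissue map
#'
#' @param map A [tissue_map()].
#' @param what One of "label", "ac", "sos", "density".
#' @return A ggplot object.
#' @export
plot_phantom <- function(map, what = c("label", "ac", "sos", "density")) {
  what <- match.arg(what)
  m <- if (what == "label") map$label else map[[what]]
  df <- tibble::tibble(
    z = rep((seq_len(nrow(m)) - 0.5) * map$cell_size, ncol(m)),
    x = rep((seq_len(ncol(m)) - 0.5) * map$cell_size, each = nrow(m)),
    value = as.vector(m)
  )
  if (what == "label") {
    df$value <- factor(TISSUE_LEVELS[df$value + 1L], levels = TISSUE_LEVELS)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral [mm]", y = "depth [mm]", fill = what)
  if (what != "label") p <- p + ggplot2::scale_fill_viridis_c()
  p
}
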