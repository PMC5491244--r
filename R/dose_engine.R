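#' Beam direction unit vector for a coplanar field
#'
#' Axial beam angles follow the gantry convention in LPS coordinates:
#' 0 = anterior, 90 = left, 180 = posterior, 270 = right; the beam travels
#' from the source through the patient, so a 0-degree (anterior) field
#' travels in +y (posterior) direction.
#'
#' @param angle_deg axial angle in degrees, in [0, 360).
#' @return numeric(3) unit vector of the direction of travel.
#' @export
beam_direction <- function(angle_deg) {
  th <- angle_deg * pi / 180
  c(-sin(th), cos(th), 0)
}

# water-equivalent density grid from a material map
density_grid <- function(materials) {
  array(WATER_EQUIV_DENSITY[materials$labels + 1L], materials$geom$dim)
}

#' Radiological depth along a beam direction
#'
#' Line integral of water-equivalent density (air 0; soft tissue, brain and
#' tumor 1.0; bone 1.4) from the body entry surface to each query point
#' along the beam direction of travel, by stepped ray tracing (nearest-
#' neighbour sampling at 1-mm segments).
#'
#' @param materials a `material_map`.
#' @param beam a [beam_spec()] (only the angle is used).
#' @param points n x 3 matrix of physical coordinates (cm); defaults to all
#'   in-body voxel centres.
#' @param step ray sampling step in cm.
#' @return numeric vector of radiological depths (cm), one per point.
#' @export
radiological_depth <- function(materials, beam, points = NULL, step = 0.1) {
  stopifnot(inherits(materials, "material_map"))
  geom <- materials$geom
  if (is.null(points))
    points <- mask_coords(materials$labels != MATERIALS[["air"]], geom)
  ray_line_integral(as.numeric(density_grid(materials)), geom$dim,
                    geom$spacing, geom$origin, points,
                    beam_direction(beam$angle), step)
}

#' Geometric depth inside a body mask along a beam direction
#'
#' Like [radiological_depth()] but integrating the body indicator (density
#' 1 inside, 0 outside): the geometric distance from the body entry surface,
#' as measured on CT images.
#'
#' @param body_mask logical array.
#' @param geom a [grid_geometry()].
#' @param angle_deg beam angle in degrees.
#' @param points n x 3 coordinate matrix (cm).
#' @param step ray sampling step in cm.
#' @return numeric vector of geometric depths (cm).
#' @export
geometric_depth <- function(body_mask, geom, angle_deg, points,
                            step = 0.05) {
  ray_line_integral(as.numeric(body_mask), geom$dim, geom$spacing,
                    geom$origin, points, beam_direction(angle_deg), step)
}

#' Trace one field: per-component physical dose-rate maps
#'
#' For every in-body voxel, each component's dose rate is the on-axis
#' depth-dose rate evaluated at the voxel's radiological depth, times the
#' radial profile at the voxel's perpendicular distance from the beam axis
#' (a parallel beam through the isocenter).  Voxels outside the body get
#' zero.
#'
#' @param materials a `material_map`.
#' @param structures a `structure_set`; used to place the isocenter at the
#'   CTV centroid when `isocenter` is not given.
#' @param beam a [beam_spec()].
#' @param bm a [beam_model_params()].
#' @param isocenter numeric(3) beam axis point (cm); default CTV centroid.
#' @return An object of class `component_dose_map`: list of four 3D arrays
#'   (Gy/min) named `thermal`, `fast`, `photon`, `b10` (the latter at the
#'   reference boron concentration), plus `geom`, `beam`, `isocenter` and
#'   a `drsf_applied` flag.
#' @export
trace_field <- function(materials, structures, beam,
                        bm = default_beam_model(), isocenter = NULL) {
  stopifnot(inherits(materials, "material_map"),
            inherits(bm, "beam_model_params"))
  geom <- materials$geom
  if (is.null(isocenter)) {
    ctv <- structures$masks$CTV
    isocenter <- colMeans(mask_coords(ctv, geom))
  }
  body <- materials$labels != MATERIALS[["air"]]
  if (!any(body)) {
    warning("beam misses the body; returning all-zero dose maps")
    zero <- array(0, geom$dim)
    return(structure(list(thermal = zero, fast = zero, photon = zero,
                          b10 = zero, geom = geom, beam = beam,
                          isocenter = isocenter, drsf_applied = FALSE),
                     class = "component_dose_map"))
  }
  pts <- mask_coords(body, geom)
  depth <- radiological_depth(materials, beam, pts)
  d <- beam_direction(beam$angle)
  rel <- sweep(pts, 2, isocenter)
  along <- rel %*% d
  perp <- sqrt(pmax(rowSums(rel^2) - along^2, 0))
  prof <- radial_profile(perp, bm, depth)
  maps <- lapply(BEAM_COMPONENTS, function(cmp) {
    m <- array(0, geom$dim)
    m[body] <- component_depth_dose_rate(depth, cmp, bm) * prof
    m
  })
  names(maps) <- BEAM_COMPONENTS
  structure(c(maps, list(geom = geom, beam = beam, isocenter = isocenter,
                         drsf_applied = FALSE)),
            class = "component_dose_map")
}

#' Apply dose-rate scaling factors to a component dose map
#'
#' Multiplies each component by its fixed DRSF, yielding the adjusted
#' components.  Applying the scaling twice would silently corrupt the
#' dose, so a provenance flag is set and a second application is refused.
#'
#' @param raw a `component_dose_map`.
#' @param rb a [radiobiology_params()].
#' @return the adjusted `component_dose_map` with `drsf_applied = TRUE`.
#' @export
apply_drsf <- function(raw, rb = radiobiology_params()) {
  stopifnot(inherits(raw, "component_dose_map"))
  if (isTRUE(raw$drsf_applied))
    stop("DRSF already applied to this dose map")
  for (cmp in BEAM_COMPONENTS)
    raw[[cmp]] <- raw[[cmp]] * rb$drsf[[cmp]]
  raw$drsf_applied <- TRUE
  raw
}

#' Boron concentration map
#'
#' The reference concentration everywhere inside the body, T/N times the
#' reference inside the CTV, zero in air.
#'
#' @param structures a `structure_set`.
#' @param rb a [radiobiology_params()] (supplies the T/N ratio).
#' @param ref_conc normal-tissue boron concentration in ppm (> 0).
#' @return 3D numeric array of ppm with attribute `ref_conc`.
#' @export
build_boron_map <- function(structures, rb = radiobiology_params(),
                            ref_conc = 25) {
  stopifnot(inherits(structures, "structure_set"), ref_conc > 0)
  b <- array(0, structures$geom$dim)
  b[structures$masks$body] <- ref_conc
  b[structures$masks$CTV] <- rb$tn_ratio * ref_conc
  attr(b, "ref_conc") <- ref_conc
  b
}

#' Biologically weighted (RBE) dose map of one field
#'
#' Combines the DRSF-adjusted components into gray-equivalent dose per
#' voxel: `minutes * (RBE_th * D_th + RBE_fast * D_fast + RBE_ph * D_ph +
#' CBE(tissue) * (boron / ref_conc) * D_b10)`, with the tumor CBE inside
#' the CTV mask and the brain CBE elsewhere in the body.  The CTV mask
#' (not the material label) selects the tumor CBE, since target voxels are
#' tumor radiobiologically even where their density is brain-like.
#'
#' @param adj a `component_dose_map` with DRSF applied.
#' @param boron a boron map from [build_boron_map()].
#' @param structures a `structure_set` on the same grid.
#' @param rb a [radiobiology_params()].
#' @param beam_minutes irradiation time in minutes.
#' @return An object of class `rbe_dose_map`: `dose` (3D array, Gy-Eq),
#'   `geom`, `minutes`, `beam`.
#' @export
rbe_weighted_dose <- function(adj, boron, structures,
                              rb = radiobiology_params(),
                              beam_minutes = 1) {
  stopifnot(inherits(adj, "component_dose_map"))
  if (!isTRUE(adj$drsf_applied))
    stop("apply_drsf() must be applied before RBE weighting")
  if (!identical(dim(adj$thermal), dim(boron)) ||
      !identical(dim(adj$thermal), dim(structures$masks$CTV)))
    stop("dose, boron and structure grids do not match")
  ref <- attr(boron, "ref_conc")
  cbe <- array(0, adj$geom$dim)
  cbe[structures$masks$body] <- rb$cbe[["brain"]]
  cbe[structures$masks$CTV] <- rb$cbe[["tumor"]]
  dose <- beam_minutes *
    (rb$rbe[["thermal"]] * adj$thermal +
     rb$rbe[["fast"]] * adj$fast +
     rb$rbe[["photon"]] * adj$photon +
     cbe * (boron / ref) * adj$b10)
  structure(list(dose = dose, geom = adj$geom, minutes = beam_minutes,
                 beam = adj$beam),
            class = "rbe_dose_map")
}

#' Export a dose map with a provenance sidecar
#'
#' Writes a 3D dose (or dose-rate) array as a NIfTI volume plus a JSON
#' sidecar (`<path>.json`) recording how it was produced: field angles,
#' relative weights, beam-on minutes and the MD5 hash of the beam
#' parameter file, when given.
#'
#' @param dose 3D array, or an `rbe_dose_map`.
#' @param geom a [grid_geometry()] (taken from the map if omitted).
#' @param path output NIfTI path.
#' @param angles,weights,minutes provenance fields.
#' @param params_file beam parameter YAML whose MD5 hash is recorded.
#' @return `path`, invisibly.
#' @export
export_dose_map <- function(dose, geom = NULL, path, angles = NULL,
                            weights = NULL, minutes = NULL,
                            params_file = NULL) {
  if (inherits(dose, "rbe_dose_map")) {
    if (is.null(geom)) geom <- dose$geom
    if (is.null(minutes)) minutes <- dose$minutes
    if (is.null(angles) && !is.null(dose$beam)) angles <- dose$beam$angle
    dose <- dose$dose
  }
  write_volume(dose, geom, path)
  prov <- list(angles = angles, weights = weights, minutes = minutes,
               params_md5 = if (!is.null(params_file))
                 unname(tools::md5sum(params_file)))
  prov <- prov[!vapply(prov, is.null, logical(1))]
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Weighted dose-rate map of one field (convenience)
#'
#' Full single-field chain trace -> DRSF -> RBE weighting at 1 minute,
#' returning the 3D Gy-Eq/min array.
#'
#' @inheritParams trace_field
#' @param rb a [radiobiology_params()].
#' @param boron optional precomputed boron map.
#' @return 3D array of Gy-Eq per minute.
#' @export
field_rbe_rate <- function(materials, structures, beam,
                           bm = default_beam_model(),
                           rb = radiobiology_params(), boron = NULL) {
  if (is.null(boron)) boron <- build_boron_map(structures, rb,
                                               bm$reference_boron_ppm)
  raw <- trace_field(materials, structures, beam, bm)
  adj <- apply_drsf(raw, rb)
  rbe_weighted_dose(adj, boron, structures, rb, beam_minutes = 1)$dose
}
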