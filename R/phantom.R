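#' Material codes used in label volumes
#'
#' Integer codes of the five materials a phantom distinguishes.  This is a
#' deliberate simplification of full CT-derived tissue libraries: only the
#' water-equivalent density contrast that matters for an epithermal neutron
#' beam (air / unit-density soft tissue / bone) plus the brain and tumor
#' labels needed to assign radiobiological weights.
#'
#' @format Named integer vector.
#' @export
MATERIALS <- c(air = 0L, soft_tissue = 1L, bone = 2L, brain = 3L, tumor = 4L)

# water-equivalent densities for neutron attenuation, by material code + 1
WATER_EQUIV_DENSITY <- c(0, 1, 1.4, 1, 1)

#' Default CT numbers per material (HU)
#' @format Named numeric vector.
#' @export
HU_MEANS <- c(air = -1000, soft_tissue = 40, bone = 700, brain = 35,
              tumor = 38)

#' Parameters of the synthetic head phantom
#'
#' The phantom is a family of nested superellipsoids: a soft-tissue scalp
#' over a bone skull shell over a soft-tissue (CSF-like) gap containing
#' the brain, with a brainstem clinical target volume (CTV) inside the
#' brain, two optic-nerve cylinders and a circle-of-Willis torus; below
#' the skull base the cross-section continues downward as a neck.
#' Anatomical realism is not the goal; the defaults are tuned so that the
#' deepest CTV depth from the body surface per beam angle and the structure
#' volumes emulate the statistics of a published 12-patient DIPG cohort
#' (deepest depth 8.3--12.8 cm depending on angle, normal brain near
#' 1166 cm^3, optic nerves near 1.6--1.7 cm^3, circle of Willis near
#' 1 cm^3).  All lengths in cm.
#'
#' @param head_semiaxes numeric(3), outer head semi-axes
#'   (left-right, anterior-posterior, inferior-superior).
#' @param head_exponent axial superellipse exponent of the head (and skull)
#'   cross-section: 2 is a true ellipse; lower values flatten the
#'   anterolateral surface and shorten the oblique-beam depths relative to
#'   the cardinal ones.
#' @param head_z_exponent superellipse exponent of the head profile along z:
#'   values above 2 keep the head near full width down to the skull base
#'   (as real heads do at the mastoid level) instead of tapering like an
#'   ellipsoid.
#' @param scalp_thickness scalp (soft tissue) thickness outside the skull.
#' @param skull_thickness bone shell thickness.
#' @param brain_semiaxes numeric(3), brain semi-axes.
#' @param brain_exponent axial superellipse exponent of the brain
#'   cross-section; a value below the head's leaves more clearance between
#'   brain and skull along the diagonals (the CSF-filled basal cisterns and
#'   sylvian region) than along the cardinal directions.
#' @param brain_center numeric(3), brain centre (cm, LPS).
#' @param ctv_center numeric(3), CTV centre; the brainstem target sits
#'   slightly posterior and inferior of the brain centre.
#' @param ctv_semiaxes numeric(3), CTV ellipsoid semi-axes.
#' @param on_radius,on_y_range,on_x_offset,on_z optic-nerve cylinder
#'   radius, anterior-posterior extent, lateral offset and axial level.
#' @param cw_center,cw_major_radius,cw_minor_radius circle-of-Willis torus
#'   (anterior-inferior to the target, clear of the CTV).
#' @param neck_base_z axial level (cm) below which the head cross-section is
#'   continued downward unchanged as a neck.  A closed ellipsoid would taper
#'   to a thin inferior tip that opposed lateral fields both enter at shallow
#'   depth -- an artifact a real head-on-neck does not have.
#' @param axis_scale_sd per-axis multiplicative jitter (sd) applied jointly
#'   to head and brain semi-axes, emulating inter-patient head size
#'   variation.
#' @param ctv_center_jitter_cm sd of the CTV centre jitter per axis.
#' @param ctv_scale_sd per-axis multiplicative jitter (sd) of the CTV size.
#' @param hu_noise_sd CT-number noise (HU) used by [synthesize_hu()].
#' @param voxel_cm isotropic voxel size; 0.2 cm by default (2-mm slices).
#' @param margin_cm air margin around the nominal head extent.
#' @param seed integer seed making the phantom reproducible.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(head_semiaxes = c(8.45, 9.35, 8.0),
                           head_exponent = 1.95,
                           head_z_exponent = 3,
                           scalp_thickness = 0.5,
                           skull_thickness = 0.7,
                           brain_semiaxes = c(6.95, 8.0, 5.8),
                           brain_exponent = 1.4,
                           brain_center = c(0, 0, 0),
                           ctv_center = c(0.04, 1.28, -2.0),
                           ctv_semiaxes = c(1.3, 1.3, 1.6),
                           on_radius = 0.41,
                           on_y_range = c(-5.2, -1.9),
                           on_x_offset = 1.5,
                           on_z = -0.5,
                           cw_center = c(0, -1.0, -3.4),
                           cw_major_radius = 1.1,
                           cw_minor_radius = 0.215,
                           neck_base_z = -6.4,
                           axis_scale_sd = 0.015,
                           ctv_center_jitter_cm = 0.05,
                           ctv_scale_sd = 0.03,
                           hu_noise_sd = 15,
                           voxel_cm = 0.2,
                           margin_cm = 1.5,
                           seed = 1L) {
  p <- as.list(environment())
  stopifnot(all(p$head_semiaxes > 0), all(p$brain_semiaxes > 0),
            all(p$ctv_semiaxes > 0), p$scalp_thickness > 0,
            p$skull_thickness > 0, p$voxel_cm > 0, p$hu_noise_sd >= 0)
  structure(p, class = "phantom_params")
}

#' Read/write phantom parameters as YAML
#' @param path YAML file path.
#' @return [read_phantom_params()]: a [phantom_params()];
#'   [write_phantom_params()]: `path` invisibly.
#' @export
read_phantom_params <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(phantom_params, lapply(y, function(v)
    if (is.list(v)) unlist(v) else v))
}

#' @rdname read_phantom_params
#' @param params a [phantom_params()].
#' @export
write_phantom_params <- function(params, path) {
  stopifnot(inherits(params, "phantom_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

# squared normalized ellipsoid coordinate; <= 1 means inside
ellipsoid_q <- function(x, y, z, center, semiaxes) {
  ((x - center[1]) / semiaxes[1])^2 +
    ((y - center[2]) / semiaxes[2])^2 +
    ((z - center[3]) / semiaxes[3])^2
}

# superellipsoid with exponent n in the axial (x, y) plane and exponent m
# along z; n = m = 2 recovers the ellipsoid
superellipsoid_q <- function(x, y, z, center, semiaxes, n, m = 2) {
  q2 <- (abs(x - center[1]) / semiaxes[1])^n +
    (abs(y - center[2]) / semiaxes[2])^n
  q2^(2 / n) + (abs(z - center[3]) / semiaxes[3])^m
}

#' Generate a voxelized head phantom
#'
#' Builds the labelled material grid and the structure set (body, CTV,
#' normal brain NB = brain minus CTV, left/right optic nerves, circle of
#' Willis) from [phantom_params()].  Inter-patient variation is emulated by
#' seeded multiplicative jitter on the head/brain axes and the CTV; the
#' result is deterministic given `params$seed`.
#'
#' @param params a [phantom_params()].
#' @return list with `materials` (class `material_map`: `labels` integer
#'   array + `geom`) and `structures` (class `structure_set`: named logical
#'   `masks`, `geom`, `volumes_cm3`).
#' @export
generate_head_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  p <- with_seed(params$seed, {
    s <- 1 + rnorm(3, 0, params$axis_scale_sd)
    q <- params
    q$head_semiaxes <- params$head_semiaxes * s
    q$brain_semiaxes <- params$brain_semiaxes * s
    q$ctv_center <- params$ctv_center +
      rnorm(3, 0, params$ctv_center_jitter_cm)
    q$ctv_semiaxes <- params$ctv_semiaxes *
      (1 + rnorm(3, 0, params$ctv_scale_sd))
    q
  })

  # grid is sized from the *nominal* head so all seeds share one geometry
  half <- params$head_semiaxes + params$margin_cm
  geom <- grid_geometry(dim = 2 * ceiling(half / params$voxel_cm) + 1,
                        spacing = params$voxel_cm)
  x <- axis_coords(geom, 1); y <- axis_coords(geom, 2); z <- axis_coords(geom, 3)
  X <- array(x, geom$dim)
  Y <- array(rep(y, each = geom$dim[1]), geom$dim)
  Z <- array(rep(z, each = prod(geom$dim[1:2])), geom$dim)

  hc <- c(0, 0, 0)                    # head centred on the grid
  ne <- p$head_exponent
  mz <- p$head_z_exponent
  body <- superellipsoid_q(X, Y, Z, hc, p$head_semiaxes, ne, mz) <= 1
  skull_outer <- superellipsoid_q(X, Y, Z, hc,
                                  p$head_semiaxes - p$scalp_thickness,
                                  ne, mz) <= 1
  skull_inner <- superellipsoid_q(X, Y, Z, hc,
    p$head_semiaxes - p$scalp_thickness - p$skull_thickness, ne, mz) <= 1
  brain <- superellipsoid_q(X, Y, Z, p$brain_center, p$brain_semiaxes,
                            p$brain_exponent) <= 1
  ctv_q <- ellipsoid_q(X, Y, Z, p$ctv_center, p$ctv_semiaxes)
  ctv <- ctv_q <= 1

  if (any(ctv & !brain))
    stop("geometry error: CTV extends outside the brain")
  if (any(brain & !skull_inner))
    stop("geometry error: brain extends into or beyond the skull")

  labels <- array(MATERIALS[["air"]], geom$dim)
  labels[body] <- MATERIALS[["soft_tissue"]]
  labels[skull_outer & !skull_inner] <- MATERIALS[["bone"]]
  labels[brain] <- MATERIALS[["brain"]]
  labels[ctv] <- MATERIALS[["tumor"]]

  # continue the neck-base cross-section down to the grid floor
  k_base <- max(which(z <= p$neck_base_z))
  if (any(brain[, , seq_len(k_base)]))
    stop("geometry error: brain extends below the neck base")
  neck <- labels[, , k_base]
  for (k in seq_len(k_base - 1)) labels[, , k] <- neck
  body <- labels != MATERIALS[["air"]]

  # optic nerves: cylinders along y, anterior to the target
  lon <- ((X - p$on_x_offset)^2 + (Z - p$on_z)^2 <= p$on_radius^2) &
    Y >= p$on_y_range[1] & Y <= p$on_y_range[2]
  ron <- ((X + p$on_x_offset)^2 + (Z - p$on_z)^2 <= p$on_radius^2) &
    Y >= p$on_y_range[1] & Y <= p$on_y_range[2]
  # circle of Willis: torus with vertical axis at the skull base
  cw <- (sqrt((X - p$cw_center[1])^2 + (Y - p$cw_center[2])^2) -
           p$cw_major_radius)^2 + (Z - p$cw_center[3])^2 <=
    p$cw_minor_radius^2

  masks <- list(body = body, CTV = ctv, NB = brain & !ctv,
                L_ON = lon & body, R_ON = ron & body, CW = cw & body)
  vv <- voxel_volume_cm3(geom)
  volumes <- vapply(masks, function(m) sum(m) * vv, numeric(1))

  materials <- structure(list(labels = labels, geom = geom),
                         class = "material_map")
  structures <- structure(list(masks = masks, geom = geom,
                               volumes_cm3 = volumes),
                          class = "structure_set")
  list(materials = materials, structures = structures)
}

#' Synthesize a CT-number (HU) grid from a material map
#'
#' Stands in for a simulation CT: each material gets its mean CT number
#' plus Gaussian noise.
#'
#' @param materials a `material_map`.
#' @param noise_sd Gaussian noise sd in HU (>= 0).
#' @param seed integer seed.
#' @param means named HU means per material (default [HU_MEANS]).
#' @return 3D numeric array of HU on the same grid.
#' @export
synthesize_hu <- function(materials, noise_sd = 15, seed = 1L,
                          means = HU_MEANS) {
  stopifnot(inherits(materials, "material_map"), noise_sd >= 0)
  hu <- array(means[materials$labels + 1L], materials$geom$dim)
  if (noise_sd > 0)
    hu <- hu + with_seed(seed, array(rnorm(length(hu), 0, noise_sd),
                                     materials$geom$dim))
  hu
}

#' Classify an HU grid into materials by thresholding
#'
#' Two strictly increasing thresholds split HU into air / soft tissue /
#' bone (defaults -500 and +300 HU).  Brain and tumor are not separable by
#' CT number (their means differ by a few HU), so they classify as soft
#' tissue; the round trip with [synthesize_hu()] at zero noise is exact for
#' maps containing only air, soft tissue and bone.
#'
#' @param hu 3D numeric array of CT numbers.
#' @param thresholds numeric(2), strictly increasing (air|soft, soft|bone).
#' @param geom a [grid_geometry()]; defaults to 0.2-cm voxels.
#' @return a `material_map`.
#' @export
assign_materials <- function(hu, thresholds = c(-500, 300), geom = NULL) {
  if (length(thresholds) != 2 || diff(thresholds) <= 0)
    stop("thresholds must be two strictly increasing values")
  if (is.null(geom)) geom <- grid_geometry(dim(hu))
  labels <- array(MATERIALS[["soft_tissue"]], dim(hu))
  labels[hu < thresholds[1]] <- MATERIALS[["air"]]
  labels[hu >= thresholds[2]] <- MATERIALS[["bone"]]
  structure(list(labels = labels, geom = geom), class = "material_map")
}
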