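rb <- radiobiology_params()

# minimal component map for arithmetic tests: constant unit components on a
# tiny grid whose first voxel is tumor, rest brain
tiny_setup <- function(value = 1) {
  geom <- grid_geometry(c(2, 2, 1), 1)
  maps <- setNames(lapply(1:4, function(i) array(value, geom$dim)),
                   c("thermal", "fast", "photon", "b10"))
  cdm <- structure(c(maps, list(geom = geom, beam = beam_spec(0),
                                isocenter = c(0, 0, 0),
                                drsf_applied = FALSE)),
                   class = "component_dose_map")
  ctv <- array(FALSE, geom$dim); ctv[1, 1, 1] <- TRUE
  body <- array(TRUE, geom$dim)
  st <- structure(list(masks = list(body = body, CTV = ctv,
                                    NB = body & !ctv),
                       geom = geom,
                       volumes_cm3 = c(body = sum(body), CTV = sum(ctv),
                                       NB = sum(body & !ctv))),
                  class = "structure_set")
  list(cdm = cdm, st = st)
}

test_that("radiological depth integrates water-equivalent density", {
  slab <- water_slab()
  # 5 cm beyond the anterior entry surface of a homogeneous slab
  entry_y <- axis_coords(slab$geom, 2)[2]   # first soft-tissue voxel
  pt <- cbind(0, entry_y + 5, 0)
  expect_equal(radiological_depth(slab, beam_spec(0), pt), 5,
               tolerance = 0.15)
  # entry voxel is at ~zero depth (within its own half-voxel)
  expect_lte(radiological_depth(slab, beam_spec(0), cbind(0, entry_y, 0)),
             0.31)
  # 1 cm bone then brain: depth at 4 cm past the bone = 1*1.4 + 4*1.0
  m <- water_slab()
  y <- axis_coords(m$geom, 2)
  bone_band <- y >= entry_y - 0.01 & y < entry_y + 0.99
  m$labels[, bone_band, ] <- MATERIALS[["bone"]]
  pt <- cbind(0, entry_y + 5, 0)   # 1 cm bone + 4 cm soft
  expect_equal(radiological_depth(m, beam_spec(0), pt), 5.4,
               tolerance = 0.2)
})

test_that("DRSF application multiplies each component once and only once", {
  ts <- tiny_setup(1)
  adj <- apply_drsf(ts$cdm, rb)
  expect_equal(adj$thermal[1], 0.64)
  expect_equal(adj$fast[1], 1.39)
  expect_equal(adj$photon[1], 0.96)
  expect_equal(adj$b10[1], 0.65)
  expect_error(apply_drsf(adj, rb), "already")
  ts2 <- tiny_setup(2)
  expect_equal(apply_drsf(ts2$cdm, rb)$fast[1], 2.78)
  rb1 <- radiobiology_params(drsf = c(thermal = 1, fast = 1, photon = 1,
                                      b10 = 1))
  id <- apply_drsf(tiny_setup(3)$cdm, rb1)
  expect_equal(id$thermal, tiny_setup(3)$cdm$thermal)
})

test_that("boron map encodes the T/N uptake ratio exactly", {
  st <- tiny_setup()$st
  b <- build_boron_map(st, rb, ref_conc = 25)
  expect_equal(b[st$masks$CTV][1], 87.5)
  expect_equal(unique(b[st$masks$body & !st$masks$CTV]), 25)
  expect_equal(mean(b[st$masks$CTV]) / mean(b[st$masks$NB]), 3.5)
  u <- build_boron_map(st, radiobiology_params(tn_ratio = 1), 25)
  expect_equal(length(unique(u[st$masks$body])), 1L)
})

test_that("RBE weighting reproduces hand-computed voxel values exactly", {
  ts <- tiny_setup(1)
  # bypass DRSF: unit *adjusted* components
  adj <- ts$cdm; adj$drsf_applied <- TRUE
  # with boron at the reference concentration everywhere, the weighting is
  # the plain RBE/CBE sum: 3.2 + 3.2 + 0.5 + CBE
  flat <- build_boron_map(ts$st, radiobiology_params(tn_ratio = 1), 25)
  dm <- rbe_weighted_dose(adj, flat, ts$st, rb, beam_minutes = 1)
  expect_equal(dm$dose[2, 1, 1], 8.2, tolerance = 1e-12)
  expect_equal(dm$dose[1, 1, 1], 10.7, tolerance = 1e-12)
  # with the T/N-scaled boron map the tumor boron term scales by T/N
  boron <- build_boron_map(ts$st, rb, 25)
  dm2 <- rbe_weighted_dose(adj, boron, ts$st, rb, beam_minutes = 1)
  expect_equal(dm2$dose[2, 1, 1], 8.2, tolerance = 1e-12)
  expect_equal(dm2$dose[1, 1, 1],
               3.2 + 3.2 + 0.5 + 3.8 * 3.5, tolerance = 1e-12)
  zero <- ts$cdm
  for (cmp in c("thermal", "fast", "photon", "b10"))
    zero[[cmp]] <- array(0, dim(zero[[cmp]]))
  zero$drsf_applied <- TRUE
  expect_true(all(rbe_weighted_dose(zero, boron, ts$st, rb)$dose == 0))
  # weighting refuses unadjusted components
  expect_error(rbe_weighted_dose(ts$cdm, boron, ts$st, rb), "apply_drsf")
})

test_that("RBE dose is linear in beam time and superposes across fields", {
  ph <- fixture_phantom()
  bm <- fixture_beam_model()
  st <- ph$structures
  boron <- build_boron_map(st, rb, bm$reference_boron_ppm)
  adj <- apply_drsf(trace_field(ph$materials, st, beam_spec(90), bm), rb)
  d1 <- rbe_weighted_dose(adj, boron, st, rb, beam_minutes = 1)$dose
  d2 <- rbe_weighted_dose(adj, boron, st, rb, beam_minutes = 2)$dose
  expect_equal(d2, 2 * d1)
  r270 <- field_rbe_rate(ph$materials, st, beam_spec(270), bm, rb, boron)
  combined <- combine_fields(list(d1, r270), c(1, 1))
  expect_equal(combined, 0.5 * d1 + 0.5 * r270)
})

test_that("opposed beams on a left-right symmetric phantom mirror", {
  p <- phantom_params(ctv_center = c(0, 1.28, -2), axis_scale_sd = 0,
                      ctv_center_jitter_cm = 0, ctv_scale_sd = 0)
  ph <- generate_head_phantom(p)
  bm <- fixture_beam_model()
  st <- ph$structures
  boron <- build_boron_map(st, rb, bm$reference_boron_ppm)
  left <- field_rbe_rate(ph$materials, st, beam_spec(90), bm, rb, boron)
  right <- field_rbe_rate(ph$materials, st, beam_spec(270), bm, rb, boron)
  nx <- dim(left)[1]
  mirrored <- right[nx:1, , ]
  expect_equal(max(abs(left - mirrored)) / max(left), 0, tolerance = 0.02)
})

test_that("tracing a beam that misses the body warns and returns zeros", {
  geom <- grid_geometry(c(4, 4, 4), 0.5)
  mats <- structure(list(labels = array(MATERIALS[["air"]], geom$dim),
                         geom = geom), class = "material_map")
  st <- tiny_setup()$st
  expect_warning(cdm <- trace_field(mats, st, beam_spec(0),
                                    fixture_beam_model(),
                                    isocenter = c(0, 0, 0)),
                 "misses")
  expect_true(all(cdm$thermal == 0))
})

test_that("on-axis weighted curves in water cross at the advantage depth", {
  bm <- fixture_beam_model()
  # engine consistency: a homogeneous water slab traced by the engine gives
  # tumor- and normal-weighted doses whose crossing is the model AD
  slab <- water_slab(nx = 30, ny = 70, nz = 20, spacing = 0.4)
  geom <- slab$geom
  y <- axis_coords(geom, 2)
  entry_y <- y[2]
  st_masks <- slab$labels != MATERIALS[["air"]]
  ad <- compute_advantage_depth(bm, rb)
  # normal maximum along the axis, from engine-traced dose
  pts <- cbind(0, y[y > entry_y & y < entry_y + 20], 0)
  depth <- radiological_depth(slab, beam_spec(0), pts)
  tum <- weighted_depth_dose(depth, bm, rb, "tumor")
  nor <- weighted_depth_dose(depth, bm, rb, "normal")
  crossing <- depth[max(which(tum >= max(nor)))]
  expect_equal(crossing, ad, tolerance = 0.25)
})

test_that("dose maps export with a provenance sidecar", {
  geom <- grid_geometry(c(4, 4, 2), 0.5)
  dose <- array(runif(32), geom$dim)
  path <- tempfile(fileext = ".nii.gz")
  params_file <- system.file("extdata", "thor_default.yaml",
                             package = "bnctplan")
  export_dose_map(dose, geom, path, angles = c(90, 270),
                  weights = c(1.02, 0.98), minutes = 55.3,
                  params_file = params_file)
  rt <- read_volume(path)
  expect_equal(rt$vol, dose, tolerance = 1e-6, ignore_attr = TRUE)
  prov <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(prov$angles, c(90, 270))
  expect_equal(prov$minutes, 55.3)
  expect_equal(prov$params_md5, unname(tools::md5sum(params_file)))
  unlink(c(path, paste0(path, ".json")))
})
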