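geom8 <- grid_geometry(c(4, 2, 1), 0.5)   # 8 voxels of 0.125 cm^3

test_that("cumulative DVH counts voxels exactly", {
  mask <- array(TRUE, geom8$dim)
  uni <- array(2, geom8$dim)
  dvh <- cumulative_dvh(uni, mask, geom8, bin_width = 0.05)
  expect_equal(dvh$volume_fraction[1], 1)
  expect_equal(dvh$volume_fraction[length(dvh$volume_fraction)], 0)
  # step function: full volume up to the uniform dose, zero after
  expect_equal(dose_at_volume(dvh, 0.999), 2, tolerance = 0.051)
  expect_equal(dvh$volume_cm3, 8 * 0.125)
  # half volume at 1, half at 3: plateau at 0.5 on (1, 3]
  half <- array(c(rep(1, 4), rep(3, 4)), geom8$dim)
  dvh2 <- cumulative_dvh(half, mask, geom8, bin_width = 0.05)
  mid <- dvh2$dose > 1.01 & dvh2$dose <= 3
  expect_true(all(dvh2$volume_fraction[mid] == 0.5))
  expect_true(all(diff(dvh2$volume_fraction) <= 0))
  expect_error(cumulative_dvh(uni, array(FALSE, geom8$dim), geom8), "empty")
})

test_that("dose_at_volume inverts the cumulative curve linearly", {
  # synthetic linear DVH from (0, 1) to (10, 0): D at v is 10 * (1 - v)
  dvh <- structure(list(dose = seq(0, 10, 0.5),
                        volume_fraction = seq(1, 0, length.out = 21),
                        volume_cm3 = 1), class = "dvh")
  expect_equal(dose_at_volume(dvh, 0.95), 0.5)
  expect_equal(dose_at_volume(dvh, 0.05), 9.5)
  expect_equal(dose_at_volume(dvh, 0.5), 5)
})

test_that("DVH inversion agrees with brute-force voxel percentiles", {
  set.seed(11)
  geom <- grid_geometry(c(20, 20, 5), 0.2)
  dose <- array(rgamma(prod(geom$dim), shape = 4, scale = 3), geom$dim)
  mask <- array(runif(prod(geom$dim)) < 0.6, geom$dim)
  dvh <- cumulative_dvh(dose, mask, geom, bin_width = 0.05)
  d <- dose[mask]
  for (v in c(0.95, 0.8, 0.5, 0.2, 0.05)) {
    oracle <- as.numeric(quantile(d, 1 - v, type = 1))
    expect_equal(dose_at_volume(dvh, v), oracle, tolerance = 0.051)
  }
})

test_that("homogeneity index is D5 over D95", {
  mask <- array(TRUE, geom8$dim)
  uni <- cumulative_dvh(array(7, geom8$dim), mask, geom8)
  expect_equal(homogeneity_index(uni), 1, tolerance = 0.02)
  dvh <- structure(list(dose = seq(0, 30, 0.05),
                        volume_fraction = NA, volume_cm3 = 1),
                   class = "dvh")
  # piecewise linear with D95 = 19, D5 = 24
  dvh$volume_fraction <- stats::approx(c(0, 19, 24, 30), c(1, 0.95, 0.05, 0),
                                       xout = dvh$dose)$y
  expect_equal(homogeneity_index(dvh), 24 / 19, tolerance = 1e-6)
})

test_that("integral dose equals the voxelwise sum oracle", {
  mask <- array(TRUE, geom8$dim)
  uni <- array(2, geom8$dim)
  # uniform 2 Gy-Eq over 1 cm^3 = 0.001 L -> 0.002; scale to the 0.5-L case
  expect_equal(integral_dose(uni, mask, geom8), 2 * (8 * 0.125) / 1000)
  set.seed(4)
  dose <- array(runif(8, 0, 5), geom8$dim)
  oracle <- sum(dose) * voxel_volume_cm3(geom8) / 1000
  expect_equal(integral_dose(dose, mask, geom8), oracle)
  expect_equal(integral_dose(0 * dose, mask, geom8), 0)
  # additivity over disjoint masks
  m1 <- array(c(rep(TRUE, 4), rep(FALSE, 4)), geom8$dim)
  expect_equal(integral_dose(dose, m1, geom8) +
                 integral_dose(dose, !m1, geom8),
               integral_dose(dose, mask, geom8))
})

test_that("therapeutic gain is the CTVmin / NTmax ratio", {
  expect_equal(therapeutic_gain(16, 8), 2)
  expect_error(therapeutic_gain(16, 0), "positive")
})

test_that("OAR metrics apply strict tolerances and report absences", {
  ph <- fixture_phantom()
  st <- ph$structures
  dose <- array(0, st$geom$dim)
  dose[st$masks$NB] <- 7
  dose[st$masks$L_ON] <- 10    # exactly at the 10 Gy-Eq limit: strict fail
  dose[st$masks$CW] <- 3
  o <- oar_metrics(dose, st)
  expect_true(o$pass[o$structure == "NB"])
  expect_false(o$pass[o$structure == "L_ON"])
  expect_true(o$pass[o$structure == "CW"])
  expect_equal(o$Dmean[o$structure == "CW"], o$Dmax[o$structure == "CW"])
  # missing structure is reported, not skipped
  o2 <- oar_metrics(dose, st, tolerances = c(NB = 13, retina = 5))
  expect_false(o2$present[o2$structure == "retina"])
  expect_true(is.na(o2$pass[o2$structure == "retina"]))
})

test_that("deepest depth in a sphere with centred target is radius plus r", {
  p <- phantom_params(head_semiaxes = c(7, 7, 7), head_exponent = 2,
                      head_z_exponent = 2, brain_semiaxes = c(5, 5, 5),
                      ctv_center = c(0, 0, 0), ctv_semiaxes = c(1, 1, 1),
                      neck_base_z = -6.2, axis_scale_sd = 0,
                      ctv_center_jitter_cm = 0, ctv_scale_sd = 0)
  ph <- generate_head_phantom(p)
  for (a in c(0, 60, 90, 180, 270, 300))
    expect_equal(max_tumor_depth(ph$structures$masks$body,
                                 ph$structures$masks$CTV, a,
                                 ph$structures$geom),
                 8, tolerance = 0.1)
})

test_that("depth is invariant under joint rotation of phantom and beam", {
  # 90-degree rotation of the grid about z maps angle a to a + 90
  ph <- fixture_phantom()
  st <- ph$structures
  d0 <- max_tumor_depth(st$masks$body, st$masks$CTV, 0, st$geom)
  rot <- function(m) aperm(m, c(2, 1, 3))[dim(m)[2]:1, , ]  # x,y -> -y,x
  body_r <- rot(st$masks$body); ctv_r <- rot(st$masks$CTV)
  geom_r <- grid_geometry(dim(body_r), st$geom$spacing)
  d90 <- max_tumor_depth(body_r, ctv_r, 90, geom_r)
  expect_equal(d90, d0, tolerance = 0.1)
})

test_that("structure metrics obey the DVH ordering chain", {
  set.seed(9)
  geom <- grid_geometry(c(15, 15, 6), 0.2)
  dose <- array(rgamma(prod(geom$dim), 5, 1), geom$dim)
  mask <- array(TRUE, geom$dim)
  sm <- structure_metrics(dose, mask, geom)
  expect_lte(sm$Dmin, sm$D95 + 0.05)
  expect_lte(sm$D95, sm$Dmean + 0.05)
  expect_lte(sm$Dmean, sm$D5 + 0.05)
  expect_lte(sm$D5, sm$Dmax + 0.05)
  expect_gte(sm$HI, 1)
  expect_equal(sm$ID_GyEqL, mean(dose) * mask_volume_cm3(mask, geom) / 1000)
})
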