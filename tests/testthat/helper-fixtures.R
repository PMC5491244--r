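# Small shared fixtures built in code.

# a coarse default phantom reused across tests (2-mm grid, deterministic)
fixture_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- generate_head_phantom(phantom_params(seed = 2))
    ph
  }
})

fixture_beam_model <- local({
  bm <- NULL
  function() {
    if (is.null(bm)) bm <<- default_beam_model()
    bm
  }
})

# tiny homogeneous water slab: soft tissue filling the grid except an air rim
water_slab <- function(nx = 40, ny = 40, nz = 20, spacing = 0.5) {
  geom <- grid_geometry(c(nx, ny, nz), spacing)
  labels <- array(MATERIALS[["soft_tissue"]], geom$dim)
  labels[c(1, nx), , ] <- MATERIALS[["air"]]
  labels[, c(1, ny), ] <- MATERIALS[["air"]]
  structure(list(labels = labels, geom = geom), class = "material_map")
}
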