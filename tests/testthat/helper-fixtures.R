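# Shared fixtures, generated once per test run and cached across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

# compact phantom for unit tests (fast to build and to mold)
small_phantom_spec <- function() {
  phantom_spec(kidney_semiaxes_mm = c(30, 17, 14), tumor_radius_mm = 12,
               fat_range_mm = c(3, 8), fat_min_mm = 1, hilum_notch_mm = 8,
               map_spacing_mm = 2)
}

small_anatomy <- function() {
  fixture("small_anatomy", function() make_anatomy(small_phantom_spec(), seed = 3))
}

small_build <- function() {
  fixture("small_build", function() {
    build_mold(small_anatomy()$study, mode = "transverse",
               spec = mold_spec(slice_spacing_mm = 5, hole_diameter_mm = 10),
               target_faces = 12000)
  })
}

# the full-size phantom and mold under the default study conditions
default_anatomy <- function() {
  fixture("default_anatomy", function() make_anatomy(phantom_spec(), seed = 7))
}

default_build <- function() {
  fixture("default_build", function() {
    build_mold(default_anatomy()$study, mode = "transverse")
  })
}

# dense sphere meshes for the geometry oracles
sphere_field <- function(r = 15, spacing = 1, pad = 4) {
  n <- ceiling(2 * (r + pad) / spacing) + 1
  ctr <- (n - 1) / 2 * spacing
  co <- (0:(n - 1)) * spacing - ctr
  D <- sqrt(outer(outer(co^2, co^2, `+`), co^2, `+`))
  list(field = r - D, mask = D <= r, spacing = rep(spacing, 3),
       center = rep(ctr, 3), r = r, n = n)
}

sphere_mesh <- function(r = 15, spacing = 1) {
  fixture(paste0("sphere_mesh_", r, "_", spacing), function() {
    sf <- sphere_field(r, spacing)
    extract_surface(sf$field, sf$spacing, 0)
  })
}

# a synthetic one-mask study on an identity-affine lattice (sphere tumor),
# already expressed in a frame; used by carve/cross-section oracles
sphere_study <- function(r = 15, spacing = 1) {
  fixture(paste0("sphere_study_", r, "_", spacing), function() {
    sf <- sphere_field(r, spacing)
    aff <- diag(c(rep(spacing, 3), 1))
    seg <- segmentation_set(list(tumor = sf$mask), aff)
    ctr <- sf$center
    # anchors on the -y side: the transverse frame for this geometry has
    # up = +y, so they sit at the cavity bottom where the holes are carved
    lms <- landmark_set(list(
      upper_pole = ctr + c(r, 0, 0),
      lower_pole = ctr - c(r, 0, 0),
      hilum = ctr + c(-r / 2, -r * sqrt(3) / 2, 0),
      tumor_contact = ctr + c(r / 2, -r * sqrt(3) / 2, 0)))
    study <- mri_study(seg, lms)
    frame <- sectioning_frame(lms, ctr, "transverse")
    resample_to_frame(study, frame, spacing_mm = spacing)
  })
}

expect_watertight <- function(mesh) {
  expect_true(mesh_is_watertight(mesh))
  expect_gt(mesh_volume(mesh), 0)
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}
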