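# Desk-scale phantom used across tests: 32^3 at 1 mm.
tiny_spec <- function(noise_sd = 0, seed = 1L) {
  phantom_spec(grid_shape = c(32L, 32L, 32L), class_noise_sd = noise_sd,
               seed = seed)
}

# A flat 1-D-like volume for intensity arithmetic tests: values laid along
# the first axis of an n x 1 x 1 grid.
line_volume <- function(values, voxel_dims = c(1, 1, 1), id = "line") {
  image_volume(array(values, dim = c(length(values), 1, 1)),
               diag(c(voxel_dims, 1)), id = id)
}

line_mask <- function(bits, voxel_dims = c(1, 1, 1), id = "linemask") {
  binary_mask(array(as.double(bits), dim = c(length(bits), 1, 1)),
              diag(c(voxel_dims, 1)), id = id)
}

# Centered affine so that hemisphere tests can place voxels at world x < 0
# and x > 0.
centered_volume <- function(arr, voxel_dims = c(1, 1, 1), id = "vol") {
  d <- dim(arr)
  aff <- diag(c(voxel_dims, 1))
  aff[1:3, 4] <- -voxel_dims * (d - 1) / 2
  image_volume(arr, aff, id = id)
}

centered_mask <- function(arr, voxel_dims = c(1, 1, 1), id = "mask") {
  v <- centered_volume(arr, voxel_dims, id)
  binary_mask(v$data, v$affine, id = id)
}

# One unilateral bright homogeneous lesion transplanted into a noise-free
# control phantom; the scenario used for mechanism tests.
mechanism_case <- function(mean_ui = 6, volume_mm3 = 800, seed = 3L) {
  host <- generate_phantom(tiny_spec(0, seed = 11L), id = "P1")
  ctl <- generate_phantom(tiny_spec(0, seed = 12L), id = "C1")
  les <- generate_synthetic_lesion(
    host,
    synthetic_lesion_spec(volume_mm3, mean_intensity_ui = mean_ui,
                          sd_intensity_ui = 0, hemisphere = "lh",
                          seed = seed),
    lesion_id = "L1"
  )
  list(control = ctl,
       case = transplant(extract_patch(les$patient, les$mask), ctl$image))
}
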