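test_that("1/f noise masks match target statistics and spectral slope", {
  spec <- noise_mask_spec(128)
  nm <- make_noise_mask(spec, seed = 3)
  expect_lt(abs(mean(nm) - 0.5), 1e-9)
  expect_lt(abs(rms_contrast(nm) - 0.12), 1e-9)
  # radially averaged log amplitude vs log frequency slope ~ -1
  FF <- abs(stats::fft(nm - mean(nm)))
  fr <- c(0:63, -64:-1) / 128
  r <- sqrt(outer(fr^2, fr^2, `+`))
  mid <- r > 0.03 & r < 0.3
  bins <- cut(log10(r[mid]), 12)
  la <- tapply(log10(FF[mid]), bins, mean)
  lf <- tapply(log10(r[mid]), bins, mean)
  slope <- stats::coef(stats::lm(la ~ lf))[2]
  expect_lt(abs(slope + 1), 0.15)
  # determinism contract
  expect_identical(make_noise_mask(spec, seed = 3), nm)
  expect_false(identical(make_noise_mask(spec, seed = 4), nm))
})

test_that("synthetic faces are deterministic, identity-distinct, and carry
           more horizontal than vertical structure", {
  id1 <- face_identity_params(1)
  expect_identical(generate_synthetic_face(id1, 5, 96, 98),
                   generate_synthetic_face(id1, 5, 96, 98))
  f1 <- small_face(1, 2)
  f2 <- small_face(3, 2)
  expect_gt(sqrt(mean((f1 - f2)^2)), 0)
  # horizontal feature bands: the 90-degree filter retains more energy
  z <- normalize_image(f1, 0, 1)
  rms90 <- rms_contrast(orientation_filter(z, orientation_filter_spec(90)))
  rms0 <- rms_contrast(orientation_filter(z, orientation_filter_spec(0)))
  expect_gt(rms90, rms0)
})

test_that("aperture mask is elliptical with a soft edge and blends to grey", {
  faces <- lapply(1:3, function(i) small_face(i, i + 10))
  mask <- make_aperture_mask(faces, background = 0.5)
  expect_true(all(mask >= 0 & mask <= 1))
  expect_equal(mask[48, 49], 1)        # face center visible
  expect_equal(mask[1, 1], 0)          # corner hidden
  img <- matrix(0.5, 96, 98)
  expect_equal(blend_aperture(img, mask), img)  # background-grey image fixed
  blended <- blend_aperture(faces[[1]], mask)
  expect_equal(blended[1, 1], 0.5)
  expect_error(make_aperture_mask(list(faces[[1]], matrix(0.5, 4, 4))),
               "dimensions")
})

test_that("generated stimulus set is equalized, barely clipped, reproducible", {
  set <- generate_stimulus_set(n_identities = 3, images_per_identity = 2,
                               height_px = 96, width_px = 98, pad_px = 30,
                               seed = 5)
  expect_true(all(set$clipped$clipped_fraction < 0.03))
  expect_equal(nrow(set$clipped), 3 * 2 * 7)
  # every stimulus in displayable range after clipping + aperture
  s <- set$stimuli[[2]][[1]][["60"]]
  expect_true(all(s >= 0 & s <= 1))
  set2 <- generate_stimulus_set(n_identities = 3, images_per_identity = 2,
                                height_px = 96, width_px = 98, pad_px = 30,
                                seed = 5)
  expect_identical(set2$stimuli[[1]][[1]][["0"]], set$stimuli[[1]][[1]][["0"]])
  # stimulus-type rendering: involutions, and negation commutes with the blend
  nat <- render_stimulus(set, 1, 1, "90", "natural")
  expect_identical(invert_image(render_stimulus(set, 1, 1, "90", "inverted")),
                   nat)
  expect_lt(max(abs(negate_image(render_stimulus(set, 1, 1, "90", "negated")) -
                      nat)), 1e-15)
})
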