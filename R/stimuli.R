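#' Generate an orientation-filtered stimulus set
#'
#' Runs the full stimulus pipeline on a synthetic face set:
#' mirror padding (100 px), normalization to mean 0 / RMS 1, wrapped-Gaussian
#' orientation filtering of the Fourier amplitude spectrum (centers 0..150 in
#' 30-degree steps, sigma 25), cropping of the pad, renormalization to the
#' image-set statistics (mean 0.5, RMS contrast 0.12), clipping to \[0, 1\]
#' (the clipped fraction is recorded per image and must stay below 3\%), and
#' blending with the elliptical aperture fitted to the set average.
#'
#' Only the natural (upright, positive-contrast) stimuli are materialized:
#' inverted stimuli are `invert_image()` of the natural ones and negated
#' stimuli are `negate_image()` applied before the aperture blend — both are
#' cheap involutions, available through [render_stimulus()].
#'
#' @param n_identities,images_per_identity size of the face set (defaults
#'   10 x 3, the 30 images used in the experiment proper).
#' @param filter_centers_deg orientation filter centers.
#' @param sigma_deg filter standard deviation in degrees.
#' @param height_px,width_px face image size.
#' @param pad_px mirror padding in pixels.
#' @param target_mean,target_rms final luminance statistics.
#' @param seed integer seed (identities + image jitters).
#' @param out_dir optional directory: if given, natural stimuli are written
#'   as PNG under `out_dir/<filter>/` with a `manifest.csv`.
#' @return a list with elements `stimuli` (nested list
#'   `[[identity]][[image]][[filter_label]]`, filter labels `"0"`..`"150"` and
#'   `"fullspectrum"`, aperture already blended), `aperture` (the mask),
#'   `manifest` (data frame), and `clipped` (data frame per image x filter of
#'   the equalized mean, RMS contrast and pre-clip clipped fraction).
#' @export
generate_stimulus_set <- function(n_identities = 10, images_per_identity = 3,
                                  filter_centers_deg = seq(0, 150, by = 30),
                                  sigma_deg = 25,
                                  height_px = 302, width_px = 309,
                                  pad_px = 100,
                                  target_mean = 0.5, target_rms = 0.12,
                                  seed = 1, out_dir = NULL) {
  ids <- sample_identities(n_identities, seed = seed)
  faces <- render_face_set(ids, images_per_identity, seed = seed + 1L,
                           height_px = height_px, width_px = width_px)

  specs <- lapply(filter_centers_deg, orientation_filter_spec,
                  sigma_deg = sigma_deg)
  names(specs) <- as.character(filter_centers_deg)

  filtered <- vector("list", n_identities)
  clipped <- list()
  for (i in seq_len(n_identities)) {
    filtered[[i]] <- vector("list", images_per_identity)
    for (k in seq_len(images_per_identity)) {
      padded <- normalize_image(mirror_pad(faces[[i]][[k]], pad_px), 0, 1)
      out <- list()
      for (lab in names(specs)) {
        flt <- crop_pad(orientation_filter(padded, specs[[lab]]), pad_px)
        flt <- normalize_image(flt, target_mean, target_rms)
        clipped[[length(clipped) + 1L]] <-
          data.frame(identity = i, image = k, filter = lab,
                     mean = mean(flt), rms = rms_contrast(flt),
                     clipped_fraction = clipped_fraction(flt))
        out[[lab]] <- clip_image(flt)
      }
      fs <- normalize_image(faces[[i]][[k]], target_mean, target_rms)
      clipped[[length(clipped) + 1L]] <-
        data.frame(identity = i, image = k, filter = "fullspectrum",
                   mean = mean(fs), rms = rms_contrast(fs),
                   clipped_fraction = clipped_fraction(fs))
      out[["fullspectrum"]] <- clip_image(fs)
      filtered[[i]][[k]] <- out
    }
  }
  clipped <- do.call(rbind, clipped)

  # fit the ellipse to the raw face average, whose background is exactly
  # mid-grey; the renormalized stimuli shift the background grey slightly
  aperture <- make_aperture_mask(unlist(faces, recursive = FALSE),
                                 background = 0.5)
  for (i in seq_len(n_identities))
    for (k in seq_len(images_per_identity))
      filtered[[i]][[k]] <- lapply(filtered[[i]][[k]], blend_aperture,
                                   mask = aperture, background = target_mean)

  labs <- c(names(specs), "fullspectrum")
  manifest <- expand.grid(identity = seq_len(n_identities),
                          image = seq_len(images_per_identity),
                          filter = labs, stringsAsFactors = FALSE)
  manifest$image_id <- paste0("id", manifest$identity, "_img", manifest$image)

  if (!is.null(out_dir)) {
    for (lab in labs) {
      d <- file.path(out_dir, "natural", lab)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_len(n_identities))
        for (k in seq_len(images_per_identity))
          write_image_png(filtered[[i]][[k]][[lab]],
                          file.path(d, sprintf("id%d_img%d.png", i, k)))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }

  list(stimuli = filtered, aperture = aperture, manifest = manifest,
       clipped = clipped)
}

#' Render one stimulus in a given stimulus type
#'
#' Maps a natural (pre-aperture logic already applied) stimulus to the
#' requested stimulus type: `"natural"` returns it unchanged, `"inverted"`
#' rotates it 180 degrees in the picture plane, `"negated"` reverses contrast
#' polarity about the background grey. Negation of an aperture-blended image
#' about the background level equals blending the negated face, so the
#' pipeline order (negate before blend) is respected.
#'
#' @param set result of [generate_stimulus_set()].
#' @param identity,image,filter indices/label into the set.
#' @param stimulus_type one of `"natural"`, `"inverted"`, `"negated"`.
#' @export
render_stimulus <- function(set, identity, image, filter,
                            stimulus_type = c("natural", "inverted", "negated")) {
  stimulus_type <- match.arg(stimulus_type)
  img <- set$stimuli[[identity]][[image]][[as.character(filter)]]
  if (is.null(img)) stop("no such stimulus", call. = FALSE)
  switch(stimulus_type,
         natural = img,
         inverted = invert_image(img),
         negated = negate_image(img))
}
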