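# Synthetic fundus phantoms: a circular field of view with radial
# illumination falloff, dark curved vessels, a bright soft-edged elliptical
# optic disc containing a brighter optic cup, plus per-domain appearance
# presets. Everything other modules need (paired masks with cup inside disc,
# appearance shifts between domains, deterministic rendering under a seed)
# is emulated; photorealism and pathology are explicit non-goals.

#' Phantom specification
#'
#' @param image_size square image side in pixels.
#' @param fov_radius_frac field-of-view radius as a fraction of half-size.
#' @param disc_center `(row, col)`; defaults to the image center.
#' @param disc_radii semi-axes `(a, b)` of the disc ellipse in pixels.
#' @param cup_to_disc_ratio linear cup-to-disc ratio in (0, 1); the cup
#'   ellipse has semi-axes `ratio * disc_radii`.
#' @param cup_offset cup center offset `(row, col)` relative to the disc
#'   center (clipped so the cup stays strictly inside the disc).
#' @param background,disc_color,cup_color RGB triples in `[0, 1]`.
#' @param boundary_softness edge softness in pixels.
#' @param vessel_count number of vessel strokes.
#' @param vessel_darkness multiplicative darkening of vessel pixels.
#' @param vessel_width stroke width in pixels.
#' @param noise_sigma Gaussian pixel noise standard deviation.
#' @param seed RNG seed making the rendering deterministic.
#' @return a `fundseg_phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 512, fov_radius_frac = 0.95,
                         disc_center = NULL, disc_radii = c(55, 50),
                         cup_to_disc_ratio = 0.5, cup_offset = c(0, 0),
                         background = c(0.80, 0.42, 0.20),
                         disc_color = c(0.98, 0.82, 0.55),
                         cup_color = c(1.00, 0.95, 0.75),
                         boundary_softness = 2.5,
                         vessel_count = 4, vessel_darkness = 0.45,
                         vessel_width = 4, noise_sigma = 0.02, seed = 1) {
  if (is.null(disc_center)) disc_center <- c(image_size / 2, image_size / 2)
  sp <- list(image_size = as.integer(image_size),
             fov_radius_frac = fov_radius_frac, disc_center = disc_center,
             disc_radii = disc_radii, cup_to_disc_ratio = cup_to_disc_ratio,
             cup_offset = cup_offset, background = background,
             disc_color = disc_color, cup_color = cup_color,
             boundary_softness = boundary_softness,
             vessel_count = as.integer(vessel_count),
             vessel_darkness = vessel_darkness, vessel_width = vessel_width,
             noise_sigma = noise_sigma, seed = seed)
  validate_phantom_spec(sp)
}

validate_phantom_spec <- function(sp) {
  if (sp$cup_to_disc_ratio <= 0 || sp$cup_to_disc_ratio >= 1)
    stopf("cup_to_disc_ratio must be strictly inside (0, 1)")
  fov_r <- sp$fov_radius_frac * sp$image_size / 2
  ctr <- sp$image_size / 2
  if (sqrt(sum((sp$disc_center - ctr)^2)) + max(sp$disc_radii) > fov_r)
    stopf("disc ellipse must lie inside the field of view")
  # cup strictly inside disc: offset + ratio * radius < radius
  margin <- (1 - sp$cup_to_disc_ratio) * min(sp$disc_radii)
  if (sqrt(sum(sp$cup_offset^2)) >= margin)
    stopf("cup ellipse must lie strictly inside the disc ellipse")
  structure(sp, class = "fundseg_phantom_spec")
}

# normalized elliptical distance: <=1 inside the ellipse
ellipse_q <- function(rr, cc, center, radii) {
  sqrt(((rr - center[1]) / radii[1])^2 + ((cc - center[2]) / radii[2])^2)
}

#' Render a fundus phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (`[s, s, 3]`, values in `[0, 1]`), `mask`
#'   (integer matrix; 0 background, 1 disc rim, 2 cup) and `metadata`
#'   (true center, radii, cup-to-disc ratio, seed).
#' @export
generate_phantom <- function(spec) {
  spec <- validate_phantom_spec(spec)
  s <- spec$image_size
  with_seed(spec$seed, {
    rr <- matrix(seq_len(s), s, s)
    cc <- matrix(seq_len(s), s, s, byrow = TRUE)
    ctr <- (s + 1) / 2
    fov_r <- spec$fov_radius_frac * s / 2
    d_ctr <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
    fov <- d_ctr <= fov_r
    illum <- (1 - 0.45 * (d_ctr / fov_r)^2) * fov
    img <- array(0, c(s, s, 3))
    for (ch in 1:3) img[, , ch] <- spec$background[ch] * illum
    # vessels: quadratic Bezier strokes from the FOV edge through mid-field
    vs <- matrix(0, s, s)
    for (v in seq_len(spec$vessel_count)) {
      th <- stats::runif(1, 0, 2 * pi)
      p0 <- c(ctr + 0.95 * fov_r * sin(th), ctr + 0.95 * fov_r * cos(th))
      p2 <- c(ctr + stats::runif(1, -0.3, 0.3) * fov_r,
              ctr + stats::runif(1, -0.3, 0.3) * fov_r)
      p1 <- (p0 + p2) / 2 + stats::runif(2, -0.25, 0.25) * fov_r
      t <- seq(0, 1, length.out = 4 * s)
      bez_r <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1]
      bez_c <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
      w <- max(1L, round(spec$vessel_width / 2))
      off <- expand.grid(dr = -w:w, dc = -w:w)
      off <- off[off$dr^2 + off$dc^2 <= w^2 + 1e-9, ]
      pr <- clamp(round(rep(bez_r, each = nrow(off)) + off$dr), 1, s)
      pc <- clamp(round(rep(bez_c, each = nrow(off)) + off$dc), 1, s)
      vs[cbind(pr, pc)] <- 1
    }
    dark <- 1 - spec$vessel_darkness * vs
    for (ch in 1:3) img[, , ch] <- img[, , ch] * dark
    # disc and cup (soft-edged in the image, exact in the mask)
    qd <- ellipse_q(rr, cc, spec$disc_center, spec$disc_radii)
    cup_center <- spec$disc_center + spec$cup_offset
    cup_radii <- spec$cup_to_disc_ratio * spec$disc_radii
    qc <- ellipse_q(rr, cc, cup_center, cup_radii)
    soft <- function(q, radii) {
      clamp((1 - q) * min(radii) / spec$boundary_softness, 0, 1)
    }
    ad <- soft(qd, spec$disc_radii)
    ac <- soft(qc, cup_radii)
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] * (1 - ad) + spec$disc_color[ch] * illum * ad
      img[, , ch] <- img[, , ch] * (1 - ac) + spec$cup_color[ch] * illum * ac
    }
    if (spec$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), sd = spec$noise_sigma),
                         dim(img))
    img <- clamp(img, 0, 1)
    mask <- matrix(0L, s, s)
    mask[qd <= 1] <- 1L
    mask[qc <= 1] <- 2L
    list(image = img, mask = mask,
         metadata = list(disc_center = spec$disc_center,
                         disc_radii = spec$disc_radii,
                         cup_center = cup_center, cup_radii = cup_radii,
                         cup_to_disc_ratio = spec$cup_to_disc_ratio,
                         seed = spec$seed))
  })
}

#' Domain appearance presets
#'
#' Four named presets (D1-D4) emulating acquisition shifts between centers
#' and devices: multiplicative color casts, contrast scaling, brightness
#' offsets, noise levels and disc-size distributions differ between
#' domains.
#'
#' @return named list of preset parameter lists.
#' @export
domain_presets <- function() {
  list(
    D1 = list(name = "D1", color_cast = c(1.00, 1.00, 1.00),
              contrast = 1.00, brightness = 0.00, noise = 0.02,
              disc_radius_range = c(45, 70), cdr_range = c(0.3, 0.7)),
    D2 = list(name = "D2", color_cast = c(1.08, 0.90, 0.78),
              contrast = 1.15, brightness = 0.06, noise = 0.035,
              disc_radius_range = c(55, 80), cdr_range = c(0.4, 0.8)),
    D3 = list(name = "D3", color_cast = c(0.85, 0.95, 1.10),
              contrast = 0.85, brightness = -0.05, noise = 0.015,
              disc_radius_range = c(40, 60), cdr_range = c(0.3, 0.6)),
    D4 = list(name = "D4", color_cast = c(0.95, 1.05, 0.90),
              contrast = 1.05, brightness = 0.10, noise = 0.05,
              disc_radius_range = c(35, 55), cdr_range = c(0.35, 0.75)))
}

sample_spec_from_preset <- function(preset, image_size, seed) {
  # preset radius ranges are expressed at the reference 512 px frame
  scale <- image_size / 512
  a <- scale * stats::runif(1, preset$disc_radius_range[1],
                            preset$disc_radius_range[2])
  b <- a * stats::runif(1, 0.85, 1.0)
  jit <- image_size * 0.06
  cdr <- stats::runif(1, preset$cdr_range[1], preset$cdr_range[2])
  # keep the cup strictly inside the disc at any frame size
  off <- 0.4 * (1 - cdr) * min(a, b) / sqrt(2)
  phantom_spec(
    image_size = image_size,
    disc_center = image_size / 2 + stats::runif(2, -jit, jit),
    disc_radii = c(a, b),
    cup_to_disc_ratio = cdr,
    cup_offset = stats::runif(2, -off, off),
    vessel_count = sample(3:6, 1),
    noise_sigma = preset$noise,
    seed = seed)
}

apply_preset_appearance <- function(img, preset) {
  for (ch in 1:3) img[, , ch] <- img[, , ch] * preset$color_cast[ch]
  img <- (img - 0.5) * preset$contrast + 0.5 + preset$brightness
  clamp(img, 0, 1)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/mask PNG pairs, per-image metadata JSON and a manifest
#' CSV (columns `image_path`, `mask_path`, `split`, `crop_size`) with a 4:1
#' train/validation split.
#'
#' @param n number of phantoms.
#' @param preset a preset from [domain_presets()] (or its name).
#' @param dir output directory.
#' @param seed RNG seed; the whole dataset is a pure function of it.
#' @param image_size phantom side in pixels.
#' @param crop_size crop size written to the manifest.
#' @param display_masks write masks with display labels {0, 128, 255}
#'   instead of raw labels {0, 1, 2}.
#' @return the manifest path, invisibly; the manifest tibble as attribute.
#' @export
generate_domain_dataset <- function(n, preset = "D1", dir, seed = 112316,
                                    image_size = 512, crop_size = 320,
                                    display_masks = FALSE) {
  stopifnot(n >= 1)
  if (is.character(preset)) preset <- domain_presets()[[preset]]
  if (is.null(preset)) stopf("unknown domain preset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, n)
    for (i in seq_len(n)) {
      sp <- sample_spec_from_preset(preset, image_size, seeds[i])
      ph <- generate_phantom(sp)
      img <- apply_preset_appearance(ph$image, preset)
      img_path <- file.path(dir, sprintf("img_%03d.png", i))
      msk_path <- file.path(dir, sprintf("mask_%03d.png", i))
      png::writePNG(img, img_path)
      mlab <- ph$mask
      if (display_masks) mlab <- c(0L, 128L, 255L)[mlab + 1L]
      png::writePNG(matrix(mlab / 255, nrow(mlab), ncol(mlab)), msk_path)
      jsonlite::write_json(ph$metadata,
                           file.path(dir, sprintf("meta_%03d.json", i)),
                           auto_unbox = TRUE, digits = NA)
      rows[[i]] <- tibble::tibble(
        image_path = basename(img_path), mask_path = basename(msk_path),
        split = if (i <= round(0.8 * n)) "train" else "val",
        crop_size = crop_size)
    }
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(structure(mp, manifest = manifest))
}
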