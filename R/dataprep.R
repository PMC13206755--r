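# Preprocessing and postprocessing: optic-disc-centered cropping, inter-area
# resizing, augmentation strategies, Z-score normalization, and exact
# restoration of predictions to original image coordinates.

#' Crop record
#'
#' Geometry needed to crop an OD-centered window and later restore a
#' prediction to the original coordinates exactly.
#'
#' @param original_height,original_width original image size in pixels.
#' @param od_center numeric `(row, col)` of the optic-disc center in
#'   original coordinates.
#' @param crop_size side of the square crop window (default 800).
#' @param input_size network input side after resizing (default 256).
#' @return a `fundseg_crop_record` list.
#' @export
crop_record <- function(original_height, original_width, od_center,
                        crop_size = 800, input_size = 256) {
  stopifnot(crop_size > 0, input_size > 0, length(od_center) == 2)
  structure(list(original_height = as.integer(original_height),
                 original_width = as.integer(original_width),
                 od_center = as.numeric(od_center),
                 crop_size = as.integer(crop_size),
                 input_size = as.integer(input_size)),
            class = "fundseg_crop_record")
}

crop_window <- function(record) {
  half <- record$crop_size %/% 2
  cr <- round(record$od_center)
  r0 <- cr[1] - half + 1; c0 <- cr[2] - half + 1
  r1 <- r0 + record$crop_size - 1; c1 <- c0 + record$crop_size - 1
  vr <- max(1, r0):min(record$original_height, r1)
  vc <- max(1, c0):min(record$original_width, c1)
  list(r0 = r0, c0 = c0, vr = vr, vc = vc,
       pad_top = vr[1] - r0, pad_left = vc[1] - c0)
}

## ---- OD center location ---------------------------------------------------

circle_from <- function(pts) {
  n <- nrow(pts)
  if (n == 0) return(list(c = c(0, 0), r = -1))
  if (n == 1) return(list(c = pts[1, ], r = 0))
  if (n == 2) {
    ctr <- (pts[1, ] + pts[2, ]) / 2
    return(list(c = ctr, r = sqrt(sum((pts[1, ] - ctr)^2))))
  }
  a <- pts[1, ]; b <- pts[2, ]; cc <- pts[3, ]
  d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) + cc[1] * (a[2] - b[2]))
  if (abs(d) < 1e-9) {
    # collinear: use the farthest pair's diameter circle
    prs <- utils::combn(3, 2)
    best <- NULL; bestr <- -1
    for (j in seq_len(ncol(prs))) {
      cir <- circle_from(pts[prs[, j], , drop = FALSE])
      if (cir$r > bestr) { best <- cir; bestr <- cir$r }
    }
    return(best)
  }
  ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
           sum(cc^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
           sum(cc^2) * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(c = ctr, r = sqrt(sum((a - ctr)^2)))
}

in_circle <- function(p, cir, tol = 1e-7) {
  cir$r >= 0 && sqrt(sum((p - cir$c)^2)) <= cir$r + tol
}

welzl_rec <- function(P, R) {
  if (nrow(P) == 0 || nrow(R) == 3) return(circle_from(R))
  p <- P[1, ]
  D <- welzl_rec(P[-1, , drop = FALSE], R)
  if (in_circle(p, D)) return(D)
  welzl_rec(P[-1, , drop = FALSE], rbind(R, p))
}

#' Minimum enclosing circle
#'
#' Exact smallest enclosing circle of a 2-D point set (Welzl's algorithm on
#' the convex hull).
#'
#' @param pts matrix with columns (row, col).
#' @return list with `c` (center, length 2) and `r` (radius).
#' @export
min_enclosing_circle <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  if (nrow(pts) > 3) {
    h <- grDevices::chull(pts[, 2], pts[, 1])
    pts <- pts[h, , drop = FALSE]
  }
  pts <- pts[sample.int(nrow(pts)), , drop = FALSE]
  welzl_rec(pts, matrix(0, 0, 2))
}

#' Locate the optic-disc center from a coarse mask
#'
#' Connected components of the coarse binary mask are filtered by an area
#' check (component area as a fraction of image area within `area_bounds`)
#' and a circularity check (`4 pi A / P^2` with `P` the boundary-pixel
#' count); the largest surviving component's minimum enclosing circle gives
#' the center.
#'
#' @param coarse_mask binary map (any detector output or ground truth).
#' @param area_bounds allowed component-area fraction range.
#' @param circularity_min minimum `4 pi A / P^2`.
#' @return integer `(row, col)` center.
#' @export
locate_od_center <- function(coarse_mask, area_bounds = c(5e-4, 0.15),
                             circularity_min = 0.5) {
  m <- as_binary_mask(coarse_mask)
  img_area <- length(m)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
  nlab <- max(lab)
  if (nlab == 0)
    stopf("no component found in coarse mask; fall back to the image center")
  best <- NULL; best_area <- -1
  for (k in seq_len(nlab)) {
    comp <- lab == k
    A <- sum(comp)
    frac <- A / img_area
    if (frac < area_bounds[1] || frac > area_bounds[2]) next
    bp <- boundary_points(comp)
    P <- nrow(bp)
    if (4 * pi * A / P^2 < circularity_min) next
    if (A > best_area) { best_area <- A; best <- bp }
  }
  if (is.null(best))
    stopf(paste0("no plausible optic-disc component passed the area and ",
                 "circularity checks; fall back to the image center"))
  cir <- min_enclosing_circle(best)
  as.integer(round(cir$c))
}

## ---- crop / resize / restore ---------------------------------------------

#' Crop an OD-centered window and resize to the network input size
#'
#' The `crop_size` window centered on the recorded OD center is extracted
#' (clipped at borders and zero-padded back to the full window), the image
#' is resized by area-based resampling (pixel-area relation) and the mask by
#' nearest neighbor so labels are preserved.
#'
#' @param image array `[H, W, C]` (values in `[0, 1]`).
#' @param mask optional integer label matrix `[H, W]`.
#' @param record a [crop_record()]; its `od_center` must lie in the image.
#' @return list with `image` (`input_size` square), `mask` (or `NULL`) and
#'   the `record` (unchanged; it already determines the geometry exactly).
#' @export
crop_and_resize <- function(image, mask = NULL, record) {
  d <- dim(image)
  if (d[1] != record$original_height || d[2] != record$original_width)
    stopf("image size %dx%d does not match record (%dx%d)",
          d[1], d[2], record$original_height, record$original_width)
  cr <- round(record$od_center)
  if (cr[1] < 1 || cr[1] > d[1] || cr[2] < 1 || cr[2] > d[2])
    stopf("od_center outside the image")
  w <- crop_window(record)
  cs <- record$crop_size
  C <- if (length(d) >= 3) d[3] else 1L
  canvas <- array(0, c(cs, cs, C))
  rows <- w$pad_top + seq_along(w$vr)
  cols <- w$pad_left + seq_along(w$vc)
  canvas[rows, cols, ] <- array(image, c(d[1], d[2], C))[w$vr, w$vc, , drop = FALSE]
  out_img <- resample_image(canvas, record$input_size, record$input_size, "area")
  out_mask <- NULL
  if (!is.null(mask)) {
    mcanvas <- matrix(0L, cs, cs)
    mcanvas[rows, cols] <- mask[w$vr, w$vc]
    out_mask <- resample_image(mcanvas, record$input_size, record$input_size,
                               "nearest")
  }
  list(image = out_img, mask = out_mask, record = record)
}

#' Restore a prediction to original image coordinates
#'
#' Per-class planes (one-hot of a label mask, or probability maps) are
#' bicubically upsampled from the input size to the crop size, re-argmaxed,
#' the border padding/clipping is inverted, and the labels are placed into a
#' zero (background) canvas of the original size at the recorded window.
#'
#' @param pred label matrix `[input_size, input_size]`, or probability array
#'   `[input_size, input_size, K]`.
#' @param record the [crop_record()] used for cropping.
#' @param K number of classes (inferred from probabilities or labels if
#'   missing).
#' @return integer label matrix `[original_height, original_width]`.
#' @export
restore_to_original <- function(pred, record, K = NULL) {
  ip <- record$input_size
  if (length(dim(pred)) == 3) {
    if (dim(pred)[1] != ip) stopf("prediction side does not match record")
    planes <- pred
    K <- dim(pred)[3]
  } else {
    if (!all(dim(pred) == c(ip, ip)))
      stopf("prediction side does not match record")
    if (is.null(K)) K <- max(pred) + 1
    planes <- array(0, c(ip, ip, K))
    for (k in seq_len(K)) planes[, , k] <- (pred == (k - 1)) * 1
  }
  cs <- record$crop_size
  up <- resample_image(planes, cs, cs, "bicubic")
  lab <- matrix(0L, cs, cs)
  best <- up[, , 1]
  if (K > 1) for (k in 2:K) {
    upd <- up[, , k] > best
    lab[upd] <- k - 1L
    best[upd] <- up[, , k][upd]
  }
  w <- crop_window(record)
  rows <- w$pad_top + seq_along(w$vr)
  cols <- w$pad_left + seq_along(w$vc)
  out <- matrix(0L, record$original_height, record$original_width)
  out[w$vr, w$vc] <- lab[rows, cols]
  out
}

#' Per-channel Z-score normalization
#'
#' Subtracts each channel's mean and divides by its standard deviation
#' (plus 1e-8).
#'
#' @param image array `[H, W, C]` (or a matrix).
#' @return normalized array of the same shape.
#' @export
zscore_normalize <- function(image) {
  d <- dim(image)
  if (length(d) == 2) d <- c(d, 1L)
  m <- matrix(image, d[1] * d[2], d[3])
  m <- sweep(m, 2, colMeans(m), "-")
  m <- sweep(m, 2, apply(m, 2, stats::sd) + 1e-8, "/")
  array(m, dim(image))
}

## ---- augmentation ---------------------------------------------------------

#' Augmentation parameters for a named strategy
#'
#' `"none"` applies nothing; `"spatial"` random rotation (uniform +-30
#' degrees, p = 0.5), vertical and horizontal flips (p = 0.5 each);
#' `"designed"` adds Gaussian blur, Gaussian noise, brightness shift,
#' contrast scaling and gamma correction at the listed probabilities.
#' Geometric transforms are applied identically to image and mask
#' (bicubic/nearest interpolation respectively); photometric transforms
#' touch the image only.
#'
#' @param strategy `"none"`, `"spatial"` or `"designed"`.
#' @return named list of per-transform parameters (probabilities, ranges).
#' @export
augmentation_params <- function(strategy = c("none", "spatial", "designed")) {
  strategy <- match.arg(strategy)
  spatial <- list(rotation = list(p = 0.5, range = c(-30, 30)),
                  vflip = list(p = 0.5),
                  hflip = list(p = 0.5))
  photometric <- list(blur = list(p = 0.2, sigma = c(0.5, 1.5)),
                      noise = list(p = 0.15, sigma = c(0, 0.05)),
                      brightness = list(p = 0.15, delta = c(-0.1, 0.1)),
                      contrast = list(p = 0.15, range = c(0.75, 1.25)),
                      gamma = list(p = 0.15, range = c(0.7, 1.5)))
  switch(strategy, none = list(), spatial = spatial,
         designed = c(spatial, photometric))
}

gaussian_blur <- function(img, sigma) {
  r <- max(1, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(img)
  C <- if (length(d) >= 3) d[3] else 1L
  m <- array(img, c(d[1], d[2], C))
  conv1 <- function(v, k, r) {
    # replicate-padded 1-D convolution along rows of a matrix
    n <- nrow(v)
    vp <- rbind(v[rep(1, r), , drop = FALSE], v, v[rep(n, r), , drop = FALSE])
    out <- 0
    for (j in seq_along(k)) out <- out + k[j] * vp[j:(j + n - 1), , drop = FALSE]
    out
  }
  for (c in seq_len(C)) {
    m[, , c] <- conv1(m[, , c], k, r)
    m[, , c] <- t(conv1(t(m[, , c]), k, r))
  }
  array(m, dim(img))
}

#' Apply an augmentation strategy to an image/mask pair
#'
#' Transform decisions are drawn from the current RNG stream in a fixed
#' order, so results are deterministic for a fixed seed.
#'
#' @param image array `[H, W, C]` in `[0, 1]`.
#' @param mask integer label matrix (or `NULL`).
#' @param strategy `"none"`, `"spatial"` or `"designed"`, or a parameter
#'   list from [augmentation_params()].
#' @return list with `image` and `mask`.
#' @export
augment <- function(image, mask = NULL, strategy = "none") {
  pars <- if (is.character(strategy)) augmentation_params(strategy)
  else strategy
  img <- image
  if (!is.null(pars$rotation) && stats::runif(1) < pars$rotation$p) {
    ang <- stats::runif(1, pars$rotation$range[1], pars$rotation$range[2])
    img <- rotate_image(img, ang, "bicubic")
    if (!is.null(mask)) mask <- rotate_image(mask, ang, "nearest")
  }
  if (!is.null(pars$vflip) && stats::runif(1) < pars$vflip$p) {
    img <- img[rev(seq_len(nrow(img))), , , drop = FALSE]
    if (!is.null(mask)) mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  if (!is.null(pars$hflip) && stats::runif(1) < pars$hflip$p) {
    img <- img[, rev(seq_len(ncol(img))), , drop = FALSE]
    if (!is.null(mask)) mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (!is.null(pars$blur) && stats::runif(1) < pars$blur$p) {
    img <- gaussian_blur(img, stats::runif(1, pars$blur$sigma[1],
                                           pars$blur$sigma[2]))
  }
  if (!is.null(pars$noise) && stats::runif(1) < pars$noise$p) {
    s <- stats::runif(1, pars$noise$sigma[1], pars$noise$sigma[2])
    img <- img + array(stats::rnorm(length(img), sd = s), dim(img))
  }
  if (!is.null(pars$brightness) && stats::runif(1) < pars$brightness$p) {
    img <- img + stats::runif(1, pars$brightness$delta[1],
                              pars$brightness$delta[2])
  }
  if (!is.null(pars$contrast) && stats::runif(1) < pars$contrast$p) {
    f <- stats::runif(1, pars$contrast$range[1], pars$contrast$range[2])
    img <- (img - mean(img)) * f + mean(img)
  }
  if (!is.null(pars$gamma) && stats::runif(1) < pars$gamma$p) {
    g <- stats::runif(1, pars$gamma$range[1], pars$gamma$range[2])
    img <- clamp(img, 0, 1)^g
  }
  if (length(pars)) img <- clamp(img, 0, 1)
  list(image = img, mask = mask)
}

# augment a training sample then Z-score normalize the image
augment_sample <- function(s, strategy) {
  a <- augment(s$image, s$mask, strategy)
  list(image = zscore_normalize(a$image), mask = a$mask %||% s$mask,
       record = s$record)
}

## ---- dataset manifests ----------------------------------------------------

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `image_path`, `mask_path`, `split`
#' (train/val/test) and `crop_size`; paths are resolved relative to the
#' manifest's directory.
#'
#' @param path manifest CSV path.
#' @return tibble with absolute paths.
#' @export
read_manifest <- function(path) {
  m <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("image_path", "mask_path", "split", "crop_size")
  miss <- setdiff(need, names(m))
  if (length(miss)) stopf("manifest lacks column(s): %s",
                          paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", m$image_path)
  m$image_path[rel] <- file.path(base, m$image_path[rel])
  rel <- !grepl("^(/|[A-Za-z]:)", m$mask_path)
  m$mask_path[rel] <- file.path(base, m$mask_path[rel])
  m
}

read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  x[, , 1:3, drop = FALSE]
}

read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  lab <- round(x * 255)
  # accept raw labels {0,1,2} or display labels {0,128,255}
  if (max(lab) > 8) lab <- round(lab / 127.5)
  matrix(as.integer(lab), nrow(lab), ncol(lab))
}

#' Load and preprocess one manifest row
#'
#' Reads the image and mask, locates the OD center from the ground-truth
#' disc region (the coarse-mask interface), crops and resizes.
#'
#' @param row one manifest row (list/tibble row).
#' @param input_size network input side.
#' @return a sample list: `image` (raw `[0,1]` crop), `mask`, `record`.
#' @export
load_sample <- function(row, input_size = 256) {
  img <- read_image_png(row$image_path)
  msk <- read_mask_png(row$mask_path)
  ctr <- tryCatch(locate_od_center(msk > 0),
                  error = function(e) round(dim(msk) / 2))
  rec <- crop_record(nrow(msk), ncol(msk), ctr,
                     crop_size = row$crop_size, input_size = input_size)
  cr <- crop_and_resize(img, msk, rec)
  list(image = cr$image, mask = cr$mask, record = rec)
}
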