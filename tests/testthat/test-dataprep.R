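# OD-center location, crop/restore geometry, augmentation and normalization.

disc_mask <- function(h, w, center, r) {
  rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= r^2
}

test_that("locate_od_center recovers a disc center and filters clutter", {
  set.seed(20)
  m <- disc_mask(512, 512, c(120, 200), 40)
  expect_true(all(abs(locate_od_center(m) - c(120, 200)) <= 1))
  # a 3-px speck fails the area check and does not move the center
  m2 <- m; m2[400, 100:102] <- TRUE
  expect_true(all(abs(locate_od_center(m2) - c(120, 200)) <= 1))
  # an elongated smear fails the circularity check
  m3 <- m; m3[450:454, 50:450] <- TRUE
  expect_true(all(abs(locate_od_center(m3) - c(120, 200)) <= 1))
  expect_error(locate_od_center(matrix(FALSE, 64, 64)), "center")
  # a full-frame blob fails the area upper bound
  expect_error(locate_od_center(matrix(TRUE, 64, 64)), "center")
})

test_that("minimum enclosing circle is exact on known configurations", {
  set.seed(21)
  pts <- rbind(c(0, 0), c(0, 10), c(10, 0), c(10, 10), c(5, 5))
  cir <- min_enclosing_circle(pts)
  expect_equal(cir$c, c(5, 5), tolerance = 1e-9)
  expect_equal(cir$r, sqrt(50), tolerance = 1e-9)
  # all points are enclosed for random sets
  for (i in 1:20) {
    p <- matrix(runif(40, 0, 100), 20, 2)
    cir <- min_enclosing_circle(p)
    d <- sqrt((p[, 1] - cir$c[1])^2 + (p[, 2] - cir$c[2])^2)
    expect_true(all(d <= cir$r + 1e-7))
  }
})

test_that("locate_od_center tracks the true phantom center within 2 px", {
  set.seed(22)
  errs <- vapply(1:100, function(i) {
    s <- 192
    ctr <- s / 2 + runif(2, -20, 20)
    sp <- phantom_spec(image_size = s, disc_center = ctr,
                       disc_radii = c(runif(1, 25, 38), runif(1, 24, 34)),
                       vessel_count = 2, seed = i)
    ph <- generate_phantom(sp)
    found <- locate_od_center(ph$mask > 0)
    # the enclosing-circle center of an ellipse is its center
    sqrt(sum((found - sp$disc_center)^2))
  }, numeric(1))
  expect_true(all(errs <= 2))
})

test_that("crop geometry round-trips masks almost losslessly", {
  set.seed(23)
  for (i in 1:5) {
    s <- 320
    sp <- phantom_spec(image_size = s, disc_center = s / 2 + runif(2, -25, 25),
                       disc_radii = c(runif(1, 35, 50), runif(1, 32, 45)),
                       cup_to_disc_ratio = 0.55, vessel_count = 2, seed = 100 + i)
    ph <- generate_phantom(sp)
    rec <- crop_record(s, s, locate_od_center(ph$mask > 0),
                       crop_size = 220, input_size = 128)
    cr <- crop_and_resize(ph$image, ph$mask, rec)
    expect_equal(dim(cr$image), c(128L, 128L, 3L))
    expect_true(all(cr$mask %in% 0:2))
    back <- restore_to_original(cr$mask, rec, K = 3)
    expect_equal(dim(back), c(s, s))
    expect_true(all(back %in% 0:2))
    expect_gte(dsc(back > 0, ph$mask > 0), 0.98)
    expect_gte(dsc(back == 2, ph$mask == 2), 0.95)
    # region centroid displaced < 2 px by the round trip
    c0 <- colMeans(which(ph$mask > 0, arr.ind = TRUE))
    c1 <- colMeans(which(back > 0, arr.ind = TRUE))
    expect_lt(sqrt(sum((c0 - c1)^2)), 2)
  }
})

test_that("crops at the border are clipped, padded and still restorable", {
  set.seed(24)
  img <- array(runif(200 * 200 * 3), c(200, 200, 3))
  msk <- matrix(0L, 200, 200); msk[disc_mask(200, 200, c(30, 25), 18)] <- 1L
  rec <- crop_record(200, 200, c(10, 10), crop_size = 120, input_size = 64)
  cr <- crop_and_resize(img, msk, rec)
  expect_equal(dim(cr$image), c(64L, 64L, 3L))
  back <- restore_to_original(cr$mask, rec, K = 2)
  expect_equal(dim(back), c(200L, 200L))
  # all-background prediction restores to all background
  expect_true(all(restore_to_original(matrix(0L, 64, 64), rec, K = 2) == 0L))
  expect_error(crop_and_resize(img, msk, crop_record(200, 200, c(300, 10),
                                                     120, 64)),
               "outside")
})

test_that("z-score normalization centers and scales per channel", {
  set.seed(25)
  x <- array(runif(32 * 32 * 3, 0.2, 0.8), c(32, 32, 3))
  z <- zscore_normalize(x)
  for (c in 1:3) {
    expect_lt(abs(mean(z[, , c])), 1e-6)
    expect_equal(stats::sd(z[, , c]), 1, tolerance = 1e-4)
  }
  expect_true(all(zscore_normalize(array(0.5, c(8, 8, 3))) == 0))
  # affine invariance
  z2 <- zscore_normalize(2.5 * x + 0.3)
  expect_equal(z2, z, tolerance = 1e-6)
})

test_that("augmentation strategies honor identity, determinism and spec", {
  set.seed(26)
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  msk <- matrix(sample(0:2, 48 * 48, TRUE), 48, 48)
  a0 <- augment(img, msk, "none")
  expect_identical(a0$image, img)
  expect_identical(a0$mask, msk)
  # zero probabilities equal identity for every strategy
  for (strat in c("spatial", "designed")) {
    pars <- augmentation_params(strat)
    pars <- lapply(pars, function(p) { p$p <- 0; p })
    az <- augment(img, msk, pars)
    expect_identical(az$image, img)
  }
  # spatial transform set is a subset of the designed set
  expect_true(all(names(augmentation_params("spatial")) %in%
                    names(augmentation_params("designed"))))
  set.seed(7); a1 <- augment(img, msk, "designed")
  set.seed(7); a2 <- augment(img, msk, "designed")
  expect_identical(a1, a2)
  # geometric transforms move image and mask together
  pars <- augmentation_params("spatial")
  pars$rotation$p <- 0; pars$vflip$p <- 0; pars$hflip$p <- 1
  af <- augment(img, msk, pars)
  expect_identical(af$image, img[, 48:1, , drop = FALSE])
  expect_identical(af$mask, msk[, 48:1])
})

test_that("transform gates fire at their configured probabilities", {
  set.seed(27)
  pars <- augmentation_params("designed")
  pars$rotation$p <- 0; pars$vflip$p <- 0
  for (nm in c("blur", "noise", "brightness", "contrast", "gamma"))
    pars[[nm]]$p <- 0
  img <- array(runif(4 * 4 * 3), c(4, 4, 3))
  flipped <- vapply(seq_len(10000), function(i) {
    a <- augment(img, NULL, pars)
    !identical(a$image, img)
  }, logical(1))
  expect_lt(abs(mean(flipped) - 0.5), 0.02)
})

test_that("manifest reading validates columns and resolves paths", {
  td <- withr::local_tempdir()
  write.csv(data.frame(image_path = "a.png", mask_path = "b.png",
                       split = "train", crop_size = 320),
            file.path(td, "manifest.csv"), row.names = FALSE)
  m <- read_manifest(file.path(td, "manifest.csv"))
  expect_true(startsWith(m$image_path[1], td))
  write.csv(data.frame(image_path = "a.png"), file.path(td, "bad.csv"),
            row.names = FALSE)
  expect_error(read_manifest(file.path(td, "bad.csv")), "mask_path")
})
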