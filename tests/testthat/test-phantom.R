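# Synthetic fundus phantoms: geometric invariants, measured cup-to-disc
# ratio, determinism, and domain-preset separation.

test_that("phantom specs enforce their geometric invariants", {
  expect_error(phantom_spec(cup_to_disc_ratio = 1.2), "cup_to_disc_ratio")
  expect_error(phantom_spec(image_size = 128, disc_radii = c(70, 70)),
               "field of view")
  expect_error(phantom_spec(cup_to_disc_ratio = 0.9,
                            cup_offset = c(20, 0)), "strictly inside")
})

test_that("rendered masks have one disc, one cup, and cup inside disc", {
  set.seed(30)
  for (i in 1:10) {
    sp <- phantom_spec(image_size = 160,
                       disc_center = 80 + runif(2, -10, 10),
                       disc_radii = c(runif(1, 22, 34), runif(1, 20, 30)),
                       cup_to_disc_ratio = runif(1, 0.3, 0.7),
                       cup_offset = runif(2, -2, 2), seed = i)
    ph <- generate_phantom(sp)
    expect_setequal(sort(unique(as.vector(ph$mask))), 0:2)
    # every cup pixel lies inside the disc ellipse
    cup <- which(ph$mask == 2L, arr.ind = TRUE)
    q <- fundseg:::ellipse_q(cup[, 1], cup[, 2], sp$disc_center, sp$disc_radii)
    expect_true(all(q <= 1))
    # exactly one connected component each for disc region and cup
    lab_od <- EBImage::bwlabel(EBImage::Image((ph$mask > 0) * 1))
    lab_oc <- EBImage::bwlabel(EBImage::Image((ph$mask == 2) * 1))
    expect_equal(max(lab_od), 1)
    expect_equal(max(lab_oc), 1)
    expect_true(all(ph$image >= 0 & ph$image <= 1))
  }
})

test_that("the measured cup-to-disc ratio matches the requested value", {
  ph <- generate_phantom(phantom_spec(image_size = 256, disc_radii = c(60, 60),
                                      cup_to_disc_ratio = 0.5, seed = 4))
  measured <- sqrt(sum(ph$mask == 2) / sum(ph$mask > 0))
  expect_equal(measured, 0.5, tolerance = 0.1)  # 0.5 +- 0.05 absolute
  expect_lt(abs(measured - 0.5), 0.05)
})

test_that("rendering is bit-identical under a fixed seed", {
  sp <- phantom_spec(seed = 77, image_size = 128, disc_radii = c(25, 22))
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
  p3 <- generate_phantom(phantom_spec(seed = 78, image_size = 128,
                                      disc_radii = c(25, 22)))
  expect_false(identical(p1$image, p3$image))
})

test_that("domain datasets are written with a 4:1 split and metadata", {
  td <- withr::local_tempdir()
  mp <- generate_domain_dataset(10, "D1", td, seed = 1, image_size = 96,
                                crop_size = 64)
  man <- read_manifest(file.path(td, "manifest.csv"))
  expect_equal(nrow(man), 10)
  expect_equal(sum(man$split == "train"), 8)
  expect_equal(sum(man$split == "val"), 2)
  expect_length(list.files(td, "^img_\\d+\\.png$"), 10)
  expect_length(list.files(td, "^mask_\\d+\\.png$"), 10)
  expect_length(list.files(td, "^meta_\\d+\\.json$"), 10)
  # masks survive the PNG round trip with raw labels
  m1 <- fundseg:::read_mask_png(man$mask_path[1])
  expect_true(all(m1 %in% 0:2))
  expect_gt(sum(m1 == 2), 0)
  meta <- jsonlite::read_json(file.path(td, "meta_001.json"),
                              simplifyVector = TRUE)
  expect_true(all(c("disc_center", "cup_to_disc_ratio") %in% names(meta)))
  # same seed reproduces the manifest and pixel data exactly
  td2 <- withr::local_tempdir()
  generate_domain_dataset(10, "D1", td2, seed = 1, image_size = 96,
                          crop_size = 64)
  expect_identical(readLines(file.path(td, "manifest.csv")),
                   readLines(file.path(td2, "manifest.csv")))
  expect_identical(png::readPNG(file.path(td, "img_003.png")),
                   png::readPNG(file.path(td2, "img_003.png")))
})

test_that("domain presets are visibly distinct in appearance", {
  presets <- domain_presets()
  expect_setequal(names(presets), c("D1", "D2", "D3", "D4"))
  # pairwise distinct in at least two fields
  fields <- c("contrast", "brightness", "noise")
  for (a in 1:3) for (b in (a + 1):4) {
    pa <- presets[[a]]; pb <- presets[[b]]
    ndiff <- sum(!mapply(identical, pa[fields], pb[fields])) +
      !identical(pa$color_cast, pb$color_cast) +
      !identical(pa$disc_radius_range, pb$disc_radius_range)
    expect_gte(ndiff, 2)
  }
  td <- withr::local_tempdir()
  generate_domain_dataset(50, "D1", file.path(td, "d1"), seed = 3,
                          image_size = 96)
  generate_domain_dataset(50, "D2", file.path(td, "d2"), seed = 3,
                          image_size = 96)
  mean_rgb <- function(dir) {
    f <- list.files(dir, "^img_", full.names = TRUE)
    rowMeans(vapply(f, function(p) {
      im <- png::readPNG(p)
      c(mean(im[, , 1]), mean(im[, , 2]), mean(im[, , 3]))
    }, numeric(3)))
  }
  delta <- abs(mean_rgb(file.path(td, "d1")) - mean_rgb(file.path(td, "d2")))
  expect_gt(max(delta), 5 / 255)
})

test_that("a model trained on one domain transfers to a shifted domain
           within the smoke-level gap", {
  td <- withr::local_tempdir()
  generate_domain_dataset(20, "D1", file.path(td, "d1"), seed = 501,
                          image_size = 128, crop_size = 96)
  generate_domain_dataset(8, "D2", file.path(td, "d2"), seed = 502,
                          image_size = 128, crop_size = 96)
  load_all <- function(dir, split) {
    m <- read_manifest(file.path(dir, "manifest.csv"))
    rows <- m[m$split %in% split, ]
    lapply(seq_len(nrow(rows)), function(i) load_sample(rows[i, ], 64))
  }
  train <- load_all(file.path(td, "d1"), "train")     # 16 phantoms
  d1_test <- load_all(file.path(td, "d1"), "val")     # held-out D1
  d2_test <- load_all(file.path(td, "d2"), c("train", "val"))
  set.seed(31)
  model <- build_model(model_config("tiny", input_size = 64L,
                                    norm_kind = "group"))
  fit_model(model, train, d1_test,
            train_config(batch_size = 2, max_epochs = 20, seed = 112316,
                         validation_interval = 10,
                         checkpoint_dir = tempfile()))
  in_dsc <- fundseg:::validation_dsc(model, d1_test)
  out_dsc <- fundseg:::validation_dsc(model, d2_test)
  expect_gte(in_dsc, out_dsc - 0.3)
  expect_gt(in_dsc, 0.3)   # the model did learn something in-domain
})
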