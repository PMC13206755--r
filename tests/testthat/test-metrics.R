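# DSC, HD95, ASD, bootstrap CI: frozen examples, brute-force oracle
# equivalence, and symmetry properties.

test_that("dsc matches hand-counted overlaps and conventions", {
  m <- matrix(FALSE, 4, 4)
  a <- m; a[1:2, ] <- TRUE      # rows 1-2, 8 px
  b <- m; b[2:3, ] <- TRUE      # rows 2-3, 8 px -> TP=4, FP=4, FN=4
  expect_equal(dsc(a, b), 0.5)
  expect_equal(dsc(a, a), 1)
  d <- m; d[4, ] <- TRUE
  expect_equal(dsc(a, d), 0)
  expect_equal(dsc(m, m), 1)    # both empty
  expect_equal(dsc(a, m), 0)    # exactly one empty
  expect_error(dsc(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("directional 95% distance follows the nearest-rank convention", {
  A <- matrix(c(0, 0), 1, 2)
  B <- matrix(c(3, 4), 1, 2)
  expect_equal(directional_h95(A, B), 5)
  # 20 minima at distance 1 and one at 100: ceil(0.95 * 21) = 20th order
  # statistic -> 1
  A <- rbind(matrix(c(seq_len(20), rep(2, 20)), 20, 2), c(100, 100))
  B <- matrix(c(seq_len(20), rep(1, 20)), 20, 2)
  expect_equal(directional_h95(A, B), 1)
})

test_that("hd95 and asd agree with frozen point geometry", {
  m <- matrix(FALSE, 8, 8)
  a <- m; a[1, 1] <- TRUE
  b <- m; b[4, 5] <- TRUE       # Euclidean distance 5
  expect_equal(as.numeric(hd95(a, b)), 5)
  expect_equal(as.numeric(asd(a, b)), 5)
  expect_equal(as.numeric(hd95(a, a)), 0)
  expect_equal(as.numeric(asd(a, a)), 0)
  # empty-region sentinel: image diagonal, flagged
  h <- hd95(a, m)
  expect_equal(as.numeric(h), sqrt(128))
  expect_true(attr(h, "empty"))
  expect_equal(hd95(m, m), 0)
})

test_that("dsc/hd95/asd match exhaustive brute-force oracles exactly", {
  set.seed(9)
  n_pairs <- 200
  for (i in seq_len(n_pairs)) {
    h <- sample(8:64, 1); w <- sample(8:64, 1)
    a <- random_mask(h, w); b <- random_mask(h, w)
    expect_identical(dsc(a, b), oracle_dsc(a, b))
    expect_identical(as.numeric(hd95(a, b)), oracle_hd95(a, b))
    expect_identical(as.numeric(asd(a, b)), oracle_asd(a, b))
  }
})

test_that("dsc and hd95 are symmetric; printed ASD is not", {
  set.seed(10)
  for (i in 1:20) {
    a <- random_mask(32, 32, p_empty = 0)
    b <- random_mask(32, 32, p_empty = 0)
    expect_identical(dsc(a, b), dsc(b, a))
    expect_identical(as.numeric(hd95(a, b)), as.numeric(hd95(b, a)))
  }
  # constructed asymmetric pair: a tiny region against a large one
  a <- matrix(FALSE, 32, 32); a[16, 16] <- TRUE
  b <- matrix(FALSE, 32, 32); b[8:24, 8:24] <- TRUE
  expect_false(isTRUE(all.equal(as.numeric(asd(a, b)), as.numeric(asd(b, a)))))
  sym <- asd(a, b, symmetric = TRUE)
  expect_equal(as.numeric(sym),
               (as.numeric(asd(a, b)) + as.numeric(asd(b, a))) / 2)
})

test_that("dsc is invariant under simultaneous translation", {
  set.seed(11)
  a <- matrix(FALSE, 40, 40); a[10:20, 12:22] <- TRUE
  b <- matrix(FALSE, 40, 40); b[12:24, 10:18] <- TRUE
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  for (d in list(c(3, 5), c(0, 7), c(9, 0))) {
    expect_identical(dsc(shift(a, d[1], d[2]), shift(b, d[1], d[2])),
                     dsc(a, b))
  }
})

test_that("bootstrap CI is degenerate on constants, seeded, and bounded", {
  expect_equal(unname(bootstrap_ci(rep(0.9, 12), reps = 500, seed = 1)),
               c(0.9, 0.9))
  v <- c(rep(0, 10), rep(1, 10))
  ci <- bootstrap_ci(v, reps = 4000, seed = 2)
  expect_true(ci["low"] < 0.5 && ci["high"] > 0.5)
  expect_true(ci["low"] >= 0 && ci["high"] <= 1)
  set.seed(99)
  vals <- runif(25, 0.7, 0.99)
  ci1 <- bootstrap_ci(vals, reps = 2000, seed = 112316)
  ci2 <- bootstrap_ci(vals, reps = 2000, seed = 112316)
  expect_identical(ci1, ci2)
  expect_error(bootstrap_ci(numeric(0)), "empty")
  # the caller's RNG stream is untouched
  set.seed(5); r1 <- runif(1)
  set.seed(5); invisible(bootstrap_ci(vals, reps = 10, seed = 3)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("evaluate_dataset aggregates regions per the label convention", {
  set.seed(12)
  gt <- lapply(1:4, function(i) {
    m <- matrix(0L, 48, 48)
    m[10:38, 10:38][(row(m[10:38, 10:38]) - 15)^2 +
                      (col(m[10:38, 10:38]) - 15)^2 <= 140] <- 1L
    m[20:28, 20:28] <- 2L
    m
  })
  rep0 <- evaluate_dataset(gt, gt, K = 3, ci_reps = 200)
  expect_equal(rep0$summary$dsc_mean, c(1, 1))
  expect_equal(rep0$summary$hd95_mean, c(0, 0))
  expect_equal(rep0$summary$asd_mean, c(0, 0))
  expect_equal(rep0$summary$dsc_ci_low, c(1, 1), ignore_attr = TRUE)
  expect_equal(rep0$summary$dsc_ci_high, c(1, 1), ignore_attr = TRUE)
  expect_setequal(rep0$summary$region, c("OD", "OC"))
  # single image: CI degenerate at its DSC
  r1 <- evaluate_dataset(gt[1], gt[1], K = 3, ci_reps = 100)
  expect_equal(r1$summary$dsc_ci_low, r1$summary$dsc_mean, ignore_attr = TRUE)
  expect_error(evaluate_dataset(gt, gt[1:2], K = 3), "2")
  # K = 2 evaluates the disc only
  gt2 <- lapply(gt, function(m) (m > 0) * 1L)
  r2 <- evaluate_dataset(gt2, gt2, K = 2, ci_reps = 100)
  expect_identical(r2$summary$region, "OD")
})

test_that("perturbed masks reproduce an independent per-image recount", {
  set.seed(13)
  dilate1 <- function(m) {
    p <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
    p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    (p[1:nrow(m), 2:(ncol(m) + 1)] | p[3:(nrow(m) + 2), 2:(ncol(m) + 1)] |
       p[2:(nrow(m) + 1), 1:ncol(m)] | p[2:(nrow(m) + 1), 3:(ncol(m) + 2)] |
       m)
  }
  gt <- lapply(1:5, function(i) {
    ph <- generate_phantom(phantom_spec(image_size = 96,
                                       disc_radii = c(20, 18),
                                       cup_to_disc_ratio = 0.5,
                                       vessel_count = 2, seed = i))
    ph$mask
  })
  pred <- lapply(gt, function(m) {
    od <- dilate1(m > 0); oc <- dilate1(m == 2)
    out <- matrix(0L, nrow(m), ncol(m))
    out[od] <- 1L; out[oc] <- 2L
    out
  })
  rep1 <- evaluate_dataset(pred, gt, K = 3, ci_reps = 100)
  manual_od <- mean(vapply(1:5, function(i)
    oracle_dsc(pred[[i]] > 0, gt[[i]] > 0), 0))
  manual_oc <- mean(vapply(1:5, function(i)
    oracle_dsc(pred[[i]] == 2, gt[[i]] == 2), 0))
  expect_identical(rep1$summary$dsc_mean[rep1$summary$region == "OD"], manual_od)
  expect_identical(rep1$summary$dsc_mean[rep1$summary$region == "OC"], manual_oc)
  expect_true(all(rep1$per_image$dsc < 1))
})
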