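# Architecture construction, geometry, freezing, parameter accounting and
# the exact residual-identity properties of the adapter modules.

tiny <- function(...) model_config("tiny", ...)

test_that("configuration invariants are enforced", {
  expect_error(model_config("canonical", canvas_size = 225),
               "divisible")
  expect_error(model_config("canonical", patch_size = 14),
               "configuration error")
  expect_error(model_config("tiny", num_classes = 4), "num_classes")
  expect_error(model_config("tiny", skip_taps = c(1, 3, 2, 4)),
               "strictly increasing")
  expect_error(model_config("tiny", skip_taps = c(1, 2, 3, 9)), "depth")
  expect_error(model_config("tiny", nonsense_field = 1), "unknown")
  cfg <- model_config("canonical")
  expect_identical(cfg$grid_size, 14L)
  expect_identical(cfg$n_stages, 4L)
})

test_that("the encoder backbone is frozen; unfreeze_last_n releases blocks", {
  set.seed(1)
  m <- build_model(tiny())
  frozen <- names(Filter(function(p) p$frozen, m$params))
  trainable <- names(Filter(function(p) !p$frozen, m$params))
  expect_true(all(grepl("^(patch\\.|blocks\\.|enc_norm\\.)", frozen)))
  expect_true(any(grepl("^patch\\.", frozen)))
  expect_true(all(!grepl("adapter", frozen)))
  expect_true(any(grepl("^decoder\\.", trainable)))
  expect_true(any(grepl("^pre\\.", trainable)))
  m2 <- build_model(tiny(unfreeze_last_n = 2))
  expect_false(m2$params[["blocks.4.attn.qkv_w"]]$frozen)
  expect_false(m2$params[["blocks.3.mlp_fc1.weight"]]$frozen)
  expect_true(m2$params[["blocks.2.attn.qkv_w"]]$frozen)
  expect_true(m2$params[["patch.weight"]]$frozen)
})

# closed-form tunable-parameter count, derived independently layer by layer
closed_form_count <- function(cfg) {
  D <- cfg$embed_dim; Dd <- cfg$decoder_dim; K <- cfg$num_classes
  mid <- cfg$adapter_mid; sc <- cfg$skip_channels; pm <- cfg$pre_adapter_mid
  lin <- function(i, o) i * o + o
  conv <- function(k, i, o) k * k * i * o + o
  norm2 <- function(c) 2 * c
  cnn_block <- function(i, o) conv(3, i, o) + norm2(o)
  vit_block <- function(d) 2 * d + lin(d, 3 * d) + lin(d, d) + 2 * d +
    lin(d, 4 * d) + lin(4 * d, d)
  adapter <- function(d) lin(d, mid) + lin(mid, d)
  n <- 0
  if (cfg$use_pre_adapter)
    n <- n + cnn_block(3, pm) + cnn_block(pm, pm) + conv(3, pm, 3) + 3
  if (cfg$use_block_adapters) n <- n + cfg$depth * adapter(D)
  n <- n + cfg$unfreeze_last_n * vit_block(D)
  # decoder: input projection, K class embeddings, blocks, final norm,
  # patch/class projection matrices (no bias), mask norm over K
  n <- n + lin(D, Dd) + K * Dd + cfg$decoder_depth * vit_block(Dd) +
    2 * Dd + 2 * Dd * Dd + 2 * K
  if (cfg$use_skips) {
    cbam_mid <- min(sc, max(sc %/% 16, 4))
    cbam <- lin(sc, cbam_mid) + lin(cbam_mid, sc) + conv(7, 2, 1)
    n <- n + 4 * (conv(1, D, sc) + cnn_block(sc, sc) + cbam)
  }
  if (cfg$use_post_adapter) {
    n <- n + cnn_block(K, sc) + (cfg$n_stages - 1) * cnn_block(sc, sc) +
      cnn_block(sc, sc) + conv(1, sc, K)
    if (cfg$use_skips) n <- n + 4 * cnn_block(2 * sc, sc)
  }
  n
}

test_that("count_tunable_parameters matches the closed form over configs", {
  set.seed(42)
  cases <- list(
    tiny(),
    tiny(num_classes = 2),
    tiny(unfreeze_last_n = 1),
    tiny(use_skips = FALSE),
    tiny(use_pre_adapter = FALSE, use_block_adapters = FALSE),
    model_config("tiny", embed_dim = 96L, num_heads = 3L, depth = 5L,
                 skip_taps = c(2L, 3L, 4L, 5L), decoder_dim = 48L,
                 decoder_heads = 4L, skip_channels = 8L))
  for (cfg in cases) {
    m <- build_model(cfg)
    expect_identical(count_tunable_parameters(m), closed_form_count(cfg))
  }
})

test_that("a single ViT block adapter counts 263,296 parameters at full width", {
  # two affine maps 1024 -> 128 -> 1024 with offsets
  expect_equal((1024 * 128 + 128) + (128 * 1024 + 1024), 263296)
  set.seed(1)
  m <- build_model(tiny(embed_dim = 1024L, num_heads = 16L,
                        adapter_mid = 128L))
  adp <- m$params[c("blocks.1.adapter.down.weight", "blocks.1.adapter.down.bias",
                    "blocks.1.adapter.up.weight", "blocks.1.adapter.up.bias")]
  expect_equal(sum(vapply(adp, function(p) length(p$value), 0)), 263296)
})

test_that("pre-adapter maps arbitrary sizes to the canvas and reduces to a
           plain bicubic downsample when its CNN path is zeroed", {
  set.seed(2)
  m <- build_model(tiny())
  x <- array(runif(256 * 256 * 3), c(256, 256, 3, 1))
  y <- pre_adapter_forward(x, m)
  expect_equal(dim(y), c(224L, 224L, 3L, 1L))
  x2 <- array(runif(160 * 96 * 3), c(160, 96, 3, 1))
  expect_equal(dim(pre_adapter_forward(x2, m)), c(224L, 224L, 3L, 1L))
  expect_error(pre_adapter_forward(array(0, c(64, 64, 2, 1)), m), "3-channel")
  # residual identity: zero final conv -> output is the bicubic downsample
  m$params[["pre.conv3.weight"]]$value[] <- 0
  m$params[["pre.conv3.bias"]]$value[] <- 0
  y0 <- pre_adapter_forward(x, m)
  expect_identical(y0, resample_image(x, 224, 224, "bicubic"))
})

test_that("encoder produces grid-squared tokens and four taps; a zeroed
           adapter up-projection reproduces the adapter-free block exactly", {
  set.seed(3)
  m <- build_model(tiny())
  x <- array(runif(224 * 224 * 3), c(224, 224, 3, 1))
  enc <- encoder_forward(x, m)
  expect_equal(dim(enc$tokens), c(196L, 64L))
  expect_length(enc$taps, 4)
  expect_equal(dim(enc$taps[[3]]), c(196L, 64L))
  expect_error(encoder_forward(array(0, c(64, 64, 3, 1)), m), "224")
  for (b in seq_len(m$config$depth)) {
    m$params[[sprintf("blocks.%d.adapter.up.weight", b)]]$value[] <- 0
    m$params[[sprintf("blocks.%d.adapter.up.bias", b)]]$value[] <- 0
  }
  with_adapter <- encoder_forward(x, m)$tokens
  for (b in seq_len(m$config$depth))
    m$layers$blocks[[b]]$children$adapter <- NULL
  without_adapter <- encoder_forward(x, m)$tokens
  expect_identical(with_adapter, without_adapter)
})

test_that("decoder emits K mask maps via normalized inner products", {
  set.seed(4)
  for (K in c(3L, 2L)) {
    m <- build_model(tiny(num_classes = K))
    tok <- matrix(rnorm(196 * 64), 196, 64)
    maps <- decoder_forward(list(tokens = tok, n_images = 1), m)
    expect_equal(dim(maps), c(14L, 14L, K, 1L))
  }
  # scalar-product primitive: zero patch features give a zero mask row,
  # orthonormal features give the identity pattern
  P <- rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 0))
  C <- rbind(c(1, 0, 0), c(0, 1, 0))
  mm <- mask_inner_product(P, C)
  expect_equal(mm[3, ], c(0, 0))
  expect_equal(mm[1:2, ], diag(2))
  expect_true(all(abs(mask_inner_product(matrix(rnorm(40), 10, 4),
                                         matrix(rnorm(12), 3, 4))) <= 1 + 1e-12))
})

test_that("skip branches deliver maps at canvas, /2, /4, /8 sides and CBAM
           with gates forced open is the identity", {
  set.seed(5)
  m <- build_model(tiny())
  x <- array(runif(224 * 224 * 3), c(224, 224, 3, 1))
  enc <- encoder_forward(x, m)
  sk <- skip_branch_forward(enc, m)
  expect_equal(vapply(sk, function(s) dim(s)[1], 0), c(224, 112, 56, 28))
  expect_equal(dim(sk[[4]]), c(28L, 28L, 8L, 1L))
  expect_error(skip_branch_forward(enc$taps[1:3], m), "4 tapped")
  # force both CBAM gates to sigmoid(+Inf-ish) = 1
  cb <- fundseg:::layer_cbam(8, reduction = 2)
  cb$params$fc1_w$value[] <- 0; cb$params$fc1_b$value[] <- 0
  cb$params$fc2_w$value[] <- 0; cb$params$fc2_b$value[] <- 50
  cb$children$sp_conv$params$weight$value[] <- 0
  cb$children$sp_conv$params$bias$value[] <- 50
  xin <- array(runif(12 * 12 * 8 * 2), c(12, 12, 8, 2))
  expect_equal(cb$fwd(xin, train = FALSE), xin, tolerance = 1e-12)
})

test_that("post-adapter reaches the requested size, visits doubling stages,
           names side mismatches, and works without skips", {
  set.seed(6)
  m <- build_model(tiny())
  x <- array(runif(224 * 224 * 3), c(224, 224, 3, 1))
  enc <- encoder_forward(x, m)
  maps <- decoder_forward(enc, m)
  sk <- skip_branch_forward(enc, m)
  logits <- post_adapter_forward(maps, sk, m, input_size = 256)
  expect_equal(dim(logits), c(256L, 256L, 3L, 1L))
  bad <- sk; bad[[4]] <- bad[[4]][1:27, 1:27, , , drop = FALSE]
  expect_error(post_adapter_forward(maps, bad, m, input_size = 256),
               "stage 1")
  m2 <- build_model(tiny(use_skips = FALSE))
  enc2 <- encoder_forward(x, m2)
  logits2 <- post_adapter_forward(decoder_forward(enc2, m2), NULL, m2,
                                  input_size = 192)
  expect_equal(dim(logits2), c(192L, 192L, 3L, 1L))
})

test_that("geometry invariance: output side equals the input size over sizes", {
  set.seed(7)
  m <- build_model(tiny())
  for (s in c(96L, 128L, 200L)) {
    x <- array(runif(s * s * 3), c(s, s, 3, 1))
    logits <- fundseg:::model_forward(m, x, train = FALSE, input_size = s)
    expect_equal(dim(logits), c(s, s, 3L, 1L))
  }
})

test_that("predictions are on the probability simplex with declared tie rule", {
  set.seed(8)
  m <- build_model(tiny())
  x <- array(runif(96 * 96 * 3 * 2), c(96, 96, 3, 2))
  pr <- predict(m, x)
  sums <- apply(pr$probs, c(1, 2, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(pr$labels %in% 0:2))
  # constructed logits: class 0 strictly maximal -> all background
  z <- array(0, c(4, 4, 3, 1)); z[, , 1, ] <- 5
  expect_true(all(fundseg:::softmax_predict(z)$labels == 0L))
  # exact ties -> lowest class index
  zt <- array(1, c(4, 4, 3, 1))
  expect_true(all(fundseg:::softmax_predict(zt)$labels == 0L))
})
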