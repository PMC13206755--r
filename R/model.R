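# The full segmentation network: pre-adapter -> frozen ViT encoder with
# per-block bottleneck adapters -> mask-transformer decoder -> post-adapter
# fused with CBAM skip branches -> softmax/argmax. Forward passes cache the
# intermediates the manual backward pass needs; model_backward() drives the
# whole reverse sweep and accumulates gradients on trainable parameters.

#' Build the segmentation model
#'
#' Constructs the network described by a [model_config()]. The encoder
#' backbone (patch embedding, positional embeddings, transformer blocks,
#' final norm) is frozen except for the last `unfreeze_last_n` blocks; all
#' adapter and decoder parameters are trainable. Decoder class embeddings
#' are initialized from a truncated normal distribution (sd 0.02, +-2 sd)
#' and the pre-adapter residual scalars start at 0.1.
#'
#' @param config a `fundseg_config`.
#' @param pretrained optional path to an encoder checkpoint (an `.rds` file
#'   with MAE/ViT-large style names); see [import_encoder_weights()].
#' @return an object of class `fundseg_model`.
#' @export
build_model <- function(config, pretrained = NULL) {
  cfg <- validate_config(config)
  D <- cfg$embed_dim; K <- cfg$num_classes; nk <- cfg$norm_kind
  frozen_block <- function(i) i <= cfg$depth - cfg$unfreeze_last_n
  layers <- list()

  if (cfg$use_pre_adapter) {
    mid <- cfg$pre_adapter_mid
    layers$pre <- list(
      cnn1 = layer_cnn_block(3, mid, nk),
      cnn2 = layer_cnn_block(mid, mid, nk),
      conv3 = layer_conv2d(3, mid, 3),
      scalars = new_param(rep(0.1, 3)),
      cache = new.env(parent = emptyenv()))
  }
  layers$patch <- layer_patch_embed(cfg$canvas_size, cfg$patch_size, D,
                                    frozen = TRUE)
  layers$blocks <- lapply(seq_len(cfg$depth), function(i)
    layer_vit_block(D, cfg$num_heads,
                    adapter_mid = if (cfg$use_block_adapters) cfg$adapter_mid,
                    frozen = frozen_block(i)))
  layers$enc_norm <- layer_layernorm(D, frozen = TRUE)

  Dd <- cfg$decoder_dim
  layers$decoder <- list(
    proj_in = layer_linear(D, Dd),
    cls = new_param(matrix(rtruncnorm(K * Dd, sd = 0.02), K, Dd)),
    blocks = lapply(seq_len(cfg$decoder_depth), function(i)
      layer_vit_block(Dd, cfg$decoder_heads)),
    norm = layer_layernorm(Dd),
    proj_patch = new_param(matrix(stats::rnorm(Dd * Dd, sd = Dd^-0.5), Dd, Dd)),
    proj_cls = new_param(matrix(stats::rnorm(Dd * Dd, sd = Dd^-0.5), Dd, Dd)),
    mask_norm = layer_layernorm(K),
    cache = new.env(parent = emptyenv()))

  if (cfg$use_skips) {
    layers$skips <- lapply(1:4, function(i) list(
      proj = layer_conv2d(1, D, cfg$skip_channels),
      cnn = layer_cnn_block(cfg$skip_channels, cfg$skip_channels, nk),
      cbam = layer_cbam(cfg$skip_channels)))
  }

  if (cfg$use_post_adapter) {
    sc <- cfg$skip_channels
    layers$post <- list(
      stages = lapply(seq_len(cfg$n_stages), function(s)
        layer_cnn_block(if (s == 1) K else sc, sc, nk)),
      fuses = if (cfg$use_skips) lapply(1:4, function(i)
        layer_cnn_block(2 * sc, sc, nk)),
      final = layer_cnn_block(sc, sc, nk),
      out = layer_conv2d(1, sc, K),
      cache = new.env(parent = emptyenv()))
  }

  model <- structure(list(config = cfg, layers = layers),
                     class = "fundseg_model")
  model$params <- collect_params(layers)
  if (!is.null(pretrained)) model <- import_encoder_weights(model, pretrained)
  model
}

#' Count tunable (non-frozen) parameters
#'
#' Sums element counts over all parameters that participate in gradient
#' updates. For the canonical joint-task configuration this reproduces the
#' architecture's headline figure of about 35.57 million tunable parameters.
#'
#' @param model a `fundseg_model`.
#' @return a non-negative integer (numeric scalar).
#' @export
count_tunable_parameters <- function(model) {
  sum(vapply(model$params, function(p)
    if (p$frozen) 0 else length(p$value), numeric(1)))
}

count_total_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' @method print fundseg_model
#' @export
print.fundseg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<fundseg_model> %s geometry: depth %d, dim %d, K=%d\n",
                     "  parameters: %.2fM tunable / %.2fM total\n"),
              cfg$preset %||% "custom", cfg$depth, cfg$embed_dim,
              cfg$num_classes, count_tunable_parameters(x) / 1e6,
              count_total_parameters(x) / 1e6))
  invisible(x)
}

## ---- forward pieces -------------------------------------------------------

#' Pre-adapter forward pass
#'
#' Inverted-residual input adapter: the image is pushed through a small CNN
#' (3->mid->mid->3 channels), bicubically downsampled to the canvas size and
#' scaled by three per-channel scalars, then added to a plain bicubic
#' downsample of the input.
#'
#' @param x array `[H, W, 3, N]` with `H, W >= 32`.
#' @param model a `fundseg_model` built with `use_pre_adapter = TRUE`.
#' @param train logical; training mode for the normalization layers.
#' @return array `[canvas, canvas, 3, N]`.
#' @export
pre_adapter_forward <- function(x, model, train = FALSE) {
  d <- dim(x)
  if (length(d) == 3) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[3] != 3) stopf("pre-adapter expects 3-channel input, got %d channels", d[3])
  if (d[1] < 32 || d[2] < 32) stopf("pre-adapter input must be at least 32x32")
  pre <- model$layers$pre
  if (is.null(pre)) stopf("model was built without a pre-adapter")
  cv <- model$config$canvas_size
  h <- pre$cnn1$fwd(x, train)
  h <- pre$cnn2$fwd(h, train)
  h <- pre$conv3$fwd(h)
  mask <- h > 0
  h <- h * mask
  hd <- resample_image(h, cv, cv, "bicubic")
  w3 <- pre$scalars$value
  base <- resample_image(x, cv, cv, "bicubic")
  y <- base + hd * rep(w3, each = cv * cv)
  pre$cache$mask <- mask
  pre$cache$hd <- hd
  pre$cache$in_h <- d[1]
  pre$cache$in_w <- d[2]
  y
}

pre_adapter_backward <- function(g, model) {
  pre <- model$layers$pre
  cc <- pre$cache
  cv <- model$config$canvas_size
  w3 <- pre$scalars$value
  ghd <- g * rep(w3, each = cv * cv)
  gw <- .colSums(matrix(g * cc$hd, cv * cv, 3 * dim(g)[4]), cv * cv, 3 * dim(g)[4])
  add_grad(pre$scalars, rowSums(matrix(gw, 3)))
  gh <- resample_backward(ghd, cc$in_h, cc$in_w, "bicubic")
  gh <- gh * cc$mask
  gh <- pre$conv3$bwd(gh)
  gh <- pre$cnn2$bwd(gh)
  pre$cnn1$bwd(gh)
  invisible(NULL)
}

tokens_to_map <- function(tok, grid, N) {
  D <- ncol(tok)
  T <- grid * grid
  out <- array(0, c(grid, grid, D, N))
  for (n in seq_len(N))
    out[, , , n] <- array(tok[((n - 1) * T + 1):(n * T), ], c(grid, grid, D))
  out
}

map_to_tokens <- function(map) {
  d <- dim(map)
  T <- d[1] * d[2]
  out <- matrix(0, T * d[4], d[3])
  for (n in seq_len(d[4]))
    out[((n - 1) * T + 1):(n * T), ] <- matrix(map[, , , n], T, d[3])
  out
}

#' Encoder forward pass
#'
#' Patch embedding plus positional embeddings followed by the transformer
#' blocks; when block adapters are enabled each block computes
#' `x + MHA(adapter(LN(x)))` followed by the usual MLP sub-block. Outputs
#' after the blocks listed in `skip_taps` are captured for the skip branches.
#'
#' @param x array `[canvas, canvas, 3, N]`.
#' @param model a `fundseg_model`.
#' @return list with `tokens` (the final normalized `(N*T) x D` token
#'   matrix), `taps` (list of 4 tapped token matrices) and `n_images`.
#' @export
encoder_forward <- function(x, model) {
  cfg <- model$config
  d <- dim(x)
  if (length(d) == 3) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[1] != cfg$canvas_size || d[2] != cfg$canvas_size)
    stopf("encoder expects %dx%d input, got %dx%d",
          cfg$canvas_size, cfg$canvas_size, d[1], d[2])
  T <- cfg$grid_size^2
  tok <- model$layers$patch$fwd(x)
  taps <- vector("list", 4)
  for (b in seq_len(cfg$depth)) {
    tok <- model$layers$blocks[[b]]$fwd(tok, T)
    hit <- which(cfg$skip_taps == b)
    if (length(hit)) taps[[hit]] <- tok
  }
  tok <- model$layers$enc_norm$fwd(tok)
  list(tokens = tok, taps = taps, n_images = d[4])
}

encoder_backward <- function(g_tokens, g_taps, model) {
  cfg <- model$config
  g <- model$layers$enc_norm$bwd(g_tokens)
  for (b in rev(seq_len(cfg$depth))) {
    hit <- which(cfg$skip_taps == b)
    if (length(hit) && !is.null(g_taps[[hit]])) g <- g + g_taps[[hit]]
    g <- model$layers$blocks[[b]]$bwd(g)
  }
  model$layers$patch$bwd(g)
}

#' Mask-transformer decoder forward pass
#'
#' Projects the encoder tokens, appends K learned class embeddings, runs the
#' decoder transformer blocks, then forms mask maps as inner products
#' between the (projected, L2-normalized) class embeddings and patch
#' features; a final layer norm acts over the class dimension.
#'
#' @param enc result of [encoder_forward()], or an `(N*T) x D` token matrix
#'   (then `n_images` must divide its row count via the grid size).
#' @param model a `fundseg_model`.
#' @return mask maps, array `[grid, grid, K, N]`.
#' @export
decoder_forward <- function(enc, model) {
  cfg <- model$config
  tok <- if (is.list(enc)) enc$tokens else enc
  N <- if (is.list(enc)) enc$n_images else nrow(tok) / cfg$grid_size^2
  dec <- model$layers$decoder
  T <- cfg$grid_size^2
  K <- cfg$num_classes
  Dd <- cfg$decoder_dim
  z <- dec$proj_in$fwd(tok)
  Tk <- T + K
  z2 <- matrix(0, N * Tk, Dd)
  for (n in seq_len(N)) {
    z2[((n - 1) * Tk + 1):((n - 1) * Tk + T), ] <-
      z[((n - 1) * T + 1):(n * T), ]
    z2[((n - 1) * Tk + T + 1):(n * Tk), ] <- dec$cls$value
  }
  for (blk in dec$blocks) z2 <- blk$fwd(z2, Tk)
  z2 <- dec$norm$fwd(z2)
  pat_rows <- as.vector(vapply(seq_len(N), function(n)
    ((n - 1) * Tk + 1):((n - 1) * Tk + T), integer(T)))
  cls_rows <- as.vector(vapply(seq_len(N), function(n)
    ((n - 1) * Tk + T + 1):(n * Tk), integer(K)))
  Zp <- z2[pat_rows, , drop = FALSE]
  Zc <- z2[cls_rows, , drop = FALSE]
  P <- Zp %*% dec$proj_patch$value
  Cc <- Zc %*% dec$proj_cls$value
  np <- l2_normalize_rows(P); nc <- l2_normalize_rows(Cc)
  masks <- matrix(0, N * T, K)
  for (n in seq_len(N)) {
    pr <- ((n - 1) * T + 1):(n * T)
    cr <- ((n - 1) * K + 1):(n * K)
    masks[pr, ] <- tcrossprod(np$y[pr, , drop = FALSE],
                              nc$y[cr, , drop = FALSE])
  }
  raw <- masks
  masks <- dec$mask_norm$fwd(masks)
  cch <- dec$cache
  cch$N <- N; cch$T <- T; cch$K <- K; cch$Zp <- Zp; cch$Zc <- Zc
  cch$np <- np; cch$nc <- nc; cch$pat_rows <- pat_rows
  cch$cls_rows <- cls_rows; cch$Tk <- Tk; cch$raw <- raw
  tokens_to_map(masks, cfg$grid_size, N)
}

decoder_backward <- function(g_maps, model) {
  cfg <- model$config
  dec <- model$layers$decoder
  cc <- dec$cache
  N <- cc$N; T <- cc$T; K <- cc$K
  g <- map_to_tokens(g_maps)
  g <- dec$mask_norm$bwd(g)
  gnp <- matrix(0, N * T, cfg$decoder_dim)
  gnc <- matrix(0, N * K, cfg$decoder_dim)
  for (n in seq_len(N)) {
    pr <- ((n - 1) * T + 1):(n * T)
    cr <- ((n - 1) * K + 1):(n * K)
    gm <- g[pr, , drop = FALSE]
    gnp[pr, ] <- gm %*% cc$nc$y[cr, , drop = FALSE]
    gnc[cr, ] <- crossprod(gm, cc$np$y[pr, , drop = FALSE])
  }
  rn_bwd <- function(gy, yn, r) (gy - yn$y * rowSums(gy * yn$y)) / r
  gP <- rn_bwd(gnp, cc$np, cc$np$r)
  gC <- rn_bwd(gnc, cc$nc, cc$nc$r)
  add_grad(dec$proj_patch, crossprod(cc$Zp, gP))
  add_grad(dec$proj_cls, crossprod(cc$Zc, gC))
  gZp <- gP %*% t(dec$proj_patch$value)
  gZc <- gC %*% t(dec$proj_cls$value)
  gz2 <- matrix(0, N * cc$Tk, cfg$decoder_dim)
  gz2[cc$pat_rows, ] <- gZp
  gz2[cc$cls_rows, ] <- gZc
  gz2 <- dec$norm$bwd(gz2)
  for (blk in rev(dec$blocks)) gz2 <- blk$bwd(gz2)
  gtok <- matrix(0, N * T, ncol(gz2))
  gcls <- matrix(0, K, ncol(gz2))
  for (n in seq_len(N)) {
    gtok[((n - 1) * T + 1):(n * T), ] <-
      gz2[((n - 1) * cc$Tk + 1):((n - 1) * cc$Tk + T), , drop = FALSE]
    gcls <- gcls + gz2[((n - 1) * cc$Tk + T + 1):(n * cc$Tk), , drop = FALSE]
  }
  add_grad(dec$cls, gcls)
  dec$proj_in$bwd(gtok)
}

#' Inner-product mask maps
#'
#' The decoder's mask-map primitive: rows of `patch_features` and
#' `class_embeddings` are L2-normalized (zero rows stay zero via an epsilon
#' guard) and every patch/class pair is scored by their scalar product.
#'
#' @param patch_features `T x D` matrix of patch features.
#' @param class_embeddings `K x D` matrix of class embeddings.
#' @return `T x K` matrix of mask-map values in `[-1, 1]`.
#' @export
mask_inner_product <- function(patch_features, class_embeddings) {
  tcrossprod(l2_normalize_rows(patch_features)$y,
             l2_normalize_rows(class_embeddings)$y)
}

l2_normalize_rows <- function(m) {
  r <- pmax(sqrt(rowSums(m * m)), 1e-12)
  list(y = m / r, r = r)
}

skip_sides <- function(cfg) cfg$canvas_size / 2^(0:3)

#' Skip-branch forward pass
#'
#' Each tapped token sequence is reshaped to its spatial grid, projected to
#' `skip_channels` by a 1x1 convolution, bicubically upsampled to its target
#' side (canvas, canvas/2, canvas/4, canvas/8 for taps 1..4), passed through
#' a basic CNN block and gated by CBAM (channel then spatial attention).
#'
#' @param enc result of [encoder_forward()] (or a list of 4 tapped token
#'   matrices plus `n_images`).
#' @param model a `fundseg_model` built with `use_skips = TRUE`.
#' @param train logical; training mode for normalization layers.
#' @return list of 4 arrays `[side_i, side_i, skip_channels, N]`.
#' @export
skip_branch_forward <- function(enc, model, train = FALSE) {
  cfg <- model$config
  taps <- if (is.list(enc) && !is.null(enc$taps)) enc$taps else enc
  if (length(taps) != 4) stopf("expected 4 tapped layers, got %d", length(taps))
  N <- if (!is.null(enc$n_images)) enc$n_images
  else nrow(taps[[1]]) / cfg$grid_size^2
  sides <- skip_sides(cfg)
  out <- vector("list", 4)
  for (i in 1:4) {
    br <- model$layers$skips[[i]]
    m <- tokens_to_map(taps[[i]], cfg$grid_size, N)
    m <- br$proj$fwd(m)
    m <- resample_image(m, sides[i], sides[i], "bicubic")
    m <- br$cnn$fwd(m, train)
    out[[i]] <- br$cbam$fwd(m, train)
  }
  out
}

skip_branch_backward <- function(g_list, model) {
  cfg <- model$config
  g_taps <- vector("list", 4)
  for (i in 1:4) {
    if (is.null(g_list[[i]])) next
    br <- model$layers$skips[[i]]
    g <- br$cbam$bwd(g_list[[i]])
    g <- br$cnn$bwd(g)
    g <- resample_backward(g, cfg$grid_size, cfg$grid_size, "bicubic")
    g <- br$proj$bwd(g)
    g_taps[[i]] <- map_to_tokens(g)
  }
  g_taps
}

#' Post-adapter forward pass
#'
#' Four stages of basic CNN block + 2x bicubic upsampling take the mask maps
#' from the token grid to the canvas size; after each stage the same-side
#' CBAM skip map is concatenated along channels and fused by a CNN block.
#' A final CNN block, a 1x1 output convolution and a bicubic resize to the
#' requested input size produce the mask logits.
#'
#' @param mask_maps array `[grid, grid, K, N]` from [decoder_forward()].
#' @param skips list of 4 skip maps from [skip_branch_forward()], or `NULL`
#'   when the model was built with `use_skips = FALSE`.
#' @param model a `fundseg_model`.
#' @param input_size output side in pixels (defaults to the configured one).
#' @param train logical; training mode for normalization layers.
#' @return logits, array `[input_size, input_size, K, N]`.
#' @export
post_adapter_forward <- function(mask_maps, skips, model,
                                 input_size = model$config$input_size,
                                 train = FALSE) {
  cfg <- model$config
  post <- model$layers$post
  if (is.null(post)) stopf("model was built without a post-adapter")
  use_skips <- cfg$use_skips && !is.null(skips)
  cur <- mask_maps
  post$cache$use_skips <- use_skips
  post$cache$input_size <- input_size
  for (s in seq_len(cfg$n_stages)) {
    cur <- post$stages[[s]]$fwd(cur, train)
    side <- dim(cur)[1] * 2L
    cur <- resample_image(cur, side, side, "bicubic")
    if (use_skips) {
      sk <- skips[[cfg$n_stages + 1 - s]]
      if (dim(sk)[1] != side)
        stopf("post-adapter stage %d: skip map side %d does not match stage side %d",
              s, dim(sk)[1], side)
      cur <- abind4(cur, sk)
      cur <- post$fuses[[s]]$fwd(cur, train)
    }
  }
  cur <- post$final$fwd(cur, train)
  cur <- post$out$fwd(cur)
  post$cache$canvas <- dim(cur)[1]
  resample_image(cur, input_size, input_size, "bicubic")
}

post_adapter_backward <- function(g, model) {
  cfg <- model$config
  post <- model$layers$post
  cv <- post$cache$canvas
  g <- resample_backward(g, cv, cv, "bicubic")
  g <- post$out$bwd(g)
  g <- post$final$bwd(g)
  g_skips <- vector("list", 4)
  sc <- cfg$skip_channels
  for (s in rev(seq_len(cfg$n_stages))) {
    if (post$cache$use_skips) {
      g <- post$fuses[[s]]$bwd(g)
      g_skips[[cfg$n_stages + 1 - s]] <- g[, , (sc + 1):(2 * sc), , drop = FALSE]
      g <- g[, , 1:sc, , drop = FALSE]
    }
    side <- dim(g)[1] / 2L
    g <- resample_backward(g, side, side, "bicubic")
    g <- post$stages[[s]]$bwd(g)
  }
  list(g_mask = g, g_skips = g_skips)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

## ---- full forward / backward / predict -----------------------------------

model_forward <- function(model, x, train = FALSE,
                          input_size = NULL) {
  cfg <- model$config
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  if (is.null(input_size)) input_size <- dim(x)[1]
  x224 <- if (cfg$use_pre_adapter) pre_adapter_forward(x, model, train)
  else {
    if (dim(x)[1] != cfg$canvas_size)
      resample_image(x, cfg$canvas_size, cfg$canvas_size, "bicubic") else x
  }
  enc <- encoder_forward(x224, model)
  maps <- decoder_forward(enc, model)
  skips <- if (cfg$use_skips) skip_branch_forward(enc, model, train)
  if (cfg$use_post_adapter) {
    post_adapter_forward(maps, skips, model, input_size, train)
  } else {
    resample_image(maps, input_size, input_size, "bicubic")
  }
}

model_backward <- function(model, g_logits) {
  cfg <- model$config
  if (cfg$use_post_adapter) {
    pb <- post_adapter_backward(g_logits, model)
    g_maps <- pb$g_mask
    g_skip_list <- pb$g_skips
  } else {
    g_maps <- resample_backward(g_logits, cfg$grid_size, cfg$grid_size, "bicubic")
    g_skip_list <- vector("list", 4)
  }
  g_tok <- decoder_backward(g_maps, model)
  g_taps <- if (cfg$use_skips) skip_branch_backward(g_skip_list, model)
  else vector("list", 4)
  gx224 <- encoder_backward(g_tok, g_taps, model)
  if (cfg$use_pre_adapter) pre_adapter_backward(gx224, model)
  invisible(NULL)
}

#' Segment images
#'
#' Runs the full forward pass, applies a per-pixel softmax over the K
#' classes and takes the argmax (ties broken toward the lowest class index)
#' to obtain label masks.
#'
#' @param object a `fundseg_model`.
#' @param x image array `[H, W, 3]` or `[H, W, 3, N]`, range-normalized.
#' @param ... unused.
#' @return list with `probs` (array `[H, W, K, N]`, per-pixel simplex) and
#'   `labels` (integer array `[H, W, N]`, values in `0..K-1`).
#' @export
predict.fundseg_model <- function(object, x, ...) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  logits <- model_forward(object, x, train = FALSE, input_size = dim(x)[1])
  softmax_predict(logits)
}

softmax_predict <- function(logits) {
  d <- dim(logits)
  K <- d[3]
  m <- matrix(aperm(logits, c(3, 1, 2, 4)), K)
  M <- ncol(m)
  mx <- m[1, ]
  if (K > 1) for (k in 2:K) mx <- pmax(mx, m[k, ])
  e <- exp(m - rep(mx, each = K))
  p <- e / rep(.colSums(e, K, M), each = K)
  lab <- rep(0L, M)
  best <- p[1, ]
  if (K > 1) for (k in 2:K) {
    upd <- p[k, ] > best
    lab[upd] <- k - 1L
    best[upd] <- p[k, upd]
  }
  probs <- aperm(array(p, c(K, d[1], d[2], d[4])), c(2, 3, 1, 4))
  labels <- array(lab, c(d[1], d[2], d[4]))
  list(probs = probs, labels = labels)
}
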