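# Spatial layers over [H, W, C, N] arrays: convolution (compiled im2col+GEMM
# kernels), batch/group normalization, the basic CNN block (conv3x3 + norm +
# ReLU), CBAM attention, and the ViT patch embedding.

# per-channel sums of an [H*W, C, N]-shaped array given as the raw vector
chan_sum <- function(a, HW, C, N) {
  rowSums(matrix(.colSums(a, HW, C * N), C, N))
}

layer_conv2d <- function(k, c_in, c_out, frozen = FALSE, bias = TRUE) {
  sd <- sqrt(2 / (k * k * c_in))
  w <- array(stats::rnorm(k * k * c_in * c_out, sd = sd), c(k, k, c_in, c_out))
  l <- new_layer("conv2d",
                 list(weight = new_param(w, frozen),
                      bias = new_param(numeric(c_out), frozen)))
  l$k <- k; l$c_in <- c_in; l$c_out <- c_out
  l$fwd <- function(x) {
    l$x <- x
    conv2d_fw_cpp(x, dim(x), l$params$weight$value,
                  dim(l$params$weight$value), l$params$bias$value)
  }
  l$bwd <- function(g) {
    r <- conv2d_bw_cpp(l$x, dim(l$x), l$params$weight$value,
                       dim(l$params$weight$value), g)
    add_grad(l$params$weight, r$gw)
    add_grad(l$params$bias, r$gb)
    r$gx
  }
  l
}

# Batch normalization (stats over H, W and batch per channel; running stats
# for inference) or group normalization (8 groups, per-image stats).
layer_norm2d <- function(channels, kind = c("batch", "group"), groups = 8,
                         frozen = FALSE, eps = 1e-5, momentum = 0.1) {
  kind <- match.arg(kind)
  l <- new_layer("norm2d",
                 list(gamma = new_param(rep(1, channels), frozen),
                      beta = new_param(numeric(channels), frozen)))
  l$kind <- kind
  l$run_mean <- numeric(channels)
  l$run_var <- rep(1, channels)
  if (kind == "group") {
    groups <- min(groups, channels)
    while (channels %% groups != 0) groups <- groups - 1
  }
  l$groups <- groups
  gamma_b <- function(d) rep(rep(l$params$gamma$value, each = d[1] * d[2]),
                             times = d[4])
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    if (l$kind == "batch") {
      if (train) {
        M <- HW * N
        mean_c <- chan_sum(x, HW, C, N) / M
        var_c <- chan_sum(x * x, HW, C, N) / M - mean_c^2
        l$run_mean <- (1 - momentum) * l$run_mean + momentum * mean_c
        l$run_var <- (1 - momentum) * l$run_var + momentum * var_c * M / max(M - 1, 1)
      } else {
        mean_c <- l$run_mean; var_c <- l$run_var
      }
      inv_c <- 1 / sqrt(var_c + eps)
      xhat <- (x - rep(mean_c, each = HW)) * rep(inv_c, each = HW)
      l$inv <- inv_c
    } else {
      G <- l$groups; cg <- C / G
      m <- matrix(x, HW * cg, G * N)
      mu <- .colMeans(m, HW * cg, G * N)
      v <- .colMeans(m * m, HW * cg, G * N) - mu^2
      inv <- 1 / sqrt(v + eps)
      xhat <- (x - rep(mu, each = HW * cg)) * rep(inv, each = HW * cg)
      dim(xhat) <- d
      l$inv <- inv
    }
    l$xhat <- xhat; l$train_mode <- train
    y <- xhat * rep(l$params$gamma$value, each = HW) +
      rep(l$params$beta$value, each = HW)
    dim(y) <- d
    y
  }
  l$bwd <- function(g) {
    d <- dim(g); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    xhat <- l$xhat
    add_grad(l$params$gamma, chan_sum(g * xhat, HW, C, N))
    add_grad(l$params$beta, chan_sum(g, HW, C, N))
    dxhat <- g * rep(l$params$gamma$value, each = HW)
    if (l$kind == "batch") {
      if (!l$train_mode) {
        gx <- dxhat * rep(l$inv, each = HW); dim(gx) <- d; return(gx)
      }
      M <- HW * N
      s1 <- chan_sum(dxhat, HW, C, N)
      s2 <- chan_sum(dxhat * xhat, HW, C, N)
      gx <- (dxhat - (rep(s1, each = HW) + xhat * rep(s2, each = HW)) / M) *
        rep(l$inv, each = HW)
    } else {
      G <- l$groups; cg <- C / G; M <- HW * cg
      s1 <- .colSums(matrix(dxhat, M, G * N), M, G * N)
      s2 <- .colSums(matrix(dxhat * xhat, M, G * N), M, G * N)
      gx <- (dxhat - (rep(s1, each = M) + xhat * rep(s2, each = M)) / M) *
        rep(l$inv, each = M)
    }
    dim(gx) <- d
    gx
  }
  l
}

layer_relu2d <- function() {
  l <- new_layer("relu")
  l$fwd <- function(x) { l$mask <- x > 0; x * l$mask }
  l$bwd <- function(g) g * l$mask
  l
}

# Basic CNN block: 3x3 conv -> normalization -> ReLU.
layer_cnn_block <- function(c_in, c_out, norm_kind = "batch", k = 3) {
  l <- new_layer("cnn_block")
  l$children <- list(conv = layer_conv2d(k, c_in, c_out),
                     norm = layer_norm2d(c_out, norm_kind),
                     act = layer_relu2d())
  l$fwd <- function(x, train = TRUE) {
    l$children$act$fwd(l$children$norm$fwd(l$children$conv$fwd(x), train))
  }
  l$bwd <- function(g) {
    l$children$conv$bwd(l$children$norm$bwd(l$children$act$bwd(g)))
  }
  l
}

## ---- CBAM: channel attention then spatial attention ----------------------

layer_cbam <- function(channels, reduction = 16, spatial_k = 7) {
  mid <- min(channels, max(channels %/% reduction, 4))
  l <- new_layer("cbam",
                 list(fc1_w = new_param(init_linear_weight(channels, mid,
                                                           sd = sqrt(2 / channels))),
                      fc1_b = new_param(numeric(mid)),
                      fc2_w = new_param(init_linear_weight(mid, channels,
                                                           sd = sqrt(2 / mid))),
                      fc2_b = new_param(numeric(channels))))
  l$children <- list(sp_conv = layer_conv2d(spatial_k, 2, 1))
  mlp_fwd <- function(A) {
    h <- sweep(A %*% l$params$fc1_w$value, 2, l$params$fc1_b$value, "+")
    hr <- pmax(h, 0)
    z <- sweep(hr %*% l$params$fc2_w$value, 2, l$params$fc2_b$value, "+")
    list(z = z, hr = hr, pos = h > 0, A = A)
  }
  mlp_bwd <- function(cache, gz) {
    add_grad(l$params$fc2_w, crossprod(cache$hr, gz))
    add_grad(l$params$fc2_b, colSums(gz))
    gh <- (gz %*% t(l$params$fc2_w$value)) * cache$pos
    add_grad(l$params$fc1_w, crossprod(cache$A, gh))
    add_grad(l$params$fc1_b, colSums(gh))
    gh %*% t(l$params$fc1_w$value)
  }
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    m2 <- matrix(x, HW, C * N)
    avg <- .colMeans(m2, HW, C * N)
    arg <- integer(C * N); mxv <- numeric(C * N)
    for (j in seq_len(C * N)) {
      arg[j] <- which.max(m2[, j]); mxv[j] <- m2[arg[j], j]
    }
    A <- t(matrix(avg, C, N))   # N x C
    Mx <- t(matrix(mxv, C, N))
    ca <- mlp_fwd(A); cm <- mlp_fwd(Mx)
    sc <- 1 / (1 + exp(-(ca$z + cm$z)))          # N x C channel gate
    gc_full <- rep(as.vector(t(sc)), each = HW)  # broadcast to [HW, C, N]
    x1 <- x * gc_full
    # spatial attention on the channel-gated map
    x13 <- matrix(x1, HW, C * N)
    mean_sp <- matrix(0, HW, N); max_sp <- matrix(0, HW, N)
    argc <- matrix(1L, HW, N)
    for (n in seq_len(N)) {
      cols <- ((n - 1) * C + 1):(n * C)
      blk <- x13[, cols, drop = FALSE]
      mean_sp[, n] <- .rowMeans(blk, HW, C)
      mm <- blk[, 1]; wa <- rep(1L, HW)
      if (C > 1) for (cc in 2:C) {
        upd <- blk[, cc] > mm
        mm[upd] <- blk[upd, cc]; wa[upd] <- cc
      }
      max_sp[, n] <- mm; argc[, n] <- wa
    }
    sp_in <- array(0, c(d[1], d[2], 2, N))
    sp_in[, , 1, ] <- mean_sp
    sp_in[, , 2, ] <- max_sp
    s_logit <- l$children$sp_conv$fwd(sp_in)
    s <- 1 / (1 + exp(-matrix(s_logit, HW, N)))
    s_full <- array(0, c(HW, C, N))
    for (n in seq_len(N)) s_full[, , n] <- s[, n]
    y <- x1 * as.vector(s_full)
    dim(y) <- d
    l$x <- x; l$gc <- sc; l$gc_full <- gc_full; l$x1 <- x1
    l$s <- s; l$s_full <- s_full; l$arg_ch <- arg; l$arg_sp <- argc
    l$ca <- ca; l$cm <- cm; l$d <- d
    y
  }
  l$bwd <- function(g) {
    d <- l$d; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    x1m <- matrix(l$x1, HW, C * N)
    gm <- matrix(g, HW, C * N)
    # through spatial gate y = x1 * s
    ds <- matrix(0, HW, N)
    for (n in seq_len(N)) {
      cols <- ((n - 1) * C + 1):(n * C)
      ds[, n] <- .rowSums(gm[, cols, drop = FALSE] * x1m[, cols, drop = FALSE],
                          HW, C)
    }
    dx1 <- g * as.vector(l$s_full)
    dlogit <- ds * l$s * (1 - l$s)
    gsp <- l$children$sp_conv$bwd(array(dlogit, c(d[1], d[2], 1, N)))
    dmean <- matrix(gsp[, , 1, ], HW, N)
    dmax <- matrix(gsp[, , 2, ], HW, N)
    dx1m <- matrix(dx1, HW, C * N)
    for (n in seq_len(N)) {
      cols <- ((n - 1) * C + 1):(n * C)
      dx1m[, cols] <- dx1m[, cols] + dmean[, n] / C
      sel <- cbind(seq_len(HW), cols[l$arg_sp[, n]])
      idx <- sel[, 1] + HW * (sel[, 2] - 1)
      dx1m[idx] <- dx1m[idx] + dmax[, n]
    }
    # through channel gate x1 = x * gc
    xm <- matrix(l$x, HW, C * N)
    dx <- dx1m * l$gc_full
    dgc <- .colSums(dx1m * xm, HW, C * N)               # per (c, n)
    dgc_t <- t(matrix(dgc, C, N))                       # N x C
    dz <- dgc_t * l$gc * (1 - l$gc)
    dA <- mlp_bwd(l$ca, dz)
    dM <- mlp_bwd(l$cm, dz)
    # avg-pool backward: spread evenly over spatial positions
    dx <- dx + rep(as.vector(t(dA)), each = HW) / HW
    # max-pool backward: route to the argmax position of each (c, n)
    pos <- l$arg_ch + HW * (seq_len(C * N) - 1)
    dx[pos] <- dx[pos] + as.vector(t(dM))
    dim(dx) <- d
    dx
  }
  l
}

## ---- patch embedding ------------------------------------------------------

# Splits a canvas-sized image into non-overlapping patches, flattens each and
# projects it linearly; learned positional embeddings are added (no class
# token in the fine-tuned forward path).
layer_patch_embed <- function(canvas, patch, d, in_ch = 3, frozen = FALSE) {
  g <- canvas %/% patch
  P <- patch * patch * in_ch
  tt <- seq_len(g * g) - 1
  gr <- tt %% g; gc <- tt %/% g
  ff <- seq_len(P) - 1
  ph <- ff %% patch; pw <- (ff %/% patch) %% patch; ch <- ff %/% (patch * patch)
  idx <- outer(gr * patch, ph, "+") + 1 +
    canvas * outer(gc * patch, pw, "+") +
    canvas * canvas * matrix(ch, g * g, P, byrow = TRUE)
  l <- new_layer("patch_embed",
                 list(weight = new_param(init_linear_weight(P, d), frozen),
                      bias = new_param(numeric(d), frozen),
                      pos = new_param(matrix(rtruncnorm(g * g * d, sd = 0.02),
                                             g * g, d), frozen)))
  l$idx <- as.vector(idx)
  l$grid <- g; l$P <- P; l$canvas <- canvas; l$in_ch <- in_ch
  l$fwd <- function(x) {
    d4 <- dim(x); N <- d4[4]
    T <- g * g
    l$patches <- vector("list", N)
    out <- matrix(0, N * T, d)
    for (n in seq_len(N)) {
      xi <- x[, , , n]
      pm <- matrix(xi[l$idx], T, P)
      l$patches[[n]] <- pm
      out[((n - 1) * T + 1):(n * T), ] <-
        pm %*% l$params$weight$value + l$params$pos$value
    }
    out <- sweep(out, 2, l$params$bias$value, "+")
    l$N <- N
    out
  }
  l$bwd <- function(gtok) {
    T <- g * g; N <- l$N
    gx <- array(0, c(canvas, canvas, in_ch, N))
    for (n in seq_len(N)) {
      gi <- gtok[((n - 1) * T + 1):(n * T), , drop = FALSE]
      add_grad(l$params$weight, crossprod(l$patches[[n]], gi))
      add_grad(l$params$pos, gi)
      gp <- gi %*% t(l$params$weight$value)
      plane <- numeric(canvas * canvas * in_ch)
      plane[l$idx] <- as.vector(gp)
      gx[, , , n] <- plane
    }
    add_grad(l$params$bias, colSums(gtok))
    gx
  }
  l
}
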