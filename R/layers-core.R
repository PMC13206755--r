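# Minimal layer framework with explicit forward/backward passes.
#
# A parameter is an environment holding $value, $grad (accumulated) and
# $frozen; a layer is an environment of class "fs_layer" holding its
# parameters, a forward closure that caches what the backward pass needs,
# and a backward closure that accumulates parameter gradients and returns
# the gradient with respect to its input. Token tensors are stored as
# stacked matrices: (n_images * n_tokens) x dim, image-major blocks.

new_param <- function(value, frozen = FALSE) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$frozen <- frozen
  p
}

new_layer <- function(type, params = list()) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- params
  class(l) <- c(paste0("fs_", type), "fs_layer")
  l
}

param_size <- function(p) length(p$value)

add_grad <- function(p, g) {
  if (p$frozen) return(invisible(NULL))
  if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
  invisible(NULL)
}

# Recursively collect parameter environments from nested lists/layers.
collect_params <- function(x, prefix = "") {
  if (inherits(x, "fs_layer")) {
    out <- list()
    for (nm in names(x$params))
      out[[paste0(prefix, nm)]] <- x$params[[nm]]
    if (!is.null(x$children))
      out <- c(out, collect_params(x$children, prefix = paste0(prefix, "")))
    return(out)
  }
  if (is.environment(x) && !is.null(x$value)) {
    out <- list(); out[[sub("\\.$", "", prefix)]] <- x; return(out)
  }
  if (is.list(x)) {
    out <- list()
    nms <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x)) {
      nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
      pre <- if (prefix == "") nm else paste0(prefix, nm)
      out <- c(out, collect_params(x[[i]], prefix = paste0(pre, ".")))
    }
    return(out)
  }
  list()
}

# Recursively collect layer environments (named by path), e.g. to reach
# normalization layers' running statistics.
collect_layers <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "fs_layer")) {
    out[[sub("\\.$", "", prefix)]] <- x
    if (!is.null(x$children))
      out <- c(out, collect_layers(x$children, prefix = prefix))
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x)) {
      nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
      pre <- if (prefix == "") nm else paste0(prefix, nm)
      out <- c(out, collect_layers(x[[i]], prefix = paste0(pre, ".")))
    }
  }
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

init_linear_weight <- function(d_in, d_out, sd = 0.02) {
  matrix(rtruncnorm(d_in * d_out, sd = sd), d_in, d_out)
}

## ---- dense (token) layers ------------------------------------------------

layer_linear <- function(d_in, d_out, bias = TRUE, frozen = FALSE, sd = 0.02) {
  params <- list(weight = new_param(init_linear_weight(d_in, d_out, sd), frozen))
  if (bias) params$bias <- new_param(numeric(d_out), frozen)
  l <- new_layer("linear", params)
  l$fwd <- function(x) {
    l$x <- x
    y <- x %*% l$params$weight$value
    if (!is.null(l$params$bias))
      y <- sweep(y, 2, l$params$bias$value, "+")
    y
  }
  l$bwd <- function(g) {
    add_grad(l$params$weight, crossprod(l$x, g))
    if (!is.null(l$params$bias)) add_grad(l$params$bias, colSums(g))
    g %*% t(l$params$weight$value)
  }
  l
}

layer_layernorm <- function(d, frozen = FALSE, eps = 1e-6) {
  l <- new_layer("layernorm",
                 list(gamma = new_param(rep(1, d), frozen),
                      beta = new_param(numeric(d), frozen)))
  l$fwd <- function(x) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * inv
    l$xhat <- xhat; l$inv <- inv
    sweep(xhat, 2, l$params$gamma$value, "*") +
      rep(l$params$beta$value, each = nrow(x))
  }
  l$bwd <- function(g) {
    xhat <- l$xhat; inv <- l$inv
    dxhat <- sweep(g, 2, l$params$gamma$value, "*")
    add_grad(l$params$gamma, colSums(g * xhat))
    add_grad(l$params$beta, colSums(g))
    d <- ncol(g)
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
  }
  l
}

layer_gelu <- function() {
  l <- new_layer("gelu")
  l$fwd <- function(x) { l$x <- x; x * stats::pnorm(x) }
  l$bwd <- function(g) {
    x <- l$x
    g * (stats::pnorm(x) + x * stats::dnorm(x))
  }
  l
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

# Multi-head self-attention over stacked token matrices. `n_tok` tokens per
# image; rows of x are image-major blocks.
layer_mha <- function(d, heads, frozen = FALSE) {
  stopifnot(d %% heads == 0)
  l <- new_layer("mha",
                 list(qkv_w = new_param(init_linear_weight(d, 3 * d), frozen),
                      qkv_b = new_param(numeric(3 * d), frozen),
                      proj_w = new_param(init_linear_weight(d, d), frozen),
                      proj_b = new_param(numeric(d), frozen)))
  l$heads <- heads
  l$fwd <- function(x, n_tok) {
    n_img <- nrow(x) / n_tok
    dh <- d / heads
    qkv <- sweep(x %*% l$params$qkv_w$value, 2, l$params$qkv_b$value, "+")
    ctx <- matrix(0, nrow(x), d)
    cache <- vector("list", n_img)
    for (i in seq_len(n_img)) {
      rows <- ((i - 1) * n_tok + 1):(i * n_tok)
      qkv_i <- qkv[rows, , drop = FALSE]
      hc <- vector("list", heads)
      for (h in seq_len(heads)) {
        cq <- ((h - 1) * dh + 1):(h * dh)
        Q <- qkv_i[, cq, drop = FALSE]
        K <- qkv_i[, d + cq, drop = FALSE]
        V <- qkv_i[, 2 * d + cq, drop = FALSE]
        A <- softmax_rows(tcrossprod(Q, K) / sqrt(dh))
        ctx[rows, cq] <- A %*% V
        hc[[h]] <- list(Q = Q, K = K, V = V, A = A)
      }
      cache[[i]] <- hc
    }
    l$x <- x; l$cache <- cache; l$n_tok <- n_tok; l$ctx <- ctx
    sweep(ctx %*% l$params$proj_w$value, 2, l$params$proj_b$value, "+")
  }
  l$bwd <- function(g) {
    n_tok <- l$n_tok
    n_img <- nrow(g) / n_tok
    dh <- d / heads
    add_grad(l$params$proj_w, crossprod(l$ctx, g))
    add_grad(l$params$proj_b, colSums(g))
    gctx <- g %*% t(l$params$proj_w$value)
    gqkv <- matrix(0, nrow(g), 3 * d)
    for (i in seq_len(n_img)) {
      rows <- ((i - 1) * n_tok + 1):(i * n_tok)
      for (h in seq_len(heads)) {
        cq <- ((h - 1) * dh + 1):(h * dh)
        cc <- l$cache[[i]][[h]]
        gO <- gctx[rows, cq, drop = FALSE]
        gA <- tcrossprod(gO, cc$V)
        gV <- crossprod(cc$A, gO)
        # softmax backward per row
        gS <- cc$A * (gA - rowSums(gA * cc$A))
        gS <- gS / sqrt(dh)
        gQ <- gS %*% cc$K
        gK <- crossprod(gS, cc$Q)
        gqkv[rows, cq] <- gQ
        gqkv[rows, d + cq] <- gK
        gqkv[rows, 2 * d + cq] <- gV
      }
    }
    add_grad(l$params$qkv_w, crossprod(l$x, gqkv))
    add_grad(l$params$qkv_b, colSums(gqkv))
    gqkv %*% t(l$params$qkv_w$value)
  }
  l
}

# Bottleneck adapter with residual skip: x + W2 gelu(W1 x).
layer_adapter <- function(d, mid) {
  l <- new_layer("adapter")
  l$children <- list(down = layer_linear(d, mid),
                     act = layer_gelu(),
                     up = layer_linear(mid, d))
  l$fwd <- function(x) {
    x + l$children$up$fwd(l$children$act$fwd(l$children$down$fwd(x)))
  }
  l$bwd <- function(g) {
    g + l$children$down$bwd(l$children$act$bwd(l$children$up$bwd(g)))
  }
  l
}

# Pre-norm transformer block; when `adapter_mid` is given, a trainable
# bottleneck adapter sits between the layer norm and the attention block.
layer_vit_block <- function(d, heads, mlp_ratio = 4, adapter_mid = NULL,
                            frozen = FALSE) {
  l <- new_layer("vit_block")
  ch <- list(norm1 = layer_layernorm(d, frozen),
             attn = layer_mha(d, heads, frozen),
             norm2 = layer_layernorm(d, frozen),
             mlp_fc1 = layer_linear(d, d * mlp_ratio, frozen = frozen),
             mlp_act = layer_gelu(),
             mlp_fc2 = layer_linear(d * mlp_ratio, d, frozen = frozen))
  if (!is.null(adapter_mid)) ch$adapter <- layer_adapter(d, adapter_mid)
  l$children <- ch
  l$fwd <- function(x, n_tok) {
    h <- l$children$norm1$fwd(x)
    if (!is.null(l$children$adapter)) h <- l$children$adapter$fwd(h)
    x <- x + l$children$attn$fwd(h, n_tok)
    h <- l$children$mlp_fc1$fwd(l$children$norm2$fwd(x))
    x + l$children$mlp_fc2$fwd(l$children$mlp_act$fwd(h))
  }
  l$bwd <- function(g) {
    gh <- l$children$mlp_fc2$bwd(g)
    gh <- l$children$mlp_act$bwd(gh)
    gh <- l$children$mlp_fc1$bwd(gh)
    g <- g + l$children$norm2$bwd(gh)
    gh <- l$children$attn$bwd(g)
    if (!is.null(l$children$adapter)) gh <- l$children$adapter$bwd(gh)
    g + l$children$norm1$bwd(gh)
  }
  l
}
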