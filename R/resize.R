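# Separable image resampling as sparse linear operators. One convention is
# used everywhere: half-pixel-centered sampling (no corner alignment), with
# border replication for the bicubic kernel. Because every resampling layer
# is a fixed linear map, its backward pass is the transposed operator.

cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * (x^3 - 5 * x^2 + 8 * x - 4), 0))
}

# n_out x n_in sparse row-stochastic bicubic interpolation matrix
resample_matrix_bicubic <- function(n_in, n_out) {
  scale <- n_in / n_out
  i <- seq_len(n_out) - 1
  src <- (i + 0.5) * scale - 0.5
  base <- floor(src)
  t <- src - base
  rows <- cols <- vals <- vector("list", 4)
  for (k in 0:3) {
    j <- base + k - 1
    w <- cubic_kernel(t - (k - 1))
    rows[[k + 1]] <- i + 1
    cols[[k + 1]] <- clamp(j, 0, n_in - 1) + 1
    vals[[k + 1]] <- w
  }
  m <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                            x = unlist(vals), dims = c(n_out, n_in))
  methods::as(m, "CsparseMatrix")
}

# n_out x n_in area-weighted (pixel-area relation) resampling matrix
resample_matrix_area <- function(n_in, n_out) {
  scale <- n_in / n_out
  rows <- cols <- vals <- list()
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo)
    j1 <- min(ceiling(hi), n_in)
    j <- seq.int(j0, j1 - 1)
    w <- pmin(hi, j + 1) - pmax(lo, j)
    keep <- w > 1e-12
    rows[[i]] <- rep.int(i, sum(keep))
    cols[[i]] <- j[keep] + 1
    vals[[i]] <- w[keep] / scale
  }
  m <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                            x = unlist(vals), dims = c(n_out, n_in))
  methods::as(m, "CsparseMatrix")
}

nearest_index <- function(n_in, n_out) {
  scale <- n_in / n_out
  clamp(floor((seq_len(n_out) - 0.5) * scale), 0, n_in - 1) + 1
}

resample_op <- function(kind, n_in, n_out, transpose = FALSE) {
  key <- paste(kind, n_in, n_out, sep = ":")
  op <- .fundseg_cache[[key]]
  if (is.null(op)) {
    op <- switch(kind,
                 bicubic = resample_matrix_bicubic(n_in, n_out),
                 area = resample_matrix_area(n_in, n_out),
                 stopf("unknown resampling kind '%s'", kind))
    .fundseg_cache[[key]] <- op
    .fundseg_cache[[paste0(key, ":t")]] <- Matrix::t(op)
  }
  if (transpose) .fundseg_cache[[paste0(key, ":t")]] else op
}

# Apply the separable operator pair to a [H, W, C, N] array (C, N optional).
apply_separable <- function(x, Rh, Rw) {
  d <- dim(x)
  if (is.null(d)) stopf("resample: input must be an array")
  if (length(d) == 2) d <- c(d, 1L, 1L)
  if (length(d) == 3) d <- c(d, 1L)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  y <- as.matrix(Rh %*% matrix(x, H, W * C * N))
  Ho <- nrow(Rh)
  y <- aperm(array(y, c(Ho, W, C, N)), c(2, 1, 3, 4))
  y <- as.matrix(Rw %*% matrix(y, W, Ho * C * N))
  Wo <- nrow(Rw)
  aperm(array(y, c(Wo, Ho, C, N)), c(2, 1, 3, 4))
}

#' Resample an image or feature array
#'
#' @param x array `[H, W]`, `[H, W, C]` or `[H, W, C, N]`.
#' @param out_h,out_w output sides in pixels.
#' @param method `"bicubic"` (half-pixel-centered Keys kernel, a = -0.5),
#'   `"area"` (pixel-area relation, the inter-area convention used for
#'   downscaling network inputs) or `"nearest"` (used for label masks).
#' @return array of the same rank with spatial sides `out_h`, `out_w`.
#' @export
resample_image <- function(x, out_h, out_w = out_h,
                           method = c("bicubic", "area", "nearest")) {
  method <- match.arg(method)
  d <- dim(x)
  rank <- length(d)
  if (rank < 2) stopf("resample_image: input must have at least 2 dimensions")
  if (method == "nearest") {
    ih <- nearest_index(d[1], out_h)
    iw <- nearest_index(d[2], out_w)
    y <- if (rank == 2) x[ih, iw, drop = FALSE]
    else if (rank == 3) x[ih, iw, , drop = FALSE]
    else x[ih, iw, , , drop = FALSE]
    return(y)
  }
  Rh <- resample_op(method, d[1], out_h)
  Rw <- resample_op(method, d[2], out_w)
  y <- apply_separable(x, Rh, Rw)
  if (rank == 2) dim(y) <- c(out_h, out_w)
  if (rank == 3) dim(y) <- c(out_h, out_w, d[3])
  y
}

# Gradient of resample_image (linear map): pushes a gradient at the output
# resolution back to the input resolution with the transposed operators.
resample_backward <- function(g, in_h, in_w, method = "bicubic") {
  d <- dim(g)
  Rh <- resample_op(method, in_h, d[1], transpose = TRUE)
  Rw <- resample_op(method, in_w, d[2], transpose = TRUE)
  apply_separable(g, Rh, Rw)
}

#' Rotate an image about its center
#'
#' Inverse-mapped rotation with bicubic sampling for images and
#' nearest-neighbor sampling for label masks; pixels mapped from outside the
#' source are set to `fill`.
#'
#' @param x array `[H, W]` or `[H, W, C]`.
#' @param degrees counter-clockwise rotation angle.
#' @param method `"bicubic"` or `"nearest"`.
#' @param fill value for out-of-bounds samples.
#' @return rotated array, same shape as `x`.
#' @export
rotate_image <- function(x, degrees, method = c("bicubic", "nearest"), fill = 0) {
  method <- match.arg(method)
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- if (length(d) >= 3) d[3] else 1L
  th <- degrees * pi / 180
  cth <- cos(th); sth <- sin(th)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  r <- rep(seq_len(H) - 1 - cy, times = W)
  c0 <- rep(seq_len(W) - 1 - cx, each = H)
  sr <- cth * r + sth * c0 + cy
  sc <- -sth * r + cth * c0 + cx
  xm <- matrix(x, H * W, C)
  out <- matrix(fill, H * W, C)
  if (method == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 0 & ri < H & ci >= 0 & ci < W
    idx <- ri[ok] + 1 + H * ci[ok]
    out[ok, ] <- xm[idx, , drop = FALSE]
  } else {
    inside <- sr > -1 & sr < H & sc > -1 & sc < W
    b_r <- floor(sr); t_r <- sr - b_r
    b_c <- floor(sc); t_c <- sc - b_c
    acc <- matrix(0, H * W, C)
    wsum <- numeric(H * W)
    for (kr in 0:3) {
      wr <- cubic_kernel(t_r - (kr - 1))
      rr <- clamp(b_r + kr - 1, 0, H - 1)
      for (kc in 0:3) {
        wc <- cubic_kernel(t_c - (kc - 1))
        w <- wr * wc
        cc <- clamp(b_c + kc - 1, 0, W - 1)
        idx <- rr + 1 + H * cc
        acc <- acc + w * xm[idx, , drop = FALSE]
        wsum <- wsum + w
      }
    }
    ok <- inside & wsum > 1e-9
    out[ok, ] <- acc[ok, , drop = FALSE] / wsum[ok]
  }
  array(out, d)
}
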