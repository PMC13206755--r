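# Combined Dice + cross-entropy training objective.
#
# The Dice term is the soft formulation: per class (background included) and
# per image, TP/FP/FN are computed from post-softmax probabilities against
# one-hot targets with linear denominator terms and a smoothing constant of
# 1e-5; the per-class Dice fractions are averaged over classes and the batch
# and the loss is one minus that mean. The cross-entropy term is the mean
# negative log-probability of the true class over all pixels.

EPS_DICE <- 1e-5
EPS_LOG <- 1e-12

check_probs_target <- function(probs, target) {
  dp <- dim(probs)
  if (length(dp) == 3) { dim(probs) <- c(dp, 1L); dp <- dim(probs) }
  dt <- dim(target)
  if (is.null(dt)) stopf("target must be an array")
  if (length(dt) == 2) dim(target) <- c(dt, 1L)
  dt <- dim(target)
  if (!all(dp[c(1, 2, 4)] == dt)) stopf("probs and target shapes do not match")
  K <- dp[3]
  if (any(target < 0 | target >= K))
    stopf("target contains labels outside 0..%d", K - 1)
  list(probs = probs, target = target, K = K,
       HW = dp[1] * dp[2], N = dp[4])
}

# per-image, per-class soft-Dice fractions -> K x N matrix
soft_dice_fractions <- function(probs, target, K, HW, N) {
  pm <- matrix(probs, HW, K * N)
  tv <- as.integer(target)
  num <- den <- matrix(0, K, N)
  for (n in seq_len(N)) {
    t_n <- tv[((n - 1) * HW + 1):(n * HW)]
    for (k in seq_len(K)) {
      p <- pm[, (n - 1) * K + k]
      tk <- t_n == (k - 1L)
      num[k, n] <- 2 * sum(p[tk]) + EPS_DICE
      den[k, n] <- sum(p) + sum(tk) + EPS_DICE
    }
  }
  list(frac = num / den, num = num, den = den)
}

#' Soft Dice loss
#'
#' One minus the mean soft-Dice overlap between class probability maps and
#' one-hot targets, averaged over all classes (background included) and
#' images.
#'
#' @param probs array `[H, W, K]` or `[H, W, K, N]` of per-pixel class
#'   probabilities.
#' @param target integer label array `[H, W]` or `[H, W, N]`, values in
#'   `0..K-1`.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(probs, target) {
  a <- check_probs_target(probs, target)
  sd <- soft_dice_fractions(a$probs, a$target, a$K, a$HW, a$N)
  1 - mean(sd$frac)
}

#' Cross-entropy loss
#'
#' Mean negative log-probability of the true class over all pixels;
#' probabilities are clipped below at 1e-12 before the logarithm.
#'
#' @inheritParams dice_loss
#' @return non-negative scalar.
#' @export
cross_entropy_loss <- function(probs, target) {
  a <- check_probs_target(probs, target)
  pm <- matrix(a$probs, a$HW, a$K * a$N)
  tv <- as.integer(a$target)
  n_blk <- rep(seq_len(a$N) - 1L, each = a$HW)
  cols <- n_blk * a$K + tv + 1L
  rows <- rep(seq_len(a$HW), times = a$N)
  p_true <- pm[cbind(rows, cols)]
  -mean(log(pmax(p_true, EPS_LOG)))
}

#' Combined segmentation loss
#'
#' @inheritParams dice_loss
#' @return list with components `dice`, `ce` and `total = dice + ce`.
#' @export
total_loss <- function(probs, target) {
  d <- dice_loss(probs, target)
  ce <- cross_entropy_loss(probs, target)
  list(dice = d, ce = ce, total = d + ce)
}

# Gradient of the combined loss with respect to the *logits* (softmax fused
# in), for probability maps produced by softmax_predict(). Returns an array
# shaped like probs.
total_loss_grad_logits <- function(probs, target) {
  a <- check_probs_target(probs, target)
  K <- a$K; HW <- a$HW; N <- a$N
  pm <- matrix(a$probs, HW, K * N)
  tv <- as.integer(a$target)
  sd <- soft_dice_fractions(a$probs, a$target, K, HW, N)
  gp <- matrix(0, HW, K * N)   # dL/dprobs
  for (n in seq_len(N)) {
    t_n <- tv[((n - 1) * HW + 1):(n * HW)]
    for (k in seq_len(K)) {
      col <- (n - 1) * K + k
      tk <- (t_n == (k - 1L)) * 1
      # d(1 - mean frac)/dp = -(2*t*den - num) / den^2 / (K*N)
      gp[, col] <- -((2 * tk * sd$den[k, n] - sd$num[k, n]) /
                       sd$den[k, n]^2) / (K * N)
    }
    # cross entropy: -log p_true averaged over all HW*N pixels
    cols <- (n - 1) * K + t_n + 1L
    idx <- cbind(seq_len(HW), cols)
    p_true <- pmax(pm[idx], EPS_LOG)
    gp[idx] <- gp[idx] - 1 / (p_true * HW * N)
  }
  # chain through softmax: dL/dz_k = p_k * (g_k - sum_j g_j p_j)
  gz <- matrix(0, HW, K * N)
  for (n in seq_len(N)) {
    cols <- (n - 1) * K + seq_len(K)
    pb <- pm[, cols, drop = FALSE]
    gb <- gp[, cols, drop = FALSE]
    dot <- .rowSums(gb * pb, HW, K)
    gz[, cols] <- pb * (gb - dot)
  }
  array(gz, dim(a$probs))
}
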