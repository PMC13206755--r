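# Training: AdamW on the trainable parameter set, combined Dice + CE loss,
# per-epoch validation by mean foreground Dice, best-checkpoint selection.

#' Training configuration
#'
#' Defaults follow the published training recipe: AdamW with learning rate
#' 0.001, weight decay 0.001, batch size 32 and random seed 112316; the
#' published maximum epoch budget is 20,000 but the default here is a far
#' smaller 500 suited to CPU-scale experiments (the full budget remains one
#' `max_epochs = 20000` away).
#'
#' @param learning_rate AdamW step size.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum number of epochs.
#' @param seed RNG seed set before any sampling.
#' @param augmentation_strategy `"none"`, `"spatial"` or `"designed"`.
#' @param validation_interval validate every this many epochs.
#' @param early_stop_dsc optional mean-validation-DSC target; training stops
#'   once reached (the epoch budget is the other stopping rule).
#' @param checkpoint_dir directory for the best-weights checkpoint; a
#'   temporary directory by default.
#' @param verbose print per-epoch losses and validation DSC.
#' @return a `fundseg_train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0.001,
                         batch_size = 32, max_epochs = 500, seed = 112316,
                         augmentation_strategy = c("none", "spatial", "designed"),
                         validation_interval = 1, early_stop_dsc = NULL,
                         checkpoint_dir = tempfile("fundseg_ckpt_"),
                         verbose = FALSE) {
  augmentation_strategy <- match.arg(augmentation_strategy)
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, validation_interval >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 augmentation_strategy = augmentation_strategy,
                 validation_interval = as.integer(validation_interval),
                 early_stop_dsc = early_stop_dsc,
                 checkpoint_dir = checkpoint_dir, verbose = verbose),
            class = "fundseg_train_config")
}

adamw_new <- function(params, lr, wd, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0
  st$lr <- lr; st$wd <- wd; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$params <- Filter(function(p) !p$frozen, params)
  st
}

adamw_step <- function(st) {
  st$t <- st$t + 1
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (nm in names(st$params)) {
    p <- st$params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    m <- st$m[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 } else v <- st$v[[nm]]
    m <- st$beta1 * m + (1 - st$beta1) * g
    v <- st$beta2 * v + (1 - st$beta2) * g * g
    st$m[[nm]] <- m; st$v[[nm]] <- v
    p$value <- p$value -
      st$lr * ((m / bc1) / (sqrt(v / bc2) + st$eps) + st$wd * p$value)
  }
  invisible(NULL)
}

# Stack a list of [H, W, 3] images / [H, W] masks into batch arrays.
stack_samples <- function(samples) {
  H <- dim(samples[[1]]$image)[1]; W <- dim(samples[[1]]$image)[2]
  N <- length(samples)
  x <- array(0, c(H, W, 3, N))
  y <- array(0L, c(H, W, N))
  for (i in seq_len(N)) {
    x[, , , i] <- samples[[i]]$image
    y[, , i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

validation_dsc <- function(model, val_set) {
  K <- model$config$num_classes
  sizes <- vapply(val_set, function(s) dim(s$image)[1], 0L)
  per_image_dsc <- function(lab, mask) {
    mean(vapply(seq_len(K - 1), function(k)
      dsc(lab == k, mask == k), numeric(1)))
  }
  if (length(unique(sizes)) == 1L) {
    # uniform sizes: one batched forward pass
    norm <- lapply(val_set, function(s)
      list(image = zscore_normalize(s$image), mask = s$mask))
    batch <- stack_samples(norm)
    pr <- predict(model, batch$x)
    scores <- vapply(seq_along(val_set), function(i)
      per_image_dsc(pr$labels[, , i], val_set[[i]]$mask), numeric(1))
  } else {
    scores <- vapply(val_set, function(s) {
      pr <- predict(model, zscore_normalize(s$image))
      per_image_dsc(pr$labels[, , 1], s$mask)
    }, numeric(1))
  }
  mean(scores)
}

#' Fit the segmentation model
#'
#' Mini-batch AdamW training with the combined Dice + cross-entropy loss.
#' After every `validation_interval` epochs the mean foreground Dice on the
#' validation set is computed and the weights achieving the running maximum
#' are saved as the checkpoint. Deterministic for a fixed seed and data.
#'
#' @param model a `fundseg_model` (modified in place; parameters are
#'   reference objects).
#' @param train_set,val_set lists of samples, each a list with `image`
#'   (`[H, W, 3]`, normalized), `mask` (`[H, W]` integer labels) and
#'   optionally `record` (a crop record).
#' @param config a [train_config()].
#' @return a `fundseg_fit` object: `best_epoch`, `best_val_dsc`, `history`
#'   (tibble: epoch, step, train_dice, train_ce, train_total, val_dsc),
#'   `checkpoint` (path), `config`.
#' @export
fit_model <- function(model, train_set, val_set, config = train_config()) {
  if (!length(train_set)) stopf("empty training set")
  if (!length(val_set)) stopf("empty validation set")
  set.seed(config$seed)
  dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  ckpt <- file.path(config$checkpoint_dir, "best.rds")
  opt <- adamw_new(model$params, config$learning_rate, config$weight_decay)
  n <- length(train_set)
  bs <- min(config$batch_size, n)
  best_dsc <- -Inf; best_epoch <- NA_integer_
  hist <- vector("list", config$max_epochs)
  step <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_dice <- ep_ce <- 0; nb <- 0L
    for (b0 in seq(1, n, by = bs)) {
      sel <- ord[b0:min(b0 + bs - 1, n)]
      samples <- lapply(train_set[sel], function(s)
        augment_sample(s, config$augmentation_strategy))
      batch <- stack_samples(samples)
      logits <- model_forward(model, batch$x, train = TRUE,
                              input_size = dim(batch$x)[1])
      sp <- softmax_predict(logits)
      lv <- total_loss(sp$probs, batch$y)
      if (!is.finite(lv$total))
        stopf("non-finite loss (dice=%g, ce=%g) at epoch %d; aborting",
              lv$dice, lv$ce, epoch)
      gz <- total_loss_grad_logits(sp$probs, batch$y)
      zero_grads(model$params)
      model_backward(model, gz)
      adamw_step(opt)
      step <- step + 1L
      ep_dice <- ep_dice + lv$dice; ep_ce <- ep_ce + lv$ce; nb <- nb + 1L
    }
    val <- NA_real_
    if (epoch %% config$validation_interval == 0) {
      val <- validation_dsc(model, val_set)
      if (val > best_dsc) {
        best_dsc <- val; best_epoch <- epoch
        save_weights(model, ckpt)
      }
    }
    if (isTRUE(config$verbose))
      message(sprintf("epoch %d: loss %.4f (dice %.4f, ce %.4f) val DSC %.4f",
                      epoch, (ep_dice + ep_ce) / nb, ep_dice / nb,
                      ep_ce / nb, val))
    hist[[epoch]] <- c(epoch = epoch, step = step, train_dice = ep_dice / nb,
                       train_ce = ep_ce / nb,
                       train_total = (ep_dice + ep_ce) / nb, val_dsc = val)
    if (!is.null(config$early_stop_dsc) && !is.na(val) &&
        val >= config$early_stop_dsc) break
  }
  hist <- tibble::as_tibble(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  res <- structure(list(best_epoch = best_epoch, best_val_dsc = best_dsc,
                        history = hist, checkpoint = ckpt, config = config,
                        model_config = model$config),
                   class = "fundseg_fit")
  res
}

#' @method print fundseg_fit
#' @export
print.fundseg_fit <- function(x, ...) {
  cat(sprintf("<fundseg_fit> %d epochs; best val DSC %.4f at epoch %d\n",
              nrow(x$history), x$best_val_dsc, x$best_epoch))
  invisible(x)
}

write_training_log <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
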